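# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Hypergeometric upper tail by explicit combination counts.
hyper_tail_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Minimum M statistic by exhaustive cutoff enumeration with the choose-sum
# tail; ties broken toward the smallest a + b.
m_score_oracle <- function(x1, x2, direction = "group1") {
  n1 <- length(x1); n2 <- length(x2)
  cutoffs <- sort(unique(c(x1, x2)))
  eval_side <- function(elevated) {
    best <- NULL
    for (t in cutoffs) {
      a <- sum(x1 >= t); b <- sum(x2 >= t)
      p <- if (elevated == "group1")
        hyper_tail_oracle(n1 + n2, n1, a + b, a)
      else hyper_tail_oracle(n1 + n2, n2, a + b, b)
      if (is.null(best) || p < best$score * (1 - 1e-9) ||
          (p <= best$score * (1 + 1e-9) && (a + b) < (best$a + best$b)))
        best <- list(score = p, cutoff = t, a = a, b = b)
    }
    best$direction <- elevated
    best
  }
  if (direction == "both") {
    r1 <- eval_side("group1"); r2 <- eval_side("group2")
    if (r2$score < r1$score * (1 - 1e-9)) r2 else r1
  } else eval_side(direction)
}

# Brute-force recount of preselection: row-by-row, rule-by-rule.
preselect_oracle <- function(v, rules) {
  out <- character()
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (rule in rules)
      if (sum(v[i, rule$columns]) < rule$min_sum) ok <- FALSE
    if (ok) out <- c(out, rownames(v)[i])
  }
  out
}

# A small random array scan for round-trip properties.
random_scan <- function(n_spots = 20, sample_id = "S1", seed = 1) {
  set.seed(seed)
  ncols <- 5L
  data.frame(
    block = rep(1L, n_spots),
    row = ((seq_len(n_spots) - 1L) %/% ncols) + 1L,
    column = ((seq_len(n_spots) - 1L) %% ncols) + 1L,
    name = sprintf("Prot %d", seq_len(n_spots)),
    id = sprintf("ID_%04d", seq_len(n_spots)),
    f_median = as.numeric(sample(0:65535, n_spots, replace = TRUE)),
    b_median = as.numeric(sample(0:500, n_spots, replace = TRUE)),
    flags = sample(c(0L, 0L, 0L, -50L, -75L, 100L), n_spots, replace = TRUE),
    stringsAsFactors = FALSE
  ) -> spots
  array_scan(sample_id, spots, meta = c(lot = "lot1", ScanDate = "2020-01-01"))
}

# Small in-memory simulated study, collapsed and normalized — shared by the
# selection/validation tests.
small_study_matrix <- function(cfg) {
  sim <- simulate_study(cfg)
  m <- collapse_features(sim$scans)
  m <- quantile_normalize(log2_transform(m))
  list(sim = sim, m = m)
}
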