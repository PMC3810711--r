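#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` samples without
#' replacement from a population of `N` containing `K` marked members.
#' Computed in log space for numerical stability; exact for the study
#' sizes involved here (N well below 1e4).
#'
#' @param N population size.
#' @param K number of marked members (group-1 size).
#' @param n number of draws.
#' @param k observed number of marked members among the draws.
#' @return The exceedance probability, in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k))
    if (!is_count(v)) stop_fmt("hypergeometric arguments must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    stop_fmt("hypergeometric arguments out of range (N=%d, K=%d, n=%d, k=%d)",
             N, K, n, k)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' The minimum M statistic ("M score") for two groups
#'
#' A subgroup-sensitive two-group statistic: over every candidate cutoff
#' `t` among the observed intensities, count `a = #\{x1 >= t\}` and
#' `b = #\{x2 >= t\}` and evaluate the hypergeometric upper-tail
#' probability of drawing at least that many members of the elevated
#' group in `a + b` draws from the pooled samples. The score is the
#' minimum of this probability over all cutoffs — small when the high end
#' of the pooled intensity ordering is enriched for one group, even if
#' only a subgroup of that group responds.
#'
#' Scores are minima of tail probabilities, not p-values, and are not
#' adjusted for multiple testing.
#'
#' @param x1 numeric vector, group-1 intensities (>= 2 values).
#' @param x2 numeric vector, group-2 intensities (>= 2 values).
#' @param direction which group is tested as elevated: `"group1"`,
#'   `"group2"`, or `"both"` (minimum over both orientations).
#' @return A list of class `mscore` with `score`, `cutoff` (the observed
#'   intensity attaining the minimum), counts `a` and `b` at that cutoff,
#'   and `direction`. Ties across cutoffs are broken toward the smallest
#'   `a + b` (the most specific subgroup).
#' @export
m_score <- function(x1, x2, direction = c("group1", "group2", "both")) {
  direction <- match.arg(direction)
  if (length(x1) < 2L || length(x2) < 2L)
    stop_fmt("m_score needs at least 2 values per group (got %d and %d)",
             length(x1), length(x2))
  if (!all(is.finite(x1)) || !all(is.finite(x2)))
    stop_fmt("m_score requires finite intensity values")
  n1 <- length(x1); n2 <- length(x2)
  cutoffs <- sort(unique(c(x1, x2)))
  a <- colSums(outer(x1, cutoffs, ">="))
  b <- colSums(outer(x2, cutoffs, ">="))

  one_side <- function(ka, kb, K) {
    # tail prob of >= ka marked among (ka+kb) draws; log-space phyper
    p <- exp(stats::phyper(ka - 1, K, n1 + n2 - K, ka + kb,
                           lower.tail = FALSE, log.p = TRUE))
    # equal tail probabilities can differ in the last ulp across cutoffs;
    # group them with a relative tolerance so the tie-break is exact
    best <- which(p <= min(p) * (1 + 1e-9))
    # a+b strictly decreases across distinct cutoffs, so smallest a+b is unique
    pick <- best[which.min((ka + kb)[best])]
    list(score = p[[pick]], cutoff = cutoffs[[pick]],
         a = as.integer(a[[pick]]), b = as.integer(b[[pick]]))
  }

  res1 <- if (direction != "group2") one_side(a, b, n1)
  res2 <- if (direction != "group1") one_side(b, a, n2)
  # one_side always reports a/b in group1/group2 orientation
  if (direction == "both") {
    # prefer group1 on a tie (again up to ulp noise)
    if (res2$score < res1$score * (1 - 1e-9)) {
      out <- res2; out$direction <- "group2"
    } else {
      out <- res1; out$direction <- "group1"
    }
  } else if (direction == "group1") {
    out <- res1; out$direction <- "group1"
  } else {
    out <- res2; out$direction <- "group2"
  }
  out$n1 <- n1; out$n2 <- n2
  class(out) <- "mscore"
  out
}

#' @export
print.mscore <- function(x, ...) {
  cat(sprintf("M score %.4g at cutoff %.4g (a=%d/%d, b=%d/%d, elevated: %s)\n",
              x$score, x$cutoff, x$a, x$n1, x$b, x$n2, x$direction))
  invisible(x)
}

#' M-score table for one two-group comparison
#'
#' Computes the minimum M statistic for every protein of an intensity
#' matrix between two sample groups defined by a design column — the
#' clinical `group` for comparisons such as HC vs PD, or the production
#' `lot` for the lot1-vs-lot2 artifact screen.
#'
#' @param m an `intensity_matrix`.
#' @param design a `study_design` covering the matrix samples.
#' @param group_a,group_b the two labels to compare (group_a is "group1").
#' @param variable design column holding the labels: `"group"` or `"lot"`.
#' @param direction passed to [m_score()]; the convention for clinical
#'   comparisons is one-sided with the case group elevated.
#' @param comparison comparison identifier recorded in the table; default
#'   `"<group_a>vs<group_b>"`.
#' @param adjust add a Benjamini-Hochberg-adjusted column (off by
#'   default: scores are not p-values).
#' @return A data frame of class `mscore_table` with columns
#'   `protein_id`, `comparison`, `score`, `cutoff`, `a`, `b`,
#'   `direction`.
#' @export
m_score_table <- function(m, design, group_a, group_b,
                          variable = c("group", "lot"),
                          direction = c("group1", "group2", "both"),
                          comparison = NULL, adjust = FALSE) {
  stopifnot(inherits(m, "intensity_matrix"))
  variable <- match.arg(variable)
  direction <- match.arg(direction)
  design <- study_design(as.data.frame(design))
  labels <- design[[variable]][match(colnames(m$values), design$sample_id)]
  if (anyNA(labels))
    stop_fmt("design lacks rows for sample(s): %s",
             paste(colnames(m$values)[is.na(labels)], collapse = ", "))
  for (g in c(group_a, group_b))
    if (!g %in% labels)
      stop_fmt("label '%s' not present in design column '%s' (available: %s)",
               g, variable, paste(sort(unique(labels)), collapse = ", "))
  i1 <- which(labels == group_a); i2 <- which(labels == group_b)
  if (length(i1) < 2L || length(i2) < 2L)
    stop_fmt("need at least 2 samples per group")
  comparison <- comparison %||% paste0(group_a, "vs", group_b)

  res <- apply(m$values, 1L, function(row)
    unclass(m_score(row[i1], row[i2], direction = direction))[
      c("score", "cutoff", "a", "b", "direction")])
  out <- data.frame(
    protein_id = rownames(m$values),
    comparison = comparison,
    score = vapply(res, `[[`, 0, "score"),
    cutoff = vapply(res, `[[`, 0, "cutoff"),
    a = vapply(res, `[[`, 0L, "a"),
    b = vapply(res, `[[`, 0L, "b"),
    direction = vapply(res, `[[`, "", "direction"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (adjust) out$bh <- stats::p.adjust(out$score, method = "BH")
  class(out) <- c("mscore_table", "data.frame")
  out
}

#' The four standard study comparisons
#'
#' Runs HC vs PD, DC vs PD, HC vs DC and lot1 vs lot2 (or the study's own
#' label equivalents). All four are one-sided with the second label's
#' group tested as elevated — the convention of autoantibody screens,
#' where case signal means elevated binding; pass `direction = "both"`
#' to [m_score_table()] directly for a two-sided screen.
#'
#' @param m an `intensity_matrix`.
#' @param design a `study_design`.
#' @param case,control1,control2 clinical labels (defaults PD, HC, DC).
#' @param lots the two lot labels (default the design's first two).
#' @return Named list of `mscore_table`s keyed by comparison id.
#' @export
standard_comparisons <- function(m, design, case = "PD",
                                 control1 = "HC", control2 = "DC",
                                 lots = NULL) {
  design <- study_design(as.data.frame(design))
  lots <- lots %||% sort(unique(design$lot))[1:2]
  tabs <- list(
    m_score_table(m, design, control1, case, direction = "group2"),
    m_score_table(m, design, control2, case, direction = "group2"),
    m_score_table(m, design, control1, control2, direction = "group2"),
    m_score_table(m, design, lots[[1L]], lots[[2L]], variable = "lot",
                  direction = "group2")
  )
  stats::setNames(tabs, vapply(tabs, function(t) t$comparison[[1L]], ""))
}

#' Write / read an M-score table as TSV
#' @param table an `mscore_table`.
#' @param path file path.
#' @export
write_mscore_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mscore_table
#' @export
read_mscore_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("mscore_table", "data.frame")
  df
}
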