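fake_tables <- function(scores) {
  # scores: named list comparison -> numeric vector over shared proteins
  ids <- sprintf("P%03d", seq_along(scores[[1]]))
  lapply(scores, function(s) {
    df <- data.frame(protein_id = ids, comparison = "x", score = s,
                     cutoff = 1, a = 1L, b = 0L, direction = "group1",
                     stringsAsFactors = FALSE)
    class(df) <- c("mscore_table", "data.frame")
    df
  }) -> tabs
  for (nm in names(tabs)) tabs[[nm]]$comparison <- nm
  tabs
}

test_that("score votes apply the four default rules as published", {
  tabs <- fake_tables(list(
    HCvsPD = c(0.01, 0.2), DCvsPD = c(0.03, 0.01),
    HCvsDC = c(0.2, 0.01), lot1vslot2 = c(0.5, 1e-6)))
  v <- score_votes(tabs)
  # protein 1: small case scores, large control/lot scores -> all four votes
  expect_equal(unname(unclass(v)[1, ]), c(1L, 1L, 1L, 1L))
  # protein 2: lot score 1e-6 < 0.00001 -> lot vote 0 (lot-discriminating)
  expect_equal(unname(unclass(v)[2, 4]), 0L)
  expect_equal(attr(v, "kind"), rep("score", 4))
})

test_that("score-vote column sums equal a brute-force recount on random scores", {
  set.seed(31)
  for (i in 1:10) {
    sc <- replicate(4, runif(80, 1e-7, 1), simplify = FALSE)
    names(sc) <- c("HCvsPD", "DCvsPD", "HCvsDC", "lot1vslot2")
    v <- unclass(score_votes(fake_tables(sc)))
    rules <- default_score_rules(names(sc))
    for (j in 1:4) {
      s <- sc[[j]]
      want <- if (rules[[j]]$op == "<") sum(s < rules[[j]]$threshold)
              else sum(s >= rules[[j]]$threshold)
      expect_equal(sum(v[, j]), want)
    }
  }
  expect_error(score_votes(fake_tables(list(HCvsPD = runif(5))),
                           default_score_rules(c("HCvsPD", "nope", "x", "y"))),
               "nope")
})

test_that("manual vote files round-trip and reject non-binary entries", {
  v <- vote_matrix(matrix(c(1L, 0L, 1L, 1L, 1L, 0L), 3,
                          dimnames = list(paste0("P", 1:3),
                                          paste0("manual:v", 1:2))),
                   kind = c("manual", "manual"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_manual_votes(v, f)
  back <- load_manual_votes(f, expected_voters = 2)
  expect_equal(unclass(back), unclass(v))
  expect_warning(load_manual_votes(f, expected_voters = 5), "expected 5")

  lines <- readLines(f)
  lines[2] <- sub("\t1", "\t2", lines[2])
  writeLines(lines, f)
  expect_error(load_manual_votes(f), "non-binary")
})

test_that("all-ones manual votes give full row sums", {
  v <- vote_matrix(matrix(1L, 3, 5, dimnames = list(paste0("P", 1:3),
                                                    paste0("manual:v", 1:5))),
                   kind = rep("manual", 5))
  expect_equal(unname(rowSums(unclass(v))), rep(5, 3))
})

test_that("preselect is the conjunction of vote-sum rules and excludes lot hits", {
  v <- vote_matrix(rbind(P1 = c(1L, 1L, 1L, 1L),
                         P2 = c(1L, 1L, 1L, 0L),
                         P3 = c(0L, 1L, 1L, 1L)),
                   kind = rep("score", 4))
  colnames_v <- paste0("score:c", 1:4)
  dimnames(v) <- list(c("P1", "P2", "P3"), colnames_v)
  rule_all <- list(list(columns = colnames_v, min_sum = 4L))
  expect_equal(preselect(v, rule_all), "P1")  # P2: lot vote 0 -> excluded
  expect_equal(preselect(v, list(list(columns = colnames_v, min_sum = 3L))),
               c("P1", "P2", "P3"))
  expect_error(preselect(v, list(list(columns = "score:c9", min_sum = 1L))),
               "score:c9")
  expect_error(preselect(v, list(list(columns = colnames_v, min_sum = 5L))),
               "exceeds")
})

test_that("preselect and manual_select equal brute-force recounts on random votes", {
  set.seed(32)
  for (i in 1:10) {
    v <- matrix(rbinom(60 * 9, 1, 0.5), 60,
                dimnames = list(sprintf("P%03d", 1:60),
                                c(paste0("score:c", 1:4), paste0("manual:v", 1:5))))
    votes <- vote_matrix(v, kind = rep(c("score", "manual"), c(4, 5)))
    rules <- list(list(columns = paste0("score:c", 1:4), min_sum = sample(0:4, 1)),
                  list(columns = paste0("manual:v", 1:5), min_sum = sample(0:5, 1)))
    expect_equal(preselect(votes, rules), preselect_oracle(v, rules))

    pre <- preselect(votes, rules)
    thr <- sample(0:9, 1)
    got <- manual_select(votes, pre, thr)
    expect_equal(got$protein_id, pre[rowSums(v[pre, , drop = FALSE]) >= thr])
  }
})

test_that("manual_select honors thresholds and warns on impossible ones", {
  v <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L,
                1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"),
                              c(paste0("score:c", 1:4), paste0("manual:v", 1:5))))
  votes <- vote_matrix(v, kind = rep(c("score", "manual"), c(4, 5)))
  sel <- manual_select(votes, c("A", "B", "C"), 7L)
  expect_equal(sel$protein_id, c("A", "B"))  # sums 9, 7, 4
  expect_equal(manual_select(votes, c("A", "B", "C"), 0L)$protein_id,
               c("A", "B", "C"))
  expect_warning(out <- manual_select(votes, "A", 10L), "exceeds")
  expect_equal(nrow(out), 0)
  expect_error(manual_select(votes, "Z", 1L), "Z")
})

test_that("combine_panels forms the de-duplicated union with provenance", {
  manual <- biomarker_panel(sprintf("M%02d", 1:22), "manual")
  auto_ids <- c(sprintf("M%02d", 1:4), sprintf("A%02d", 1:14))  # 4 shared, 18 total
  automatic <- biomarker_panel(auto_ids, "automatic")
  final <- combine_panels(manual, automatic)
  expect_equal(nrow(final), 36)
  expect_equal(sum(final$provenance == "both"), 4)
  expect_equal(final$protein_id[1:22], manual$protein_id)  # manual first

  d1 <- biomarker_panel(c("a", "b"), "manual")
  d2 <- biomarker_panel(c("c", "d", "e"), "automatic")
  expect_equal(nrow(combine_panels(d1, d2)), 5)
  sub <- biomarker_panel("a", "automatic")
  expect_equal(nrow(combine_panels(d1, sub)), 2)  # absorption

  # idempotent and commutative up to order
  again <- combine_panels(final, final)
  expect_setequal(again$protein_id, final$protein_id)
  swapped <- combine_panels(automatic, manual)
  expect_setequal(swapped$protein_id, final$protein_id)
})

test_that("intensity plots create one collision-free file per protein", {
  set.seed(33)
  vals <- matrix(rnorm(6 * 6, 10), 6,
                 dimnames = list(c("P/1", "P 1", "B", "C", "D", "E"),
                                 paste0("S", 1:6)))
  design <- study_design(data.frame(
    sample_id = paste0("S", 1:6), group = rep(c("HC", "PD"), 3),
    lot = rep(c("lot1", "lot2"), each = 3), stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  files <- render_intensity_plots(intensity_matrix(vals), design,
                                  rownames(vals)[1:3], dir)
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_equal(anyDuplicated(files), 0)  # "P/1" vs "P 1" sanitize apart
  expect_error(render_intensity_plots(intensity_matrix(vals), design,
                                      "missing", dir), "missing")
})

test_that("panel TSV round trip preserves ids and provenance", {
  p <- biomarker_panel(c("x", "y", "z"), c("manual", "both", "automatic"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, f)
  expect_equal(read_panel(f), p)
})
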