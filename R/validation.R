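#' Collapse a multi-group design to a two-class labeling
#'
#' Builds the case-vs-rest labeling used for panel validation, e.g. PD
#' versus the combined "HC+DC" group.
#'
#' @param design a `study_design`.
#' @param positive the case label.
#' @param negatives labels pooled into the combined negative class.
#' @return Named character vector (by sample_id) with two levels: the
#'   positive label and the `+`-joined negatives. Class counts are
#'   attached as attribute `"counts"`.
#' @export
binarize_groups <- function(design, positive, negatives) {
  design <- study_design(as.data.frame(design))
  if (!length(negatives)) stop_fmt("`negatives` must name at least one group")
  if (positive %in% negatives)
    stop_fmt("positive label '%s' also listed among negatives", positive)
  unknown <- setdiff(c(positive, negatives), unique(design$group))
  if (length(unknown))
    stop_fmt("unknown group label(s): %s", paste(unknown, collapse = ", "))
  keep <- design$group %in% c(positive, negatives)
  neg_label <- paste(negatives, collapse = "+")
  labels <- ifelse(design$group[keep] == positive, positive, neg_label)
  names(labels) <- design$sample_id[keep]
  attr(labels, "counts") <- table(labels)
  labels
}

#' Specification of the repeated stratified split protocol
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 2/3).
#' @param n_subruns number of independent random splits (default 10).
#' @param seed base seed; each subrun derives its own stream from
#'   `(seed, subrun)`.
#' @export
split_spec <- function(train_fraction = 2 / 3, n_subruns = 10L, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_fmt("train_fraction must be in (0, 1)")
  if (!is_count(n_subruns) || n_subruns < 1)
    stop_fmt("n_subruns must be a positive integer")
  structure(list(train_fraction = train_fraction,
                 n_subruns = as.integer(n_subruns), seed = as.integer(seed)),
            class = "split_spec")
}

#' One stratified train/test split
#'
#' Per-class training counts follow largest-remainder rounding of
#' `train_fraction * class size`, so group proportions are conserved; the
#' split is reproducible from `(spec$seed, subrun)`.
#'
#' @param labels class label vector.
#' @param spec a [split_spec()].
#' @param subrun subrun index (1-based).
#' @return List with integer vectors `train` and `test`, a disjoint
#'   exhaustive partition of `seq_along(labels)`.
#' @export
split_stratified <- function(labels, spec = split_spec(), subrun = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop_fmt("class '%s' has fewer than 2 samples", names(which.min(tab)))
  quota <- spec$train_fraction * as.numeric(tab)
  base <- floor(quota)
  want <- round(sum(quota))
  rem <- quota - base
  extra <- integer(length(tab))
  if (want > sum(base)) {
    take <- order(rem, decreasing = TRUE)[seq_len(want - sum(base))]
    extra[take] <- 1L
  }
  n_train <- pmin(pmax(base + extra, 1L), as.numeric(tab) - 1L)
  names(n_train) <- names(tab)
  with_seed(derive_seed(spec$seed, subrun), {
    train <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      sample(idx, n_train[[cl]])
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

rf_accuracy <- function(xtr, ytr, xte, yte, trees, seed) {
  with_seed(seed, {
    rf <- randomForest::randomForest(xtr, ytr, ntree = trees)
    list(
      resub = 100 * mean(stats::predict(rf, xtr) == ytr),
      oob = 100 * mean(rf$predicted == ytr),
      test = 100 * mean(stats::predict(rf, xte) == yte)
    )
  })
}

new_validation_report <- function(strategy, subruns, panels, config) {
  structure(list(strategy = strategy, subruns = subruns,
                 panels = panels, config = config),
            class = "validation_report")
}

#' Validate a fixed biomarker panel on repeated splits
#'
#' For each subrun: split the samples stratified by class, train a random
#' forest on the panel's features in the training set, and record the
#' training accuracy (both resubstitution and out-of-bag) and the
#' independent test-set accuracy. The panel is fixed in advance, so its
#' own selection optimism (if it was selected on all data) is *not*
#' corrected here — this mirrors how fixed candidate panels are commonly
#' validated, and is flagged in the documentation.
#'
#' @param m an `intensity_matrix`.
#' @param labels two-class (or multiclass) label vector named by
#'   sample_id, e.g. from [binarize_groups()].
#' @param panel a `biomarker_panel` (or character vector of ids).
#' @param spec a [split_spec()].
#' @param trees random-forest tree count (default 500).
#' @return A `validation_report`.
#' @export
validate_fixed_panel <- function(m, labels, panel, spec = split_spec(),
                                 trees = 500L) {
  stopifnot(inherits(m, "intensity_matrix"))
  ids <- if (inherits(panel, "biomarker_panel")) panel$protein_id else as.character(panel)
  if (!length(ids)) stop_fmt("panel is empty")
  missing <- setdiff(ids, rownames(m$values))
  if (length(missing))
    stop_fmt("panel id(s) absent from matrix: %s", paste(missing, collapse = ", "))
  samples <- names(labels)
  x <- t(m$values[ids, samples, drop = FALSE])
  y <- factor(as.character(labels))
  rows <- lapply(seq_len(spec$n_subruns), function(s) {
    sp <- split_stratified(y, spec, s)
    acc <- rf_accuracy(x[sp$train, , drop = FALSE], y[sp$train],
                       x[sp$test, , drop = FALSE], y[sp$test],
                       trees, derive_seed(spec$seed, 100000L + s))
    data.frame(subrun = s, train_resub = acc$resub, train_oob = acc$oob,
               test = acc$test)
  })
  new_validation_report("hybrid", do.call(rbind, rows), panels = NULL,
                        config = list(panel = ids, trees = trees, spec = spec))
}

#' Validate per-split top-k M-score selection ("M score only")
#'
#' The default-workflow baseline: in each subrun the k proteins with the
#' smallest M scores *computed on the training split only* are selected,
#' a random forest is trained on them, and the test split is classified.
#' Selection never sees test data; the overfitting this strategy shows on
#' weak-signal data comes from the selection itself chasing the training
#' split.
#'
#' @param m an `intensity_matrix`.
#' @param labels two-class label vector named by sample_id; the first
#'   element of `positive` is the class treated as elevated.
#' @param positive label of the elevated (case) class.
#' @param k panel size selected per split (default 36).
#' @param spec a [split_spec()].
#' @param trees random-forest tree count.
#' @return A `validation_report`; `$panels` stores each subrun's selected
#'   protein ids.
#' @export
validate_mscore_only <- function(m, labels, positive, k = 36L,
                                 spec = split_spec(), trees = 500L) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!is_count(k) || k < 1) stop_fmt("k must be a positive integer")
  if (k > nrow(m$values))
    stop_fmt("k = %d exceeds the %d proteins available", k, nrow(m$values))
  samples <- names(labels)
  vals <- m$values[, samples, drop = FALSE]
  y <- factor(as.character(labels))
  pos <- as.character(labels) == positive
  if (!any(pos)) stop_fmt("positive label '%s' not present", positive)
  rows <- list(); panels <- list()
  for (s in seq_len(spec$n_subruns)) {
    sp <- split_stratified(y, spec, s)
    tr_pos <- intersect(sp$train, which(pos))
    tr_neg <- setdiff(sp$train, tr_pos)
    scores <- apply(vals, 1L, function(row)
      m_score(row[tr_pos], row[tr_neg], direction = "group1")$score)
    sel <- order(scores)[seq_len(k)]  # ties broken by protein order
    panel_ids <- rownames(vals)[sort(sel)]
    x <- t(vals[panel_ids, , drop = FALSE])
    acc <- rf_accuracy(x[sp$train, , drop = FALSE], y[sp$train],
                       x[sp$test, , drop = FALSE], y[sp$test],
                       trees, derive_seed(spec$seed, 100000L + s))
    rows[[s]] <- data.frame(subrun = s, train_resub = acc$resub,
                            train_oob = acc$oob, test = acc$test)
    panels[[s]] <- panel_ids
  }
  new_validation_report("mscore_only", do.call(rbind, rows), panels = panels,
                        config = list(k = k, positive = positive,
                                      trees = trees, spec = spec))
}

#' Round an average accuracy the way the summary table prints it
#'
#' Half-up to one decimal; a mean that falls exactly on the midpoint of
#' the first decimal (x.y5) is printed exactly at two decimals instead of
#' being rounded away.
#'
#' @param x numeric value (percent).
#' @export
round_accuracy <- function(x) {
  cents <- x * 100
  if (abs(cents - round(cents)) < 1e-9 && round(cents) %% 10 == 5)
    round(cents) / 100
  else floor(x * 10 + 0.5) / 10
}

#' Subrun-accuracy table with averages
#'
#' Builds the per-subrun accuracy table with a final `"Average"` row, the
#' layout used to report repeated-split validation: one row per subrun
#' plus the arithmetic mean of each column, rounded per
#' [round_accuracy()].
#'
#' @param columns named list of equal-length numeric vectors (accuracy
#'   percentages per subrun).
#' @return A data frame with a `subrun` column (`1..n`, `"Average"`).
#' @export
summarize_accuracies <- function(columns) {
  stopifnot(length(columns) >= 1L)
  n <- length(columns[[1L]])
  for (col in columns) stopifnot(length(col) == n)
  avg <- vapply(columns, function(col) round_accuracy(mean(col)), 0)
  out <- data.frame(subrun = c(as.character(seq_len(n)), "Average"),
                    stringsAsFactors = FALSE)
  for (nm in names(columns)) out[[nm]] <- c(columns[[nm]], avg[[nm]])
  out
}

#' Summarize a validation report
#'
#' @param object a `validation_report`.
#' @param train which training accuracy to tabulate:
#'   `"resubstitution"` (comparable with per-split selection baselines)
#'   or `"oob"`; both are stored in the report.
#' @param ... unused.
#' @return A data frame of per-subrun train/test accuracies plus the
#'   `"Average"` row.
#' @export
summary.validation_report <- function(object, train = c("resubstitution", "oob"),
                                      ...) {
  train <- match.arg(train)
  col <- if (train == "resubstitution") "train_resub" else "train_oob"
  summarize_accuracies(list(train = object$subruns[[col]],
                            test = object$subruns$test))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: strategy '%s', %d subruns\n",
              x$strategy, nrow(x$subruns)))
  print(summary(x))
  invisible(x)
}

#' Mean accuracies of a validation report
#' @param report a `validation_report`.
#' @export
mean_accuracies <- function(report) {
  c(train_resub = mean(report$subruns$train_resub),
    train_oob = mean(report$subruns$train_oob),
    test = mean(report$subruns$test))
}
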