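#' Default score-voting rules
#'
#' The study's published convention: a protein earns a vote for a small
#' score in each case comparison (`< 0.05` for HCvsPD and DCvsPD), for a
#' *large* score in the control-vs-control comparison (`>= 0.05` for
#' HCvsDC — proteins separating the two control groups are suspect), and
#' for a large score in the production-lot screen (`>= 0.00001` for
#' lot1vslot2 — lot-discriminating features are manufacturing artifacts
#' and must be excluded).
#'
#' @param comparisons character vector of the four comparison ids, in the
#'   order case-vs-control1, case-vs-control2, control-vs-control, lot.
#' @return A list of rules, each `list(comparison, op, threshold)`.
#' @export
default_score_rules <- function(comparisons = c("HCvsPD", "DCvsPD",
                                                "HCvsDC", "lot1vslot2")) {
  list(
    list(comparison = comparisons[[1L]], op = "<",  threshold = 0.05),
    list(comparison = comparisons[[2L]], op = "<",  threshold = 0.05),
    list(comparison = comparisons[[3L]], op = ">=", threshold = 0.05),
    list(comparison = comparisons[[4L]], op = ">=", threshold = 0.00001)
  )
}

check_rule <- function(rule) {
  if (is.null(rule$comparison) || is.null(rule$op) || is.null(rule$threshold))
    stop_fmt("score-vote rule needs fields comparison, op, threshold")
  if (!rule$op %in% c("<", ">="))
    stop_fmt("score-vote operator must be '<' or '>=' (got '%s')", rule$op)
  if (rule$threshold <= 0 || rule$threshold > 1)
    stop_fmt("score-vote threshold must be in (0, 1]")
  rule
}

#' Score votes from M-score tables
#'
#' Applies each rule to its comparison's scores and records a binary
#' vote per protein: 1 if the score satisfies the rule's operator and
#' threshold, 0 otherwise.
#'
#' @param tables named list of `mscore_table`s keyed by comparison id,
#'   all over the same protein universe.
#' @param rules list of rules as returned by [default_score_rules()].
#' @return A binary `vote_matrix` (proteins x vote columns) with a
#'   `"kind"` attribute (`"score"` per column).
#' @export
score_votes <- function(tables, rules = default_score_rules(names(tables))) {
  rules <- lapply(rules, check_rule)
  ids <- tables[[1L]]$protein_id
  cols <- lapply(rules, function(rule) {
    tab <- tables[[rule$comparison]]
    if (is.null(tab))
      stop_fmt("no M-score table for comparison '%s'", rule$comparison)
    if (!identical(tab$protein_id, ids))
      stop_fmt("M-score tables do not share one protein universe")
    if (rule$op == "<") as.integer(tab$score < rule$threshold)
    else as.integer(tab$score >= rule$threshold)
  })
  v <- do.call(cbind, cols)
  dimnames(v) <- list(ids, vapply(rules, function(r)
    sprintf("score:%s%s%g", r$comparison, r$op, r$threshold), ""))
  vote_matrix(v, kind = rep("score", ncol(v)))
}

#' Construct a vote matrix
#'
#' @param v integer matrix of 0/1 votes, proteins x columns, dimnames set.
#' @param kind per-column vote kind, `"score"` or `"manual"`.
#' @export
vote_matrix <- function(v, kind) {
  if (!all(v %in% c(0L, 1L))) stop_fmt("vote entries must be 0 or 1")
  if (anyDuplicated(colnames(v))) stop_fmt("vote column ids must be unique")
  if (length(kind) != ncol(v)) stop_fmt("one kind per vote column required")
  storage.mode(v) <- "integer"
  structure(v, kind = kind, class = c("vote_matrix", class(matrix())))
}

#' Combine vote matrices over the same proteins
#' @param ... `vote_matrix` objects with identical row names.
#' @export
combine_votes <- function(...) {
  ms <- list(...)
  ids <- rownames(ms[[1L]])
  for (m in ms[-1L])
    if (!identical(rownames(m), ids))
      stop_fmt("vote matrices do not share one protein universe")
  vote_matrix(do.call(cbind, lapply(ms, unclass)),
              kind = unlist(lapply(ms, attr, "kind")))
}

#' Load manual votes from TSV
#'
#' Expects a header `protein_id` plus one column per voter; entries must
#' be 0 or 1 (each voter's judgement that the protein's intensity plot
#' looks differential).
#'
#' @param path TSV path.
#' @param expected_voters if given, warn when the voter count differs.
#' @return A `vote_matrix` with `kind = "manual"`.
#' @export
load_manual_votes <- function(path, expected_voters = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[[1L]] != "protein_id")
    stop_fmt("manual vote file must start with a protein_id column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(vals == 0 | vals == 1), arr.ind = TRUE)
  if (nrow(bad))
    stop_fmt("non-binary vote '%s' at protein '%s', voter '%s'",
             vals[bad[1L, , drop = FALSE]], df$protein_id[bad[1L, 1L]],
             colnames(vals)[bad[1L, 2L]])
  if (!is.null(expected_voters) && ncol(vals) != expected_voters)
    warning(sprintf("expected %d voters, found %d", expected_voters, ncol(vals)),
            call. = FALSE)
  rownames(vals) <- df$protein_id
  colnames(vals) <- paste0("manual:", colnames(vals))
  vote_matrix(vals, kind = rep("manual", ncol(vals)))
}

#' Write a manual-vote matrix as TSV
#' @param votes a `vote_matrix` of kind `"manual"`.
#' @param path output path.
#' @export
write_manual_votes <- function(votes, path) {
  v <- unclass(votes)
  df <- data.frame(protein_id = rownames(v), v, check.names = FALSE)
  names(df)[-1] <- sub("^manual:", "", names(df)[-1])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-protein intensity plots for manual voting
#'
#' One image per protein: a per-sample stripchart of intensity grouped by
#' clinical group, with the point symbol encoding the production lot, the
#' layout a human rater inspects when voting a protein differential.
#'
#' @param m an `intensity_matrix`.
#' @param design a `study_design`.
#' @param proteins protein ids to plot.
#' @param outdir output directory (created if needed).
#' @param width,height device size in pixels.
#' @return Invisibly, the vector of created file paths.
#' @export
render_intensity_plots <- function(m, design, proteins, outdir,
                                   width = 640, height = 480) {
  stopifnot(inherits(m, "intensity_matrix"))
  design <- study_design(as.data.frame(design))
  missing <- setdiff(proteins, rownames(m$values))
  if (length(missing))
    stop_fmt("unknown protein id(s): %s", paste(missing, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grp <- factor(design$group[match(colnames(m$values), design$sample_id)])
  lot <- factor(design$lot[match(colnames(m$values), design$sample_id)])
  safe <- gsub("[^A-Za-z0-9._-]", "_", proteins)
  # guarantee collision-free names even after sanitization
  files <- file.path(outdir, sprintf("%s_%04d.png", safe, seq_along(proteins)))
  for (i in seq_along(proteins)) {
    grDevices::png(files[[i]], width = width, height = height)
    y <- m$values[proteins[[i]], ]
    # deterministic horizontal spread: within-group index, not jitter
    off <- stats::ave(seq_along(y), grp, FUN = function(ii)
      (seq_along(ii) - (length(ii) + 1) / 2) / (length(ii) + 1) * 0.6)
    graphics::plot(as.integer(grp) + off, y, pch = as.integer(lot),
                   xaxt = "n", xlim = c(0.5, nlevels(grp) + 0.5),
                   main = proteins[[i]], ylab = "intensity",
                   xlab = "clinical group")
    graphics::axis(1, at = seq_len(nlevels(grp)), labels = levels(grp))
    graphics::legend("topright", legend = levels(lot), pch = seq_along(levels(lot)),
                     title = "lot", bty = "n")
    grDevices::dev.off()
  }
  invisible(files)
}

#' Preselect proteins by conjunctive vote-sum rules
#'
#' A protein is preselected when it satisfies *every* rule: for each rule,
#' the sum of its votes over the rule's columns reaches `min_sum`. With
#' the default score rules this keeps proteins that discriminate the case
#' group from both control groups while discarding proteins that separate
#' the control groups or the production lots.
#'
#' @param votes a `vote_matrix`.
#' @param rules list of `list(columns, min_sum)`; `columns` may be column
#'   names or a kind (`"score"`/`"manual"`) to select all columns of that
#'   kind.
#' @return Character vector of preselected protein ids, in input order.
#' @export
preselect <- function(votes, rules) {
  v <- unclass(votes)
  kind <- attr(votes, "kind")
  keep <- rep(TRUE, nrow(v))
  for (rule in rules) {
    cols <- rule$columns
    if (length(cols) == 1L && cols %in% c("score", "manual"))
      cols <- colnames(v)[kind == cols]
    unknown <- setdiff(cols, colnames(v))
    if (length(unknown))
      stop_fmt("unknown vote column(s): %s", paste(unknown, collapse = ", "))
    if (rule$min_sum > length(cols))
      stop_fmt("min_sum %d exceeds the %d rule column(s)", rule$min_sum, length(cols))
    keep <- keep & rowSums(v[, cols, drop = FALSE]) >= rule$min_sum
  }
  rownames(v)[keep]
}

#' Manual selection by overall vote-sum threshold
#'
#' Narrows the preselected list to proteins whose total vote sum (score
#' votes + manual votes) reaches `overall_min_sum`.
#'
#' @param votes a `vote_matrix` holding all vote columns.
#' @param preselected preselected protein ids (subset of the vote rows).
#' @param overall_min_sum required total vote sum.
#' @return A `biomarker_panel` with provenance `"manual"`.
#' @export
manual_select <- function(votes, preselected, overall_min_sum) {
  v <- unclass(votes)
  missing <- setdiff(preselected, rownames(v))
  if (length(missing))
    stop_fmt("preselected id(s) absent from vote matrix: %s",
             paste(missing, collapse = ", "))
  if (overall_min_sum > ncol(v))
    warning(sprintf("threshold %d exceeds the %d vote columns; empty panel",
                    overall_min_sum, ncol(v)), call. = FALSE)
  sums <- rowSums(v[preselected, , drop = FALSE])
  biomarker_panel(preselected[sums >= overall_min_sum], "manual")
}

#' Construct a biomarker panel
#'
#' @param ids protein ids (unique, ordered).
#' @param provenance single value or per-id vector: `"manual"`,
#'   `"automatic"` or `"both"`.
#' @export
biomarker_panel <- function(ids, provenance) {
  if (anyDuplicated(ids)) stop_fmt("panel ids must be unique")
  structure(data.frame(protein_id = as.character(ids),
                       provenance = rep_len(provenance, length(ids)),
                       stringsAsFactors = FALSE),
            class = c("biomarker_panel", "data.frame"))
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel: %d proteins (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$provenance)),
                            as.integer(table(x$provenance))), collapse = ", ")))
  invisible(x)
}

#' Combine manual and automatic panels
#'
#' De-duplicated union, manual panel first; proteins found by both routes
#' get provenance `"both"`.
#'
#' @param manual,automatic `biomarker_panel` objects.
#' @return The final `biomarker_panel`.
#' @export
combine_panels <- function(manual, automatic) {
  shared <- intersect(manual$protein_id, automatic$protein_id)
  ids <- c(manual$protein_id, setdiff(automatic$protein_id, manual$protein_id))
  prov <- ifelse(ids %in% shared, "both",
                 ifelse(ids %in% manual$protein_id, "manual", "automatic"))
  biomarker_panel(ids, prov)
}

#' Write / read a biomarker panel as TSV (with provenance column)
#' @param panel a `biomarker_panel`.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  biomarker_panel(df$protein_id, df$provenance %||% "manual")
}
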