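#' Configuration of a simulated protein-microarray study
#'
#' Emulates a multi-group, multi-lot single-channel protein-array study:
#' proteins spotted in duplicate plus control features, log-normal
#' background, multiplicative production-lot effects on a feature subset,
#' and "subgroup-responder" markers — true case markers elevated in only
#' a random fraction of case samples, the regime the minimum M statistic
#' is designed for.
#'
#' Defaults mirror a large discovery study: three clinical groups of 72
#' samples (cases `PD`, healthy controls `HC`, disease controls `DC`)
#' balanced over two production lots, 4652 non-control proteins plus 100
#' controls spotted in duplicate (9504 spots per array).
#'
#' @param n_proteins non-control proteins.
#' @param n_controls control features (names match the default control
#'   patterns).
#' @param duplicate_spots spots per feature (default 2).
#' @param group_sizes named vector of samples per clinical group.
#' @param case_group the group carrying the planted markers.
#' @param lots lot labels (default `lot1`, `lot2`).
#' @param lot_assignment `"balanced"` (groups distributed equally over
#'   lots) or `"confounded"` (cases all in the first lot, everyone else
#'   in the second — the criticized design).
#' @param n_days processing days, rotated over samples.
#' @param n_markers planted true case markers.
#' @param marker_effect log2 intensity shift added for responders.
#' @param responder_fraction fraction of case samples elevated per marker.
#' @param n_lot_features proteins with a production-lot artifact.
#' @param lot_effect log2 shift added to all samples of the second lot
#'   for lot features.
#' @param background_mean,background_sd log2 location/scale of baseline
#'   protein intensities.
#' @param sample_sd per-sample biological/technical noise (log2).
#' @param array_scale_sd per-array global scale jitter (log2).
#' @param duplicate_cv multiplicative replicate noise between duplicate
#'   spots.
#' @param flag_rate fraction of spots flagged bad.
#' @param seed RNG seed.
#' @export
sim_config <- function(n_proteins = 4652L, n_controls = 100L,
                       duplicate_spots = 2L,
                       group_sizes = c(HC = 72L, PD = 72L, DC = 72L),
                       case_group = "PD",
                       lots = c("lot1", "lot2"),
                       lot_assignment = c("balanced", "confounded"),
                       n_days = 8L,
                       n_markers = 36L, marker_effect = 1.5,
                       responder_fraction = 0.5,
                       n_lot_features = 50L, lot_effect = 1.0,
                       background_mean = 10, background_sd = 1,
                       sample_sd = 0.5, array_scale_sd = 0,
                       duplicate_cv = 0.1, flag_rate = 0.01,
                       seed = 1L) {
  lot_assignment <- match.arg(lot_assignment)
  if (n_markers + n_lot_features > n_proteins)
    stop_fmt("n_markers + n_lot_features exceeds n_proteins")
  if (responder_fraction < 0 || responder_fraction > 1 ||
      flag_rate < 0 || flag_rate > 1)
    stop_fmt("fractions must be in [0, 1]")
  if (lot_assignment == "confounded" && length(lots) < 2L)
    stop_fmt("confounded lot assignment needs at least 2 lots")
  if (!case_group %in% names(group_sizes))
    stop_fmt("case_group '%s' not among group_sizes", case_group)
  structure(as.list(environment()), class = "sim_config")
}

sim_sample_ids <- function(cfg) {
  unlist(lapply(names(cfg$group_sizes), function(g)
    sprintf("%s_%03d", g, seq_len(cfg$group_sizes[[g]]))), use.names = FALSE)
}

#' Study designs for a simulated study
#'
#' `balanced_design()` distributes each clinical group equally over the
#' production lots (the recommended setup); `confounded_design()`
#' reproduces the criticized design in which every case is processed with
#' one lot and every control with another, so lot artifacts masquerade as
#' disease markers.
#'
#' @param cfg a [sim_config()].
#' @return A `study_design`.
#' @export
balanced_design <- function(cfg) sim_design(cfg, "balanced")

#' @rdname balanced_design
#' @export
confounded_design <- function(cfg) sim_design(cfg, "confounded")

sim_design <- function(cfg, policy) {
  ids <- sim_sample_ids(cfg)
  group <- rep(names(cfg$group_sizes), cfg$group_sizes)
  lot <- if (policy == "confounded") {
    ifelse(group == cfg$case_group, cfg$lots[[1L]], cfg$lots[[2L]])
  } else {
    # rotate lots within each group: equal distribution
    unlist(lapply(cfg$group_sizes, function(n)
      rep_len(cfg$lots, n)), use.names = FALSE)
  }
  day <- paste0("day", rep_len(seq_len(cfg$n_days), length(ids)))
  study_design(data.frame(sample_id = ids, group = group, lot = lot, day = day,
                          stringsAsFactors = FALSE))
}

sim_layout <- function(cfg) {
  prot_ids <- sprintf("PROT_%05d", seq_len(cfg$n_proteins))
  ctrl_ids <- sprintf("CTRL_%03d", seq_len(cfg$n_controls))
  ids <- rep(c(prot_ids, ctrl_ids), each = cfg$duplicate_spots)
  names_ <- rep(c(prot_ids, paste0("Control-", seq_len(cfg$n_controls))),
                each = cfg$duplicate_spots)
  n_spots <- length(ids)
  ncol_grid <- 24L
  data.frame(
    block = ((seq_len(n_spots) - 1L) %/% 192L) + 1L,
    row = (((seq_len(n_spots) - 1L) %% 192L) %/% ncol_grid) + 1L,
    column = ((seq_len(n_spots) - 1L) %% ncol_grid) + 1L,
    name = names_, id = ids, stringsAsFactors = FALSE
  )
}

#' Simulate a complete study with known ground truth
#'
#' Generates per-sample arrays from the model in [sim_config()]: baseline
#' log2 intensity per protein, per-sample noise, marker shifts for a
#' random responder subset of case samples, additive log-scale lot shifts
#' for lot features, duplicate spots with multiplicative replicate noise,
#' and a random fraction of flagged-bad spots. Fully seed-reproducible.
#'
#' @param cfg a [sim_config()].
#' @param dir if non-`NULL`, write one gpr file per sample (plus
#'   `design.tsv` and `truth.tsv`) into this directory.
#' @param design optional `study_design` overriding the policy-derived
#'   one (must cover the same sample ids).
#' @return List with `scans` (named list of `array_scan`), `design`, and
#'   `truth` — a data frame of `protein_id`, `role`
#'   (`marker`/`lot_feature`/`null`) and comma-separated responder
#'   sample ids for markers.
#' @export
simulate_study <- function(cfg, dir = NULL, design = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- design %||% sim_design(cfg, cfg$lot_assignment)
  layout <- sim_layout(cfg)
  prot_ids <- sprintf("PROT_%05d", seq_len(cfg$n_proteins))

  with_seed(cfg$seed, {
    marker_ids <- if (cfg$n_markers) sample(prot_ids, cfg$n_markers) else character()
    lot_ids <- if (cfg$n_lot_features)
      sample(setdiff(prot_ids, marker_ids), cfg$n_lot_features) else character()
    baseline <- stats::rnorm(cfg$n_proteins, cfg$background_mean, cfg$background_sd)
    names(baseline) <- prot_ids
    ctrl_baseline <- stats::rnorm(cfg$n_controls, cfg$background_mean,
                                  cfg$background_sd)
    case_ids <- design$sample_id[design$group == cfg$case_group]
    n_resp <- max(1L, round(cfg$responder_fraction * length(case_ids)))
    responders <- stats::setNames(
      lapply(marker_ids, function(p) sort(sample(case_ids, n_resp))), marker_ids)

    lot2_samples <- design$sample_id[design$lot == cfg$lots[[min(2L, length(cfg$lots))]]]
    spot_is_prot <- layout$id %in% prot_ids
    prot_idx <- match(layout$id, prot_ids)

    scans <- vector("list", nrow(design))
    for (si in seq_len(nrow(design))) {
      sid <- design$sample_id[[si]]
      logint <- c(baseline, stats::setNames(ctrl_baseline,
                                            sprintf("CTRL_%03d", seq_len(cfg$n_controls))))
      logint[prot_ids] <- logint[prot_ids] +
        stats::rnorm(cfg$n_proteins, 0, cfg$sample_sd)
      if (cfg$array_scale_sd > 0)
        logint <- logint + stats::rnorm(1, 0, cfg$array_scale_sd)
      for (p in marker_ids)
        if (sid %in% responders[[p]]) logint[[p]] <- logint[[p]] + cfg$marker_effect
      if (sid %in% lot2_samples)
        logint[lot_ids] <- logint[lot_ids] + cfg$lot_effect
      spot_log <- logint[layout$id]
      mult <- exp(stats::rnorm(length(spot_log), 0, cfg$duplicate_cv))
      b <- round(2^6 * exp(stats::rnorm(length(spot_log), 0, 0.2)))
      f <- round(2^spot_log * mult) + b
      flags <- ifelse(stats::runif(length(spot_log)) < cfg$flag_rate, -50L, 0L)
      spots <- data.frame(block = layout$block, row = layout$row,
                          column = layout$column, name = layout$name,
                          id = layout$id, f_median = f, b_median = b,
                          flags = flags, stringsAsFactors = FALSE)
      scans[[si]] <- array_scan(sid, spots,
                                meta = c(lot = design$lot[[si]],
                                         group = design$group[[si]]))
    }
    names(scans) <- design$sample_id

    role <- rep("null", cfg$n_proteins)
    role[prot_ids %in% marker_ids] <- "marker"
    role[prot_ids %in% lot_ids] <- "lot_feature"
    truth <- data.frame(
      protein_id = prot_ids, role = role,
      responders = vapply(prot_ids, function(p)
        if (p %in% marker_ids) paste(responders[[p]], collapse = ",") else "",
        ""),
      row.names = NULL, stringsAsFactors = FALSE
    )

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (s in scans) write_gpr(s, file.path(dir, paste0(s$sample_id, ".gpr")))
      write_design(design, file.path(dir, "design.tsv"))
      utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(scans = scans, design = design, truth = truth)
  })
}

#' Simulated manual votes
#'
#' Surrogate for human raters: each voter independently votes 1 on a true
#' marker with probability `sensitivity` and 1 on any other protein with
#' probability `1 - specificity`.
#'
#' @param truth ground-truth table from [simulate_study()].
#' @param proteins protein ids to vote on (e.g. the preselected list).
#' @param n_voters number of raters (default 5).
#' @param sensitivity,specificity rater operating point.
#' @param seed RNG seed.
#' @param path if non-`NULL`, also write a TSV loadable by
#'   [load_manual_votes()].
#' @return A `vote_matrix` with `kind = "manual"`.
#' @export
simulate_votes <- function(truth, proteins, n_voters = 5L,
                           sensitivity = 0.9, specificity = 0.9,
                           seed = 1L, path = NULL) {
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1))
    stop_fmt("sensitivity and specificity must be in [0, 1]")
  is_marker <- proteins %in% truth$protein_id[truth$role == "marker"]
  p1 <- ifelse(is_marker, sensitivity, 1 - specificity)
  v <- with_seed(seed, {
    matrix(as.integer(stats::runif(length(proteins) * n_voters) <
                        rep(p1, n_voters)),
           nrow = length(proteins),
           dimnames = list(proteins, paste0("manual:voter", seq_len(n_voters))))
  })
  votes <- vote_matrix(v, kind = rep("manual", n_voters))
  if (!is.null(path)) write_manual_votes(votes, path)
  votes
}
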