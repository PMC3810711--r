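#' Default preselection rules
#'
#' A single conjunctive rule requiring every score vote: the protein must
#' discriminate the case group from both control groups, must *not*
#' separate the two control groups, and must not be lot-discriminating.
#'
#' @param votes a `vote_matrix` (used to name the score columns).
#' @export
default_preselect_rules <- function(votes) {
  cols <- colnames(votes)[attr(votes, "kind") == "score"]
  list(list(columns = cols, min_sum = length(cols)))
}

#' The hybrid feature-selection scheme, end to end
#'
#' Runs the full candidate-selection cascade on an assembled, normalized
#' matrix: the four standard two-group M-score comparisons, score voting,
#' combination with manual votes, conjunctive preselection, manual
#' selection by overall vote sum, evolutionary-wrapper automatic
#' selection over the preselected proteins, and the union of the manual
#' and automatic panels.
#'
#' @param m a normalized `intensity_matrix`.
#' @param design a `study_design`.
#' @param manual_votes a `vote_matrix` of kind `"manual"` over the same
#'   proteins (e.g. from [load_manual_votes()] or [simulate_votes()]).
#' @param case,control1,control2 clinical group labels.
#' @param score_rules score-voting rules; default
#'   [default_score_rules()] over the four standard comparisons.
#' @param preselect_rules preselection rules; default
#'   [default_preselect_rules()].
#' @param overall_min_sum manual-selection overall vote-sum threshold
#'   (default: all score columns plus a majority of manual votes).
#' @param ea an [ea_config()]; `NULL` skips automatic selection.
#' @return List with `tables`, `votes`, `preselected`, `manual_panel`,
#'   `automatic_panel` and `final_panel`.
#' @export
hybrid_selection <- function(m, design, manual_votes,
                             case = "PD", control1 = "HC", control2 = "DC",
                             score_rules = NULL, preselect_rules = NULL,
                             overall_min_sum = NULL, ea = ea_config()) {
  tables <- standard_comparisons(m, design, case = case,
                                 control1 = control1, control2 = control2)
  sv <- score_votes(tables, score_rules %||% default_score_rules(names(tables)))
  votes <- combine_votes(sv, manual_votes)
  rules <- preselect_rules %||% default_preselect_rules(votes)
  preselected <- preselect(votes, rules)
  n_manual <- sum(attr(votes, "kind") == "manual")
  overall_min_sum <- overall_min_sum %||%
    (ncol(sv) + ceiling(n_manual / 2) + 1L)
  manual_panel <- manual_select(votes, preselected, overall_min_sum)
  automatic_panel <- if (!is.null(ea) && length(preselected) > 1L)
    ea_wrapper_select(m, design, ea, proteins = preselected)
  else biomarker_panel(character(), character(0))
  list(tables = tables, votes = votes, preselected = preselected,
       manual_panel = manual_panel, automatic_panel = automatic_panel,
       final_panel = combine_panels(manual_panel, automatic_panel))
}
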