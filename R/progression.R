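#' Bin a biomarker's first-change time into a familial-disease stage
#'
#' In autosomal dominant (familial) Alzheimer's disease the clinical onset
#' age is predictable, so biomarker trajectories can be expressed in years
#' relative to onset (negative = before onset). The first moment a marker
#' departs from normal is binned into four stages:
#' Early (25+ years before onset), Mid (25-5 years before onset),
#' Onset (5 years before to 5 years after onset), Late (5+ years after).
#'
#' Boundary convention (the prose bins overlap at -25, -5 and +5):
#' `Early` is `t <= -25`, `Mid` is `-25 < t < -5`, `Onset` is
#' `-5 <= t <= 5`, `Late` is `t > 5`. The bins partition the real line. The
#' cut points are configurable.
#'
#' @param first_change_years Finite numeric vector, years relative to
#'   clinical onset.
#' @param early_cut,onset_lo,onset_hi Stage boundaries (defaults -25, -5, 5).
#' @return Character vector of stages (`"Early"`, `"Mid"`, `"Onset"`,
#'   `"Late"`).
#' @examples
#' assign_stage(c(-30, 0, 10))  # Early, Onset, Late
#' @export
assign_stage <- function(first_change_years, early_cut = -25,
                         onset_lo = -5, onset_hi = 5) {
  if (any(!is.finite(first_change_years)))
    stop("first_change_years must be finite", call. = FALSE)
  stopifnot(early_cut < onset_lo, onset_lo <= onset_hi)
  ifelse(first_change_years <= early_cut, "Early",
         ifelse(first_change_years < onset_lo, "Mid",
                ifelse(first_change_years <= onset_hi, "Onset", "Late")))
}

#' Read a stage table (symbol, first_change_years, direction)
#'
#' @param path TSV with columns `symbol`, `first_change_years`, `direction`
#'   (`"up"`/`"down"`).
#' @return Data frame with an added `stage` column via [assign_stage()].
#' @export
read_stage_table <- function(path) {
  tab <- utils::read.delim(path, sep = infer_delim(path), header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("symbol", "first_change_years", "direction")
  absent <- setdiff(need, names(tab))
  if (length(absent))
    stop("stage table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  tab$symbol <- harmonize_protein_id(tab$symbol)
  tab$direction <- tolower(tab$direction)
  if (!all(tab$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'", call. = FALSE)
  tab$stage <- assign_stage(tab$first_change_years)
  tab
}

#' Agreement between staged trajectory directions and cross-study consistency
#'
#' Matches a familial-disease stage table against direction-consistency calls
#' from the cross-study compilation and reports, per matched symbol, whether
#' the trajectory direction (up/down) agrees with the consistent direction of
#' change.
#'
#' @param stage_table Data frame from [read_stage_table()] (columns `symbol`,
#'   `direction`, optionally `stage`).
#' @param consistency Data frame from [classify_direction_consistency()].
#' @return List with `table` (per-symbol comparison with logical `agree`),
#'   `fraction_agree` (over matched symbols with a consistent CSF direction)
#'   and `unmatched` (stage-table symbols with no consistency call).
#' @export
stage_direction_agreement <- function(stage_table, consistency) {
  idx <- match(stage_table$symbol, consistency$symbol)
  unmatched <- stage_table$symbol[is.na(idx)]
  tab <- stage_table[!is.na(idx), , drop = FALSE]
  cat_csf <- consistency$category[idx[!is.na(idx)]]
  csf_direction <- ifelse(cat_csf == "consistent_up", "up",
                          ifelse(cat_csf == "consistent_down", "down", NA))
  comp <- data.frame(symbol = tab$symbol,
                     stage = if (!is.null(tab$stage)) tab$stage else NA,
                     trajectory_direction = tab$direction,
                     csf_direction = csf_direction,
                     stringsAsFactors = FALSE)
  comp$agree <- !is.na(comp$csf_direction) &
    comp$trajectory_direction == comp$csf_direction
  comparable <- !is.na(comp$csf_direction)
  list(table = comp,
       fraction_agree = if (any(comparable))
         mean(comp$agree[comparable]) else NA_real_,
       unmatched = unmatched)
}

#' Direction concordance between CSF and brain-tissue compilations
#'
#' Compares CSF direction calls for a protein set with a brain-tissue
#' differential-expression compilation carrying a recurrence score (how many
#' tissue studies reported the protein consistently changed). Tissue rows
#' below the recurrence threshold are excluded before comparison.
#'
#' @param csf_directions Data frame with columns `symbol` and `direction`
#'   (`"up"`/`"down"`), e.g. derived from [classify_direction_consistency()]
#'   or [forest_table()] calls.
#' @param tissue_table Data frame with columns `symbol`, `direction`,
#'   `recurrence`.
#' @param min_recurrence Minimum tissue recurrence (default 5, compared with
#'   `>=`).
#' @return List with `table` (columns `symbol`, `csf_direction`,
#'   `tissue_direction`, `tissue_recurrence`, `concordant`) and `summary`
#'   (named counts `up_up`, `down_down`, `discordant`, summing to the number
#'   of compared symbols).
#' @export
tissue_concordance <- function(csf_directions, tissue_table,
                               min_recurrence = 5) {
  need <- c("symbol", "direction", "recurrence")
  absent <- setdiff(need, names(tissue_table))
  if (length(absent))
    stop("tissue table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  bad_dir <- is.na(tissue_table$direction) |
    !tolower(tissue_table$direction) %in% c("up", "down")
  if (any(bad_dir)) {
    warning("skipping ", sum(bad_dir), " tissue row(s) with missing/unknown ",
            "direction", call. = FALSE)
    tissue_table <- tissue_table[!bad_dir, , drop = FALSE]
  }
  tissue_table <- tissue_table[tissue_table$recurrence >= min_recurrence, ,
                               drop = FALSE]
  idx <- match(csf_directions$symbol, tissue_table$symbol)
  keep <- !is.na(idx)
  tab <- data.frame(
    symbol = csf_directions$symbol[keep],
    csf_direction = tolower(csf_directions$direction[keep]),
    tissue_direction = tolower(tissue_table$direction[idx[keep]]),
    tissue_recurrence = tissue_table$recurrence[idx[keep]],
    stringsAsFactors = FALSE)
  tab$concordant <- tab$csf_direction == tab$tissue_direction
  summary <- c(
    up_up = sum(tab$concordant & tab$csf_direction == "up"),
    down_down = sum(tab$concordant & tab$csf_direction == "down"),
    discordant = sum(!tab$concordant))
  list(table = tab, summary = summary)
}
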