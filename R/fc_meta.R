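#' Map a fold-change to log2 scale
#'
#' Log2-scale values pass through unchanged; linear values are mapped by log
#' base 2 and must be strictly positive. `NA` passes through.
#'
#' @param fc Numeric vector of fold-changes.
#' @param scale `"log2"` or `"linear"`.
#' @return Numeric vector on log2 scale.
#' @export
to_log2 <- function(fc, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (scale == "log2") return(fc)
  if (any(fc <= 0, na.rm = TRUE))
    stop("linear fold-changes must be strictly positive", call. = FALSE)
  log2(fc)
}

#' Harmonize fold-change direction across contrast orientations
#'
#' Makes positive log2 fold-change always mean upregulation in cases:
#' values from a `control_over_case` contrast are negated, others pass
#' through. Applying a flip twice is the identity.
#'
#' @param log2fc Numeric vector.
#' @param orientation `"case_over_control"` or `"control_over_case"`.
#' @return Numeric vector in case-over-control orientation.
#' @export
harmonize_direction <- function(log2fc,
                                orientation = c("case_over_control",
                                                "control_over_case")) {
  orientation <- match.arg(orientation)
  if (orientation == "control_over_case") -log2fc else log2fc
}

#' Mean effect with t-based confidence interval
#'
#' Arithmetic mean of per-study log2 fold-changes with a symmetric
#' t-distribution confidence interval, `mean +/- t_{(1+level)/2, n-1} *
#' sd/sqrt(n)`. Contributing-study counts are small (a dozen or fewer), so a
#' normal interval would be anti-conservative. With a single study no
#' interval is defined: `ci_low`/`ci_high` are `NA` and `single_study` is
#' `TRUE` rather than fabricating an interval.
#'
#' @param log2fcs Non-empty numeric vector of per-study log2 fold-changes.
#' @param level Confidence level, default 0.95.
#' @return List with `mean_log2fc`, `ci_low`, `ci_high`,
#'   `n_studies_quantified`, `single_study`.
#' @examples
#' mean_ci(c(0, 2))  # 1 +/- 12.7062
#' @export
mean_ci <- function(log2fcs, level = 0.95) {
  log2fcs <- log2fcs[!is.na(log2fcs)]
  if (!length(log2fcs))
    stop("at least one fold-change is required", call. = FALSE)
  stopifnot(level > 0, level < 1)
  n <- length(log2fcs)
  m <- mean(log2fcs)
  if (n == 1L)
    return(list(mean_log2fc = m, ci_low = NA_real_, ci_high = NA_real_,
                n_studies_quantified = 1L, single_study = TRUE))
  half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(log2fcs) / sqrt(n)
  list(mean_log2fc = m, ci_low = m - half, ci_high = m + half,
       n_studies_quantified = n, single_study = FALSE)
}

# per-symbol comparable log2 fold-changes: MS studies quantifying the symbol,
# regardless of significance; affinity effect scores never enter
comparable_fcs <- function(symbol, datasets, significant_only = FALSE) {
  vals <- lapply(datasets, function(d) {
    if (d$meta$platform != "MS" || d$meta$fc_scale == "none") return(NULL)
    rows <- d$measurements[d$measurements$symbol == symbol, , drop = FALSE]
    if (significant_only) rows <- rows[rows$significant, , drop = FALSE]
    v <- rows$log2fc
    v[!is.na(v)]
  })
  unlist(vals, use.names = FALSE)
}

#' Compile per-protein forest statistics across studies
#'
#' For each symbol, collects case-over-control log2 fold-changes from every
#' MS study quantifying it -- regardless of significance -- and computes the
#' mean and 95% t-interval via [mean_ci()]. Affinity-platform effect scores
#' (Olink; SomaScan "beta") are not comparable to a fold-change and never
#' enter the compilation. A protein is called `"down"` when the mean and both
#' interval bounds are below 0, `"up"` when all are above 0, otherwise
#' `"indeterminate"` (single-study proteins are always indeterminate).
#'
#' @param top_symbols Character vector of symbols to compile.
#' @param datasets List of [study_dataset()] objects (or a registry's
#'   `$datasets`).
#' @param cluster_map Optional named character vector mapping symbols to
#'   functional cluster labels; unmapped symbols get `"unclustered"`.
#' @param level Confidence level.
#' @return Data frame (one row per symbol with at least one comparable
#'   fold-change) with columns `symbol`, `cluster`, `mean_log2fc`, `ci_low`,
#'   `ci_high`, `n_studies_quantified`, `call`; ordered by cluster then mean.
#'   Symbols with no comparable fold-change are dropped and listed in
#'   `attr(, "no_fc")`.
#' @export
forest_table <- function(top_symbols, datasets, cluster_map = NULL,
                         level = 0.95) {
  if (inherits(datasets, "study_registry")) datasets <- datasets$datasets
  rows <- lapply(top_symbols, function(sym) {
    v <- comparable_fcs(sym, datasets)
    if (!length(v)) return(NULL)
    ci <- mean_ci(v, level = level)
    call <- if (ci$single_study || is.na(ci$ci_low)) "indeterminate"
      else if (ci$mean_log2fc > 0 && ci$ci_low > 0) "up"
      else if (ci$mean_log2fc < 0 && ci$ci_high < 0) "down"
      else "indeterminate"
    data.frame(symbol = sym,
               cluster = if (!is.null(cluster_map) && sym %in% names(cluster_map))
                 cluster_map[[sym]] else "unclustered",
               mean_log2fc = ci$mean_log2fc, ci_low = ci$ci_low,
               ci_high = ci$ci_high,
               n_studies_quantified = ci$n_studies_quantified,
               call = call, stringsAsFactors = FALSE)
  })
  no_fc <- top_symbols[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(symbol = character(0), cluster = character(0),
                      mean_log2fc = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), n_studies_quantified = integer(0),
                      call = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$mean_log2fc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_fc") <- no_fc
  out
}

#' Long-format per-study fold-change points for forest plotting
#'
#' @param top_symbols Symbols to extract.
#' @param datasets List of [study_dataset()] objects or a registry.
#' @return Data frame `symbol`, `study_id`, `log2fc`, `significant` over MS
#'   studies with a comparable fold-change.
#' @export
forest_points <- function(top_symbols, datasets) {
  if (inherits(datasets, "study_registry")) datasets <- datasets$datasets
  rows <- lapply(datasets, function(d) {
    if (d$meta$platform != "MS" || d$meta$fc_scale == "none") return(NULL)
    m <- d$measurements
    m <- m[m$symbol %in% top_symbols & !is.na(m$log2fc), , drop = FALSE]
    if (!nrow(m)) return(NULL)
    data.frame(symbol = m$symbol, study_id = d$meta$study_id,
               log2fc = m$log2fc, significant = m$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(symbol = character(0), study_id = character(0),
                      log2fc = numeric(0), significant = logical(0))
  rownames(out) <- NULL
  out
}
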