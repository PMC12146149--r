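#' Study metadata for one case-control comparison
#'
#' Each compiled comparison (a study, or a sub-cohort within a study) carries
#' the metadata needed to interpret its protein table: quantification platform,
#' group sizes, the FDR cutoff the study itself used to declare significance,
#' the orientation of the published contrast, and the scale of any reported
#' fold-changes. Affinity platforms (Olink, SomaScan) report effect scores
#' that are not comparable to a log2 fold-change, so `fc_scale = "none"` marks
#' a study whose direction/magnitude cannot enter fold-change compilation.
#'
#' @param study_id Short unique identifier for the comparison.
#' @param platform One of `"MS"`, `"Olink"`, `"SomaScan"`.
#' @param n_case,n_control Positive integer group sizes.
#' @param cohort_label Optional free-text cohort label (sub-cohorts of one
#'   publication are separate comparisons).
#' @param ms_flavor Optional MS acquisition type (e.g. `"TMT"`, `"DIA"`).
#' @param fdr_cutoff The study's own FDR significance cutoff, in (0, 1].
#' @param contrast_orientation `"case_over_control"` (positive fold-change =
#'   higher in cases) or `"control_over_case"`.
#' @param fc_scale Scale of the study's reported fold-changes: `"log2"`,
#'   `"linear"`, or `"none"` when no comparable fold-change exists.
#' @return An object of class `"study_meta"`.
#' @examples
#' study_meta("bader2020_swe", "MS", n_case = 29, n_control = 31,
#'            ms_flavor = "DIA", fc_scale = "log2")
#' @export
study_meta <- function(study_id, platform, n_case, n_control,
                       cohort_label = "", ms_flavor = NA_character_,
                       fdr_cutoff = 0.05,
                       contrast_orientation = c("case_over_control",
                                                "control_over_case"),
                       fc_scale = c("log2", "linear", "none")) {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  platform <- match.arg(platform, c("MS", "Olink", "SomaScan"))
  contrast_orientation <- match.arg(contrast_orientation)
  fc_scale <- match.arg(fc_scale)
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  if (is.na(n_case) || n_case < 1L || is.na(n_control) || n_control < 1L)
    stop("n_case and n_control must be positive integers", call. = FALSE)
  if (!is.numeric(fdr_cutoff) || fdr_cutoff <= 0 || fdr_cutoff > 1)
    stop("fdr_cutoff must lie in (0, 1]", call. = FALSE)
  structure(
    list(study_id = study_id, cohort_label = cohort_label,
         platform = platform, ms_flavor = ms_flavor,
         n_case = n_case, n_control = n_control,
         fdr_cutoff = fdr_cutoff,
         contrast_orientation = contrast_orientation,
         fc_scale = fc_scale),
    class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cat(sprintf("<study_meta> %s [%s%s] %d cases vs %d controls, FDR <= %g, fc_scale=%s\n",
              x$study_id, x$platform,
              if (!is.na(x$ms_flavor)) paste0("/", x$ms_flavor) else "",
              x$n_case, x$n_control, x$fdr_cutoff, x$fc_scale))
  invisible(x)
}

#' Construct a harmonized study dataset
#'
#' Bundles study metadata with its harmonized protein measurement table. The
#' measurement table has one row per harmonized symbol with columns `symbol`,
#' `log2fc` (case over control, `NA` when no comparable fold-change exists),
#' `p_value`, `adj_p` and logical `significant`. Significant rows form the
#' study's differentially-expressed-protein (DEP) set.
#'
#' @param meta A [study_meta()] object.
#' @param measurements Data frame with at least columns `symbol` and
#'   `significant`; `log2fc`, `p_value`, `adj_p` are added as `NA` if missing.
#' @return An object of class `"study_dataset"`.
#' @seealso [read_study_table()] which builds one from a file.
#' @export
study_dataset <- function(meta, measurements) {
  stopifnot(inherits(meta, "study_meta"), is.data.frame(measurements))
  required <- c("symbol", "significant")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols))
    stop("measurements lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c("log2fc", "p_value", "adj_p"))
    if (is.null(measurements[[col]])) measurements[[col]] <- NA_real_
  measurements <- measurements[, c("symbol", "log2fc", "p_value", "adj_p",
                                   "significant")]
  measurements$symbol <- as.character(measurements$symbol)
  measurements$significant <- as.logical(measurements$significant)
  measurements$significant[is.na(measurements$significant)] <- FALSE
  if (anyDuplicated(measurements$symbol))
    stop("duplicate harmonized symbols in study ", meta$study_id,
         "; collapse before constructing the dataset", call. = FALSE)
  pv <- c(measurements$p_value, measurements$adj_p)
  if (any(pv < 0 | pv > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1] in study ", meta$study_id, call. = FALSE)
  rownames(measurements) <- NULL
  structure(list(meta = meta, measurements = measurements),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %s: %d proteins measured, %d significant\n",
              x$meta$study_id, nrow(x$measurements),
              sum(x$measurements$significant)))
  invisible(x)
}

#' DEP symbols of a study dataset
#'
#' @param dataset A [study_dataset()].
#' @return Character vector of symbols flagged significant.
#' @export
dep_symbols <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  dataset$measurements$symbol[dataset$measurements$significant]
}

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read and harmonize one published study table
#'
#' Reads a delimited per-protein table (TSV or CSV, inferred from the file
#' extension), harmonizes identifiers with [harmonize_protein_id()], collapses
#' duplicate symbols, converts fold-changes to case-over-control log2 scale
#' using the study metadata, and derives significance flags.
#'
#' Duplicate symbols after harmonization are collapsed to the row with the
#' smallest p-value (first occurrence when no p-value is available); collapses
#' are reported via `message()`. When the table has no significance column,
#' flags are derived as `adj_p <= meta$fdr_cutoff`. Fold-changes on linear
#' scale are mapped through [to_log2()]; a `control_over_case` contrast is
#' sign-flipped with [harmonize_direction()] so that positive log2fc always
#' means higher in cases. Studies with `fc_scale = "none"` get `log2fc = NA`.
#'
#' @param path Path to the study table.
#' @param column_map Named list mapping roles to column names in the file.
#'   `id` is required; `log2fc`, `p_value`, `adj_p`, `significant` are
#'   optional.
#' @param meta A [study_meta()] object.
#' @return A [study_dataset()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(Protein = c("A;B", "C-1", "c"), padj = c(0.01, 0.2, 0.6)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' ds <- read_study_table(tf, list(id = "Protein", adj_p = "padj"),
#'                        study_meta("s1", "MS", 10, 10, fc_scale = "none"))
#' ds$measurements
#' @export
read_study_table <- function(path, column_map, meta) {
  stopifnot(inherits(meta, "study_meta"))
  if (!file.exists(path)) stop("study table not found: ", path, call. = FALSE)
  if (is.null(column_map$id))
    stop("column_map must name the identifier column as 'id'", call. = FALSE)
  tab <- utils::read.delim(path, sep = infer_delim(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mapped <- unlist(column_map, use.names = FALSE)
  absent <- setdiff(mapped, names(tab))
  if (length(absent))
    stop("study ", meta$study_id, ": mapped column(s) absent from ", path,
         ": ", paste(absent, collapse = ", "), call. = FALSE)

  if (nrow(tab) == 0L) {
    empty <- data.frame(symbol = character(0), log2fc = numeric(0),
                        p_value = numeric(0), adj_p = numeric(0),
                        significant = logical(0))
    return(study_dataset(meta, empty))
  }

  num_col <- function(role) {
    if (is.null(column_map[[role]])) return(rep(NA_real_, nrow(tab)))
    raw <- tab[[column_map[[role]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad))
      stop("study ", meta$study_id, ": non-numeric ", role, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    val
  }

  out <- data.frame(
    symbol = harmonize_protein_id(tab[[column_map$id]]),
    log2fc = num_col("log2fc"),
    p_value = num_col("p_value"),
    adj_p = num_col("adj_p"),
    stringsAsFactors = FALSE)

  if (!is.null(column_map$significant)) {
    flag <- tab[[column_map$significant]]
    if (!is.logical(flag))
      flag <- tolower(as.character(flag)) %in% c("true", "yes", "1", "t", "y")
    out$significant <- flag
  } else {
    out$significant <- !is.na(out$adj_p) & out$adj_p <= meta$fdr_cutoff
  }

  # scale and orientation harmonization
  if (meta$fc_scale == "none") {
    out$log2fc <- NA_real_
  } else {
    out$log2fc <- to_log2(out$log2fc, meta$fc_scale)
    out$log2fc <- harmonize_direction(out$log2fc, meta$contrast_orientation)
  }

  # collapse duplicate symbols: smallest p-value wins, else first occurrence
  if (anyDuplicated(out$symbol)) {
    dup_syms <- unique(out$symbol[duplicated(out$symbol)])
    message("study ", meta$study_id, ": collapsing ", length(dup_syms),
            " duplicated symbol(s): ",
            paste(utils::head(dup_syms, 5L), collapse = ", "),
            if (length(dup_syms) > 5L) ", ..." else "")
    key <- ifelse(is.na(out$p_value), Inf, out$p_value)
    ord <- order(match(out$symbol, out$symbol), key)  # stable within symbol
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$symbol), , drop = FALSE]
  }
  out <- out[order(out$symbol), , drop = FALSE]  # row-order insensitivity
  study_dataset(meta, out)
}

#' Write a normalized study table
#'
#' @param dataset A [study_dataset()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  utils::write.table(dataset$measurements, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the registry of compiled comparisons
#'
#' @param datasets List of [study_dataset()] objects with unique study ids.
#' @return An object of class `"study_registry"`: the datasets (named by
#'   study id) plus comparison count, per-platform counts and the union of
#'   measured symbols.
#' @examples
#' m <- study_meta("s1", "MS", 5, 5)
#' d <- study_dataset(m, data.frame(symbol = "A", significant = TRUE))
#' build_registry(list(d))
#' @export
build_registry <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  ok <- vapply(datasets, inherits, logical(1), "study_dataset")
  if (!all(ok)) stop("all elements must be study_dataset objects", call. = FALSE)
  ids <- vapply(datasets, function(d) d$meta$study_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate study_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(datasets) <- ids
  platforms <- vapply(datasets, function(d) d$meta$platform, character(1))
  structure(
    list(datasets = datasets,
         n_comparisons = length(datasets),
         platform_counts = table(factor(platforms,
                                        levels = c("MS", "Olink", "SomaScan"))),
         measured_union = sort(unique(unlist(
           lapply(datasets, function(d) d$measurements$symbol))))),
    class = "study_registry")
}

#' @export
print.study_registry <- function(x, ...) {
  pc <- x$platform_counts
  cat(sprintf("<study_registry> %d comparisons (MS: %d, Olink: %d, SomaScan: %d)\n",
              x$n_comparisons, pc[["MS"]], pc[["Olink"]], pc[["SomaScan"]]))
  cat(sprintf("  union of measured symbols: %d\n", length(x$measured_union)))
  invisible(x)
}

#' Read a registry of study tables from a JSON configuration
#'
#' The configuration is a JSON array of objects, one per comparison, each with
#' fields `path` (relative paths resolve against the config file's directory),
#' `study_id`, `platform`, `n_case`, `n_control`, and optionally
#' `cohort_label`, `ms_flavor`, `fdr_cutoff`, `contrast_orientation`,
#' `fc_scale`, and a `columns` object mapping `id`/`log2fc`/`p_value`/
#' `adj_p`/`significant` roles to file columns.
#'
#' @param config_path Path to the JSON configuration.
#' @return A [build_registry()] result.
#' @export
read_registry_config <- function(config_path) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = FALSE)
  base <- dirname(normalizePath(config_path))
  datasets <- lapply(cfg, function(entry) {
    meta <- study_meta(
      study_id = entry$study_id,
      platform = entry$platform,
      n_case = entry$n_case, n_control = entry$n_control,
      cohort_label = entry$cohort_label %||% "",
      ms_flavor = entry$ms_flavor %||% NA_character_,
      fdr_cutoff = entry$fdr_cutoff %||% 0.05,
      contrast_orientation = entry$contrast_orientation %||% "case_over_control",
      fc_scale = entry$fc_scale %||% "log2")
    path <- entry$path
    if (!file.exists(path)) path <- file.path(base, entry$path)
    cmap <- entry$columns %||% list(id = "symbol", log2fc = "log2fc",
                                    p_value = "p_value", adj_p = "adj_p",
                                    significant = "significant")
    read_study_table(path, cmap, meta)
  })
  build_registry(datasets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
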