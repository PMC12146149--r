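#' Count per-protein recurrence across studies
#'
#' One record per protein significant in at least one study: how many
#' comparisons flagged it, which ones, and which platform classes those
#' comparisons used.
#'
#' @param datasets List of [study_dataset()] objects or a [build_registry()]
#'   result.
#' @return Data frame with columns `symbol`, `n_studies_significant`,
#'   `significant_in` (semicolon-joined study ids) and `platforms`
#'   (semicolon-joined platform classes), ordered by decreasing recurrence
#'   then symbol.
#' @examples
#' # dep sets {A,B}, {B,C}, {B} -> B:3, A:1, C:1
#' @export
count_study_overlap <- function(datasets) {
  if (inherits(datasets, "study_registry")) datasets <- datasets$datasets
  stopifnot(length(datasets) >= 1L)
  per_study <- lapply(datasets, function(d)
    if (length(dep_symbols(d)))
      data.frame(symbol = dep_symbols(d), study_id = d$meta$study_id,
                 platform = d$meta$platform, stringsAsFactors = FALSE)
    else NULL)
  long <- do.call(rbind, per_study)
  if (is.null(long) || !nrow(long))
    return(data.frame(symbol = character(0), n_studies_significant = integer(0),
                      significant_in = character(0), platforms = character(0),
                      stringsAsFactors = FALSE))
  sp <- split(long, long$symbol)
  out <- data.frame(
    symbol = names(sp),
    n_studies_significant = vapply(sp, function(x)
      length(unique(x$study_id)), integer(1)),
    significant_in = vapply(sp, function(x)
      paste(sort(unique(x$study_id)), collapse = ";"), character(1)),
    platforms = vapply(sp, function(x)
      paste(sort(unique(x$platform)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_studies_significant, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top recurrent DEPs
#'
#' @param records Output of [count_study_overlap()].
#' @param min_studies Minimum number of studies a protein must be significant
#'   in (>= 1).
#' @return Character vector of symbols with recurrence >= `min_studies`.
#' @export
select_top_deps <- function(records, min_studies) {
  if (!is.numeric(min_studies) || length(min_studies) != 1L || min_studies < 1)
    stop("min_studies must be a single integer >= 1", call. = FALSE)
  sort(records$symbol[records$n_studies_significant >= min_studies])
}

#' Exact set-membership (UpSet) intersection counts
#'
#' Groups the `top_n` most recurrent DEPs by their exact study-membership
#' pattern, the quantity an UpSet plot displays. Patterns are ordered by
#' decreasing protein count, ties broken lexicographically by pattern.
#'
#' @param records Output of [count_study_overlap()].
#' @param top_n Number of most-recurrent proteins to include (ties at the
#'   recurrence boundary broken alphabetically by symbol).
#' @return Data frame `pattern` (ampersand-joined study ids), `degree`
#'   (number of studies in the pattern), `count`, `symbols`
#'   (semicolon-joined). Counts sum to the number of proteins considered.
#' @export
upset_intersections <- function(records, top_n = nrow(records)) {
  if (!is.numeric(top_n) || top_n < 1)
    stop("top_n must be >= 1", call. = FALSE)
  take <- utils::head(records[order(-records$n_studies_significant,
                                    records$symbol), , drop = FALSE], top_n)
  if (!nrow(take))
    return(data.frame(pattern = character(0), degree = integer(0),
                      count = integer(0), symbols = character(0)))
  pattern <- vapply(strsplit(take$significant_in, ";", fixed = TRUE),
                    function(x) paste(sort(x), collapse = "&"), character(1))
  sp <- split(take$symbol, pattern)
  out <- data.frame(
    pattern = names(sp),
    degree = lengths(strsplit(names(sp), "&", fixed = TRUE)),
    count = lengths(sp),
    symbols = vapply(sp, function(x) paste(sort(x), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an UpSet membership matrix
#'
#' Emits a binary protein-by-study membership matrix (TSV) consumable by
#' standard UpSet plotting tools.
#'
#' @param records Output of [count_study_overlap()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_upset_matrix <- function(records, path) {
  studies <- sort(unique(unlist(strsplit(records$significant_in, ";",
                                         fixed = TRUE))))
  mat <- vapply(studies, function(s)
    as.integer(vapply(strsplit(records$significant_in, ";", fixed = TRUE),
                      function(x) s %in% x, logical(1))),
    integer(nrow(records)))
  out <- cbind(data.frame(symbol = records$symbol, stringsAsFactors = FALSE),
               as.data.frame(mat))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition DEPs by platform class
#'
#' @param records Output of [count_study_overlap()].
#' @return Named integer vector `ms_only`, `affinity_only`, `both`; the three
#'   mutually exclusive counts sum to `nrow(records)`.
#' @export
platform_partition <- function(records) {
  plat <- strsplit(records$platforms, ";", fixed = TRUE)
  if (any(lengths(plat) == 0L))
    stop("every record must carry at least one platform", call. = FALSE)
  has_ms <- vapply(plat, function(p) "MS" %in% p, logical(1))
  has_aff <- vapply(plat, function(p) any(p %in% c("Olink", "SomaScan")),
                    logical(1))
  c(ms_only = sum(has_ms & !has_aff),
    affinity_only = sum(!has_ms & has_aff),
    both = sum(has_ms & has_aff))
}

#' Classify direction consistency of recurrent DEPs
#'
#' For each symbol, collects the case-over-control log2 fold-changes from the
#' studies where it was significant and a comparable fold-change exists (MS
#' studies; affinity effect scores are excluded). A protein is
#' `consistent_up` when every such fold-change is positive, `consistent_down`
#' when every one is negative, `inconsistent` when both signs occur. A
#' fold-change of exactly 0 counts toward neither direction; proteins with no
#' comparable fold-change at all (or only zeros) are `unclassifiable` and
#' excluded from category tallies.
#'
#' @param symbols Character vector of symbols to classify.
#' @param datasets List of [study_dataset()] objects or a registry.
#' @return Data frame `symbol`, `n_up`, `n_down`, `n_zero`, `category`.
#' @export
classify_direction_consistency <- function(symbols, datasets) {
  if (inherits(datasets, "study_registry")) datasets <- datasets$datasets
  rows <- lapply(symbols, function(sym) {
    v <- comparable_fcs(sym, datasets, significant_only = TRUE)
    n_up <- sum(v > 0); n_down <- sum(v < 0); n_zero <- sum(v == 0)
    category <- if (n_up == 0 && n_down == 0) "unclassifiable"
      else if (n_down == 0) "consistent_up"
      else if (n_up == 0) "consistent_down"
      else "inconsistent"
    data.frame(symbol = sym, n_up = n_up, n_down = n_down, n_zero = n_zero,
               category = category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(symbol = character(0), n_up = integer(0),
                      n_down = integer(0), n_zero = integer(0),
                      category = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-platform proportions of up/down regulated DEPs
#'
#' For each platform class: the number of distinct proteins measured, and the
#' number of DEPs whose significant fold-changes within that platform are all
#' positive (`n_up`) or all negative (`n_down`). Platforms without comparable
#' fold-changes contribute zero directional counts.
#'
#' @param datasets List of [study_dataset()] objects or a registry.
#' @return Data frame `platform`, `n_measured`, `n_deps`, `n_up`, `n_down`,
#'   `prop_up`, `prop_down`.
#' @export
platform_proportions <- function(datasets) {
  if (inherits(datasets, "study_registry")) datasets <- datasets$datasets
  platforms <- vapply(datasets, function(d) d$meta$platform, character(1))
  rows <- lapply(unique(platforms), function(pl) {
    ds <- datasets[platforms == pl]
    measured <- unique(unlist(lapply(ds, function(d) d$measurements$symbol)))
    deps <- unique(unlist(lapply(ds, dep_symbols)))
    cls <- classify_direction_consistency(deps, ds)
    n_up <- sum(cls$category == "consistent_up")
    n_down <- sum(cls$category == "consistent_down")
    data.frame(platform = pl, n_measured = length(measured),
               n_deps = length(deps), n_up = n_up, n_down = n_down,
               prop_up = if (length(measured)) n_up / length(measured) else 0,
               prop_down = if (length(measured)) n_down / length(measured) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Headline compilation counts for a study registry
#'
#' Recomputes the summary counts that describe a compiled multi-study
#' differential-expression landscape: total distinct DEPs; how many were
#' found in a single study, in 2 to `min_studies` studies, and in at least
#' `min_studies` studies (the "top" set); the platform partition; direction
#' consistency within the top set; and how many top DEPs were seen on all
#' three platform classes.
#'
#' @param registry A [build_registry()] result (or list of datasets).
#' @param min_studies Recurrence threshold defining the top set (default 6).
#' @return A list of counts; see examples in the package vignette.
#' @export
compile_summary <- function(registry, min_studies = 6) {
  datasets <- if (inherits(registry, "study_registry")) registry$datasets
              else registry
  rec <- count_study_overlap(datasets)
  top <- select_top_deps(rec, min_studies)
  cls_top <- classify_direction_consistency(top, datasets)
  part <- platform_partition(rec)
  n_platforms <- lengths(strsplit(rec$platforms[match(top, rec$symbol)], ";",
                                  fixed = TRUE))
  list(
    n_deps_total = nrow(rec),
    n_single_study = sum(rec$n_studies_significant == 1L),
    n_multi_study = sum(rec$n_studies_significant > 1L),
    n_mid = sum(rec$n_studies_significant > 1L &
                  rec$n_studies_significant < min_studies),
    n_top = length(top),
    top_symbols = top,
    platform_partition = part,
    n_top_consistent_up = sum(cls_top$category == "consistent_up"),
    n_top_consistent_down = sum(cls_top$category == "consistent_down"),
    n_top_inconsistent = sum(cls_top$category == "inconsistent"),
    n_top_unclassifiable = sum(cls_top$category == "unclassifiable"),
    n_top_all_platforms = sum(n_platforms == 3L))
}
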