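#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one term per line, tab-separated -- term id,
#' description, then member symbols. Members are harmonized with
#' [harmonize_protein_id()] so annotation symbols match study data.
#'
#' @param path GMT file path.
#' @return List of annotation sets, each a list with `term_id`, `term_name`
#'   and character `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need id, description, >=1 member): ",
           substr(ln, 1, 60), call. = FALSE)
    list(term_id = parts[[1L]], term_name = parts[[2L]],
         members = unique(harmonize_protein_id(parts[-(1:2)])))
  })
}

#' Write gene sets to a GMT file
#'
#' @param annotations List of annotation sets as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(annotations, function(a)
    paste(c(a$term_id, a$term_name, a$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the measured-protein background for enrichment
#'
#' The enrichment universe is the union of all proteins quantified across the
#' mass-spectrometry studies -- the set that had a chance to be detected --
#' not the whole proteome. Affinity-platform panels are excluded because
#' their targeted composition would bias the universe.
#'
#' @param datasets List of [study_dataset()] objects or a registry.
#' @return Sorted character vector of background symbols.
#' @export
build_background <- function(datasets) {
  if (inherits(datasets, "study_registry")) datasets <- datasets$datasets
  ms <- Filter(function(d) d$meta$platform == "MS", datasets)
  if (!length(ms))
    stop("background requires at least one MS dataset", call. = FALSE)
  sort(unique(unlist(lapply(ms, function(d) d$measurements$symbol))))
}

#' Hypergeometric over-representation analysis with a custom background
#'
#' For each annotation term, tests whether the query set contains more term
#' members than expected when drawing `n` proteins from the `N`-protein
#' background containing `K` term members: the upper-tail hypergeometric
#' probability P(X >= k). P-values are BH-adjusted across the tested term
#' universe (terms with at least `min_term_size` background members).
#' `strength = log10((k/n)/(K/N))` is the log10 observed/expected ratio.
#'
#' Query symbols absent from the background are dropped with a warning;
#' annotation members are restricted to the background before testing.
#'
#' @param query Character vector of query symbols.
#' @param background Character vector, the measured-protein universe.
#' @param annotations List of annotation sets ([read_gmt()] layout).
#' @param max_fdr Keep terms with BH-FDR at or below this (default 0.05).
#' @param min_strength Keep terms with strength at or above this (default 0.01).
#' @param min_term_size Minimum background members for a term to enter the
#'   tested universe (default 2).
#' @param filter If `FALSE`, return all tested terms unfiltered.
#' @return Data frame with columns `term_id`, `term_name`, `k_hits`,
#'   `K_term_in_background`, `n_query`, `N_background`, `p_value`, `fdr`,
#'   `strength`, sorted by `fdr` then decreasing `strength`.
#' @examples
#' bg <- paste0("P", 1:10)
#' ann <- list(list(term_id = "T1", term_name = "t", members = bg[1:5]))
#' hypergeometric_enrichment(bg[1:5], bg, ann, filter = FALSE)  # p = 1/252
#' @export
hypergeometric_enrichment <- function(query, background, annotations,
                                      max_fdr = 0.05, min_strength = 0.01,
                                      min_term_size = 2, filter = TRUE) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query symbol(s) outside background dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ..." else "", call. = FALSE)
    query <- intersect(query, background)
  }
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      k_hits = integer(0), K_term_in_background = integer(0),
                      n_query = integer(0), N_background = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      strength = numeric(0), stringsAsFactors = FALSE)
  if (!length(query)) {
    warning("empty query after background restriction", call. = FALSE)
    return(empty)
  }
  N <- length(background); n <- length(query)
  rows <- lapply(annotations, function(a) {
    members <- intersect(a$members, background)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = a$term_id, term_name = a$term_name, k_hits = k,
               K_term_in_background = K, n_query = n, N_background = N,
               p_value = p,
               strength = if (k > 0) log10((k / n) / (K / N)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[, c("term_id", "term_name", "k_hits", "K_term_in_background",
                 "n_query", "N_background", "p_value", "fdr", "strength")]
  if (filter)
    out <- out[out$k_hits > 0 & out$fdr <= max_fdr &
                 !is.na(out$strength) & out$strength >= min_strength, ,
               drop = FALSE]
  out <- out[order(out$fdr, -out$strength, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster a query set by annotation membership
#'
#' Functional grouping of the query proteins by k-means on their binary
#' protein-by-term membership vectors. This is a deterministic, local
#' stand-in for network-based clustering services: proteins with similar
#' annotation profiles land in the same cluster, but the clusters are not a
#' replica of any external network clustering. Query members with no
#' annotation at all get the sentinel label `"unclustered"`.
#'
#' @param query Character vector of query symbols.
#' @param annotations List of annotation sets ([read_gmt()] layout).
#' @param k_clusters Number of clusters among annotated members (default 9).
#'   When it exceeds the number of distinct annotation profiles, each
#'   distinct profile becomes its own cluster.
#' @param seed Integer seed; identical input and seed give identical labels.
#' @return Named character vector over `query`: `"cluster_1"`, ...,
#'   `"cluster_k"` or `"unclustered"`.
#' @export
cluster_query <- function(query, annotations, k_clusters = 9, seed = 1) {
  if (!is.numeric(k_clusters) || k_clusters < 1)
    stop("k_clusters must be >= 1", call. = FALSE)
  query <- unique(query)
  terms <- lapply(annotations, `[[`, "members")
  mem <- vapply(terms, function(m) as.integer(query %in% m),
                integer(length(query)))
  mem <- matrix(mem, nrow = length(query))
  rownames(mem) <- query
  annotated <- rowSums(mem) > 0
  labels <- stats::setNames(rep("unclustered", length(query)), query)
  if (!any(annotated)) return(labels)
  m <- mem[annotated, , drop = FALSE]
  if (k_clusters > sum(annotated))
    stop("k_clusters exceeds the number of annotated query members",
         call. = FALSE)
  prof <- apply(m, 1L, paste, collapse = "")
  uniq <- !duplicated(prof)
  k_eff <- min(k_clusters, sum(uniq))
  if (k_eff == sum(uniq)) {
    cl_uniq <- seq_len(sum(uniq))
  } else {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
    km <- stats::kmeans(m[uniq, , drop = FALSE], centers = k_eff,
                        nstart = 10, iter.max = 100)
    cl_uniq <- km$cluster
  }
  cl <- cl_uniq[match(prof, prof[uniq])]
  labels[annotated] <- paste0("cluster_", cl)
  labels
}
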