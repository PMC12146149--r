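#' Configuration for the multi-study synthetic data generator
#'
#' Describes a synthetic compilation world: `n_studies` comparisons over the
#' three platform classes, partially overlapping measured panels drawn from a
#' protein universe, and a planted set of recurrent DEPs with signed log2
#' effects. Defaults mirror the compiled real-world landscape: 21 comparisons
#' (16 MS, 3 Olink, 2 SomaScan), a 6704-protein universe, 61 planted top DEPs
#' each significant in at least 6 studies, roughly one planted effect in five
#' negative, and a 0.05 per-study significance level.
#'
#' @param n_studies Number of comparisons.
#' @param platform_assignment Character vector of length `n_studies` over
#'   `"MS"`, `"Olink"`, `"SomaScan"`.
#' @param n_proteins_universe Size of the protein universe.
#' @param panel_size Proteins measured per study.
#' @param panel_overlap_fraction Fraction of each panel shared by all studies
#'   (the common core), in \[0, 1\].
#' @param n_planted_top Number of planted recurrent DEPs.
#' @param planted_min_recurrence Studies each planted DEP is significant in
#'   (must not exceed `n_studies`).
#' @param effect_size_log2 Absolute planted effect on log2 scale.
#' @param effect_sd Per-study Gaussian noise SD on log2 effects (>= 0).
#' @param within_sd Within-study per-sample SD of log2 abundances (> 0);
#'   scales the significance z-statistic of planted proteins.
#' @param frac_down Fraction of planted effects that are negative.
#' @param alpha Per-study significance level.
#' @param n_case,n_control Group sizes per study.
#' @param deterministic_sig If `TRUE`, significance is noiseless: planted
#'   proteins are significant exactly in their assigned studies and null
#'   proteins never are (used for exact-recovery validation).
#' @param seed Integer seed.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_studies = 21,
                       platform_assignment = rep(c("MS", "Olink", "SomaScan"),
                                                 c(16, 3, 2)),
                       n_proteins_universe = 6704,
                       panel_size = 1400,
                       panel_overlap_fraction = 0.5,
                       n_planted_top = 61,
                       planted_min_recurrence = 6,
                       effect_size_log2 = 0.5,
                       effect_sd = 0.2,
                       within_sd = 1,
                       frac_down = 11 / 61,
                       alpha = 0.05,
                       n_case = 50, n_control = 50,
                       deterministic_sig = FALSE,
                       seed = 1) {
  cfg <- list(n_studies = as.integer(n_studies),
              platform_assignment = platform_assignment,
              n_proteins_universe = as.integer(n_proteins_universe),
              panel_size = as.integer(panel_size),
              panel_overlap_fraction = panel_overlap_fraction,
              n_planted_top = as.integer(n_planted_top),
              planted_min_recurrence = as.integer(planted_min_recurrence),
              effect_size_log2 = effect_size_log2,
              effect_sd = effect_sd, within_sd = within_sd,
              frac_down = frac_down, alpha = alpha,
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              deterministic_sig = isTRUE(deterministic_sig),
              seed = as.integer(seed))
  if (length(cfg$platform_assignment) != cfg$n_studies)
    stop("platform_assignment must have length n_studies", call. = FALSE)
  if (!all(cfg$platform_assignment %in% c("MS", "Olink", "SomaScan")))
    stop("unknown platform in platform_assignment", call. = FALSE)
  if (cfg$planted_min_recurrence > cfg$n_studies)
    stop("infeasible config: planted_min_recurrence exceeds n_studies",
         call. = FALSE)
  if (cfg$n_planted_top > cfg$n_proteins_universe)
    stop("infeasible config: more planted DEPs than universe proteins",
         call. = FALSE)
  if (cfg$n_planted_top > cfg$panel_size)
    stop("infeasible config: planted DEPs cannot exceed the panel size",
         call. = FALSE)
  if (cfg$panel_size > cfg$n_proteins_universe)
    stop("infeasible config: panel_size exceeds the universe", call. = FALSE)
  if (cfg$panel_overlap_fraction < 0 || cfg$panel_overlap_fraction > 1)
    stop("panel_overlap_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$effect_sd < 0 || cfg$within_sd <= 0 ||
      cfg$frac_down < 0 || cfg$frac_down > 1 ||
      cfg$alpha <= 0 || cfg$alpha > 1)
    stop("invalid noise/direction/alpha parameters", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-study compilation with planted truth
#'
#' Builds `n_studies` [study_dataset()] objects plus the planted ground
#' truth. Each study measures a panel sampled from the universe (a common
#' core shared by all studies plus study-specific picks). Planted DEPs are
#' assigned to exactly `planted_min_recurrence` studies each (forced into
#' those panels); in an assigned study a planted protein carries a log2
#' effect `effect_size_log2 * direction + N(0, effect_sd)`; null proteins
#' carry zero-centred `N(0, effect_sd)` effects.
#'
#' Significance emulates each study applying its own cutoff: null proteins
#' draw p ~ Uniform(0, 1) and are flagged at rate `alpha` (the per-study
#' false-positive calibration the validation suite checks); planted proteins
#' in assigned studies get a p-value from the z-statistic
#' `realized_effect * sqrt(n_eff) / within_sd` with
#' `n_eff = 1/(1/n_case + 1/n_control)`. With `deterministic_sig = TRUE` the
#' noiseless regime makes planted recurrence exact by construction. Olink and SomaScan
#' studies emit significance flags but no comparable fold-change
#' (`fc_scale = "none"`), mirroring the platform asymmetry of published
#' panels.
#'
#' @param config A [sim_config()].
#' @return List with `datasets` (list of [study_dataset()]) and `truth`
#'   (list: `true_top_set`, `true_direction_map` named `"up"`/`"down"`,
#'   `membership` logical proteins-by-studies matrix).
#' @export
generate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  U <- config$n_proteins_universe
  universe <- sprintf("PROT%05d", seq_len(U))
  top <- sort(sample(universe, config$n_planted_top))
  n_down <- round(config$frac_down * config$n_planted_top)
  dir_sign <- stats::setNames(
    sample(c(rep(-1, n_down), rep(1, config$n_planted_top - n_down))), top)

  study_ids <- sprintf("sim%02d", seq_len(config$n_studies))
  membership <- matrix(FALSE, nrow = config$n_planted_top,
                       ncol = config$n_studies,
                       dimnames = list(top, study_ids))
  for (sym in top)
    membership[sym, sample(config$n_studies,
                           config$planted_min_recurrence)] <- TRUE

  core_n <- round(config$panel_overlap_fraction * config$panel_size)
  core <- sample(universe, core_n)
  neff <- 1 / (1 / config$n_case + 1 / config$n_control)

  datasets <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    platform <- config$platform_assignment[[s]]
    forced <- top[membership[, s]]
    extra_n <- config$panel_size - core_n
    panel <- unique(c(core,
                      sample(setdiff(universe, core), extra_n), forced))
    panel <- sort(panel)
    planted_here <- panel %in% forced
    lfc <- stats::rnorm(length(panel), 0, config$effect_sd)
    lfc[planted_here] <- config$effect_size_log2 *
      dir_sign[panel[planted_here]] +
      stats::rnorm(sum(planted_here), 0, config$effect_sd)

    if (config$deterministic_sig) {
      p <- ifelse(planted_here, 0, 1)
    } else {
      p <- stats::runif(length(panel))
      z <- lfc[planted_here] * sqrt(neff) / config$within_sd
      p[planted_here] <- 2 * stats::pnorm(-abs(z))
    }
    significant <- p <= config$alpha

    meas <- data.frame(
      symbol = panel,
      log2fc = if (platform == "MS") lfc else NA_real_,
      p_value = p, adj_p = bh_adjust(p), significant = significant,
      stringsAsFactors = FALSE)
    meta <- study_meta(study_ids[[s]], platform,
                       n_case = config$n_case, n_control = config$n_control,
                       fdr_cutoff = config$alpha,
                       fc_scale = if (platform == "MS") "log2" else "none")
    datasets[[s]] <- study_dataset(meta, meas)
  }
  list(datasets = datasets,
       truth = list(
         true_top_set = top,
         true_direction_map = stats::setNames(
           ifelse(dir_sign > 0, "up", "down"), top),
         membership = membership))
}

#' Generate a raw per-sample abundance matrix with known effects
#'
#' Log2-scale abundances: control samples are `baseline + N(0, noise_sd)`;
#' case samples add the per-protein effect. Feeds the differential-expression
#' recomputation path.
#'
#' @param n_case,n_control Group sizes (>= 2).
#' @param effects Named numeric vector of log2 effects (names = symbols).
#' @param noise_sd Per-sample Gaussian noise SD.
#' @param seed Integer seed.
#' @param baseline Baseline log2 abundance (default 20).
#' @return An [abundance_matrix()] on log2 scale.
#' @export
generate_raw_matrix <- function(n_case, n_control, effects, noise_sd,
                                seed = 1, baseline = 20) {
  stopifnot(n_case >= 2, n_control >= 2, !is.null(names(effects)))
  set.seed(seed)
  P <- length(effects)
  case <- matrix(stats::rnorm(P * n_case, baseline, noise_sd), nrow = P) +
    effects
  ctrl <- matrix(stats::rnorm(P * n_control, baseline, noise_sd), nrow = P)
  abundance_matrix(names(effects), case, ctrl, scale = "log2")
}

#' Generate synthetic annotation sets with one planted term
#'
#' The first term (`"TERM_PLANTED"`) is exactly `planted_term`; the remaining
#' terms are random draws from the universe. Writable with [write_gmt()] and
#' designed so that, for a query containing the planted term, that term
#' attains the smallest hypergeometric p-value.
#'
#' @param universe Character vector of background symbols.
#' @param n_terms Total number of terms (>= 1).
#' @param planted_term Character vector, a subset of `universe`.
#' @param seed Integer seed.
#' @param size_range Length-2 integer range for random term sizes.
#' @return List of annotation sets ([read_gmt()] layout).
#' @export
generate_annotations <- function(universe, n_terms, planted_term, seed = 1,
                                 size_range = c(10, 40)) {
  stopifnot(n_terms >= 1, all(planted_term %in% universe))
  set.seed(seed)
  ann <- vector("list", n_terms)
  ann[[1L]] <- list(term_id = "TERM_PLANTED", term_name = "planted signal",
                    members = sort(planted_term))
  if (n_terms > 1L) {
    sizes <- sample(size_range[1]:size_range[2], n_terms - 1L, replace = TRUE)
    for (i in seq_len(n_terms - 1L)) {
      ann[[i + 1L]] <- list(
        term_id = sprintf("TERM%04d", i),
        term_name = sprintf("random term %d", i),
        members = sort(sample(universe, min(sizes[[i]], length(universe)))))
    }
  }
  ann
}

#' Write a synthetic simulation to disk
#'
#' Emits per-study normalized TSVs, a registry configuration JSON consumable
#' by [read_registry_config()], and the planted truth as JSON.
#'
#' @param sim Result of [generate_studies()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- lapply(sim$datasets, function(d) {
    fname <- paste0(d$meta$study_id, ".tsv")
    write_study_table(d, file.path(dir, fname))
    list(path = fname, study_id = d$meta$study_id,
         platform = d$meta$platform, n_case = d$meta$n_case,
         n_control = d$meta$n_control, fdr_cutoff = d$meta$fdr_cutoff,
         contrast_orientation = d$meta$contrast_orientation,
         fc_scale = if (d$meta$fc_scale == "none") "none" else "log2",
         columns = list(id = "symbol", log2fc = "log2fc",
                        p_value = "p_value", adj_p = "adj_p",
                        significant = "significant"))
  })
  jsonlite::write_json(unname(cfg), file.path(dir, "registry.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  truth <- sim$truth
  jsonlite::write_json(
    list(true_top_set = truth$true_top_set,
         true_direction_map = as.list(truth$true_direction_map),
         membership = apply(truth$membership, 1L, function(r)
           colnames(truth$membership)[r], simplify = FALSE)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
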