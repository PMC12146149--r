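#' Overview of 21 published CSF case-control proteomics comparisons
#'
#' A compiled study-level overview of 21 Alzheimer's disease versus control
#' CSF proteomics comparisons published between 2015 and 2024 (18 studies;
#' sub-cohorts analysed separately), spanning mass spectrometry (16
#' comparisons), Olink (3) and SomaScan (2). Each row carries the source DOI,
#' group sizes, the number of proteins measured after QC, the number of
#' significant proteins at the study's own FDR cutoff, and whether the study
#' reported fold-changes comparable across platforms. This table drives the
#' worked covariate examples: study-level counts suffice for those analyses,
#' no per-protein data are needed.
#'
#' @return Data frame with columns `study_id`, `author`, `doi`, `year`,
#'   `sub_cohort`, `platform`, `ms_flavor`, `n_case`, `n_control`,
#'   `n_measured`, `n_significant`, `fc_included`.
#' @examples
#' head(csf_study_overview())
#' @export
csf_study_overview <- function() {
  path <- system.file("extdata", "csf_study_overview.tsv",
                      package = "csfcompile", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$fc_included <- tab$fc_included == "yes"
  tab
}

#' Covariate table from the shipped study overview
#'
#' Convenience adapter: reshapes [csf_study_overview()] into the layout
#' [covariate_analysis()] expects.
#'
#' @return Data frame `study_id`, `platform`, `n_total_samples`,
#'   `n_proteins_measured`, `n_deps`.
#' @export
overview_covariates <- function() {
  tab <- csf_study_overview()
  data.frame(study_id = tab$study_id, platform = tab$platform,
             n_total_samples = tab$n_case + tab$n_control,
             n_proteins_measured = tab$n_measured,
             n_deps = tab$n_significant, stringsAsFactors = FALSE)
}
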