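#' Pearson correlation with a two-sided t-test p-value
#'
#' Computed from the closed form: `r = cov(x, y) / (sd(x) sd(y))`, tested
#' with `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("need equal-length vectors with at least 3 complete pairs",
         call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(list(r = r, p_value = 0, n = n))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Simple linear regression by closed-form least squares
#'
#' Fits `y = intercept + slope * x` with the ordinary least-squares closed
#' form. For the simple regression the slope's two-sided p-value equals the
#' Pearson correlation p-value, and `adj_r_squared = 1 - (1 - r^2)(n - 1)/
#' (n - 2)`. Both the raw and adjusted coefficients of determination are
#' reported: with small study counts they differ noticeably and published
#' summaries may quote either.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return List with `slope`, `intercept`, `r_squared`, `adj_r_squared`,
#'   `p_slope`, `n`.
#' @export
simple_lm <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("need equal-length vectors with at least 3 complete pairs",
         call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate predictor: zero variance", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  p_slope <- if (ss_tot == 0 || ss_res == 0) 0 else {
    se_slope <- sqrt(ss_res / (n - 2) / sxx)
    2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r_squared = r2,
       adj_r_squared = adj_r2, p_slope = p_slope, n = n)
}

#' Study-level covariate table
#'
#' One row per comparison: total sample size, panel size, and DEP count --
#' the covariates for asking what drives the number of DEPs a study reports.
#'
#' @param registry A [build_registry()] result or list of datasets.
#' @return Data frame `study_id`, `platform`, `n_total_samples`,
#'   `n_proteins_measured`, `n_deps`.
#' @export
covariate_table <- function(registry) {
  datasets <- if (inherits(registry, "study_registry")) registry$datasets
              else registry
  rows <- lapply(datasets, function(d)
    data.frame(study_id = d$meta$study_id, platform = d$meta$platform,
               n_total_samples = d$meta$n_case + d$meta$n_control,
               n_proteins_measured = nrow(d$measurements),
               n_deps = sum(d$measurements$significant),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate analysis of DEP counts
#'
#' Two questions, answered on one platform class at a time: does screening
#' depth (panel size) drive the number of DEPs a study finds, and does sample
#' size? The panel-size analysis optionally excludes very small studies
#' (given by their total sample size), which otherwise act as high-leverage
#' points: a deep-panel study with a handful of samples has no power and
#' distorts the depth-DEP relationship. The sample-size correlation uses all
#' comparisons of the platform.
#'
#' @param covariates Data frame from [covariate_table()] (columns `platform`,
#'   `n_total_samples`, `n_proteins_measured`, `n_deps`).
#' @param platform Platform class to analyse (default `"MS"`).
#' @param exclude_total_n Total sample sizes to drop from the panel-size
#'   correlation and regression (default 13; use `integer(0)` to keep all).
#' @return List with `measured_vs_deps` ([pearson_r()] result), `fit`
#'   ([simple_lm()] of DEPs on panel size), `samplesize_vs_deps`
#'   ([pearson_r()] over all platform comparisons) and the row subsets used.
#' @export
covariate_analysis <- function(covariates, platform = "MS",
                               exclude_total_n = 13L) {
  cv <- covariates[covariates$platform == platform, , drop = FALSE]
  if (nrow(cv) < 3L)
    stop("need at least 3 comparisons on platform ", platform, call. = FALSE)
  depth <- cv[!cv$n_total_samples %in% exclude_total_n, , drop = FALSE]
  list(
    measured_vs_deps = pearson_r(depth$n_proteins_measured, depth$n_deps),
    fit = simple_lm(depth$n_proteins_measured, depth$n_deps),
    samplesize_vs_deps = pearson_r(cv$n_total_samples, cv$n_deps),
    depth_subset = depth$study_id,
    all_subset = cv$study_id)
}
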