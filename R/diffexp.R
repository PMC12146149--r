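#' Log2 fold-change between two groups
#'
#' On log2 scale data the fold-change is the difference of group means; on
#' linear scale it is the log2 ratio of group means. Linear-scale values must
#' be strictly positive.
#'
#' @param case_values,control_values Non-empty numeric vectors.
#' @param scale `"log2"` or `"linear"`.
#' @return The log2 fold-change (case relative to control).
#' @examples
#' compute_log2fc(c(2, 2), c(1, 1), "log2")    # 1
#' compute_log2fc(c(4, 4), c(1, 1), "linear")  # 2
#' @export
compute_log2fc <- function(case_values, control_values,
                           scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  case_values <- case_values[!is.na(case_values)]
  control_values <- control_values[!is.na(control_values)]
  if (!length(case_values) || !length(control_values))
    stop("both groups must contain at least one value", call. = FALSE)
  if (scale == "log2")
    return(mean(case_values) - mean(control_values))
  if (any(case_values <= 0) || any(control_values <= 0))
    stop("linear-scale abundances must be strictly positive", call. = FALSE)
  log2(mean(case_values) / mean(control_values))
}

#' Unpaired two-sided t-test
#'
#' Closed-form two-sample t-test used when recomputing significance from raw
#' abundance matrices. Welch's unequal-variance form is the default; the
#' classic pooled-variance form is available with `var_equal = TRUE`. When
#' both groups have zero variance the statistic is degenerate: p is reported
#' as exactly 0 when the means differ and 1 when they are equal, with a
#' warning.
#'
#' @param case_values,control_values Numeric vectors with at least 2
#'   non-missing values each.
#' @param var_equal Use the pooled-variance form?
#' @return List with `t_statistic`, `df` and two-sided `p_value`.
#' @examples
#' unpaired_t_test(c(3, 4, 5), c(1, 2, 3), var_equal = TRUE)
#' @export
unpaired_t_test <- function(case_values, control_values, var_equal = FALSE) {
  x <- case_values[!is.na(case_values)]
  y <- control_values[!is.na(control_values)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("each group needs at least 2 values for a t-test", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  delta <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    warning("zero variance in both groups; degenerate t-test", call. = FALSE)
    return(list(t_statistic = if (delta == 0) 0 else sign(delta) * Inf,
                df = nx + ny - 2, p_value = if (delta == 0) 1 else 0))
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- delta / se
  list(t_statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the BH step-up procedure from its definition:
#' `adj[i] = min over ranks j >= rank(i) of p_(j) * m / j`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  ord <- order(p_values)
  scaled <- p_values[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Per-sample abundance matrix for one study
#'
#' Container for studies that publish raw per-sample protein abundances
#' instead of summary statistics, so that fold-changes and significance can
#' be recomputed.
#'
#' @param symbols Character vector of harmonized protein symbols (rows).
#' @param case_values,control_values Numeric matrices, proteins x samples,
#'   with `length(symbols)` rows and the declared group sizes as columns.
#' @param scale `"log2"` or `"linear"`. Linear values must be non-negative.
#' @return An object of class `"abundance_matrix"`.
#' @export
abundance_matrix <- function(symbols, case_values, control_values,
                             scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  case_values <- as.matrix(case_values)
  control_values <- as.matrix(control_values)
  stopifnot(length(symbols) == nrow(case_values),
            length(symbols) == nrow(control_values))
  if (scale == "linear" &&
      (any(case_values < 0, na.rm = TRUE) || any(control_values < 0, na.rm = TRUE)))
    stop("linear-scale abundances cannot be negative", call. = FALSE)
  structure(list(symbols = as.character(symbols),
                 case_values = case_values,
                 control_values = control_values, scale = scale),
            class = "abundance_matrix")
}

#' Read a wide abundance matrix plus sample-to-group map
#'
#' @param matrix_path TSV with proteins in rows (first column = identifier)
#'   and samples in columns.
#' @param group_map_path Two-column TSV (`sample`, `group`) with groups
#'   `"case"` and `"control"`.
#' @param scale Abundance scale, `"log2"` or `"linear"`.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(matrix_path, group_map_path,
                                  scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  mat <- utils::read.delim(matrix_path, sep = infer_delim(matrix_path),
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  map <- utils::read.delim(group_map_path, sep = infer_delim(group_map_path),
                           header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(map)))
    stop("group map needs columns 'sample' and 'group'", call. = FALSE)
  absent <- setdiff(map$sample, names(mat))
  if (length(absent))
    stop("samples absent from matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  symbols <- harmonize_protein_id(mat[[1L]])
  case_cols <- map$sample[map$group == "case"]
  ctrl_cols <- map$sample[map$group == "control"]
  abundance_matrix(symbols,
                   as.matrix(mat[, case_cols, drop = FALSE]),
                   as.matrix(mat[, ctrl_cols, drop = FALSE]),
                   scale = scale)
}

#' Recompute differential expression from an abundance matrix
#'
#' Per protein: log2 fold-change via [compute_log2fc()], two-sided t-test
#' via [unpaired_t_test()], and BH adjustment via [bh_adjust()] across all
#' testable proteins. Missing values are dropped per group; proteins with
#' fewer than 2 values in either group are excluded from testing and reported
#' via a message and the `"excluded"` attribute of the result.
#'
#' @param abund An [abundance_matrix()].
#' @param fdr_cutoff Significance cutoff applied to the BH-adjusted p-values.
#' @param var_equal Passed to [unpaired_t_test()].
#' @return Data frame with columns `symbol`, `log2fc`, `p_value`, `adj_p`,
#'   `significant`; excluded symbols in `attr(, "excluded")`.
#' @export
recompute_diffexp <- function(abund, fdr_cutoff = 0.05, var_equal = FALSE) {
  stopifnot(inherits(abund, "abundance_matrix"))
  n_ok <- function(v) sum(!is.na(v))
  testable <- vapply(seq_along(abund$symbols), function(i) {
    n_ok(abund$case_values[i, ]) >= 2L && n_ok(abund$control_values[i, ]) >= 2L
  }, logical(1))
  excluded <- abund$symbols[!testable]
  if (length(excluded))
    message("excluding ", length(excluded),
            " protein(s) with <2 values in a group")
  idx <- which(testable)
  res <- lapply(idx, function(i) {
    cs <- abund$case_values[i, ]; ct <- abund$control_values[i, ]
    cs <- cs[!is.na(cs)]; ct <- ct[!is.na(ct)]
    tt <- unpaired_t_test(cs, ct, var_equal = var_equal)
    c(log2fc = compute_log2fc(cs, ct, abund$scale), p_value = tt$p_value)
  })
  out <- data.frame(symbol = abund$symbols[idx],
                    log2fc = vapply(res, `[[`, numeric(1), "log2fc"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"),
                    stringsAsFactors = FALSE)
  out$adj_p <- if (nrow(out)) bh_adjust(out$p_value) else numeric(0)
  out$significant <- !is.na(out$adj_p) & out$adj_p <= fdr_cutoff
  attr(out, "excluded") <- excluded
  out
}
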