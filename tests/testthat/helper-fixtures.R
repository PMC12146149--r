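# shared fixture builders and independent oracles

make_dataset <- function(study_id, platform = "MS", symbols, log2fc = NULL,
                         significant = NULL, p_value = NULL,
                         n_case = 10, n_control = 10, fc_scale = NULL) {
  if (is.null(significant)) significant <- rep(TRUE, length(symbols))
  if (is.null(fc_scale)) fc_scale <- if (platform == "MS") "log2" else "none"
  n <- length(symbols)
  meas <- data.frame(symbol = symbols,
                     log2fc = if (is.null(log2fc)) rep(NA_real_, n) else log2fc,
                     p_value = if (is.null(p_value)) rep(NA_real_, n) else p_value,
                     adj_p = rep(NA_real_, n),
                     significant = significant, stringsAsFactors = FALSE)
  study_dataset(study_meta(study_id, platform, n_case, n_control,
                           fc_scale = fc_scale), meas)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

# brute-force upper-tail hypergeometric oracle: enumerate all C(N, n) draws
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # background items 1..K are term members
  mean(hits >= k)
}

# literal step-up BH from the definition, independent of bh_adjust's cummin
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
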