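#' Harmonize a published protein identifier to a single comparable symbol
#'
#' Published CSF proteomics tables identify proteins inconsistently: protein
#' groups (`"YWHAZ;YWHAB;YWHAG"`), UniProt isoform accessions (`"P05067-2"`),
#' and mixed-case gene symbols all occur. Cross-study counting requires one
#' symbol per row, produced by deterministic string rules:
#'
#' 1. split on the group separator `";"` and keep the first token;
#' 2. strip a trailing `-<digits>` isoform suffix, but only when the remaining
#'    stem looks like a UniProt accession (a letter followed by 5 or 9
#'    alphanumerics) -- hyphenated gene symbols such as `"NKX2-1"` are left
#'    intact;
#' 3. uppercase.
#'
#' The function is idempotent: `harmonize_protein_id(harmonize_protein_id(x))`
#' equals `harmonize_protein_id(x)`.
#'
#' @param raw_id Character vector of identifiers as published. Must contain no
#'   empty or whitespace-only entries.
#' @return Character vector of harmonized symbols, same length as `raw_id`.
#' @examples
#' harmonize_protein_id(c("YWHAZ;YWHAB;YWHAG", "P05067-2", "smoc1", "NKX2-1"))
#' @export
harmonize_protein_id <- function(raw_id) {
  if (length(raw_id) == 0L) return(character(0))
  raw_id <- as.character(raw_id)
  bad <- is.na(raw_id) | !nzchar(trimws(raw_id))
  if (any(bad)) {
    stop("empty or whitespace-only protein identifier at row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  first <- trimws(vapply(strsplit(raw_id, ";", fixed = TRUE),
                         function(x) x[[1L]], character(1)))
  first <- toupper(first)
  # trailing -<digits> is an isoform suffix only on accession-like stems
  has_suffix <- grepl("-[0-9]+$", first)
  stem <- sub("-[0-9]+$", "", first)
  accession_like <- grepl("^[A-Z][A-Z0-9]{5}$|^[A-Z][A-Z0-9]{9}$", stem)
  ifelse(has_suffix & accession_like, stem, first)
}
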