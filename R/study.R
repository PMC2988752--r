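#' Per-study differential-expression summary
#'
#' The unit of evidence the meta-analysis consumes: one row per gene
#' with a p-value and the direction of the expression change (up/down
#' in the more adverse phenotype), plus study metadata.  P-values are
#' clamped into `[eps, 1 - eps]` on ingest so the later normal-quantile
#' conversion stays finite; direction tokens are case-normalized.
#'
#' @param study_id identifier string.
#' @param cancer_type tissue of origin (e.g. `"breast"`).
#' @param contrast `"normal_vs_tumor"` or `"localized_vs_metastatic"`.
#' @param gene character vector of gene symbols (uppercased; unique).
#' @param p_value numeric vector in `[0, 1]`.
#' @param direction character vector of `"up"`/`"down"` tokens (case
#'   insensitive).
#' @param n1,n2 optional group sample sizes.
#' @param eps clamp width for [clamp_p()].
#' @return A `study_summary`: list with the metadata fields and a
#'   `data` data.frame (`gene`, `p_value`, `direction`).
#' @export
study_summary <- function(study_id, cancer_type, contrast,
                          gene, p_value, direction,
                          n1 = NA_integer_, n2 = NA_integer_,
                          eps = 1e-15) {
  gene <- toupper(as.character(gene))
  if (anyDuplicated(gene)) {
    stop("duplicate gene symbols in study '", study_id, "': ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "),
         call. = FALSE)
  }
  p_raw <- as.numeric(p_value)
  p <- clamp_p(p_raw, eps = eps)
  n_clamped <- sum(p != p_raw)
  if (n_clamped > 0) {
    message("study '", study_id, "': clamped ", n_clamped,
            " boundary p-values into [eps, 1-eps]")
  }
  direction <- tolower(as.character(direction))
  bad <- which(!direction %in% c("up", "down"))
  if (length(bad)) {
    stop("study '", study_id, "': invalid direction token(s) at row(s) ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(gene) != length(p) || length(gene) != length(direction)) {
    stop("gene, p_value and direction must have equal length", call. = FALSE)
  }
  structure(list(study_id = as.character(study_id),
                 cancer_type = tolower(as.character(cancer_type)),
                 contrast = as.character(contrast),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 data = data.frame(gene = gene, p_value = p,
                                   direction = direction,
                                   stringsAsFactors = FALSE)),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study '%s' (%s, %s): %d genes, n1=%s n2=%s\n",
              x$study_id, x$cancer_type, x$contrast, nrow(x$data),
              x$n1, x$n2))
  invisible(x)
}

#' Convert one study's summary to signed deviates
#'
#' Applies [p_to_signed_z()] row-wise; the per-study precursor of
#' [combine_stouffer()].
#'
#' @param study a [study_summary()].
#' @return data.frame with columns `gene`, `z`.
#' @export
study_z_table <- function(study) {
  stopifnot(inherits(study, "study_summary"))
  data.frame(gene = study$data$gene,
             z = p_to_signed_z(study$data$p_value, study$data$direction),
             stringsAsFactors = FALSE)
}
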