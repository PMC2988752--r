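#' Signed Z-score table
#'
#' The central container of the package: one signed standard-normal
#' deviate per gene, together with the number of studies that
#' contributed to it and a provenance label (cancer type or
#' meta-analysis level).  Positive z means up-regulation in the more
#' adverse phenotype.
#'
#' @param gene character vector of gene symbols (uppercased on ingest;
#'   must be unique).
#' @param z numeric vector of finite signed deviates.
#' @param n_studies integer vector (recycled) of contributing-study
#'   counts, all `>= 1`.
#' @param label provenance string, e.g. `"breast"`, `"level1"`.
#' @return A `signed_z_table`: a data.frame with columns `gene`, `z`,
#'   `n_studies` and a `label` attribute.
#' @examples
#' signed_z_table(c("TP53", "PTEN"), c(2.1, -1.3), 4, label = "breast")
#' @export
signed_z_table <- function(gene, z, n_studies = 1L, label = "") {
  gene <- toupper(as.character(gene))
  z <- as.numeric(z)
  if (length(gene) != length(z)) {
    stop("`gene` and `z` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene symbols: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(z) && any(!is.finite(z))) {
    stop("all z values must be finite", call. = FALSE)
  }
  n_studies <- rep_len(as.integer(n_studies), length(gene))
  if (length(n_studies) && any(n_studies < 1L)) {
    stop("n_studies must be >= 1 for every gene", call. = FALSE)
  }
  out <- data.frame(gene = gene, z = z, n_studies = n_studies,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- as.character(label)
  class(out) <- c("signed_z_table", "data.frame")
  out
}

#' @export
print.signed_z_table <- function(x, ...) {
  cat(sprintf("Signed Z table '%s': %d genes, z in [%.3g, %.3g]\n",
              ztab_label(x), nrow(x),
              if (nrow(x)) min(x$z) else NA, if (nrow(x)) max(x$z) else NA))
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

ztab_label <- function(x) {
  lab <- attr(x, "label", exact = TRUE)
  if (is.null(lab)) "" else lab
}

is_signed_z_table <- function(x) inherits(x, "signed_z_table")

assert_ztab <- function(x, arg = deparse(substitute(x))) {
  if (!is_signed_z_table(x)) {
    stop("`", arg, "` must be a signed_z_table", call. = FALSE)
  }
  invisible(x)
}
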