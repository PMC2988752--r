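# Proof-of-principle and validation statistics: gene-set relative-Z
# enrichment, correlation of Z vectors between tissues, Fisher r-to-z
# comparison of correlations, rank validation against an external
# log-ratio table, and the equal-variance t machinery used for the
# two-group expression matrix.

#' Named gene set
#'
#' @param name set name.
#' @param genes character vector of symbols; uppercased and deduplicated
#'   on ingest, must be nonempty.
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) {
    stop("gene set '", name, "' is empty", call. = FALSE)
  }
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

set_members <- function(table, set) {
  stopifnot(inherits(set, "gene_set"))
  assert_ztab(table)
  intersect(set$genes, table$gene)
}

#' Relative Z score of a gene set
#'
#' The enrichment measure of the multilevel design: mean |z| over the
#' set members present in the table divided by the mean |z| over all
#' genes.  Values above 1 indicate the set carries stronger evidence
#' than the transcriptome-wide background; for a sound pipeline the
#' ratio for genes truly tied to progression should rise from level 1
#' to level 3.
#'
#' @param table a [signed_z_table()].
#' @param set a [gene_set()] intersecting the table.
#' @return list with `ratio`, `mean_set`, `mean_all`, `n_set`.
#' @export
relative_z <- function(table, set) {
  members <- set_members(table, set)
  if (!length(members)) {
    stop("gene set '", set$name, "' does not intersect the table",
         call. = FALSE)
  }
  mean_set <- mean(abs(table$z[match(members, table$gene)]))
  mean_all <- mean(abs(table$z))
  list(ratio = mean_set / mean_all, mean_set = mean_set,
       mean_all = mean_all, n_set = length(members))
}

# Pooled-variance two-sample t.  Zero pooled variance with unequal
# means yields +/-Inf; equal means yield t = 0.
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- mean(x) - mean(y)
  t <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / se
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Equal-variance t-test for gene-set enrichment
#'
#' Compares the absolute deviates of set members against all non-member
#' genes with a pooled-variance two-sample t-test (df = total genes - 2).
#'
#' @inheritParams relative_z
#' @return list with `t`, `df`, `p`, `mean_set`, `mean_rest`, `n_set`.
#' @export
enrichment_ttest <- function(table, set) {
  members <- set_members(table, set)
  in_set <- table$gene %in% members
  if (sum(in_set) < 2L || sum(!in_set) < 2L) {
    stop("need >= 2 member and >= 2 non-member genes", call. = FALSE)
  }
  x <- abs(table$z[in_set]); y <- abs(table$z[!in_set])
  tt <- pooled_t(x, y)
  c(tt, list(mean_set = mean(x), mean_rest = mean(y), n_set = length(x)))
}

#' Pearson correlation of two Z vectors
#'
#' Correlates the signed deviates of two tables over their shared genes
#' — the tissue-similarity check (e.g. breast vs prostate
#' normal-vs-tumor signatures).
#'
#' @param tableA,tableB [signed_z_table()]s sharing at least 3 genes.
#' @return list with `r` and `n` (shared-gene count).
#' @export
pearson_z_correlation <- function(tableA, tableB) {
  assert_ztab(tableA); assert_ztab(tableB)
  shared <- intersect(tableA$gene, tableB$gene)
  if (length(shared) < 3L) stop("need >= 3 shared genes", call. = FALSE)
  r <- cor(tableA$z[match(shared, tableA$gene)],
           tableB$z[match(shared, tableB$gene)])
  list(r = r, n = length(shared))
}

#' Compare two independent correlation coefficients
#'
#' Fisher r-to-z test:
#' \eqn{Z = (\mathrm{atanh}\, r_1 - \mathrm{atanh}\, r_2) /
#'   \sqrt{1/(n_1-3) + 1/(n_2-3)}}.
#' Assumes the two correlations come from independent samples.
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n1,n2 sample sizes, both `> 3`.
#' @return list with `z` and two-sided `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("n must be > 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Spearman rank validation against an external log-ratio table
#'
#' Correlates the ranks of the meta-analysis deviates with the ranks of
#' per-gene expression log-ratios from an independent two-group
#' comparison; ties receive average ranks.
#'
#' @param table a [signed_z_table()].
#' @param per_gene_logratio either a named numeric vector (names = gene
#'   symbols) or a data.frame with columns `gene` and `log_ratio`.
#' @return list with `rho`, `n`, `p`.
#' @export
spearman_rank_validation <- function(table, per_gene_logratio) {
  assert_ztab(table)
  if (is.data.frame(per_gene_logratio)) {
    lr <- stats::setNames(as.numeric(per_gene_logratio$log_ratio),
                          toupper(per_gene_logratio$gene))
  } else {
    lr <- stats::setNames(as.numeric(per_gene_logratio),
                          toupper(names(per_gene_logratio)))
  }
  shared <- intersect(table$gene, names(lr))
  if (length(shared) < 3L) stop("need >= 3 shared genes", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(table$z[match(shared, table$gene)], lr[shared],
             method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), n = length(shared), p = ct$p.value)
}

#' Signed mean Z of externally defined up/down gene sets
#'
#' Computes the signed mean deviate (with standard error) for an
#' external study's up-regulated genes, its down-regulated genes, and
#' all genes — the numerical form of comparing the three Z-score
#' distributions.  Concordance shows as mean_up > mean_all > mean_down.
#'
#' @param table a [signed_z_table()].
#' @param up_set,down_set [gene_set()]s intersecting the table.
#' @return list with `mean_up`, `se_up`, `n_up`, `mean_down`, `se_down`,
#'   `n_down`, `mean_all`, `se_all`.
#' @export
set_mean_z <- function(table, up_set, down_set) {
  up <- set_members(table, up_set)
  down <- set_members(table, down_set)
  if (!length(up) || !length(down)) {
    stop("up/down set does not intersect the table", call. = FALSE)
  }
  stat <- function(z) list(mean = mean(z),
                           se = if (length(z) > 1L)
                             sd(z) / sqrt(length(z)) else NA_real_)
  su <- stat(table$z[match(up, table$gene)])
  sd_ <- stat(table$z[match(down, table$gene)])
  sa <- stat(table$z)
  list(mean_up = su$mean, se_up = su$se, n_up = length(up),
       mean_down = sd_$mean, se_down = sd_$se, n_down = length(down),
       mean_all = sa$mean, se_all = sa$se)
}

#' Per-gene equal-variance t-test on a two-group expression matrix
#'
#' For every gene: pooled-variance two-sample t comparing the case group
#' (first factor level) with the control group, two-sided p-value,
#' log-ratio = case mean - control mean (log-scale intensities), and
#' direction = sign of the log-ratio.  Genes with zero pooled variance
#' get p = 1 with a warning.
#'
#' @param matrix an `expression_matrix` (see
#'   [generate_expression_matrix()]), or a list with `values` and
#'   two-level `groups`.
#' @return data.frame with columns `gene`, `t`, `p_value`, `log_ratio`,
#'   `direction`.
#' @export
per_gene_ttest <- function(matrix) {
  vals <- matrix$values
  groups <- matrix$groups
  stopifnot(is.matrix(vals), nlevels(factor(groups)) == 2L)
  groups <- factor(groups)
  case <- vals[, groups == levels(groups)[1L], drop = FALSE]
  ctrl <- vals[, groups == levels(groups)[2L], drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group", call. = FALSE)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  lr <- m1 - m2
  t <- ifelse(se == 0, 0, lr / se)
  p <- ifelse(se == 0, 1, 2 * pt(abs(t), df = df, lower.tail = FALSE))
  if (any(se == 0)) {
    warning(sum(se == 0), " gene(s) with zero pooled variance: p set to 1")
  }
  data.frame(gene = if (is.null(rownames(vals)))
               sprintf("G%05d", seq_len(nrow(vals))) else rownames(vals),
             t = t, p_value = p, log_ratio = lr,
             direction = ifelse(lr >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` over the m supplied p-values, via [stats::p.adjust()]
#' after range validation.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "bonferroni")
}
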