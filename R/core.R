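# Signed-Z mathematics: p -> Z conversion, Stouffer combination across
# studies, cross-group |Z| balancing, and the linear contrast/average
# operations the three meta-analysis levels are built from.

#' Clamp p-values away from 0 and 1
#'
#' Guards the normal quantile function: p-values of exactly 0 or 1 (as
#' emitted by some DE tools after rounding) would map to infinite
#' deviates.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param eps clamp width; defaults to `1e-15`, which leaves any
#'   realistic p-value untouched.
#' @return `p` clamped into `[eps, 1 - eps]`.
#' @export
clamp_p <- function(p, eps = 1e-15) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Convert a directional p-value to a signed normal deviate
#'
#' An up-regulated gene with p-value p maps to the upper-tail deviate
#' \eqn{z = \Phi^{-1}(1 - p)} (positive for p < 0.5); a down-regulated
#' gene maps to \eqn{z = \Phi^{-1}(p)} (negative for p < 0.5).  The sign
#' therefore encodes the direction of expression change in the more
#' adverse phenotype, and the magnitude the strength of evidence.
#'
#' @param p numeric vector of p-values strictly inside (0, 1); apply
#'   [clamp_p()] first if your source tables contain 0 or 1.
#' @param direction character vector, `"up"` or `"down"` (case
#'   insensitive), recycled against `p`.
#' @return numeric vector of signed deviates.
#' @examples
#' p_to_signed_z(0.05, "up")    #  1.645
#' p_to_signed_z(0.05, "down")  # -1.645
#' @export
p_to_signed_z <- function(p, direction) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p-values must lie strictly inside (0, 1); see clamp_p()",
         call. = FALSE)
  }
  direction <- tolower(as.character(direction))
  if (!all(direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }
  direction <- rep_len(direction, length(p))
  z <- numeric(length(p))
  up <- direction == "up"
  z[up] <- qnorm(p[up], lower.tail = FALSE)
  z[!up] <- qnorm(p[!up])
  z
}

#' Stouffer combination of per-study deviates
#'
#' Combines signed deviates gene-wise across studies with Rosenthal's
#' extension of Stouffer's method: \eqn{Z_i = \sum_j z_{ij} / \sqrt{N_i}},
#' where \eqn{N_i} is the number of studies in which gene i was measured.
#' Genes absent from a study's platform simply do not contribute there,
#' so per-gene N varies under partial platform overlap.
#'
#' @param z_tables a data.frame with columns `gene` and `z`, or a list of
#'   such data.frames (one per study, e.g. from [study_z_table()]).
#' @param label provenance label for the combined table.
#' @return A [signed_z_table()] with one row per gene present in at
#'   least one input; `n_studies` records per-gene N.
#' @export
combine_stouffer <- function(z_tables, label = "combined") {
  if (is.data.frame(z_tables)) z_tables <- list(z_tables)
  if (!length(z_tables)) stop("no study tables supplied", call. = FALSE)
  gene <- unlist(lapply(z_tables, function(t) toupper(as.character(t$gene))),
                 use.names = FALSE)
  z <- unlist(lapply(z_tables, function(t) as.numeric(t$z)),
              use.names = FALSE)
  keep <- is.finite(z)
  if (!all(keep)) {
    warning(sum(!keep), " non-finite deviates dropped before combination")
    gene <- gene[keep]
    z <- z[keep]
  }
  if (!length(gene)) stop("no finite deviates to combine", call. = FALSE)
  f <- factor(gene)
  sums <- rowsum(z, f)               # rows ordered by sorted levels
  n <- tabulate(f, nbins = nlevels(f))
  signed_z_table(levels(f), as.vector(sums) / sqrt(n), n, label = label)
}

#' Equalize average |Z| across groups
#'
#' When different cancer types contribute different numbers of studies,
#' the type with more (or larger) studies dominates any cross-type
#' aggregate.  This adjustment rescales each group's deviates by
#' `target / mean(|Z|_group)`, where the target is the unweighted mean
#' of the per-group mean absolute deviates, so that after adjustment
#' every group has the same average |Z| and contributes equally.
#'
#' @param tables named list of [signed_z_table()]s, one per group
#'   (cancer type); all nonempty.
#' @return list with elements `tables` (adjusted, same names),
#'   `factors` (named numeric, the per-group multipliers) and `target`
#'   (the common post-adjustment mean |Z|).
#' @examples
#' a <- signed_z_table(c("A", "B"), c(1.0, 2.74), label = "breast")
#' b <- signed_z_table(c("A", "B"), c(2.0, -3.7), label = "lung")
#' bal <- balance_groups(list(breast = a, lung = b))
#' round(bal$target, 2)          # 2.36
#' round(bal$factors, 2)         # 1.26, 0.83
#' @export
balance_groups <- function(tables) {
  if (!is.list(tables) || !length(tables)) {
    stop("`tables` must be a nonempty list of signed_z_table", call. = FALSE)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("`tables` must be a named list (one name per group)", call. = FALSE)
  }
  for (t in tables) assert_ztab(t, "tables[[i]]")
  if (any(vapply(tables, nrow, 0L) == 0L)) {
    stop("every group table must be nonempty", call. = FALSE)
  }
  means <- vapply(tables, function(t) mean(abs(t$z)), numeric(1))
  if (any(means == 0)) {
    stop("degenerate group with mean |Z| = 0: ",
         paste(names(tables)[means == 0], collapse = ", "), call. = FALSE)
  }
  target <- mean(means)
  factors <- target / means
  adjusted <- Map(function(t, f) {
    signed_z_table(t$gene, t$z * f, t$n_studies, label = ztab_label(t))
  }, tables, factors)
  list(tables = adjusted, factors = factors, target = target)
}

#' Contrast two signed-Z tables
#'
#' Gene-wise difference `zA - zB`, used to subtract the non-bone
#' signature from the bone signature: the common normal-vs-tumor
#' component cancels and phenotype-specific genes remain.  A difference
#' needs both sides, so by default genes present in only one table are
#' dropped (with a logged count); `policy = "zero_fill"` instead treats
#' the missing side as 0.
#'
#' @param zA,zB [signed_z_table()]s.
#' @param policy missing-gene policy, `"intersect"` (default) or
#'   `"zero_fill"`.
#' @param label provenance label of the result.
#' @return A [signed_z_table()]; `n_studies` is the sum of the inputs'
#'   contributing counts.
#' @export
contrast_tables <- function(zA, zB, policy = c("intersect", "zero_fill"),
                            label = "contrast") {
  assert_ztab(zA); assert_ztab(zB)
  policy <- match.arg(policy)
  if (policy == "intersect") {
    genes <- sort(intersect(zA$gene, zB$gene))
    dropped <- length(union(zA$gene, zB$gene)) - length(genes)
    if (dropped > 0) {
      message("contrast_tables: dropped ", dropped,
              " genes absent from one side")
    }
    ia <- match(genes, zA$gene)
    ib <- match(genes, zB$gene)
    signed_z_table(genes, zA$z[ia] - zB$z[ib],
                   zA$n_studies[ia] + zB$n_studies[ib], label = label)
  } else {
    genes <- sort(union(zA$gene, zB$gene))
    ia <- match(genes, zA$gene)
    ib <- match(genes, zB$gene)
    a <- ifelse(is.na(ia), 0, zA$z[ia])
    b <- ifelse(is.na(ib), 0, zB$z[ib])
    na <- ifelse(is.na(ia), 0L, zA$n_studies[ia])
    nb <- ifelse(is.na(ib), 0L, zB$n_studies[ib])
    signed_z_table(genes, a - b, pmax(na + nb, 1L), label = label)
  }
}

#' Average two signed-Z tables
#'
#' Gene-wise mean `(zX + zY) / 2` — the nesting step of the multilevel
#' design.  Because levels are averaged pairwise and in order, the last
#' table folded in carries weight 1/2 while earlier ones are diluted
#' (three nested averages give weights 1/4, 1/4, 1/2).  Default policy
#' `"carry"` keeps the available value for genes present on only one
#' side, which is how partially overlapping platforms are merged;
#' `"intersect"` restricts to shared genes.
#'
#' @inheritParams contrast_tables
#' @param zX,zY [signed_z_table()]s.
#' @return A [signed_z_table()].
#' @export
average_tables <- function(zX, zY, policy = c("carry", "intersect"),
                           label = "average") {
  assert_ztab(zX); assert_ztab(zY)
  policy <- match.arg(policy)
  if (policy == "intersect") {
    genes <- sort(intersect(zX$gene, zY$gene))
    zX <- signed_z_table(genes, zX$z[match(genes, zX$gene)],
                         zX$n_studies[match(genes, zX$gene)],
                         label = ztab_label(zX))
    zY <- signed_z_table(genes, zY$z[match(genes, zY$gene)],
                         zY$n_studies[match(genes, zY$gene)],
                         label = ztab_label(zY))
  }
  pool_mean_tables(list(zX, zY), label = label)
}

# Gene-wise mean over a list of tables, carrying values for genes
# missing from some tables; n_studies summed over contributors.
pool_mean_tables <- function(tables, label = "pooled") {
  stopifnot(length(tables) >= 1L)
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"),
                              use.names = FALSE)))
  zmat <- vapply(tables, function(t) t$z[match(genes, t$gene)],
                 numeric(length(genes)))
  nmat <- vapply(tables, function(t) t$n_studies[match(genes, t$gene)],
                 integer(length(genes)))
  if (length(genes) == 1L) {
    zmat <- matrix(zmat, nrow = 1L)
    nmat <- matrix(nmat, nrow = 1L)
  }
  z <- rowMeans(zmat, na.rm = TRUE)
  n <- as.integer(rowSums(nmat, na.rm = TRUE))
  signed_z_table(genes, z, n, label = label)
}
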