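# Orchestration of the three meta-analysis levels:
#   level 1  bone-vs-non-bone contrast of normal-vs-tumor signatures
#   level 2  average with the prostate normal-vs-localized meta-table
#   level 3  average with the localized-vs-metastatic meta-table
# The pairwise nesting gives effective weights 1/4, 1/4, 1/2 to the
# three components for genes present everywhere, deliberately
# up-weighting the metastasis comparison.

# Stouffer-combine one cancer type's studies into a per-type table.
combine_type <- function(studies, label) {
  combine_stouffer(lapply(studies, study_z_table), label = label)
}

split_by_type <- function(studies) {
  types <- vapply(studies, function(s) s$cancer_type, character(1))
  split(studies, types)
}

#' Level 1: bone vs non-bone metastasizing cancers
#'
#' Per cancer type, converts each study's p-values to signed deviates
#' and Stouffer-combines them; balances average |Z| across all cancer
#' types jointly (one common target, so no single type dominates); takes
#' the unweighted mean of the adjusted per-type tables within each side;
#' and returns the bone-minus-non-bone contrast.  The subtraction
#' removes the normal-vs-tumor component common to all carcinomas and
#' leaves the bone-metastasis-specific signal.
#'
#' @param bone_studies list of [study_summary()]s from bone-metastasizing
#'   cancers (grouped internally by their `cancer_type`).
#' @param nonbone_studies list of [study_summary()]s from
#'   non-bone-metastasizing cancers.
#' @param contrast_policy missing-gene policy for [contrast_tables()].
#' @return A [signed_z_table()] labelled `"level1"`, with attributes
#'   `factors` (per-type adjustment multipliers) and `target` (the
#'   common mean |Z|) from [balance_groups()].
#' @export
run_level1 <- function(bone_studies, nonbone_studies,
                       contrast_policy = "intersect") {
  if (!length(bone_studies) || !length(nonbone_studies)) {
    stop("configuration error: need >= 1 study on each side", call. = FALSE)
  }
  bone_by_type <- split_by_type(bone_studies)
  nonbone_by_type <- split_by_type(nonbone_studies)
  shared <- intersect(names(bone_by_type), names(nonbone_by_type))
  if (length(shared)) {
    stop("cancer type(s) on both sides: ", paste(shared, collapse = ", "),
         call. = FALSE)
  }
  type_tables <- c(
    lapply(names(bone_by_type), function(ty)
      combine_type(bone_by_type[[ty]], label = ty)),
    lapply(names(nonbone_by_type), function(ty)
      combine_type(nonbone_by_type[[ty]], label = ty))
  )
  names(type_tables) <- c(names(bone_by_type), names(nonbone_by_type))
  bal <- balance_groups(type_tables)
  bone_tab <- pool_mean_tables(bal$tables[names(bone_by_type)],
                               label = "bone")
  nonbone_tab <- pool_mean_tables(bal$tables[names(nonbone_by_type)],
                                  label = "nonbone")
  res <- contrast_tables(bone_tab, nonbone_tab, policy = contrast_policy,
                         label = "level1")
  attr(res, "factors") <- bal$factors
  attr(res, "target") <- bal$target
  res
}

#' Level 2: fold in the prostate normal-vs-localized comparison
#'
#' Stouffer-combines the prostate normal-vs-tumor studies into one
#' meta-table (no cross-type balancing: a single tissue) and averages it
#' gene-wise with the level-1 contrast.
#'
#' @param level1 the [run_level1()] table.
#' @param prostate_nt_studies list of prostate normal-vs-tumor
#'   [study_summary()]s.
#' @param average_policy missing-gene policy for [average_tables()].
#' @return A [signed_z_table()] labelled `"level2"`.
#' @export
run_level2 <- function(level1, prostate_nt_studies,
                       average_policy = "carry") {
  if (!length(prostate_nt_studies)) {
    stop("configuration error: need >= 1 prostate normal-vs-tumor study",
         call. = FALSE)
  }
  prost <- combine_type(prostate_nt_studies, label = "prostate_nt")
  average_tables(level1, prost, policy = average_policy, label = "level2")
}

#' Level 3: fold in the localized-vs-metastatic comparison
#'
#' Stouffer-combines the localized-vs-metastatic prostate studies and
#' averages the result with the level-2 table.  Because this is the last
#' pairwise average, the metastasis comparison carries effective weight
#' 1/2 in the final score — the intended up-weighting of the most
#' progression-specific evidence.
#'
#' @param level2 the [run_level2()] table.
#' @param loc_vs_met_studies list of localized-vs-metastatic
#'   [study_summary()]s.
#' @inheritParams run_level2
#' @return A [signed_z_table()] labelled `"level3"`.
#' @export
run_level3 <- function(level2, loc_vs_met_studies,
                       average_policy = "carry") {
  if (!length(loc_vs_met_studies)) {
    stop("configuration error: need >= 1 localized-vs-metastatic study",
         call. = FALSE)
  }
  met <- combine_type(loc_vs_met_studies, label = "loc_vs_met")
  average_tables(level2, met, policy = average_policy, label = "level3")
}

#' Rank candidate genes from a signed-Z table
#'
#' @param table a [signed_z_table()] (typically level 3).
#' @param k list length; defaults to 250 top up- and 250 top
#'   down-regulated candidates (truncated to the available gene count).
#' @return list with data.frames `top_up` (k largest z, descending) and
#'   `top_down` (k smallest z, ascending); ties are broken by gene
#'   symbol so rankings are reproducible.
#' @export
rank_candidates <- function(table, k = 250) {
  assert_ztab(table)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  kk <- min(k, nrow(table))
  ord_up <- order(-table$z, table$gene)
  ord_down <- order(table$z, table$gene)
  up <- data.frame(gene = table$gene[ord_up], z = table$z[ord_up],
                   stringsAsFactors = FALSE)[seq_len(kk), , drop = FALSE]
  down <- data.frame(gene = table$gene[ord_down], z = table$z[ord_down],
                     stringsAsFactors = FALSE)[seq_len(kk), , drop = FALSE]
  rownames(up) <- rownames(down) <- NULL
  list(top_up = up, top_down = down)
}

resolve_studies <- function(x, role) {
  if (!length(x)) {
    stop("configuration error: missing studies for role '", role, "'",
         call. = FALSE)
  }
  lapply(x, function(s) {
    if (inherits(s, "study_summary")) s
    else if (is.character(s) && length(s) == 1L) read_study_tsv(s)
    else stop("role '", role,
              "': entries must be study_summary objects or file paths",
              call. = FALSE)
  })
}

#' Run the full three-level meta-analysis
#'
#' @param config list with element `studies`, itself a named list with
#'   roles `bone`, `nonbone`, `prostate_normal_vs_tumor` and
#'   `localized_vs_metastatic`; each role holds [study_summary()]
#'   objects and/or paths to study TSV files.  Optional elements: `k`
#'   (candidate list size, default 250), `contrast_policy`,
#'   `average_policy`.
#' @return A `meta_run_result`: list with the three level tables, the
#'   per-type balancing `factors_by_group` and `balance_target`, the
#'   ranked `top_up`/`top_down` lists, and `config_echo`.  Deterministic
#'   given the inputs (no randomness in the pipeline itself).
#' @export
run_pipeline <- function(config) {
  roles <- c("bone", "nonbone", "prostate_normal_vs_tumor",
             "localized_vs_metastatic")
  studies <- config$studies
  for (role in roles) {
    if (is.null(studies[[role]]) || !length(studies[[role]])) {
      stop("configuration error: missing studies for role '", role, "'",
           call. = FALSE)
    }
  }
  st <- lapply(stats::setNames(roles, roles),
               function(r) resolve_studies(studies[[r]], r))
  k <- if (is.null(config$k)) 250L else as.integer(config$k)
  cp <- if (is.null(config$contrast_policy)) "intersect" else
    config$contrast_policy
  ap <- if (is.null(config$average_policy)) "carry" else
    config$average_policy

  level1 <- run_level1(st$bone, st$nonbone, contrast_policy = cp)
  level2 <- run_level2(level1, st$prostate_normal_vs_tumor,
                       average_policy = ap)
  level3 <- run_level3(level2, st$localized_vs_metastatic,
                       average_policy = ap)
  ranked <- rank_candidates(level3, k = k)
  message(sprintf(
    "pipeline: level1 %d genes, level2 %d, level3 %d; k = %d",
    nrow(level1), nrow(level2), nrow(level3), k))
  structure(list(level1 = level1, level2 = level2, level3 = level3,
                 factors_by_group = attr(level1, "factors"),
                 balance_target = attr(level1, "target"),
                 top_up = ranked$top_up, top_down = ranked$top_down,
                 config_echo = config[setdiff(names(config), "studies")]),
            class = "meta_run_result")
}

#' @export
print.meta_run_result <- function(x, ...) {
  cat(sprintf(
    "Three-level meta-analysis: %d genes at level 3; %d + %d candidates\n",
    nrow(x$level3), nrow(x$top_up), nrow(x$top_down)))
  cat("Balancing factors:",
      paste(names(x$factors_by_group),
            sprintf("%.3f", x$factors_by_group), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
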