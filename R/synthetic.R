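# Synthetic multi-study generator.  Emulates the kind of evidence the
# meta-analysis consumes -- per-study p-value/direction tables from
# two-group comparisons on partially overlapping platforms, a gene
# interaction network with planted hubs, and small two-group expression
# matrices -- with full ground truth, so every downstream stage can be
# benchmarked without external downloads.

BONE_TYPES <- c("breast", "lung", "prostate")

#' Ground truth for a synthetic experiment
#'
#' Plants signed standardized-mean-difference effects for three
#' biological components, on disjoint gene sets:
#' * `"tumor"` — shared normal-vs-tumor signature of every cancer type
#'   (cancelled by the level-1 subtraction);
#' * `"bone"` — signature specific to bone-metastasizing cancers
#'   (breast, lung, prostate), active in their normal-vs-tumor studies;
#' * `"metastasis"` — localized-vs-metastatic prostate signature.
#'
#' Within each component half the planted genes are up- and half
#' down-regulated (odd counts resolve toward up).  Hub genes are drawn
#' from the metastasis-planted genes when possible, mimicking drivers
#' sitting inside the progression signature.
#'
#' @param n_genes gene-universe size.
#' @param n_effect_per_contrast planted genes per component.
#' @param effect_size_mean mean planted |effect| (standardized mean
#'   difference, unitless).
#' @param n_hubs number of planted network hubs.
#' @param seed integer seed (required; the object is deterministic in it).
#' @param effect_size_sd spread of planted |effect| around the mean
#'   (default 0: all planted effects have the same magnitude).
#' @return A `synthetic_truth`: list with `gene_ids`, `effect` (named
#'   list of full-length named numeric vectors, one per component;
#'   unplanted genes are exactly 0), `hub_genes`, `seed`.
#' @export
generate_truth <- function(n_genes = 10000, n_effect_per_contrast = 100,
                           effect_size_mean = 1.0, n_hubs = 10, seed,
                           effect_size_sd = 0) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_genes <- as.integer(n_genes)
  n_eff <- as.integer(n_effect_per_contrast)
  n_hubs <- as.integer(n_hubs)
  if (n_genes < 1L || n_eff < 0L || n_hubs < 0L) {
    stop("counts must be non-negative (n_genes >= 1)", call. = FALSE)
  }
  contrasts <- c("tumor", "bone", "metastasis")
  if (3L * n_eff > n_genes) {
    stop("n_effect_per_contrast too large for disjoint planting",
         call. = FALSE)
  }
  if (n_hubs > n_genes) stop("n_hubs exceeds n_genes", call. = FALSE)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  withr::with_seed(as.integer(seed), {
    planted <- if (n_eff > 0L) sample(gene_ids, 3L * n_eff) else character(0)
    effect <- lapply(seq_along(contrasts), function(k) {
      e <- stats::setNames(numeric(n_genes), gene_ids)
      if (n_eff > 0L) {
        g <- planted[((k - 1L) * n_eff + 1L):(k * n_eff)]
        n_up <- ceiling(n_eff / 2)
        signs <- c(rep(1, n_up), rep(-1, n_eff - n_up))
        mag <- effect_size_mean + effect_size_sd * rnorm(n_eff)
        mag <- pmax(mag, 0.05)  # keep planted effects bounded away from 0
        e[g] <- signs * mag
      }
      e
    })
    names(effect) <- contrasts
    hub_pool <- names(which(effect$metastasis != 0))
    if (length(hub_pool) < n_hubs) {
      hub_pool <- union(hub_pool,
                        names(which(Reduce(`+`, lapply(effect, abs)) != 0)))
    }
    if (length(hub_pool) < n_hubs) hub_pool <- gene_ids
    hubs <- if (n_hubs > 0L) sort(sample(hub_pool, n_hubs)) else character(0)
  })

  structure(list(gene_ids = gene_ids, effect = effect, hub_genes = hubs,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  n_planted <- vapply(x$effect, function(e) sum(e != 0), 0L)
  cat(sprintf("Synthetic truth: %d genes; planted per component: %s; %d hubs (seed %d)\n",
              length(x$gene_ids),
              paste(names(n_planted), n_planted, sep = "=", collapse = ", "),
              length(x$hub_genes), x$seed))
  invisible(x)
}

#' Describe one synthetic study
#'
#' @param study_id identifier string.
#' @param cancer_type one of breast, lung, colon, ovarian, prostate (any
#'   string accepted; breast/lung/prostate count as bone-metastasizing).
#' @param contrast `"normal_vs_tumor"` or `"localized_vs_metastatic"`.
#' @param n1,n2 group sample sizes, both `>= 2`.
#' @param platform_fraction fraction of the gene universe measured by
#'   this study's platform, in (0, 1].
#' @return A `study_design` list.
#' @export
study_design <- function(study_id, cancer_type,
                         contrast = c("normal_vs_tumor",
                                      "localized_vs_metastatic"),
                         n1, n2, platform_fraction = 1) {
  contrast <- match.arg(contrast)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 2L || n2 < 2L) stop("n1 and n2 must be >= 2", call. = FALSE)
  if (!(platform_fraction > 0 && platform_fraction <= 1)) {
    stop("platform_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(list(study_id = as.character(study_id),
                 cancer_type = tolower(as.character(cancer_type)),
                 contrast = contrast, n1 = n1, n2 = n2,
                 platform_fraction = platform_fraction),
            class = "study_design")
}

# Which planted components act in a given study design.
effect_for_design <- function(truth, design) {
  if (design$contrast == "normal_vs_tumor") {
    e <- truth$effect$tumor
    if (design$cancer_type %in% BONE_TYPES) e <- e + truth$effect$bone
    e
  } else {
    truth$effect$metastasis
  }
}

#' Simulate one study's differential-expression summary
#'
#' Draws, for each gene on the study's platform (a seeded uniform
#' subsample of `round(platform_fraction * n_genes)` genes), a two-sample
#' t-statistic from the noncentral t distribution with noncentrality
#' `effect * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of
#' freedom, and reports the two-sided p-value plus the direction implied
#' by the statistic's sign (a statistic of exactly 0 counts as "up").
#' Larger samples therefore sharpen p-values for the same effect, and
#' off-platform genes are absent from the table, just as in real
#' cross-platform collections.
#'
#' @param truth a [generate_truth()] object.
#' @param design a [study_design()].
#' @param seed integer seed for this study's draws.
#' @return A [study_summary()].
#' @export
simulate_study <- function(truth, design, seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(design, "study_design"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_genes <- length(truth$gene_ids)
  m <- max(1L, round(design$platform_fraction * n_genes))
  df <- design$n1 + design$n2 - 2L
  ncp_scale <- sqrt(design$n1 * design$n2 / (design$n1 + design$n2))
  withr::with_seed(as.integer(seed), {
    platform <- sort(sample(truth$gene_ids, m))
    ncp <- effect_for_design(truth, design)[platform] * ncp_scale
    tstat <- rt(m, df = df, ncp = ncp)
    p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
    direction <- ifelse(tstat >= 0, "up", "down")
  })
  study_summary(study_id = design$study_id,
                cancer_type = design$cancer_type,
                contrast = design$contrast,
                gene = platform, p_value = p, direction = direction,
                n1 = design$n1, n2 = design$n2)
}

#' Default synthetic study collection
#'
#' The study-count structure mirrors the multi-study design the method
#' was built for: 4 breast and 9 lung normal-vs-tumor studies on the
#' bone-metastasizing side, 5 colon and 5 ovarian on the non-bone side,
#' 11 prostate normal-vs-localized studies, and 7 prostate
#' localized-vs-metastatic studies (prostate group sizes follow the
#' published study roster; other sample sizes are realistic invented
#' values).  Platform fractions cycle through 0.7–1.0 to emulate
#' partially overlapping array designs.
#'
#' @return Named list of [study_design()] lists by role: `bone`,
#'   `nonbone`, `prostate_normal_vs_tumor`, `localized_vs_metastatic`.
#' @export
default_study_designs <- function() {
  pf <- function(i) c(1, 0.85, 0.9, 0.7, 0.95, 0.8, 0.75, 1, 0.9)[(i - 1) %% 9 + 1]
  mk <- function(prefix, type, contrast, sizes) {
    lapply(seq_along(sizes), function(i) {
      study_design(sprintf("%s_%02d", prefix, i), type, contrast,
                   n1 = sizes[[i]][1], n2 = sizes[[i]][2],
                   platform_fraction = pf(i))
    })
  }
  nt <- "normal_vs_tumor"
  list(
    bone = c(
      mk("breast", "breast", nt,
         list(c(20, 40), c(13, 27), c(7, 36), c(30, 30))),
      mk("lung", "lung", nt,
         list(c(17, 86), c(10, 58), c(24, 24), c(15, 45), c(30, 60),
              c(8, 20), c(20, 39), c(12, 32), c(25, 50)))
    ),
    nonbone = c(
      mk("colon", "colon", nt,
         list(c(22, 25), c(10, 40), c(18, 18), c(9, 27), c(25, 36))),
      mk("ovarian", "ovarian", nt,
         list(c(4, 42), c(15, 30), c(8, 24), c(19, 37), c(10, 28)))
    ),
    prostate_normal_vs_tumor = mk("prostate_nt", "prostate", nt,
      list(c(22, 59), c(12, 25), c(4, 23), c(41, 62), c(9, 16), c(3, 22),
           c(22, 30), c(8, 27), c(6, 7), c(9, 25), c(23, 64))),
    localized_vs_metastatic = mk("prostate_met", "prostate",
      "localized_vs_metastatic",
      list(c(59, 20), c(25, 6), c(30, 19), c(64, 25), c(27, 5), c(23, 9),
           c(23, 9)))
  )
}

#' Simulate a whole study collection
#'
#' Fans one master seed out across studies with a counter-based scheme,
#' so each study has its own reproducible stream regardless of
#' evaluation order.
#'
#' @param truth a [generate_truth()] object.
#' @param designs named list of design lists by role, as returned by
#'   [default_study_designs()].
#' @param seed master integer seed.
#' @return Named list (same roles) of lists of [study_summary()]s.
#' @export
simulate_study_collection <- function(truth,
                                      designs = default_study_designs(),
                                      seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  counter <- 0L
  lapply(designs, function(role_designs) {
    lapply(role_designs, function(d) {
      counter <<- counter + 1L
      simulate_study(truth, d, seed = derive_seed(seed, counter))
    })
  })
}

#' Generate a gene interaction network with planted hubs
#'
#' Builds an undirected simple graph over the truth's gene universe.
#' Each planted hub is wired to at least `hub_degree_min` partners,
#' drawn preferentially from the planted-effect genes — the picture of
#' driver genes regulating the members of the expression signature — and
#' `n_background_edges` further edges are placed uniformly at random.
#'
#' @param truth a [generate_truth()] object.
#' @param n_background_edges number of uniform background edges.
#' @param hub_degree_min minimum degree guaranteed to each planted hub.
#' @param seed integer seed.
#' @return An [igraph::igraph] undirected simple graph whose vertex
#'   names are the gene symbols (isolated genes included as vertices).
#' @export
generate_interactome <- function(truth, n_background_edges = 20000,
                                 hub_degree_min = 10, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  hub_degree_min <- as.integer(hub_degree_min)
  if (hub_degree_min < 1L) stop("hub_degree_min must be >= 1", call. = FALSE)
  n_background_edges <- as.integer(n_background_edges)
  if (n_background_edges < 0L) {
    stop("n_background_edges must be non-negative", call. = FALSE)
  }
  genes <- truth$gene_ids
  n <- length(genes)
  capacity <- n * (n - 1) / 2
  if (n_background_edges + length(truth$hub_genes) * hub_degree_min >
      capacity) {
    stop("requested edges exceed simple-graph capacity", call. = FALSE)
  }

  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  planted <- names(which(Reduce(`+`, lapply(truth$effect, abs)) != 0))

  withr::with_seed(as.integer(seed), {
    from <- character(0); to <- character(0); keys <- character(0)
    for (h in truth$hub_genes) {
      pool <- setdiff(planted, h)
      if (length(pool) < hub_degree_min) {
        pool <- c(pool, setdiff(genes, c(pool, h)))
      }
      # exclude partners already adjacent to h from earlier hub wiring
      pool <- pool[!(edge_key(h, pool) %in% keys)]
      deg_h <- sum(from == h | to == h)
      need <- hub_degree_min - deg_h
      if (need > 0L) {
        partners <- sample(pool, need)
        from <- c(from, rep(h, need)); to <- c(to, partners)
        keys <- c(keys, edge_key(h, partners))
      }
    }
    added <- 0L
    while (added < n_background_edges) {
      k <- ceiling((n_background_edges - added) * 1.3) + 8L
      a <- genes[sample.int(n, k, replace = TRUE)]
      b <- genes[sample.int(n, k, replace = TRUE)]
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      kk <- edge_key(a, b)
      ok <- !duplicated(kk) & !(kk %in% keys)
      a <- a[ok]; b <- b[ok]; kk <- kk[ok]
      take <- seq_len(min(length(a), n_background_edges - added))
      from <- c(from, a[take]); to <- c(to, b[take])
      keys <- c(keys, kk[take])
      added <- added + length(take)
    }
  })

  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = genes)
}

#' Generate a two-group expression matrix
#'
#' Genes-by-samples matrix of independent normal deviates with the
#' planted effect added to the case group — a stand-in for a normalized
#' log-intensity matrix from a case-control profiling experiment (the
#' defaults, 9 cases vs 5 controls, mirror an advanced-cancer vs benign
#' hyperplasia comparison).
#'
#' @param truth a [generate_truth()] object.
#' @param contrast character vector of effect components to sum into the
#'   case-group shift; default all three (an advanced tumor carries the
#'   whole signature).
#' @param n_case,n_control group sizes, both `>= 2`.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return An `expression_matrix`: list with `values` (genes x samples
#'   numeric matrix, rownames = gene symbols) and `groups` (factor with
#'   the case level first).
#' @export
generate_expression_matrix <- function(truth,
                                       contrast = c("tumor", "bone",
                                                    "metastasis"),
                                       n_case = 9, n_control = 5,
                                       noise_sd = 1, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  if (n_case < 2L || n_control < 2L) {
    stop("n_case and n_control must be >= 2", call. = FALSE)
  }
  bad <- setdiff(contrast, names(truth$effect))
  if (length(bad)) {
    stop("unknown effect component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  shift <- Reduce(`+`, truth$effect[contrast])
  n_genes <- length(truth$gene_ids)
  withr::with_seed(as.integer(seed), {
    vals <- matrix(rnorm(n_genes * (n_case + n_control), sd = noise_sd),
                   nrow = n_genes)
  })
  vals[, seq_len(n_case)] <- vals[, seq_len(n_case)] + shift
  rownames(vals) <- truth$gene_ids
  colnames(vals) <- c(sprintf("CASE_%02d", seq_len(n_case)),
                      sprintf("CTRL_%02d", seq_len(n_control)))
  groups <- factor(rep(c("case", "control"), c(n_case, n_control)),
                   levels = c("case", "control"))
  structure(list(values = vals, groups = groups),
            class = "expression_matrix")
}
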