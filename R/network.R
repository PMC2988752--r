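# Interaction-network hub nomination.  Networks are undirected simple
# igraph graphs with gene symbols as vertex names; directionality of
# the underlying interactions (regulation, binding) is collapsed since
# the hub criterion does not use it.

#' Induce the subnetwork of a candidate gene list
#'
#' Restricts the interactome to the supplied genes and keeps only those
#' with at least one interaction inside the list — the "genes that form
#' the network" among the top candidates.
#'
#' @param net an undirected [igraph::igraph] with named vertices.
#' @param genes character vector of gene symbols.
#' @return induced [igraph::igraph] with isolated vertices removed.
#' @export
induce_subnetwork <- function(net, genes) {
  stopifnot(igraph::is_igraph(net))
  keep <- intersect(toupper(as.character(genes)), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, keep)
  igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
}

#' Select hub genes by degree and connectivity ratio
#'
#' A gene is nominated as a hub when (a) it interacts with at least
#' `min_degree` other genes inside the candidate subnetwork and (b) its
#' local connectivity is at least `ratio_threshold` times its overall
#' connectivity.  Connectivity is normalized as edge density:
#' `degree / (network size - 1)` in the subnetwork vs the full
#' interactome (`normalization = "density"`, the default), so the two
#' scales are comparable; `normalization = "degree"` uses the raw
#' degree ratio instead.
#'
#' @param sub the candidate subnetwork (a subgraph of `full`, e.g. from
#'   [induce_subnetwork()]); must have at least 2 vertices.
#' @param full the full interactome.
#' @param min_degree minimum subnetwork degree (default 5).
#' @param ratio_threshold minimum local/overall connectivity ratio
#'   (default 2).
#' @param normalization `"density"` or `"degree"`.
#' @return data.frame of selected hubs, sorted by subnetwork degree
#'   (descending, ties by symbol): columns `gene`, `degree_sub`,
#'   `degree_full`, `local_connectivity`, `overall_connectivity`,
#'   `ratio`.
#' @export
select_hubs <- function(sub, full, min_degree = 5, ratio_threshold = 2,
                        normalization = c("density", "degree")) {
  stopifnot(igraph::is_igraph(sub), igraph::is_igraph(full))
  normalization <- match.arg(normalization)
  if (igraph::vcount(sub) < 2L) {
    stop("subnetwork must have >= 2 vertices", call. = FALSE)
  }
  genes <- igraph::V(sub)$name
  if (!all(genes %in% igraph::V(full)$name)) {
    stop("subnetwork vertices must all belong to the full network",
         call. = FALSE)
  }
  deg_s <- igraph::degree(sub)
  deg_f <- igraph::degree(full)[genes]
  if (normalization == "density") {
    local <- deg_s / (igraph::vcount(sub) - 1L)
    overall <- deg_f / (igraph::vcount(full) - 1L)
  } else {
    local <- deg_s
    overall <- deg_f
  }
  ratio <- ifelse(overall == 0, ifelse(local == 0, 0, Inf),
                  local / overall)
  keep <- deg_s >= min_degree & ratio >= ratio_threshold
  out <- data.frame(gene = genes, degree_sub = as.integer(deg_s),
                    degree_full = as.integer(deg_f),
                    local_connectivity = local,
                    overall_connectivity = unname(overall),
                    ratio = unname(ratio),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-out$degree_sub, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benchmark hub selection against planted truth
#'
#' @param truth a [generate_truth()] object with planted hubs.
#' @param hubs character vector of selected hub symbols, or the
#'   data.frame returned by [select_hubs()].
#' @return list with `precision`, `recall`, `n_selected`, `n_planted`,
#'   and `precision_defined` (FALSE when nothing was selected, in which
#'   case precision is reported as 0).
#' @export
hub_recovery_report <- function(truth, hubs) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.data.frame(hubs)) hubs <- hubs$gene
  hubs <- unique(toupper(as.character(hubs)))
  planted <- truth$hub_genes
  if (!length(planted)) stop("truth has no planted hubs", call. = FALSE)
  tp <- length(intersect(hubs, planted))
  defined <- length(hubs) > 0L
  list(precision = if (defined) tp / length(hubs) else 0,
       recall = tp / length(planted),
       n_selected = length(hubs), n_planted = length(planted),
       precision_defined = defined)
}

#' Read / write interaction edge lists
#'
#' Two-column tab-separated edge lists.  The reader enforces what the
#' writer guarantees: no self-loops and no duplicate (undirected) edges.
#'
#' @param path file path.
#' @param nodes optional full vertex set (so isolated genes survive a
#'   round trip).
#' @return [read_edge_tsv()]: an undirected [igraph::igraph];
#'   [write_edge_tsv()]: the path, invisibly.
#' @export
read_edge_tsv <- function(path, nodes = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2L) stop("edge list needs two columns", call. = FALSE)
  a <- toupper(df[[1L]]); b <- toupper(df[[2L]])
  if (any(a == b)) stop("self-loop(s) in edge list", call. = FALSE)
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) {
    stop("duplicate undirected edge(s) in edge list", call. = FALSE)
  }
  verts <- if (is.null(nodes)) sort(unique(c(a, b))) else
    toupper(as.character(nodes))
  igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                directed = FALSE, vertices = verts)
}

#' @rdname read_edge_tsv
#' @param net an undirected [igraph::igraph].
#' @export
write_edge_tsv <- function(net, path) {
  stopifnot(igraph::is_igraph(net))
  df <- igraph::as_data_frame(net, what = "edges")[, c("from", "to")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
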