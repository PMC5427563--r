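#' Count unordered protein pairs
#'
#' Bookkeeping for all-against-all enumeration: the number of distinct
#' unordered pairs among `n` proteins, n(n-1)/2, optionally including
#' self-pairs (then n(n+1)/2).
#'
#' @param n number of proteins.
#' @param include_self include self-pairs (default FALSE).
#' @return pair count (numeric, exact for n below ~9e7).
#' @export
count_pairs <- function(n, include_self = FALSE) {
  stopifnot(n >= 0)
  n <- as.numeric(n)
  if (include_self) n * (n + 1) / 2 else n * (n - 1) / 2
}

#' Build a PPI network from predicted pairs
#'
#' Assembles an undirected simple graph: duplicate pairs (in either order)
#' collapse to one edge and self-pairs are skipped with a warning count.
#'
#' @param predicted_pairs data.frame with columns `protein_a`, `protein_b`
#'   (or a two-column matrix).
#' @param nodes optional full node set (ids without any edge are kept as
#'   isolated nodes).
#' @return an `igraph` graph.
#' @export
build_network <- function(predicted_pairs, nodes = NULL) {
  m <- as.matrix(predicted_pairs[, 1:2])
  mode(m) <- "character"
  self <- m[, 1] == m[, 2]
  if (any(self)) {
    warning(sum(self), " self-pair(s) skipped")
    m <- m[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(m, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(nodes)) {
    extra <- setdiff(as.character(nodes), igraph::V(g)$name)
    if (length(extra) > 0) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  g
}

#' Topology metrics of a PPI network
#'
#' Mean degree (2|E|/|V|), diameter of the largest connected component
#' (unweighted shortest paths), and the mean local clustering coefficient
#' over all nodes (nodes of degree < 2 contribute 0, the Watts-Strogatz
#' convention). The global transitivity is also reported.
#'
#' @param net an `igraph` graph (>= 1 node).
#' @return list of class `network_metrics`: `mean_degree`, `diameter`,
#'   `mean_clustering_coefficient`, `global_transitivity`, `n_nodes`,
#'   `n_edges`.
#' @export
network_metrics <- function(net) {
  nv <- igraph::vcount(net)
  if (nv == 0L) stop("empty graph")
  ne <- igraph::ecount(net)
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  diam <- if (igraph::vcount(sub) >= 2L) igraph::diameter(sub, weights = NA) else 0
  cc <- igraph::transitivity(net, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) cc <- 0
  structure(list(mean_degree = 2 * ne / nv,
                 diameter = diam,
                 mean_clustering_coefficient = cc,
                 global_transitivity = {
                   gt <- igraph::transitivity(net, type = "global")
                   if (is.nan(gt)) 0 else gt
                 },
                 n_nodes = nv, n_edges = ne),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> %d nodes, %d edges | mean degree %.2f, diameter %d, mean clustering %.3f\n",
    x$n_nodes, x$n_edges, x$mean_degree, x$diameter,
    x$mean_clustering_coefficient))
  invisible(x)
}

#' Uniform random simple graph with fixed node and edge counts
#'
#' G(n, m) null model: `n_edges` edges assigned uniformly at random to
#' distinct node pairs — the same-nodes-same-edges random network used for
#' topology comparison.
#'
#' @param n_nodes,n_edges graph size; `n_edges <= n_nodes*(n_nodes-1)/2`.
#' @param seed integer seed.
#' @return an `igraph` graph with nodes named "n1".."nN".
#' @export
random_network <- function(n_nodes, n_edges, seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("n_edges exceeds the simple-graph maximum")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- igraph::sample_gnm(n_nodes, n_edges, directed = FALSE, loops = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n_nodes))
  g
}

#' Overlay reference interactions onto a predicted network
#'
#' Labels each edge of the union of predicted and reference edge sets:
#' predicted-and-reference edges are true positives, predicted-only edges
#' are positive predictions, reference-only edges are false negatives.
#'
#' @param net predicted network (`igraph`) or a pairs data.frame.
#' @param reference_edges data.frame with two id columns.
#' @return list with `labels` (data.frame: protein_a, protein_b, label) and
#'   `summary` (named counts).
#' @export
overlay_reference <- function(net, reference_edges) {
  pred <- if (inherits(net, "igraph")) {
    e <- igraph::as_edgelist(net)
    if (nrow(e) == 0) matrix(character(0), ncol = 2) else e
  } else {
    as.matrix(net[, 1:2])
  }
  ref <- as.matrix(reference_edges[, 1:2])
  canon <- function(m) {
    if (nrow(m) == 0) return(character(0))
    unique(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "\r"))
  }
  kp <- canon(pred); kr <- canon(ref)
  tp <- intersect(kp, kr)
  pp <- setdiff(kp, kr)
  fn <- setdiff(kr, kp)
  unkey <- function(keys, label) {
    if (length(keys) == 0) {
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        label = character(0)))
    }
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(protein_a = parts[, 1], protein_b = parts[, 2], label = label)
  }
  labels <- rbind(unkey(tp, "true_positive"),
                  unkey(pp, "positive_prediction"),
                  unkey(fn, "false_negative"))
  list(labels = labels,
       summary = c(true_positive = length(tp),
                   positive_prediction = length(pp),
                   false_negative = length(fn)))
}

#' Hive-plot axis grouping and ordering
#'
#' Assigns each node to a degree axis — low (d < 50), medium (50 <= d <= 80)
#' or high (d > 80) — and orders nodes within an axis by ascending local
#' clustering coefficient (ties broken by node id).
#'
#' @param net an `igraph` graph.
#' @param low_max,high_min degree-bin boundaries (defaults 50 and 80; a
#'   degree equal to `low_max` is medium, equal to `high_min` is medium).
#' @return data.frame: node, degree, clustering, axis, order (1-based
#'   within axis).
#' @export
hive_groups <- function(net, low_max = 50, high_min = 80) {
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  nodes <- if (!is.null(igraph::V(net)$name)) igraph::V(net)$name
           else as.character(seq_len(igraph::vcount(net)))
  axis <- ifelse(deg < low_max, "low", ifelse(deg <= high_min, "medium", "high"))
  df <- data.frame(node = nodes, degree = as.integer(deg), clustering = cc,
                   axis = axis)
  df <- df[order(df$axis, df$clustering, df$node), ]
  df$order <- stats::ave(seq_len(nrow(df)), df$axis, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Read an edge list TSV
#' @param path TSV with two id columns (header optional, detected by a
#'   "protein_a" first field).
#' @return data.frame with `protein_a`, `protein_b` (+ extra columns).
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("^protein_a\t", first)
  df <- utils::read.delim(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:2] <- c("protein_a", "protein_b")
  df
}

#' Write an edge list TSV
#' @param edges data.frame with at least two id columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
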