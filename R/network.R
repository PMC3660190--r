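#' Permutation-derived MI significance threshold
#'
#' Null-calibrates the MI scale: in each repetition every gene's sample
#' values are independently permuted (destroying all between-gene
#' dependence), the full pairwise MI matrix is recomputed, and its maximum
#' off-diagonal entry recorded.  The threshold is the largest of these null
#' maxima, so an edge must exceed everything ever seen under independence.
#'
#' @param values Genes x samples matrix or `expression_dataset`
#'   (standardize first if using the default bandwidth).
#' @param h Kernel bandwidth (default 0.25).
#' @param n_perm Number of permutation repetitions (default 30).
#' @param seed Integer seed.
#' @return Numeric threshold with attribute `maxima` (per-repetition null
#'   maxima, length `n_perm`).
#' @export
permutation_threshold <- function(values, h = 0.25, n_perm = 30L, seed = 1L) {
  if (inherits(values, "expression_dataset")) values <- values$values
  values <- as.matrix(values)
  stopifnot(n_perm >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- ncol(values)
  maxima <- vapply(seq_len(n_perm), function(rep) {
    perm <- t(apply(values, 1L, sample))
    mi <- pairwise_mi(perm, h)$values
    diag(mi) <- -Inf
    max(mi)
  }, numeric(1))
  structure(max(maxima), maxima = maxima)
}

#' Build a target network from an MI matrix
#'
#' Undirected weighted graph over the genes: the edge `(a, b)` is present iff
#' `MI(a, b)` strictly exceeds the threshold (`a != b`); isolated nodes are
#' retained.
#'
#' @param m An `mi_matrix`.
#' @param threshold Edge threshold (typically from
#'   [permutation_threshold()]).
#' @param permutation_count Number of permutations behind the threshold
#'   (metadata only).
#' @return A `target_network` with fields `nodes`, `edges` (data frame
#'   `gene_a`, `gene_b`, `mi`), `threshold`, `permutation_count`.
#' @export
build_network <- function(m, threshold, permutation_count = NA_integer_) {
  stopifnot(inherits(m, "mi_matrix"))
  v <- m$values
  N <- nrow(v)
  pairs <- which(upper.tri(v) & v > threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = m$gene_ids[pairs[, 1L]],
                      gene_b = m$gene_ids[pairs[, 2L]],
                      mi = v[pairs],
                      stringsAsFactors = FALSE)
  structure(list(nodes = m$gene_ids, edges = edges,
                 threshold = threshold,
                 permutation_count = as.integer(permutation_count)),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("target_network: %d nodes, %d edges (MI > %.4g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Convert a target network to an igraph graph
#'
#' @param net A `target_network`.
#' @return An undirected [igraph::igraph] with edge attribute `mi`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "target_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Write / read a target network
#'
#' `graphml` keeps node ids and `mi` edge weights (via igraph); `edgelist`
#' writes a 3-column TSV `gene_a, gene_b, mi` (plus a `# nodes:` metadata
#' line so isolated nodes round-trip).
#'
#' @param net A `target_network`.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `read_network` returns a `target_network` (threshold metadata is
#'   restored from edge-list files only).
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "target_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# nodes: %s", paste(net$nodes, collapse = ",")), con)
    writeLines(sprintf("# threshold: %.17g permutations: %d",
                       net$threshold, net$permutation_count), con)
    utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(gene_a = ed$from, gene_b = ed$to,
                        mi = if (nrow(ed)) ed$mi else numeric(0),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = igraph::V(g)$name, edges = edges,
                          threshold = NA_real_,
                          permutation_count = NA_integer_),
                     class = "target_network"))
  }
  header <- readLines(path, n = 2L)
  nodes <- strsplit(sub("^# nodes: ", "", header[1L]), ",")[[1L]]
  meta <- header[2L]
  thr <- as.numeric(sub("^# threshold: ([^ ]+).*", "\\1", meta))
  np <- suppressWarnings(as.integer(sub(".*permutations: ", "", meta)))
  edges <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        mi = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, threshold = thr,
                 permutation_count = np),
            class = "target_network")
}

#' Clustergram ordering of an MI matrix
#'
#' Agglomerative hierarchical clustering of the MI-matrix rows under
#' Euclidean distance (average linkage); the resulting leaf order is the
#' clustergram's display order, with ties resolved by gene input order
#' (deterministic).
#'
#' @param m An `mi_matrix`.
#' @return A `cluster_order` with fields `order` (gene ids, leaf order),
#'   `hclust` (the merge tree), and `reordered` (the permuted MI matrix for
#'   heatmap rendering).
#' @export
cluster_order <- function(m) {
  stopifnot(inherits(m, "mi_matrix"))
  if (length(m$gene_ids) < 2L) stop("need at least 2 genes to cluster")
  hc <- stats::hclust(stats::dist(m$values, method = "euclidean"),
                      method = "average")
  ord <- hc$order
  structure(list(order = m$gene_ids[ord], hclust = hc,
                 reordered = m$values[ord, ord]),
            class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat(sprintf("cluster_order over %d genes: %s%s\n",
              length(x$order),
              paste(utils::head(x$order, 6), collapse = ", "),
              if (length(x$order) > 6) ", ..." else ""))
  invisible(x)
}
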