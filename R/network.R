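#' Identity-by-state genotype distance matrix
#'
#' For each pair the shared-allele count at a SNP is `2 - |x_i - x_j|` for
#' doses x (so a heterozygote pair shares both allele copies), and
#' `d(i,j) = 1 - sum(shared) / (2 * #non-missing SNPs for the pair)`.  The
#' alternative `"hamming"` flavour is the proportion of pairwise non-missing
#' SNPs with differing genotype codes.
#'
#' @param genotypes a [genotype_matrix()] with at least two samples.
#' @param flavour `"ibs"` (1 - IBS, the default) or `"hamming"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(genotypes, flavour = c("ibs", "hamming")) {
  flavour <- match.arg(flavour)
  X <- genotypes$doses
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  ids <- genotypes$sample_ids
  if (!anyNA(X)) {
    if (flavour == "ibs") {
      D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * ncol(X))
    } else {
      D <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        D[i, j] <- D[j, i] <- mean(X[i, ] != X[j, ])
    }
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- !is.na(X[i, ]) & !is.na(X[j, ])
        if (!any(ok))
          stop("pair (", ids[i], ", ", ids[j], ") has no overlapping non-missing SNPs")
        d_abs <- abs(X[i, ok] - X[j, ok])
        D[i, j] <- D[j, i] <- if (flavour == "ibs") sum(d_abs) / (2 * sum(ok))
                              else mean(d_abs > 0)
      }
    }
  }
  dimnames(D) <- list(ids, ids)
  D
}

#' Mutual k-nearest-neighbour relationship network
#'
#' NetView-style construction: an undirected edge joins i and j iff each is
#' among the other's k nearest neighbours.  Ties among equal distances are
#' broken by sample order (reported via the `tie_break` attribute).
#' Connected components are computed on the resulting graph.
#'
#' @param dist symmetric distance matrix (zero diagonal), e.g. from
#'   [ibs_distance()] or [kinship_to_distance()].
#' @param k neighbourhood size (the clustering k; default 10).
#' @param labels optional per-sample labels (e.g. case/control status),
#'   either a named/aligned character vector or a phenotype table.
#' @return list of class `"relnet"`: `nodes` (id, label, component, degree)
#'   and `edges` (from, to, distance).
#' @export
mutual_knn_network <- function(dist, k = 10, labels = NULL) {
  if (k <= 0) stop("configuration error: k must be positive")
  n <- nrow(dist)
  if (k >= n) stop("configuration error: k must be smaller than the sample count")
  ids <- rownames(dist) %||% sprintf("S%03d", seq_len(n))
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(dist[i, ], seq_len(n))       # ties by sample order
    ord <- ord[ord != i][seq_len(k)]
    nn[i, ord] <- TRUE
  }
  adj <- nn & t(nn)
  ew <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[ew[, 1]], to = ids[ew[, 2]],
                      distance = dist[ew], stringsAsFactors = FALSE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  lab <- rep(NA_character_, n)
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab <- labels$status[match(ids, labels$sample_id)]
    } else if (!is.null(names(labels))) {
      lab <- unname(labels[ids])
    } else lab <- as.character(labels)
  }
  nodes <- data.frame(id = ids, label = lab, component = as.integer(comp),
                      degree = rowSums(adj), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, k = k,
                 tie_break = "sample order"),
            class = "relnet")
}

#' @export
print.relnet <- function(x, ...) {
  cat(sprintf("Mutual %d-NN relationship network: %d nodes, %d edges, %d component(s)\n",
              x$k, nrow(x$nodes), nrow(x$edges), max(x$nodes$component)))
  if (!all(is.na(x$nodes$label))) {
    tb <- table(x$nodes$label, x$nodes$component)
    cat("label x component counts:\n"); print(tb)
  }
  invisible(x)
}

#' Plot a relationship network
#' @param x a `"relnet"` object.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.relnet <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes)
  col <- ifelse(is.na(igraph::V(g)$label), "grey70",
                ifelse(igraph::V(g)$label == "case", "firebrick", "steelblue"))
  igraph::plot.igraph(g, vertex.size = 4, vertex.label = NA,
                      vertex.color = col, ...)
  invisible(x)
}

#' Export network as edge-list and node-attribute TSVs
#' @param network a `"relnet"` object.
#' @param edge_path,node_path output paths.
#' @export
write_network <- function(network, edge_path, node_path) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(network$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}
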