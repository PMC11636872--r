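# Geodesic superpixel graph.

#' Build the weighted adjacency graph of superpixels
#'
#' Nodes are the superpixels; edges join spatially adjacent superpixels
#' (sharing at least one 4-neighbor pixel pair); edge weights are the
#' appearance distance `d_app(p, q)`, the Euclidean distance between the
#' chosen feature components of the two superpixels. The default uses the
#' CIE-Lab components only, so large homogeneous regions stay geodesically
#' close regardless of spatial extent; `"full"` uses all 8 features.
#'
#' @param spmap a `superpixel_map`.
#' @param features the matching `feature_matrix`.
#' @param feature_subset `"lab"` (L, a, b; default) or `"full"` (all 8).
#' @return a `superpixel_graph`: list with `graph` (igraph), `edges`
#'   (data.frame `from`, `to` as 0-based labels, `weight`), `k`, and
#'   `feature_subset`.
#' @export
build_graph <- function(spmap, features, feature_subset = c("lab", "full")) {
  feature_subset <- match.arg(feature_subset)
  if (features$k != spmap$k) stop("features and superpixel map disagree on k")
  l <- spmap$labels
  H <- nrow(l); W <- ncol(l)
  a <- c(l[-H, ], l[, -W])
  b <- c(l[-1, ], l[, -1])
  keep <- a != b
  pairs <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  cols <- if (feature_subset == "lab") 4:6 else 1:8
  Fm <- features$F[, cols, drop = FALSE]
  d <- sqrt(rowSums((Fm[pairs[, 1] + 1L, , drop = FALSE] -
                     Fm[pairs[, 2] + 1L, , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = spmap$k, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(pairs + 1L)))
  igraph::E(g)$weight <- d
  if (!igraph::is_connected(g))
    stop("superpixel adjacency graph is disconnected (invalid label map)")
  structure(
    list(graph = g,
         edges = data.frame(from = pairs[, 1], to = pairs[, 2], weight = d),
         k = spmap$k, feature_subset = feature_subset),
    class = "superpixel_graph"
  )
}

#' All-pairs geodesic distances between superpixels
#'
#' The geodesic distance `d_geo(p, q)` is the minimum total appearance
#' weight along any path joining `p` and `q` in the adjacency graph
#' (all-pairs Dijkstra).
#'
#' @param graph a `superpixel_graph`.
#' @return a symmetric k x k matrix with zero diagonal.
#' @export
geodesic_distances <- function(graph) {
  d <- igraph::distances(graph$graph, weights = igraph::E(graph$graph)$weight,
                         algorithm = "dijkstra")
  if (any(!is.finite(d)))
    stop("disconnected superpixel graph: infinite geodesic distance")
  dimnames(d) <- NULL
  d
}
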