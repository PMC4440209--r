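# Node influence metrics -----------------------------------------------------
#
# Degree: count of incident links. Eigen-influence: component of the dominant
# eigenvector of the weighted connection matrix (eigenvector centrality),
# rescaled so the maximum is 1; the network-level influence is the spectral
# radius. Betweenness: fraction-weighted geodesic counting on the binarized
# graph (Brandes-style pair splitting), endpoints excluded.

.check_node <- function(net, node) {
  if (!node %in% net$nodes) {
    stop("unknown node '", node, "'; nodes are: ", paste(net$nodes, collapse = ", "))
  }
  node
}

#' Node degree
#'
#' Number of links incident to a node: the count of strictly positive
#' off-diagonal entries in the node's row of the connection matrix.
#'
#' @param net A `connection_matrix`.
#' @param node Node name; if `NULL`, all degrees are returned as a named
#'   integer vector.
#' @return Integer degree(s).
#' @export
node_degree <- function(net, node = NULL) {
  stopifnot(inherits(net, "connection_matrix"))
  deg <- rowSums(net$weights > 0)
  storage.mode(deg) <- "integer"
  if (is.null(node)) return(deg)
  deg[[.check_node(net, node)]]
}

#' Eigendecomposition-based influence analysis
#'
#' Full real eigendecomposition of the symmetric connection matrix. The
#' network-level influence is the spectral radius (largest absolute
#' eigenvalue); per-node eigen-influence is the absolute component of the
#' eigenvector of the largest eigenvalue, rescaled to maximum 1 (for a
#' nonnegative symmetric matrix this is the Perron eigenvector, taken with
#' nonnegative entries). The asymptotic state dynamics `S(t) = C^t S(0)`
#' align with this eigenvector, which is why its components measure each
#' node's long-run influence.
#'
#' @param net A `connection_matrix` (symmetric weights required).
#' @return List of class `eigen_influence`: `values` (all eigenvalues,
#'   decreasing), `spectral_radius`, `dominant_vector`, and `influence`
#'   (named, max 1; all zero for an empty network).
#' @export
eigen_analysis <- function(net) {
  stopifnot(inherits(net, "connection_matrix"))
  C <- net$weights
  if (!isSymmetric(unname(C), tol = 1e-10)) stop("connection matrix must be symmetric")
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  radius <- max(abs(vals))
  vec <- e$vectors[, 1]  # eigenvector of the largest eigenvalue
  if (max(abs(vec)) > 0) {
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    infl <- abs(vec) / max(abs(vec))
  } else {
    infl <- rep(0, length(vec))
  }
  if (radius == 0) infl <- rep(0, length(vec))
  names(infl) <- names(vec) <- net$nodes
  structure(
    list(values = vals, spectral_radius = radius,
         dominant_vector = vec, influence = infl),
    class = "eigen_influence"
  )
}

# BFS shortest-path distances and geodesic counts from every source on the
# binarized graph. Returns dist (Inf for unreachable) and counts sigma.
.geodesic_counts <- function(adj) {
  k <- nrow(adj)
  nbrs <- lapply(seq_len(k), function(i) which(adj[i, ]))
  dist <- matrix(Inf, k, k)
  sigma <- matrix(0, k, k)
  for (s in seq_len(k)) {
    d <- rep(Inf, k); d[s] <- 0
    np <- rep(0, k); np[s] <- 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          np[w] <- np[v]
          queue <- c(queue, w)
        } else if (d[w] == d[v] + 1) {
          np[w] <- np[w] + np[v]
        }
      }
    }
    dist[s, ] <- d
    sigma[s, ] <- np
  }
  list(dist = dist, sigma = sigma)
}

#' Betweenness centrality
#'
#' For every unordered source-target pair (excluding the node itself), the
#' node accrues the share of shortest paths between that pair that pass
#' through it. Computed on the binarized graph (a link is a link, whatever
#' its weight); disconnected pairs contribute nothing. `mode = "fractional"`
#' (default) adds `sigma_st(v)/sigma_st` per pair — the standard fractional
#' pair-splitting; `mode = "count"` adds the raw number of geodesics through
#' the node.
#'
#' @param net A `connection_matrix`.
#' @param node Node name, or `NULL` for all nodes.
#' @param mode `"fractional"` or `"count"`.
#' @return Betweenness score(s), named when `node` is `NULL`.
#' @export
betweenness <- function(net, node = NULL, mode = c("fractional", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "connection_matrix"))
  if (!is.null(node)) .check_node(net, node)
  adj <- net$weights > 0
  k <- nrow(adj)
  g <- .geodesic_counts(adj)
  b <- numeric(k)
  for (v in seq_len(k)) {
    for (s in seq_len(k - 1)) {
      if (s == v) next
      for (t in (s + 1):k) {
        if (t == v || is.infinite(g$dist[s, t])) next
        if (g$dist[s, v] + g$dist[v, t] == g$dist[s, t]) {
          through <- g$sigma[s, v] * g$sigma[v, t]
          b[v] <- b[v] + if (mode == "fractional") through / g$sigma[s, t] else through
        }
      }
    }
  }
  names(b) <- net$nodes
  if (is.null(node)) b else b[[node]]
}

#' Propagate an influence state through the network
#'
#' Iterates the discrete influence dynamics `S(t) = C^t S(0)`: each step
#' multiplies the state by the connection matrix. `t = 0` returns the initial
#' state unchanged.
#'
#' @param net A `connection_matrix`.
#' @param s0 Initial state vector, one entry per node.
#' @param t Non-negative integer number of steps.
#' @return List of class `influence_state` with `t` and `state` (named).
#' @export
propagate_influence <- function(net, s0, t) {
  stopifnot(inherits(net, "connection_matrix"))
  if (length(s0) != length(net$nodes)) {
    stop("s0 must have one entry per node (", length(net$nodes), ")")
  }
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  s <- as.numeric(s0)
  for (i in seq_len(t)) s <- as.numeric(net$weights %*% s)
  names(s) <- net$nodes
  structure(list(t = as.integer(t), state = s), class = "influence_state")
}

#' Stability of the influence dynamics
#'
#' Classifies the network by its spectral radius: states grow without bound
#' along the dominant eigendirection when the radius exceeds 1, decay to zero
#' when it is below 1, and are marginal at 1 (within tolerance).
#'
#' @param net A `connection_matrix`.
#' @param tol Half-width of the marginal band around 1.
#' @return `"growing"`, `"decaying"` or `"marginal"`.
#' @export
stability_class <- function(net, tol = 1e-9) {
  radius <- eigen_analysis(net)$spectral_radius
  if (radius > 1 + tol) "growing" else if (radius < 1 - tol) "decaying" else "marginal"
}

#' Per-node influence metrics table
#'
#' Degree, eigen-influence and betweenness for every node, with the
#' network-level eigenvalue list, spectral radius and stability class
#' attached as attributes.
#'
#' @param net A `connection_matrix`.
#' @param betweenness_mode Passed to [betweenness()].
#' @return data.frame of class `node_metrics` (`node`, `degree`,
#'   `eigen_influence`, `betweenness`) with attributes `eigenvalues`,
#'   `spectral_radius`, `stability`.
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7))
#' net <- build_network(cohort, intensity = 1)
#' node_metrics(net)
#' @export
node_metrics <- function(net, betweenness_mode = c("fractional", "count")) {
  betweenness_mode <- match.arg(betweenness_mode)
  ea <- eigen_analysis(net)
  out <- data.frame(
    node = net$nodes,
    degree = as.integer(node_degree(net)),
    eigen_influence = unname(ea$influence),
    betweenness = unname(betweenness(net, mode = betweenness_mode)),
    stringsAsFactors = FALSE
  )
  attr(out, "eigenvalues") <- ea$values
  attr(out, "spectral_radius") <- ea$spectral_radius
  attr(out, "stability") <- stability_class(net)
  class(out) <- c("node_metrics", "data.frame")
  out
}

#' Maximal nodes per influence metric
#'
#' Identifies the hub (maximum degree), the maximum eigen-influence node and
#' the maximum betweenness node. Ties are reported in full, ordered by node
#' name — never silently broken.
#'
#' @param metrics A `node_metrics` table.
#' @return List with character vectors `hub`, `max_eigen`, `max_betweenness`.
#' @export
rank_nodes <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  argmax <- function(x) sort(metrics$node[x == max(x)])
  list(
    hub = argmax(metrics$degree),
    max_eigen = argmax(metrics$eigen_influence),
    max_betweenness = argmax(metrics$betweenness)
  )
}
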