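# Independent oracle implementations and graph fixtures used across tests.
# These deliberately avoid the package's own code paths.

# Pearson correlation straight from the covariance/SD definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cov_xy / (sqrt(sum((x - mean(x))^2) / (n - 1)) * sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_F <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  N <- length(y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - mean(y))^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Betweenness by exhaustive enumeration of all shortest simple paths.
# Exponential; only for small graphs (<= ~7 nodes).
oracle_betweenness_enum <- function(adj, mode = c("fractional", "count")) {
  mode <- match.arg(mode)
  k <- nrow(adj)
  shortest_paths_st <- function(s, t) {
    res <- list()
    best <- Inf
    dfs <- function(path) {
      v <- path[length(path)]
      if (length(path) - 1 > best) return(invisible(NULL))
      if (v == t) {
        len <- length(path) - 1
        if (len < best) { best <<- len; res <<- list() }
        if (len == best) res[[length(res) + 1]] <<- path
        return(invisible(NULL))
      }
      for (w in which(adj[v, ])) if (!(w %in% path)) dfs(c(path, w))
      invisible(NULL)
    }
    dfs(s)
    res
  }
  b <- numeric(k)
  for (s in seq_len(k - 1)) {
    for (t in (s + 1):k) {
      ps <- shortest_paths_st(s, t)
      if (!length(ps)) next
      for (v in setdiff(seq_len(k), c(s, t))) {
        through <- sum(vapply(ps, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + if (mode == "fractional") through / length(ps) else through
      }
    }
  }
  b
}

# igraph-based oracle on the binarized graph.
oracle_betweenness_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  unname(igraph::betweenness(g, directed = FALSE))
}

# Graph fixtures ---------------------------------------------------------

# Random weighted connection matrix: each pair linked with prob p_edge,
# weights uniform in [0.3, 1].
random_net <- function(k, p_edge = 0.5) {
  w <- matrix(0, k, k)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < p_edge]
  w[on] <- stats::runif(length(on), 0.3, 1)
  w <- w + t(w)
  connection_matrix(w)
}

star_net <- function(k, weight = 1) {
  w <- matrix(0, k, k)
  w[1, 2:k] <- w[2:k, 1] <- weight
  dimnames(w) <- list(paste0("n", 1:k), paste0("n", 1:k))
  connection_matrix(w)
}

path_net <- function(k, weight = 1) {
  w <- matrix(0, k, k)
  for (i in seq_len(k - 1)) w[i, i + 1] <- w[i + 1, i] <- weight
  connection_matrix(w)
}

complete_net <- function(k, weight = 1) {
  w <- matrix(weight, k, k)
  diag(w) <- 0
  connection_matrix(w)
}

# Mean and SD of a normal truncated below at zero.
truncnorm_moments <- function(mu, sd) {
  a <- mu / sd
  lam <- stats::dnorm(a) / stats::pnorm(a)
  m <- mu + sd * lam
  v <- sd^2 * (1 - a * lam - lam^2)
  list(mean = m, sd = sqrt(v))
}
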