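# Thresholded Pearson correlation networks -----------------------------------
#
# Variables are nodes; a link exists between two variables when the Pearson
# correlation of their values across participants (within one intensity) is
# moderate or high in magnitude. Links are undirected and weighted by the
# correlation magnitude (optionally normalised by the maximum magnitude over
# all links), giving a symmetric zero-diagonal connection matrix C with
# entries in [0, 1].

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires equal-length
#' vectors of at least 3 observations and non-constant inputs (a constant
#' vector has no defined correlation; subject-level variables with zero
#' variance trigger this).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("correlation undefined: 'x' is constant")
  if (stats::sd(y) == 0) stop("correlation undefined: 'y' is constant")
  stats::cor(x, y)
}

#' Classify a correlation coefficient as weak, moderate or high
#'
#' Magnitude-based three-way classification: weak below the moderate
#' threshold, moderate from there up to the high threshold, high at or above
#' it. Boundary values are assigned to the stronger class (the defining
#' inequalities are strict on both sides, leaving the boundaries unassigned;
#' closing the lower bound of the stronger class is a measure-zero,
#' deterministic convention).
#'
#' @param r Correlation coefficient(s) in `[-1, 1]` (vectorised).
#' @param thresholds Numeric `c(moderate, high)` magnitude cutoffs, default
#'   `c(0.3, 0.7)`.
#' @return Character vector: `"weak"`, `"moderate"` or `"high"`.
#' @examples
#' classify_correlation(c(0.75, 0, -0.5))
#' @export
classify_correlation <- function(r, thresholds = c(0.3, 0.7)) {
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-12)) {
    stop("correlation coefficients must lie in [-1, 1]")
  }
  if (length(thresholds) != 2 || thresholds[1] <= 0 || thresholds[2] <= thresholds[1]) {
    stop("thresholds must be c(moderate, high) with 0 < moderate < high")
  }
  a <- abs(r)
  ifelse(a >= thresholds[2], "high", ifelse(a >= thresholds[1], "moderate", "weak"))
}

#' Weight of a network link from its correlation
#'
#' A surviving (moderate or high) correlation becomes a link weighted by its
#' magnitude: a correlation score of 0.75 is weighted at 75% influence. In
#' `"max_normalized"` mode the magnitude is further divided by the maximum
#' magnitude over all links, so the strongest link has weight 1.
#'
#' @param r Correlation coefficient(s); must classify as moderate or high.
#' @param mode `"raw"` (weight = |r|, default) or `"max_normalized"`.
#' @param max_abs_r Maximum |r| over all links; required (> 0) for
#'   `"max_normalized"`.
#' @param thresholds Passed to [classify_correlation()].
#' @return Link weight(s) in `[0, 1]`.
#' @examples
#' link_weight(0.75)  # 0.75, i.e. 75% influence
#' @export
link_weight <- function(r, mode = c("raw", "max_normalized"), max_abs_r = NULL,
                        thresholds = c(0.3, 0.7)) {
  mode <- match.arg(mode)
  cls <- classify_correlation(r, thresholds)
  if (any(cls == "weak")) {
    stop("weak correlations form no link and have no weight")
  }
  w <- abs(r)
  if (mode == "max_normalized") {
    if (is.null(max_abs_r) || !is.finite(max_abs_r) || max_abs_r <= 0) {
      stop("max_normalized mode requires max_abs_r > 0")
    }
    w <- w / max_abs_r
  }
  w
}

#' Build the weighted connection matrix for one intensity
#'
#' Correlates every unordered pair of node variables across participants
#' within one intensity slice, classifies each correlation, and turns the
#' moderate/high pairs into bidirectional weighted links. Weak pairs get a
#' zero entry. Constant variables (zero variance) are kept as isolated nodes
#' with a warning.
#'
#' @param cohort A cohort data.frame (one row per participant x intensity).
#' @param intensity Intensity label to slice on; may be omitted if `cohort`
#'   already holds a single intensity.
#' @param variables Node variables to include (default [fatigue_nodes()]).
#' @param mode Link weighting mode, `"raw"` or `"max_normalized"`.
#' @param thresholds Magnitude cutoffs `c(moderate, high)`.
#' @return A `connection_matrix`: list with `nodes`, `weights` (symmetric
#'   zero-diagonal matrix in `[0, 1]`), `mode`, `intensity`, `thresholds` and
#'   `records` (one row per unordered pair: `node_a`, `node_b`, `r`, `class`,
#'   `weight`, where weak pairs have weight 0).
#' @examples
#' cohort <- generate_cohort(generator_config(n_participants = 9, seed = 1))
#' net <- build_network(cohort, intensity = 1)
#' net
#' @export
build_network <- function(cohort, intensity = NULL,
                          variables = fatigue_nodes(),
                          mode = c("raw", "max_normalized"),
                          thresholds = c(0.3, 0.7)) {
  mode <- match.arg(mode)
  if (!is.null(intensity)) {
    cohort <- cohort[cohort$intensity == intensity, , drop = FALSE]
    if (!nrow(cohort)) stop("no rows at intensity ", intensity)
  } else {
    ints <- unique(cohort$intensity)
    if (length(ints) > 1) stop("cohort spans several intensities; pass `intensity`")
    intensity <- ints
  }
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars)) {
    stop("variables absent from cohort: ", paste(missing_vars, collapse = ", "))
  }
  if (nrow(cohort) < 3) stop("need at least 3 participants to correlate")

  x <- as.matrix(cohort[, variables, drop = FALSE])
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("constant variable(s) kept as isolated nodes: ",
            paste(variables[const], collapse = ", "))
  }
  k <- length(variables)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (const[a] || const[b]) NA_real_ else stats::cor(x[, a], x[, b])
  }, numeric(1))

  cls <- rep("weak", length(r))
  ok <- !is.na(r)
  cls[ok] <- classify_correlation(r[ok], thresholds)
  linked <- ok & cls != "weak"
  max_abs_r <- if (any(linked)) max(abs(r[linked])) else NA_real_
  weight <- numeric(length(r))
  if (any(linked)) {
    weight[linked] <- link_weight(r[linked], mode = mode,
                                  max_abs_r = max_abs_r, thresholds = thresholds)
  }

  records <- data.frame(
    node_a = variables[pairs[, 1]],
    node_b = variables[pairs[, 2]],
    r = r, class = cls, weight = weight,
    stringsAsFactors = FALSE
  )

  C <- matrix(0, k, k, dimnames = list(variables, variables))
  C[cbind(pairs[, 1], pairs[, 2])] <- weight
  C <- C + t(C)

  structure(
    list(nodes = variables, weights = C, mode = mode,
         intensity = intensity, thresholds = thresholds,
         max_abs_r = max_abs_r, n = nrow(cohort), records = records),
    class = "connection_matrix"
  )
}

#' Construct a connection matrix directly from a weight matrix
#'
#' Mainly for tests and worked examples: validates symmetry, zero diagonal
#' and the `[0, 1]` weight range.
#'
#' @param weights Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`; dimnames become node names (defaults `n1..nk`).
#' @param intensity Optional intensity label.
#' @param mode Weight mode label.
#' @return A `connection_matrix`.
#' @export
connection_matrix <- function(weights, intensity = NA, mode = "raw") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (!isSymmetric(unname(weights), tol = 1e-10)) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  if (any(weights < 0) || any(weights > 1)) stop("weights must lie in [0, 1]")
  if (is.null(rownames(weights))) {
    dimnames(weights) <- list(paste0("n", seq_len(nrow(weights))),
                              paste0("n", seq_len(nrow(weights))))
  }
  structure(
    list(nodes = rownames(weights), weights = weights, mode = mode,
         intensity = intensity, thresholds = c(0.3, 0.7),
         max_abs_r = NA_real_, n = NA_integer_, records = NULL),
    class = "connection_matrix"
  )
}

#' Surviving links of a network
#'
#' @param net A `connection_matrix`.
#' @return data.frame of the moderate/high pairs (`node_a`, `node_b`, `r`,
#'   `class`, `weight`); derived from the weight matrix when per-pair records
#'   are unavailable.
#' @export
link_list <- function(net) {
  stopifnot(inherits(net, "connection_matrix"))
  if (!is.null(net$records)) {
    out <- net$records[net$records$weight > 0, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  data.frame(node_a = net$nodes[idx[, 1]], node_b = net$nodes[idx[, 2]],
             r = NA_real_, class = NA_character_,
             weight = net$weights[idx], stringsAsFactors = FALSE)
}

#' Number of links in a network
#'
#' @param net A `connection_matrix`.
#' @return Count of unordered linked pairs (half the positive off-diagonal
#'   entries of C).
#' @export
n_links <- function(net) {
  stopifnot(inherits(net, "connection_matrix"))
  sum(net$weights[upper.tri(net$weights)] > 0)
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("Connection matrix: %d nodes, %d links (%s weights%s)\n",
              length(x$nodes), n_links(x), x$mode,
              if (is.na(x$intensity)) "" else paste0(", intensity ", x$intensity)))
  invisible(x)
}
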