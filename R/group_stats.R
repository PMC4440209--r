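# Cross-intensity comparisons: one-way ANOVA followed by the Student-Newman-
# Keuls stepwise multiple-comparison procedure at P < 0.05, reported with the
# letter scheme a/b/c = "different from intensity 1/2/3".

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F is the ratio of the between-group
#' to the within-group mean square, referred to F(k-1, N-k). Delegates to
#' [stats::oneway.test()] with `var.equal = TRUE`.
#'
#' @param groups List of numeric sample vectors (>= 2 groups, each >= 2
#'   observations).
#' @return List: `F_statistic`, `p_value`, `df`, `group_means`, `group_n`,
#'   `ms_within`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need a list of >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  ssb <- sum(lengths(groups) * (means - mean(y))^2)
  if (ssw == 0 && ssb == 0) {
    stop("degenerate ANOVA: zero within-group variance and equal group means")
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  df2 <- length(y) - length(groups)
  list(
    F_statistic = unname(ft$statistic),
    p_value = unname(ft$p.value),
    df = unname(ft$parameter),
    group_means = means,
    group_n = lengths(groups),
    ms_within = ssw / df2,
    df_within = df2
  )
}

#' Student-Newman-Keuls post hoc comparisons
#'
#' Stepwise studentized-range procedure on the ordered group means: the
#' widest span is tested first against the critical value
#' `qtukey(1 - alpha, p, df)` for its stretch `p`; a significant span is
#' split and its sub-spans tested in turn, while every pair inside a
#' non-significant span is declared not different (the blocking rule).
#' Unbalanced groups use the harmonic mean group size. Literally identical
#' groups (zero error variance, equal means) yield no differences.
#'
#' @param groups List of numeric sample vectors.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return List of class `snk_posthoc`: `different` (k x k logical matrix in
#'   the original group order), `pairs` (data.frame of the different pairs
#'   with their q statistic and critical value), `letters` (per-group strings
#'   marking which lower-numbered groups they differ from: "a" = group 1,
#'   "b" = group 2, "c" = group 3, ...), `alpha`.
#' @export
snk_posthoc <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.list(groups) || length(groups) < 2) stop("need a list of >= 2 groups")
  k <- length(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  N <- sum(n)
  df2 <- N - k
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  mse <- ssw / df2
  n_h <- k / sum(1 / n)  # harmonic mean group size

  ord <- order(means)
  m_sorted <- means[ord]
  diff_mat <- matrix(FALSE, k, k)
  decided <- matrix(FALSE, k, k)
  q_rec <- list()

  if (mse == 0) {
    # zero error variance: means either coincide (no difference) or are
    # separated with certainty
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      diff_mat[i, j] <- diff_mat[j, i] <- means[i] != means[j]
    }
  } else {
    test_span <- function(lo, hi) {
      if (hi <= lo) return(invisible(NULL))
      if (decided[lo, hi]) return(invisible(NULL))
      p <- hi - lo + 1
      q_obs <- (m_sorted[hi] - m_sorted[lo]) / sqrt(mse / n_h)
      q_crit <- stats::qtukey(1 - alpha, nmeans = p, df = df2)
      a <- ord[lo]; b <- ord[hi]
      if (q_obs > q_crit) {
        diff_mat[a, b] <<- diff_mat[b, a] <<- TRUE
        decided[lo, hi] <<- TRUE
        q_rec[[length(q_rec) + 1]] <<- data.frame(
          group_a = min(a, b), group_b = max(a, b),
          q = q_obs, q_critical = q_crit, stretch = p)
        test_span(lo, hi - 1)
        test_span(lo + 1, hi)
      } else {
        # blocking: every pair inside a retained span is not different
        for (i in lo:(hi - 1)) for (j in (i + 1):hi) decided[i, j] <<- TRUE
      }
      invisible(NULL)
    }
    test_span(1, k)
  }

  letter_for <- function(i) {
    marks <- letters[seq_len(min(k - 1, 26))]
    got <- marks[which(diff_mat[i, seq_len(i - 1)])]
    if (!length(got)) "" else paste(got, collapse = "")
  }
  lab <- vapply(seq_len(k), function(i) {
    if (i == 1) "" else letter_for(i)
  }, character(1))

  pairs <- if (length(q_rec)) do.call(rbind, q_rec) else
    data.frame(group_a = integer(), group_b = integer(),
               q = numeric(), q_critical = numeric(), stretch = integer())
  structure(
    list(different = diff_mat, pairs = pairs, letters = lab, alpha = alpha),
    class = "snk_posthoc"
  )
}

#' Compare variables across intensities
#'
#' For each variable, runs a one-way ANOVA across the intensity groups
#' followed by SNK post hoc comparisons, and reports the per-intensity
#' difference letters ("a" = differs from intensity 1, "b" = from 2, "c" =
#' from 3). Subject-level variables are constant across intensities and are
#' skipped with `NA` statistics.
#'
#' @param cohort A cohort data.frame.
#' @param variables Variables to compare (default the nine per-intensity
#'   variables).
#' @param alpha Significance level for the post hoc procedure.
#' @return data.frame: `variable`, `F_statistic`, `p_value`, then one
#'   `letters_<intensity>` column per intensity.
#' @export
compare_intensities <- function(cohort,
                                variables = intersect(.per_intensity_vars, names(cohort)),
                                alpha = 0.05) {
  ints <- unique(cohort$intensity)
  if (length(ints) < 2) stop("need at least 2 intensities to compare")
  rows <- lapply(variables, function(v) {
    groups <- lapply(ints, function(i) cohort[cohort$intensity == i, v])
    base <- data.frame(variable = v, F_statistic = NA_real_, p_value = NA_real_,
                       stringsAsFactors = FALSE)
    lets <- rep(NA_character_, length(ints))
    constant <- all(vapply(groups, function(x) stats::sd(x) == 0, logical(1))) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1
    if (!constant) {
      an <- anova_oneway(groups)
      snk <- snk_posthoc(groups, alpha = alpha)
      base$F_statistic <- an$F_statistic
      base$p_value <- an$p_value
      lets <- snk$letters
    }
    for (j in seq_along(ints)) base[[paste0("letters_", ints[j])]] <- lets[j]
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
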