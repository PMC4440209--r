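# Synthetic cohort generation ------------------------------------------------
#
# Multivariate-normal backbone: per intensity, latent standard normals with a
# target correlation matrix are rescaled to the configured means/SDs. Subject-
# level variables are drawn once per participant; the per-intensity block is
# drawn conditional on the subject-level latents (Gaussian conditioning), so
# the full target correlation holds at every intensity while subject-level
# values stay constant within a participant. Positivity is enforced by
# bounded resampling, which truncates the normal at zero (see vignette for
# the induced bias when mean/SD is small).

#' Configuration for the synthetic cohort generator
#'
#' @param n_participants Number of participants (>= 3).
#' @param intensities Ordered vector of intensity labels (default 1:4).
#' @param means,sds Variables x intensities numeric matrices of per-intensity
#'   means/SDs (rows named by the nine per-intensity variables, columns one
#'   per intensity). Defaults: [default_means()], [default_sds()], recycled
#'   across columns if fewer intensities are requested.
#' @param subject_means,subject_sds Named numeric vectors over the four
#'   subject-level variables.
#' @param correlation Target correlation matrix over all 13 variables
#'   (symmetric, unit diagonal, positive semi-definite), or a list of one such
#'   matrix per intensity. Default [default_correlation()].
#' @param physics_consistency If `TRUE`, mechanical identities are imposed
#'   after sampling: `power_mean = force * velocity`, `time_limit =
#'   AWC/(power_mean - CP)` using the participant's anaerobic capacity (kJ,
#'   converted to J) and aerobic capacity (W), and `work = power_mean *
#'   time_limit / 1000` (kJ), each perturbed by relative Gaussian noise of
#'   scale `noise_scale`. Records with `power_mean <= CP` keep a positive
#'   resample of the marginal time limit instead.
#' @param noise_scale Relative SD of the consistency noise (0 = exact).
#' @param positive_only Enforce strictly positive measurements by bounded
#'   resampling (default `TRUE`).
#' @param seed Integer random seed; fixed seed gives bit-identical cohorts.
#'
#' @return An object of class `generator_config`.
#' @seealso [generate_cohort()], [planted_hub_config()]
#' @export
generator_config <- function(n_participants = 9,
                             intensities = 1:4,
                             means = NULL, sds = NULL,
                             subject_means = default_subject_means(),
                             subject_sds = default_subject_sds(),
                             correlation = default_correlation(),
                             physics_consistency = FALSE,
                             noise_scale = 0.05,
                             positive_only = TRUE,
                             seed = 1L) {
  if (n_participants < 3) stop("n_participants must be >= 3")
  n_int <- length(intensities)
  if (n_int < 1 || anyDuplicated(intensities)) {
    stop("intensities must be a non-empty vector of unique labels")
  }
  if (is.null(means)) means <- .default_means[, seq_len(min(n_int, 4)), drop = FALSE]
  if (is.null(sds))  sds  <- .default_sds[, seq_len(min(n_int, 4)), drop = FALSE]
  means <- .recycle_cols(as.matrix(means), n_int, .per_intensity_vars)
  sds   <- .recycle_cols(as.matrix(sds),   n_int, .per_intensity_vars)
  colnames(means) <- colnames(sds) <- as.character(intensities)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  subject_means <- subject_means[.subject_vars]
  subject_sds <- subject_sds[.subject_vars]
  if (anyNA(subject_means) || anyNA(subject_sds)) {
    stop("subject_means/subject_sds must cover: ", paste(.subject_vars, collapse = ", "))
  }
  if (any(subject_sds < 0)) stop("all SDs must be >= 0")

  if (!is.list(correlation)) correlation <- list(correlation)
  correlation <- rep_len(correlation, n_int)
  correlation <- lapply(correlation, .check_correlation_shape)
  names(correlation) <- as.character(intensities)

  structure(
    list(
      n_participants = as.integer(n_participants),
      intensities = intensities,
      means = means, sds = sds,
      subject_means = subject_means, subject_sds = subject_sds,
      correlation = correlation,
      physics_consistency = isTRUE(physics_consistency),
      noise_scale = noise_scale,
      positive_only = isTRUE(positive_only),
      seed = as.integer(seed),
      repair = NULL
    ),
    class = "generator_config"
  )
}

.recycle_cols <- function(m, n, rows) {
  if (is.null(rownames(m))) rownames(m) <- rows
  m <- m[rows, , drop = FALSE]
  if (anyNA(m)) stop("means/sds must have one row per variable: ", paste(rows, collapse = ", "))
  m[, rep_len(seq_len(ncol(m)), n), drop = FALSE]
}

.check_correlation_shape <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) dimnames(m) <- list(.all_vars, .all_vars)
  m <- m[.all_vars, .all_vars]
  if (!isSymmetric(m, tol = 1e-8)) stop("target correlation matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("target correlation matrix must have unit diagonal")
  m
}

# Eigenvalue clipping repair: negative eigenvalues are raised to eps and the
# diagonal re-normalised to 1 (cov2cor).
#' Repair a symmetric matrix to the nearest positive semi-definite correlation
#'
#' Clips negative eigenvalues to `eps`, reconstructs, and rescales the
#' diagonal back to 1. Used to fix hand-built target correlation matrices.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param eps Floor for clipped eigenvalues.
#' @return List with `matrix` (repaired, or `m` unchanged), `repaired`
#'   (logical) and `min_eigenvalue` of the input.
#' @export
nearest_psd <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  min_ev <- min(e$values)
  if (min_ev >= -1e-10) {
    return(list(matrix = m, repaired = FALSE, min_eigenvalue = min_ev))
  }
  v <- pmax(e$values, eps)
  m2 <- e$vectors %*% (v * t(e$vectors))
  m2 <- stats::cov2cor(m2)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 1
  dimnames(m2) <- dimnames(m)
  list(matrix = m2, repaired = TRUE, min_eigenvalue = min_ev)
}

#' Hub-structured target correlation matrix
#'
#' Builds a correlation matrix in which one variable (the planted hub) is
#' correlated at `hub_strength` with every other variable, and all remaining
#' pairs sit at `background`. Hand-built matrices of this shape are often not
#' positive semi-definite (the minimum eigenvalue of the zero-background case
#' is `1 - hub_strength * sqrt(k - 1)`), so the result is repaired with
#' [nearest_psd()] when needed; the repair is recorded in the `"repair"`
#' attribute.
#'
#' @param hub_variable Name of the hub variable (one of
#'   `fatigue_variables()$variable`).
#' @param hub_strength Correlation of the hub with every other variable.
#' @param background Correlation between all non-hub pairs;
#'   `0 <= background < hub_strength <= 0.95`.
#' @return Correlation matrix over all 13 variables with attribute `"repair"`.
#' @export
planted_hub_matrix <- function(hub_variable, hub_strength, background = 0) {
  if (!hub_variable %in% .all_vars) {
    stop("unknown hub_variable '", hub_variable, "'; expected one of: ",
         paste(.all_vars, collapse = ", "))
  }
  if (!(background >= 0 && background < hub_strength && hub_strength <= 0.95)) {
    stop("require 0 <= background < hub_strength <= 0.95")
  }
  v <- .all_vars
  m <- matrix(background, length(v), length(v), dimnames = list(v, v))
  m[hub_variable, ] <- m[, hub_variable] <- hub_strength
  diag(m) <- 1
  rep <- nearest_psd(m)
  out <- rep$matrix
  attr(out, "repair") <- rep[c("repaired", "min_eigenvalue")]
  out
}

#' Generator configuration with a planted hub correlation structure
#'
#' Convenience wrapper around [generator_config()] whose target correlation
#' links `hub_variable` to all other variables at `hub_strength` and all
#' remaining pairs at `background` — the fixture used to check that the
#' network pipeline recovers a known hub. `hub_variable` may be a vector with
#' one hub per intensity (recycled), planting different hubs at different
#' intensities.
#'
#' @inheritParams planted_hub_matrix
#' @param ... Passed to [generator_config()] (e.g. `n_participants`, `seed`).
#' @return A `generator_config` whose `repair` field records any PSD repair.
#' @export
planted_hub_config <- function(hub_variable, hub_strength, background = 0, ...) {
  cfg <- generator_config(...)
  hubs <- rep_len(hub_variable, length(cfg$intensities))
  mats <- lapply(hubs, planted_hub_matrix,
                 hub_strength = hub_strength, background = background)
  cfg$correlation <- lapply(mats, function(m) .check_correlation_shape(unclass(m)))
  names(cfg$correlation) <- as.character(cfg$intensities)
  cfg$repair <- lapply(mats, attr, "repair")
  cfg$hub <- hubs
  cfg
}

#' Generate a synthetic participant-by-intensity cohort
#'
#' Draws a complete participant x intensity grid of measurements with the
#' configured means, SDs and inter-variable correlation structure. See
#' [generator_config()] for the sampling model.
#'
#' @param config A `generator_config`.
#' @return A data.frame of class `fatigue_cohort`: columns `participant_id`,
#'   `intensity`, then the 13 measurement variables; one row per participant
#'   x intensity cell. The generator metadata (seed, any PSD repair) is
#'   attached as attribute `"generator"`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_participants = 9, seed = 42))
#' head(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  for (i in seq_along(config$correlation)) {
    ev <- eigen(config$correlation[[i]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop(sprintf(
        "target correlation matrix for intensity %s is not positive semi-definite (min eigenvalue %.6g); repair it first (see nearest_psd)",
        names(config$correlation)[i], min(ev)))
    }
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  p <- config$n_participants
  s_idx <- .subject_vars
  pi_idx <- .per_intensity_vars

  # subject-level latents from the first intensity's subject block
  sig1 <- config$correlation[[1]]
  z_s <- .draw_positive_block(
    n = p, sigma = sig1[s_idx, s_idx],
    mu = config$subject_means, sd = config$subject_sds,
    positive_only = config$positive_only, what = "subject-level variables"
  )

  rows <- vector("list", length(config$intensities))
  for (i in seq_along(config$intensities)) {
    sig <- config$correlation[[i]]
    x <- .draw_conditional_block(
      z_s$z, sig, s_idx, pi_idx,
      mu = config$means[, i], sd = config$sds[, i],
      positive_only = config$positive_only,
      intensity = config$intensities[i]
    )
    df <- data.frame(
      participant_id = sprintf("P%02d", seq_len(p)),
      intensity = config$intensities[i],
      x, z_s$x,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    rows[[i]] <- df
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  if (config$physics_consistency) {
    cohort <- .apply_physics(cohort, config)
  }

  attr(cohort, "generator") <- list(
    seed = config$seed, repair = config$repair,
    physics_consistency = config$physics_consistency,
    n_participants = p, intensities = config$intensities
  )
  class(cohort) <- c("fatigue_cohort", "data.frame")
  cohort
}

# Draw n rows ~ N(0, sigma), rescale to mu/sd, resample rows with nonpositive
# entries (bounded). Returns latents z and values x.
.draw_positive_block <- function(n, sigma, mu, sd, positive_only, what,
                                 max_attempts = 200) {
  z <- MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma)
  z <- matrix(z, nrow = n)
  x <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
  if (positive_only) {
    for (attempt in seq_len(max_attempts)) {
      bad <- which(apply(x, 1, function(r) any(r <= 0)))
      if (!length(bad)) break
      znew <- matrix(MASS::mvrnorm(length(bad), mu = rep(0, ncol(sigma)),
                                   Sigma = sigma), nrow = length(bad))
      z[bad, ] <- znew
      x[bad, ] <- sweep(sweep(znew, 2, sd, "*"), 2, mu, "+")
    }
    if (any(x <= 0)) {
      stop("could not draw strictly positive ", what,
           " after ", max_attempts, " resampling attempts")
    }
  }
  colnames(x) <- colnames(z) <- colnames(sigma)
  list(z = z, x = as.data.frame(x))
}

# Per-intensity block conditional on subject latents: z_p | z_s ~
# N(A z_s, Sigma_pp - A Sigma_sp), A = Sigma_ps Sigma_ss^{-1}.
.draw_conditional_block <- function(z_s, sig, s_idx, p_idx, mu, sd,
                                    positive_only, intensity,
                                    max_attempts = 200) {
  n <- nrow(z_s)
  sig_ss <- sig[s_idx, s_idx]
  sig_ps <- sig[p_idx, s_idx]
  A <- sig_ps %*% MASS::ginv(sig_ss)
  cond <- sig[p_idx, p_idx] - A %*% t(sig_ps)
  cond <- (cond + t(cond)) / 2
  ec <- eigen(cond, symmetric = TRUE)
  ec$values <- pmax(ec$values, 0)  # clip conditioning round-off
  cond <- ec$vectors %*% (ec$values * t(ec$vectors))
  mu_z <- z_s %*% t(A)

  draw <- function(idx) {
    e <- matrix(MASS::mvrnorm(length(idx), mu = rep(0, length(p_idx)),
                              Sigma = cond), nrow = length(idx))
    z <- mu_z[idx, , drop = FALSE] + e
    x <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
    x
  }
  x <- draw(seq_len(n))
  if (positive_only) {
    for (attempt in seq_len(max_attempts)) {
      bad <- which(apply(x, 1, function(r) any(r <= 0)))
      if (!length(bad)) break
      x[bad, ] <- draw(bad)
    }
    if (any(x <= 0)) {
      stop("could not draw strictly positive measurements at intensity ",
           intensity, " after ", max_attempts, " resampling attempts")
    }
  }
  colnames(x) <- p_idx
  as.data.frame(x)
}

# Mechanical identities: P = F*v, Tlim = AWC/(P - CP), W = P*Tlim/1000, each
# with relative Gaussian noise. CP (W) and AWC (J) come from the participant's
# aerobic/anaerobic capacities.
.apply_physics <- function(cohort, config, max_attempts = 200) {
  ns <- config$noise_scale
  rel_noise <- function(n) 1 + stats::rnorm(n, 0, ns)
  n <- nrow(cohort)
  p_mean <- cohort$force * cohort$velocity * rel_noise(n)
  cp <- cohort$aerobic_capacity
  awc_j <- cohort$anaerobic_capacity * 1000
  tlim <- cohort$time_limit
  feas <- p_mean > cp
  tlim[feas] <- (awc_j[feas] / (p_mean[feas] - cp[feas])) * rel_noise(sum(feas))
  if (any(!feas)) {
    # power at or below critical power: exhaustion time is not defined by the
    # hyperbola; keep a positive marginal resample of the configured tlim
    idx <- which(!feas)
    int_col <- match(as.character(cohort$intensity[idx]), colnames(config$means))
    mu <- config$means["time_limit", int_col]
    sd <- config$sds["time_limit", int_col]
    t_new <- stats::rnorm(length(idx), mu, sd)
    for (attempt in seq_len(max_attempts)) {
      bad <- t_new <= 0
      if (!any(bad)) break
      t_new[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    }
    if (any(t_new <= 0)) {
      stop("could not resample a positive time limit for participant(s) ",
           paste(unique(cohort$participant_id[idx][t_new <= 0]), collapse = ", "))
    }
    tlim[idx] <- t_new
  }
  work <- p_mean * tlim / 1000 * rel_noise(n)
  cohort$power_mean <- p_mean
  cohort$time_limit <- tlim
  cohort$work <- work
  cohort
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator config\n")
  cat("  participants:", x$n_participants,
      " intensities:", paste(x$intensities, collapse = ", "), "\n")
  cat("  physics consistency:", x$physics_consistency,
      " noise scale:", x$noise_scale, " seed:", x$seed, "\n")
  if (!is.null(x$repair)) {
    rep_any <- any(vapply(x$repair, function(r) isTRUE(r$repaired), logical(1)))
    cat("  correlation targets PSD-repaired:", rep_any, "\n")
  }
  invisible(x)
}
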