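# Hyperbolic critical-power model: Tlim = AWC / (P - CP). CP (W) is the power
# asymptote sustainable without fatigue; AWC (J) the finite work capacity
# above it.

#' Critical-power model parameters
#'
#' @param critical_power Critical power CP in watts (> 0).
#' @param anaerobic_work_capacity Anaerobic work capacity AWC in joules (> 0).
#' @param fit_method Label: `"hyperbolic"`, `"linearized"` or `"manual"`.
#' @param rss Residual sum of squares of the fit (`s^2` for the hyperbolic
#'   fit, `W^2` for the linearized fit), `NA` for manual parameters.
#' @return Object of class `cp_params`.
#' @export
cp_params <- function(critical_power, anaerobic_work_capacity,
                      fit_method = "manual", rss = NA_real_) {
  if (!is.finite(critical_power) || critical_power <= 0) {
    stop("critical_power must be a positive number (W)")
  }
  if (!is.finite(anaerobic_work_capacity) || anaerobic_work_capacity <= 0) {
    stop("anaerobic_work_capacity must be a positive number (J)")
  }
  structure(
    list(critical_power = critical_power,
         anaerobic_work_capacity = anaerobic_work_capacity,
         fit_method = fit_method, rss = rss,
         units = c(critical_power = "W", anaerobic_work_capacity = "J")),
    class = "cp_params"
  )
}

#' @export
print.cp_params <- function(x, ...) {
  cat(sprintf("Critical-power model (%s fit)\n", x$fit_method))
  cat(sprintf("  CP  = %.2f W\n  AWC = %.2f J (%.2f kJ)\n",
              x$critical_power, x$anaerobic_work_capacity,
              x$anaerobic_work_capacity / 1000))
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Predict time to exhaustion at a supra-critical power
#'
#' Evaluates `Tlim = AWC / (P - CP)` in seconds. Only defined above the
#' critical power: at or below CP the model predicts the effort can be
#' sustained without fatigue, and an error is raised.
#'
#' @param params A [cp_params()] object.
#' @param power Power output P in watts (vectorised).
#' @return Predicted time limit(s) in seconds.
#' @examples
#' predict_tlim(cp_params(100, 20000), 200)  # 200 s
#' @export
predict_tlim <- function(params, power) {
  stopifnot(inherits(params, "cp_params"))
  if (any(power <= params$critical_power)) {
    stop(sprintf(
      "power at or below critical power (%.2f W): effort sustainable without fatigue, time limit undefined",
      params$critical_power))
  }
  params$anaerobic_work_capacity / (power - params$critical_power)
}

.check_series <- function(power, time_limit) {
  if (length(power) != length(time_limit)) stop("power and time_limit lengths differ")
  if (length(power) < 2) stop("need at least 2 exhaustive trials")
  if (any(!is.finite(power)) || any(!is.finite(time_limit)) ||
      any(power <= 0) || any(time_limit <= 0)) {
    stop("all power and time_limit values must be positive and finite")
  }
  if (length(unique(power)) < 2) {
    stop("singular fit: all trial powers are identical")
  }
  out <- time_limit < 120 | time_limit > 600
  if (any(out)) {
    warning(sprintf(
      "%d trial(s) outside the 2-10 min exhaustion window usually recommended for critical-power estimation",
      sum(out)))
  }
  invisible(NULL)
}

#' Fit the critical-power model by linear regression of P on 1/t
#'
#' The hyperbola `Tlim = AWC/(P - CP)` rearranges to the linear form
#' `P = CP + AWC * (1/Tlim)`; ordinary least squares of power on inverse time
#' gives CP as the intercept and AWC as the slope (watt-seconds = joules).
#'
#' @param power Trial powers in watts (>= 2 distinct values).
#' @param time_limit Times to exhaustion in seconds.
#' @return A [cp_params()] with `fit_method = "linearized"`; RSS in W^2.
#' @export
fit_cp_linearized <- function(power, time_limit) {
  .check_series(power, time_limit)
  fit <- stats::lm(power ~ I(1 / time_limit))
  co <- stats::coef(fit)
  cp_params(critical_power = unname(co[1]),
            anaerobic_work_capacity = unname(co[2]),
            fit_method = "linearized",
            rss = sum(stats::residuals(fit)^2))
}

#' Fit the critical-power model by nonlinear least squares on the hyperbola
#'
#' Minimises `sum((t_obs - AWC/(P - CP))^2)` directly with Levenberg-
#' Marquardt, constraining CP below the smallest observed trial power (the
#' hyperbola is undefined otherwise). When `init` is omitted the linearized
#' fit supplies starting values, projected into the feasible region if its CP
#' estimate exceeds the smallest trial power.
#'
#' @inheritParams fit_cp_linearized
#' @param init Optional [cp_params()] with starting values; its CP must lie
#'   below `min(power)` or it is projected to `0.95 * min(power)` with a
#'   warning.
#' @param max_iter Iteration cap for the optimiser.
#' @return A [cp_params()] with `fit_method = "hyperbolic"`; RSS in s^2. On
#'   non-convergence an error is raised whose condition carries the best
#'   iterate as field `best`.
#' @examples
#' p <- c(180, 220, 300, 420)
#' t <- predict_tlim(cp_params(139.26, 47140), p)
#' fit_cp_hyperbolic(p, t)
#' @export
fit_cp_hyperbolic <- function(power, time_limit, init = NULL, max_iter = 200) {
  .check_series(power, time_limit)
  if (length(power) < 3) {
    warning("fewer than 3 trials: hyperbolic fit is exactly interpolating")
  }
  pmin_obs <- min(power)
  if (is.null(init)) {
    co <- stats::coef(stats::lm(power ~ I(1 / time_limit)))
    cp0 <- unname(co[1])
    awc0 <- unname(co[2])
  } else {
    stopifnot(inherits(init, "cp_params"))
    cp0 <- init$critical_power
    awc0 <- init$anaerobic_work_capacity
    if (cp0 >= pmin_obs) {
      warning(sprintf(
        "initial CP (%.2f W) at or above the smallest trial power (%.2f W); projected into the feasible region",
        cp0, pmin_obs))
    }
  }
  if (!is.finite(cp0) || cp0 <= 0 || cp0 >= pmin_obs) cp0 <- 0.95 * pmin_obs
  if (!is.finite(awc0) || awc0 <= 0) {
    awc0 <- max(stats::median(time_limit * (power - cp0)), 1)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      time_limit ~ awc / (power - cp),
      start = list(awc = awc0, cp = cp0),
      lower = c(awc = 1e-6, cp = 1e-6),
      upper = c(awc = Inf, cp = pmin_obs * (1 - 1e-9)),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    best <- cp_params(cp0, awc0, fit_method = "hyperbolic")
    cond <- simpleError(paste0("hyperbolic critical-power fit failed: ",
                               conditionMessage(fit)))
    cond$best <- best
    stop(cond)
  }
  co <- stats::coef(fit)
  cp_params(critical_power = unname(co["cp"]),
            anaerobic_work_capacity = unname(co["awc"]),
            fit_method = "hyperbolic",
            rss = sum(stats::residuals(fit)^2))
}

#' Fit critical-power parameters for every participant in a cohort
#'
#' Uses each participant's (mean power, time limit) pairs across intensities.
#'
#' @param cohort A `fatigue_cohort` data.frame (see [generate_cohort()],
#'   [read_cohort()]).
#' @param method `"hyperbolic"` (default) or `"linearized"`.
#' @return data.frame with one row per participant: `participant_id`,
#'   `critical_power_w`, `awc_j`, `awc_kj`, `fit_method`, `rss`.
#' @export
fit_cp_cohort <- function(cohort, method = c("hyperbolic", "linearized")) {
  method <- match.arg(method)
  ids <- unique(cohort$participant_id)
  rows <- lapply(ids, function(id) {
    d <- cohort[cohort$participant_id == id, ]
    fit <- withCallingHandlers(
      if (method == "hyperbolic") {
        tryCatch(fit_cp_hyperbolic(d$power_mean, d$time_limit),
                 error = function(e)
                   tryCatch(fit_cp_linearized(d$power_mean, d$time_limit),
                            error = function(e2) NULL))
      } else {
        tryCatch(fit_cp_linearized(d$power_mean, d$time_limit),
                 error = function(e) NULL)
      },
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(fit)) {
      warning("critical-power fit failed for participant ", id, "; reported as NA")
      fit <- list(critical_power = NA_real_, anaerobic_work_capacity = NA_real_,
                  fit_method = "failed", rss = NA_real_)
    }
    data.frame(participant_id = id,
               critical_power_w = fit$critical_power,
               awc_j = fit$anaerobic_work_capacity,
               awc_kj = fit$anaerobic_work_capacity / 1000,
               fit_method = fit$fit_method,
               rss = fit$rss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
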