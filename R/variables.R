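#' @keywords internal
"_PACKAGE"

# Canonical variable catalogue ------------------------------------------------
#
# Two roles: "per_intensity" variables are measured at every test intensity;
# "subject" variables characterise the participant and are constant across
# intensities. The network node set excludes time_limit, which is the fatigue
# outcome rather than a node.

.per_intensity_vars <- c(
  "power_mean", "power_peak", "force", "velocity", "time_limit",
  "work", "lactate_peak", "lactate_time", "heart_rate"
)

.subject_vars <- c("aerobic_capacity", "anaerobic_capacity", "lean_mass", "ipaq")

.all_vars <- c(.per_intensity_vars, .subject_vars)

.node_vars <- setdiff(.all_vars, "time_limit")

.var_units <- c(
  power_mean = "W", power_peak = "W", force = "N", velocity = "m/s",
  time_limit = "s", work = "kJ", lactate_peak = "mmol/L", lactate_time = "s",
  heart_rate = "bpm", aerobic_capacity = "W", anaerobic_capacity = "kJ",
  lean_mass = "%", ipaq = "a.u."
)

#' Variable catalogue for tethered-running fatigue tests
#'
#' Lists the mechanical, physiological and subject-level variables the package
#' models, with their measurement unit and role. Variables with role
#' `"per_intensity"` are measured once per participant at every exercise
#' intensity; `"subject"` variables are measured once per participant and are
#' constant across intensities. All variables except `time_limit` (the
#' time-to-exhaustion outcome) act as network nodes.
#'
#' @return A data.frame with columns `variable`, `role`, `unit`, `is_node`.
#' @examples
#' fatigue_variables()
#' @export
fatigue_variables <- function() {
  data.frame(
    variable = .all_vars,
    role = ifelse(.all_vars %in% .subject_vars, "subject", "per_intensity"),
    unit = unname(.var_units[.all_vars]),
    is_node = .all_vars %in% .node_vars,
    stringsAsFactors = FALSE
  )
}

#' Default network node set
#'
#' The twelve variables used as network nodes: five mechanical (force,
#' velocity, mean power, peak power, work), six physiological (heart rate,
#' peak blood lactate, lactate time, lean mass, aerobic and anaerobic
#' capacity) and the physical-activity questionnaire score.
#'
#' @return Character vector of node variable names.
#' @export
fatigue_nodes <- function() .node_vars

# Study-calibrated defaults ---------------------------------------------------
# Group means and SDs of a nine-participant, four-intensity tethered-running
# study; rows are variables, columns intensities 1..4.

.default_means <- matrix(
  c(
    247.84, 294.46, 412.71, 512.42,   # power_mean (W)
    380.34, 445.23, 585.19, 784.63,   # power_peak (W)
    120.05, 136.65, 161.86, 187.90,   # force (N)
    2.11,   2.19,   2.54,   2.77,     # velocity (m/s)
    626.08, 462.67, 236.64, 173.75,   # time_limit (s)
    162.45, 135.48,  92.00,  77.73,   # work (kJ)
    12.20,  12.52,  15.12,  15.34,    # lactate_peak (mmol/L)
    819.41, 709.33, 583.30, 433.75,   # lactate_time (s)
    180.11, 179.00, 180.00, 179.55    # heart_rate (bpm)
  ),
  nrow = 9, byrow = TRUE,
  dimnames = list(.per_intensity_vars, paste0("intensity_", 1:4))
)

.default_sds <- matrix(
  c(
    47.46,  40.18,  93.75, 105.25,
    48.91,  48.79, 123.14,  96.00,
    11.32,  17.53,  25.30,  27.55,
    0.33,   0.38,   0.40,   0.56,
    149.27, 133.29,  97.24,  62.68,
    56.04,  45.02,  25.03,  16.15,
    3.38,   4.49,   5.00,   5.49,
    287.44, 260.12, 219.01, 251.68,
    10.54,   9.82,   9.53,   8.42
  ),
  nrow = 9, byrow = TRUE,
  dimnames = list(.per_intensity_vars, paste0("intensity_", 1:4))
)

.default_subject_means <- c(
  aerobic_capacity = 139.26, anaerobic_capacity = 47.14,
  lean_mass = 91.49, ipaq = 2106.66
)

.default_subject_sds <- c(
  aerobic_capacity = 43.65, anaerobic_capacity = 26.06,
  lean_mass = 3.24, ipaq = 1162.06
)

#' Default per-intensity means and standard deviations
#'
#' Group means (`default_means()`) and standard deviations (`default_sds()`)
#' of the nine per-intensity variables at the four test intensities used to
#' calibrate the synthetic cohort generator.
#'
#' @return A 9 x 4 numeric matrix (variables x intensities).
#' @export
default_means <- function() .default_means

#' @rdname default_means
#' @export
default_sds <- function() .default_sds

#' Default subject-level means and standard deviations
#'
#' @return Named numeric vector over the four subject-level variables.
#' @export
default_subject_means <- function() .default_subject_means

#' @rdname default_subject_means
#' @export
default_subject_sds <- function() .default_subject_sds

#' Default target correlation matrix
#'
#' A plausible, block-structured inter-variable correlation matrix used as the
#' generator default. It is NOT an observed matrix from any study (raw
#' inter-variable correlations are not published for the calibration data);
#' it merely encodes strong correlations among the mechanical variables,
#' moderate correlations within the physiological block and between fitness
#' capacities and mechanical output, and weak residual coupling elsewhere.
#' The matrix is validated positive semi-definite.
#'
#' @return A 13 x 13 symmetric correlation matrix over all variables
#'   (per-intensity and subject-level), unit diagonal.
#' @export
default_correlation <- function() {
  v <- .all_vars
  k <- length(v)
  m <- matrix(0.15, k, k, dimnames = list(v, v))
  mech <- c("power_mean", "power_peak", "force", "velocity", "work")
  phys <- c("lactate_peak", "lactate_time", "heart_rate")
  caps <- c("aerobic_capacity", "anaerobic_capacity", "lean_mass", "ipaq")
  m[mech, mech] <- 0.6
  m[phys, phys] <- 0.35
  m[caps, caps] <- 0.3
  m[mech, caps] <- m[caps, mech] <- 0.4
  m[mech, phys] <- m[phys, mech] <- 0.25
  m["time_limit", ] <- m[, "time_limit"] <- 0.2
  m["time_limit", "work"] <- m["work", "time_limit"] <- 0.5
  m["time_limit", caps] <- m[caps, "time_limit"] <- 0.35
  diag(m) <- 1
  m
}
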