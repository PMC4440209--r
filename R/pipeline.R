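# End-to-end pipeline: simulate or ingest a cohort, fit the critical-power
# model per participant, build one thresholded correlation network per
# intensity, compute influence metrics, compare variables across intensities,
# and assemble a deterministic report.

# Accepted header aliases, canonicalised by lowercasing and squashing
# non-alphanumerics to "_".
.col_aliases <- list(
  participant_id = c("participant_id", "participant", "subject", "id"),
  intensity = c("intensity", "model", "test"),
  power_mean = c("power_mean", "mean_power", "power"),
  power_peak = c("power_peak", "peak_power"),
  force = "force",
  velocity = c("velocity", "speed"),
  time_limit = c("time_limit", "tlim", "time_to_exhaustion"),
  work = "work",
  lactate_peak = c("lactate_peak", "peak_lactate", "blood_lactate", "lactate"),
  lactate_time = c("lactate_time", "peak_lactate_time", "time_to_peak_lactate"),
  heart_rate = c("heart_rate", "hr"),
  aerobic_capacity = c("aerobic_capacity", "critical_power_capacity"),
  anaerobic_capacity = c("anaerobic_capacity", "awc"),
  lean_mass = c("lean_mass", "lean_mass_pct"),
  ipaq = c("ipaq", "ipaq_score")
)

.canon_header <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(trimws(x))))

#' Read a cohort from CSV
#'
#' One row per participant x intensity. Headers are matched case-insensitively
#' against documented aliases (e.g. "mean power" maps to `power_mean`).
#' Validates that every measurement cell is numeric and that the participant
#' x intensity grid is complete.
#'
#' @param path CSV file path.
#' @return A `fatigue_cohort` data.frame with canonical column names.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(raw) || !ncol(raw)) stop("empty cohort file: ", path)
  canon <- .canon_header(names(raw))
  lookup <- unlist(lapply(names(.col_aliases), function(k) {
    stats::setNames(rep(k, length(.col_aliases[[k]])), .col_aliases[[k]])
  }))
  mapped <- lookup[canon]
  if (anyNA(mapped)) {
    stop("unknown column(s): ", paste(names(raw)[is.na(mapped)], collapse = ", "),
         "; accepted names (or aliases of): ",
         paste(names(.col_aliases), collapse = ", "))
  }
  if (anyDuplicated(mapped)) {
    stop("duplicate columns after alias mapping: ",
         paste(mapped[duplicated(mapped)], collapse = ", "))
  }
  names(raw) <- mapped
  missing <- setdiff(c("participant_id", "intensity", .all_vars), mapped)
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))

  for (v in .all_vars) {
    col <- raw[[v]]
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   col[bad], v, bad))
    }
    raw[[v]] <- num
  }
  validate_cohort(raw)
}

#' Validate a cohort table
#'
#' Checks grid completeness (every participant at every intensity, no
#' duplicates) and positivity of all measurements.
#'
#' @param cohort data.frame with canonical columns.
#' @return The cohort, classed `fatigue_cohort`.
#' @export
validate_cohort <- function(cohort) {
  ids <- unique(cohort$participant_id)
  ints <- unique(cohort$intensity)
  tab <- table(cohort$participant_id, cohort$intensity)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete or duplicated grid: participant '%s' x intensity '%s' appears %d time(s)",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]],
                 tab[bad[1], bad[2]]))
  }
  vals <- as.matrix(cohort[, .all_vars])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all measurements must be positive and finite")
  }
  if (!inherits(cohort, "fatigue_cohort")) {
    class(cohort) <- c("fatigue_cohort", class(cohort))
  }
  cohort
}

#' Write a cohort to CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, c("participant_id", "intensity", .all_vars)],
                   path, row.names = FALSE)
  invisible(path)
}

# FNV-1a 32-bit hash of a string, for report provenance.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply in doubles without exceeding 2^53
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full fatigue-network analysis pipeline
#'
#' Stages: obtain a cohort (simulate via the generator, or read a CSV), fit
#' the critical-power model per participant, build one thresholded
#' correlation network per intensity, compute node influence metrics and
#' maximal nodes, compare variables across intensities (ANOVA + SNK), and
#' assemble a report. With a fixed configuration (including the generator
#' seed) the report is byte-identical across runs.
#'
#' @param input `"simulate"` (default) to draw a synthetic cohort from
#'   `config$generator`, a path to a cohort CSV, or a cohort data.frame.
#' @param config List of settings: `generator` (a [generator_config()]),
#'   `weight_mode` (`"raw"`/`"max_normalized"`), `thresholds`
#'   (`c(moderate, high)`), `variables` (node set), `alpha`,
#'   `betweenness_mode`, `cp_method`. Missing entries take defaults.
#' @param out_dir Optional directory: writes `report.json`, `cohort.csv`,
#'   per-intensity `links_<i>.csv` and `metrics_<i>.csv`, and
#'   `group_stats.csv`.
#' @return A `run_report` list: `provenance`, `cohort`, `cp`,
#'   `intensity_summaries`, `networks`, `metrics`, `group_stats`.
#' @examples
#' rep <- run_pipeline(config = list(generator = generator_config(seed = 3)))
#' rep$intensity_summaries[[1]]$hub_nodes
#' @export
run_pipeline <- function(input = "simulate", config = list(), out_dir = NULL) {
  defaults <- list(
    generator = generator_config(),
    weight_mode = "raw",
    thresholds = c(0.3, 0.7),
    variables = fatigue_nodes(),
    alpha = 0.05,
    betweenness_mode = "fractional",
    cp_method = "hyperbolic"
  )
  config <- utils::modifyList(defaults, config)

  cohort <- if (is.data.frame(input)) {
    validate_cohort(input)
  } else if (identical(input, "simulate")) {
    generate_cohort(config$generator)
  } else {
    read_cohort(input)
  }
  ints <- unique(cohort$intensity)

  cp <- fit_cp_cohort(cohort, method = config$cp_method)

  networks <- list()
  metrics <- list()
  summaries <- list()
  for (i in seq_along(ints)) {
    net <- build_network(cohort, intensity = ints[i],
                         variables = config$variables,
                         mode = config$weight_mode,
                         thresholds = config$thresholds)
    mt <- node_metrics(net, betweenness_mode = config$betweenness_mode)
    rk <- rank_nodes(mt)
    networks[[i]] <- net
    metrics[[i]] <- mt
    summaries[[i]] <- list(
      intensity = ints[i],
      n_links = n_links(net),
      mean_time_limit = mean(cohort$time_limit[cohort$intensity == ints[i]]),
      hub_nodes = rk$hub,
      max_eigen_nodes = rk$max_eigen,
      max_betweenness_nodes = rk$max_betweenness,
      spectral_radius = attr(mt, "spectral_radius"),
      stability = attr(mt, "stability")
    )
  }
  names(networks) <- names(metrics) <- names(summaries) <- as.character(ints)

  stats_vars <- intersect(.per_intensity_vars, config$variables)
  stats_vars <- union(stats_vars, "time_limit")
  group_stats <- compare_intensities(cohort, variables = stats_vars,
                                     alpha = config$alpha)

  provenance <- list(
    package_version = as.character(utils::packageVersion("fatiguenet")),
    seed = config$generator$seed,
    weight_mode = config$weight_mode,
    thresholds = config$thresholds,
    alpha = config$alpha,
    betweenness_mode = config$betweenness_mode,
    cp_method = config$cp_method,
    input = if (is.data.frame(input)) "data.frame" else input,
    config_hash = .fnv1a(.serialize_config(config))
  )

  report <- structure(
    list(provenance = provenance, cohort = cohort, cp = cp,
         intensity_summaries = summaries, networks = networks,
         metrics = metrics, group_stats = group_stats),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

.serialize_config <- function(config) {
  cfg <- config
  cfg$generator <- unclass(cfg$generator)
  as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                force = TRUE))
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (provenance, critical-power fits, per-intensity
#' summaries with 6-significant-digit numbers, group statistics), plus
#' full-precision CSV sidecars: the cohort, a link list and node-metrics
#' table per intensity, and the group-statistics table.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig6 <- function(x) signif(x, 6)

  json <- list(
    provenance = report$provenance,
    cp = lapply(seq_len(nrow(report$cp)), function(i) {
      r <- report$cp[i, ]
      list(participant_id = r$participant_id,
           critical_power_w = sig6(r$critical_power_w),
           awc_kj = sig6(r$awc_kj), fit_method = r$fit_method,
           rss = sig6(r$rss))
    }),
    intensity_summaries = lapply(report$intensity_summaries, function(s) {
      s$mean_time_limit <- sig6(s$mean_time_limit)
      s$spectral_radius <- sig6(s$spectral_radius)
      s
    }),
    group_stats = lapply(seq_len(nrow(report$group_stats)), function(i) {
      r <- as.list(report$group_stats[i, ])
      r$F_statistic <- sig6(r$F_statistic)
      r$p_value <- sig6(r$p_value)
      r
    })
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  write_cohort(report$cohort, file.path(out_dir, "cohort.csv"))
  for (i in names(report$networks)) {
    utils::write.csv(link_list(report$networks[[i]]),
                     file.path(out_dir, paste0("links_intensity_", i, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$metrics[[i]]),
                     file.path(out_dir, paste0("metrics_intensity_", i, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$group_stats, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Fatigue-network pipeline report\n")
  for (s in x$intensity_summaries) {
    cat(sprintf(
      "  intensity %s: %d links, mean tlim %.1f s, hub: %s, max eigen: %s, max betweenness: %s, radius %.3f (%s)\n",
      s$intensity, s$n_links, s$mean_time_limit,
      paste(s$hub_nodes, collapse = "/"),
      paste(s$max_eigen_nodes, collapse = "/"),
      paste(s$max_betweenness_nodes, collapse = "/"),
      s$spectral_radius, s$stability))
  }
  invisible(x)
}
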