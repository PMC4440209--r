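# Synthetic cohort generator: moments, correlation structure, determinism,
# physics identities, planted-hub configs.

test_that("zero SDs and diagonal correlation give the configured means exactly", {
  cfg <- generator_config(
    n_participants = 5, intensities = 1:2,
    means = default_means()[, 1:2], sds = default_means()[, 1:2] * 0,
    subject_sds = default_subject_sds() * 0,
    correlation = diag(13), seed = 1
  )
  co <- generate_cohort(cfg)
  for (i in 1:2) {
    slice <- co[co$intensity == i, rownames(default_means())]
    expect_true(all(vapply(seq_along(slice), function(j) {
      all(slice[[j]] == default_means()[j, i])
    }, logical(1))))
  }
  expect_true(all(co$ipaq == default_subject_means()["ipaq"]))
})

test_that("cohort is a complete grid with subject variables constant per participant", {
  co <- generate_cohort(generator_config(n_participants = 7, seed = 2))
  expect_equal(nrow(co), 7 * 4)
  expect_true(all(table(co$participant_id, co$intensity) == 1))
  for (v in c("lean_mass", "aerobic_capacity", "anaerobic_capacity", "ipaq")) {
    per_id <- tapply(co[[v]], co$participant_id, function(x) length(unique(x)))
    expect_true(all(per_id == 1))
  }
  expect_true(all(as.matrix(co[, fatigue_variables()$variable]) > 0))
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  cfg <- generator_config(n_participants = 9, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # and a different seed does not
  cfg2 <- generator_config(n_participants = 9, seed = 124)
  expect_false(identical(generate_cohort(cfg)$force, generate_cohort(cfg2)$force))
})

test_that("a targeted pairwise correlation is recovered in large samples", {
  m <- diag(13)
  dimnames(m) <- list(fatigue_variables()$variable, fatigue_variables()$variable)
  m["force", "power_mean"] <- m["power_mean", "force"] <- 0.9
  cfg <- generator_config(n_participants = 500, intensities = 1,
                          correlation = m, seed = 7)
  co <- generate_cohort(cfg)
  expect_lt(abs(cor(co$force, co$power_mean) - 0.9), 0.05)
})

test_that("the full sample correlation matrix tracks the target at every intensity", {
  cfg <- generator_config(n_participants = 2000, seed = 11,
                          positive_only = FALSE)
  co <- generate_cohort(cfg)
  vars <- fatigue_variables()$variable
  for (i in 1:4) {
    slice <- as.matrix(co[co$intensity == i, vars])
    dev <- abs(cor(slice) - default_correlation())
    expect_lt(max(dev), 0.1)
  }
})

test_that("sample moments match configuration; positivity truncation follows the closed form", {
  # Without truncation the configured means/SDs are exact population moments.
  cfg <- generator_config(n_participants = 10000, seed = 31, positive_only = FALSE)
  co <- generate_cohort(cfg)
  for (i in 1:4) {
    slice <- co[co$intensity == i, ]
    for (v in rownames(default_means())) {
      expect_lt(abs(mean(slice[[v]]) - default_means()[v, i]),
                0.02 * default_means()[v, i])
      expect_lt(abs(sd(slice[[v]]) - default_sds()[v, i]),
                0.02 * default_means()[v, i] + 0.03 * default_sds()[v, i])
    }
  }
  # With truncation-by-resampling (the default), the study calibration target
  # still holds where mean/SD is large ...
  co_t <- generate_cohort(generator_config(n_participants = 10000, seed = 32))
  tl1 <- co_t$time_limit[co_t$intensity == 1]
  expect_lt(abs(mean(tl1) - 626.08), 0.02 * 626.08)
  # ... and the induced bias matches the zero-truncated normal closed form for
  # the one per-intensity cell where it is material (lactate time, intensity 4).
  lt4 <- co_t$lactate_time[co_t$intensity == 4]
  tm <- truncnorm_moments(433.75, 251.68)
  expect_lt(abs(mean(lt4) - tm$mean), 0.025 * tm$mean)
  expect_lt(abs(sd(lt4) - tm$sd), 0.04 * tm$sd)
  expect_gt(min(lt4), 0)
})

test_that("physics consistency imposes the mechanical identities", {
  cfg <- generator_config(n_participants = 50, physics_consistency = TRUE,
                          noise_scale = 0, seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(co$power_mean, co$force * co$velocity, tolerance = 1e-12)
  expect_equal(co$work, co$power_mean * co$time_limit / 1000, tolerance = 1e-12)
  # where power exceeds CP, the hyperbola fixes the time limit
  feas <- co$power_mean > co$aerobic_capacity
  expect_true(any(feas))
  expect_equal(co$time_limit[feas],
               co$anaerobic_capacity[feas] * 1000 /
                 (co$power_mean[feas] - co$aerobic_capacity[feas]),
               tolerance = 1e-12)
  expect_true(all(co$time_limit > 0))
})

test_that("non-PSD correlation targets are rejected with the offending eigenvalue", {
  m <- diag(13)
  dimnames(m) <- list(fatigue_variables()$variable, fatigue_variables()$variable)
  m["force", "velocity"] <- m["velocity", "force"] <- 0.9
  m["force", "work"] <- m["work", "force"] <- 0.9
  m["velocity", "work"] <- m["work", "velocity"] <- -0.9  # impossible triangle
  cfg <- generator_config(correlation = m, seed = 1)
  expect_error(generate_cohort(cfg), "positive semi-definite.*eigenvalue|eigenvalue")
})

test_that("planted hub matrices have the hub structure, with PSD repair recorded", {
  ph <- planted_hub_matrix("velocity", 0.8, 0.1)
  off <- setdiff(colnames(ph), "velocity")
  # hub row constant and strictly above the constant background
  expect_equal(length(unique(round(ph["velocity", off], 10))), 1)
  bg <- ph[off, off][upper.tri(diag(length(off)))]
  expect_equal(length(unique(round(bg, 10))), 1)
  expect_gt(ph["velocity", off[1]], bg[1])
  expect_gte(min(eigen(ph, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_true(attr(ph, "repair")$repaired)

  # a strong hub over many variables is never PSD as drawn: the minimum
  # eigenvalue of the zero-background construction is 1 - s*sqrt(k-1)
  ph2 <- planted_hub_matrix("force", 0.9, 0)
  k <- ncol(ph2)
  expect_equal(attr(ph2, "repair")$min_eigenvalue, 1 - 0.9 * sqrt(k - 1),
               tolerance = 1e-8)
  expect_true(attr(ph2, "repair")$repaired)
})

test_that("planted hub config validates its preconditions", {
  expect_error(planted_hub_config("not_a_variable", 0.8, 0.1), "unknown hub_variable")
  expect_error(planted_hub_config("velocity", 0.5, 0.5), "background < hub_strength")
  expect_error(planted_hub_config("velocity", 0.99, 0.1), "hub_strength <= 0.95")
})

test_that("generator config rejects invalid shapes", {
  expect_error(generator_config(n_participants = 2), ">= 3")
  bad <- default_correlation(); bad[1, 2] <- 0.5  # asymmetric
  expect_error(generator_config(correlation = bad), "symmetric")
  bad2 <- default_correlation(); diag(bad2)[3] <- 0.9
  expect_error(generator_config(correlation = bad2), "unit diagonal")
})
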