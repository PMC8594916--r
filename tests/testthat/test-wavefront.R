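lbs_grid <- seq(1.9, 2.9, by = 0.05)

test_that("wavefront fits reproduce the exact linear and exponential families", {
  alpha <- 0.01
  tab_e <- make_growth_table(lbs_grid, "exponential", list(alpha = alpha))
  fits_e <- fit_wavefronts(tab_e)
  expect_equal(fits_e$slope, exp(alpha * fits_e$t), tolerance = 1e-8)
  expect_equal(fits_e$intercept, rep(0, nrow(fits_e)), tolerance = 1e-8)

  a <- 0.03
  tab_l <- make_growth_table(lbs_grid, "linear", list(a = a))
  fits_l <- fit_wavefronts(tab_l)
  expect_equal(fits_l$slope, rep(1, nrow(fits_l)), tolerance = 1e-8)
  expect_equal(fits_l$intercept, a * fits_l$t, tolerance = 1e-8)
})

test_that("quadratic wavefront terms vanish on linear-in-lb data", {
  tab <- make_growth_table(lbs_grid, "exponential", list(alpha = 0.01))
  fits2 <- fit_wavefronts(tab, order = 2)
  expect_lt(max(abs(fits2$quad)), 1e-7)
  # no meaningful goodness-of-fit gain over order 1
  fits1 <- fit_wavefronts(tab, order = 1)
  expect_equal(sum(fits2$residual_sd^2), sum(fits1$residual_sd^2),
               tolerance = 1e-6)
})

test_that("division cutoff is the minimum generation time with a proper cdf", {
  tab <- make_divided_table(lb = c(2, 2.2, 2.4), ld = c(3.5, 4, 4.5),
                            T = c(42, 51, 63))
  cut <- division_cutoff(tab)
  expect_equal(cut$t_cut, 42)
  expect_equal(cut$divided_fraction(0), 0)
  expect_equal(cut$divided_fraction(41.9), 0)
  expect_equal(cut$divided_fraction(63), 1)
  expect_true(all(diff(cut$divided_fraction(seq(0, 70, 1))) >= 0))
})

test_that("conditioning on survivors underestimates population growth rates", {
  cfg <- sim_config(growth_mode = "linear", growth_cv = 0.2,
                    division_rule = "adder", meas_noise_sd = 0,
                    n_cells = 500, n_founders = 50)
  tr <- attr(simulate_colony(cfg, seed = 29), "truth")
  div <- tr[!is.na(tr$generation_time_true), ]
  t_cut <- min(div$generation_time_true)
  survivors <- div$growth_multiplier[div$generation_time_true > t_cut + 15]
  expect_lt(mean(survivors), mean(div$growth_multiplier))
})

test_that("trajectory families evaluate the fits and mask post-cutoff times", {
  alpha <- 0.01
  tab <- make_growth_table(lbs_grid, "exponential", list(alpha = alpha), T = 45)
  fits <- fit_wavefronts(tab)
  fam <- build_trajectories(fits, lb_grid = c(2.0, 2.5), t_cut = 30)
  expect_equal(fam$surface[, 1], 2.0 * exp(alpha * fam$time), tolerance = 1e-8)
  expect_false(any(fam$valid[fam$time > 30]))
  expect_true(all(fam$valid[fam$time <= 30]))
  expect_warning(build_trajectories(fits, lb_grid = c(2.0, 5.0), t_cut = 30),
                 "extrapolation")
})

test_that("trajectory families match per-cell averages of similar-born cells", {
  cfg <- sim_config(growth_mode = "rag", meas_noise_sd = 0.05,
                    n_cells = 600, n_founders = 60)
  tab <- simulate_colony(cfg, seed = 77)
  inf <- infer_elongation(tab, lb_grid = c(2.1, 2.5))
  tr <- attr(tab, "truth")
  for (j in c(1, 2)) {
    lb0 <- inf$family$lb[j]
    ids <- tr$cell_id[abs(tr$lb_true - lb0) <= 0.05]
    sub <- tab$frames[tab$frames$cell_id %in% ids, ]
    avg <- tapply(sub$length_um, sub$time_min, mean)
    tt <- as.numeric(names(avg))
    keep <- tt %in% inf$family$time[inf$family$valid] &
      tapply(sub$length_um, sub$time_min, length) >= 10
    pred <- inf$family$surface[match(tt[keep], inf$family$time), j]
    expect_equal(as.numeric(avg[keep]), as.numeric(pred), tolerance = 0.05)
  }
})

test_that("the attenuation factor matches the regression-dilution oracle", {
  cfg <- sim_config(growth_mode = "exponential", growth_cv = 0,
                    meas_noise_sd = 0.05, n_cells = 2000, n_founders = 100)
  tab <- simulate_colony(cfg, seed = 57)
  tr <- attr(tab, "truth")
  lam_true <- var(tr$lb_true) / (var(tr$lb_true) + 0.05^2)
  att <- estimate_attenuation(tab)
  expect_equal(att$lambda, lam_true, tolerance = 0.01)
  expect_equal(att$noise_sd, 0.05, tolerance = 0.1)
  # supplying the known noise sd gives the analytic factor for observed lb
  att2 <- estimate_attenuation(tab, noise_sd = 0.05)
  expect_equal(att2$lambda, 1 - 0.05^2 / var(tab$cells$lb), tolerance = 1e-12)
  expect_error(estimate_attenuation(tab, noise_sd = 10), "degenerate")
})

test_that("bias correction is the identity without noise and fixes attenuation", {
  tab0 <- make_growth_table(lbs_grid, "exponential", list(alpha = 0.01))
  fits0 <- fit_wavefronts(tab0)
  corr0 <- correct_birth_bias(tab0, fits0)
  expect_equal(corr0$slope, fits0$slope, tolerance = 1e-6)
  expect_equal(corr0$intercept, fits0$intercept, tolerance = 1e-6)

  cfg <- sim_config(growth_mode = "exponential", growth_cv = 0,
                    meas_noise_sd = 0.05, n_cells = 1500, n_founders = 80)
  tab <- simulate_colony(cfg, seed = 61)
  alpha <- cfg$growth_params$alpha
  fits <- fit_wavefronts(tab)
  corr <- correct_birth_bias(tab, fits)
  # corrected family starts exactly on the identity
  fam <- suppressWarnings(build_trajectories(corr, lb_grid = c(2.0, 2.5),
                                             t_cut = Inf))
  expect_equal(fam$surface[fam$time == 0, ], c(2.0, 2.5),
               ignore_attr = TRUE, tolerance = 1e-12)
  # recovered exponential rate within 5% of truth
  use <- corr$t > 0 & corr$t <= division_cutoff(tab)$t_cut
  alpha_hat <- sum(corr$t[use] * log(corr$slope[use])) / sum(corr$t[use]^2)
  expect_equal(alpha_hat, alpha, tolerance = 0.05)
  # uncorrected slopes are attenuated below the corrected ones
  expect_true(all(fits$slope[fits$t > 0] < corr$slope[corr$t > 0]))
})

test_that("elongation-rate curves match the generating laws", {
  a <- 0.03
  fam_l <- build_trajectories(fit_wavefronts(
    make_growth_table(lbs_grid, "linear", list(a = a))),
    lb_grid = c(2.0, 2.4, 2.8), t_cut = Inf)
  r_l <- elongation_rate_curves(fam_l)
  expect_equal(as.vector(r_l$rate), rep(a, length(r_l$rate)),
               tolerance = 1e-8)

  alpha <- 0.01
  fam_e <- build_trajectories(fit_wavefronts(
    make_growth_table(lbs_grid, "exponential", list(alpha = alpha))),
    lb_grid = c(2.0, 2.4, 2.8), t_cut = Inf)
  r_e <- elongation_rate_curves(fam_e)
  interior <- seq(3, length(r_e$time) - 2)
  L <- fam_e$surface[interior, ]
  expect_equal(as.vector(r_e$rate[interior, ]) / as.vector(alpha * L),
               rep(1, length(L)), tolerance = 0.005)

  expect_error(elongation_rate_curves(fam_e, smoothing_window = 4), "odd")
  expect_error(elongation_rate_curves(fam_e, smoothing_window = 99),
               "larger than the valid")
})

test_that("noise-free RAG families are recovered within 3% RMS", {
  p <- rag_params(v_sat = 0.04, s0 = 0.65, beta = log(2) / 8)
  cfg <- sim_config(growth_mode = "rag", growth_params = p, growth_cv = 0,
                    meas_noise_sd = 0, n_cells = 300, n_founders = 30)
  tab <- simulate_colony(cfg, seed = 83)
  inf <- infer_elongation(tab)
  truth <- sapply(inf$rates$lb, function(lb) rag_rate(inf$rates$time, p))
  rms <- sqrt(mean((inf$rates$rate - truth)^2)) / mean(truth)
  expect_lt(rms, 0.03)
})

test_that("inference is idempotent on reconstructed noise-free families", {
  alpha <- 0.01
  fam <- build_trajectories(fit_wavefronts(
    make_growth_table(lbs_grid, "exponential", list(alpha = alpha))),
    lb_grid = seq(2.0, 2.8, 0.1), t_cut = Inf)
  # feed the averaged trajectories back in as cells
  frames <- do.call(rbind, lapply(seq_along(fam$lb), function(j)
    data.frame(cell_id = sprintf("avg%02d", j), parent_id = NA_character_,
               time_min = fam$time, length_um = fam$surface[, j])))
  fam2 <- build_trajectories(fit_wavefronts(lineage_table(frames)),
                             lb_grid = fam$lb, t_cut = Inf)
  expect_equal(fam2$surface, fam$surface, tolerance = 1e-8)
})

test_that("reverse-time families match the generating laws until the bound", {
  a <- 0.03
  tab_l <- make_growth_table(seq(1.9, 2.9, 0.05), "linear", list(a = a), T = 45)
  rev_l <- reverse_time_family(tab_l, ld_grid = c(3.5, 4.0))
  r <- elongation_rate_curves(rev_l)
  expect_equal(as.vector(r$rate), rep(a, length(r$rate)), tolerance = 1e-8)

  alpha <- 0.01
  tab_e <- make_growth_table(seq(1.9, 2.9, 0.05), "exponential",
                             list(alpha = alpha), T = 45)
  rev_e <- reverse_time_family(tab_e, ld_grid = c(3.5, 4.0))
  expect_equal(rev_e$surface[, 1], 3.5 * exp(alpha * rev_e$time),
               tolerance = 1e-8)
  expect_true(all(rev_e$valid))
})

test_that("bootstrap bands bracket the estimate and shrink with sample size", {
  cfg_s <- sim_config(growth_mode = "rag", n_cells = 150, n_founders = 15)
  tab_s <- simulate_colony(cfg_s, seed = 3)
  expect_error(bootstrap_bands(tab_s, n_boot = 50), "at least 100")
  bb_s <- suppressWarnings(bootstrap_bands(tab_s, n_boot = 150, seed = 5))
  expect_true(all(bb_s$band_lower <= bb_s$rate + 1e-12, na.rm = TRUE))
  expect_true(all(bb_s$band_upper >= bb_s$rate - 1e-12, na.rm = TRUE))

  cfg_b <- sim_config(growth_mode = "rag", n_cells = 600, n_founders = 60)
  bb_b <- suppressWarnings(bootstrap_bands(simulate_colony(cfg_b, seed = 3),
                                           n_boot = 150, seed = 5))
  ratio <- median(bb_b$band_sd, na.rm = TRUE) /
    median(bb_s$band_sd, na.rm = TRUE)
  expect_equal(ratio, 0.5, tolerance = 0.5)
})
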