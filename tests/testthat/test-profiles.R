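test_that("background correction subtracts the mid-zone minimum and is idempotent", {
  # flat profile corrects to zero everywhere
  flat <- intensity_profile("f", seq(0, 4, 0.02), rep(100, 201))
  cf <- correct_background(flat)
  expect_equal(cf$corrected, rep(0, 201))
  expect_equal(attr(cf, "background"), 100)

  # plasma 50 + polar peaks: mid-cell ~ 0, peaks reduced by 50
  p <- make_profile(baseline = 50)
  cp <- correct_background(p)
  mid <- abs(cp$positions - 2) < 0.3
  expect_lt(max(cp$corrected[mid]), 1e-6)
  expect_equal(max(cp$corrected), max(p$intensities) - 50, tolerance = 1e-9)
  expect_false(attr(cp, "septal_flag"))

  # idempotent: correcting twice equals correcting once
  cpp <- correct_background(cp)
  expect_equal(cpp$corrected, cp$corrected)

  # a septal peak at mid-cell: minimum taken beside the peak, flagged
  x <- seq(0, 4, 0.02)
  y <- 50 + 80 * exp(-((x - 2) / 0.1)^2)
  sept <- correct_background(intensity_profile("s", x, y))
  expect_equal(attr(sept, "background"), 50, tolerance = 1)
  expect_true(attr(sept, "septal_flag"))
})

test_that("polar intensities quantify the pole regions symmetrically", {
  zero <- intensity_profile("z", seq(0, 4, 0.02), rep(0, 201))
  zero$corrected <- zero$intensities
  pi0 <- polar_intensity(zero)
  expect_equal(unlist(pi0), c(new_pole = 0, old_pole = 0, total = 0))

  # single peak fully within the new-pole region
  x <- seq(0, 4, 0.02)
  y <- 30 * dnorm(x, 0.3, 0.08)
  p <- intensity_profile("n", x, y)
  p$corrected <- p$intensities
  pin <- polar_intensity(p)
  expect_gt(pin$new_pole, 1)
  expect_equal(pin$old_pole, 0, tolerance = 1e-9)

  # reversing the profile swaps the pole values
  pr <- intensity_profile("r", x, rev(y))
  pr$corrected <- pr$intensities
  pir <- polar_intensity(pr)
  expect_equal(pir$old_pole, pin$new_pole, tolerance = 1e-9)
  expect_equal(pir$new_pole, pin$old_pole, tolerance = 1e-9)
  expect_equal(pir$total, pin$total, tolerance = 1e-9)

  expect_error(polar_intensity(p, width = 3), "overlap")
  expect_error(polar_intensity(intensity_profile("u", x, y)),
               "not background-corrected")
})

test_that("moving averages over length match brute force", {
  expect_equal(moving_average_by_length(c(2, 3, 4), c(5, 5, 5))$mean,
               rep(5, nrow(moving_average_by_length(c(2, 3, 4), c(5, 5, 5)))))
  set.seed(8)
  lens <- runif(100, 2, 6)
  vals <- rnorm(100)
  at <- seq(2.5, 5.5, by = 0.25)
  got <- moving_average_by_length(lens, vals, window = 0.7, at = at)
  brute <- vapply(at, function(x) mean(vals[abs(lens - x) <= 0.7]), numeric(1))
  expect_equal(got$mean, brute[!is.nan(brute)])
  # identity curve on dense uniform data
  lens2 <- seq(2, 6, by = 0.01)
  got2 <- moving_average_by_length(lens2, lens2, window = 0.5,
                                   at = seq(3, 5, 0.25))
  expect_equal(got2$mean, got2$length, tolerance = 1e-9)
})

test_that("tip segments partition the polar signal", {
  p <- correct_background(make_profile(baseline = 20))
  edges <- c(0, 0.2, 0.4, 0.6, 0.8)
  seg <- tip_segment_intensities(p, edges)
  expect_equal(nrow(seg), 4L)
  # weighted segment means reconstruct the mean over the union
  d_new <- p$positions
  sel <- d_new < 0.8
  w <- vapply(seq_len(4), function(i)
    sum(d_new >= edges[i] & d_new < edges[i + 1]), numeric(1))
  expect_equal(sum(seg$new_pole * w) / sum(w), mean(p$corrected[sel]),
               tolerance = 1e-9)
  zero <- intensity_profile("z", seq(0, 4, 0.02), rep(0, 201))
  zero$corrected <- zero$intensities
  expect_true(all(tip_segment_intensities(zero, edges)$new_pole == 0))
  expect_error(tip_segment_intensities(p, c(0.4, 0.2)), "increasing")
})

test_that("proportionality is detected and offsets are flagged", {
  x <- seq(1, 10, length.out = 20)
  pf <- proportionality_fit(x, 3 * x)
  expect_equal(pf$slope, 3, tolerance = 1e-9)
  expect_equal(pf$intercept, 0, tolerance = 1e-9)
  expect_true(pf$intercept_consistent_with_zero)
  expect_equal(pf$max_relative_deviation, 0, tolerance = 1e-9)

  pf2 <- proportionality_fit(x, 3 * x + 10)
  expect_false(pf2$intercept_consistent_with_zero)

  # 5% noise, n = 50: the zero-intercept flag holds in >= 90% of replicates
  set.seed(15)
  hits <- replicate(50, {
    xx <- runif(50, 1, 10)
    yy <- 3 * xx * (1 + rnorm(50, 0, 0.05))
    proportionality_fit(xx, yy)$intercept_consistent_with_zero
  })
  expect_gte(mean(hits), 0.9)
  expect_error(proportionality_fit(rep(1, 5), 1:5), "degenerate")
})

test_that("demographs sort by length and orient the stronger pole", {
  p_small <- make_profile(L = 2, amp_new = 10, amp_old = 5, id = "small")
  p_big <- make_profile(L = 3, amp_new = 5, amp_old = 20, id = "big")
  dg <- build_demograph(list(p_big, p_small), n_positions = 51)
  expect_equal(attr(dg, "cell_ids"), c("small", "big"))
  expect_equal(attr(dg, "lengths"), c(2, 3))
  # small cell: stronger left (new) pole -> flipped; big cell: stronger right
  expect_true(attr(dg, "flipped")[1])
  expect_false(attr(dg, "flipped")[2])
  # both rows end with their stronger pole on the same (right) side
  expect_gt(dg[1, 51], dg[1, 1])
  expect_gt(dg[2, 51], dg[2, 1])
})

test_that("septum onset detects sustained mid-cell signal increases", {
  expect_true(is.na(septum_onset(rep(5, 20))))
  sig <- c(rep(10, 11), rep(40, 9)) + rep(c(0.1, -0.1), 10)
  times <- seq(0, 57, by = 3)
  expect_equal(septum_onset(sig, times), times[12])
  expect_equal(septum_onset(sig), 12)
  # a single-frame spike is not an onset
  spike <- rep(10, 20) + c(rep(0.1, 19), 0) * rep(c(1, -1), 10)
  spike[12] <- 50
  expect_true(is.na(septum_onset(spike + rnorm(20, 0, 0.01))))
  expect_error(septum_onset(1:4), "shorter")

  # noisy step (snr 5): detected within one frame in >= 90% of replicates
  set.seed(16)
  hits <- replicate(100, {
    s <- c(rep(0, 11), rep(5, 9)) + rnorm(20, 0, 1)
    on <- septum_onset(s, baseline_window = 5)
    !is.na(on) && abs(on - 12) <= 1
  })
  expect_gte(mean(hits), 0.9)
})

test_that("corrected polar intensity recovers the generating elongation rate", {
  cfg <- sim_config(growth_mode = "rag", growth_cv = 0, meas_noise_sd = 0,
                    n_cells = 80, n_founders = 10)
  tab <- simulate_colony(cfg, seed = 44)
  prof_df <- simulate_profiles(tab, cfg, baseline = 40, noise_sd = 0,
                               step = 0.005, seed = 45)
  truth <- attr(prof_df, "truth")
  profs <- profiles_from_table(prof_df)
  totals <- vapply(profs, function(p)
    polar_intensity(correct_background(p))$total, numeric(1))
  rates <- truth$rate[match(names(profs), truth$cell_id)]
  pf <- proportionality_fit(rates, totals)
  expect_true(pf$intercept_consistent_with_zero ||
                abs(pf$intercept) < 0.05 * mean(totals))
  expect_gt(cor(rates, totals), 0.99)

  # intensity noise only degrades, never destroys, the relation
  noisy_df <- simulate_profiles(tab, cfg, baseline = 40, noise_sd = 0.5,
                                step = 0.005, seed = 45)
  noisy <- profiles_from_table(noisy_df)
  tot_n <- vapply(noisy, function(p)
    polar_intensity(correct_background(p))$total, numeric(1))
  expect_gt(cor(attr(noisy_df, "truth")$rate[match(names(noisy),
                                                   attr(noisy_df, "truth")$cell_id)],
                tot_n), 0.95)

  # profile files round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs[1:3], path)
  back <- read_profiles(path)
  expect_equal(length(back), 3L)
  expect_equal(back[[1]]$intensities, profs[[1]]$intensities,
               tolerance = 1e-9)
})
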