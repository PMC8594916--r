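test_that("Michaelis-Menten rate evaluates its limits and values", {
  expect_equal(mm_rate(C = 1e6, N = 50, Km = 1, alpha = 0.01),
               0.01 * 50, tolerance = 1e-4)
  expect_equal(mm_rate(C = 1, N = 50, Km = 1, alpha = 0.01), 0.01 * 50 / 2)
  expect_equal(mm_rate(C = 2, N = 100, Km = 1, alpha = 0.01), 2 / 3,
               tolerance = 1e-12)
  expect_error(mm_rate(C = 0, N = 1, Km = 0, alpha = 1), "positive")
})

test_that("the RAG rate starts at v_sat*s0, saturates, and halves its gap", {
  p <- rag_params(v_sat = 0.04, s0 = 0.65, beta = log(2) / 8)
  expect_equal(rag_rate(0, p), 0.04 * 0.65)
  expect_equal(rag_rate(1e5, p), 0.04, tolerance = 1e-9)
  # gap to saturation is halved every log(2)/beta minutes, at every t
  t <- seq(0, 60, by = 1.7)
  gap <- p$v_sat - rag_rate(t, p)
  gap_shift <- p$v_sat - rag_rate(t + log(2) / p$beta, p)
  expect_equal(gap_shift, gap / 2, tolerance = 1e-12)
  # monotone non-decreasing and bounded by v_sat for random parameters
  set.seed(4)
  for (i in 1:20) {
    pp <- rag_params(v_sat = runif(1, 0.01, 0.1), s0 = runif(1, 0.05, 1),
                     beta = runif(1, 0.01, 0.5),
                     gamma = sample(c(0, runif(1, 0.001, 0.1)), 1))
    v <- rag_rate(seq(0, 100, 2), pp)
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v <= pp$v_sat + 1e-12))
  }
})

test_that("the accelerated-recruitment form reduces to first order as gamma -> 0", {
  p0 <- rag_params(0.04, 0.65, 0.0866, gamma = 0)
  pg <- rag_params(0.04, 0.65, 0.0866, gamma = 1e-9)
  t <- seq(0, 90, by = 3)
  expect_equal(rag_rate(t, pg), rag_rate(t, p0), tolerance = 1e-6)
})

test_that("RAG lengths match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  ode_length <- function(t, lb, p) {
    f <- function(tt, y, parms) list(rag_rate(tt, p))
    unname(deSolve::lsoda(c(L = lb), c(0, t), f, NULL,
                          rtol = 1e-10, atol = 1e-12)[2, "L"])
  }
  expect_equal(rag_length(0, 2.1, rag_params(0.04, 0.65, 0.0866)), 2.1)
  # s0 = 1: pure linear growth from birth
  expect_equal(rag_length(25, 2, rag_params(0.04, 1, 0.0866)),
               2 + 0.04 * 25, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:10) {
    p <- rag_params(v_sat = runif(1, 0.02, 0.08), s0 = runif(1, 0.3, 0.95),
                    beta = runif(1, 0.02, 0.3),
                    gamma = sample(c(0, runif(1, 0.001, 0.08)), 1))
    lb <- runif(1, 1.9, 2.9)
    t <- runif(1, 10, 80)
    expect_equal(rag_length(t, lb, p), ode_length(t, lb, p),
                 tolerance = 1e-8)
  }
  # length curves are convex then linear: second differences shrink to 0
  p <- rag_params(0.04, 0.65, 0.0866)
  L <- rag_length(seq(0, 120, 3), 2.3, p)
  d2 <- diff(diff(L))
  expect_true(all(d2 >= -1e-12))
  expect_lt(d2[length(d2)], 1e-6)
})

test_that("RAG fitting recovers known parameters from noise-free curves", {
  tt <- seq(0, 45, by = 3)
  lbs <- c(2.0, 2.3, 2.6, 2.9)
  R <- sapply(lbs, function(lb)
    rag_rate(tt, rag_params(0.02 + 0.008 * lb, 0.65, log(2) / 8)))
  fit <- fit_rag(rate_family(tt, R, lb = lbs), "eq2")
  expect_equal(fit$beta, log(2) / 8, tolerance = 0.01)
  expect_equal(fit$curves$s0, rep(0.65, 4), tolerance = 0.01)
  expect_equal(fit$curves$v_sat, 0.02 + 0.008 * lbs, tolerance = 0.01)
  expect_equal(fit$halving_time, 8, tolerance = 0.01)

  # accelerated variant: recovery and nesting
  R3 <- sapply(lbs, function(lb)
    rag_rate(tt, rag_params(0.015 * lb, 0.8, 0.02, gamma = 0.05)))
  fit3 <- fit_rag(rate_family(tt, R3, lb = lbs), "eq3")
  expect_equal(fit3$gamma, 0.05, tolerance = 0.02)
  expect_equal(fit3$curves$s0, rep(0.8, 4), tolerance = 0.01)
  # eq3 on eq2-generated data: gamma collapses, fit no worse than eq2
  fit32 <- fit_rag(rate_family(tt, R, lb = lbs), "eq3")
  expect_lt(fit32$gamma, 1e-3)
  expect_lte(fit32$rss, fit$rss + 1e-15)
})

test_that("saturation at birth is the rate ratio v(0)/v_sat", {
  expect_equal(saturation_at_birth(rag_params(0.04, 0.65, 0.1)), 0.65)
  expect_equal(0.026 / 0.04, 0.65)
  expect_equal(saturation_at_birth(rag_params(0.04, 1, 0.1)), 1)
  tt <- seq(0, 45, by = 3)
  R <- sapply(c(2.0, 2.5), function(lb)
    rag_rate(tt, rag_params(0.015 * lb, 0.8, 0.0866)))
  expect_equal(saturation_at_birth(fit_rag(rate_family(tt, R), "eq2")),
               c(0.8, 0.8), tolerance = 0.01)
})

test_that("scale factors between rate families are recovered", {
  tt <- seq(0, 45, by = 3)
  lbs <- c(2.0, 2.5)
  A <- sapply(lbs, function(lb) rag_rate(tt, rag_params(0.016 * lb, 0.65, 0.0866)))
  B <- 0.5 * A
  sf <- fit_scale_factor(rate_family(tt, A, lb = lbs),
                         rate_family(tt, B, lb = lbs))
  expect_equal(sf$ratio, 2, tolerance = 1e-12)
  expect_equal(sf$residual, 0, tolerance = 1e-12)

  # same kinetics, different v_sat: pure scaling, ratio = v_sat ratio
  A2 <- sapply(lbs, function(lb) rag_rate(tt, rag_params(0.05, 0.65, 0.0866)))
  B2 <- sapply(lbs, function(lb) rag_rate(tt, rag_params(0.02, 0.65, 0.0866)))
  sf2 <- fit_scale_factor(rate_family(tt, A2), rate_family(tt, B2))
  expect_equal(sf2$ratio, 2.5, tolerance = 1e-9)
  expect_lt(sf2$residual, 1e-9)

  # different recruitment kinetics: shapes differ beyond pure scaling
  A3 <- sapply(lbs, function(lb) rag_rate(tt, rag_params(0.04, 0.5, 0.03)))
  B3 <- sapply(lbs, function(lb)
    rag_rate(tt, rag_params(0.04, 0.5, 0.03, gamma = 0.08)))
  sf3 <- fit_scale_factor(rate_family(tt, A3), rate_family(tt, B3))
  expect_gt(sf3$residual, 0.01)
})

test_that("rate-vs-length curves reflect the growth law", {
  lbs <- seq(1.9, 2.9, 0.05)
  a <- 0.03
  fam_l <- build_trajectories(fit_wavefronts(
    make_growth_table(lbs, "linear", list(a = a))),
    lb_grid = seq(2.0, 2.8, 0.2), t_cut = Inf)
  rl <- rate_vs_length(elongation_rate_curves(fam_l), fam_l)
  expect_equal(rl$rate, rep(a, nrow(rl)), tolerance = 1e-6)

  alpha <- 0.01
  fam_e <- build_trajectories(fit_wavefronts(
    make_growth_table(lbs, "exponential", list(alpha = alpha))),
    lb_grid = seq(2.0, 2.8, 0.2), t_cut = Inf)
  re <- rate_vs_length(elongation_rate_curves(fam_e), fam_e, window = 0.2)
  re <- re[3:(nrow(re) - 2), ]  # windows at the range ends are one-sided
  pf <- proportionality_fit(re$length, re$rate)
  expect_equal(pf$slope_origin, alpha, tolerance = 0.02)
  expect_lt(pf$max_relative_deviation, 0.05)
})
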