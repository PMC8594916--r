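#' Per-timepoint wavefront fits of length against birth length
#'
#' The core of the growth-inference method: for every discrete sampling
#' time `t` since birth, cell length `L(t)` is regressed on birth length
#' `lb` across all cells that have not yet divided at `t` ("wavefront"
#' fits). For purely linear growth `L(t, lb) = a t + lb` (slope 1), for
#' purely exponential growth `L(t, lb) = lb exp(alpha t)` (intercept 0);
#' both — and every mixture encountered in practice — are linear in `lb`,
#' which is why the default polynomial order is 1. Times retained must have
#' at least `min_cells` cells; only on-grid frames (multiples of the
#' sampling interval) enter the fits.
#'
#' @param table a [lineage_table()].
#' @param order polynomial order of the per-time fit (1 or 2). Order 2 is
#'   provided to verify that the quadratic term is negligible.
#' @param min_cells minimum number of cells per retained time (default 3).
#' @return A data frame of class `wavefront_fits` with one row per time:
#'   `t` (min), `intercept` (um), `slope`, (`quad` if `order = 2`), `n`,
#'   `residual_sd` (um), `mean_lb` (mean birth length of contributing
#'   cells). Attributes record the sampling interval, order, and the
#'   observed birth-length range/mean/variance.
#' @export
fit_wavefronts <- function(table, order = 1, min_cells = 3) {
  stopifnot(inherits(table, "lineage_table"), order %in% c(1L, 2L))
  fr <- table$frames
  if (nrow(fr) == 0L) stop("empty lineage table", call. = FALSE)
  dt <- table$metadata$interval_min
  cells <- table$cells
  lb_of <- stats::setNames(cells$lb, cells$cell_id)

  k <- round(fr$time_min / dt)
  on_grid <- abs(fr$time_min - k * dt) < 1e-6
  fr <- fr[on_grid, , drop = FALSE]
  k <- k[on_grid]
  lb <- unname(lb_of[fr$cell_id])

  rows <- lapply(sort(unique(k)), function(kk) {
    sel <- k == kk
    x <- lb[sel]
    y <- fr$length_um[sel]
    n <- length(x)
    if (n < min_cells || stats::var(x) < 1e-12) return(NULL)
    X <- if (order == 1L) cbind(1, x) else cbind(1, x, x^2)
    f <- stats::lm.fit(X, y)
    co <- f$coefficients
    out <- data.frame(t = kk * dt, intercept = co[1L], slope = co[2L])
    if (order == 2L) out$quad <- co[3L]
    out$n <- n
    out$residual_sd <- sqrt(sum(f$residuals^2) / max(n - order - 1L, 1L))
    out$mean_lb <- mean(x)
    out
  })
  fits <- do.call(rbind, rows)
  if (is.null(fits)) stop("no time point has enough cells", call. = FALSE)
  rownames(fits) <- NULL
  attr(fits, "interval") <- dt
  attr(fits, "order") <- order
  attr(fits, "lb_range") <- range(cells$lb)
  attr(fits, "lb_mean") <- mean(cells$lb)
  attr(fits, "lb_var") <- stats::var(cells$lb)
  attr(fits, "corrected") <- FALSE
  class(fits) <- c("wavefront_fits", "data.frame")
  fits
}

#' Estimate the birth-length attenuation factor
#'
#' Measurement noise in the birth length attenuates every wavefront slope
#' by the classical regression-dilution factor
#' `lambda = var(true lb) / (var(true lb) + var(noise))
#'         = 1 - var(noise)/var(observed lb)`.
#' When the noise sd is supplied it is used directly. Otherwise it is
#' estimated from the residual variance of the earliest positive-time
#' wavefront fits (the time-0 residual is identically zero because the
#' birth length *is* the first recorded length): under additive
#' measurement noise the residual variance at time `t` satisfies
#' `R_t^2 = sn^2 (1 + s_t^2 / lambda)` with `s_t` the observed slope, which
#' is solved for the noise variance `sn^2`. Growth-rate variability across
#' cells inflates the residuals and therefore makes this estimate
#' conservative (an upper bound on the noise).
#'
#' @param table a [lineage_table()].
#' @param fits optional [fit_wavefronts()] result (computed if missing).
#' @param noise_sd optional known measurement-noise sd (um).
#' @param n_times number of earliest positive-time fits pooled for the
#'   residual-based estimate (default 3).
#' @return List with `lambda`, `noise_sd` (estimate or supplied value) and
#'   `lb_var` (observed birth-length variance).
#' @export
estimate_attenuation <- function(table, fits = NULL, noise_sd = NULL,
                                 n_times = 3) {
  stopifnot(inherits(table, "lineage_table"))
  V <- stats::var(table$cells$lb)
  if (!is.null(noise_sd)) {
    if (noise_sd^2 >= V)
      stop("measurement-noise variance exceeds the observed birth-length ",
           "variance; attenuation correction is degenerate", call. = FALSE)
    return(list(lambda = 1 - noise_sd^2 / V, noise_sd = noise_sd, lb_var = V))
  }
  if (is.null(fits)) fits <- fit_wavefronts(table)
  use <- fits[fits$t > 0, , drop = FALSE]
  use <- use[seq_len(min(n_times, nrow(use))), , drop = FALSE]
  if (nrow(use) == 0L)
    stop("no positive-time wavefront fits available", call. = FALSE)
  R2 <- use$residual_sd^2
  s2 <- use$slope^2
  gap <- function(sn2) mean(R2 - sn2 * (1 + s2 * V / (V - sn2)))
  upper <- 0.99 * V
  if (gap(1e-12) <= 0) {
    sn2 <- 0
  } else if (gap(upper) > 0) {
    stop("estimated measurement-noise variance exceeds the observed ",
         "birth-length variance; attenuation correction is degenerate",
         call. = FALSE)
  } else {
    sn2 <- stats::uniroot(gap, c(1e-12, upper), tol = 1e-12)$root
  }
  list(lambda = 1 - sn2 / V, noise_sd = sqrt(sn2), lb_var = V)
}

#' Correct wavefront fits for birth-length measurement bias
#'
#' Rescales the conditioning variable of a family of wavefront fits so
#' that trajectories are conditioned on the *true* birth length: for every
#' positive time the slope is divided by the attenuation factor `lambda`
#' and the intercept is shifted by `-slope_corrected * (1 - lambda) *
#' mean(lb)` (the per-time mean of the contributing observed birth
#' lengths). After correction the trajectory family satisfies
#' `L(0, lb) = lb` (the time-0 fit is the exact identity and is left
#' untouched), and simulated noisy exponential growth is recovered without
#' attenuation. With zero measurement noise (`lambda = 1`) the correction
#' is the identity.
#'
#' @param table the [lineage_table()] the fits came from.
#' @param fits a [fit_wavefronts()] result of order 1.
#' @param noise_sd optional known measurement-noise sd passed to
#'   [estimate_attenuation()].
#' @return The corrected `wavefront_fits` (attributes `corrected = TRUE`,
#'   `lambda`, `noise_sd`).
#' @export
correct_birth_bias <- function(table, fits, noise_sd = NULL) {
  stopifnot(inherits(fits, "wavefront_fits"))
  if (attr(fits, "order") != 1L)
    stop("bias correction is defined for order-1 wavefront fits",
         call. = FALSE)
  att <- estimate_attenuation(table, fits, noise_sd = noise_sd)
  lambda <- att$lambda
  out <- fits
  pos <- out$t > 0
  slope_c <- out$slope[pos] / lambda
  out$intercept[pos] <- out$intercept[pos] -
    slope_c * (1 - lambda) * out$mean_lb[pos]
  out$slope[pos] <- slope_c
  attr(out, "corrected") <- TRUE
  attr(out, "lambda") <- lambda
  attr(out, "noise_sd") <- att$noise_sd
  out
}

#' First-division cutoff and cumulative divided fraction
#'
#' Average trajectories conditioned on cells that have not yet divided
#' become biased once cells start dividing: for a given birth length,
#' faster-growing cells divide earlier, so the surviving subpopulation
#' under-represents fast growers. Only the part of each trajectory before
#' the first division event is therefore used. This returns that cutoff
#' (the minimum generation time over divided cells) and the cumulative
#' fraction of cells divided as a function of time since birth.
#'
#' @param table a [lineage_table()].
#' @return List with `t_cut` (min), `divided_fraction` (a function of
#'   time), `n_divided` and `flagged` (`TRUE` when no cell divided, in
#'   which case `t_cut` falls back to the last common observed time).
#' @export
division_cutoff <- function(table) {
  stopifnot(inherits(table, "lineage_table"))
  Tg <- table$cells$generation_time[table$cells$divided]
  if (length(Tg) == 0L) {
    sp <- split(table$frames$time_min, table$frames$cell_id)
    t_cut <- min(vapply(sp, max, numeric(1)))
    warning("no divided cells; t_cut set to the last common observed time")
    return(list(t_cut = t_cut,
                divided_fraction = function(t) rep(0, length(t)),
                n_divided = 0L, flagged = TRUE))
  }
  ec <- stats::ecdf(Tg)
  list(t_cut = min(Tg),
       divided_fraction = function(t) ifelse(t < min(Tg), 0, ec(t)),
       n_divided = length(Tg), flagged = FALSE)
}

#' Build a family of average elongation trajectories
#'
#' Evaluates a family of wavefront fits on a grid of conditioning birth
#' lengths, giving the average trajectory surface
#' `L(t, lb) = intercept_t + slope_t * lb` (plus the quadratic term for
#' order-2 fits). Times beyond the first-division cutoff are computed but
#' masked invalid, mirroring the biased (dashed) part of the curves.
#'
#' @param fits a [fit_wavefronts()] (ideally bias-corrected) result.
#' @param lb_grid conditioning birth lengths (um), default
#'   `seq(1.9, 2.9, by = 0.1)`.
#' @param t_cut first-division cutoff from [division_cutoff()]; `Inf`
#'   masks nothing.
#' @param divided_fraction optional function of time (from
#'   [division_cutoff()]) evaluated and stored on the time grid.
#' @return An object of class `trajectory_family`: list with `alignment`
#'   (`"birth"`), `time`, `lb` (the grid), `surface` (`[time x lb]`
#'   matrix, um), `valid` (logical per time), `divided_fraction`,
#'   `interval`.
#' @export
build_trajectories <- function(fits, lb_grid = seq(1.9, 2.9, by = 0.1),
                               t_cut = Inf, divided_fraction = NULL) {
  stopifnot(inherits(fits, "wavefront_fits"))
  rng <- attr(fits, "lb_range")
  outside <- lb_grid < rng[1] | lb_grid > rng[2]
  if (any(outside))
    warning("lb_grid point(s) outside the observed birth-length range [",
            sprintf("%.3g, %.3g", rng[1], rng[2]), "]: ",
            paste(sprintf("%.2f", lb_grid[outside]), collapse = ", "),
            " (extrapolation)")
  S <- outer(fits$intercept, rep(1, length(lb_grid))) +
    outer(fits$slope, lb_grid)
  if (!is.null(fits$quad)) S <- S + outer(fits$quad, lb_grid^2)
  dimnames(S) <- list(NULL, sprintf("lb_%.2f", lb_grid))
  structure(list(alignment = "birth",
                 time = fits$t, lb = lb_grid, surface = S,
                 valid = fits$t <= t_cut + 1e-9,
                 divided_fraction = if (is.null(divided_fraction)) NULL else
                   divided_fraction(fits$t),
                 interval = attr(fits, "interval")),
            class = "trajectory_family")
}

#' @export
print.trajectory_family <- function(x, ...) {
  cat(sprintf(paste0("Trajectory family (%s-aligned): %d times x %d ",
                     "conditioning lengths, %d valid times\n"),
              x$alignment, length(x$time), length(x$lb), sum(x$valid)))
  invisible(x)
}

# smoothed derivative on a uniform grid: local quadratic (Savitzky-Golay)
# least squares over `window` points, windows shifted to stay in range at
# the edges; exact for trajectories linear in time, second-order accurate
# elsewhere (much less edge bias than one-sided differences)
smooth_derivative <- function(y, dt, window) {
  n <- length(y)
  if (n < window) return(rep(NA_real_, n))
  # derivative filter weights for each position of the target inside the
  # window (edge windows are one-sided but still fit a local quadratic)
  W <- t(vapply(seq_len(window), function(p) {
    tt <- (seq_len(window) - p) * dt
    X <- cbind(1, tt, tt^2)
    solve(crossprod(X), t(X))[2L, ]
  }, numeric(window)))
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- min(max(i - h, 1L), n - window + 1L)
    sum(W[i - lo + 1L, ] * y[lo:(lo + window - 1L)])
  }, numeric(1))
}

#' Construct a rate family
#'
#' Container for elongation-rate curves per conditioning length, as
#' produced by [elongation_rate_curves()] and [bootstrap_bands()] and
#' consumed by [fit_rag()], [fit_scale_factor()] and [rate_vs_length()].
#' Exported so rate curves can also be built directly (for example from
#' [rag_rate()] when validating the fitting machinery).
#'
#' @param time time grid (min).
#' @param rate `[time x curve]` matrix of elongation rates (um/min).
#' @param lb optional conditioning lengths, one per curve (um).
#' @param band_sd optional `[time x curve]` matrix of bootstrap sds;
#'   `band_lower`/`band_upper` are then `rate -/+ 2 * band_sd`.
#' @param valid optional logical mask per time (default all valid).
#' @param smoothing_window,interval bookkeeping fields.
#' @return An object of class `rate_family`.
#' @export
rate_family <- function(time, rate, lb = NULL, band_sd = NULL, valid = NULL,
                        smoothing_window = NA_integer_,
                        interval = if (length(time) > 1L) diff(time[1:2]) else NA_real_) {
  rate <- as.matrix(rate)
  stopifnot(length(time) == nrow(rate))
  if (is.null(valid)) valid <- rep(TRUE, length(time))
  out <- list(time = time, lb = lb, rate = rate,
              band_sd = band_sd,
              band_lower = if (is.null(band_sd)) NULL else rate - 2 * band_sd,
              band_upper = if (is.null(band_sd)) NULL else rate + 2 * band_sd,
              valid = valid, smoothing_window = smoothing_window,
              interval = interval)
  class(out) <- "rate_family"
  out
}

#' @export
print.rate_family <- function(x, ...) {
  cat(sprintf("Rate family: %d times x %d curves", length(x$time), ncol(x$rate)))
  if (!is.null(x$band_sd)) cat(" (with 2-sigma bootstrap bands)")
  cat("\n")
  invisible(x)
}

#' Elongation-rate curves from a trajectory family
#'
#' Numerical derivative of smoothed average trajectories: per conditioning
#' length the valid part of `L(t, lb)` is differentiated with a local
#' quadratic (Savitzky-Golay) least-squares filter over
#' `smoothing_window` frames, which smooths and differentiates in one
#' pass; at the mask edges the windows are one-sided but still fit a local
#' quadratic, avoiding the systematic bias of one-sided finite
#' differences on curved trajectories.
#'
#' @param family a [trajectory_family()].
#' @param smoothing_window odd number of frames, at least 3; default 5
#'   (15 min at 3-min sampling).
#' @return A [rate_family()] on the valid time grid.
#' @export
elongation_rate_curves <- function(family, smoothing_window = 5) {
  stopifnot(inherits(family, "trajectory_family"))
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 3L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be an odd integer of at least 3",
         call. = FALSE)
  tv <- family$time[family$valid]
  S <- family$surface[family$valid, , drop = FALSE]
  if (length(tv) < smoothing_window)
    stop("smoothing window larger than the valid time range", call. = FALSE)
  dt <- family$interval
  R <- apply(S, 2L, function(col) smooth_derivative(col, dt, smoothing_window))
  rate_family(time = tv, rate = R, lb = family$lb,
              smoothing_window = smoothing_window, interval = dt)
}

#' Run the full elongation-rate inference pipeline
#'
#' Convenience wrapper chaining [fit_wavefronts()], [correct_birth_bias()],
#' [division_cutoff()], [build_trajectories()] and
#' [elongation_rate_curves()].
#'
#' @param table a [lineage_table()].
#' @param lb_grid conditioning birth lengths (um).
#' @param order polynomial order of the wavefront fits.
#' @param smoothing_window smoothing window in frames.
#' @param noise_sd optional known measurement-noise sd (um); estimated from
#'   the wavefront residuals when `NULL`.
#' @param correct apply the birth-length bias correction (default `TRUE`;
#'   only available for `order = 1`).
#' @return List with `fits`, `cutoff`, `family` (a
#'   [trajectory_family()]) and `rates` (a [rate_family()]).
#' @export
infer_elongation <- function(table, lb_grid = seq(1.9, 2.9, by = 0.1),
                             order = 1, smoothing_window = 5,
                             noise_sd = NULL, correct = (order == 1)) {
  fits <- fit_wavefronts(table, order = order)
  if (correct) fits <- correct_birth_bias(table, fits, noise_sd = noise_sd)
  cut <- division_cutoff(table)
  fam <- build_trajectories(fits, lb_grid = lb_grid, t_cut = cut$t_cut,
                            divided_fraction = cut$divided_fraction)
  rates <- elongation_rate_curves(fam, smoothing_window = smoothing_window)
  list(fits = fits, cutoff = cut, family = fam, rates = rates)
}

#' Bootstrap confidence bands for elongation-rate curves
#'
#' Resamples whole cells with replacement (preserving within-cell
#' correlation), reruns the inference pipeline (wavefront fits, bias
#' correction, trajectory building, smoothing, differentiation) on every
#' replicate, and reports 2-sigma bands (`point estimate +/- 2 *
#' bootstrap sd`) per time and conditioning length. Replicates are run on
#' the fixed time grid of the full-data fit; a replicate contributes no
#' value at times where fewer than 3 distinct cells remain (tracked in
#' `n_boot_eff`). The measurement-noise sd entering the bias correction is
#' estimated once from the full data and held fixed across replicates.
#'
#' @param table a [lineage_table()].
#' @param lb_grid conditioning birth lengths (um).
#' @param smoothing_window smoothing window in frames.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @param noise_sd optional known measurement-noise sd (um).
#' @return A [rate_family()] with `band_sd`, `band_lower`, `band_upper`
#'   and `n_boot_eff` (replicates contributing per time).
#' @export
bootstrap_bands <- function(table, lb_grid = seq(1.9, 2.9, by = 0.1),
                            smoothing_window = 5, n_boot = 200, seed = 1,
                            noise_sd = NULL) {
  stopifnot(inherits(table, "lineage_table"))
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  point <- infer_elongation(table, lb_grid = lb_grid, order = 1,
                            smoothing_window = smoothing_window,
                            noise_sd = noise_sd)
  sn <- attr(point$fits, "noise_sd")

  # compact per-time structures for fast weighted refits
  dt <- table$metadata$interval_min
  tv <- point$rates$time
  cells <- table$cells
  ncell <- nrow(cells)
  cell_idx <- match(table$frames$cell_id, cells$cell_id)
  kk <- round(table$frames$time_min / dt)
  on_grid <- abs(table$frames$time_min - kk * dt) < 1e-6
  per_t <- lapply(round(tv / dt), function(k) {
    sel <- which(on_grid & kk == k)
    list(ci = cell_idx[sel], y = table$frames$length_um[sel])
  })
  lb_all <- cells$lb

  set.seed(as.integer(seed))
  nt <- length(tv)
  nlb <- length(lb_grid)
  sum1 <- matrix(0, nt, nlb)
  sum2 <- matrix(0, nt, nlb)
  cnt <- matrix(0L, nt, nlb)

  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(ncell, ncell, replace = TRUE), nbins = ncell)
    # attenuation for this replicate (weighted lb variance, fixed noise sd)
    sw <- sum(w)
    mu <- sum(w * lb_all) / sw
    V <- sum(w * (lb_all - mu)^2) / (sw - 1)
    lam <- if (sn > 0 && sn^2 < V) 1 - sn^2 / V else 1

    ic <- numeric(nt); sl <- numeric(nt); ok <- logical(nt)
    for (i in seq_len(nt)) {
      p <- per_t[[i]]
      ww <- w[p$ci]
      pos <- ww > 0
      if (sum(pos) < 3L) { ok[i] <- FALSE; next }
      x <- lb_all[p$ci[pos]]; y <- p$y[pos]; wv <- ww[pos]
      Sw <- sum(wv); Swx <- sum(wv * x); Swy <- sum(wv * y)
      Swxx <- sum(wv * x * x); Swxy <- sum(wv * x * y)
      den <- Sw * Swxx - Swx^2
      if (abs(den) < 1e-12) { ok[i] <- FALSE; next }
      b1 <- (Sw * Swxy - Swx * Swy) / den
      b0 <- (Swy - b1 * Swx) / Sw
      if (tv[i] > 0) {
        b1c <- b1 / lam
        b0 <- b0 - b1c * (1 - lam) * (Swx / Sw)
        b1 <- b1c
      }
      ic[i] <- b0; sl[i] <- b1; ok[i] <- TRUE
    }
    Sb <- outer(ic, rep(1, nlb)) + outer(sl, lb_grid)
    Sb[!ok, ] <- NA_real_
    for (j in seq_len(nlb)) {
      col <- Sb[, j]
      if (anyNA(col)) {
        # use the longest valid prefix; later gaps invalidate derivatives
        good <- which(is.na(col))[1L] - 1L
        if (is.na(good) || good < smoothing_window) next
        idx <- seq_len(good)
      } else idx <- seq_len(nt)
      r <- smooth_derivative(col[idx], dt, smoothing_window)
      sum1[idx, j] <- sum1[idx, j] + r
      sum2[idx, j] <- sum2[idx, j] + r^2
      cnt[idx, j] <- cnt[idx, j] + 1L
    }
  }

  m <- sum1 / cnt
  v <- pmax(sum2 / cnt - m^2, 0) * cnt / pmax(cnt - 1L, 1L)
  band_sd <- sqrt(v)
  band_sd[cnt < 2L] <- NA_real_
  out <- rate_family(time = tv, rate = point$rates$rate, lb = lb_grid,
                     band_sd = band_sd,
                     smoothing_window = smoothing_window, interval = dt)
  out$n_boot <- n_boot
  out$n_boot_eff <- cnt
  out$point <- point
  out
}

#' Division-aligned (reverse-time) trajectory family
#'
#' Analogue of the birth-aligned construction for the approach to
#' division: for every non-positive offset `tau = t - td` (time until
#' division), cell length is regressed on division length `ld` across
#' divided cells, yielding average trajectories `L(tau, ld)`. Per-cell
#' lengths at `td + tau` are obtained by linear interpolation of the
#' recorded series (records end at the exact division event). Offsets are
#' valid only while `|tau|` does not exceed the shortest single-cell
#' generation time; beyond that the averages condition on long-lived cells
#' and become biased.
#'
#' @param table a [lineage_table()].
#' @param ld_grid conditioning division lengths (um); default a 0.1 um grid
#'   between the 10% and 90% quantiles of the observed division lengths.
#' @param min_cells minimum cells per retained offset (default 3).
#' @return A [trajectory_family()] with `alignment = "division"` and
#'   `time` holding the (negative) offsets in increasing order.
#' @export
reverse_time_family <- function(table, ld_grid = NULL, min_cells = 3) {
  stopifnot(inherits(table, "lineage_table"))
  cells <- table$cells[table$cells$divided, , drop = FALSE]
  if (nrow(cells) < min_cells)
    stop("need at least ", min_cells, " divided cells", call. = FALSE)
  dt <- table$metadata$interval_min
  if (is.null(ld_grid)) {
    q <- stats::quantile(cells$ld, c(0.1, 0.9), names = FALSE)
    ld_grid <- seq(ceiling(q[1] * 10) / 10, floor(q[2] * 10) / 10, by = 0.1)
  }
  Tmin <- min(cells$generation_time)
  Tmax <- max(cells$generation_time)
  taus <- -rev(seq(0, floor(Tmax / dt) * dt, by = dt))

  sp <- split(table$frames[, c("time_min", "length_um")], table$frames$cell_id)
  rows <- lapply(taus, function(tau) {
    ids <- cells$cell_id[cells$generation_time >= -tau - 1e-9]
    if (length(ids) < min_cells) return(NULL)
    L <- vapply(ids, function(id) {
      s <- sp[[id]]
      Td <- cells$generation_time[cells$cell_id == id]
      stats::approx(s$time_min, s$length_um, xout = Td + tau, rule = 1)$y
    }, numeric(1))
    x <- cells$ld[match(ids, cells$cell_id)]
    keep <- !is.na(L)
    if (sum(keep) < min_cells || stats::var(x[keep]) < 1e-12) return(NULL)
    f <- stats::lm.fit(cbind(1, x[keep]), L[keep])
    data.frame(t = tau, intercept = f$coefficients[1L],
               slope = f$coefficients[2L], n = sum(keep))
  })
  fits <- do.call(rbind, rows)
  if (is.null(fits)) stop("no offset has enough cells", call. = FALSE)
  rownames(fits) <- NULL
  S <- outer(fits$intercept, rep(1, length(ld_grid))) +
    outer(fits$slope, ld_grid)
  dimnames(S) <- list(NULL, sprintf("ld_%.2f", ld_grid))
  structure(list(alignment = "division",
                 time = fits$t, lb = ld_grid, surface = S,
                 valid = -fits$t <= Tmin + 1e-9,
                 divided_fraction = NULL, interval = dt),
            class = "trajectory_family")
}
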