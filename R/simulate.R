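# truncated-normal draws by rejection; bounds keep biology sane (positive
# lengths, septum fraction away from the poles)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) {
      out[bad] <- pmin(pmax(out[bad], lower), upper)
      break
    }
  }
  out
}

#' Configuration of the synthetic colony generator
#'
#' Collects every knob of [simulate_colony()]: the single-cell growth law,
#' the division-control rule, septum-placement asymmetry, measurement noise
#' and sampling. Defaults emulate time-lapse microscopy of an apically
#' growing rod (3-min frames over several generations, birth lengths around
#' 1.9-2.9 um, wide generation-time spread, asymmetric septum placement,
#' additive length measurement noise).
#'
#' @param growth_mode single-cell growth law: `"linear"` (constant rate
#'   `a`), `"exponential"` (rate `alpha`) or `"rag"` (asymptotically linear,
#'   see [rag_params()]).
#' @param growth_params mode-specific parameters: `list(a = )` for linear
#'   (um/min), `list(alpha = )` for exponential (1/min), or a
#'   [rag_params()] object for `"rag"`. Defaults: `a = 0.03`,
#'   `alpha = log(2)/60`, `rag_params(0.04, 0.65, log(2)/8)`.
#' @param growth_cv coefficient of variation of the per-cell growth-rate
#'   multiplier (applied to `a`, `alpha` or `v_sat`; truncated normal with
#'   mean 1). Default 0.15; set 0 for deterministic growth given birth
#'   length.
#' @param division_rule `"adder"` (divide after adding `delta`), `"sizer"`
#'   (divide at `target_length`), `"timer"` (divide after `target_time`) or
#'   `"near_adder"` (`ld = slope * lb + offset + noise`).
#' @param division_params list overriding rule parameters: `delta` (um,
#'   default 2.3), `target_length` (um, default 4.6), `target_time` (min,
#'   default 60), `slope` (default 0.91), `offset` (um, default
#'   `(2 - slope) * 2.3` so the stationary birth length stays near 2.3 um),
#'   `size_sd` (um, sd of the size-additive division noise, default 0.15),
#'   `time_sd` (min, sd of the time-additive noise for the timer rule,
#'   default 6).
#' @param asym_mean,asym_sd mean and sd of the septum-position fraction
#'   (truncated Gaussian); defaults 0.5 and 0.05.
#' @param asym_range truncation interval of the septum fraction, default
#'   `c(0.2, 0.8)`.
#' @param meas_noise_sd additive Gaussian measurement noise on every
#'   recorded length (um); default 0.05. True lengths drive the dynamics.
#' @param sampling_interval sampling interval in minutes, default 3.
#' @param birth_mean,birth_sd,birth_range founder birth-length distribution
#'   (truncated Gaussian), defaults 2.3, 0.2, `c(1.9, 2.9)` um.
#' @param n_cells cap on the number of recorded cells (default 500).
#' @param n_generations number of typical generations simulated before the
#'   observation window closes (default 8; with the default founder count
#'   the `n_cells` cap usually binds first).
#' @param n_founders number of founder cells, default 50.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(growth_mode = c("rag", "linear", "exponential"),
                       growth_params = NULL,
                       growth_cv = 0.15,
                       division_rule = c("adder", "sizer", "timer", "near_adder"),
                       division_params = list(),
                       asym_mean = 0.5, asym_sd = 0.05,
                       asym_range = c(0.2, 0.8),
                       meas_noise_sd = 0.05,
                       sampling_interval = 3,
                       birth_mean = 2.3, birth_sd = 0.2,
                       birth_range = c(1.9, 2.9),
                       n_cells = 500, n_generations = 8, n_founders = 50) {
  growth_mode <- match.arg(growth_mode)
  division_rule <- match.arg(division_rule)
  if (is.null(growth_params)) {
    growth_params <- switch(growth_mode,
                            linear = list(a = 0.03),
                            exponential = list(alpha = log(2) / 60),
                            rag = rag_params(v_sat = 0.04, s0 = 0.65,
                                             beta = log(2) / 8))
  }
  dp <- list(delta = 2.3, target_length = 4.6, target_time = 60,
             slope = 0.91, offset = NULL, size_sd = 0.15, time_sd = 6)
  dp[names(division_params)] <- division_params
  if (is.null(dp$offset)) dp$offset <- (2 - dp$slope) * 2.3
  stopifnot(asym_mean > 0, asym_mean < 1, asym_sd >= 0,
            asym_range[1] >= 0.2 - 1e-12, asym_range[2] <= 0.8 + 1e-12,
            meas_noise_sd >= 0, sampling_interval > 0,
            birth_mean > 0, birth_sd >= 0, growth_cv >= 0,
            dp$delta > 0, dp$target_length > 0, dp$target_time > 0,
            dp$size_sd >= 0, dp$time_sd >= 0,
            n_cells >= 1, n_founders >= 1, n_generations >= 1)
  structure(list(growth_mode = growth_mode, growth_params = growth_params,
                 growth_cv = growth_cv,
                 division_rule = division_rule, division_params = dp,
                 asym_mean = asym_mean, asym_sd = asym_sd,
                 asym_range = asym_range,
                 meas_noise_sd = meas_noise_sd,
                 sampling_interval = sampling_interval,
                 birth_mean = birth_mean, birth_sd = birth_sd,
                 birth_range = birth_range,
                 n_cells = n_cells, n_generations = n_generations,
                 n_founders = n_founders),
            class = "sim_config")
}

#' Noise-free cell length under a growth law
#'
#' @param mode `"linear"`, `"exponential"` or `"rag"`.
#' @param t time since birth (min), vectorised.
#' @param lb birth length (um).
#' @param params mode parameters as in [sim_config()] (`list(a=)`,
#'   `list(alpha=)`, or a [rag_params()]).
#' @return Length(s) at time `t` in um.
#' @export
#' @examples
#' growth_length("linear", 10, 2.0, list(a = 0.03))       # 2.3
#' growth_length("exponential", log(2) / 0.02, 2.0, list(alpha = 0.02)) # 4.0
growth_length <- function(mode, t, lb, params) {
  stopifnot(all(t >= 0), lb > 0)
  switch(mode,
         linear = lb + params$a * t,
         exponential = lb * exp(params$alpha * t),
         rag = rag_length(t, lb, params),
         stop("unknown growth mode: ", mode, call. = FALSE))
}

#' Instantaneous elongation rate under a growth law
#'
#' @inheritParams growth_length
#' @return Elongation rate(s) dL/dt in um/min.
#' @export
growth_rate <- function(mode, t, lb, params) {
  stopifnot(all(t >= 0), lb > 0)
  switch(mode,
         linear = rep(params$a, length(t)),
         exponential = params$alpha * lb * exp(params$alpha * t),
         rag = rag_rate(t, params),
         stop("unknown growth mode: ", mode, call. = FALSE))
}

# invert the growth law: time to reach length ld from lb (internal)
growth_time_to_length <- function(mode, ld, lb, params) {
  if (ld <= lb) return(0)
  switch(mode,
         linear = (ld - lb) / params$a,
         exponential = log(ld / lb) / params$alpha,
         rag = rag_time_to_length(ld, lb, params),
         stop("unknown growth mode: ", mode, call. = FALSE))
}

# scale the rate parameter of a growth law by a per-cell multiplier
scale_growth_params <- function(mode, params, m) {
  if (m == 1) return(params)
  switch(mode,
         linear = list(a = params$a * m),
         exponential = list(alpha = params$alpha * m),
         rag = {
           p <- params
           p$v_sat <- p$v_sat * m
           p
         })
}

#' Simulate a growing colony
#'
#' Stochastic multi-generation simulation of single cells growing under a
#' configurable growth law and dividing under a configurable division rule,
#' sampled at the configured frame interval. True lengths drive the
#' dynamics; additive Gaussian measurement noise is applied to the recorded
#' lengths only. Each divided cell's final recorded sample is the exact
#' division event, so division-rule identities (for example
#' `ld - lb = delta` for a noise-free adder) hold exactly on the recorded
#' series; the final sampling interval of a record may therefore be shorter
#' than the frame interval. Daughters receive fractions `f` and `1 - f` of
#' the mother's division length, with `f` drawn from the configured
#' truncated Gaussian. Fully reproducible given `seed`.
#'
#' Cells are processed in order of birth; recording stops at the
#' `n_cells` cap (flagged as `truncated` in the metadata) or at the end of
#' the observation window (`n_generations` typical generation times), in
#' which case still-growing cells are recorded as censored.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return A [lineage_table()]. The true (noise-free) per-cell quantities
#'   are attached as `attr(, "truth")`: a data frame with `cell_id`,
#'   `lb_true`, `ld_true`, `generation_time_true`, `growth_multiplier`,
#'   `birth_time` and `generation`.
#' @export
simulate_colony <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  dt <- config$sampling_interval
  mode <- config$growth_mode
  dp <- config$division_params

  # typical generation time (noise-free cell at the mean birth length)
  typical_ld <- switch(config$division_rule,
                       adder = config$birth_mean + dp$delta,
                       sizer = dp$target_length,
                       near_adder = dp$slope * config$birth_mean + dp$offset,
                       timer = NA_real_)
  t_typ <- if (config$division_rule == "timer") dp$target_time else
    growth_time_to_length(mode, typical_ld, config$birth_mean,
                          config$growth_params)
  t_end <- config$n_generations * t_typ

  founder_lb <- rtruncnorm(config$n_founders, config$birth_mean,
                           config$birth_sd, config$birth_range[1],
                           config$birth_range[2])
  founder_birth <- stats::runif(config$n_founders, 0, t_typ)

  queue <- data.frame(lb = founder_lb, birth = founder_birth,
                      parent = NA_character_, gen = 0L,
                      stringsAsFactors = FALSE)
  frames_list <- list()
  truth_list <- list()
  n_recorded <- 0L
  truncated <- FALSE
  next_id <- 1L

  while (nrow(queue) > 0L) {
    queue <- queue[order(queue$birth), , drop = FALSE]
    cell <- queue[1L, ]
    queue <- queue[-1L, , drop = FALSE]
    if (n_recorded >= config$n_cells) {
      truncated <- TRUE
      break
    }
    id <- sprintf("c%05d", next_id)
    next_id <- next_id + 1L

    m <- if (config$growth_cv > 0)
      rtruncnorm(1L, 1, config$growth_cv, max(0.2, 1 - 3 * config$growth_cv),
                 1 + 3 * config$growth_cv) else 1
    gp <- scale_growth_params(mode, config$growth_params, m)

    # division target on true lengths
    if (config$division_rule == "timer") {
      Tdiv <- rtruncnorm(1L, dp$target_time, dp$time_sd,
                         lower = dt / 2, upper = Inf)
      ld_true <- growth_length(mode, Tdiv, cell$lb, gp)
    } else {
      target <- switch(config$division_rule,
                       adder = cell$lb + dp$delta,
                       sizer = dp$target_length,
                       near_adder = dp$slope * cell$lb + dp$offset)
      ld_true <- rtruncnorm(1L, target, dp$size_sd,
                            lower = cell$lb + 0.05, upper = Inf)
      Tdiv <- growth_time_to_length(mode, ld_true, cell$lb, gp)
    }

    divides <- (cell$birth + Tdiv) <= t_end
    if (divides) {
      k <- floor(Tdiv / dt - 1e-9)
      tt <- seq(0, k * dt, by = dt)
      if (Tdiv - k * dt > 1e-9) tt <- c(tt, Tdiv)
    } else {
      obs <- t_end - cell$birth
      tt <- seq(0, max(0, floor(obs / dt)) * dt, by = dt)
    }
    ll <- growth_length(mode, tt, cell$lb, gp)
    frames_list[[id]] <- data.frame(cell_id = id, parent_id = cell$parent,
                                    time_min = tt, length_um = ll,
                                    stringsAsFactors = FALSE)
    truth_list[[id]] <- data.frame(cell_id = id, lb_true = cell$lb,
                                   ld_true = if (divides) ld_true else NA_real_,
                                   generation_time_true =
                                     if (divides) Tdiv else NA_real_,
                                   growth_multiplier = m,
                                   birth_time = cell$birth,
                                   generation = cell$gen,
                                   stringsAsFactors = FALSE)
    n_recorded <- n_recorded + 1L

    if (divides) {
      f <- rtruncnorm(1L, config$asym_mean, config$asym_sd,
                      config$asym_range[1], config$asym_range[2])
      queue <- rbind(queue,
                     data.frame(lb = c(f, 1 - f) * ld_true,
                                birth = cell$birth + Tdiv,
                                parent = id, gen = cell$gen + 1L,
                                stringsAsFactors = FALSE))
    }
  }

  frames <- do.call(rbind, frames_list)
  rownames(frames) <- NULL
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  meta <- list(interval_min = dt, length_unit = "um",
               strain = "synthetic",
               growth_mode = mode, division_rule = config$division_rule,
               meas_noise_sd = config$meas_noise_sd,
               truncated = truncated, seed = as.integer(seed))
  tab <- lineage_table(frames, meta)
  if (config$meas_noise_sd > 0)
    tab <- apply_measurement_noise(tab, config$meas_noise_sd, seed = NULL)
  attr(tab, "truth") <- truth
  tab
}

#' Add measurement noise to recorded lengths
#'
#' Applies i.i.d. additive Gaussian noise to every recorded length and
#' recomputes the per-cell summaries (`lb`, `ld`) from the noisy series.
#'
#' @param table a [lineage_table()].
#' @param sd noise standard deviation (um), `>= 0`.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return A new [lineage_table()] with noisy lengths; the metadata field
#'   `meas_noise_sd` is updated.
#' @export
apply_measurement_noise <- function(table, sd, seed = NULL) {
  stopifnot(inherits(table, "lineage_table"), sd >= 0)
  if (sd == 0) return(table)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fr <- table$frames
  fr$length_um <- fr$length_um + stats::rnorm(nrow(fr), 0, sd)
  meta <- table$metadata
  meta$meas_noise_sd <- sd
  out <- lineage_table(fr, meta)
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Simulate per-cell 1D fluorescence profiles
#'
#' Generates a synthetic pole-anchored intensity profile for each divided
#' cell of a simulated colony, emulating a stain of nascent peptidoglycan:
#' a uniform cytoplasmic baseline plus one Gaussian peak per pole whose
#' integrated intensity is proportional to that pole's insertion
#' (elongation) rate, plus additive Gaussian noise. Under the RAG law the
#' old pole is saturated (rate `v_sat/2` of the cell's scaled maximum) and
#' the new pole carries the remainder; for linear and exponential laws the
#' rate is split evenly. Each cell is profiled at one uniformly drawn
#' moment of its life. Positions run from the new pole (0) to the cell
#' length.
#'
#' @param table a [lineage_table()] from [simulate_colony()] (its `truth`
#'   attribute supplies true birth lengths and growth multipliers).
#' @param config the [sim_config()] used to generate `table`.
#' @param baseline cytoplasmic baseline intensity (AU), default 50.
#' @param gain integrated peak intensity per unit elongation rate
#'   (AU.um / (um/min)), default 1000.
#' @param peak_sd Gaussian peak width (um), default 0.15.
#' @param noise_sd additive intensity noise sd (AU), default 2.
#' @param step position sampling step (um), default 0.02.
#' @param seed integer RNG seed.
#' @return Long data frame with columns `cell_id`, `length_um`,
#'   `position_um`, `intensity_au` (the on-disk profile format), with the
#'   generating truth attached as `attr(, "truth")`: per-cell `time`,
#'   `length`, `rate`, `rate_new`, `rate_old`.
#' @export
simulate_profiles <- function(table, config, baseline = 50, gain = 1000,
                              peak_sd = 0.15, noise_sd = 2, step = 0.02,
                              seed = 1) {
  stopifnot(inherits(table, "lineage_table"), inherits(config, "sim_config"))
  truth <- attr(table, "truth")
  if (is.null(truth))
    stop("table carries no generator truth; simulate_profiles needs ",
         "simulate_colony output", call. = FALSE)
  set.seed(as.integer(seed))
  mode <- config$growth_mode
  div <- truth[!is.na(truth$generation_time_true), , drop = FALSE]
  out <- vector("list", nrow(div))
  tr <- vector("list", nrow(div))
  for (i in seq_len(nrow(div))) {
    gp <- scale_growth_params(mode, config$growth_params,
                              div$growth_multiplier[i])
    u <- stats::runif(1, 0, div$generation_time_true[i])
    L <- growth_length(mode, u, div$lb_true[i], gp)
    v <- growth_rate(mode, u, div$lb_true[i], gp)
    if (mode == "rag") {
      rate_old <- gp$v_sat / 2
      rate_new <- max(v - rate_old, 0)
    } else {
      rate_old <- v / 2
      rate_new <- v / 2
    }
    x <- seq(0, L, by = step)
    intens <- baseline +
      gain * rate_new * stats::dnorm(x, 0, peak_sd) +
      gain * rate_old * stats::dnorm(x, L, peak_sd)
    if (noise_sd > 0) intens <- intens + stats::rnorm(length(x), 0, noise_sd)
    out[[i]] <- data.frame(cell_id = div$cell_id[i], length_um = L,
                           position_um = x, intensity_au = intens,
                           stringsAsFactors = FALSE)
    tr[[i]] <- data.frame(cell_id = div$cell_id[i], time = u, length = L,
                          rate = v, rate_new = rate_new, rate_old = rate_old,
                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- do.call(rbind, tr)
  res
}
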