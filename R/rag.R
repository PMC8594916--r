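#' Rate-limiting apical growth (RAG) model parameters
#'
#' Kinetic parameters for the RAG model of single-cell elongation. Elongation
#' follows Michaelis-Menten kinetics in the Lipid-II concentration `C` and is
#' proportional to the number of polar transglycosylase (TG) sites `N(t)`.
#' Under the model's working assumption (either `C` constant or `C >> Km`)
#' the rate is proportional to `N(t)` alone, so the elongation-rate curve is
#' fully parameterised by the asymptotic rate `v_sat`, the relative
#' saturation at birth `s0 = v(0)/v_sat`, the recruitment rate constant
#' `beta`, and optionally the DivIVA self-recruitment rate `gamma`:
#' \itemize{
#'   \item `gamma = 0` (first-order recruitment, dN/dt = beta (Nmax - N)):
#'     `v(t) = v_sat - v_sat (1 - s0) exp(-beta t)`.
#'   \item `gamma > 0` (recruitment accelerated by an exponentially growing
#'     DivIVA cluster, dN/dt = beta e^(gamma t) (Nmax - N)):
#'     `v(t) = v_sat - v_sat (1 - s0) exp(-(beta/gamma)(e^(gamma t) - 1))`.
#' }
#' The gap to saturation in the first form is halved every `log(2)/beta`
#' minutes.
#'
#' @param v_sat asymptotic elongation rate (um/min), proportional to
#'   `alpha * Nmax * C/(Km + C)`.
#' @param s0 saturation at birth, `N(0)/Nmax`, in (0, 1].
#' @param beta recruitment rate constant (1/min).
#' @param gamma DivIVA self-recruitment rate (1/min); 0 selects the
#'   first-order recruitment form.
#' @param alpha_mm optional Michaelis-Menten proportionality (um/min per
#'   site), kept for bookkeeping only.
#' @param Km,C optional Michaelis constant and Lipid-II concentration
#'   (same arbitrary units), kept for bookkeeping only.
#' @return An object of class `rag_params`.
#' @seealso [rag_rate()], [rag_length()], [fit_rag()]
#' @export
#' @examples
#' p <- rag_params(v_sat = 0.04, s0 = 0.65, beta = log(2) / 8)
#' rag_rate(c(0, 8, 100), p)
rag_params <- function(v_sat, s0, beta, gamma = 0,
                       alpha_mm = NULL, Km = NULL, C = NULL) {
  stopifnot(is.numeric(v_sat), length(v_sat) == 1L, v_sat > 0,
            is.numeric(s0), length(s0) == 1L, s0 > 0, s0 <= 1,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  structure(list(v_sat = v_sat, s0 = s0, beta = beta, gamma = gamma,
                 alpha_mm = alpha_mm, Km = Km, C = C),
            class = "rag_params")
}

#' @export
print.rag_params <- function(x, ...) {
  cat(sprintf("RAG parameters: v_sat = %.4g um/min, s0 = %.3f, beta = %.4g /min",
              x$v_sat, x$s0, x$beta))
  if (x$gamma > 0) cat(sprintf(", gamma = %.4g /min", x$gamma))
  cat(sprintf("  (saturation-gap halving time %.2f min)\n", log(2) / x$beta))
  invisible(x)
}

#' Michaelis-Menten elongation rate
#'
#' Elongation rate of a cell with `N` polar transglycosylase sites at
#' Lipid-II concentration `C`: `alpha * C * N / (Km + C)`.
#'
#' @param C Lipid-II concentration (arbitrary units, >= 0).
#' @param N number of polar TG sites (>= 0).
#' @param Km Michaelis constant (same units as `C`).
#' @param alpha cell-wall production per site (um/min per site).
#' @return Elongation rate in um/min.
#' @export
mm_rate <- function(C, N, Km, alpha) {
  stopifnot(all(C >= 0), all(N >= 0), all(Km >= 0), all(alpha >= 0))
  if (any(Km + C == 0)) stop("Km + C must be positive", call. = FALSE)
  alpha * C * N / (Km + C)
}

#' RAG elongation rate as a function of time since birth
#'
#' @param t time since birth (min), vectorised.
#' @param p a [rag_params()] object.
#' @return Elongation rate(s) in um/min; non-decreasing in `t` and bounded
#'   by `p$v_sat`.
#' @export
rag_rate <- function(t, p) {
  stopifnot(inherits(p, "rag_params"), all(t >= 0))
  if (p$gamma == 0) {
    p$v_sat - p$v_sat * (1 - p$s0) * exp(-p$beta * t)
  } else {
    # expm1 keeps the gamma -> 0 limit numerically stable
    p$v_sat - p$v_sat * (1 - p$s0) * exp(-(p$beta / p$gamma) * expm1(p$gamma * t))
  }
}

#' RAG cell length as a function of time since birth
#'
#' Integral of [rag_rate()] from birth. For `gamma = 0` the closed form
#' `lb + v_sat t - v_sat (1 - s0) (1 - exp(-beta t)) / beta` is used; for
#' `gamma > 0` the rate is integrated by adaptive quadrature (absolute
#' tolerance 1e-9 um).
#'
#' @param t time since birth (min), vectorised.
#' @param lb birth length (um).
#' @param p a [rag_params()] object.
#' @return Cell length(s) in um.
#' @export
rag_length <- function(t, lb, p) {
  stopifnot(inherits(p, "rag_params"), all(t >= 0), lb > 0)
  if (p$gamma == 0) {
    lb + p$v_sat * t - p$v_sat * (1 - p$s0) * (1 - exp(-p$beta * t)) / p$beta
  } else {
    added <- vapply(t, function(ti) {
      if (ti == 0) return(0)
      q <- stats::integrate(rag_rate, 0, ti, p = p,
                            abs.tol = 1e-9, rel.tol = 1e-10,
                            subdivisions = 500L)
      if (q$message != "OK")
        stop("quadrature of the RAG rate failed: ", q$message, call. = FALSE)
      q$value
    }, numeric(1))
    lb + added
  }
}

# time for a cell of birth length lb to reach target length ld (internal)
rag_time_to_length <- function(ld, lb, p, upper = NULL) {
  if (ld <= lb) return(0)
  if (is.null(upper)) {
    upper <- (ld - lb) / (p$v_sat * p$s0) + 1 / p$beta
    while (rag_length(upper, lb, p) < ld) upper <- upper * 2
  }
  stats::uniroot(function(t) rag_length(t, lb, p) - ld,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Relative transglycosylase saturation at birth
#'
#' The ratio of the elongation rate at birth to the asymptotic
#' (linear-regime) rate, `s0 = v(0)/v_sat`, interpreted as the relative
#' TG-site occupancy of the poles at birth. Accepts either a
#' [rag_params()] object or a fitted model from [fit_rag()] (in which case
#' the per-curve values are returned).
#'
#' @param p a `rag_params` or `rag_fit` object.
#' @return Saturation fraction(s) in (0, 1].
#' @export
saturation_at_birth <- function(p) {
  if (inherits(p, "rag_fit")) return(p$curves$s0)
  stopifnot(inherits(p, "rag_params"))
  p$s0
}

#' Fit the RAG model to elongation-rate curves
#'
#' Nonlinear least squares of the RAG elongation-rate law against a family
#' of rate curves (one per conditioning birth length). The recruitment
#' kinetics (`beta`, and `gamma` for the self-accelerated variant) are
#' shared across curves, while `v_sat` and `s0` are free per curve. For
#' fixed kinetics the model is linear in `(v_sat, v_sat (1 - s0))`, so the
#' per-curve parameters are profiled out by (weighted) linear least squares
#' and only the shared kinetics are searched numerically: a log-spaced
#' multi-start grid refined by one-dimensional (`eq2`) or Nelder-Mead
#' (`eq3`) optimisation. When bootstrap bands are present, residuals are
#' weighted by `1/sd^2`.
#'
#' @param rates a [rate_family()] (or any list with elements `time`,
#'   `rate` matrix `[time x curve]`, optional `band_sd` matrix, optional
#'   logical `valid`).
#' @param variant `"eq2"` for first-order recruitment (`gamma = 0`) or
#'   `"eq3"` for DivIVA-accelerated recruitment (`gamma` fitted).
#' @param beta_range search range for `beta` (1/min).
#' @param n_starts number of log-spaced multi-start values for the shared
#'   kinetics.
#' @return An object of class `rag_fit`: list with `beta`, `gamma`,
#'   `halving_time` (`log(2)/beta`), `curves` (data frame of per-curve
#'   `v_sat`, `s0`), `rss`, `fitted` (matrix like `rate`), `variant`.
#' @export
fit_rag <- function(rates, variant = c("eq2", "eq3"),
                    beta_range = c(1e-3, 1), n_starts = 8) {
  variant <- match.arg(variant)
  tt <- rates$time
  R <- as.matrix(rates$rate)
  if (!is.null(rates$valid)) {
    keep <- rates$valid
    tt <- tt[keep]
    R <- R[keep, , drop = FALSE]
  }
  if (ncol(R) < 2L || nrow(R) < 5L)
    stop("need at least 2 rate curves with at least 5 valid time points",
         call. = FALSE)
  W <- if (!is.null(rates$band_sd)) {
    sd <- as.matrix(rates$band_sd)
    if (!is.null(rates$valid)) sd <- sd[rates$valid, , drop = FALSE]
    w <- 1 / pmax(sd, max(sd, na.rm = TRUE) * 1e-3)^2
    w[!is.finite(w)] <- 0
    w
  } else {
    matrix(1, nrow(R), ncol(R))
  }

  decay <- function(beta, gamma) {
    if (gamma <= 0) exp(-beta * tt) else exp(-(beta / gamma) * expm1(gamma * tt))
  }
  # profile the per-curve linear parameters v = v_sat + c * E(t), c <= 0
  profile_rss <- function(beta, gamma) {
    E <- decay(beta, gamma)
    rss <- 0
    pars <- matrix(NA_real_, ncol(R), 2L)
    for (j in seq_len(ncol(R))) {
      w <- W[, j]
      X <- cbind(1, E)
      cf <- tryCatch(
        stats::lm.wfit(X, R[, j], w)$coefficients,
        error = function(e) c(NA_real_, NA_real_))
      if (anyNA(cf)) return(list(rss = Inf, pars = pars))
      # constrain to a physical curve: v_sat > 0, -v_sat <= c <= 0
      if (cf[1] <= 0) cf <- c(max(mean(R[, j]), 1e-8), 0)
      if (cf[2] > 0) cf[2] <- 0
      if (cf[2] < -cf[1]) cf[2] <- -cf[1] * (1 - 1e-9)
      rss <- rss + sum(w * (R[, j] - (cf[1] + cf[2] * E))^2)
      pars[j, ] <- cf
    }
    list(rss = rss, pars = pars)
  }

  lb_grid <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                     length.out = max(n_starts, 2L) * 8L))
  if (variant == "eq2") {
    grid_rss <- vapply(lb_grid, function(b) profile_rss(b, 0)$rss, numeric(1))
    b0 <- lb_grid[which.min(grid_rss)]
    opt <- stats::optimize(function(lb) profile_rss(exp(lb), 0)$rss,
                           interval = log(b0) + c(-1, 1), tol = 1e-10)
    beta <- exp(opt$minimum)
    gamma <- 0
  } else {
    gamma_min <- 1e-9
    starts <- expand.grid(lb = log(exp(seq(log(beta_range[1]),
                                           log(beta_range[2]),
                                           length.out = n_starts))),
                          lg = log(c(gamma_min, 0.005, 0.02, 0.08)))
    # include the eq2 optimum (gamma ~ 0) as a start so eq3 never fits worse
    grid_rss <- vapply(lb_grid, function(b) profile_rss(b, 0)$rss, numeric(1))
    starts <- rbind(starts,
                    data.frame(lb = log(lb_grid[which.min(grid_rss)]),
                               lg = log(gamma_min)))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(c(starts$lb[i], starts$lg[i]),
                     function(par) profile_rss(exp(par[1]), exp(par[2]))$rss,
                     method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best))
      stop("RAG fit did not converge from any start", call. = FALSE)
    beta <- exp(best$par[1])
    gamma <- exp(best$par[2])
    if (gamma < 1e-8) gamma <- 0
  }

  pr <- profile_rss(beta, gamma)
  E <- decay(beta, gamma)
  fitted <- sapply(seq_len(ncol(R)), function(j) pr$pars[j, 1] + pr$pars[j, 2] * E)
  v_sat <- pr$pars[, 1]
  s0 <- pmin(pmax(1 + pr$pars[, 2] / v_sat, 0), 1)
  curves <- data.frame(curve = seq_len(ncol(R)), v_sat = v_sat, s0 = s0)
  if (!is.null(rates$lb)) curves$lb <- rates$lb
  structure(list(beta = beta, gamma = gamma,
                 halving_time = log(2) / beta,
                 curves = curves, rss = pr$rss,
                 fitted = fitted, time = tt, variant = variant),
            class = "rag_fit")
}

#' @export
print.rag_fit <- function(x, ...) {
  cat(sprintf("RAG fit (%s): beta = %.4g /min (halving time %.1f min)",
              x$variant, x$beta, x$halving_time))
  if (x$gamma > 0) cat(sprintf(", gamma = %.4g /min", x$gamma))
  cat(sprintf(", rss = %.3g\n", x$rss))
  print(x$curves, digits = 4)
  invisible(x)
}

#' Scale factor between two elongation-rate families
#'
#' Least-squares scalar `k` minimising `||A - k B||` over the common valid
#' grid, used to test whether two rate families (for example wild type and
#' a mutant with lowered cell-wall production per TG site) differ only by a
#' global scale. The relative residual quantifies shape mismatch beyond
#' pure scaling.
#'
#' @param ratesA,ratesB two [rate_family()] objects on overlapping grids.
#' @return List with `ratio` (`k`), `residual` (relative RMS of `A - k B`)
#'   and `n` (points compared).
#' @export
fit_scale_factor <- function(ratesA, ratesB) {
  ta <- ratesA$time; tb <- ratesB$time
  va <- if (is.null(ratesA$valid)) rep(TRUE, length(ta)) else ratesA$valid
  vb <- if (is.null(ratesB$valid)) rep(TRUE, length(tb)) else ratesB$valid
  common_t <- intersect(ta[va], tb[vb])
  if (length(common_t) == 0L)
    stop("rate families share no valid time points", call. = FALSE)
  ia <- match(common_t, ta); ib <- match(common_t, tb)
  A <- as.matrix(ratesA$rate)[ia, , drop = FALSE]
  B <- as.matrix(ratesB$rate)[ib, , drop = FALSE]
  if (ncol(A) != ncol(B))
    stop("rate families have different numbers of curves", call. = FALSE)
  k <- sum(A * B) / sum(B * B)
  list(ratio = k,
       residual = sqrt(mean((A - k * B)^2)) / mean(abs(A)),
       n = length(A))
}

#' Average elongation rate as a function of cell length
#'
#' Pools the (length, rate) pairs of a trajectory/rate family over its
#' valid mask, weights each conditioning birth length by a supplied density
#' (for example the observed birth-length distribution), and applies a
#' moving average over cell length. This converts rate-vs-time curves into
#' the rate-vs-length curve that polar fluorescence intensities can be
#' compared against.
#'
#' @param rates a [rate_family()].
#' @param family the matching [trajectory_family()] (same grids).
#' @param window half-width of the moving-average window in um (points
#'   within `window` of each query length are averaged).
#' @param lb_weights optional numeric vector of weights, one per
#'   conditioning length (defaults to equal weights).
#' @param at optional query lengths; defaults to a 0.1 um grid spanning the
#'   pooled lengths.
#' @return Data frame with columns `length`, `rate` and `n` (points in the
#'   window); rows with an empty window are dropped.
#' @export
rate_vs_length <- function(rates, family, window = 0.7, lb_weights = NULL,
                           at = NULL) {
  if (!all(rates$time %in% family$time))
    stop("rate and trajectory families are on different time grids",
         call. = FALSE)
  it <- match(rates$time, family$time)
  L <- as.matrix(family$surface)[it, , drop = FALSE]
  V <- as.matrix(rates$rate)
  keep <- if (is.null(rates$valid)) rep(TRUE, length(rates$time)) else rates$valid
  L <- L[keep, , drop = FALSE]; V <- V[keep, , drop = FALSE]
  nlb <- ncol(V)
  if (is.null(lb_weights)) lb_weights <- rep(1, nlb)
  stopifnot(length(lb_weights) == nlb)
  w <- rep(lb_weights, each = nrow(V))
  x <- as.vector(L); y <- as.vector(V)
  if (is.null(at)) at <- seq(min(x), max(x), by = 0.1)
  rows <- lapply(at, function(q) {
    sel <- abs(x - q) <= window
    if (!any(sel)) return(NULL)
    data.frame(length = q,
               rate = sum(w[sel] * y[sel]) / sum(w[sel]),
               n = sum(sel))
  })
  do.call(rbind, rows)
}
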