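#' Adder regression of division length on birth length
#'
#' Ordinary least squares of division length `ld` on birth length `lb` over
#' all divided cells, with a bootstrap (resampling cells with replacement)
#' percentile confidence interval for the slope. The slope diagnoses the
#' division-control archetype: 1 for a pure adder (cells add a fixed
#' length), 0 for a pure sizer (cells divide at a fixed length).
#'
#' @param table a [lineage_table()] with at least 3 divided cells.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @param conf confidence level of the percentile interval, default 0.95.
#' @return An object of class `adder_fit`: list with `slope`, `intercept`
#'   (um), `ci_slope` (percentile bounds), `n_cells`, `n_boot`.
#' @export
adder_regression <- function(table, n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(inherits(table, "lineage_table"))
  cells <- table$cells[table$cells$divided, , drop = FALSE]
  n <- nrow(cells)
  if (n < 3L)
    stop("adder regression needs at least 3 divided cells (found ", n, ")",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, cells$lb), cells$ld)
  slope <- fit$coefficients[2L]
  intercept <- fit$coefficients[1L]
  set.seed(as.integer(seed))
  boot_slopes <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::var(cells$lb[i]) < 1e-12) return(NA_real_)
    stats::lm.fit(cbind(1, cells$lb[i]), cells$ld[i])$coefficients[2L]
  }, numeric(1))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- stats::quantile(boot_slopes, probs, na.rm = TRUE, names = FALSE)
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 ci_slope = ci, n_cells = n, n_boot = n_boot, conf = conf),
            class = "adder_fit")
}

#' @export
print.adder_fit <- function(x, ...) {
  cat(sprintf(paste0("Adder regression (ld on lb, %d cells): slope %.3f ",
                     "[%.3f, %.3f] (%.0f%% bootstrap CI), intercept %.3f um\n"),
              x$n_cells, x$slope, x$ci_slope[1], x$ci_slope[2],
              100 * x$conf, x$intercept))
  invisible(x)
}

#' Exponential-growth consistency test
#'
#' For an exponential grower with a common rate `alpha`, the per-generation
#' averages of `log(ld/lb)` against generation time `T` lie on a straight
#' line through the origin with slope `alpha`. This test groups divided
#' cells by generation time (one bin per frame count, since frame-sampled
#' data take discrete generation times), computes the bin means and SEMs of
#' `log(ld/lb)` (bins with fewer than 3 cells are dropped), and fits the
#' origin-constrained slope by least squares over the bin means. Systematic
#' residual patterns (short-`T` bins above the line, long-`T` bins below)
#' indicate non-exponential growth.
#'
#' @param table a [lineage_table()].
#' @return An object of class `exp_test`: list with `bins` (data frame of
#'   `T_mean`, `mean_log_ratio`, `sem`, `n`), `alpha_hat` (1/min) and
#'   `residuals` (bin means minus fitted line).
#' @export
exp_growth_test <- function(table) {
  stopifnot(inherits(table, "lineage_table"))
  cells <- table$cells[table$cells$divided, , drop = FALSE]
  if (nrow(cells) == 0L)
    stop("no divided cells", call. = FALSE)
  dt <- table$metadata$interval_min
  ratio <- log(cells$ld / cells$lb)
  bin <- ceiling(cells$generation_time / dt - 1e-9)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(cells)), bin), function(i) {
    data.frame(T_mean = mean(cells$generation_time[i]),
               mean_log_ratio = mean(ratio[i]),
               sem = stats::sd(ratio[i]) / sqrt(length(i)),
               n = length(i))
  }))
  agg <- agg[agg$n >= 3L, , drop = FALSE]
  if (nrow(agg) == 0L)
    stop("no generation-time bin holds at least 3 cells", call. = FALSE)
  rownames(agg) <- NULL
  alpha_hat <- sum(agg$T_mean * agg$mean_log_ratio) / sum(agg$T_mean^2)
  structure(list(bins = agg, alpha_hat = alpha_hat,
                 residuals = agg$mean_log_ratio - alpha_hat * agg$T_mean),
            class = "exp_test")
}

#' @export
print.exp_test <- function(x, ...) {
  cat(sprintf(paste0("Exponential-growth test: %d generation-time bins, ",
                     "origin-constrained slope alpha = %.5f /min\n"),
              nrow(x$bins), x$alpha_hat))
  invisible(x)
}
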