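#' Per-cell 1D fluorescence intensity profiles
#'
#' An `intensity_profile` holds one cell's 1D fluorescence profile in
#' pole-anchored coordinates: positions from the new pole (0) to the cell
#' length, with raw and (optionally) background-corrected intensities.
#'
#' @param cell_id cell identifier.
#' @param positions positions along the cell axis (um), sorted, within
#'   `[0, cell_length]`.
#' @param intensities raw intensities (AU), same length as `positions`.
#' @param cell_length cell length (um); defaults to `max(positions)`.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(cell_id, positions, intensities,
                              cell_length = max(positions)) {
  stopifnot(length(positions) == length(intensities),
            !is.unsorted(positions),
            positions[1] >= -1e-9,
            positions[length(positions)] <= cell_length + 1e-9)
  structure(list(cell_id = as.character(cell_id),
                 cell_length = cell_length,
                 positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 corrected = NULL),
            class = "intensity_profile")
}

#' Split a long profile table into intensity profiles
#'
#' @param df data frame with columns `cell_id`, `length_um`,
#'   `position_um`, `intensity_au` (the canonical profile file format, and
#'   the output of [simulate_profiles()]).
#' @return Named list of [intensity_profile()] objects.
#' @export
profiles_from_table <- function(df) {
  mandatory <- c("cell_id", "length_um", "position_um", "intensity_au")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L)
    stop("profile table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sp <- split(df, df$cell_id)
  lapply(sp, function(d) {
    d <- d[order(d$position_um), , drop = FALSE]
    intensity_profile(d$cell_id[1L], d$position_um, d$intensity_au,
                      cell_length = d$length_um[1L])
  })
}

#' Read / write profile tables
#'
#' The canonical profile file is UTF-8 comma-separated text with one row
#' per cell per position and columns
#' `cell_id,length_um,position_um,intensity_au`.
#'
#' @param path file path.
#' @return `read_profiles()` returns a named list of
#'   [intensity_profile()]s; `write_profiles()` invisibly returns `path`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("cell_id" %in% names(df)) df$cell_id <- as.character(df$cell_id)
  profiles_from_table(df)
}

#' @rdname read_profiles
#' @param profiles a list of [intensity_profile()]s or a long profile
#'   data frame.
#' @export
write_profiles <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else
    do.call(rbind, lapply(profiles, function(p)
      data.frame(cell_id = p$cell_id, length_um = p$cell_length,
                 position_um = p$positions, intensity_au = p$intensities)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Background-correct an intensity profile
#'
#' Subtracts the cytoplasmic contribution estimated as the minimum
#' intensity within a mid-cell window (the central `midzone_fraction` of
#' the cell), where non-dividing cells consistently show their profile
#' minimum. Negative corrected values are clipped to 0 (counted in the
#' `n_clipped` attribute). If the mid-cell point itself sits well above
#' the windowed minimum — the signature of a septal peak in a dividing
#' cell — the profile is flagged (`septal_flag` attribute); the windowed
#' minimum is then taken beside the peak.
#'
#' Applying the correction twice equals applying it once (idempotent).
#'
#' @param p an [intensity_profile()].
#' @param midzone_fraction fraction of the cell length centred on mid-cell
#'   searched for the minimum (default 0.3).
#' @param septal_factor flag threshold: mid-cell intensity above
#'   `septal_factor` times the interquartile range over the windowed
#'   minimum (default 1).
#' @return The profile with its `corrected` field filled.
#' @export
correct_background <- function(p, midzone_fraction = 0.3, septal_factor = 1) {
  stopifnot(inherits(p, "intensity_profile"),
            midzone_fraction > 0, midzone_fraction <= 1)
  y <- if (is.null(p$corrected)) p$intensities else p$corrected
  mid <- p$cell_length / 2
  half <- midzone_fraction * p$cell_length / 2
  in_zone <- abs(p$positions - mid) <= half
  if (sum(in_zone) < 5L)
    stop("fewer than 5 samples inside the mid-cell window", call. = FALSE)
  bg <- min(y[in_zone])
  corrected <- pmax(y - bg, 0)
  mid_val <- y[which.min(abs(p$positions - mid))]
  iqr <- stats::IQR(y)
  p$corrected <- corrected
  attr(p, "background") <- bg
  attr(p, "n_clipped") <- sum(y - bg < 0)
  attr(p, "septal_flag") <- (mid_val - bg) > septal_factor * max(iqr, 1e-12)
  p
}

#' Polar intensities of a corrected profile
#'
#' Mean background-corrected intensity within `width` of each cell tip
#' (new pole at position 0, old pole at the cell length), plus their sum.
#' The default width of 0.77 um matches a 60-pixel polar region at
#' ~12.8 nm/px; results are not strongly dependent on this definition.
#'
#' @param p a background-corrected [intensity_profile()].
#' @param width polar-region width from each tip (um), default 0.77.
#' @return List with `new_pole`, `old_pole`, `total` (AU).
#' @export
polar_intensity <- function(p, width = 0.77) {
  stopifnot(inherits(p, "intensity_profile"))
  if (is.null(p$corrected))
    stop("profile is not background-corrected; run correct_background()",
         call. = FALSE)
  if (width > p$cell_length / 2)
    stop("polar regions overlap: width exceeds half the cell length",
         call. = FALSE)
  new_sel <- p$positions <= width
  old_sel <- p$positions >= p$cell_length - width
  new_pole <- if (any(new_sel)) mean(p$corrected[new_sel]) else 0
  old_pole <- if (any(old_sel)) mean(p$corrected[old_sel]) else 0
  list(new_pole = new_pole, old_pole = old_pole,
       total = new_pole + old_pole)
}

#' Moving average of values over cell length
#'
#' At each query length `x`, the mean (and SEM) of all values whose cell
#' length lies within `window` of `x` — the moving average used to present
#' per-cell quantities (polar intensities, predicted elongation rates) as
#' smooth functions of cell length.
#'
#' @param lengths per-cell lengths (um).
#' @param values per-cell values (same length).
#' @param window window half-width (um), default 0.7.
#' @param at query lengths; defaults to a 0.05 um grid over the data.
#' @return Data frame with `length`, `mean`, `sem`, `n`; query points with
#'   an empty window are dropped.
#' @export
moving_average_by_length <- function(lengths, values, window = 0.7,
                                     at = NULL) {
  stopifnot(length(lengths) == length(values), length(lengths) >= 1L)
  if (is.null(at)) at <- seq(min(lengths), max(lengths), by = 0.05)
  rows <- lapply(at, function(x) {
    sel <- abs(lengths - x) <= window
    n <- sum(sel)
    if (n == 0L) return(NULL)
    data.frame(length = x, mean = mean(values[sel]),
               sem = if (n > 1L) stats::sd(values[sel]) / sqrt(n) else NA_real_,
               n = n)
  })
  do.call(rbind, rows)
}

#' Mean intensity in segments measured from the cell tips
#'
#' Mean background-corrected intensity within each `[edge_i, edge_(i+1))`
#' band of distance from the tip, for both poles — used to ask whether
#' insertion close to the tip stays constant across cell lengths while
#' more distal bands grow.
#'
#' @param p a background-corrected [intensity_profile()].
#' @param segment_edges increasing distances from the tip (um), for
#'   example `c(0, 0.2, 0.4, 0.6, 0.8)`.
#' @return Data frame with `segment` (label), `from`, `to`, `new_pole`,
#'   `old_pole` mean intensities.
#' @export
tip_segment_intensities <- function(p, segment_edges) {
  stopifnot(inherits(p, "intensity_profile"))
  if (is.null(p$corrected))
    stop("profile is not background-corrected; run correct_background()",
         call. = FALSE)
  if (is.unsorted(segment_edges, strictly = TRUE))
    stop("segment_edges must be strictly increasing", call. = FALSE)
  d_new <- p$positions
  d_old <- p$cell_length - p$positions
  k <- length(segment_edges) - 1L
  out <- lapply(seq_len(k), function(i) {
    lo <- segment_edges[i]; hi <- segment_edges[i + 1L]
    sn <- d_new >= lo & d_new < hi
    so <- d_old >= lo & d_old < hi
    data.frame(segment = sprintf("[%.2f,%.2f)", lo, hi), from = lo, to = hi,
               new_pole = if (any(sn)) mean(p$corrected[sn]) else NA_real_,
               old_pole = if (any(so)) mean(p$corrected[so]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Test a linear relation for proportionality
#'
#' Ordinary least squares of `y` on `x`, flagging the intercept as
#' consistent with zero when its magnitude is within twice its standard
#' error, and reporting the maximum relative deviation of the fitted line
#' from the best through-origin line over the observed `x` range.
#'
#' @param x,y numeric vectors (at least 3 points, non-degenerate `x`).
#' @return List with `slope`, `intercept`, `intercept_se`,
#'   `intercept_consistent_with_zero`, `slope_origin` (through-origin
#'   slope), `max_relative_deviation`.
#' @export
proportionality_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) < 1e-12) stop("degenerate x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # an exactly collinear input triggers a harmless perfect-fit warning
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  k0 <- sum(x * y) / sum(x * x)
  xr <- x[x > 0]
  dev <- if (length(xr) > 0L && k0 != 0)
    max(abs((co[1L] + co[2L] * xr) - k0 * xr) / abs(k0 * xr)) else NA_real_
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       intercept_se = unname(se[1L]),
       intercept_consistent_with_zero =
         abs(co[1L]) <= 2 * se[1L] + 1e-8 * max(abs(y)),
       slope_origin = k0,
       max_relative_deviation = unname(dev))
}

#' Assemble a demograph
#'
#' Stacks per-cell profiles into a matrix for visual inspection: rows are
#' cells sorted by length, each profile is resampled by linear
#' interpolation onto a common relative-position axis (mid-cell at 0) and
#' flipped so the stronger pole points the same way.
#'
#' @param profiles list of [intensity_profile()]s (>= 2). Corrected
#'   intensities are used when present, raw otherwise.
#' @param n_positions number of resampled positions (default 101).
#' @param pole_width width (um) used to decide which pole is stronger,
#'   default 0.77.
#' @return Matrix `[cells x positions]` with attributes `lengths`
#'   (sorted), `cell_ids`, `flipped` (logical per row) and
#'   `rel_positions` (from -0.5 to 0.5).
#' @export
build_demograph <- function(profiles, n_positions = 101, pole_width = 0.77) {
  stopifnot(length(profiles) >= 2L)
  lens <- vapply(profiles, function(p) p$cell_length, numeric(1))
  ord <- order(lens)
  rel <- seq(-0.5, 0.5, length.out = n_positions)
  rows <- matrix(NA_real_, length(profiles), n_positions)
  flipped <- logical(length(profiles))
  for (i in seq_along(ord)) {
    p <- profiles[[ord[i]]]
    y <- if (is.null(p$corrected)) p$intensities else p$corrected
    L <- p$cell_length
    w <- min(pole_width, L / 2)
    left <- mean(y[p$positions <= w])
    right <- mean(y[p$positions >= L - w])
    if (left > right) {
      y <- rev(y)
      pos <- L - rev(p$positions)
      flipped[i] <- TRUE
    } else pos <- p$positions
    rows[i, ] <- stats::approx(pos / L - 0.5, y, xout = rel, rule = 2)$y
  }
  structure(rows, lengths = lens[ord],
            cell_ids = vapply(profiles[ord], function(p) p$cell_id,
                              character(1)),
            flipped = flipped, rel_positions = rel)
}

#' Detect the onset of septum formation from a mid-cell signal
#'
#' A sharp, sustained increase of the mid-cell scaffold-protein signal
#' (for example DivIVA) marks the onset of septum formation. The detector
#' declares onset at the first frame where the signal exceeds
#' `baseline mean + k * baseline sd` and stays above for at least 2
#' consecutive frames.
#'
#' @param mid_signal numeric time series of mid-cell intensity (AU).
#' @param times optional frame times (min); the onset is then returned in
#'   time units, else as a frame index.
#' @param baseline_window number of initial frames defining the baseline
#'   (default 5).
#' @param threshold_k threshold in baseline sds (default 3).
#' @return Onset time (or index), or `NA` if no sustained increase is
#'   found (including a flat series with zero baseline variance).
#' @export
septum_onset <- function(mid_signal, times = NULL, baseline_window = 5,
                         threshold_k = 3) {
  n <- length(mid_signal)
  if (n < baseline_window + 2L)
    stop("series shorter than baseline_window + 2", call. = FALSE)
  base <- mid_signal[seq_len(baseline_window)]
  mu <- mean(base)
  s <- stats::sd(base)
  if (s == 0 && max(mid_signal) <= mu) return(NA_real_)
  thr <- mu + threshold_k * s
  above <- mid_signal > thr
  for (i in seq(baseline_window + 1L, n - 1L)) {
    if (above[i] && above[i + 1L])
      return(if (is.null(times)) i else times[i])
  }
  NA_real_
}
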