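# Small in-code fixtures shared across test files.

# a 2-cell toy lineage in long format (mother "m" with daughter "m.1")
toy_frames <- function() {
  data.frame(cell_id = c("m", "m", "m", "m.1", "m.1", "m.1"),
             parent_id = c(NA, NA, NA, "m", "m", "m"),
             time_min = c(0, 3, 6, 0, 3, 6),
             length_um = c(2.0, 2.2, 2.4, 1.2, 1.4, 1.6),
             stringsAsFactors = FALSE)
}

# deterministic colony of cells growing under an exact growth law, all
# divided at their given generation times (stub daughters mark division;
# daughters carry a single birth frame and are censored)
make_growth_table <- function(lbs, mode, params, T = 45, dt = 3,
                              interval = dt) {
  T <- rep_len(T, length(lbs))
  frames <- list()
  for (i in seq_along(lbs)) {
    id <- sprintf("g%04d", i)
    tt <- seq(0, floor(T[i] / dt) * dt, by = dt)
    if (T[i] - max(tt) > 1e-9) tt <- c(tt, T[i])
    ll <- growth_length(mode, tt, lbs[i], params)
    frames[[length(frames) + 1L]] <-
      data.frame(cell_id = id, parent_id = NA_character_,
                 time_min = tt, length_um = ll, stringsAsFactors = FALSE)
    ld <- ll[length(ll)]
    frames[[length(frames) + 1L]] <-
      data.frame(cell_id = paste0(id, ".1"), parent_id = id,
                 time_min = 0, length_um = ld / 2, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      data.frame(cell_id = paste0(id, ".2"), parent_id = id,
                 time_min = 0, length_um = ld / 2, stringsAsFactors = FALSE)
  }
  lineage_table(do.call(rbind, frames), list(interval_min = interval))
}

# minimal table of divided cells with prescribed (lb, ld) pairs
make_divided_table <- function(lb, ld, T = 30, dt = 3) {
  stopifnot(length(lb) == length(ld))
  T <- rep_len(T, length(lb))
  frames <- list()
  for (i in seq_along(lb)) {
    id <- sprintf("d%04d", i)
    tt <- seq(0, T[i], by = dt)
    ll <- seq(lb[i], ld[i], length.out = length(tt))
    frames[[length(frames) + 1L]] <-
      data.frame(cell_id = id, parent_id = NA_character_,
                 time_min = tt, length_um = ll, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      data.frame(cell_id = paste0(id, ".1"), parent_id = id,
                 time_min = 0, length_um = ld[i] / 2, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      data.frame(cell_id = paste0(id, ".2"), parent_id = id,
                 time_min = 0, length_um = ld[i] / 2, stringsAsFactors = FALSE)
  }
  lineage_table(do.call(rbind, frames), list(interval_min = dt))
}

# synthetic intensity profile: baseline + two polar Gaussian peaks
make_profile <- function(L = 4, baseline = 50, amp_new = 30, amp_old = 20,
                         peak_sd = 0.15, step = 0.02, id = "p1") {
  x <- seq(0, L, by = step)
  y <- baseline + amp_new * peak_sd * sqrt(2 * pi) * dnorm(x, 0, peak_sd) +
    amp_old * peak_sd * sqrt(2 * pi) * dnorm(x, L, peak_sd)
  intensity_profile(id, x, y, cell_length = L)
}
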