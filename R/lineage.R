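#' Lineage tables of single-cell time-lapse measurements
#'
#' A `lineage_table` is the universal input of the package: per-cell time
#' series of lengths together with genealogy. It is built from a long-format
#' data frame with one row per cell per frame and the columns
#' `cell_id`, `parent_id`, `time_min`, `length_um` and optionally
#' `area_um2` and `midcell_au`. Times are relative to each cell's birth
#' (first frame at 0) and sampled at a uniform interval (default 3 min);
#' a divided cell's final row may fall at the exact division time, so the
#' last interval of a record may be shorter than the sampling interval.
#'
#' A cell is considered divided when other cells reference it as their
#' parent; cells without children are treated as censored (no division
#' length, no generation time).
#'
#' @param frames data frame with one row per cell per frame (see Details).
#' @param metadata named list; recognised entries include `interval_min`
#'   (sampling interval, default inferred from the data), `length_unit`,
#'   `strain`, `meas_noise_sd` (measurement noise sd in um, used by
#'   [validate_lineage()] to set the mass-conservation tolerance) and
#'   `truncated` (logical, set by [simulate_colony()] when the population
#'   cap was hit).
#'
#' @return An object of class `lineage_table`: a list with elements
#'   `frames` (the per-frame table, ordered by cell then time), `cells`
#'   (per-cell summary: `cell_id`, `parent_id`, `n_frames`, `lb`, `ld`,
#'   `generation_time`, `divided`) and `metadata`.
#' @seealso [read_lineage_table()], [write_lineage_table()],
#'   [validate_lineage()], [simulate_colony()]
#' @export
#' @examples
#' fr <- data.frame(cell_id = rep(c("a", "a.1", "a.2"), each = 3),
#'                  parent_id = rep(c(NA, "a", "a"), each = 3),
#'                  time_min = rep(c(0, 3, 6), 3),
#'                  length_um = c(2.0, 2.1, 2.2, 1.1, 1.2, 1.3, 1.1, 1.2, 1.3))
#' tab <- lineage_table(fr)
#' tab$cells
lineage_table <- function(frames, metadata = list()) {
  frames <- as.data.frame(frames)
  mandatory <- c("cell_id", "parent_id", "time_min", "length_um")
  missing_cols <- setdiff(mandatory, names(frames))
  if (length(missing_cols) > 0L)
    stop("lineage frames lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frames$cell_id <- as.character(frames$cell_id)
  frames$parent_id <- as.character(frames$parent_id)
  frames$parent_id[!is.na(frames$parent_id) & frames$parent_id == ""] <- NA_character_
  frames <- frames[order(frames$cell_id, frames$time_min), , drop = FALSE]
  rownames(frames) <- NULL

  # per-cell summary
  sp <- split(seq_len(nrow(frames)), frames$cell_id)
  ids <- names(sp)
  parent_of <- vapply(sp, function(i) frames$parent_id[i[1L]], character(1))
  nf <- lengths(sp)
  first_i <- vapply(sp, `[`, integer(1), 1L)
  last_i <- vapply(sp, function(i) i[length(i)], integer(1))
  has_child <- ids %in% parent_of[!is.na(parent_of)]
  cells <- data.frame(
    cell_id = ids,
    parent_id = unname(parent_of),
    n_frames = unname(nf),
    lb = frames$length_um[first_i],
    ld = ifelse(has_child, frames$length_um[last_i], NA_real_),
    generation_time = ifelse(has_child, frames$time_min[last_i], NA_real_),
    divided = unname(has_child),
    stringsAsFactors = FALSE
  )
  rownames(cells) <- NULL

  if (is.null(metadata$interval_min)) {
    dts <- if (length(sp) > 0L) diff(frames$time_min[sp[[which.max(nf)]]]) else numeric(0)
    metadata$interval_min <- if (length(dts) > 0L) stats::median(dts) else 3
  }
  if (is.null(metadata$length_unit)) metadata$length_unit <- "um"

  structure(list(frames = frames, cells = cells, metadata = metadata),
            class = "lineage_table")
}

#' @export
print.lineage_table <- function(x, ...) {
  nd <- sum(x$cells$divided)
  cat("Lineage table: ", nrow(x$cells), " cells (", nd, " divided, ",
      nrow(x$cells) - nd, " censored), ", nrow(x$frames), " frames, ",
      "sampling interval ", x$metadata$interval_min, " min\n", sep = "")
  if (nd > 0) {
    cat(sprintf("  birth length: %.2f-%.2f %s; generation time: %.1f-%.1f min\n",
                min(x$cells$lb), max(x$cells$lb), x$metadata$length_unit,
                min(x$cells$generation_time, na.rm = TRUE),
                max(x$cells$generation_time, na.rm = TRUE)))
  }
  invisible(x)
}

#' Read a lineage table from delimited text
#'
#' Reads the canonical lineage file: UTF-8 comma-separated text with a header
#' row and columns `cell_id,parent_id,time_min,length_um[,area_um2][,midcell_au]`;
#' a missing parent is encoded as an empty field.
#'
#' @param path path to a CSV file (or a connection).
#' @param metadata optional metadata list passed to [lineage_table()].
#' @return A [lineage_table()].
#' @export
read_lineage_table <- function(path, metadata = list()) {
  frames <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("cell_id", "parent_id", "time_min", "length_um")
  missing_cols <- setdiff(mandatory, names(frames))
  if (length(missing_cols) > 0L)
    stop("lineage file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  frames$cell_id <- as.character(frames$cell_id)
  frames$parent_id <- as.character(frames$parent_id)
  dup <- duplicated(frames[, c("cell_id", "time_min")])
  if (any(dup)) {
    bad <- unique(frames$cell_id[dup])
    stop("duplicated (cell_id, time) rows for cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tab <- lineage_table(frames, metadata)
  # fail fast on non-monotone times, naming the offending cell
  sp <- split(tab$frames$time_min, tab$frames$cell_id)
  mono <- vapply(sp, function(tt) all(diff(tt) > 0), logical(1))
  if (any(!mono))
    stop("non-monotone times within cell(s): ",
         paste(utils::head(names(sp)[!mono], 5), collapse = ", "),
         call. = FALSE)
  tab
}

#' Write a lineage table to delimited text
#'
#' Emits the canonical lineage format (see [read_lineage_table()]) with
#' deterministic row order: by `cell_id`, then time. Numeric fields keep
#' full double precision, so a write/read round trip is lossless.
#'
#' @param table a [lineage_table()].
#' @param path output file path (or connection).
#' @return Invisibly, `path`.
#' @export
write_lineage_table <- function(table, path) {
  stopifnot(inherits(table, "lineage_table"))
  fr <- table$frames
  fr$parent_id[is.na(fr$parent_id)] <- ""
  utils::write.csv(fr, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a lineage table
#'
#' Checks the structural invariants of a [lineage_table()] and reports every
#' violation found (an empty report means the table is valid):
#' \itemize{
#'   \item times start at 0, strictly increase, and are uniformly spaced
#'     at the sampling interval (the final interval of a divided cell may
#'     be shorter, since it ends at the division event);
#'   \item lengths strictly positive;
#'   \item cell ids unique per frame-time, parent links resolvable and
#'     acyclic, at most two children per parent;
#'   \item a cell with children must itself be divided (have a final
#'     division frame);
#'   \item daughters' birth lengths sum to the mother's division length
#'     within `septum_tol` plus a measurement-noise allowance of
#'     `5 * sqrt(3) * meas_noise_sd` when the table's metadata records a
#'     measurement-noise sd.
#' }
#'
#' @param table a [lineage_table()].
#' @param septum_tol length (um) allowed to be lost at the septum; default 0
#'   (exact conservation).
#' @return Character vector of violation messages, `character(0)` if valid,
#'   with class `lineage_validation`.
#' @export
validate_lineage <- function(table, septum_tol = 0) {
  stopifnot(inherits(table, "lineage_table"))
  fr <- table$frames
  cells <- table$cells
  dt <- table$metadata$interval_min
  msg <- character(0)

  dup <- duplicated(fr[, c("cell_id", "time_min")])
  if (any(dup))
    msg <- c(msg, paste0("duplicated (cell_id, time) rows for cell(s): ",
                         paste(unique(fr$cell_id[dup]), collapse = ", ")))

  sp <- split(seq_len(nrow(fr)), fr$cell_id)
  tol <- 1e-6
  for (id in names(sp)) {
    tt <- fr$time_min[sp[[id]]]
    ll <- fr$length_um[sp[[id]]]
    if (tt[1L] != 0)
      msg <- c(msg, paste0("cell ", id, ": times do not start at 0"))
    d <- diff(tt)
    if (length(d) > 0L) {
      if (any(d <= 0)) {
        msg <- c(msg, paste0("cell ", id, ": times not strictly increasing"))
      } else {
        body <- if (length(d) > 1L) d[-length(d)] else numeric(0)
        if (any(abs(body - dt) > tol))
          msg <- c(msg, paste0("cell ", id, ": non-uniform sampling interval"))
        if (d[length(d)] > dt + tol)
          msg <- c(msg, paste0("cell ", id, ": final interval exceeds the sampling interval"))
      }
    }
    if (any(ll <= 0))
      msg <- c(msg, paste0("cell ", id, ": non-positive length"))
  }

  # genealogy
  known <- cells$cell_id
  orphan <- !is.na(cells$parent_id) & !(cells$parent_id %in% known)
  if (any(orphan))
    msg <- c(msg, paste0("unresolved parent_id for cell(s): ",
                         paste(cells$cell_id[orphan], collapse = ", ")))
  kid_counts <- table(cells$parent_id[!is.na(cells$parent_id)])
  if (any(kid_counts > 2L))
    msg <- c(msg, paste0("more than two children for parent(s): ",
                         paste(names(kid_counts)[kid_counts > 2L], collapse = ", ")))
  # cycles: follow parent chain, must terminate within n steps
  parent_of <- stats::setNames(cells$parent_id, cells$cell_id)
  n <- nrow(cells)
  for (id in cells$cell_id) {
    cur <- id
    steps <- 0L
    while (!is.na(parent_of[cur]) && parent_of[cur] %in% known) {
      cur <- parent_of[[cur]]
      steps <- steps + 1L
      if (steps > n) {
        msg <- c(msg, paste0("cycle in parent links involving cell ", id))
        break
      }
    }
  }

  # mass conservation at division
  noise_sd <- table$metadata$meas_noise_sd
  mass_tol <- septum_tol +
    if (!is.null(noise_sd) && noise_sd > 0) 5 * sqrt(3) * noise_sd else 1e-8
  pids <- unique(cells$parent_id[!is.na(cells$parent_id)])
  for (pid in pids) {
    if (!(pid %in% known)) next
    kids <- cells$cell_id[!is.na(cells$parent_id) & cells$parent_id == pid]
    if (length(kids) != 2L) next
    ld <- cells$ld[cells$cell_id == pid]
    if (is.na(ld)) {
      msg <- c(msg, paste0("cell ", pid, " has children but no division frame"))
      next
    }
    s <- sum(cells$lb[cells$cell_id %in% kids])
    if (abs(s - ld) > mass_tol)
      msg <- c(msg, paste0("cell ", pid, ": daughters' birth lengths sum to ",
                           format(s, digits = 6), " but division length is ",
                           format(ld, digits = 6)))
  }

  structure(msg, class = c("lineage_validation", "character"))
}

#' @export
print.lineage_validation <- function(x, ...) {
  if (length(x) == 0L) {
    cat("Lineage table valid: no violations found.\n")
  } else {
    cat("Lineage validation found", length(x), "violation(s):\n")
    for (m in x) cat(" -", m, "\n")
  }
  invisible(x)
}
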