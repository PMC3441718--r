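# Reversal detection and reversal-frequency statistics for single-cell
# time-lapse tracks of gliding rod-shaped cells.

#' Detect reversals in a single-cell trajectory
#'
#' A reversal is an inversion of the leading/lagging polarity axis: the cell
#' resumes movement in the opposite direction along its long axis. Each
#' frame-to-frame displacement is projected onto the cell's long axis (the
#' `axis_angle_rad` of the earlier frame); a frame's direction is the sign of
#' the projected displacement where its magnitude is at least `min_step`
#' pixels, otherwise the frame counts as paused. A reversal is scored when a
#' run of at least `min_run` same-sign frames follows a run of at least
#' `min_run` frames of the opposite sign; paused frames may sit between the
#' runs, and shorter runs of either sign (sampling jitter) neither score a
#' reversal nor reset the established direction.
#'
#' @param traj data frame with columns `frame`, `x`, `y`, `axis_angle_rad`
#'   for one cell (rows in frame order; one row per frame).
#' @param min_run minimum sustained run length in frames for a direction to
#'   count (default 2 frames, i.e. 1 min at 30-s sampling).
#' @param min_step minimum projected displacement in pixels for a frame to
#'   count as movement rather than a pause (default 1).
#' @return List with `count` (number of reversals) and `frames` (1-based
#'   displacement index at which each scored reversal begins).
#' @export
detect_reversals <- function(traj, min_run = 2L, min_step = 1) {
  if (!all(c("frame", "x", "y", "axis_angle_rad") %in% names(traj))) {
    stop2("traj needs columns frame, x, y, axis_angle_rad")
  }
  if (!is_count(min_run, 1)) stop2("min_run must be a positive integer")
  traj <- traj[order(traj$frame), , drop = FALSE]
  n_disp <- nrow(traj) - 1L
  if (n_disp < 2L * min_run) {
    stop2("track has ", n_disp, " displacements; need at least 2 * min_run = ",
          2L * min_run)
  }
  dx <- diff(traj$x); dy <- diff(traj$y)
  a <- traj$axis_angle_rad[-nrow(traj)]
  proj <- dx * cos(a) + dy * sin(a)
  s <- ifelse(abs(proj) >= min_step, sign(proj), 0)
  moving <- which(s != 0)
  if (length(moving) == 0L) return(list(count = 0L, frames = integer(0)))
  runs <- rle(s[moving])
  count <- 0L
  frames <- integer(0)
  confirmed <- 0  # last direction established by a qualifying run
  pos <- cumsum(c(1L, runs$lengths))  # start index of each run within `moving`
  for (i in seq_along(runs$values)) {
    if (runs$lengths[i] < min_run) next
    v <- runs$values[i]
    if (confirmed != 0 && v != confirmed) {
      count <- count + 1L
      frames <- c(frames, moving[pos[i]])
    }
    confirmed <- v
  }
  list(count = count, frames = frames)
}

#' Per-cell reversal counts for a set of tracks
#'
#' Applies [detect_reversals()] to each cell in a multi-cell track table and
#' normalizes counts to the full observation window. Cells observed for at
#' least `min_coverage` of the window are scaled to reversals per window;
#' shorter tracks are excluded (with a message).
#'
#' @param tracks data frame with columns `frame`, `cell_id`, `x`, `y`,
#'   `axis_angle_rad`, e.g. from [generate_trajectories()] or
#'   [read_tracks()].
#' @param window_min observation window in minutes (default 15).
#' @param frame_interval_s frame interval in seconds (default 30).
#' @param min_coverage minimum fraction of window frames a cell must have to
#'   be included (default 0.8).
#' @inheritParams detect_reversals
#' @return Data frame with columns `cell_id` and `n_reversals` (per window).
#' @export
reversal_counts <- function(tracks, min_run = 2L, min_step = 1,
                            window_min = 15, frame_interval_s = 30,
                            min_coverage = 0.8) {
  if (!all(c("frame", "cell_id", "x", "y", "axis_angle_rad") %in% names(tracks))) {
    stop2("tracks needs columns frame, cell_id, x, y, axis_angle_rad")
  }
  full_disp <- window_min * 60 / frame_interval_s
  cells <- split(tracks, tracks$cell_id)
  res <- lapply(names(cells), function(id) {
    tr <- cells[[id]]
    n_disp <- nrow(tr) - 1L
    if (n_disp < min_coverage * full_disp) {
      message("excluding ", id, ": only ", n_disp, " of ", full_disp,
              " intervals observed")
      return(NULL)
    }
    det <- detect_reversals(tr, min_run = min_run, min_step = min_step)
    data.frame(cell_id = id,
               n_reversals = det$count * full_disp / n_disp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(cell_id = character(0),
                                      n_reversals = numeric(0))
  rownames(out) <- NULL
  out
}

#' Box-plot statistics of per-cell reversal counts
#'
#' Summarizes reversals per observation window across cells the way the
#' field displays them: a box enclosing the 25th and 75th percentiles, a line
#' at the mean, whiskers at the 10th and 90th percentiles, and outliers
#' (points strictly outside the whiskers) drawn individually. Percentiles
#' use linear interpolation between order statistics (the common
#' spreadsheet/statistics default, `stats::quantile()` type 7).
#'
#' @param counts numeric vector of per-cell reversal counts (one observation
#'   window each), or the data frame returned by [reversal_counts()].
#' @return Object of class `reversal_summary`: list with `per_cell_counts`,
#'   `mean`, `p10`, `p25`, `p75`, `p90`, `outliers`, `n_cells`, and
#'   `percentile_method`.
#' @export
reversal_stats <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$n_reversals
  if (length(counts) == 0L) stop2("no reversal counts supplied")
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop2("counts must be non-negative numbers")
  }
  q <- stats::quantile(counts, probs = c(0.10, 0.25, 0.75, 0.90),
                       type = 7, names = FALSE)
  structure(
    list(per_cell_counts = counts, mean = mean(counts),
         p10 = q[1L], p25 = q[2L], p75 = q[3L], p90 = q[4L],
         outliers = counts[counts < q[1L] | counts > q[4L]],
         n_cells = length(counts),
         percentile_method = "linear interpolation (type 7)"),
    class = "reversal_summary"
  )
}

#' @export
print.reversal_summary <- function(x, ...) {
  cat(sprintf(
    "<reversal_summary> n = %d cells; mean %.2f reversals/window\n", x$n_cells,
    x$mean))
  cat(sprintf("  p10 %.2f | p25 %.2f | p75 %.2f | p90 %.2f | %d outlier(s)\n",
              x$p10, x$p25, x$p75, x$p90, length(x$outliers)))
  invisible(x)
}

#' Compare reversal frequencies across strains
#'
#' Orders strains by mean reversal frequency and flags strains whose mean
#' differs from a designated reference strain by more than a configurable
#' factor as hyper- or hypo-reversing.
#'
#' @param summaries named list of [reversal_stats()] summaries, one per
#'   strain (at least two).
#' @param reference name of the reference strain (e.g. the wild type).
#' @param factor fold change in mean reversal frequency beyond which a
#'   strain is flagged (default 2).
#' @return Data frame with columns `strain`, `mean`, `p25`, `p75`, `flag`
#'   (`"hyper"`, `"hypo"`, or `""`), ordered by increasing mean.
#' @export
compare_strains <- function(summaries, reference, factor = 2) {
  if (length(summaries) < 2L) stop2("need summaries for at least 2 strains")
  if (is.null(names(summaries)) || any(names(summaries) == "")) {
    stop2("summaries must be named by strain")
  }
  if (!reference %in% names(summaries)) {
    stop2("unknown reference strain: ", reference)
  }
  if (!is_number(factor) || factor < 1) stop2("factor must be >= 1")
  means <- vapply(summaries, function(s) s$mean, numeric(1L))
  ref_mean <- means[[reference]]
  flag <- rep("", length(means))
  flag[means > factor * ref_mean] <- "hyper"
  flag[means < ref_mean / factor] <- "hypo"
  flag[names(means) == reference] <- ""
  out <- data.frame(
    strain = names(means), mean = unname(means),
    p25 = vapply(summaries, function(s) s$p25, numeric(1L)),
    p75 = vapply(summaries, function(s) s$p75, numeric(1L)),
    flag = flag, stringsAsFactors = FALSE)
  out <- out[order(out$mean, out$strain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Box plot of reversal frequencies per strain
#'
#' Draws the field's standard reversal-frequency display: boxes from the
#' 25th to the 75th percentile, a dark line at the mean, whiskers at the
#' 10th and 90th percentiles, and outliers as open diamonds.
#'
#' @param summaries named list of [reversal_stats()] summaries.
#' @param ylab y-axis label.
#' @return Invisibly, the summaries.
#' @export
plot_reversal_boxes <- function(summaries,
                                ylab = "Reversals per 15 min") {
  n <- length(summaries)
  if (n == 0L) stop2("nothing to plot")
  ymax <- max(vapply(summaries, function(s) max(s$per_cell_counts), numeric(1L)))
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(0, ymax * 1.05),
                 xaxt = "n", xlab = "", ylab = ylab)
  graphics::axis(1, at = seq_len(n), labels = names(summaries), las = 2)
  for (i in seq_len(n)) {
    s <- summaries[[i]]
    graphics::rect(i - 0.3, s$p25, i + 0.3, s$p75, col = "grey85")
    graphics::segments(i - 0.3, s$mean, i + 0.3, s$mean, lwd = 3,
                       col = "grey30")
    graphics::segments(i, s$p75, i, s$p90)
    graphics::segments(i, s$p25, i, s$p10)
    graphics::segments(i - 0.15, s$p90, i + 0.15, s$p90)
    graphics::segments(i - 0.15, s$p10, i + 0.15, s$p10)
    if (length(s$outliers) > 0L) {
      graphics::points(rep(i, length(s$outliers)), s$outliers, pch = 5)
    }
  }
  invisible(summaries)
}
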