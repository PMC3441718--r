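# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth, so all downstream stages are
# testable without external microscopy or genome data.

#' Specification of a synthetic rod-cell fluorescence image
#'
#' Describes an axis-aligned capsule-shaped cell (rectangle with semicircular
#' caps) on a dark background, with a uniform cytoplasmic level and a polar
#' cluster of known integrated intensity planted at each pole. Pole
#' measurement regions are discs centred on the cap tips, clipped to the
#' mask; the cytoplasmic reference region is the set of mask pixels closest
#' to mid-cell with exactly the same pixel count, so no area scaling is
#' needed downstream.
#'
#' @param image_size integer `(h, w)` image dimension in pixels.
#' @param cell_length,cell_width capsule length and width in pixels. The cell
#'   must fit inside the image with a margin of at least 2 pixels.
#' @param cyto_level uniform cytoplasmic intensity, integer photons/pixel.
#' @param pole_intensities planted background-corrected integrated intensity
#'   of each polar cluster, integer photons, `>= 0`.
#' @param pole_region_radius radius (pixels) of the pole measurement discs.
#' @param noise_model `"none"`, `"poisson"` (pixel-wise shot noise), or
#'   `"gaussian"` (additive read noise with `noise_sd`).
#' @param noise_sd standard deviation of gaussian noise (photons).
#' @param seed integer RNG seed; identical specs give identical images.
#' @return Object of class `image_spec`.
#' @export
image_spec <- function(image_size = c(60L, 120L),
                       cell_length = 80,
                       cell_width = 20,
                       cyto_level = 100,
                       pole_intensities = c(500, 100),
                       pole_region_radius = 6,
                       noise_model = c("none", "poisson", "gaussian"),
                       noise_sd = 10,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_size) == 2L, all(image_size >= 1))
  if (!is_count(cell_length, 1) || !is_count(cell_width, 1)) {
    stop2("cell_length and cell_width must be positive integers")
  }
  if (cell_width > cell_length) stop2("cell_width must not exceed cell_length")
  if (cell_length > image_size[2L] - 4 || cell_width > image_size[1L] - 4) {
    stop2("cell must fit inside the image with a >= 2 pixel margin")
  }
  if (!is_count(cyto_level)) stop2("cyto_level must be a non-negative integer")
  if (length(pole_intensities) != 2L ||
      !all(vapply(pole_intensities, is_count, logical(1L)))) {
    stop2("pole_intensities must be two non-negative integers (photons)")
  }
  if (!is_number(pole_region_radius) || pole_region_radius <= 0) {
    stop2("pole_region_radius must be positive")
  }
  structure(
    list(image_size = as.integer(image_size), cell_length = cell_length,
         cell_width = cell_width, cyto_level = cyto_level,
         pole_intensities = as.numeric(pole_intensities),
         pole_region_radius = pole_region_radius,
         noise_model = noise_model, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "image_spec"
  )
}

# Deterministic pixel ordering: distance to a reference point, ties broken by
# (row, col). Used both for planting photons and picking equal-area regions.
order_by_distance <- function(px, ref) {
  d2 <- (px[, "row"] - ref[1L])^2 + (px[, "col"] - ref[2L])^2
  px[order(d2, px[, "row"], px[, "col"]), , drop = FALSE]
}

#' Generate a synthetic rod-cell image with known polar cluster intensities
#'
#' Renders the capsule cell described by an [image_spec()]. Before noise, the
#' integrated intensity over each pole region equals the planted corrected
#' intensity plus `cyto_level` times the region area, so a noiseless image
#' measured with [measure_polar_intensity()] returns the planted values
#' exactly (photon units are integers before noise; the planted photons are
#' spread over the pole disc as evenly as integer counts allow).
#'
#' @param spec an [image_spec()].
#' @return List with elements `image` (a [cell_image()]) and `truth` (list
#'   with the planted `corrected_I`, their `ratio`, and the localization
#'   `pattern` they imply at presence floor 0).
#' @export
generate_cell_image <- function(spec) {
  if (!inherits(spec, "image_spec")) stop2("spec must be an image_spec")
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  half_len <- spec$cell_length / 2
  rad <- spec$cell_width / 2
  ax0 <- cx - (half_len - rad); ax1 <- cx + (half_len - rad)

  cols <- matrix(rep(seq_len(w), each = h), nrow = h)
  rows <- matrix(rep(seq_len(h), times = w), nrow = h)
  # distance of each pixel centre to the capsule spine segment
  xx <- pmin(pmax(cols, ax0), ax1)
  mask <- (cols - xx)^2 + (rows - cy)^2 <= rad^2

  mask_px <- which(mask, arr.ind = TRUE)
  colnames(mask_px) <- c("row", "col")

  tip_left <- c(cy, cx - half_len)
  dl <- (mask_px[, "row"] - tip_left[1L])^2 + (mask_px[, "col"] - tip_left[2L])^2
  pole1 <- mask_px[dl <= spec$pole_region_radius^2, , drop = FALSE]
  if (nrow(pole1) == 0L) stop2("pole_region_radius too small: empty pole region")
  # right pole region is the mirror image, guaranteeing equal pixel counts
  pole2 <- pole1
  pole2[, "col"] <- as.integer(w + 1L - pole1[, "col"])

  i1 <- px_linear(pole1, c(h, w)); i2 <- px_linear(pole2, c(h, w))
  if (length(intersect(i1, i2)) > 0L) {
    stop2("pole regions overlap; reduce pole_region_radius or lengthen the cell")
  }

  npix <- nrow(pole1)
  centre_sorted <- order_by_distance(mask_px, c(cy, cx))
  in_pole <- px_linear(centre_sorted, c(h, w)) %in% c(i1, i2)
  cyto_candidates <- centre_sorted[!in_pole, , drop = FALSE]
  if (nrow(cyto_candidates) < npix) {
    stop2("cell too small for an equal-area cytoplasmic region")
  }
  cyto <- cyto_candidates[seq_len(npix), , drop = FALSE]

  img <- matrix(0, nrow = h, ncol = w)
  img[mask] <- spec$cyto_level
  plant <- function(img, region, photons, tip) {
    ord <- order_by_distance(region, tip)
    idx <- px_linear(ord, c(h, w))
    base <- photons %/% npix
    extra <- photons %% npix
    img[idx] <- img[idx] + base
    if (extra > 0) img[idx[seq_len(extra)]] <- img[idx[seq_len(extra)]] + 1
    img
  }
  img <- plant(img, pole1, spec$pole_intensities[1L], tip_left)
  img <- plant(img, pole2, spec$pole_intensities[2L],
               c(cy, cx + half_len))

  if (spec$noise_model != "none") {
    img <- with_seed(spec$seed, {
      switch(spec$noise_model,
        poisson = matrix(stats::rpois(length(img), img), nrow = h),
        gaussian = {
          noisy <- img + stats::rnorm(length(img), sd = spec$noise_sd)
          matrix(pmax(round(noisy), 0), nrow = h)
        })
    })
  }

  truth <- list(
    corrected_I = spec$pole_intensities,
    ratio = if (all(spec$pole_intensities > 0)) {
      round_half_up(max(spec$pole_intensities) / min(spec$pole_intensities), 1L)
    } else NA_real_,
    pattern = classify_localization(spec$pole_intensities, presence_floor = 0)
  )
  list(image = cell_image(img, mask, list(pole1, pole2), cyto), truth = truth)
}

#' Specification of synthetic single-cell time-lapse trajectories
#'
#' Cells glide along a fixed axis at constant speed and occasionally reverse,
#' inverting their direction of movement. Reversals are a Poisson process
#' with mean `reversal_rate` per observation window, simulated by thinning on
#' the frame grid: each interior frame boundary independently carries a
#' reversal with probability `reversal_rate / (n_intervals - 1)`, so the
#' expected number of reversals per window is exactly `reversal_rate` and
#' every planted event produces a sign change of the noiseless displacement
#' series. Defaults follow the standard imaging protocol: 30-s frame
#' intervals over a 15-min window, 50 cells per strain.
#'
#' @param duration observation window, minutes.
#' @param frame_interval time between frames, seconds. `duration * 60 /
#'   frame_interval` must be an integer.
#' @param reversal_rate expected reversals per window (Poisson mean).
#' @param speed gliding speed, pixels per frame.
#' @param positional_noise_sd i.i.d. gaussian localization error added to
#'   each recorded position, pixels.
#' @param pause_fraction fraction of frames in which a cell does not move,
#'   in `[0, 1]`.
#' @param n_cells number of cells (tracks).
#' @param seed integer RNG seed.
#' @return Object of class `track_spec`.
#' @export
track_spec <- function(duration = 15,
                       frame_interval = 30,
                       reversal_rate = 4,
                       speed = 5,
                       positional_noise_sd = 0.5,
                       pause_fraction = 0,
                       n_cells = 50L,
                       seed = 1L) {
  n_int <- duration * 60 / frame_interval
  if (abs(n_int - round(n_int)) > 1e-9) {
    stop2("duration / frame_interval must give an integer number of intervals")
  }
  n_int <- as.integer(round(n_int))
  if (n_int < 2L) stop2("need at least 2 frame intervals")
  if (!is_number(reversal_rate) || reversal_rate < 0) stop2("reversal_rate must be >= 0")
  if (reversal_rate > n_int - 1L) {
    stop2("reversal_rate exceeds the number of interior frame boundaries (",
          n_int - 1L, "); reversals cannot be placed")
  }
  if (reversal_rate > n_int / 2) {
    warning("mean inter-reversal time < 2 frames: reversals are undetectable ",
            "at this sampling rate", call. = FALSE)
  }
  if (!is_number(speed) || speed < 0) stop2("speed must be >= 0")
  if (!is_number(positional_noise_sd) || positional_noise_sd < 0) {
    stop2("positional_noise_sd must be >= 0")
  }
  if (!is_number(pause_fraction) || pause_fraction < 0 || pause_fraction > 1) {
    stop2("pause_fraction must be in [0, 1]")
  }
  if (!is_count(n_cells, 1)) stop2("n_cells must be a positive integer")
  structure(
    list(duration = duration, frame_interval = frame_interval,
         n_intervals = n_int, reversal_rate = reversal_rate, speed = speed,
         positional_noise_sd = positional_noise_sd,
         pause_fraction = pause_fraction, n_cells = as.integer(n_cells),
         seed = as.integer(seed)),
    class = "track_spec"
  )
}

#' Generate synthetic time-lapse trajectories with known reversal times
#'
#' @param spec a [track_spec()].
#' @return A data frame of class `pl_tracks` with columns `frame` (0-based),
#'   `cell_id`, `x`, `y`, `axis_angle_rad`, and attribute `truth`: a named
#'   list (by cell id) of true reversal frames — the 1-based displacement
#'   index at which the direction of movement flips.
#' @export
generate_trajectories <- function(spec) {
  if (!inherits(spec, "track_spec")) stop2("spec must be a track_spec")
  n_int <- spec$n_intervals
  with_seed(spec$seed, {
    out <- vector("list", spec$n_cells)
    truth <- vector("list", spec$n_cells)
    p_rev <- spec$reversal_rate / (n_int - 1L)
    for (k in seq_len(spec$n_cells)) {
      id <- sprintf("cell_%03d", k)
      theta <- stats::runif(1L, 0, 2 * pi)
      u <- c(cos(theta), sin(theta))
      # reversal at displacement t (t = 2..n_int) flips direction from t on
      flips <- which(stats::rbinom(n_int - 1L, 1L, p_rev) == 1L) + 1L
      dir0 <- sample(c(-1, 1), 1L)
      dirs <- dir0 * (-1)^cumsum(tabulate(flips, nbins = n_int))
      moving <- if (spec$pause_fraction > 0) {
        stats::rbinom(n_int, 1L, 1 - spec$pause_fraction)
      } else rep(1L, n_int)
      steps <- dirs * spec$speed * moving
      start <- stats::runif(2L, 0, 200)
      pos_x <- start[1L] + c(0, cumsum(steps * u[1L]))
      pos_y <- start[2L] + c(0, cumsum(steps * u[2L]))
      if (spec$positional_noise_sd > 0) {
        pos_x <- pos_x + stats::rnorm(n_int + 1L, sd = spec$positional_noise_sd)
        pos_y <- pos_y + stats::rnorm(n_int + 1L, sd = spec$positional_noise_sd)
      }
      out[[k]] <- data.frame(
        frame = 0:n_int, cell_id = id, x = pos_x, y = pos_y,
        axis_angle_rad = theta, stringsAsFactors = FALSE)
      truth[[k]] <- flips
      names(truth)[k] <- id
    }
    tracks <- do.call(rbind, out)
    rownames(tracks) <- NULL
    attr(tracks, "truth") <- truth
    attr(tracks, "frame_interval") <- spec$frame_interval
    class(tracks) <- c("pl_tracks", "data.frame")
    tracks
  })
}

#' Specification of a synthetic protein alignment
#'
#' Sequences are drawn column-wise i.i.d. from per-column amino-acid
#' frequency profiles, so per-column conservation (and hence the downstream
#' sequence-logo information content) is controlled exactly.
#'
#' @param n_sequences number of sequences.
#' @param column_profiles numeric matrix, one row per alignment column and 20
#'   columns named by [AA_ALPHABET_20], each row summing to 1 (tolerance
#'   1e-9). A single profile vector is accepted and recycled.
#' @param seed integer RNG seed.
#' @return Object of class `alignment_spec`.
#' @export
alignment_spec <- function(n_sequences, column_profiles, seed = 1L) {
  if (!is_count(n_sequences, 1)) stop2("n_sequences must be a positive integer")
  if (is.null(dim(column_profiles))) {
    column_profiles <- matrix(column_profiles, nrow = 1L,
                              dimnames = list(NULL, names(column_profiles)))
  }
  column_profiles <- as.matrix(column_profiles)
  if (ncol(column_profiles) != 20L) {
    stop2("column_profiles must have 20 columns (one per amino acid)")
  }
  if (is.null(colnames(column_profiles))) {
    colnames(column_profiles) <- AA_ALPHABET_20
  }
  if (!setequal(colnames(column_profiles), AA_ALPHABET_20)) {
    stop2("column_profiles columns must be the 20 canonical amino acids")
  }
  column_profiles <- column_profiles[, AA_ALPHABET_20, drop = FALSE]
  sums <- rowSums(column_profiles)
  if (any(abs(sums - 1) > 1e-9) || any(column_profiles < 0)) {
    stop2("each column profile must be a frequency vector summing to 1")
  }
  structure(
    list(n_sequences = as.integer(n_sequences),
         n_columns = nrow(column_profiles),
         column_profiles = column_profiles, seed = as.integer(seed)),
    class = "alignment_spec"
  )
}

#' Generate an alignment by column-wise sampling
#'
#' @param spec an [alignment_spec()].
#' @return A [Biostrings::AAStringSet] of `n_sequences` aligned sequences.
#' @export
generate_alignment <- function(spec) {
  if (!inherits(spec, "alignment_spec")) stop2("spec must be an alignment_spec")
  with_seed(spec$seed, {
    m <- matrix("", nrow = spec$n_sequences, ncol = spec$n_columns)
    for (j in seq_len(spec$n_columns)) {
      m[, j] <- sample(AA_ALPHABET_20, spec$n_sequences, replace = TRUE,
                       prob = spec$column_profiles[j, ])
    }
    seqs <- apply(m, 1L, paste0, collapse = "")
    names(seqs) <- sprintf("seq_%04d", seq_len(spec$n_sequences))
    Biostrings::AAStringSet(seqs)
  })
}

#' Default marker set for co-occurrence tables
#'
#' The polarity and motility markers whose joint phyletic distribution is
#' tabulated: the MglA GTPase, its GAP MglB, the two conserved RomR regions
#' (receiver domain and C-terminal domain), the Frz chemosensory system, the
#' gliding motility machinery (Glt), and type IV pili (T4P).
#' @export
DEFAULT_MARKERS <- c("MglA", "MglB", "RomR-REC", "RomR-C", "Frz", "Glt", "T4P")

#' Specification of a synthetic genome x marker presence/absence table
#'
#' @param pattern_counts named integer vector: names are pattern bit strings
#'   (one character, `0` or `1`, per marker), values are the number of
#'   genomes carrying that exact pattern (>= 1). May be empty.
#' @param markers ordered marker names; default [DEFAULT_MARKERS].
#' @param seed integer RNG seed (controls genome row shuffling).
#' @return Object of class `pattern_spec`.
#' @export
pattern_spec <- function(pattern_counts, markers = DEFAULT_MARKERS, seed = 1L) {
  if (anyDuplicated(markers)) stop2("duplicate marker names")
  if (length(pattern_counts) > 0L) {
    if (is.null(names(pattern_counts)) || any(names(pattern_counts) == "")) {
      stop2("pattern_counts must be named by pattern bit strings")
    }
    if (any(nchar(names(pattern_counts)) != length(markers)) ||
        any(!grepl("^[01]+$", names(pattern_counts)))) {
      stop2("each pattern must have one 0/1 bit per marker")
    }
    if (anyDuplicated(names(pattern_counts))) stop2("duplicate patterns")
    if (!all(vapply(pattern_counts, is_count, logical(1L), min = 1))) {
      stop2("pattern counts must be integers >= 1")
    }
  }
  structure(
    list(markers = as.character(markers),
         pattern_counts = pattern_counts, seed = as.integer(seed)),
    class = "pattern_spec"
  )
}

#' Generate a presence/absence table with planted pattern counts
#'
#' @param spec a [pattern_spec()].
#' @return A data frame (class `cooccurrence_table`): first column `genome`,
#'   one 0/1 integer column per marker, exactly the requested number of
#'   genome rows per pattern, row order shuffled by the seed.
#' @export
generate_presence_absence <- function(spec) {
  if (!inherits(spec, "pattern_spec")) stop2("spec must be a pattern_spec")
  m <- length(spec$markers)
  patterns <- rep(names(spec$pattern_counts),
                  times = as.integer(spec$pattern_counts))
  n <- length(patterns)
  bits <- if (n > 0L) {
    t(vapply(strsplit(patterns, ""), function(b) as.integer(b), integer(m)))
  } else {
    matrix(integer(0), nrow = 0L, ncol = m)
  }
  tab <- data.frame(genome = sprintf("genome_%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) tab[[spec$markers[j]]] <- bits[, j]
  if (n > 1L) {
    tab <- with_seed(spec$seed, tab[sample.int(n), , drop = FALSE])
    rownames(tab) <- NULL
  }
  class(tab) <- c("cooccurrence_table", "data.frame")
  tab
}
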