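#' Localization pattern levels
#'
#' Ordered set of localization classes assigned by [classify_localization()]:
#' a single polar cluster (`unipolar`), two clusters of clearly unequal
#' intensity (`bipolar_asymmetric`), two clusters of comparable intensity
#' (`bipolar_symmetric`), or no polar cluster at all (`diffuse`).
#'
#' @export
PATTERN_LEVELS <- c("unipolar", "bipolar_asymmetric", "bipolar_symmetric",
                    "diffuse")

as_pixel_set <- function(px, name) {
  if (is.null(px)) stop2("region '", name, "' is missing")
  px <- as.matrix(px)
  if (ncol(px) != 2L) stop2("region '", name, "' must be a 2-column (row, col) matrix")
  storage.mode(px) <- "integer"
  colnames(px) <- c("row", "col")
  if (anyNA(px)) stop2("region '", name, "' contains NA coordinates")
  px
}

px_linear <- function(px, dim) {
  (px[, "col"] - 1L) * dim[1L] + px[, "row"]
}

#' Construct a single-cell fluorescence image with measurement regions
#'
#' Bundles a 2D intensity field (photons) with the cell mask and the three
#' measurement regions used for polar cluster quantification: one pixel set
#' per pole and one cytoplasmic reference region of identical pixel count,
#' mirroring the practice of measuring the integrated intensity of each polar
#' cluster and of a similar (equal-area) cytoplasmic region.
#'
#' @param intensity numeric matrix of non-negative pixel intensities
#'   (photon counts).
#' @param cell_mask logical matrix, same dimension, `TRUE` inside the cell.
#' @param pole_regions list of two integer matrices with columns `row`, `col`
#'   (1-based pixel coordinates), one per pole. Must be disjoint, inside the
#'   mask, and of equal pixel count.
#' @param cyto_region integer matrix of pixel coordinates of the cytoplasmic
#'   reference region; its pixel count must equal that of each pole region.
#'
#' @return An object of class `cell_image`.
#' @seealso [measure_polar_intensity()], [generate_cell_image()]
#' @export
cell_image <- function(intensity, cell_mask, pole_regions, cyto_region) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity) || anyNA(intensity)) {
    stop2("intensity must be a numeric matrix without NA")
  }
  if (any(intensity < 0)) stop2("intensity must be non-negative")
  if (!is.logical(cell_mask)) cell_mask <- as.matrix(cell_mask) > 0
  if (!identical(dim(intensity), dim(cell_mask))) {
    stop2("intensity and cell_mask dimensions differ")
  }
  if (length(pole_regions) != 2L) stop2("pole_regions must contain exactly two pixel sets")
  p1 <- as_pixel_set(pole_regions[[1L]], "pole1")
  p2 <- as_pixel_set(pole_regions[[2L]], "pole2")
  cy <- as_pixel_set(cyto_region, "cyto")
  d <- dim(intensity)
  for (r in list(p1 = p1, p2 = p2, cyto = cy)) {
    if (any(r[, "row"] < 1L | r[, "row"] > d[1L] | r[, "col"] < 1L | r[, "col"] > d[2L])) {
      stop2("region coordinates fall outside the image")
    }
  }
  i1 <- px_linear(p1, d); i2 <- px_linear(p2, d); ic <- px_linear(cy, d)
  if (!all(cell_mask[i1]) || !all(cell_mask[i2]) || !all(cell_mask[ic])) {
    stop2("all measurement regions must lie inside the cell mask")
  }
  if (length(intersect(i1, i2)) > 0L) stop2("pole regions overlap")
  structure(
    list(intensity = intensity, cell_mask = cell_mask,
         pole_regions = list(p1, p2), cyto_region = cy),
    class = "cell_image"
  )
}

#' @export
print.cell_image <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<cell_image> %d x %d px, cell area %d px, pole regions %d + %d px, cyto %d px\n",
    d[1L], d[2L], sum(x$cell_mask),
    nrow(x$pole_regions[[1L]]), nrow(x$pole_regions[[2L]]),
    nrow(x$cyto_region)))
  invisible(x)
}

#' Background-corrected integrated polar intensities
#'
#' Integrates the pixel intensities over each pole region and subtracts the
#' integrated intensity of the equal-area cytoplasmic reference region, so
#' each corrected value is the cluster signal above the local cytoplasmic
#' background. Corrected intensities can be negative when a pole is dimmer
#' than the cytoplasm.
#'
#' @param img a [cell_image()].
#' @return Numeric vector of length two: corrected integrated intensity of
#'   pole 1 and pole 2, in photons.
#' @export
measure_polar_intensity <- function(img) {
  if (!inherits(img, "cell_image")) stop2("img must be a cell_image")
  d <- dim(img$intensity)
  n1 <- nrow(img$pole_regions[[1L]])
  n2 <- nrow(img$pole_regions[[2L]])
  nc <- nrow(img$cyto_region)
  if (n1 != nc || n2 != nc) {
    stop2(sprintf(
      "region pixel counts differ (pole1 = %d, pole2 = %d, cyto = %d); %s",
      n1, n2, nc,
      "the cytoplasmic reference must match each pole region in area"))
  }
  cyto_sum <- sum(img$intensity[px_linear(img$cyto_region, d)])
  vapply(img$pole_regions, function(p) {
    sum(img$intensity[px_linear(p, d)]) - cyto_sum
  }, numeric(1L))
}

#' Classify a localization pattern from corrected polar intensities
#'
#' Applies the ratio-based decision rule for polar fluorescence signals. A
#' cluster is considered present at a pole when its background-corrected
#' intensity exceeds `presence_floor`. With no cluster present the pattern is
#' `diffuse`; with a cluster at exactly one pole it is `unipolar`. With
#' clusters at both poles, the ratio r of the brighter to the dimmer
#' corrected intensity is rounded to one decimal (halves away from zero) and
#' mapped: r <= 2.0 is `bipolar_symmetric`, 2.1 <= r <= 10.0 is
#' `bipolar_asymmetric`, and r >= 10.1 is `unipolar`. On the one-decimal
#' grid these three intervals tile `[1.0, Inf)` with no gaps.
#'
#' @param corrected_I numeric vector of two corrected integrated pole
#'   intensities (photons; may be negative after background correction).
#' @param presence_floor non-negative threshold (photons) above which a
#'   corrected polar intensity counts as a cluster. Default 0; a common
#'   alternative is a small multiple of the cytoplasmic noise scale.
#' @return Length-one character: one of [PATTERN_LEVELS].
#' @export
classify_localization <- function(corrected_I, presence_floor = 0) {
  if (length(corrected_I) != 2L || !is.numeric(corrected_I)) {
    stop2("corrected_I must be a numeric vector of length 2")
  }
  if (anyNA(corrected_I) || any(!is.finite(corrected_I))) {
    stop2("corrected_I must be finite (no NA/NaN)")
  }
  if (!is_number(presence_floor) || presence_floor < 0) {
    stop2("presence_floor must be a single non-negative number")
  }
  present <- corrected_I > presence_floor
  if (!any(present)) return("diffuse")
  if (sum(present) == 1L) return("unipolar")
  r <- round_half_up(max(corrected_I) / min(corrected_I), 1L)
  if (r <= 2.0) return("bipolar_symmetric")
  if (r <= 10.0) return("bipolar_asymmetric")
  "unipolar"
}

#' Full polar measurement of one cell
#'
#' Convenience wrapper: measures corrected intensities, computes the
#' brighter/dimmer ratio (when both poles carry a cluster), and assigns the
#' localization class.
#'
#' @inheritParams measure_polar_intensity
#' @inheritParams classify_localization
#' @return An object of class `polar_measurement`: list with `corrected_I`,
#'   `ratio` (NA unless both poles exceed the floor), and `pattern`.
#' @export
polar_measurement <- function(img, presence_floor = 0) {
  ci <- measure_polar_intensity(img)
  pattern <- classify_localization(ci, presence_floor)
  ratio <- if (all(ci > presence_floor)) {
    round_half_up(max(ci) / min(ci), 1L)
  } else {
    NA_real_
  }
  structure(list(corrected_I = ci, ratio = ratio, pattern = pattern),
            class = "polar_measurement")
}

#' @export
print.polar_measurement <- function(x, ...) {
  cat(sprintf("<polar_measurement> I = (%g, %g), ratio = %s, pattern = %s\n",
              x$corrected_I[1L], x$corrected_I[2L],
              ifelse(is.na(x$ratio), "NA", format(x$ratio)), x$pattern))
  invisible(x)
}

#' Summarize localization patterns across cells
#'
#' Tabulates localization classes over a population of cells and reports the
#' percentage of cells per pattern, the per-strain summary typically shown
#' next to representative micrographs (n of a few hundred cells).
#'
#' @param measurements a character/factor vector of patterns, or a list of
#'   `polar_measurement` objects.
#' @return Object of class `pattern_summary`: list with `counts`, `percent`
#'   (each named by [PATTERN_LEVELS]) and `n_cells`.
#' @export
summarize_patterns <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements)) {
    measurements <- vapply(measurements, function(m) {
      if (inherits(m, "polar_measurement")) m$pattern else as.character(m)
    }, character(1L))
  }
  patterns <- as.character(measurements)
  if (length(patterns) == 0L) stop2("no measurements supplied")
  bad <- setdiff(unique(patterns), PATTERN_LEVELS)
  if (length(bad) > 0L) stop2("unknown pattern(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(patterns, levels = PATTERN_LEVELS))
  counts <- stats::setNames(as.integer(counts), PATTERN_LEVELS)
  n <- length(patterns)
  structure(list(counts = counts, percent = 100 * counts / n, n_cells = n),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("<pattern_summary> n = %d cells\n", x$n_cells))
  for (p in PATTERN_LEVELS) {
    cat(sprintf("  %-18s %5d  (%.1f%%)\n", p, x$counts[[p]], x$percent[[p]]))
  }
  invisible(x)
}
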