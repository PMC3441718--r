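# Colony-expansion quantification: the increase in colony diameter over an
# incubation period, measured as chords through the colony centroid.

#' Construct a colony outline
#'
#' A colony at one time point, either as a binary mask (logical/0-1 matrix)
#' or as a closed boundary polygon (data frame / matrix with columns `x`,
#' `y` in pixel coordinates, vertices in order).
#'
#' @param mask logical or 0/1 matrix, `TRUE`/1 inside the colony.
#' @param boundary boundary polygon; ignored when `mask` is given.
#' @param pixel_size physical pixel size, mm per pixel.
#' @return Object of class `colony_outline`.
#' @export
colony_outline <- function(mask = NULL, boundary = NULL, pixel_size = 0.02) {
  if (!is_number(pixel_size) || pixel_size <= 0) {
    stop2("pixel_size must be positive (mm/pixel)")
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask) > 0
    if (!any(mask)) stop2("colony mask is empty")
    structure(list(kind = "mask", mask = mask, pixel_size = pixel_size),
              class = "colony_outline")
  } else if (!is.null(boundary)) {
    b <- as.matrix(as.data.frame(boundary)[, c("x", "y")])
    if (nrow(b) < 3L) stop2("boundary polygon needs at least 3 vertices")
    structure(list(kind = "boundary", boundary = b, pixel_size = pixel_size),
              class = "colony_outline")
  } else {
    stop2("supply either a mask or a boundary polygon")
  }
}

outline_centroid <- function(outline) {
  if (outline$kind == "mask") {
    px <- which(outline$mask, arr.ind = TRUE)
    c(x = mean(px[, 2L]), y = mean(px[, 1L]))
  } else {
    # area centroid of the closed polygon (shoelace)
    b <- outline$boundary
    x <- b[, 1L]; y <- b[, 2L]
    x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
    cr <- x * y2 - x2 * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-12) return(c(x = mean(x), y = mean(y)))
    c(x = sum((x + x2) * cr) / (6 * a), y = sum((y + y2) * cr) / (6 * a))
  }
}

# Extent of the colony along direction `angle` (radians) on the line through
# the centroid: the calliper-style chord length in pixels.
chord_length <- function(outline, angle) {
  ctr <- outline_centroid(outline)
  u <- c(cos(angle), sin(angle))
  if (outline$kind == "mask") {
    d <- dim(outline$mask)
    step <- 0.05  # sub-pixel sampling; each sample tests its nearest pixel
    tmax <- sqrt(sum(d^2))
    t <- seq(-tmax, tmax, by = step)
    xs <- ctr["x"] + t * u[1L]
    ys <- ctr["y"] + t * u[2L]
    i <- round(ys); j <- round(xs)
    ok <- i >= 1 & i <= d[1L] & j >= 1 & j <= d[2L]
    inside <- rep(FALSE, length(t))
    inside[ok] <- outline$mask[cbind(i[ok], j[ok])]
    if (!any(inside)) return(0)
    diff(range(t[inside])) + step
  } else {
    b <- outline$boundary
    n <- nrow(b)
    ts <- numeric(0)
    for (k in seq_len(n)) {
      p <- b[k, ]; q <- b[if (k == n) 1L else k + 1L, ]
      e <- q - p
      den <- u[1L] * (-e[2L]) - u[2L] * (-e[1L])
      if (abs(den) < 1e-12) next
      rhs <- p - c(ctr["x"], ctr["y"])
      tt <- (rhs[1L] * (-e[2L]) - rhs[2L] * (-e[1L])) / den
      ss <- (u[1L] * rhs[2L] - u[2L] * rhs[1L]) / den
      if (ss >= 0 && ss < 1) ts <- c(ts, tt)
    }
    if (length(ts) < 2L) return(0)
    diff(range(ts))
  }
}

#' Colony diameter from two chord measurements
#'
#' Measures the colony diameter as the mean of two chord lengths through the
#' colony centroid at the given angles, converted to mm — a reproducible
#' stand-in for measuring each colony "at two positions" with callipers.
#'
#' @param outline a [colony_outline()].
#' @param angles two measurement angles in degrees (default 0 and 90:
#'   orthogonal chords).
#' @return Diameter in mm.
#' @export
colony_diameter <- function(outline, angles = c(0, 90)) {
  if (!inherits(outline, "colony_outline")) stop2("outline must be a colony_outline")
  if (length(angles) != 2L) stop2("supply exactly two measurement angles")
  chords <- vapply(angles * pi / 180, function(a) chord_length(outline, a),
                   numeric(1L))
  mean(chords) * outline$pixel_size
}

#' Colony expansion across replicate colonies
#'
#' Per-colony expansion is the diameter at the later time point minus the
#' diameter at time zero; the assay reports the mean and sample (n - 1)
#' standard deviation across replicate colonies (conventionally three per
#' strain), in mm.
#'
#' @param replicates list of replicate pairs; each element is a list with
#'   components `t0` and `t24`, both [colony_outline()] objects sharing the
#'   same `pixel_size`.
#' @param angles measurement angles passed to [colony_diameter()].
#' @return List with `mean_mm`, `sd_mm`, `n`, and per-replicate
#'   `increase_mm`. A single replicate reports `sd_mm = 0` with a warning;
#'   negative increases (shrinkage) are allowed but reported via a message.
#' @export
colony_expansion <- function(replicates, angles = c(0, 90)) {
  if (length(replicates) < 1L) stop2("need at least one replicate pair")
  inc <- vapply(replicates, function(pair) {
    if (!all(c("t0", "t24") %in% names(pair))) {
      stop2("each replicate must have elements t0 and t24")
    }
    if (!isTRUE(all.equal(pair$t0$pixel_size, pair$t24$pixel_size))) {
      stop2("t0 and t24 of a replicate must share pixel_size")
    }
    colony_diameter(pair$t24, angles) - colony_diameter(pair$t0, angles)
  }, numeric(1L))
  if (any(inc < 0)) {
    message(sum(inc < 0), " replicate(s) shrank (negative increase)")
  }
  n <- length(inc)
  sd_mm <- if (n == 1L) {
    warning("single replicate: standard deviation undefined, reported as 0",
            call. = FALSE)
    0
  } else {
    stats::sd(inc)
  }
  list(mean_mm = mean(inc), sd_mm = sd_mm, n = n, increase_mm = inc)
}

#' Synthetic disc colony mask
#'
#' Helper for building test colonies: a filled disc of the given radius
#' (pixels) centred in a square image.
#'
#' @param radius disc radius in pixels.
#' @param margin margin around the disc in pixels.
#' @param centre optional `(x, y)` centre; default image centre.
#' @return Logical matrix.
#' @export
disc_mask <- function(radius, margin = 5, centre = NULL) {
  size <- ceiling(2 * (radius + margin))
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  cols <- matrix(rep(seq_len(size), each = size), nrow = size)
  rows <- matrix(rep(seq_len(size), times = size), nrow = size)
  (cols - centre[1L])^2 + (rows - centre[2L])^2 <= radius^2
}

#' Synthetic ellipse colony mask
#'
#' @param a,b semi-axes in pixels along x (columns) and y (rows).
#' @param margin margin in pixels.
#' @return Logical matrix.
#' @export
ellipse_mask <- function(a, b, margin = 5) {
  size <- ceiling(2 * (max(a, b) + margin))
  ctr <- (size + 1) / 2
  cols <- matrix(rep(seq_len(size), each = size), nrow = size)
  rows <- matrix(rep(seq_len(size), times = size), nrow = size)
  ((cols - ctr) / a)^2 + ((rows - ctr) / b)^2 <= 1
}
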