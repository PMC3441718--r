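# Readers and writers for the formats shared by all modules.
#
# Conventions: images are single-channel 16-bit TIFF; region and track CSVs
# use 0-based pixel/frame coordinates; domain-hit TSVs use 1-based inclusive
# residue coordinates (the common domain-table convention). CSV/TSV files
# are comma/tab separated, UTF-8, '.' decimal, header row mandatory.

MAX_TIFF_VALUE <- 65535L

#' Write a cell image and its measurement regions to disk
#'
#' The intensity field is written as a single-channel 16-bit TIFF (photon
#' counts, clamped to `[0, 65535]`) and the mask plus measurement regions as
#' a CSV of 0-based pixel coordinates with a `region` label column
#' (`cell_mask`, `pole1`, `pole2`, `cyto`).
#'
#' @param img a [cell_image()].
#' @param image_path output TIFF path.
#' @param regions_path output CSV path.
#' @return Invisibly, the two paths.
#' @export
write_cell_image <- function(img, image_path, regions_path) {
  if (!inherits(img, "cell_image")) stop2("img must be a cell_image")
  if (any(img$intensity > MAX_TIFF_VALUE)) {
    stop2("intensity exceeds the 16-bit TIFF range")
  }
  tiff::writeTIFF(img$intensity / MAX_TIFF_VALUE, image_path,
                  bits.per.sample = 16L)
  mask_px <- which(img$cell_mask, arr.ind = TRUE)
  rows <- rbind(
    data.frame(region = "cell_mask", row = mask_px[, 1L] - 1L,
               col = mask_px[, 2L] - 1L),
    data.frame(region = "pole1", row = img$pole_regions[[1L]][, "row"] - 1L,
               col = img$pole_regions[[1L]][, "col"] - 1L),
    data.frame(region = "pole2", row = img$pole_regions[[2L]][, "row"] - 1L,
               col = img$pole_regions[[2L]][, "col"] - 1L),
    data.frame(region = "cyto", row = img$cyto_region[, "row"] - 1L,
               col = img$cyto_region[, "col"] - 1L))
  utils::write.csv(rows, regions_path, row.names = FALSE, quote = FALSE)
  invisible(c(image = image_path, regions = regions_path))
}

#' Read a cell image and its measurement regions
#'
#' @param image_path single-channel TIFF of photon counts (16-bit).
#' @param regions_path region CSV as written by [write_cell_image()]
#'   (0-based `row`/`col` coordinates).
#' @return A [cell_image()].
#' @export
read_cell_image <- function(image_path, regions_path) {
  if (!file.exists(image_path)) stop2("image file not found: ", image_path)
  if (!file.exists(regions_path)) stop2("regions file not found: ", regions_path)
  raw <- tiff::readTIFF(image_path, as.is = TRUE)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  regions <- utils::read.csv(regions_path, stringsAsFactors = FALSE)
  need <- c("region", "row", "col")
  if (!all(need %in% names(regions))) {
    stop2(regions_path, ": expected columns ", paste(need, collapse = ", "))
  }
  pick <- function(label) {
    r <- regions[regions$region == label, , drop = FALSE]
    if (nrow(r) == 0L) stop2(regions_path, ": no '", label, "' region")
    cbind(row = r$row + 1L, col = r$col + 1L)
  }
  mask_px <- pick("cell_mask")
  mask <- matrix(FALSE, nrow = nrow(raw), ncol = ncol(raw))
  mask[mask_px] <- TRUE
  cell_image(raw, mask, list(pick("pole1"), pick("pole2")), pick("cyto"))
}

#' Write tracks to CSV
#'
#' Columns `frame` (0-based), `cell_id`, `x`, `y`, `axis_angle_rad`.
#'
#' @param tracks track data frame (e.g. from [generate_trajectories()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("frame", "cell_id", "x", "y", "axis_angle_rad")
  if (!all(cols %in% names(tracks))) {
    stop2("tracks needs columns ", paste(cols, collapse = ", "))
  }
  df <- as.data.frame(tracks)[, cols]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path CSV with header `frame,cell_id,x,y,axis_angle_rad`.
#' @return Track data frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop2("track file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("frame", "cell_id", "x", "y", "axis_angle_rad")
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop2(path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  df
}

#' Write / read a presence/absence table (TSV)
#'
#' First column `genome`, remaining columns marker names, values 0/1.
#'
#' @param tab co-occurrence table.
#' @param path TSV path.
#' @return Invisibly `path` (write); the table (read).
#' @export
write_presence_absence <- function(tab, path) {
  check_cooccurrence_table(tab)
  utils::write.table(as.data.frame(tab), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_presence_absence
#' @export
read_presence_absence <- function(path) {
  if (!file.exists(path)) stop2("presence/absence file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "genome") {
    stop2(path, ": first column must be 'genome'")
  }
  check_cooccurrence_table(tab)
  class(tab) <- c("cooccurrence_table", "data.frame")
  tab
}

#' Read a domain-hit table (TSV)
#'
#' Columns `protein`, `domain`, `start`, `end` (1-based inclusive residue
#' coordinates), `score` (bits).
#'
#' @param path TSV path.
#' @return Data frame of domain hits.
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop2("domain-hit file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "domain", "start", "end", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop2(path, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  bad <- which(df$start > df$end)
  if (length(bad) > 0L) {
    stop2(path, ": start > end on data line ", bad[1L])
  }
  df
}

#' Write / read an aligned FASTA file
#'
#' Thin wrappers over Biostrings; alignments are equal-length sequences with
#' `-` gaps.
#'
#' @param aln [Biostrings::AAStringSet] or named character vector.
#' @param path FASTA path.
#' @return Invisibly `path` (write); an `AAStringSet` (read).
#' @export
write_alignment <- function(aln, path) {
  if (!inherits(aln, "XStringSet")) aln <- Biostrings::AAStringSet(aln)
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop2("alignment file not found: ", path)
  aln <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aln))) > 1L) {
    stop2(path, ": sequences are not aligned (unequal lengths)")
  }
  aln
}

#' Read a residue-to-class map (TSV)
#'
#' Two columns, `residue` and `class`; must cover all 20 canonical amino
#' acids.
#'
#' @param path TSV path.
#' @return Named character vector usable as `class_map` in
#'   [composition_by_class()].
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop2("class-map file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "class") %in% names(df))) {
    stop2(path, ": expected columns residue, class")
  }
  stats::setNames(df$class, toupper(df$residue))
}

#' Write run metadata
#'
#' Every pipeline output directory gets a metadata JSON recording the
#' package version, seed, parameters, and MD5 digests of the input files, so
#' a run is reproducible from its metadata alone.
#'
#' @param path output JSON path.
#' @param seed integer seed used for the run.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths (digested).
#' @return Invisibly, `path`.
#' @export
write_run_metadata <- function(path, seed, params = list(),
                               inputs = character(0)) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character(0))
  }
  meta <- list(
    package = "polarlapse",
    version = as.character(utils::packageVersion("polarlapse")),
    seed = seed,
    params = params,
    input_md5 = digests)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
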