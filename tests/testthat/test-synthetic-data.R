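test_that("noiseless cell images carry exactly the planted pole intensities", {
  cases <- list(c(0, 0), c(500, 100), c(1, 0), c(12345, 17))
  for (planted in cases) {
    g <- generate_cell_image(image_spec(pole_intensities = planted,
                                        noise_model = "none"))
    expect_identical(measure_polar_intensity(g$image), as.numeric(planted))
    expect_identical(g$truth$corrected_I, as.numeric(planted))
  }
})

test_that("pole regions are disjoint, in-mask, and area-matched to the cytoplasmic region", {
  g <- generate_cell_image(image_spec())
  img <- g$image
  n1 <- nrow(img$pole_regions[[1]])
  expect_identical(n1, nrow(img$pole_regions[[2]]))
  expect_identical(n1, nrow(img$cyto_region))
  d <- dim(img$intensity)
  lin <- function(px) (px[, "col"] - 1L) * d[1] + px[, "row"]
  expect_length(intersect(lin(img$pole_regions[[1]]),
                          lin(img$pole_regions[[2]])), 0)
  expect_length(intersect(lin(img$cyto_region),
                          c(lin(img$pole_regions[[1]]),
                            lin(img$pole_regions[[2]]))), 0)
  expect_true(all(img$cell_mask[img$pole_regions[[1]]]))
  expect_true(all(img$cell_mask[img$cyto_region]))
})

test_that("invalid image specs are rejected", {
  expect_error(image_spec(cell_length = 200, image_size = c(60, 120)),
               "margin")
  expect_error(image_spec(pole_intensities = c(-5, 10)), "non-negative")
  # poles forced to overlap: short cell, huge pole radius
  expect_error(
    generate_cell_image(image_spec(cell_length = 20, cell_width = 10,
                                   pole_region_radius = 12)),
    "overlap")
})

test_that("poisson-noise images recover the planted ratio on average", {
  reps <- 200
  ratios <- vapply(seq_len(reps), function(k) {
    g <- generate_cell_image(image_spec(pole_intensities = c(500, 100),
                                        noise_model = "poisson", seed = k))
    ci <- measure_polar_intensity(g$image)
    max(ci) / min(ci)
  }, numeric(1))
  # Monte-Carlo check: mean measured ratio within 3 SE of the planted 5.0
  expect_lt(abs(mean(ratios) - 5.0), 3 * stats::sd(ratios) / sqrt(reps))
})

test_that("generators are deterministic given spec and seed", {
  s <- image_spec(noise_model = "poisson", seed = 11)
  expect_identical(generate_cell_image(s), generate_cell_image(s))
  ts <- track_spec(reversal_rate = 3, n_cells = 10, seed = 5)
  expect_identical(generate_trajectories(ts), generate_trajectories(ts))
  as <- alignment_spec(20, rep(1 / 20, 20), seed = 3)
  expect_identical(generate_alignment(as), generate_alignment(as))
  ps <- pattern_spec(c("101" = 3, "010" = 2), markers = c("A", "B", "C"),
                     seed = 2)
  expect_identical(generate_presence_absence(ps),
                   generate_presence_absence(ps))
})

test_that("track layout matches the imaging protocol: 30-s frames for 15 min", {
  tr <- generate_trajectories(track_spec(duration = 15, frame_interval = 30,
                                         n_cells = 2))
  one <- tr[tr$cell_id == "cell_001", ]
  expect_identical(nrow(one), 31L)            # 30 intervals, 31 frames
  expect_identical(one$frame, 0:30)
  expect_error(track_spec(duration = 15, frame_interval = 7),
               "integer number of intervals")
})

test_that("rate-0 noiseless tracks are strictly monotone along their axis", {
  tr <- generate_trajectories(track_spec(reversal_rate = 0,
                                         positional_noise_sd = 0,
                                         n_cells = 20, seed = 4))
  expect_true(all(lengths(attr(tr, "truth")) == 0))
  for (id in unique(tr$cell_id)) {
    one <- tr[tr$cell_id == id, ]
    proj <- diff(one$x) * cos(one$axis_angle_rad[1]) +
      diff(one$y) * sin(one$axis_angle_rad[1])
    expect_true(all(proj > 0) || all(proj < 0))
  }
})

test_that("true reversal counts follow the requested Poisson mean", {
  tr <- generate_trajectories(track_spec(reversal_rate = 4, n_cells = 500,
                                         seed = 21))
  m <- mean(lengths(attr(tr, "truth")))
  expect_lt(abs(m - 4), 3 * sqrt(4 / 500))
})

test_that("sign changes of the noiseless displacement equal planted reversals", {
  tr <- generate_trajectories(track_spec(reversal_rate = 5, n_cells = 50,
                                         positional_noise_sd = 0, seed = 13))
  truth <- attr(tr, "truth")
  for (id in unique(tr$cell_id)) {
    one <- tr[tr$cell_id == id, ]
    proj <- diff(one$x) * cos(one$axis_angle_rad[1]) +
      diff(one$y) * sin(one$axis_angle_rad[1])
    sign_changes <- sum(diff(sign(proj)) != 0)
    expect_identical(sign_changes, length(truth[[id]]))
  }
})

test_that("excessive reversal rates warn or fail", {
  expect_warning(track_spec(reversal_rate = 16), "undetectable")
  expect_error(suppressWarnings(track_spec(reversal_rate = 40)),
               "cannot be placed")
})

test_that("alignment columns follow their profiles", {
  # point mass: whole column is that residue
  pm <- rep(0, 20); names(pm) <- AA_ALPHABET_20; pm["W"] <- 1
  aln <- generate_alignment(alignment_spec(50, pm, seed = 1))
  expect_true(all(substr(as.character(aln), 1, 1) == "W"))
  # uniform profile at n = 10000: frequencies within 3 binomial SE of 1/20
  aln2 <- generate_alignment(alignment_spec(10000, rep(1 / 20, 20), seed = 2))
  col <- substr(as.character(aln2), 1, 1)
  freqs <- table(factor(col, levels = AA_ALPHABET_20)) / 10000
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_true(all(abs(freqs - 0.05) < 3 * se))
})

test_that("presence/absence generator plants exact pattern counts", {
  counts <- c("1110000" = 26, "1100000" = 10, "0000001" = 3)
  tab <- generate_presence_absence(pattern_spec(counts, seed = 9))
  expect_identical(nrow(tab), 39L)
  got <- tabulate_cooccurrence(tab)
  expect_identical(stats::setNames(got$count, got$pattern)[names(counts)],
                   stats::setNames(as.integer(counts), names(counts)))
  # empty pattern map gives an empty table
  empty <- generate_presence_absence(pattern_spec(integer(0)))
  expect_identical(nrow(empty), 0L)
  expect_error(pattern_spec(c("11" = 2), markers = c("A", "A")), "duplicate")
})
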