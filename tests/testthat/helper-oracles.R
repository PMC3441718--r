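# Independent oracles used across the suite. These deliberately use the
# dumbest possible formulation (explicit loops, manual interpolation) so
# they share no code path with the implementation they check.

# Brute-force region summation: loop over every pixel of the image and add
# it to whichever region it belongs to.
oracle_polar_intensity <- function(img) {
  d <- dim(img$intensity)
  in_region <- function(region, i, j) {
    any(region[, "row"] == i & region[, "col"] == j)
  }
  sums <- c(pole1 = 0, pole2 = 0, cyto = 0)
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      v <- img$intensity[i, j]
      if (in_region(img$pole_regions[[1L]], i, j)) sums["pole1"] <- sums["pole1"] + v
      if (in_region(img$pole_regions[[2L]], i, j)) sums["pole2"] <- sums["pole2"] + v
      if (in_region(img$cyto_region, i, j)) sums["cyto"] <- sums["cyto"] + v
    }
  }
  c(sums[["pole1"]] - sums[["cyto"]], sums[["pole2"]] - sums[["cyto"]])
}

# Manual sort-and-interpolate percentile (type-7 definition written out).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Independent replay of the greedy overlap rule: explicit while-loop over a
# shrinking candidate list.
oracle_greedy_architecture <- function(hits) {
  accepted <- hits[0, , drop = FALSE]
  remaining <- hits
  while (nrow(remaining) > 0L) {
    ord <- order(-remaining$score, remaining$start, remaining$domain)
    best <- remaining[ord[1L], , drop = FALSE]
    accepted <- rbind(accepted, best)
    overlaps <- remaining$start <= best$end & remaining$end >= best$start
    remaining <- remaining[!overlaps, , drop = FALSE]
  }
  accepted <- accepted[order(accepted$start, accepted$end, accepted$domain), ,
                       drop = FALSE]
  rownames(accepted) <- NULL
  accepted
}

random_hits <- function(n, protein = "prot1") {
  start <- sample(1:300, n, replace = TRUE)
  len <- sample(5:80, n, replace = TRUE)
  data.frame(
    protein = protein,
    domain = sample(paste0("dom", 1:6), n, replace = TRUE),
    start = start, end = start + len,
    score = round(stats::runif(n, 5, 100), 1),
    stringsAsFactors = FALSE)
}

random_pattern_spec <- function(n_markers = 4, max_patterns = 6, seed = 1) {
  markers <- paste0("M", seq_len(n_markers))
  all_patterns <- apply(
    expand.grid(rep(list(0:1), n_markers)), 1L, paste0, collapse = "")
  k <- sample(seq_len(min(max_patterns, length(all_patterns))), 1L)
  chosen <- sample(all_patterns, k)
  counts <- stats::setNames(sample(1:8, k, replace = TRUE), chosen)
  pattern_spec(counts, markers = markers, seed = seed)
}
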