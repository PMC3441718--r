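test_that("logo information content matches its closed forms", {
  # invariant column, correction off: R = log2(20)
  inv <- column_information(rep("W", 50), correct_small_sample = FALSE)
  expect_equal(inv$R_bits, log2(20))
  expect_equal(unname(inv$heights["W"]), log2(20))
  expect_equal(sum(inv$heights), inv$R_bits)
  # uniform column, correction off: R = 0
  unif <- column_information(AA_ALPHABET_20, correct_small_sample = FALSE)
  expect_equal(unif$R_bits, 0)
  # n = 20 identical residues, correction on: R = log2(20) - 19/(40 ln 2)
  corr <- column_information(rep("E", 20), correct_small_sample = TRUE)
  expect_equal(corr$R_bits, log2(20) - 19 / (40 * log(2)))
  expect_equal(corr$e_n, 19 / (2 * log(2) * 20))
})

test_that("R decreases monotonically from point mass toward uniform", {
  # nested mixtures: (1 - w) * point mass on W + w * uniform
  n <- 2000
  R_vals <- vapply(seq(0, 1, by = 0.1), function(w) {
    n_unif <- round(w * n)
    col <- c(rep(AA_ALPHABET_20, length.out = n_unif),
             rep("W", n - n_unif))
    column_information(col, correct_small_sample = FALSE)$R_bits
  }, numeric(1))
  expect_true(all(diff(R_vals) <= 1e-12))
})

test_that("gaps are excluded from n; all-gap columns are flagged", {
  cp <- column_information(c("W", "W", "-", ".", "W"))
  expect_identical(cp$n, 3L)
  allgap <- column_information(c("-", "-", "."))
  expect_true(allgap$all_gap)
  expect_true(is.na(allgap$R_bits))
  expect_error(column_information(c("W", "X")), "non-canonical")
  expect_identical(column_information(c("W", "X", "W"), ambiguous = "gap")$n,
                   2L)
})

test_that("alignment logos peak at planted invariant columns", {
  # profile mimicking a conserved C-terminal domain: invariant Trp and Pro
  # columns, one Glu-rich column, one near-uniform column
  point <- function(res) {
    p <- rep(0, 20); names(p) <- AA_ALPHABET_20; p[res] <- 1; p
  }
  rich <- function(res, f) {
    p <- rep((1 - f) / 19, 20); names(p) <- AA_ALPHABET_20; p[res] <- f; p
  }
  profiles <- rbind(point("W"), rich("E", 0.7), rep(1 / 20, 20), point("P"))
  aln <- generate_alignment(alignment_spec(500, profiles, seed = 6))
  logo <- alignment_logo(aln, correct_small_sample = FALSE)
  expect_identical(order(logo$R_bits, decreasing = TRUE)[1:2] %in% c(1L, 4L),
                   c(TRUE, TRUE))
  expect_gt(logo$R_bits[2], logo$R_bits[3])
  expect_true(all(logo$R_bits >= 0 & logo$R_bits <= log2(20)))
})

test_that("composition by physicochemical class matches hand counts", {
  expect_equal(
    unname(composition_by_class("PPPP")$fractions["special"]), 1)
  de_kr <- composition_by_class("DEKR")
  expect_equal(unname(de_kr$fractions["acidic"]), 0.5)
  expect_equal(unname(de_kr$fractions["basic"]), 0.5)
  expect_equal(sum(de_kr$fractions), 1)
  expect_error(composition_by_class("DEB"), "position 3")
  # order invariance: pooled fractions ignore sequence order
  s1 <- composition_by_class(c("DEKR", "GGPP"))
  s2 <- composition_by_class(c("GGPP", "DEKR"))
  expect_identical(s1$fractions, s2$fractions)
})

test_that("random sequences recover known class frequencies", {
  set.seed(12)
  # classes drawn with known probabilities via residue sampling
  res_pool <- c(rep("A", 5), rep("D", 3), rep("K", 2))  # 50/30/20
  seq <- paste0(sample(res_pool, 10000, replace = TRUE), collapse = "")
  comp <- composition_by_class(seq)
  for (cs in list(c("hydrophobic", 0.5), c("acidic", 0.3), c("basic", 0.2))) {
    p <- as.numeric(cs[2])
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(comp$fractions[[cs[1]]] - p), 3 * se)
  }
})

test_that("overlap resolution keeps the highest-scoring model", {
  hits <- data.frame(
    protein = "p", domain = c("A", "B"), start = c(1, 50),
    end = c(100, 150), score = c(50, 60), stringsAsFactors = FALSE)
  out <- resolve_architecture(hits)
  expect_identical(out$domain, "B")
  disjoint <- data.frame(
    protein = "p", domain = c("REC", "RomR-C"), start = c(5, 120),
    end = c(115, 170), score = c(80, 40), stringsAsFactors = FALSE)
  both <- resolve_architecture(disjoint)
  expect_identical(both$domain, c("REC", "RomR-C"))
  # deterministic tie-break: equal scores resolved by earlier start
  tie <- data.frame(protein = "p", domain = c("Y", "Z"), start = c(10, 5),
                    end = c(60, 55), score = c(42, 42),
                    stringsAsFactors = FALSE)
  expect_identical(resolve_architecture(tie)$domain, "Z")
})

test_that("greedy resolution is idempotent, disjoint, sorted, and oracle-equal", {
  set.seed(23)
  for (k in 1:100) {
    hits <- random_hits(sample(2:8, 1))
    out <- resolve_architecture(hits)
    expect_identical(out, oracle_greedy_architecture(hits))
    expect_identical(resolve_architecture(out), out)
    if (nrow(out) > 1) {
      expect_true(all(diff(out$start) > 0))
      expect_true(all(out$start[-1] > out$end[-nrow(out)]))
    }
  }
})

test_that("co-occurrence tabulation conserves genomes and recovers patterns", {
  tab <- generate_presence_absence(
    pattern_spec(c("11111" = 5), markers = paste0("m", 1:5)))
  expect_identical(tabulate_cooccurrence(tab),
                   data.frame(pattern = "11111", count = 5L))
  empty <- generate_presence_absence(
    pattern_spec(integer(0), markers = paste0("m", 1:5)))
  expect_identical(nrow(tabulate_cooccurrence(empty)), 0L)
  for (k in 1:50) {
    spec <- random_pattern_spec(seed = k)
    tab <- generate_presence_absence(spec)
    counts <- tabulate_cooccurrence(tab)
    expect_identical(sum(counts$count), nrow(tab))
    expect_identical(
      stats::setNames(counts$count, counts$pattern)[names(spec$pattern_counts)],
      stats::setNames(as.integer(spec$pattern_counts),
                      names(spec$pattern_counts)))
    # ordering: count descending, ties by pattern bit string descending
    expect_true(all(diff(counts$count) <= 0))
    ties <- split(counts$pattern, counts$count)
    for (tie in ties) {
      expect_identical(tie, sort(tie, decreasing = TRUE))
    }
  }
})

test_that("marker queries count required and joint presence", {
  tab <- generate_presence_absence(pattern_spec(
    c("111" = 26, "110" = 34, "100" = 10, "000" = 5),
    markers = c("MglA", "MglB", "RomR"), seed = 3))
  q <- query_cooccurrence(tab, require = c("MglA", "MglB"), also = "RomR")
  expect_identical(q, c(n_require = 60L, n_also = 26L))
  expect_identical(
    unname(query_cooccurrence(tab, require = character(0))[["n_require"]]),
    75L)
  all_on <- generate_presence_absence(pattern_spec(
    c("11" = 7), markers = c("a", "b")))
  expect_identical(query_cooccurrence(all_on, require = c("a", "b"),
                                      also = "a"),
                   c(n_require = 7L, n_also = 7L))
  expect_error(query_cooccurrence(tab, require = "Frz"), "unknown marker")
})
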