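# Sequence-level tabulations: sequence-logo information content, amino-acid
# composition by physicochemical class, domain-architecture overlap
# resolution, and genome x marker co-occurrence pattern counting.

#' The 20 canonical amino acids
#' @export
AA_ALPHABET_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

#' Information content of one alignment column
#'
#' Computes the sequence-logo statistics of a single alignment column:
#' residue frequencies over the non-gap residues, Shannon entropy
#' `H = -sum f * log2 f`, information content
#' `R = log2(20) - (H + e_n)` in bits, and per-residue letter heights
#' `f * R`. The small-sample correction `e_n = (20 - 1) / (2 * ln(2) * n)`
#' compensates the downward entropy bias of small column counts and is on by
#' default; `R` is clamped to `[0, log2(20)]`.
#'
#' @param column character vector of single residues (one per sequence), or
#'   a single string. Gap characters `-` and `.` are excluded from `n`.
#' @param correct_small_sample apply the small-sample correction (default
#'   `TRUE`).
#' @param ambiguous how to treat ambiguity codes (B, J, O, U, X, Z, `*`):
#'   `"error"` (default) or `"gap"`.
#' @return Object of class `column_profile`: list with `freq` (named over
#'   the 20 residues), `n` (non-gap count), `H_bits`, `e_n`, `R_bits`,
#'   `heights`, and `all_gap` (TRUE when the column holds no residues, in
#'   which case `R_bits` is `NA` and the column is excluded from logos).
#' @export
column_information <- function(column, correct_small_sample = TRUE,
                               ambiguous = c("error", "gap")) {
  ambiguous <- match.arg(ambiguous)
  if (length(column) == 1L && nchar(column) > 1L) {
    column <- strsplit(column, "")[[1L]]
  }
  column <- toupper(as.character(column))
  amb <- !(column %in% c(AA_ALPHABET_20, GAP_CHARS))
  if (any(amb)) {
    if (ambiguous == "error") {
      stop2("non-canonical residue(s) at position(s) ",
            paste(which(amb), collapse = ", "), ": ",
            paste(unique(column[amb]), collapse = ", "))
    }
    column[amb] <- "-"
  }
  res <- column[!(column %in% GAP_CHARS)]
  n <- length(res)
  if (n == 0L) {
    return(structure(
      list(freq = stats::setNames(rep(NA_real_, 20L), AA_ALPHABET_20),
           n = 0L, H_bits = NA_real_, e_n = NA_real_, R_bits = NA_real_,
           heights = stats::setNames(rep(NA_real_, 20L), AA_ALPHABET_20),
           all_gap = TRUE),
      class = "column_profile"))
  }
  counts <- table(factor(res, levels = AA_ALPHABET_20))
  f <- as.numeric(counts) / n
  names(f) <- AA_ALPHABET_20
  H <- -sum(f[f > 0] * log2(f[f > 0]))
  e_n <- if (correct_small_sample) (20 - 1) / (2 * log(2) * n) else 0
  R <- min(max(log2(20) - (H + e_n), 0), log2(20))
  structure(
    list(freq = f, n = n, H_bits = H, e_n = e_n, R_bits = R,
         heights = f * R, all_gap = FALSE),
    class = "column_profile"
  )
}

#' Sequence logo table for an alignment
#'
#' Per-column information content and letter heights for a whole alignment,
#' the numeric content of a sequence logo. All-gap columns are kept in the
#' table with `R_bits = NA` and flagged via `all_gap`.
#'
#' @param aln a [Biostrings::AAStringSet], or a character vector of aligned
#'   sequences of equal length (gaps `-`/`.`).
#' @inheritParams column_information
#' @return Data frame with columns `position`, `n`, `R_bits`, `all_gap`, and
#'   one height column `h_<residue>` per amino acid.
#' @export
alignment_logo <- function(aln, correct_small_sample = TRUE,
                           ambiguous = c("error", "gap")) {
  ambiguous <- match.arg(ambiguous)
  if (inherits(aln, "XStringSet")) aln <- as.character(aln)
  aln <- as.character(aln)
  if (length(aln) == 0L) stop2("empty alignment")
  if (length(unique(nchar(aln))) != 1L) {
    stop2("aligned sequences must have equal length")
  }
  m <- do.call(rbind, strsplit(aln, ""))
  cols <- lapply(seq_len(ncol(m)), function(j) {
    column_information(m[, j], correct_small_sample, ambiguous)
  })
  heights <- do.call(rbind, lapply(cols, function(cp) cp$heights))
  colnames(heights) <- paste0("h_", AA_ALPHABET_20)
  out <- data.frame(
    position = seq_len(ncol(m)),
    n = vapply(cols, function(cp) cp$n, integer(1L)),
    R_bits = vapply(cols, function(cp) cp$R_bits, numeric(1L)),
    all_gap = vapply(cols, function(cp) cp$all_gap, logical(1L)))
  cbind(out, as.data.frame(heights))
}

#' Default physicochemical amino-acid classes
#'
#' Residue-to-class map used by [composition_by_class()]: hydrophobic
#' (AVLIMFWYC), polar uncharged (STNQ), acidic (DE), basic (KRH), and
#' special (GP). The partition is a package convention — common groupings
#' differ in detail — and can be replaced by any total map over the 20
#' residues.
#'
#' @return Named character vector: names are residues, values class labels.
#' @export
default_class_map <- function() {
  c(stats::setNames(rep("hydrophobic", 9L), strsplit("AVLIMFWYC", "")[[1L]]),
    stats::setNames(rep("polar", 4L), strsplit("STNQ", "")[[1L]]),
    stats::setNames(rep("acidic", 2L), c("D", "E")),
    stats::setNames(rep("basic", 3L), c("K", "R", "H")),
    stats::setNames(rep("special", 2L), c("G", "P")))
}

#' Amino-acid composition by physicochemical class
#'
#' Pools the residues of a set of sequences (e.g. the linker regions of a
#' protein family within one taxonomic group) and reports the fraction of
#' residues in each physicochemical class.
#'
#' @param sequences character vector of sequences (or an
#'   [Biostrings::AAStringSet]); gap characters are ignored.
#' @param class_map named character vector mapping each of the 20 canonical
#'   residues to a class label; default [default_class_map()].
#' @return Object of class `composition_profile`: list with `fractions`
#'   (named by class, summing to 1), `counts`, and `n_residues`.
#' @export
composition_by_class <- function(sequences, class_map = default_class_map()) {
  if (inherits(sequences, "XStringSet")) sequences <- as.character(sequences)
  sequences <- as.character(sequences)
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    stop2("sequences must be non-empty")
  }
  missing_res <- setdiff(AA_ALPHABET_20, names(class_map))
  if (length(missing_res) > 0L) {
    stop2("class_map does not cover residue(s): ",
          paste(missing_res, collapse = ", "))
  }
  classes <- sort(unique(unname(class_map)))
  counts <- stats::setNames(rep(0L, length(classes)), classes)
  for (s in seq_along(sequences)) {
    res <- strsplit(toupper(sequences[[s]]), "")[[1L]]
    res <- res[!(res %in% GAP_CHARS)]
    bad <- which(!(res %in% AA_ALPHABET_20))
    if (length(bad) > 0L) {
      stop2("sequence ", s, " position ", bad[1L],
            ": residue '", res[bad[1L]], "' outside the 20-letter alphabet")
    }
    tab <- table(factor(unname(class_map[res]), levels = classes))
    counts <- counts + as.integer(tab)
  }
  n <- sum(counts)
  if (n == 0L) stop2("sequences contain no residues")
  structure(
    list(fractions = counts / n, counts = counts, n_residues = n),
    class = "composition_profile"
  )
}

#' Resolve overlapping domain hits into a final architecture
#'
#' Greedy overlap resolution: repeatedly accept the highest-scoring
#' remaining hit and discard every hit that shares at least one residue with
#' an accepted one; the accepted hits, sorted by start, form the final
#' domain architecture. Score ties break deterministically by earlier start,
#' then lexicographic domain name. This is the conventional rule of keeping
#' the highest-scoring domain model in the event of overlaps (not a
#' maximum-weight interval scheduling optimum).
#'
#' @param hits data frame with columns `protein`, `domain`, `start`, `end`
#'   (1-based inclusive residue coordinates) and `score` (bits), for a
#'   single protein.
#' @return The accepted subset of `hits`, sorted by `start`.
#' @export
resolve_architecture <- function(hits) {
  req <- c("protein", "domain", "start", "end", "score")
  if (!all(req %in% names(hits))) {
    stop2("hits needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$protein)) > 1L) {
    stop2("hits must belong to a single protein; split by protein first")
  }
  if (any(hits$start > hits$end)) stop2("hit with start > end")
  if (any(!is.finite(hits$score))) stop2("non-finite score")
  ord <- order(-hits$score, hits$start, hits$domain)
  cand <- hits[ord, , drop = FALSE]
  acc_start <- numeric(0); acc_end <- numeric(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s <= acc_end & e >= acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s); acc_end <- c(acc_end, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start, out$end, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_cooccurrence_table <- function(tab) {
  if (!is.data.frame(tab) || !"genome" %in% names(tab)) {
    stop2("table must be a data frame with a 'genome' column")
  }
  markers <- setdiff(names(tab), "genome")
  if (anyDuplicated(tab$genome)) stop2("genome ids must be unique")
  for (m in markers) {
    v <- tab[[m]]
    if (!all(v %in% c(0L, 1L, TRUE, FALSE))) {
      stop2("marker column '", m, "' must be 0/1")
    }
  }
  markers
}

#' Collapse a presence/absence table into co-occurrence pattern counts
#'
#' Groups genomes by their full marker bit-vector and counts how many
#' genomes share each pattern, the tabulation displayed beside phyletic
#' pattern figures ("number of genomes with a given pattern of
#' co-occurrence"). Patterns are ordered by count (descending), ties by the
#' pattern bit string (descending).
#'
#' @param tab data frame with a `genome` column and one 0/1 column per
#'   marker, e.g. from [generate_presence_absence()] or
#'   [read_presence_absence()].
#' @return Data frame with columns `pattern` (bit string in marker column
#'   order) and `count`.
#' @export
tabulate_cooccurrence <- function(tab) {
  markers <- check_cooccurrence_table(tab)
  if (nrow(tab) == 0L) {
    return(data.frame(pattern = character(0), count = integer(0)))
  }
  bits <- do.call(paste0, lapply(markers, function(m) as.integer(tab[[m]])))
  cnt <- table(bits)
  out <- data.frame(pattern = names(cnt), count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern,
                   decreasing = c(FALSE, TRUE), method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count genomes carrying a marker combination
#'
#' Answers queries of the form "of the genomes encoding all markers in
#' `require`, how many also encode `also`?" — e.g. of the genomes encoding
#' both MglA and MglB, how many also encode RomR.
#'
#' @inheritParams tabulate_cooccurrence
#' @param require character vector of marker names that must all be present
#'   (empty: all genomes qualify).
#' @param also optional single marker name to intersect with.
#' @return Named integer vector: `n_require` (genomes with all required
#'   markers) and, when `also` is given, `n_also` (those that additionally
#'   carry `also`).
#' @export
query_cooccurrence <- function(tab, require = character(0), also = NULL) {
  markers <- check_cooccurrence_table(tab)
  unknown <- setdiff(c(require, also), markers)
  if (length(unknown) > 0L) {
    stop2("unknown marker(s): ", paste(unknown, collapse = ", "))
  }
  has_all <- rep(TRUE, nrow(tab))
  for (m in require) has_all <- has_all & (as.integer(tab[[m]]) == 1L)
  out <- c(n_require = sum(has_all))
  if (!is.null(also)) {
    out <- c(out, n_also = sum(has_all & (as.integer(tab[[also]]) == 1L)))
  }
  out
}
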