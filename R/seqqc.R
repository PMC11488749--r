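#' Nucleotide diversity (pi) of an alignment
#'
#' Mean, over all unordered sequence pairs, of the proportion of comparable
#' sites at which the two sequences differ. A site is comparable for a pair
#' iff both residues are unambiguous bases (`A`, `C`, `G`, `T`); gaps, `N`
#' and ambiguity codes are excluded pairwise. Pairs with zero comparable
#' sites are dropped from the average with a warning.
#'
#' @param aln A [locus_alignment] with at least two sequences.
#' @return Nucleotide diversity, a number in `[0, 1]`.
#' @examples
#' aln <- locus_alignment("sp", "coi", c("a", "b", "c"),
#'                        c("AAAA", "AAAT", "AATT"))
#' nucleotide_diversity(aln)  # 1/3
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("nucleotide diversity is undefined for fewer than 2 sequences")
  m <- seq_matrix(aln)
  ok <- base_matrix(m)
  vals <- numeric(0)
  dropped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) { dropped <- dropped + 1L; next }
      vals <- c(vals, sum(m[i, comp] != m[j, comp]) / nc)
    }
  }
  if (dropped > 0L)
    warning(sprintf("%d pair(s) with no comparable sites excluded from pi", dropped))
  if (length(vals) == 0L)
    stop("no sequence pair has comparable sites; pi undefined")
  mean(vals)
}

#' Empirical outlier bounds on a set of nucleotide-diversity values
#'
#' Flags alignments whose pi falls strictly outside the empirical
#' `[lo_q, hi_q]` quantile band across all alignments. Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param pis Numeric vector of per-alignment pi values (names retained in
#'   the flags).
#' @param lo_q,hi_q Lower and upper quantile probabilities
#'   (defaults 0.025 and 0.975).
#' @return A list with `lower`, `upper` and logical vector `flags`
#'   (`TRUE` = outlier).
#' @export
pi_outlier_bounds <- function(pis, lo_q = 0.025, hi_q = 0.975) {
  if (length(pis) == 0L) stop("empty pi list")
  if (!(lo_q >= 0 && lo_q < hi_q && hi_q <= 1))
    stop("quantile probabilities must satisfy 0 <= lo_q < hi_q <= 1")
  qs <- stats::quantile(pis, probs = c(lo_q, hi_q), names = FALSE, type = 7)
  flags <- pis < qs[1] | pis > qs[2]
  list(lower = qs[1], upper = qs[2], flags = flags)
}

#' Remove sequences missing half or more of the trailing alignment half
#'
#' A sequence is removed iff, among the trailing `ceiling(L/2)` alignment
#' columns, the fraction of residues that are not unambiguous bases
#' (anything outside `A`, `C`, `G`, `T`) is at least 0.5. This is the
#' programmatic form of dropping "short" sequences that do not overlap the
#' second half of the alignment.
#'
#' @param aln A [locus_alignment] of length >= 2 columns.
#' @return A list with `kept` (a [locus_alignment], possibly with zero
#'   sequences in which case an attribute `empty = TRUE` is set and a warning
#'   raised) and `removed` (ids in input order).
#' @export
filter_short_sequences <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  L <- aln$length
  if (L < 2L) stop("alignment must have at least 2 columns")
  half <- ceiling(L / 2)
  cols <- (L - half + 1L):L
  m <- seq_matrix(aln)
  miss_frac <- rowMeans(!base_matrix(m)[, cols, drop = FALSE])
  drop <- miss_frac >= 0.5
  removed <- aln$ids[drop]
  if (all(drop)) {
    warning(sprintf("all sequences removed from %s/%s", aln$species, aln$locus))
    kept <- structure(
      list(species = aln$species, locus = aln$locus,
           ids = character(0), sequences = character(0), length = L),
      class = "locus_alignment"
    )
    attr(kept, "empty") <- TRUE
  } else {
    kept <- locus_alignment(aln$species, aln$locus,
                            aln$ids[!drop], aln$sequences[!drop])
  }
  list(kept = kept, removed = removed)
}

#' Quality-control screen over a set of alignments
#'
#' Runs [filter_short_sequences()] on every alignment, computes pi on the
#' survivors, and flags pi outliers across the whole collection with
#' [pi_outlier_bounds()]. Alignments reduced below two sequences get `NA`
#' pi and are never flagged.
#'
#' @param alignments List of [locus_alignment] objects.
#' @param lo_q,hi_q Quantile probabilities passed to [pi_outlier_bounds()].
#' @return A list with `alignments` (filtered, same order, empty ones
#'   dropped) and `report` (data.frame: species, locus, n_before, n_after,
#'   pi, outlier_flag).
#' @export
qc_screen <- function(alignments, lo_q = 0.025, hi_q = 0.975) {
  filtered <- lapply(alignments, filter_short_sequences)
  kept <- lapply(filtered, `[[`, "kept")
  n_before <- vapply(alignments, function(a) length(a$ids), integer(1))
  n_after <- vapply(kept, function(a) length(a$ids), integer(1))
  pis <- vapply(kept, function(a) {
    if (length(a$ids) < 2L) return(NA_real_)
    nucleotide_diversity(a)
  }, numeric(1))
  flags <- rep(FALSE, length(pis))
  if (any(!is.na(pis))) {
    b <- pi_outlier_bounds(pis[!is.na(pis)], lo_q, hi_q)
    flags[!is.na(pis)] <- b$flags
  }
  report <- data.frame(
    species = vapply(alignments, `[[`, character(1), "species"),
    locus = vapply(alignments, `[[`, character(1), "locus"),
    n_before = n_before, n_after = n_after,
    pi = pis, outlier_flag = flags,
    stringsAsFactors = FALSE
  )
  list(alignments = kept[n_after > 0L], report = report)
}
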