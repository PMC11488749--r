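#' A species-delimitation result
#'
#' @param species,locus Provenance labels.
#' @param method One of `"gap"`, `"merge"`, `"gmyc"`.
#' @param assignment Named integer vector: tip id -> lineage index.
#' @param support Method-specific support scalar (gap width, gap score, or
#'   GMYC likelihood-ratio p-value).
#' @return An object of class `delimitation_result` with `n_lineages` equal
#'   to the number of distinct assignment values.
#' @export
delimitation_result <- function(species, locus, method, assignment,
                                support = NA_real_) {
  assignment <- stats::setNames(match(assignment, unique(assignment)),
                                names(assignment))
  structure(list(species = species, locus = locus, method = method,
                 n_lineages = length(unique(assignment)),
                 assignment = assignment, support = support),
            class = "delimitation_result")
}

#' @export
print.delimitation_result <- function(x, ...) {
  cat(sprintf("delimitation_result [%s] %s/%s: %d lineage(s), support %.4g\n",
              x$method, x$species, x$locus, x$n_lineages, x$support))
  invisible(x)
}

# connected components of the graph with edges where d <= threshold
# (equivalently: single-linkage clusters cut at that height)
components_at <- function(d, threshold) {
  n <- nrow(d)
  if (n == 1L) return(1L)
  if (n == 2L) return(if (d[1, 2] <= threshold) c(1L, 1L) else c(1L, 2L))
  comp <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                        h = threshold * (1 + 1e-12) + 1e-15)
  unname(match(comp, unique(comp)))
}

# One barcode-gap split attempt on the sub-matrix `d` under prior P: among
# gaps in the sorted distinct distances whose upper edge exceeds P, the
# first one whose width exceeds X times the mean width of the gaps below it
# (the prior when it is the very first gap) and clears the absolute floor
# max(P, min_gap) is significant; cut at its lower edge. Returns NULL when
# no significant gap exists.
find_gap_cut <- function(d, P, X, min_gap = 0.02) {
  vals <- sort(unique(d[upper.tri(d)]))
  if (length(vals) < 2L) return(NULL)
  lower <- vals[-length(vals)]
  upper <- vals[-1L]
  width <- upper - lower
  for (i in seq_along(width)) {
    if (upper[i] <= P) next
    # reference scale: mean gap width below the candidate; when the candidate
    # is the very first gap, the prior itself sets the intraspecific scale.
    # The floor screens coalescent-scale discontinuities: a gap narrower
    # than the prior (or the conventional barcode divergence) cannot
    # separate species whose intraspecific divergence may reach that scale.
    ref <- if (i >= 2L) mean(width[seq_len(i - 1L)]) else P
    if (width[i] <= X * ref || width[i] <= max(P, min_gap)) next
    return(list(threshold = lower[i], width = width[i]))
  }
  NULL
}

gap_partition <- function(d, P, X, min_gap = 0.02) {
  n <- nrow(d)
  if (n < 3L) return(rep(1L, n))
  cut <- find_gap_cut(d, P, X, min_gap)
  if (is.null(cut)) return(rep(1L, n))
  comp <- components_at(d, cut$threshold)
  if (length(unique(comp)) == 1L) return(rep(1L, n))
  out <- integer(n)
  nxt <- 0L
  for (g in unique(comp)) {
    idx <- which(comp == g)
    sub <- gap_partition(d[idx, idx, drop = FALSE], P, X, min_gap)
    out[idx] <- nxt + sub
    nxt <- nxt + max(sub)
  }
  out
}

#' Barcode-gap distance partitioning
#'
#' Distance-based delimitation in the spirit of automatic barcode-gap
#' discovery: for each prior `P` on the maximum intraspecific divergence,
#' the sorted distinct pairwise distances are scanned for a significant gap
#' (wider than `rel_gap_width` times the mean gap width below it, not
#' entirely below `P`, and clearing the absolute barcode floor `min_gap` —
#' coalescent variation inside one population produces gap-like
#' discontinuities below that scale); the widest such gap defines a
#' threshold, groups are the connected components of the distance graph cut
#' there, and the search recurses within groups. The reported lineage count
#' is the mode across priors (ties broken toward fewer lineages) and the
#' assignment comes from the smallest prior achieving the mode.
#'
#' @param D A `dist_matrix` (p-distance recommended).
#' @param priors Strictly positive ascending prior divergences; default 10
#'   log-spaced values in `[0.001, 0.1]`.
#' @param rel_gap_width Required width ratio of a significant gap (default 1.5).
#' @param min_gap Absolute minimum width of a significant gap
#'   (substitutions/site, default 0.02).
#' @param species,locus Provenance labels for the result.
#' @return A [delimitation_result] with method `"gap"`; support is the width
#'   of the top-level gap chosen under the selected prior (0 when unsplit).
#' @export
gap_delimit <- function(D, priors = NULL, rel_gap_width = 1.5, min_gap = 0.02,
                        species = "?", locus = "?") {
  stopifnot(inherits(D, "dist_matrix"))
  if (is.null(priors)) priors <- 10^seq(log10(0.001), log10(0.1), length.out = 10)
  if (any(diff(priors) <= 0) || any(priors <= 0))
    stop("priors must be strictly positive and ascending")
  d <- D$d
  n <- nrow(d)
  if (n < 3L) {
    warning("fewer than 3 tips: too few pairs to detect a gap")
    return(delimitation_result(species, locus, "gap",
                               stats::setNames(rep(1L, n), D$ids), support = 0))
  }
  parts <- lapply(priors, function(P)
    gap_partition(d, P, rel_gap_width, min_gap))
  counts <- vapply(parts, function(p) length(unique(p)), integer(1))
  tab <- table(counts)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  pick <- which(counts == modal)[1L]
  cut <- find_gap_cut(d, priors[pick], rel_gap_width, min_gap)
  delimitation_result(species, locus, "gap",
                      stats::setNames(parts[[pick]], D$ids),
                      support = if (is.null(cut)) 0 else cut$width)
}

#' Merge-path gap scoring
#'
#' Builds the single-linkage merge path and scores every partition it
#' induces (2 to n-1 groups) by the gap score: minimum between-group
#' distance minus maximum within-group distance. Returns the best-scoring
#' partition provided the gap is *significant*: the score must exceed both
#' `min_rel_gap` times the maximum within-group distance (coalescent
#' variation inside a single population routinely produces small positive
#' gaps, so a positive score alone is not evidence of distinct lineages) and
#' the absolute floor `min_gap` (partitions into identical-haplotype groups
#' have zero within-group distance, so a relative rule alone cannot screen
#' them; 0.02 substitutions/site is the conventional barcode divergence
#' floor). Otherwise a single lineage is reported.
#'
#' @param D A `dist_matrix`.
#' @param min_rel_gap Required ratio of gap score to maximum within-group
#'   distance (default 1: the between-group gap must at least double the
#'   within-group scale).
#' @param min_gap Absolute minimum gap score (substitutions/site,
#'   default 0.02).
#' @param species,locus Provenance labels.
#' @return A [delimitation_result] with method `"merge"`; support is the best
#'   gap score (0 when unsplit).
#' @export
merge_delimit <- function(D, min_rel_gap = 1, min_gap = 0.02,
                          species = "?", locus = "?") {
  stopifnot(inherits(D, "dist_matrix"))
  d <- D$d
  n <- nrow(d)
  one <- function(sup) delimitation_result(
    species, locus, "merge", stats::setNames(rep(1L, n), D$ids), support = sup)
  if (n < 3L) return(one(0))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  best_score <- 0; best_part <- NULL
  for (k in 2:(n - 1L)) {
    part <- stats::cutree(hc, k = k)
    same <- outer(part, part, `==`)
    within <- d[same & upper.tri(d)]
    if (length(within) == 0L) next
    between <- d[!same & upper.tri(d)]
    score <- min(between) - max(within)
    if (score <= max(min_rel_gap * max(within), min_gap)) next
    if (score > best_score) { best_score <- score; best_part <- part }
  }
  if (is.null(best_part)) return(one(0))
  delimitation_result(species, locus, "merge",
                      stats::setNames(best_part, D$ids), support = best_score)
}

#' UPGMA ultrametric tree from a distance matrix
#'
#' Average-linkage agglomeration; node height is half the average
#' inter-cluster distance, so the output is binary and ultrametric.
#' Tips are sorted lexicographically before clustering so ties break
#' deterministically.
#'
#' @param D A `dist_matrix` (JC69 recommended for tree building).
#' @return An [ape::phylo] rooted ultrametric binary tree.
#' @export
upgma_tree <- function(D) {
  stopifnot(inherits(D, "dist_matrix"))
  if (anyNA(D$d)) stop("distance matrix contains NA (saturated pairs?)")
  ord <- order(D$ids)
  d <- D$d[ord, ord]
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(d)[1], d[1, 2] / 2,
                                        rownames(d)[2], d[1, 2] / 2))
    return(tr)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)  # divides merge heights by 2: tip-to-node = h/2
}

# node heights (0 at tips) for an ultrametric tree
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  n <- length(tree$tip.label)
  h[seq_len(n)] <- pmax(h[seq_len(n)], 0)
  h
}

#' Check ultrametricity of a tree
#'
#' @param tree An [ape::phylo].
#' @param tol Absolute tolerance on root-to-tip path spread.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  diff(range(depth[seq_len(n)])) <= tol
}
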