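#' Pairwise genetic distances from an alignment
#'
#' p-distance is the proportion of differing comparable sites per pair
#' (a site is comparable iff both residues are unambiguous bases). JC69
#' applies the Jukes-Cantor correction `-(3/4) * log(1 - 4p/3)`; saturated
#' pairs (`p >= 0.75`) are set to `NA` and flagged.
#'
#' @param aln A [locus_alignment] with at least two sequences.
#' @param model `"p-distance"` (default) or `"JC69"`.
#' @return An object of class `dist_matrix`: list with `ids`, symmetric
#'   numeric matrix `d` (zero diagonal), `model`, and a logical matrix
#'   `saturated` marking pairs where the JC69 correction is undefined.
#' @examples
#' aln <- locus_alignment("sp", "coi", c("a", "b"), c("AAAAAAAAAA", "TAAAAAAAAA"))
#' pairwise_distances(aln, "JC69")$d[1, 2]  # -(3/4) log(1 - 0.4/3)
#' @export
pairwise_distances <- function(aln, model = c("p-distance", "JC69")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "locus_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  m <- seq_matrix(aln)
  # match counts via per-base indicator cross-products (BLAS-fast)
  comparable <- matrix(0, n, n)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    I <- (m == b) * 1
    matches <- matches + tcrossprod(I)
  }
  okn <- base_matrix(m) * 1
  comparable <- tcrossprod(okn)
  off <- comparable == 0 & upper.tri(comparable)
  if (any(off)) {
    w <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf("pair (%s, %s) has no comparable sites",
                 aln$ids[w[1]], aln$ids[w[2]]))
  }
  p <- (comparable - matches) / comparable
  diag(p) <- 0
  sat <- matrix(FALSE, n, n, dimnames = list(aln$ids, aln$ids))
  if (model == "JC69") {
    sat <- p >= 0.75
    diag(sat) <- FALSE
    d <- ifelse(sat, NA_real_, -0.75 * log(1 - 4 * pmin(p, 0.7499999) / 3))
  } else d <- p
  dimnames(d) <- list(aln$ids, aln$ids)
  structure(list(ids = aln$ids, d = d, model = model, saturated = sat),
            class = "dist_matrix")
}

#' Build a dist_matrix from a plain symmetric matrix
#'
#' Convenience constructor for tests and for feeding externally computed
#' distances to the delimitation methods.
#'
#' @param d Symmetric numeric matrix with zero diagonal; dimnames used as
#'   tip ids (defaults `t1..tn`).
#' @param model Distance model label.
#' @return A `dist_matrix`.
#' @export
dist_matrix <- function(d, model = "p-distance") {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("t%d", 1:n)
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  structure(list(ids = rownames(d), d = d, model = model,
                 saturated = matrix(FALSE, n, n)),
            class = "dist_matrix")
}
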