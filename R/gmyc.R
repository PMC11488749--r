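# Single-threshold general mixed Yule-coalescent model on an ultrametric
# tree. Heights are measured backward in time from the tips (height 0).
# For a threshold T, branching events older than T belong to a linear-rate
# diversification (Yule-like) process over the k between-species lineages
# alive, and events younger than T are coalescences within the clusters
# induced by the edges crossing T, with combined rate
#   b(t) = lambda_div * k(t) + lambda_coal * sum_j n_j(t) (n_j(t) - 1).
# Both rate exponents are fixed at 1. Per-process MLEs are closed form
# (events / process-weighted time); the two processes are disjoint in the
# event terms because only one branching type is possible on each side of T.

# Deterministic minimum-separation adjustment of internal node heights.
# Tied heights (typically zero-length branches from identical sequences)
# make the waiting-time likelihood degenerate (zero exposure with positive
# event count); internal nodes are spread by at least `eps`, processing
# children before parents so the tree ordering is preserved.
adjust_heights <- function(tree, eps = NULL) {
  n <- length(tree$tip.label)
  h <- node_heights(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  if (is.null(eps)) eps <- max(max(h), 1e-8) * 1e-6
  po_rank <- integer(n + tree$Nnode)
  po_rank[tree$edge[ape::postorder(tree), 1L]] <- seq_along(ape::postorder(tree))
  ord <- internal[order(h[internal], po_rank[internal])]
  floor_h <- 0
  for (nd in ord) {
    h[nd] <- max(h[nd], floor_h + eps)
    floor_h <- h[nd]
  }
  h
}

# Full threshold profile in O(n^2) using the pair-MRCA identity:
# sum_j m_j(t)(m_j(t)-1) = L_t(L_t-1) - #ordered pairs of lineages at t whose
# MRCA is older than the threshold. Pairs merging at node v contribute
# 2 a_v(t) b_v(t) (left x right subtree lineage counts), accumulated once per
# node and suffix-summed over thresholds. Candidate j places the threshold
# between the j-th and (j+1)-th oldest... i.e. between e_j and e_{j+1} in the
# ascending event heights (j = 0: all events diversification; j = m: the
# single-coalescent null).
gmyc_profile <- function(tree, h = adjust_heights(tree)) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  internal <- (n + 1L):(n + m)
  e <- sort(h[internal])
  idx <- stats::setNames(rank(h[internal]), internal)  # node -> height rank
  desc <- descendant_sets(tree)
  edge <- tree$edge

  P <- matrix(0, m, m)  # P[i, j]: pairs merging at event j, alive interval i
  for (v in internal) {
    jv <- idx[[as.character(v)]]
    ch <- edge[edge[, 1] == v, 2]
    ab <- lapply(ch, function(c) {
      set <- desc[[c]]
      tips <- sum(set <= n)
      ints <- set[set > n]
      cnt <- cumsum(tabulate(idx[as.character(ints)], nbins = m))
      # lineages of this side alive in interval i (= between e_{i-1}, e_i):
      # tips minus coalescences strictly below e_{i-1}
      i <- seq_len(jv)
      tips - c(0, cnt)[i]
    })
    P[seq_len(jv), jv] <- 2 * ab[[1]] * ab[[2]]
  }
  SufP <- t(apply(P, 1L, function(r) rev(cumsum(rev(c(r[-1L], 0))))))
  if (m == 1L) SufP <- matrix(SufP, 1L, 1L)

  L <- n - (seq_len(m) - 1L)            # lineages in interval i
  delta <- diff(c(0, e))
  LD <- L * delta
  suff_LD <- rev(cumsum(rev(LD)))       # sum_{i >= j} L_i delta_i
  suff_logL <- rev(cumsum(rev(log(L))))

  logL <- numeric(m + 1L)
  lam_div <- numeric(m + 1L)
  lam_coal <- numeric(m + 1L)
  for (j in 0:m) {
    C <- j; D <- m - j
    ll <- 0
    if (D > 0L) {
      E_div <- (n - j) * e[j + 1L] +
        if (j + 2L <= m) suff_LD[j + 2L] else 0
      lam_div[j + 1L] <- D / E_div
      ll <- ll + D * log(D / E_div) + suff_logL[j + 1L] - D
    }
    if (C > 0L) {
      i <- seq_len(j)
      B <- L[i] * (L[i] - 1L) - SufP[i, j]
      E_coal <- sum(B * delta[i])
      lam_coal[j + 1L] <- C / E_coal
      ll <- ll + C * log(C / E_coal) + sum(log(B)) - C
    }
    logL[j + 1L] <- ll
  }
  thresholds <- if (m >= 2L) c(e[1L] / 2, (e[-m] + e[-1L]) / 2, e[m] * 2)
                else c(e[1L] / 2, e[1L] * 2)
  list(e = e, logL = logL, thresholds = thresholds, n = n, m = m,
       lam_div = lam_div, lam_coal = lam_coal)
}

# clusters induced by the edges crossing threshold T: list of tip-index sets
gmyc_clusters <- function(tree, h, T) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  if (T >= max(h)) return(list(seq_len(n)))
  cross <- which(h[edge[, 2]] < T & h[edge[, 1]] > T)
  desc <- descendant_sets(tree)
  lapply(edge[cross, 2], function(c) desc[[c]][desc[[c]] <= n])
}

# per-threshold log-likelihood by direct interval sweep (reference
# implementation; gmyc_profile computes the same quantity for all candidate
# thresholds at once)
gmyc_loglik <- function(tree, T, h = adjust_heights(tree)) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  internal <- (n + 1L):(n + tree$Nnode)
  ev_h <- h[internal]                       # event heights
  rootH <- max(ev_h)

  # clusters: edges crossing T; below the root everything is one cluster
  if (T >= rootH) {
    cluster_nodes <- list(seq_len(n + tree$Nnode))
    K <- 1L
  } else {
    cross <- which(h[edge[, 2]] < T & h[edge[, 1]] > T)
    desc <- descendant_sets(tree)
    cluster_nodes <- lapply(edge[cross, 2], function(c) desc[[c]])
    K <- length(cross)
  }
  # map each node to its cluster (nodes above T map to none)
  cl_of <- integer(n + tree$Nnode)
  for (j in seq_along(cluster_nodes)) cl_of[cluster_nodes[[j]]] <- j

  div_ev <- internal[ev_h > T]
  coal_ev <- internal[ev_h <= T]
  D <- length(div_ev); C <- length(coal_ev)

  breaks <- sort(unique(c(0, ev_h, if (T < rootH) T)))
  E_div <- 0; E_coal <- 0; slog_div <- 0; slog_coal <- 0
  # cluster sizes (tips) for lineage counting
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]; mid <- (a + b) / 2
    # between-species lineages alive at mid
    if (mid >= T) {
      k_mid <- sum(h[edge[, 2]] < mid & h[edge[, 1]] > mid)
      if (mid >= rootH) k_mid <- max(k_mid, 1L)
    } else k_mid <- K
    # within-cluster lineage counts at mid
    B_mid <- 0
    if (mid < T) {
      for (j in seq_along(cluster_nodes)) {
        # edges of cluster j (child inside; the stem edge qualifies because
        # its child is the cluster root) crossing height mid
        in_cl <- cl_of[edge[, 2]] == j
        m_j <- sum(in_cl & h[edge[, 2]] < mid & h[edge[, 1]] > mid)
        B_mid <- B_mid + m_j * (m_j - 1)
      }
    }
    E_div <- E_div + k_mid * (b - a)
    E_coal <- E_coal + B_mid * (b - a)
    # events ending this interval
    for (nd in internal[abs(ev_h - b) < 1e-15]) {
      if (h[nd] > T) slog_div <- slog_div + log(k_mid)
      else slog_coal <- slog_coal + log(max(B_mid, 2))
    }
  }
  ll <- 0
  lam_div <- if (D > 0) D / E_div else 0
  lam_coal <- if (C > 0) C / E_coal else 0
  if (D > 0) ll <- ll + D * log(lam_div) + slog_div - D
  if (C > 0) ll <- ll + C * log(lam_coal) + slog_coal - C
  list(logL = ll, lambda_div = lam_div, lambda_coal = lam_coal,
       K = K, clusters = cluster_nodes, D = D, C = C)
}

# tip-and-node descendant sets (each node's subtree, itself included)
descendant_sets <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  sets <- vector("list", N)
  for (i in seq_len(N)) sets[[i]] <- i
  edge <- tree$edge
  for (e in ape::postorder(tree)) {  # children edges precede their parents
    p <- edge[e, 1]; c <- edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  lapply(sets, sort)
}

#' Single-threshold GMYC fit
#'
#' Fits the single-threshold general mixed Yule-coalescent model by profiling
#' the threshold over the midpoints between consecutive distinct node
#' heights (plus a degenerate threshold above the root, under which the model
#' collapses to the null single-coalescent). The likelihood ratio against the
#' null is referred to a chi-squared distribution with `df` degrees of
#' freedom. If `p >= alpha` the tree is reported as one lineage; otherwise
#' the entities are the clusters induced by edges crossing the fitted
#' threshold (clusters with two or more tips plus crossing singletons).
#'
#' @param tree A rooted, binary, ultrametric [ape::phylo] with >= 3 tips.
#' @param alpha Significance level for the likelihood-ratio test.
#' @param df Chi-squared degrees of freedom for the LR test (default 3: two
#'   rate parameters plus the threshold, the classical convention for this
#'   model; simulation under a single-population coalescent shows the
#'   three-degree reference holds the nominal type-I level where two degrees
#'   are anticonservative).
#' @param species,locus Provenance labels.
#' @return A list with `fit` (class `gmyc_fit`: threshold, rates, logL_alt,
#'   logL_null, LR, p_value, n_entities) and `result`
#'   (a [delimitation_result], method `"gmyc"`, support = p-value).
#' @export
gmyc_fit <- function(tree, alpha = 0.05, df = 3, species = "?", locus = "?") {
  n <- length(tree$tip.label)
  if (n < 3L) stop("GMYC needs at least 3 tips")
  if (!ape::is.binary(tree)) stop("tree must be binary")
  if (!is_ultrametric_tree(tree, tol = 1e-6 * max(node_heights(tree), 1e-12)))
    stop("tree must be ultrametric")
  h_raw <- node_heights(tree)
  ev_raw <- h_raw[(n + 1L):(n + tree$Nnode)]
  h <- adjust_heights(tree)
  one_result <- function(p, fit) list(
    fit = fit,
    result = delimitation_result(
      species, locus, "gmyc",
      stats::setNames(rep(1L, n), tree$tip.label), support = p))

  if (length(unique(signif(ev_raw, 12))) <= 1L) {
    # all node heights equal: degenerate, only the null model is identified
    null_ll <- gmyc_loglik(tree, T = max(h) * 2 + 1, h = h)
    fit <- structure(list(threshold = NA_real_, lambda_div = 0,
                          lambda_coal = null_ll$lambda_coal,
                          logL_alt = null_ll$logL, logL_null = null_ll$logL,
                          LR = 0, p_value = 1, n_entities = 1L),
                     class = "gmyc_fit")
    return(one_result(1, fit))
  }
  prof <- gmyc_profile(tree, h = h)
  m <- prof$m
  logL_null <- prof$logL[m + 1L]
  # ties toward the older (more conservative) threshold
  best <- max(which(prof$logL >= max(prof$logL) - 1e-12))
  logL_alt <- max(prof$logL[best], logL_null)
  LR <- max(2 * (logL_alt - logL_null), 0)
  p <- stats::pchisq(LR, df = df, lower.tail = FALSE)
  T_best <- prof$thresholds[best]
  clusters <- gmyc_clusters(tree, h, T_best)
  K <- length(clusters)
  fit <- structure(list(threshold = T_best,
                        lambda_div = prof$lam_div[best],
                        lambda_coal = prof$lam_coal[best],
                        logL_alt = logL_alt, logL_null = logL_null,
                        LR = LR, p_value = p, n_entities = K),
                   class = "gmyc_fit")
  if (p >= alpha || K <= 1L) return(one_result(p, fit))
  assignment <- integer(n)
  for (j in seq_along(clusters)) assignment[clusters[[j]]] <- j
  list(fit = fit,
       result = delimitation_result(species, locus, "gmyc",
                                    stats::setNames(assignment, tree$tip.label),
                                    support = p))
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf(
    "gmyc_fit: %d entities, threshold %.4g, LR %.3f, p %.4g\n",
    x$n_entities, x$threshold, x$LR, x$p_value))
  invisible(x)
}

#' Run the three delimitation methods on one alignment
#'
#' Computes p-distances for the gap and merge methods and JC69 distances for
#' the UPGMA tree fed to the GMYC, then runs the requested methods.
#'
#' @param aln A [locus_alignment].
#' @param methods Subset of `c("gap", "merge", "gmyc")`.
#' @param alpha GMYC significance level.
#' @return Named list of [delimitation_result] objects (a method is skipped
#'   with a `NULL` when the alignment is too small for it).
#' @export
delimit_alignment <- function(aln, methods = c("gap", "merge", "gmyc"),
                              alpha = 0.05) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  n <- length(aln$ids)
  if (n < 2L) return(out)
  Dp <- pairwise_distances(aln, "p-distance")
  if ("gap" %in% methods && n >= 3L)
    out$gap <- suppressWarnings(
      gap_delimit(Dp, species = aln$species, locus = aln$locus))
  if ("merge" %in% methods)
    out$merge <- merge_delimit(Dp, species = aln$species, locus = aln$locus)
  if ("gmyc" %in% methods && n >= 3L) {
    Dj <- pairwise_distances(aln, "JC69")
    if (!anyNA(Dj$d)) {
      # collapse identical haplotypes: zero-length branches are outside the
      # GMYC model (its waiting-time likelihood degenerates), so the tree is
      # built on unique haplotypes and duplicates inherit their
      # representative's lineage
      hap <- components_at(Dj$d, 0)
      reps <- vapply(unique(hap), function(g) which(hap == g)[1L], integer(1))
      if (length(reps) >= 3L) {
        Dr <- dist_matrix(Dj$d[reps, reps, drop = FALSE], model = "JC69")
        tree <- upgma_tree(Dr)
        g <- gmyc_fit(tree, alpha = alpha, species = aln$species,
                      locus = aln$locus)$result
        assignment <- g$assignment[aln$ids[reps][hap]]
        names(assignment) <- aln$ids
        out$gmyc <- delimitation_result(aln$species, aln$locus, "gmyc",
                                        assignment, support = g$support)
      }
      # fewer than 3 distinct haplotypes: the GMYC cannot run; no vote is
      # emitted (analysis not performed for lack of data)
    }
  }
  out
}

# One GMYC fit on the pooled per-locus tree; returns per-species
# delimitation_result objects. Falls back to per-species fits when the
# alignments cannot be pooled (unequal lengths or saturated distances).
gmyc_delimit_pooled <- function(alns, alpha = 0.05) {
  per_species <- function() {
    out <- list()
    for (a in alns) {
      r <- delimit_alignment(a, methods = "gmyc", alpha = alpha)
      out <- c(out, unname(r))
    }
    out
  }
  lens <- unique(vapply(alns, `[[`, numeric(1), "length"))
  if (length(lens) != 1L) return(per_species())
  ids <- unlist(lapply(alns, `[[`, "ids"))
  sp_of <- rep(vapply(alns, `[[`, character(1), "species"),
               vapply(alns, function(a) length(a$ids), integer(1)))
  if (anyDuplicated(ids)) {
    ids <- paste(sp_of, ids, sep = "::")
  }
  names(sp_of) <- ids
  pooled <- locus_alignment("pooled", alns[[1]]$locus, ids,
                            unlist(lapply(alns, `[[`, "sequences")))
  if (length(ids) < 3L) return(per_species())
  Dj <- pairwise_distances(pooled, "JC69")
  if (anyNA(Dj$d)) return(per_species())
  hap <- components_at(Dj$d, 0)
  reps <- vapply(unique(hap), function(g) which(hap == g)[1L], integer(1))
  if (length(reps) < 3L) return(per_species())
  tree <- upgma_tree(dist_matrix(Dj$d[reps, reps, drop = FALSE],
                                 model = "JC69"))
  g <- gmyc_fit(tree, alpha = alpha, species = "pooled",
                locus = alns[[1]]$locus)$result
  assignment <- g$assignment[ids[reps][hap]]
  names(assignment) <- ids
  lapply(alns, function(a) {
    tips <- ids[sp_of == a$species]
    sub <- assignment[tips]
    names(sub) <- a$ids
    delimitation_result(a$species, a$locus, "gmyc", sub, support = g$support)
  })
}

#' Delimit every alignment of a collection
#'
#' The distance methods (gap, merge) run per species x locus alignment. The
#' GMYC, following standard practice for single-locus surveys, is by default
#' fitted once per locus on the pooled tree of all species' sequences (its
#' threshold is a property of the locus-wide branching process, and a pooled
#' tree gives the likelihood-ratio test its power); each species' lineage
#' count is then the number of fitted entities among its own tips. Set
#' `gmyc_pooled = FALSE` to fit the GMYC per species instead.
#'
#' @param alignments List of [locus_alignment] objects.
#' @param methods Methods to run (see [delimit_alignment()]).
#' @param alpha GMYC significance level.
#' @param gmyc_pooled Fit one GMYC per locus on the pooled tree
#'   (default `TRUE`).
#' @return A list with `results` (flat list of [delimitation_result]) and
#'   `table` (data.frame: species, locus, method, n_lineages, support).
#' @export
delimit_all <- function(alignments, methods = c("gap", "merge", "gmyc"),
                        alpha = 0.05, gmyc_pooled = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  per_aln <- if (gmyc_pooled) setdiff(methods, "gmyc") else methods
  results <- list()
  if (length(per_aln)) {
    for (aln in alignments) {
      res <- delimit_alignment(aln, methods = per_aln, alpha = alpha)
      results <- c(results, unname(res))
    }
  }
  if (gmyc_pooled && "gmyc" %in% methods) {
    for (locus in unique(vapply(alignments, `[[`, character(1), "locus"))) {
      alns <- Filter(function(a) a$locus == locus, alignments)
      results <- c(results, gmyc_delimit_pooled(alns, alpha = alpha))
    }
  }
  tab <- data.frame(
    species = vapply(results, `[[`, character(1), "species"),
    locus = vapply(results, `[[`, character(1), "locus"),
    method = vapply(results, `[[`, character(1), "method"),
    n_lineages = vapply(results, `[[`, integer(1), "n_lineages"),
    support = vapply(results, `[[`, numeric(1), "support"),
    stringsAsFactors = FALSE
  )
  list(results = results, table = tab)
}
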