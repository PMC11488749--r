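# Small worlds and distance fixtures shared across test files.

tiny_config <- function(...) {
  world_config(n_species = 6, p_hidden = 0.5, n_seqs_per_species = 8,
               seq_length = 400, grid_size = 20, seed = 101L, ...)
}

# block distance matrix: clusters of given sizes, constant within/between
block_dist <- function(sizes, within = 0.005, between = 0.12) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  d[outer(grp, grp, `==`)] <- within
  diag(d) <- 0
  dist_matrix(d)
}

# ultrametric tree with `ncl` planted clusters of `n_per` coalescent tips
# joined on a species tree; cluster roots all at the same height
planted_gmyc_tree <- function(ncl, n_per, theta = 0.005, sp_depth = 0.08,
                              min_stem = 0.03) {
  sp <- ape::rcoal(ncl)
  sp$edge.length <- sp$edge.length / max(ape::node.depth.edgelength(sp)) *
    sp_depth
  subs <- lapply(seq_len(ncl), function(i) {
    t <- ape::rcoal(n_per)
    t$edge.length <- t$edge.length * theta / 2
    t$tip.label <- sprintf("c%d_%d", i, seq_len(n_per))
    t
  })
  dmax <- max(vapply(subs, function(t)
    max(ape::node.depth.edgelength(t)), numeric(1)))
  out <- sp
  for (i in seq_len(ncl)) {
    tipidx <- which(out$tip.label == sp$tip.label[i])
    e <- which(out$edge[, 2] == tipidx)
    out$edge.length[e] <- out$edge.length[e] + min_stem +
      (dmax - max(ape::node.depth.edgelength(subs[[i]])))
    out <- ape::bind.tree(out, subs[[i]], where = tipidx)
  }
  out
}

# brute-force best-gap bipartition: enumerate all 2-subsets, score by
# min-between minus max-within (empty within scored -Inf)
best_gap_bipartition <- function(d) {
  n <- nrow(d)
  best <- list(score = -Inf, part = rep(1L, n))
  for (code in 1:(2^(n - 1) - 1)) {
    part <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    same <- outer(part, part, `==`)
    within <- d[same & upper.tri(d)]
    if (length(within) == 0L) next
    between <- d[!same & upper.tri(d)]
    score <- min(between) - max(within)
    if (score > best$score) best <- list(score = score, part = part)
  }
  best
}
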