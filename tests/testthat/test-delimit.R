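test_that("pairwise distances match hand-computed p and JC69 values", {
  aln <- locus_alignment("sp", "coi", c("a", "b"),
                         c(strrep("A", 10), paste0("T", strrep("A", 9))))
  Dp <- pairwise_distances(aln, "p-distance")
  expect_equal(Dp$d["a", "b"], 0.1)
  Dj <- pairwise_distances(aln, "JC69")
  expect_equal(Dj$d["a", "b"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(Dj$d["a", "b"], 0.107326, tolerance = 1e-5)

  ident <- locus_alignment("sp", "coi", c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(pairwise_distances(ident, "p-distance")$d["a", "b"], 0)
  expect_equal(pairwise_distances(ident, "JC69")$d["a", "b"], 0)

  tri <- locus_alignment("sp", "coi", c("a", "b", "c"),
                         c("AAAA", "AATT", "TTTT"))
  D <- pairwise_distances(tri)$d
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # saturated pair flagged under JC69
  sat <- locus_alignment("sp", "coi", c("a", "b"), c("AAAA", "TTTT"))
  Dsat <- pairwise_distances(sat, "JC69")
  expect_true(Dsat$saturated["a", "b"])
  expect_true(is.na(Dsat$d["a", "b"]))
  # pairwise distances agree with the ape reference on clean data
  set.seed(3)
  seqs <- replicate(5, paste(sample(c("a", "c", "g", "t"), 60, TRUE),
                             collapse = ""))
  aln5 <- locus_alignment("sp", "coi", paste0("s", 1:5), seqs)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    do.call(rbind, strsplit(seqs, ""))), model = "raw"))
  expect_equal(unname(pairwise_distances(aln5)$d), unname(ref),
               tolerance = 1e-12)
})

test_that("gap partitioning separates planted clusters and leaves single clusters whole", {
  D1 <- block_dist(c(3, 3), within = 0.01, between = 0.10)
  r1 <- gap_delimit(D1)
  expect_equal(r1$n_lineages, 2)
  expect_equal(unname(r1$assignment), c(1, 1, 1, 2, 2, 2))

  # single tight cluster
  D2 <- block_dist(6, within = 0.01)
  expect_equal(gap_delimit(D2)$n_lineages, 1)

  # three equidistant clusters
  D3 <- block_dist(c(3, 3, 3), within = 0.005, between = 0.12)
  r3 <- gap_delimit(D3)
  expect_equal(r3$n_lineages, 3)
  expect_equal(length(unique(r3$assignment[1:3])), 1)

  # too few tips: warning, single lineage
  expect_warning(r <- gap_delimit(block_dist(c(1, 1), between = 0.2)),
                 "fewer than 3")
  expect_equal(r$n_lineages, 1)
})

test_that("gap partition equals the brute-force best-gap bipartition on small matrices", {
  set.seed(21)
  for (r in 1:25) {
    n <- sample(4:7, 1)
    k1 <- sample(2:(n - 2), 1)
    grp <- c(rep(1, k1), rep(2, n - k1))
    d <- matrix(0, n, n)
    within <- runif(1, 0.002, 0.012)
    between <- runif(1, 0.06, 0.2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- if (grp[i] == grp[j])
        runif(1, 0, within) else runif(1, between, between * 1.3)
    }
    oracle <- best_gap_bipartition(d)
    got <- gap_delimit(dist_matrix(d))
    expect_equal(got$n_lineages, 2)
    agree <- got$assignment == got$assignment[1]
    expect_true(all(agree == (oracle$part == oracle$part[1])))
  }
  # no planted structure: uniform distances stay together
  for (r in 1:10) {
    n <- sample(4:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.004, 0.012)
    d <- d + t(d)
    expect_equal(gap_delimit(dist_matrix(d))$n_lineages, 1)
  }
})

test_that("merge-path gap scoring splits planted clusters only", {
  r <- merge_delimit(block_dist(c(3, 3), within = 0.01, between = 0.10))
  expect_equal(r$n_lineages, 2)
  expect_gte(r$support, 0.09)

  expect_equal(merge_delimit(block_dist(6, within = 0.01))$n_lineages, 1)

  # equal distances: no positive-gap partition
  d4 <- matrix(0.2, 4, 4); diag(d4) <- 0
  expect_equal(merge_delimit(dist_matrix(d4))$n_lineages, 1)

  r3 <- merge_delimit(block_dist(c(3, 3, 3), within = 0.005, between = 0.12))
  expect_equal(r3$n_lineages, 3)
})

test_that("UPGMA trees have the hand-computed heights and are ultrametric", {
  # 2 tips at distance 0.2: root at height 0.1
  t2 <- upgma_tree(dist_matrix(matrix(c(0, .2, .2, 0), 2, 2,
                                      dimnames = list(c("A", "B"),
                                                      c("A", "B")))))
  expect_equal(max(ape::node.depth.edgelength(t2)), 0.1)

  # d(A,B)=0.1, d(A,C)=d(B,C)=0.4: (A,B) at 0.05, root at 0.2
  d3 <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_tree(dist_matrix(d3))
  h <- sort(ape::branching.times(t3))
  expect_equal(unname(h), c(0.05, 0.2))
  expect_true(is_ultrametric_tree(t3))
  expect_true(ape::is.binary(t3))

  # property: ultrametric and binary for random matrices
  set.seed(8)
  for (r in 1:10) {
    n <- sample(4:12, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 0.5)
    d <- d + t(d)
    tr <- upgma_tree(dist_matrix(d))
    expect_true(is_ultrametric_tree(tr))
    expect_true(ape::is.binary(tr))
    expect_equal(length(tr$tip.label), n)
  }
})

test_that("the GMYC alternative never falls below the nested null", {
  set.seed(12)
  for (r in 1:15) {
    tr <- ape::rcoal(sample(4:15, 1))
    f <- gmyc_fit(tr)$fit
    expect_gte(f$logL_alt, f$logL_null - 1e-9)
    expect_gte(f$LR, 0)
    expect_gte(f$p_value, 0)
    expect_lte(f$p_value, 1)
  }
})

test_that("the fast GMYC threshold profile matches the interval-sweep likelihood", {
  set.seed(13)
  for (r in 1:8) {
    tr <- ape::rcoal(sample(4:12, 1))
    h <- lineagescan:::adjust_heights(tr)
    prof <- lineagescan:::gmyc_profile(tr, h = h)
    slow <- vapply(prof$thresholds, function(T)
      lineagescan:::gmyc_loglik(tr, T, h = h)$logL, numeric(1))
    expect_equal(prof$logL, slow, tolerance = 1e-8)
  }
})

test_that("GMYC recovers planted clusters with strong support", {
  set.seed(14)
  nrep <- 20
  out <- replicate(nrep, {
    g <- gmyc_fit(planted_gmyc_tree(8, 6))
    c(sig = g$fit$p_value < 0.05, K = g$fit$n_entities)
  })
  expect_gte(mean(out["sig", ]), 0.9)
  expect_equal(median(out["K", ]), 8)
  expect_lte(mean(abs(out["K", ] - 8)), 1)
})

test_that("GMYC rejects degenerate and malformed inputs", {
  # all node heights equal -> null model
  star_d <- matrix(0.2, 4, 4); diag(star_d) <- 0
  tr <- upgma_tree(dist_matrix(star_d))
  g <- gmyc_fit(tr)
  expect_equal(g$fit$p_value, 1)
  expect_equal(g$result$n_lineages, 1)

  bad <- ape::rtree(6)  # non-ultrametric
  expect_error(gmyc_fit(bad), "ultrametric")
  expect_error(gmyc_fit(ape::rcoal(2)), "at least 3")
})

test_that("all methods report one lineage for identical sequences and ignore tip order", {
  aln <- locus_alignment("sp", "coi", paste0("s", 1:6),
                         rep(strrep("ACGT", 25), 6))
  res <- delimit_alignment(aln)
  for (r in res) expect_equal(r$n_lineages, 1)

  # permutation invariance on a structured alignment
  w <- generate_world(tiny_config())
  hid <- w$truth$labels$species[w$truth$labels$hidden][1]
  aln <- w$alignments[[paste(hid, "coi", sep = "|")]]
  base_res <- delimit_alignment(aln)
  set.seed(30)
  perm <- sample(length(aln$ids))
  perm_aln <- locus_alignment(aln$species, aln$locus, aln$ids[perm],
                              aln$sequences[perm])
  perm_res <- delimit_alignment(perm_aln)
  for (m in names(base_res))
    expect_equal(perm_res[[m]]$n_lineages, base_res[[m]]$n_lineages)
})

test_that("pooled per-locus GMYC assigns per-species lineage counts", {
  w <- generate_world(world_config(n_species = 8, p_hidden = 0.5,
                                   n_seqs_per_species = 10, grid_size = 10,
                                   seed = 9L))
  d <- delimit_all(w$alignments, methods = "gmyc")
  tab <- d$table
  expect_true(all(tab$method == "gmyc"))
  truth <- w$truth$labels
  tab$k <- truth$k[match(tab$species, truth$species)]
  coi <- tab[tab$locus == "coi", ]
  expect_gte(mean(coi$n_lineages == coi$k), 0.7)
})
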