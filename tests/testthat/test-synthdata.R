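test_that("world generation is deterministic and balances the hidden class", {
  w1 <- generate_world(tiny_config())
  w2 <- generate_world(tiny_config())
  expect_identical(w1$alignments, w2$alignments)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(w1$traits, w2$traits)
  expect_equal(sum(w1$truth$labels$hidden), round(6 * 0.5))

  w3 <- generate_world(world_config(n_species = 10, p_hidden = 0.6,
                                    n_seqs_per_species = 6, grid_size = 10,
                                    seed = 1L))
  expect_equal(sum(w3$truth$labels$hidden), 6)

  # every sequence id appears exactly once in occurrences
  occ_ids <- w1$occurrences$sequence_id
  all_ids <- unique(unlist(lapply(w1$alignments, `[[`, "ids")))
  expect_true(all(all_ids %in% occ_ids))
  expect_false(anyDuplicated(occ_ids[!is.na(occ_ids)]) > 0)
})

test_that("hidden species show a barcode gap under exhaustive pair enumeration", {
  cfg <- world_config(n_species = 8, p_hidden = 0.5, theta_within = 0.005,
                      d_between = 0.10, n_seqs_per_species = 8,
                      grid_size = 10, seed = 7L)
  w <- generate_world(cfg)
  lin <- w$truth$lineages
  for (s in w$truth$labels$species) {
    aln <- w$alignments[[paste(s, "coi", sep = "|")]]
    d <- pairwise_distances(aln, "p-distance")$d
    grp <- lin$lineage_id[match(aln$ids, lin$sequence_id)]
    same <- outer(grp, grp, `==`) & upper.tri(d)
    diff <- outer(grp, grp, `!=`) & upper.tri(d)
    if (w$truth$labels$hidden[w$truth$labels$species == s]) {
      expect_lt(max(d[same]), 0.05)
      expect_gt(min(d[diff]), 0.05)
    } else {
      expect_lt(max(d[same]), cfg$d_between)
    }
  }
})

test_that("p_hidden = 0 gives single-lineage species below the divergence scale", {
  w <- generate_world(world_config(n_species = 5, p_hidden = 0,
                                   n_seqs_per_species = 6, grid_size = 10,
                                   seed = 3L))
  expect_false(any(w$truth$labels$hidden))
  for (aln in w$alignments) {
    d <- pairwise_distances(aln, "p-distance")$d
    expect_lt(max(d), 0.08)
  }
})

test_that("config validation names the offending field", {
  expect_error(world_config(p_hidden = 1.2), "p_hidden")
  expect_error(world_config(d_between = 0.001, theta_within = 0.005),
               "d_between")
  expect_error(world_config(missing_rate = 1), "missing_rate")
  expect_error(world_config(grid_size = 1), "grid_size")
  expect_error(world_config(n_occ_per_species = 2, n_seqs_per_species = 5),
               "n_occ_per_species")
})

test_that("environmental grids are named, sized, and retrievable", {
  cfg <- tiny_config()
  grids <- generate_env_grids(cfg)
  expect_gte(length(grids), 6)
  expect_true(all(c("annual_precip", "precip_seasonality", "mean_temp",
                    "isothermality", "npp") %in% names(grids)))
  g <- grids$annual_precip
  expect_equal(dim(g$values), c(20, 20))
  # constant grid: extraction returns the constant, SD 0
  const <- env_grid("flat", 0, 0, 1, matrix(3.5, 2, 2))
  occ <- data.frame(lat = c(0.2, 1.7), lon = c(0.3, 1.1))
  s <- extract_env_summaries(occ, list(const))
  expect_equal(unname(s["flat_mean"]), 3.5)
  expect_equal(unname(s["flat_sd"]), 0)
})

test_that("the spread multiplier inflates per-species environmental SD of hidden species", {
  cfg <- world_config(n_species = 60, p_hidden = 0.5, n_seqs_per_species = 6,
                      env_sd_hidden_multiplier = 3, grid_size = 40, seed = 11L)
  w <- generate_world(cfg)
  sds <- vapply(w$truth$labels$species, function(s) {
    occ <- w$occurrences[w$occurrences$species == s, ]
    unname(extract_env_summaries(occ, w$env_grids["annual_precip"],
                                 s)["annual_precip_sd"])
  }, numeric(1))
  hid <- w$truth$labels$hidden
  wt <- wilcox.test(sds[hid], sds[!hid], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("with multiplier 1 the class spread signal is absent", {
  cfg <- world_config(n_species = 60, p_hidden = 0.5, n_seqs_per_species = 6,
                      env_sd_hidden_multiplier = 1, grid_size = 40, seed = 11L)
  w <- generate_world(cfg)
  spread <- vapply(w$truth$labels$species, function(s) {
    occ <- w$occurrences[w$occurrences$species == s, ]
    sd(occ$lat) + sd(occ$lon)
  }, numeric(1))
  hid <- w$truth$labels$hidden
  wt <- wilcox.test(spread[hid], spread[!hid])
  expect_gt(wt$p.value, 0.05)
})

test_that("trait masking is MCAR at the requested rate and spares the id column", {
  tab <- data.frame(species = sprintf("s%03d", 1:100),
                    a = rnorm(100), b = rnorm(100), c = rnorm(100),
                    d = rnorm(100), e = rnorm(100), f = rnorm(100),
                    g = rnorm(100), h = rnorm(100), i = rnorm(100),
                    j = rnorm(100), stringsAsFactors = FALSE)
  expect_identical(mask_traits(tab, 0), tab)
  m <- mask_traits(tab, 0.2, seed = 4L)
  expect_false(anyNA(m$species))
  n_cells <- 100 * 10
  n_miss <- sum(is.na(m[-1]))
  bounds <- qbinom(c(0.005, 0.995), n_cells, 0.2)
  expect_gte(n_miss, bounds[1])
  expect_lte(n_miss, bounds[2])
  expect_error(mask_traits(tab, 1), "missing_rate")
})

test_that("worlds round-trip through the plain-text layout", {
  w <- generate_world(tiny_config())
  dir <- withr::local_tempdir()
  write_world(w, dir)
  # FASTA round trip
  a0 <- w$alignments[[1]]
  a1 <- read_locus_alignment(
    file.path(dir, "alignments", sprintf("%s_%s.fasta", a0$species, a0$locus)),
    a0$species, a0$locus)
  expect_identical(a1$sequences, a0$sequences)
  expect_identical(a1$ids, a0$ids)
  # grid round trip
  g0 <- w$env_grids$npp
  g1 <- read_env_grid(file.path(dir, "grids", "npp.grid"))
  expect_equal(g1$values, g0$values, tolerance = 1e-9)
  expect_equal(g1$origin_lat, g0$origin_lat)
  expect_equal(g1$cell_size, g0$cell_size)
  occ <- read.csv(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ), nrow(w$occurrences))
})
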