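# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic hidden-lineage world
#'
#' Collects every knob of the generator. The defaults describe the study
#' conditions emulated by the package's benchmarks: ~80 nominal species of
#' which ~60% harbour two divergent lineages separated by a clear barcode
#' gap, a dozen barcode sequences per species each tied to a georeferenced
#' occurrence, smooth continental-scale environmental surfaces, and a trait
#' table with missing-at-random gaps.
#'
#' @param n_species Number of nominal species.
#' @param p_hidden Fraction of species planted with more than one lineage;
#'   exactly `round(n_species * p_hidden)` species are hidden.
#' @param k_lineages Lineages per hidden species (>= 2).
#' @param seq_length Alignment columns per locus.
#' @param theta_within Expected within-lineage pairwise diversity
#'   (substitutions/site).
#' @param d_between Between-lineage divergence (substitutions/site); must
#'   exceed `theta_within` so a barcode gap exists by construction.
#' @param species_divergence Substitutions/site from the shared locus root to
#'   each species ancestor; sets the interspecific scale of the pooled
#'   per-locus tree (pairwise p-distance between species is roughly
#'   `3/4 (1 - exp(-8 species_divergence / 3))`).
#' @param n_seqs_per_species Sequenced individuals per species.
#' @param n_occ_per_species Occurrence points per species; must be >=
#'   `n_seqs_per_species` (the first `n_seqs_per_species` points carry the
#'   sequence ids, any extras are unsequenced records).
#' @param grid_size Environmental raster cells per side.
#' @param env_sd_hidden_multiplier Inflation (>= 1) of the occurrence-cluster
#'   spread of hidden species; at 1 the hidden and not-hidden classes have the
#'   same marginal spread and the environmental-SD signal is removed.
#' @param missing_rate Probability that an imputable trait cell is masked.
#' @param locus2_rate Probability that a species also has the second locus
#'   (`cytb`); the first locus (`coi`) is always present, emulating sparse
#'   locus overlap.
#' @param base_spread_deg Baseline per-axis occurrence spread (decimal
#'   degrees) of a not-hidden species.
#' @param bbox Geographic bounding box `c(lat_min, lat_max, lon_min, lon_max)`
#'   covered by the environmental grids.
#' @param seed Integer seed; fully determines the world.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(n_species = 80, p_hidden = 0.6, k_lineages = 2,
                         seq_length = 600, theta_within = 0.005,
                         d_between = 0.08, species_divergence = 0.15,
                         n_seqs_per_species = 20,
                         n_occ_per_species = n_seqs_per_species,
                         grid_size = 50, env_sd_hidden_multiplier = 3,
                         missing_rate = 0.2, locus2_rate = 0.25,
                         base_spread_deg = 1.5,
                         bbox = c(15, 65, -135, -55), seed = 1L) {
  cfg <- list(n_species = n_species, p_hidden = p_hidden,
              k_lineages = k_lineages, seq_length = seq_length,
              theta_within = theta_within, d_between = d_between,
              species_divergence = species_divergence,
              n_seqs_per_species = n_seqs_per_species,
              n_occ_per_species = n_occ_per_species, grid_size = grid_size,
              env_sd_hidden_multiplier = env_sd_hidden_multiplier,
              missing_rate = missing_rate, locus2_rate = locus2_rate,
              base_spread_deg = base_spread_deg, bbox = bbox,
              seed = as.integer(seed))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid config field '%s': %s", field, msg))
  chk(cfg$n_species >= 1, "n_species", "must be >= 1")
  chk(cfg$p_hidden >= 0 && cfg$p_hidden <= 1, "p_hidden", "must be in [0, 1]")
  chk(cfg$k_lineages >= 2, "k_lineages", "must be >= 2")
  chk(cfg$seq_length >= 1, "seq_length", "must be >= 1")
  chk(cfg$theta_within >= 0, "theta_within", "must be >= 0")
  chk(cfg$d_between > cfg$theta_within, "d_between",
      "must exceed theta_within (barcode gap by construction)")
  chk(cfg$species_divergence >= cfg$d_between / 2, "species_divergence",
      "must be at least d_between / 2 (species at least as far apart as their lineages)")
  chk(cfg$n_seqs_per_species >= 1, "n_seqs_per_species", "must be >= 1")
  chk(cfg$n_occ_per_species >= cfg$n_seqs_per_species, "n_occ_per_species",
      "must be >= n_seqs_per_species")
  chk(cfg$grid_size >= 2, "grid_size", "must be >= 2")
  chk(cfg$env_sd_hidden_multiplier >= 1, "env_sd_hidden_multiplier",
      "must be >= 1")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
      "must be in [0, 1)")
  chk(cfg$locus2_rate >= 0 && cfg$locus2_rate <= 1, "locus2_rate",
      "must be in [0, 1]")
  chk(cfg$base_spread_deg > 0, "base_spread_deg", "must be > 0")
  chk(length(cfg$bbox) == 4 && cfg$bbox[1] < cfg$bbox[2] &&
        cfg$bbox[3] < cfg$bbox[4], "bbox",
      "must be c(lat_min, lat_max, lon_min, lon_max) with min < max")
  n_priv <- round(cfg$d_between * cfg$seq_length / 2)
  chk(cfg$k_lineages * n_priv <= cfg$seq_length, "d_between",
      "k_lineages * d_between/2 private sites exceed the sequence length")
  invisible(cfg)
}

BASES <- c("A", "C", "G", "T")

# Substitute each site independently with probability `rate`, drawing a
# different base uniformly (Jukes-Cantor-style single draw).
mutate_seq <- function(x, rate) {
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(BASES, x[i]), 1L)
  x
}

# Evolve n sequences from a lineage ancestor down a simulated Kingman
# coalescent genealogy scaled so the expected pairwise diversity is theta.
# Per-branch substitution probability uses the exact Jukes-Cantor mapping
# 3/4 (1 - exp(-4t/3)) from branch length t (substitutions/site).
sim_lineage_seqs <- function(anc, n, theta) {
  if (n == 1L)
    return(list(mutate_seq(anc, 0.75 * (1 - exp(-4 * (theta / 2) / 3)))))
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * theta / 2
  N <- n + tr$Nnode
  seqs <- vector("list", N)
  seqs[[n + 1L]] <- anc  # root
  for (e in rev(ape::postorder(tr))) {  # parents before children
    p <- tr$edge[e, 1L]; c <- tr$edge[e, 2L]
    rate <- 0.75 * (1 - exp(-4 * tr$edge.length[e] / 3))
    seqs[[c]] <- mutate_seq(seqs[[p]], rate)
  }
  seqs[seq_len(n)][order(as.integer(sub("^t", "", tr$tip.label)))]
}

#' Generate a synthetic world with planted hidden-lineage structure
#'
#' Builds, under full seed control, (i) per species x locus alignments in
#' which hidden species consist of `k_lineages` lineages whose ancestors
#' carry disjoint private substitutions (guaranteeing a barcode gap of about
#' `d_between`) and within-lineage variation arises on a simulated Kingman
#' coalescent genealogy scaled to expected pairwise diversity `theta_within`,
#' (ii) occurrence points drawn from spatially offset per-lineage clusters,
#' (iii) smooth environmental raster layers, (iv) a life-history trait table
#' with missing-at-random cells, and (v) the ground truth for all of it.
#'
#' @param cfg A [world_config()].
#' @return An object of class `synthetic_world`: list with elements
#'   `config`, `alignments` (named `"species|locus"`), `occurrences`
#'   (data.frame species, lineage_id, lat, lon, sequence_id), `env_grids`,
#'   `traits` (masked) and `truth` (list: `labels` data.frame with
#'   species/hidden/k, `lineages` data.frame with per-sequence lineage
#'   assignment, `traits_full` unmasked trait table).
#' @export
generate_world <- function(cfg) {
  if (!inherits(cfg, "world_config")) cfg <- do.call(world_config, cfg)
  validate_world_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_species
    species <- sprintf("sp%03d", seq_len(n))
    n_hidden <- round(n * cfg$p_hidden)
    hidden <- rep(FALSE, n)
    hidden[sample.int(n, n_hidden)] <- TRUE

    env_grids <- generate_env_grids(cfg, .reseed = FALSE)

    L <- cfg$seq_length
    n_priv <- round(cfg$d_between * L / 2)
    base <- cfg$base_spread_deg
    mult <- cfg$env_sd_hidden_multiplier
    margin <- mult * base * 3
    lat_rng <- c(cfg$bbox[1] + margin, cfg$bbox[2] - margin)
    lon_rng <- c(cfg$bbox[3] + margin, cfg$bbox[4] - margin)
    if (lat_rng[1] >= lat_rng[2] || lon_rng[1] >= lon_rng[2])
      stop("invalid config field 'bbox': too small for the cluster spread")

    # shared per-locus root sequences: all species descend from them, giving
    # the pooled per-locus tree a realistic interspecific scale
    root_seq <- list(coi = sample(BASES, L, replace = TRUE),
                     cytb = sample(BASES, L, replace = TRUE))
    sp_rate <- 0.75 * (1 - exp(-4 * cfg$species_divergence / 3))

    alignments <- list()
    occ <- vector("list", n)
    lin_truth <- vector("list", n)
    for (s in seq_len(n)) {
      k <- if (hidden[s]) cfg$k_lineages else 1L
      nseq <- cfg$n_seqs_per_species
      nocc <- cfg$n_occ_per_species
      # lineage assignment: as even as possible, at least one per lineage
      lin_seq <- sort(rep_len(seq_len(k), nseq))
      lin_extra <- if (nocc > nseq) sort(rep_len(seq_len(k), nocc - nseq))
                   else integer(0)
      ids <- sprintf("%s_i%02d", species[s], seq_len(nseq))

      for (locus in c("coi", "cytb")) {
        has_locus <- locus == "coi" || stats::runif(1) < cfg$locus2_rate
        # draw locus RNG deterministically even when dropped? dropout draw
        # above consumes one uniform; sequence draws only when present.
        if (!has_locus) next
        anc <- mutate_seq(root_seq[[locus]], sp_rate)
        lin_anc <- vector("list", k)
        if (k == 1L) {
          lin_anc[[1]] <- anc
        } else {
          site_pool <- sample.int(L, k * n_priv)
          for (j in seq_len(k)) {
            a <- anc
            priv <- site_pool[((j - 1L) * n_priv + 1L):(j * n_priv)]
            for (i in priv) a[i] <- sample(setdiff(BASES, a[i]), 1L)
            lin_anc[[j]] <- a
          }
        }
        seqs <- character(nseq)
        for (j in seq_len(k)) {
          members <- which(lin_seq == j)
          lseqs <- sim_lineage_seqs(lin_anc[[j]], length(members),
                                    cfg$theta_within)
          seqs[members] <- vapply(lseqs, paste, character(1), collapse = "")
        }
        alignments[[paste(species[s], locus, sep = "|")]] <-
          locus_alignment(species[s], locus, ids, seqs)
      }

      # occurrence clusters: lineage centres on a circle of radius r around
      # the species centre; per-axis spread sigma_w. Chosen so the marginal
      # per-axis SD is base*mult for hidden and base for not-hidden species
      # (identical when mult = 1, so the class signal is the multiplier only).
      ctr <- c(stats::runif(1, lat_rng[1], lat_rng[2]),
               stats::runif(1, lon_rng[1], lon_rng[2]))
      if (k == 1L) {
        r <- 0; sigma_w <- base
      } else {
        r <- base * mult
        sigma_w <- base * mult / sqrt(2)
      }
      rot <- stats::runif(1, 0, 2 * pi)
      ang <- rot + 2 * pi * (seq_len(k) - 1L) / k
      centres <- cbind(ctr[1] + r * sin(ang), ctr[2] + r * cos(ang))
      lin_all <- c(lin_seq, lin_extra)
      pts <- centres[lin_all, , drop = FALSE] +
        matrix(stats::rnorm(2 * nocc, 0, sigma_w), ncol = 2)
      pts[, 1] <- pmin(pmax(pts[, 1], cfg$bbox[1]), cfg$bbox[2])
      pts[, 2] <- pmin(pmax(pts[, 2], cfg$bbox[3]), cfg$bbox[4])
      occ[[s]] <- data.frame(
        species = species[s], lineage_id = lin_all,
        lat = pts[, 1], lon = pts[, 2],
        sequence_id = c(ids, rep(NA_character_, nocc - nseq)),
        stringsAsFactors = FALSE
      )
      lin_truth[[s]] <- data.frame(species = species[s], sequence_id = ids,
                                   lineage_id = lin_seq,
                                   stringsAsFactors = FALSE)
    }
    occurrences <- do.call(rbind, occ)
    rownames(occurrences) <- NULL

    traits_full <- data.frame(
      species = species,
      repro_strategy = sample(c("direct_developing", "larval"), n,
                              replace = TRUE, prob = c(0.4, 0.6)),
      habitat = sample(c("terrestrial", "aquatic", "semiaquatic"), n,
                       replace = TRUE),
      body_size = round(stats::rlnorm(n, log(12), 0.4), 2),
      stringsAsFactors = FALSE
    )
    traits <- mask_traits(traits_full, cfg$missing_rate,
                          seed = cfg$seed + 104729L)

    structure(
      list(config = cfg, alignments = alignments, occurrences = occurrences,
           env_grids = env_grids, traits = traits,
           truth = list(
             labels = data.frame(species = species, hidden = hidden,
                                 k = ifelse(hidden, cfg$k_lineages, 1L),
                                 stringsAsFactors = FALSE),
             lineages = do.call(rbind, lin_truth),
             traits_full = traits_full
           )),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d species (%d hidden), %d alignments, %d occurrences, %d env layers\n",
    x$config$n_species, sum(x$truth$labels$hidden), length(x$alignments),
    nrow(x$occurrences), length(x$env_grids)))
  invisible(x)
}

# ---- environmental grids -------------------------------------------------

#' An environmental raster layer
#'
#' Plain regular lat/lon grid: `values[i, j]` is the cell whose centre is
#' `(origin_lat + (i - 0.5) * cell_size, origin_lon + (j - 0.5) * cell_size)`;
#' the origin is the lower-left corner of the grid.
#'
#' @param name Layer name.
#' @param origin_lat,origin_lon Lower-left corner (decimal degrees).
#' @param cell_size Cell edge (decimal degrees).
#' @param values Numeric matrix (rows index latitude, columns longitude).
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(name, origin_lat, origin_lon, cell_size, values) {
  stopifnot(is.matrix(values), cell_size > 0)
  structure(list(name = name, origin_lat = origin_lat,
                 origin_lon = origin_lon, cell_size = cell_size,
                 values = values),
            class = "env_grid")
}

# smooth standardized random field on a grid_size x grid_size lattice
smooth_field <- function(grid_size) {
  u <- matrix(rep(seq_len(grid_size), grid_size), grid_size) / grid_size
  v <- t(u)
  f <- matrix(0, grid_size, grid_size)
  for (h in 1:4) {
    k1 <- sample(0:3, 1); k2 <- sample(0:3, 1)
    if (k1 == 0 && k2 == 0) k1 <- 1
    f <- f + stats::rnorm(1) *
      sin(2 * pi * (k1 * u + k2 * v) + stats::runif(1, 0, 2 * pi))
  }
  f <- f + stats::rnorm(1) * u + stats::rnorm(1) * v
  (f - mean(f)) / stats::sd(f)
}

#' Generate the named set of environmental raster layers
#'
#' Returns smooth spatial fields over the configured bounding box: four
#' bioclim-like layers (annual precipitation, precipitation seasonality,
#' mean temperature, isothermality), a productivity layer, and two nuisance
#' layers with no planted relationship to anything. The hidden-class
#' environmental-SD signal is *not* in the grids: it comes from the
#' occurrence-cluster spread multiplier in [generate_world()].
#'
#' @param cfg A [world_config()].
#' @param .reseed Internal; set `FALSE` when called from a context that has
#'   already seeded the RNG.
#' @return Named list of [env_grid] objects.
#' @export
generate_env_grids <- function(cfg, .reseed = TRUE) {
  if (!inherits(cfg, "world_config")) cfg <- do.call(world_config, cfg)
  gen <- function() {
    g <- cfg$grid_size
    cell <- max(cfg$bbox[2] - cfg$bbox[1], cfg$bbox[4] - cfg$bbox[3]) / g
    layers <- list(
      annual_precip = c(1200, 400), precip_seasonality = c(30, 12),
      mean_temp = c(12, 8), isothermality = c(40, 10),
      npp = c(0.6, 0.2), nuisance_a = c(0, 1), nuisance_b = c(0, 1)
    )
    out <- list()
    for (nm in names(layers)) {
      f <- smooth_field(g)
      out[[nm]] <- env_grid(nm, cfg$bbox[1], cfg$bbox[3], cell,
                            layers[[nm]][1] + layers[[nm]][2] * f)
    }
    out
  }
  if (.reseed) with_seed(cfg$seed + 7919L, gen()) else gen()
}

#' Mask trait cells completely at random
#'
#' Every imputable cell (all columns except the species identifier) is
#' masked independently with probability `missing_rate`.
#'
#' @param traits Trait data.frame whose first column is the species id.
#' @param missing_rate Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The trait table with masked cells set to `NA`.
#' @export
mask_traits <- function(traits, missing_rate, seed = 1L) {
  if (missing_rate >= 1 || missing_rate < 0)
    stop("missing_rate must be in [0, 1)")
  if (missing_rate == 0) return(traits)
  with_seed(seed, {
    for (j in seq_along(traits)[-1]) {
      hit <- stats::runif(nrow(traits)) < missing_rate
      traits[[j]][hit] <- NA
    }
    traits
  })
}
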