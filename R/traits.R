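#' Per-species environmental summaries at occurrence points
#'
#' Looks up every occurrence point in each raster layer (nearest-cell, no
#' interpolation) and returns the per-layer mean and sample standard
#' deviation (n - 1 denominator). Species with a single point get `NA` SD,
#' to be filled by imputation.
#'
#' @param occ data.frame with columns `lat` and `lon` (one species'
#'   occurrence set).
#' @param grids Named list of [env_grid] layers.
#' @param species Species name used in error messages.
#' @return Named numeric vector: `<layer>_mean` and `<layer>_sd` per layer.
#' @export
extract_env_summaries <- function(occ, grids, species = "?") {
  stopifnot(nrow(occ) >= 1L)
  out <- numeric(0)
  for (g in grids) {
    v <- extract_grid_values(g, occ$lat, occ$lon, species)
    out[paste0(g$name, "_mean")] <- mean(v)
    out[paste0(g$name, "_sd")] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
  }
  out
}

# nearest-cell raster lookup; errors for points outside the grid
extract_grid_values <- function(grid, lat, lon, species = "?") {
  g <- nrow(grid$values)
  gc <- ncol(grid$values)
  i <- floor((lat - grid$origin_lat) / grid$cell_size) + 1L
  j <- floor((lon - grid$origin_lon) / grid$cell_size) + 1L
  # points exactly on the top/right edge belong to the last cell
  i[lat == grid$origin_lat + g * grid$cell_size] <- g
  j[lon == grid$origin_lon + gc * grid$cell_size] <- gc
  bad <- i < 1L | i > g | j < 1L | j > gc
  if (any(bad)) {
    w <- which(bad)[1L]
    stop(sprintf("species %s: point (%.4f, %.4f) outside grid '%s'",
                 species, lat[w], lon[w], grid$name))
  }
  grid$values[cbind(i, j)]
}

#' Per-species geographic summaries
#'
#' Componentwise minimum, maximum, mean and length (max - min) of latitude
#' and longitude. Longitudes are treated as plain numbers: ranges spanning
#' the antimeridian are not wrapped.
#'
#' @param occ data.frame with columns `lat` and `lon`.
#' @return Named numeric vector `lat_min`, `lat_max`, `lat_mean`,
#'   `lat_length`, `lon_min`, `lon_max`, `lon_mean`, `lon_length`.
#' @export
geo_summaries <- function(occ) {
  stopifnot(nrow(occ) >= 1L)
  c(lat_min = min(occ$lat), lat_max = max(occ$lat), lat_mean = mean(occ$lat),
    lat_length = max(occ$lat) - min(occ$lat),
    lon_min = min(occ$lon), lon_max = max(occ$lon), lon_mean = mean(occ$lon),
    lon_length = max(occ$lon) - min(occ$lon))
}

#' Assemble the species x predictor table
#'
#' One row per species: environmental mean/SD per layer, geographic
#' summaries, life-history traits (possibly with missing cells), and the
#' consensus label when provided.
#'
#' @param occurrences data.frame with `species`, `lat`, `lon`.
#' @param grids Named list of [env_grid] layers.
#' @param traits Life-history data.frame keyed by its `species` column.
#' @param labels Optional data.frame `species`, `label`; species without a
#'   label (or labelled `"excluded"`) are dropped.
#' @return data.frame with attribute `"missing"`: the logical matrix of
#'   originally missing predictor cells.
#' @export
build_predictor_table <- function(occurrences, grids, traits, labels = NULL) {
  sp <- unique(occurrences$species)
  if (!is.null(labels)) {
    keep <- labels$species[labels$label != "excluded"]
    sp <- sp[sp %in% keep]
  }
  rows <- lapply(sp, function(s) {
    occ <- occurrences[occurrences$species == s, , drop = FALSE]
    c(extract_env_summaries(occ, grids, s), geo_summaries(occ))
  })
  num <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(data.frame(species = sp, stringsAsFactors = FALSE), num)
  tab <- merge(tab, traits, by = "species", all.x = TRUE, sort = FALSE)
  tab <- tab[match(sp, tab$species), , drop = FALSE]
  if (!is.null(labels)) {
    tab$label <- labels$label[match(sp, labels$species)]
  }
  rownames(tab) <- NULL
  miss <- is.na(as.matrix(tab[setdiff(names(tab), c("species", "label"))]))
  attr(tab, "missing") <- miss
  tab
}

# Bayesian-draw predictive mean matching for one numeric column.
pmm_draw_numeric <- function(Xo, yo, Xm, k_donors) {
  qrX <- qr(Xo)
  r <- qrX$rank
  piv <- qrX$pivot[seq_len(r)]
  Xo <- Xo[, piv, drop = FALSE]
  Xm <- Xm[, piv, drop = FALSE]
  XtX <- crossprod(Xo) + diag(1e-8, r)
  V <- solve(XtX)
  beta <- drop(V %*% crossprod(Xo, yo))
  res <- yo - drop(Xo %*% beta)
  df <- max(length(yo) - r, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  Vs <- (V + t(V)) / 2
  beta_star <- beta + drop(t(chol(Vs)) %*% stats::rnorm(r)) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(p) {
    donors <- order(abs(yhat_obs - p))[seq_len(min(k_donors, length(yo)))]
    yo[sample(donors, 1L)]
  }, numeric(1))
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Numeric columns are imputed by PMM: a Bayesian linear regression of the
#' target on all other predictors is drawn from its sampling distribution,
#' each missing case's prediction is matched to its `k_donors` nearest
#' observed predictions, and one donor's *observed* value is sampled.
#' Categorical columns are imputed by a multinomial-logistic draw
#' ([nnet::multinom]). Columns are visited cyclically until the imputed
#' numeric means stabilise (or `max_sweeps` sweeps). `m` independent
#' completed tables are returned under seed control.
#'
#' @param table data.frame to complete; the columns named in `exclude`
#'   (identifier / response columns) are never imputed nor used as
#'   predictors.
#' @param m Number of imputations (default 15).
#' @param k_donors Donor-pool size for PMM (default 5).
#' @param seed Integer seed.
#' @param exclude Character vector of column names to leave untouched.
#' @param max_sweeps Maximum chained-equation sweeps per imputation.
#' @return List of `m` completed data.frames.
#' @export
pmm_impute <- function(table, m = 15, k_donors = 5, seed = 1L,
                       exclude = "species", max_sweeps = 10) {
  stopifnot(m >= 1, k_donors >= 1)
  cols <- setdiff(names(table), exclude)
  for (cl in cols) {
    n_obs <- sum(!is.na(table[[cl]]))
    if (anyNA(table[[cl]]) && n_obs < max(10, k_donors + 1))
      stop(sprintf("column '%s' has too few observed values (%d)", cl, n_obs))
  }
  if (any(rowSums(!is.na(table[cols])) == 0))
    stop("table contains fully missing rows")
  if (!anyNA(table[cols]))
    return(replicate(m, table, simplify = FALSE))
  lapply(seq_len(m), function(i) {
    with_seed(seed + i * 31L, pmm_impute_once(table, cols, k_donors, max_sweeps))
  })
}

pmm_impute_once <- function(table, cols, k_donors, max_sweeps) {
  filled <- table
  is_num <- vapply(table[cols], is.numeric, logical(1))
  miss <- lapply(table[cols], is.na)
  names(miss) <- cols
  # initial fill: column mean / mode
  for (cl in cols) {
    if (!any(miss[[cl]])) next
    obs <- table[[cl]][!miss[[cl]]]
    init <- if (is.numeric(obs)) mean(obs) else names(sort(table(obs),
                                                           decreasing = TRUE))[1]
    filled[[cl]][miss[[cl]]] <- if (is.numeric(obs)) init else init
  }
  targets <- cols[vapply(miss, any, logical(1))]
  prev_means <- NULL
  for (sweep in seq_len(max_sweeps)) {
    for (cl in targets) {
      others <- setdiff(cols, cl)
      # drop predictors constant in the current fill (degenerate contrasts)
      use <- others[vapply(filled[others],
                           function(x) length(unique(x)) > 1L, logical(1))]
      X <- if (length(use))
        stats::model.matrix(~ ., data = as.data.frame(
          lapply(filled[use], function(x)
            if (is.character(x)) factor(x) else x)))
      else matrix(1, nrow(filled), 1L)
      mrows <- miss[[cl]]
      if (is.numeric(table[[cl]])) {
        filled[[cl]][mrows] <- pmm_draw_numeric(
          X[!mrows, , drop = FALSE], table[[cl]][!mrows],
          X[mrows, , drop = FALSE], k_donors)
      } else {
        y <- factor(table[[cl]][!mrows])
        if (nlevels(y) < 2L) {
          filled[[cl]][mrows] <- levels(y)[1L]
        } else {
          dfit <- data.frame(.y = y, X[!mrows, -1, drop = FALSE])
          fit <- nnet::multinom(.y ~ ., data = dfit, trace = FALSE)
          pr <- stats::predict(
            fit, newdata = data.frame(X[mrows, -1, drop = FALSE]),
            type = "probs")
          if (is.null(dim(pr))) pr <- if (nlevels(y) == 2L)
            cbind(1 - pr, pr) else matrix(pr, nrow = 1)
          filled[[cl]][mrows] <- apply(pr, 1L, function(p)
            sample(levels(y), 1L, prob = p))
        }
      }
    }
    cur_means <- vapply(targets[is_num[match(targets, cols)]],
                        function(cl) mean(filled[[cl]]), numeric(1))
    if (!is.null(prev_means) && length(cur_means) &&
        all(abs(cur_means - prev_means) <=
              1e-4 * pmax(abs(prev_means), 1e-8))) break
    prev_means <- cur_means
  }
  filled
}

#' Pool multiply imputed tables into one
#'
#' Numeric cells: mean across imputations; categorical cells: modal value
#' (ties broken to the lexicographically smallest). Observed cells pass
#' through unchanged (they are identical in every imputation).
#'
#' @param tables List of completed data.frames of identical shape.
#' @return A single completed data.frame.
#' @export
pool_imputations <- function(tables) {
  stopifnot(length(tables) >= 1L)
  shapes <- vapply(tables, function(t) paste(dim(t), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L ||
      !all(vapply(tables, function(t)
        identical(names(t), names(tables[[1]])), logical(1))))
    stop("imputed tables have mismatched shapes")
  out <- tables[[1]]
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) {
      vals <- matrix(vapply(tables, `[[`, numeric(nrow(out)), cl),
                     nrow = nrow(out))
      out[[cl]] <- rowMeans(vals)
    } else {
      vals <- matrix(vapply(tables, function(t) as.character(t[[cl]]),
                            character(nrow(out))), nrow = nrow(out))
      out[[cl]] <- apply(vals, 1L, function(v) {
        tab <- table(v)
        sort(names(tab)[tab == max(tab)])[1L]
      })
    }
  }
  out
}
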