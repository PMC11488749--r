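#' Run the full hidden-lineage pipeline on a synthetic world
#'
#' Chains every stage: world generation, alignment QC, three-method
#' delimitation per species x locus, consensus classification, predictor
#' assembly with pooled PMM imputation, correlation filtering, random-forest
#' training and held-out evaluation, importance ranking and Kruskal-Wallis
#' follow-up of the top predictors.
#'
#' @param cfg A [world_config()] (or list of its arguments).
#' @param scheme Consensus scheme: `"majority_rules"` (default) or
#'   `"all_agree"`.
#' @param cutoff Absolute-correlation cutoff for the predictor filter, or
#'   `NA` to skip filtering.
#' @param m_imputations PMM imputations to pool (default 15).
#' @param train_frac Training fraction (default 0.70).
#' @param cv_folds,cv_repeats Tuning cross-validation design.
#' @param seed Integer seed for split/training randomness (the world has its
#'   own seed inside `cfg`).
#' @return List with components `world`, `qc`, `delimitation`, `votes`,
#'   `consensus`, `predictors` (pooled, imputed), `filtered` (post-filter
#'   table + removal log), `split`, `fit`, `report` (a `model_report`),
#'   `importance_ranking` and `kruskal` (top-5 follow-up tests).
#' @export
run_pipeline <- function(cfg = world_config(), scheme = c("majority_rules",
                                                          "all_agree"),
                         cutoff = 0.90, m_imputations = 15,
                         train_frac = 0.70, cv_folds = 10, cv_repeats = 5,
                         seed = 1L) {
  scheme <- match.arg(scheme)
  world <- generate_world(cfg)
  qc <- qc_screen(world$alignments)
  delim <- delimit_all(qc$alignments)
  votes <- vote_table(delim$results)
  consensus <- if (scheme == "all_agree") consensus_all_agree(votes)
               else consensus_majority(votes)
  predictors <- build_predictor_table(world$occurrences, world$env_grids,
                                      world$traits, labels = consensus)
  imputed <- pmm_impute(predictors, m = m_imputations,
                        seed = seed, exclude = c("species", "label"))
  pooled <- pool_imputations(imputed)
  filtered <- if (is.na(cutoff)) list(table = pooled, removed = character(0))
              else {
                keep <- pooled[setdiff(names(pooled), c("species", "label"))]
                f <- correlation_filter(keep, cutoff)
                list(table = cbind(pooled[c("species", "label")], f$table),
                     removed = f$removed)
              }
  tab <- filtered$table
  split <- stratified_split(tab$label, train_frac = train_frac, seed = seed)
  fit <- train_rf(tab[split$train, , drop = FALSE], cv_folds = cv_folds,
                  cv_repeats = cv_repeats, seed = seed)
  report <- evaluate_classifier(fit, tab[split$test, , drop = FALSE])
  ranking <- rank_importance(list(fit$importance))
  top5 <- utils::head(fit$importance$predictor[order(fit$importance$MDA,
                                                     decreasing = TRUE)], 5)
  top5 <- top5[vapply(tab[top5], is.numeric, logical(1))]
  kw <- kruskal_wallis_top(tab, top5)
  list(world = world, qc = qc, delimitation = delim, votes = votes,
       consensus = consensus, predictors = pooled, filtered = filtered,
       split = split, fit = fit, report = report,
       importance_ranking = ranking, kruskal = kw)
}

#' Compare consensus labels with the planted truth
#'
#' @param consensus Consensus data.frame (from [consensus_majority()] or
#'   [consensus_all_agree()]).
#' @param truth_labels The world's `truth$labels` data.frame.
#' @return List with `n_compared`, `n_correct` and `recovery_rate`
#'   (excluded species are not compared).
#' @export
truth_recovery <- function(consensus, truth_labels) {
  cmp <- merge(consensus[consensus$label != "excluded", ],
               truth_labels, by = "species")
  correct <- (cmp$label == "hidden") == cmp$hidden
  list(n_compared = nrow(cmp), n_correct = sum(correct),
       recovery_rate = if (nrow(cmp)) mean(correct) else NA_real_)
}
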