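#' Convert a delimitation result into a hidden/not-hidden vote
#'
#' A species x locus x method analysis votes "hidden" iff it inferred more
#' than one genetic lineage.
#'
#' @param r A [delimitation_result].
#' @return A one-row data.frame: species, locus, method, hidden (logical).
#' @export
classify_result <- function(r) {
  stopifnot(inherits(r, "delimitation_result"), r$n_lineages >= 1L)
  data.frame(species = r$species, locus = r$locus, method = r$method,
             hidden = r$n_lineages > 1L, stringsAsFactors = FALSE)
}

#' Build the per-species vote table
#'
#' @param results List of [delimitation_result] objects (all loci, all
#'   methods).
#' @return A `vote_table`: data.frame with one row per vote (species, locus,
#'   method, hidden).
#' @export
vote_table <- function(results) {
  votes <- do.call(rbind, lapply(results, classify_result))
  structure(votes, class = c("vote_table", "data.frame"))
}

consensus_df <- function(votes, scheme, label_fun) {
  sp <- unique(votes$species)
  out <- lapply(sp, function(s) {
    v <- votes$hidden[votes$species == s]
    data.frame(species = s, scheme = scheme,
               label = label_fun(sum(v), sum(!v)),
               votes_for = sum(v), votes_against = sum(!v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Strict (all-agree) consensus classification
#'
#' A species is labelled hidden or not hidden only when every vote across
#' methods and loci agrees; any conflict excludes the species.
#'
#' @param votes A [vote_table()].
#' @return data.frame: species, scheme, label (`"hidden"`, `"not_hidden"`,
#'   `"excluded"`), votes_for, votes_against.
#' @export
consensus_all_agree <- function(votes) {
  consensus_df(votes, "all_agree", function(f, a) {
    if (f > 0 && a > 0) "excluded" else if (f > 0) "hidden" else "not_hidden"
  })
}

#' Majority-rules consensus classification
#'
#' Each species takes the majority label over its pooled, equally weighted
#' votes; exact ties go to "hidden" (the scheme exists to flag candidates
#' for further taxonomic evaluation, so ties err toward flagging). No
#' species is ever excluded.
#'
#' @param votes A [vote_table()].
#' @return data.frame as in [consensus_all_agree()], scheme
#'   `"majority_rules"`, label never `"excluded"`.
#' @export
consensus_majority <- function(votes) {
  consensus_df(votes, "majority_rules", function(f, a) {
    if (f >= a) "hidden" else "not_hidden"
  })
}
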