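# Penalized score a voter assigns a gene: Rank(.) is the patient's normalized
# score (0 for genes the voter never scored); the penalty factor is 1 for
# genes mutated in that patient and `delta` otherwise.
voter_scores <- function(ranked, mutated, candidates, delta) {
  r <- numeric(length(candidates))
  idx <- match(ranked$gene, candidates)
  hit <- !is.na(idx)
  r[idx[hit]] <- ranked$rank_score[hit]
  pen <- ifelse(candidates %in% mutated, 1, delta)
  list(rank = r, penalized = pen * r)
}

#' Pairwise winner between two genes for one patient
#'
#' Gene A wins exactly when `delta(A) * Rank(A) > delta(B) * Rank(B)`, where
#' `Rank(.)` is the voter's normalized score (0 for a gene the voter did not
#' score) and `delta(.)` is 1 for a gene mutated in that patient and the
#' penalty `delta` otherwise. Ties fall to B (the "otherwise" branch), so the
#' argument order is the tie-break.
#'
#' @param geneA,geneB Gene symbols.
#' @param voter A `patient_ranking`.
#' @param delta Penalty in `[0, 1]` (default 0.85).
#' @return `geneA` or `geneB`.
#' @examples
#' # a mutated gene at 0.90 beats an unmutated gene at 1.00 when delta = 0.85
#' @export
pairwise_winner <- function(geneA, geneB, voter, delta = 0.85) {
  stopifnot(inherits(voter, "patient_ranking"))
  ranked <- rank_patient(voter)
  s <- voter_scores(ranked, voter$mutated, c(geneA, geneB), delta)$penalized
  if (s[1L] > s[2L]) geneA else geneB
}

#' Aggregate per-patient rankings into a cohort-level driver ranking
#'
#' Every unordered pair of candidate genes is compared within every patient
#' using the penalized pairwise rule; a gene beats another overall when it
#' wins in strictly more patients. Genes are then ordered by Copeland tally
#' (pairs beaten minus pairs lost), with ties broken by the summed per-patient
#' normalized score and then lexicographically. The candidate set is the union
#' of each patient's `candidate_pool` best genes (spec: all scored genes when
#' the pool is large enough); a gene outside a patient's scored set gets
#' normalized score 0 for that patient.
#'
#' @param rankings A non-empty list of `patient_ranking` objects.
#' @param config A [mecorank_config()] supplying `delta`, `top_k` and
#'   `candidate_pool`.
#' @param known_drivers Optional character vector; adds a `known_driver`
#'   column to the table.
#' @return An object of class `aggregate_ranking`: a list with `table` (data
#'   frame: `rank`, `gene`, `copeland`, `score` in `[0, 1]`,
#'   `n_patients_mutated`, optionally `known_driver`), `top_k` (character
#'   vector, the first `min(top_k, n)` genes), `n_voters` and `delta`.
#' @export
condorcet_aggregate <- function(rankings, config = mecorank_config(),
                                known_drivers = NULL) {
  if (!length(rankings)) {
    stop("need at least one patient ranking", call. = FALSE)
  }
  stopifnot(all(vapply(rankings, inherits, logical(1), "patient_ranking")))
  delta <- config$delta
  tabs <- lapply(rankings, rank_patient)
  pool <- config$candidate_pool
  cand <- sort_genes(unlist(lapply(tabs, function(t) {
    utils::head(t$gene, if (is.finite(pool)) pool else nrow(t))
  })))
  G <- length(cand)
  nv <- length(rankings)
  n_mut <- integer(G)
  rank_sum <- numeric(G)
  if (G == 1L) {
    copeland <- 0L
  } else {
    M <- matrix(0L, G, G)   # M[i, j] = #voters with s_i strictly > s_j
    for (v in seq_len(nv)) {
      s <- voter_scores(tabs[[v]], rankings[[v]]$mutated, cand, delta)
      rank_sum <- rank_sum + s$rank
      n_mut <- n_mut + (cand %in% rankings[[v]]$mutated)
      M <- M + (outer(s$penalized, s$penalized, `>`) + 0L)
    }
    # For the pair (i, j) with i before j, i collects M[i, j] voters and j the
    # remaining nv - M[i, j] (ties go to the later-ordered gene).
    S <- sign(2L * M - nv)
    S[lower.tri(S, diag = TRUE)] <- 0L
    copeland <- as.integer(rowSums(S) - colSums(S))
  }
  if (G == 1L) {
    for (v in seq_len(nv)) {
      s <- voter_scores(tabs[[v]], rankings[[v]]$mutated, cand, delta)
      rank_sum <- rank_sum + s$rank
      n_mut <- n_mut + (cand %in% rankings[[v]]$mutated)
    }
  }
  score <- if (max(copeland) == min(copeland)) {
    rep(1, G)
  } else {
    (copeland - min(copeland)) / (max(copeland) - min(copeland))
  }
  ord <- order(-copeland, -rank_sum, cand, method = "radix")
  tab <- data.frame(
    rank = seq_len(G),
    gene = cand[ord],
    copeland = copeland[ord],
    score = score[ord],
    n_patients_mutated = n_mut[ord],
    stringsAsFactors = FALSE
  )
  if (!is.null(known_drivers)) {
    tab$known_driver <- tab$gene %in% known_drivers
  }
  agg <- structure(
    list(table = tab, n_voters = nv, delta = delta),
    class = "aggregate_ranking"
  )
  agg$top_k <- select_top_k(agg, config$top_k)
  agg
}

#' Select the top-k genes of an aggregate ranking
#'
#' @param agg An `aggregate_ranking`.
#' @param k Positive integer; clamped to the number of genes.
#' @return Character vector: the first `min(k, n)` genes in aggregate order.
#' @export
select_top_k <- function(agg, k = 100) {
  stopifnot(inherits(agg, "aggregate_ranking"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  utils::head(agg$table$gene, min(as.integer(k), nrow(agg$table)))
}

#' @export
print.aggregate_ranking <- function(x, ...) {
  cat(sprintf("Aggregate driver ranking: %d genes from %d patients (delta = %g)\n",
              nrow(x$table), x$n_voters, x$delta))
  print(utils::head(x$table, 10L), row.names = FALSE)
  invisible(x)
}
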