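ranking_genes <- function(ranking) {
  if (inherits(ranking, "aggregate_ranking")) {
    ranking$table$gene
  } else if (inherits(ranking, "patient_ranking")) {
    rank_patient(ranking)$gene
  } else if (is.character(ranking)) {
    ranking
  } else {
    stop("`ranking` must be an aggregate_ranking, patient_ranking or gene vector",
         call. = FALSE)
  }
}

#' Rank-cutoff curve against a known-driver list
#'
#' For each cutoff `k`, the fraction of the top-k ranked genes present in the
#' known-driver list. Cutoffs larger than the ranking use all available genes
#' and are flagged.
#'
#' @param ranking An `aggregate_ranking`, `patient_ranking`, or character
#'   vector of genes in rank order.
#' @param known_drivers Character vector of known driver symbols.
#' @param ks Cutoffs; default `seq(10, 100, by = 10)`.
#' @return Data frame with columns `k`, `fraction`, `truncated`.
#' @export
rank_cutoff_curve <- function(ranking, known_drivers,
                              ks = seq(10L, 100L, by = 10L)) {
  genes <- ranking_genes(ranking)
  if (!length(genes)) {
    stop("empty ranking", call. = FALSE)
  }
  hit <- cumsum(genes %in% known_drivers)
  kk <- pmin(ks, length(genes))
  data.frame(k = ks,
             fraction = hit[kk] / kk,
             truncated = ks > length(genes))
}

#' Average precision of the top-K ranked genes
#'
#' `mean(p_k)` for `k = 1..K`, where `p_k` is the fraction of the top-k genes
#' found in the known-driver list. When `k` exceeds the ranking length, `p_k`
#' is computed over the available genes.
#'
#' @inheritParams rank_cutoff_curve
#' @param K Largest cutoff (default 100).
#' @return A single number in `[0, 1]`.
#' @export
average_precision <- function(ranking, known_drivers, K = 100L) {
  genes <- ranking_genes(ranking)
  if (!length(genes)) {
    stop("empty ranking", call. = FALSE)
  }
  hit <- cumsum(genes %in% known_drivers)
  kk <- pmin(seq_len(K), length(genes))
  mean(hit[kk] / kk)
}

#' Sub-sampling robustness of the top-k precision
#'
#' For each sample fraction and replicate, draws that many tumor samples
#' without replacement (all normal samples retained), reruns the full
#' prioritization on the subset, and records the precision of the aggregate
#' top-k against the known-driver list.
#'
#' @param ppi A `ppi_network`.
#' @param expr An `expression_matrix` (tumor + normal).
#' @param mutations A `mutation_table`.
#' @param known_drivers Character vector of known driver symbols.
#' @param fractions Tumor-sample fractions; default `seq(0.1, 0.9, by = 0.1)`.
#'   Fractions yielding fewer than 2 tumor samples are skipped with a warning.
#' @param replicates Draws per fraction (default 10).
#' @param seed Integer seed controlling all draws.
#' @param config A [mecorank_config()].
#' @return Data frame with columns `fraction`, `replicate`, `n_samples`,
#'   `precision`.
#' @export
subsample_precision <- function(ppi, expr, mutations, known_drivers,
                                fractions = seq(0.1, 0.9, by = 0.1),
                                replicates = 10L, seed = 1L,
                                config = mecorank_config()) {
  tum <- tumor_samples(expr)
  nrm <- normal_samples(expr)
  N <- length(tum)
  set.seed(seed)
  rows <- list()
  for (f in fractions) {
    n_draw <- ceiling(f * N)
    if (n_draw < 2L) {
      warning(sprintf("fraction %g yields %d tumor sample(s) (< 2); skipped",
                      f, n_draw), call. = FALSE)
      next
    }
    for (r in seq_len(replicates)) {
      sub <- sample(tum, n_draw)
      sub_expr <- subset_samples(expr, c(sub, nrm))
      sub_mut <- mutations[mutations$sample %in% sub, , drop = FALSE]
      class(sub_mut) <- class(mutations)
      fit <- mecorank(ppi, sub_expr, sub_mut, config = config,
                      keep_patient_rankings = FALSE)
      top <- fit$top_k
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = r, n_samples = n_draw,
        precision = sum(top %in% known_drivers) / length(top))
    }
  }
  do.call(rbind, rows)
}
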