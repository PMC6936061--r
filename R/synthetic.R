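#' Generate a scale-free PPI network by preferential attachment
#'
#' Classic Barabasi-Albert construction: `edges_per_node` seed vertices start
#' without edges; every subsequent vertex attaches `edges_per_node` distinct
#' edges to existing vertices with probability proportional to their current
#' degree (the first newcomer links to all seed vertices). The result is a
#' connected simple graph with `(n_genes - edges_per_node) * edges_per_node`
#' edges and a heavy-tailed degree distribution, standing in for a real
#' protein-interaction backbone.
#'
#' @param n_genes Number of genes (vertices); symbols are `G0001`, `G0002`, ...
#' @param edges_per_node Edges attached by each new vertex (default 2).
#' @param seed Integer seed.
#' @return A `ppi_network`.
#' @examples
#' net <- generate_ppi(50, 2, seed = 7)
#' nrow(net$edges)  # (50 - 2) * 2 = 96
#' @export
generate_ppi <- function(n_genes, edges_per_node = 2L, seed = 1L) {
  m <- as.integer(edges_per_node)
  n <- as.integer(n_genes)
  if (n < m + 1L || m < 1L) {
    stop("need n_genes >= edges_per_node + 1 and edges_per_node >= 1",
         call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n))
  from <- integer((n - m) * m)
  to <- integer((n - m) * m)
  # multiset of endpoints; sampling from it is degree-proportional
  repeated <- integer(0)
  targets <- seq_len(m)
  e <- 0L
  for (v in (m + 1L):n) {
    from[e + seq_len(m)] <- v
    to[e + seq_len(m)] <- targets
    e <- e + m
    repeated <- c(repeated, targets, rep.int(v, m))
    # m distinct targets for the next vertex, degree-weighted
    targets <- integer(0)
    while (length(targets) < m) {
      cand <- repeated[sample.int(length(repeated), 1L)]
      if (!cand %in% targets) targets <- c(targets, cand)
    }
  }
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  edges <- data.frame(from = genes[lo], to = genes[hi],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  new_ppi_network(genes, edges)
}

ppi_neighbors <- function(ppi) {
  nb <- lapply(stats::setNames(vector("list", length(ppi$genes)), ppi$genes),
               function(x) character(0))
  for (g in unique(ppi$edges$from)) {
    nb[[g]] <- ppi$edges$to[ppi$edges$from == g]
  }
  for (g in unique(ppi$edges$to)) {
    nb[[g]] <- c(nb[[g]], ppi$edges$from[ppi$edges$to == g])
  }
  nb
}

ppi_degrees <- function(ppi) {
  tab <- table(c(ppi$edges$from, ppi$edges$to))
  deg <- stats::setNames(integer(length(ppi$genes)), ppi$genes)
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Default parameters of the synthetic cohort
#'
#' The defaults describe a small but non-degenerate planted-driver scenario:
#' 200 genes, 50 tumor and 20 normal samples, 5 driver genes each mutated in
#' 80% of tumor samples with a damaging mutation of probability 0.95, a 2%
#' per-gene benign passenger mutation rate, and a +2 SD expression shift on
#' the PPI neighbors of each sample's mutated drivers with unit noise.
#'
#' @param n_genes,n_tumor,n_normal,n_drivers Cohort dimensions.
#' @param edges_per_node Preferential-attachment parameter of the PPI.
#' @param driver_mut_prob Probability a tumor sample carries each driver
#'   mutated.
#' @param driver_damage_prob PolyPhen score of each driver mutation.
#' @param neighbor_shift Mean expression shift (in SD units) applied to PPI
#'   neighbors of mutated drivers in that sample.
#' @param passenger_rate Per-gene, per-sample benign mutation probability.
#' @param noise_sd SD of the noise on shifted values.
#' @return A named list of parameters.
#' @export
cohort_params <- function(n_genes = 200L, n_tumor = 50L, n_normal = 20L,
                          n_drivers = 5L, edges_per_node = 2L,
                          driver_mut_prob = 0.8, driver_damage_prob = 0.95,
                          neighbor_shift = 2.0, passenger_rate = 0.02,
                          noise_sd = 1.0) {
  if (n_drivers > n_genes) {
    stop("n_drivers cannot exceed n_genes", call. = FALSE)
  }
  list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
       n_normal = as.integer(n_normal), n_drivers = as.integer(n_drivers),
       edges_per_node = as.integer(edges_per_node),
       driver_mut_prob = driver_mut_prob,
       driver_damage_prob = driver_damage_prob,
       neighbor_shift = neighbor_shift,
       passenger_rate = passenger_rate,
       noise_sd = noise_sd)
}

#' Generate a synthetic cohort with planted driver genes
#'
#' Baseline expression is standard normal for every gene and sample. Driver
#' genes (drawn among genes with PPI degree >= 2, so the signal has somewhere
#' to go) carry one damaging mutation (`probably_damaging`, score
#' `driver_damage_prob`) in each tumor sample with probability
#' `driver_mut_prob`; every other gene is a passenger, mutated benignly at
#' `passenger_rate`. In each tumor sample the PPI neighbors of that sample's
#' mutated drivers have their expression shifted to
#' `neighbor_shift + Normal(0, noise_sd)` - the signal enters through the
#' drivers' network neighborhood, the geometry the propagation rewards.
#'
#' @param ppi Optional `ppi_network`; generated from `params` when `NULL`.
#' @param params A [cohort_params()] list.
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @return An object of class `synthetic_cohort`: a list with `ppi`, `expr`
#'   (an `expression_matrix`), `mutations` (a `mutation_table`),
#'   `planted_drivers`, `passengers`, `seed` and `params`.
#' @export
generate_cohort <- function(ppi = NULL, params = cohort_params(), seed = 1L) {
  if (is.null(ppi)) {
    ppi <- generate_ppi(params$n_genes, params$edges_per_node, seed = seed)
  }
  set.seed(seed + 1L)
  genes <- ppi$genes
  deg <- ppi_degrees(ppi)
  eligible <- names(deg)[deg >= 2L]
  if (length(eligible) < params$n_drivers) {
    eligible <- names(deg)[order(-deg)]
  }
  drivers <- sort(sample(eligible, params$n_drivers), method = "radix")
  passengers <- setdiff(genes, drivers)
  nb <- ppi_neighbors(ppi)

  tum <- sprintf("T%03d", seq_len(params$n_tumor))
  nrm <- sprintf("N%03d", seq_len(params$n_normal))
  vals <- matrix(stats::rnorm(length(genes) * (length(tum) + length(nrm))),
                 nrow = length(genes),
                 dimnames = list(genes, c(tum, nrm)))

  recs <- list()
  for (s in tum) {
    mut_drivers <- drivers[stats::runif(length(drivers)) < params$driver_mut_prob]
    if (length(mut_drivers)) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample = s, gene = mut_drivers,
        polyphen_label = "probably_damaging",
        polyphen_score = params$driver_damage_prob,
        sift_label = "tolerated",
        sift_score = round(stats::runif(length(mut_drivers), 0.2, 1), 3),
        stringsAsFactors = FALSE)
      shifted <- unique(unlist(nb[mut_drivers]))
      vals[shifted, s] <- params$neighbor_shift +
        stats::rnorm(length(shifted), 0, params$noise_sd)
    }
    mut_pass <- passengers[stats::runif(length(passengers)) < params$passenger_rate]
    if (length(mut_pass)) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample = s, gene = mut_pass,
        polyphen_label = "benign",
        polyphen_score = round(stats::runif(length(mut_pass), 0, 0.3), 3),
        sift_label = "tolerated",
        sift_score = round(stats::runif(length(mut_pass), 0.2, 1), 3),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    recs <- list(data.frame(sample = character(0), gene = character(0),
                            polyphen_label = character(0),
                            polyphen_score = numeric(0),
                            sift_label = character(0),
                            sift_score = numeric(0),
                            stringsAsFactors = FALSE))
  }
  mutations <- do.call(rbind, recs)
  mutations <- mutations[order(mutations$sample, mutations$gene,
                               method = "radix"), , drop = FALSE]
  rownames(mutations) <- NULL
  class(mutations) <- c("mutation_table", "data.frame")

  expr <- new_expression_matrix(
    round(vals, 6),
    stats::setNames(c(rep("tumor", length(tum)), rep("normal", length(nrm))),
                    c(tum, nrm)))
  structure(
    list(ppi = ppi, expr = expr, mutations = mutations,
         planted_drivers = drivers, passengers = passengers,
         seed = seed, params = params),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort (seed %d): %d genes, %d tumor + %d normal samples, %d planted drivers\n",
    x$seed, length(x$ppi$genes), sum(x$expr$condition == "tumor"),
    sum(x$expr$condition == "normal"), length(x$planted_drivers)))
  cat("  drivers:", paste(x$planted_drivers, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Produces `ppi.tsv`, `expr_tumor.tsv`, `expr_normal.tsv`, `mutations.maf`
#' and `truth_drivers.txt`, all readable back through the package's readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ppi(cohort$ppi, file.path(dir, "ppi.tsv"))
  write_expression(cohort$expr, file.path(dir, "expr_tumor.tsv"),
                   condition = "tumor")
  write_expression(cohort$expr, file.path(dir, "expr_normal.tsv"),
                   condition = "normal")
  write_mutations(cohort$mutations, file.path(dir, "mutations.maf"))
  writeLines(cohort$planted_drivers, file.path(dir, "truth_drivers.txt"))
  invisible(dir)
}
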