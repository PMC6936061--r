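#' Prioritize cancer driver genes for a patient cohort
#'
#' Fits the full model: mutation records are scored into per-sample damage
#' coefficients, each tumor sample gets a bipartite graph over the PPI network
#' (expression nodes on one side, that sample's mutated genes on the other),
#' mutation damage and standardized expression are propagated by a damped,
#' degree-normalized iteration to a converged per-patient gene score, and the
#' per-patient rankings are aggregated into one cohort-level driver list by
#' penalty-modified Condorcet voting completed with Copeland tallies.
#'
#' @param ppi A `ppi_network` from [read_ppi()] or [generate_ppi()].
#' @param expression An `expression_matrix` with tumor and normal samples.
#' @param mutations A `mutation_table` from [read_mutations()].
#' @param known_drivers Optional character vector of known driver symbols;
#'   when supplied, rank-cutoff and average-precision evaluation is attached.
#' @param config A [mecorank_config()].
#' @param keep_patient_rankings Keep the per-patient `patient_ranking`
#'   objects on the fit (default `TRUE`).
#' @param verbose Report per-patient pruning and iteration counts.
#' @return An object of class `mecorank`: a list with
#'   \describe{
#'     \item{aggregate}{the `aggregate_ranking` (see [condorcet_aggregate()])}
#'     \item{top_k}{character vector of the top-ranked candidate drivers}
#'     \item{patient_rankings}{list of `patient_ranking` objects (optional)}
#'     \item{convergence}{data frame per patient: sample, n_U, n_V, n_pruned,
#'       iterations, converged}
#'     \item{evaluation}{list with `cutoff_curve` and `average_precision`
#'       when `known_drivers` was given}
#'     \item{config, call}{the configuration and the matched call}
#'   }
#' @examples
#' cohort <- generate_cohort(params = cohort_params(n_genes = 60, n_tumor = 8,
#'                                                  n_normal = 4), seed = 1)
#' fit <- mecorank(cohort$ppi, cohort$expr, cohort$mutations,
#'                 known_drivers = cohort$planted_drivers)
#' fit
#' head(coef(fit))
#' @export
mecorank <- function(ppi, expression, mutations, known_drivers = NULL,
                     config = mecorank_config(),
                     keep_patient_rankings = TRUE, verbose = FALSE) {
  stopifnot(inherits(ppi, "ppi_network"),
            inherits(expression, "expression_matrix"),
            inherits(config, "mecorank_config"))
  damage <- damage_coefficients(mutations,
                                missing_score = config$missing_score)
  profiles <- build_profiles(expression, damage,
                             reference = config$standardize_reference)
  rankings <- vector("list", length(profiles))
  conv <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    g <- build_bipartite(profiles[[i]], ppi, config)
    g <- prune_zero_vertices(g)
    r <- propagate(g, config)
    if (verbose) {
      message(sprintf("  %s: |U| = %d, |V| = %d (%d pruned), %d iteration(s)%s",
                      r$sample, length(g$U), length(g$V), g$n_pruned,
                      r$iterations_used,
                      if (r$converged) "" else " [not converged]"))
    }
    rankings[[i]] <- r
    conv[[i]] <- data.frame(sample = r$sample, n_U = length(g$U),
                            n_V = length(g$V), n_pruned = g$n_pruned,
                            iterations = r$iterations_used,
                            converged = r$converged,
                            stringsAsFactors = FALSE)
  }
  aggregate <- condorcet_aggregate(rankings, config,
                                   known_drivers = known_drivers)
  evaluation <- NULL
  if (!is.null(known_drivers)) {
    evaluation <- list(
      cutoff_curve = rank_cutoff_curve(aggregate, known_drivers),
      average_precision = average_precision(aggregate, known_drivers,
                                            K = config$top_k))
  }
  structure(
    list(aggregate = aggregate,
         top_k = aggregate$top_k,
         patient_rankings = if (keep_patient_rankings) rankings else NULL,
         convergence = do.call(rbind, conv),
         evaluation = evaluation,
         config = config,
         call = match.call()),
    class = "mecorank"
  )
}

#' @export
print.mecorank <- function(x, ...) {
  cat("Cohort driver prioritization\n")
  cat(sprintf("  %d patients, %d candidate genes, delta = %g, lambda_u = %g\n",
              nrow(x$convergence), nrow(x$aggregate$table),
              x$config$delta, x$config$lambda_u))
  cat(sprintf("  convergence: %d/%d patients, median %g iteration(s)\n",
              sum(x$convergence$converged), nrow(x$convergence),
              stats::median(x$convergence$iterations)))
  n_show <- min(10L, length(x$top_k))
  cat(sprintf("  top %d candidate drivers:\n", n_show))
  print(utils::head(x$aggregate$table, n_show), row.names = FALSE)
  if (!is.null(x$evaluation)) {
    cat(sprintf("  average precision (top %d) vs known drivers: %.4f\n",
                x$config$top_k, x$evaluation$average_precision))
  }
  invisible(x)
}

#' @export
summary.mecorank <- function(object, ...) {
  structure(
    list(n_patients = nrow(object$convergence),
         n_candidates = nrow(object$aggregate$table),
         convergence = object$convergence,
         iteration_summary = summary(object$convergence$iterations),
         pruned_summary = summary(object$convergence$n_pruned),
         top_k = object$top_k,
         evaluation = object$evaluation,
         config = object$config),
    class = "summary.mecorank"
  )
}

#' @export
print.summary.mecorank <- function(x, ...) {
  cat("Cohort driver prioritization - summary\n")
  cat(sprintf("  patients: %d, candidate genes: %d\n",
              x$n_patients, x$n_candidates))
  cat("  propagation iterations per patient:\n")
  print(x$iteration_summary)
  cat("  pruned mutation vertices per patient:\n")
  print(x$pruned_summary)
  cat(sprintf("  top-%d set: %s%s\n", length(x$top_k),
              paste(utils::head(x$top_k, 10L), collapse = ", "),
              if (length(x$top_k) > 10L) ", ..." else ""))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  average precision: %.4f\n",
                x$evaluation$average_precision))
    print(x$evaluation$cutoff_curve, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mecorank <- function(object, ...) {
  stats::setNames(object$aggregate$table$score, object$aggregate$table$gene)
}

#' Plot a fitted driver ranking
#'
#' With evaluation attached, draws the rank-cutoff curve (fraction of known
#' drivers among the top-k as a function of k); otherwise the aggregate score
#' against rank.
#'
#' @param x A `mecorank` fit.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mecorank <- function(x, ...) {
  if (!is.null(x$evaluation)) {
    cc <- x$evaluation$cutoff_curve
    plot(cc$k, cc$fraction, type = "b", pch = 16, ylim = c(0, 1),
         xlab = "rank cutoff k", ylab = "fraction of known drivers in top k",
         main = "Rank-cutoff curve", ...)
  } else {
    tab <- x$aggregate$table
    plot(tab$rank, tab$score, type = "l",
         xlab = "aggregate rank", ylab = "aggregate score (scaled Copeland)",
         main = "Aggregate driver ranking", ...)
  }
  invisible(x)
}
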