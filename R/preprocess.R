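#' Per-sample, per-gene mutation damage coefficients
#'
#' Each mutation record contributes a damage probability: the PolyPhen score
#' when the PolyPhen label contains "damaging" (covering probably_damaging and
#' possibly_damaging), else `1 - SIFT score` when the SIFT label contains
#' "deleterious" (low SIFT means more damaging), else 0. When both filters
#' match a single record the larger of the two contributions is taken, so one
#' variant is never counted twice. Probabilities are summed over all of a
#' gene's mutations in a sample to give `p`, and the damage coefficient is
#' `y = 1 + p`, so that a mutated gene with no damaging evidence still carries
#' weight 1 in the propagation.
#'
#' @param mutations A `mutation_table` from [read_mutations()].
#' @param missing_score Damage probability used when a label passes a filter
#'   but its numeric score is missing (default 1; such uses are reported).
#' @return An object of class `damage_matrix`: a data frame with columns
#'   `sample`, `gene`, `p`, `y`, `n_mutations`, one row per (sample, gene)
#'   with at least one mutation record.
#' @examples
#' m <- data.frame(sample = "S1", gene = "TP53",
#'                 polyphen_label = c("probably_damaging", "probably_damaging"),
#'                 polyphen_score = c(0.95, 0.80),
#'                 sift_label = "", sift_score = NA_real_)
#' class(m) <- c("mutation_table", "data.frame")
#' damage_coefficients(m)  # p = 1.75, y = 2.75
#' @export
damage_coefficients <- function(mutations, missing_score = 1) {
  stopifnot(inherits(mutations, "mutation_table") || is.data.frame(mutations))
  pp_hit <- grepl("damaging", mutations$polyphen_label, ignore.case = TRUE)
  sf_hit <- grepl("deleterious", mutations$sift_label, ignore.case = TRUE)
  pp_missing <- pp_hit & is.na(mutations$polyphen_score)
  sf_missing <- sf_hit & is.na(mutations$sift_score)
  n_default <- sum(pp_missing | sf_missing)
  if (n_default > 0L) {
    message("damage_coefficients: ", n_default,
            " filtered-in record(s) had no numeric score; used default ",
            missing_score)
  }
  pp_contrib <- ifelse(pp_hit,
                       ifelse(pp_missing, missing_score,
                              mutations$polyphen_score),
                       0)
  sf_contrib <- ifelse(sf_hit,
                       ifelse(sf_missing, missing_score,
                              1 - mutations$sift_score),
                       0)
  prob <- pmax(pp_contrib, sf_contrib)
  key <- paste(mutations$sample, mutations$gene, sep = "\r")
  p <- tapply(prob, key, sum)
  n <- tapply(prob, key, length)
  parts <- strsplit(names(p), "\r", fixed = TRUE)
  out <- data.frame(
    sample = vapply(parts, `[[`, character(1), 1L),
    gene = vapply(parts, `[[`, character(1), 2L),
    p = as.numeric(p),
    y = 1 + as.numeric(p),
    n_mutations = as.integer(n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sample, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("damage_matrix", "data.frame")
  out
}

#' Merge damage matrices computed from split mutation loads
#'
#' Damage probabilities are additive over mutation records, so splitting a
#' mutation table, scoring the parts and merging reproduces the single-load
#' result.
#'
#' @param ... `damage_matrix` objects.
#' @return A single merged `damage_matrix`.
#' @export
merge_damage <- function(...) {
  all <- do.call(rbind, lapply(list(...), as.data.frame))
  key <- paste(all$sample, all$gene, sep = "\r")
  p <- tapply(all$p, key, sum)
  n <- tapply(all$n_mutations, key, sum)
  parts <- strsplit(names(p), "\r", fixed = TRUE)
  out <- data.frame(
    sample = vapply(parts, `[[`, character(1), 1L),
    gene = vapply(parts, `[[`, character(1), 2L),
    p = as.numeric(p),
    y = 1 + as.numeric(p),
    n_mutations = as.integer(n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sample, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("damage_matrix", "data.frame")
  out
}

#' Standardized expression per tumor sample
#'
#' Z-scores each gene across the reference cohort (tumor samples by default):
#' subtract the cohort mean and divide by the cohort standard deviation,
#' computed with denominator n (population SD). Genes with zero variance in
#' the reference get 0 everywhere.
#'
#' @param expr An `expression_matrix` with at least 2 reference samples.
#' @param reference `"tumor"` (default) or `"normal"`: the cohort supplying
#'   the mean and SD.
#' @return Numeric matrix, genes x tumor samples, of standardized values.
#' @export
standardize_expression <- function(expr, reference = c("tumor", "normal")) {
  reference <- match.arg(reference)
  tum <- tumor_samples(expr)
  ref <- if (reference == "tumor") tum else normal_samples(expr)
  if (length(ref) < 2L) {
    stop("standardization requires >= 2 ", reference,
         " samples (got ", length(ref), ")", call. = FALSE)
  }
  rv <- expr$values[, ref, drop = FALSE]
  mu <- rowMeans(rv)
  sdp <- sqrt(rowMeans((rv - mu)^2))
  tv <- expr$values[, tum, drop = FALSE]
  x0 <- (tv - mu) / ifelse(sdp > 0, sdp, 1)
  x0[sdp == 0, ] <- 0
  x0
}

#' Differential expression per tumor sample
#'
#' For every tumor sample and gene: the tumor expression value minus the mean
#' of that gene over all normal samples (unpaired).
#'
#' @param expr An `expression_matrix` with at least 1 normal sample.
#' @return Numeric matrix, genes x tumor samples, of differential values.
#' @export
differential_expression <- function(expr) {
  nrm <- normal_samples(expr)
  if (!length(nrm)) {
    stop("differential expression requires >= 1 normal sample", call. = FALSE)
  }
  tum <- tumor_samples(expr)
  mu_n <- rowMeans(expr$values[, nrm, drop = FALSE])
  expr$values[, tum, drop = FALSE] - mu_n
}

#' Assemble per-patient profiles
#'
#' Combines standardized expression, differential expression and that
#' sample's damage coefficients into one profile per tumor sample. Samples
#' that appear in the damage matrix but not in the expression matrix are
#' excluded with a warning; tumor samples with no mutated genes are kept with
#' an empty mutation map.
#'
#' @param expr An `expression_matrix`.
#' @param damage A `damage_matrix` from [damage_coefficients()].
#' @param reference Passed to [standardize_expression()].
#' @return A list of `patient_profile` objects, one per tumor sample, each
#'   holding `sample`, `x0` and `dx` (named numeric vectors over the
#'   expression gene set) and `mutated` (named vector of y coefficients over
#'   that sample's mutated genes).
#' @export
build_profiles <- function(expr, damage, reference = "tumor") {
  x0 <- standardize_expression(expr, reference = reference)
  dx <- differential_expression(expr)
  tum <- tumor_samples(expr)
  orphan <- setdiff(unique(damage$sample), colnames(expr$values))
  if (length(orphan)) {
    warning("mutation sample(s) absent from expression matrix, excluded: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  unmutated <- tum[!tum %in% damage$sample]
  if (length(unmutated)) {
    message("build_profiles: ", length(unmutated),
            " tumor sample(s) carry no mutated genes")
  }
  lapply(tum, function(s) {
    d <- damage[damage$sample == s, , drop = FALSE]
    structure(
      list(sample = s,
           x0 = x0[, s],
           dx = dx[, s],
           mutated = stats::setNames(d$y, d$gene)),
      class = "patient_profile"
    )
  })
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("Patient profile %s: %d genes, %d mutated\n",
              x$sample, length(x$x0), length(x$mutated)))
  invisible(x)
}
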