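#' Read a protein-protein interaction network from a two-column edge list
#'
#' Parses a whitespace- or tab-separated file with two gene-symbol columns
#' (HPRD-style). Edges are undirected and deduplicated; self-interactions are
#' dropped. A header line is skipped when both of its tokens look like column
#' names (e.g. "gene_a", "interactor_b") rather than gene symbols.
#'
#' @param path Path to the edge-list file.
#' @return An object of class `ppi_network`: a list with `genes` (sorted
#'   character vector) and `edges` (data frame with columns `from`, `to`,
#'   each row an unordered pair stored with `from < to`).
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC", "B\tA"), f)
#' net <- read_ppi(f)
#' net$genes          # "A" "B" "C"
#' nrow(net$edges)    # 2 (duplicate collapsed)
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) {
    stop("PPI file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(new_ppi_network(character(0),
                           data.frame(from = character(0), to = character(0),
                                      stringsAsFactors = FALSE)))
  }
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  short <- lengths(toks) < 2L
  if (any(short)) {
    stop("PPI parse error: line ", idx[which(short)[1L]],
         " has fewer than 2 columns", call. = FALSE)
  }
  a <- vapply(toks, `[[`, character(1), 1L)
  b <- vapply(toks, `[[`, character(1), 2L)
  header_re <- "^(gene|symbol|interactor|protein|node|source|target)"
  if (grepl(header_re, tolower(a[1L])) && grepl(header_re, tolower(b[1L]))) {
    a <- a[-1L]
    b <- b[-1L]
  }
  self <- a == b
  if (any(self)) {
    message("read_ppi: dropped ", sum(self), " self-loop(s)")
    a <- a[!self]
    b <- b[!self]
  }
  lo <- as.character(ifelse(a < b, a, b))
  hi <- as.character(ifelse(a < b, b, a))
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  if (any(dup)) {
    message("read_ppi: collapsed ", sum(dup), " duplicate edge(s)")
    lo <- lo[!dup]
    hi <- hi[!dup]
  }
  edges <- data.frame(from = lo, to = hi, stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  new_ppi_network(sort_genes(c(lo, hi)), edges)
}

new_ppi_network <- function(genes, edges) {
  stopifnot(all(edges$from < edges$to) || nrow(edges) == 0L,
            all(c(edges$from, edges$to) %in% genes))
  structure(list(genes = genes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d genes, %d undirected edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Write a PPI network back to a two-column edge list
#'
#' @param ppi A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix
#'
#' The file must be tab-separated with gene symbols in the first column and
#' sample IDs in the header. Every sample must be assigned a condition
#' ("tumor" or "normal") through `condition_map`; any non-numeric or missing
#' cell is a fatal error naming its coordinates.
#'
#' @param path Path to the TSV file.
#' @param condition_map Either a named character vector mapping sample ID to
#'   `"tumor"`/`"normal"`, or a single unnamed string applied to all samples.
#' @return An object of class `expression_matrix`: a list with `values`
#'   (numeric matrix, genes x samples) and `condition` (named character
#'   vector over samples).
#' @export
read_expression <- function(path, condition_map) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2L) {
    stop("expression file must have a gene column and >=1 sample column",
         call. = FALSE)
  }
  genes <- trimws(raw[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene row in expression file: ",
         genes[duplicated(genes)][1L], call. = FALSE)
  }
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ID in expression header: ",
         samples[duplicated(samples)][1L], call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric expression value '%s' at gene '%s', sample '%s'",
        col[bad[1L]], genes[bad[1L]], samples[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  new_expression_matrix(vals, resolve_condition_map(condition_map, samples))
}

resolve_condition_map <- function(condition_map, samples) {
  if (is.null(names(condition_map)) && length(condition_map) == 1L) {
    condition_map <- stats::setNames(rep(condition_map, length(samples)),
                                     samples)
  }
  missing <- setdiff(samples, names(condition_map))
  if (length(missing)) {
    stop("sample(s) absent from condition_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cond <- condition_map[samples]
  if (!all(cond %in% c("tumor", "normal"))) {
    stop("conditions must be 'tumor' or 'normal'", call. = FALSE)
  }
  cond
}

new_expression_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), is.numeric(values),
            identical(colnames(values), names(condition)))
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  structure(list(values = values, condition = condition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "tumor"), sum(x$condition == "normal")))
  invisible(x)
}

tumor_samples <- function(expr) names(expr$condition)[expr$condition == "tumor"]
normal_samples <- function(expr) names(expr$condition)[expr$condition == "normal"]

#' Subset an expression matrix by sample IDs
#'
#' @param expr An `expression_matrix`.
#' @param samples Character vector of sample IDs to keep (order preserved).
#' @return An `expression_matrix` restricted to `samples`.
#' @export
subset_samples <- function(expr, samples) {
  missing <- setdiff(samples, colnames(expr$values))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  new_expression_matrix(expr$values[, samples, drop = FALSE],
                        expr$condition[samples])
}

#' Combine two expression matrices over the same gene set
#'
#' Typically used to join a tumor file and a normal file read separately.
#'
#' @param a,b `expression_matrix` objects with identical gene sets and
#'   disjoint sample IDs.
#' @return A combined `expression_matrix`.
#' @export
expression_bind <- function(a, b) {
  if (!identical(rownames(a$values), rownames(b$values))) {
    stop("expression matrices have different gene sets", call. = FALSE)
  }
  if (length(intersect(colnames(a$values), colnames(b$values)))) {
    stop("expression matrices share sample IDs", call. = FALSE)
  }
  new_expression_matrix(cbind(a$values, b$values),
                        c(a$condition, b$condition))
}

#' Write an expression matrix (or one condition of it) to TSV
#'
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @param condition Optional: write only samples with this condition.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, condition = NULL) {
  vals <- expr$values
  if (!is.null(condition)) {
    vals <- vals[, expr$condition == condition, drop = FALSE]
  }
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- mutation tables ---------------------------------------------------------

maf_col <- function(nms, candidates) {
  hit <- match(candidates, tolower(nms))
  hit <- hit[!is.na(hit)]
  if (length(hit)) hit[1L] else NA_integer_
}

# split "label(score)" strings; plain labels pass through with score NA
parse_annotation <- function(label_col, score_col, what) {
  label <- trimws(label_col)
  score <- rep(NA_real_, length(label))
  combined <- grepl("^[^()]*\\([^()]*\\)$", label)
  if (any(combined)) {
    inner <- sub("^[^(]*\\(([^()]*)\\)$", "\\1", label[combined])
    outer_lab <- trimws(sub("\\([^()]*\\)$", "", label[combined]))
    num <- suppressWarnings(as.numeric(inner))
    bad <- !is.na(inner) & nzchar(trimws(inner)) & is.na(num)
    if (any(bad)) {
      warning(sum(bad), " unparseable ", what,
              " score string(s); score recorded as missing", call. = FALSE)
    }
    label[combined] <- outer_lab
    score[combined] <- num
  }
  if (!is.null(score_col)) {
    plain <- !combined
    score[plain] <- suppressWarnings(as.numeric(score_col[plain]))
  }
  out_of_range <- !is.na(score) & (score < 0 | score > 1)
  if (any(out_of_range)) {
    stop(what, " score outside [0, 1]: ", score[out_of_range][1L],
         call. = FALSE)
  }
  list(label = label, score = score)
}

#' Read a MAF-style somatic mutation table
#'
#' Expects a tab-separated file with a header naming at least a sample-ID
#' column (`Tumor_Sample_Barcode` / `sample`), a gene column (`Hugo_Symbol` /
#' `gene`), and PolyPhen and SIFT annotation columns. Annotations may be
#' combined `label(score)` strings (e.g. `probably_damaging(0.98)`) or split
#' into separate label and score columns; the dialect is detected per column.
#' No damage filtering happens here: benign records are retained.
#'
#' @param path Path to the mutation TSV.
#' @return An object of class `mutation_table`: a data frame with columns
#'   `sample`, `gene`, `polyphen_label`, `polyphen_score`, `sift_label`,
#'   `sift_score` (one row per mutation record).
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) {
    stop("mutation file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL, comment.char = "#")
  nms <- tolower(trimws(colnames(raw)))
  si <- maf_col(nms, c("tumor_sample_barcode", "sample_id", "sample"))
  gi <- maf_col(nms, c("hugo_symbol", "gene_symbol", "gene"))
  if (is.na(si) || is.na(gi)) {
    stop("mutation file must have sample and gene columns ",
         "(e.g. Tumor_Sample_Barcode, Hugo_Symbol)", call. = FALSE)
  }
  pp_label_i <- maf_col(nms, c("polyphen", "polyphen_prediction", "polyphen2"))
  pp_score_i <- maf_col(nms, c("polyphen_score", "polyphen2_score"))
  sf_label_i <- maf_col(nms, c("sift", "sift_prediction"))
  sf_score_i <- maf_col(nms, c("sift_score"))
  if (is.na(pp_label_i) && is.na(sf_label_i)) {
    stop("mutation file carries neither PolyPhen nor SIFT columns",
         call. = FALSE)
  }
  pp <- if (!is.na(pp_label_i)) {
    parse_annotation(raw[[pp_label_i]],
                     if (!is.na(pp_score_i)) raw[[pp_score_i]] else NULL,
                     "PolyPhen")
  } else {
    list(label = rep("", nrow(raw)), score = rep(NA_real_, nrow(raw)))
  }
  sf <- if (!is.na(sf_label_i)) {
    parse_annotation(raw[[sf_label_i]],
                     if (!is.na(sf_score_i)) raw[[sf_score_i]] else NULL,
                     "SIFT")
  } else {
    list(label = rep("", nrow(raw)), score = rep(NA_real_, nrow(raw)))
  }
  tab <- data.frame(
    sample = trimws(raw[[si]]),
    gene = trimws(raw[[gi]]),
    polyphen_label = pp$label,
    polyphen_score = pp$score,
    sift_label = sf$label,
    sift_score = sf$score,
    stringsAsFactors = FALSE
  )
  unannotated <- !nzchar(tab$polyphen_label) & is.na(tab$polyphen_score) &
    !nzchar(tab$sift_label) & is.na(tab$sift_score)
  if (any(unannotated)) {
    warning("dropped ", sum(unannotated),
            " mutation record(s) with no PolyPhen or SIFT annotation",
            call. = FALSE)
    tab <- tab[!unannotated, , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("mutation_table", "data.frame")
  tab
}

#' Write a mutation table as a MAF-style TSV
#'
#' Annotations are written in the combined `label(score)` dialect that
#' [read_mutations()] accepts.
#'
#' @param mutations A `mutation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  fmt <- function(label, score) {
    ifelse(nzchar(label) & !is.na(score),
           sprintf("%s(%g)", label, score),
           ifelse(nzchar(label), label,
                  ifelse(is.na(score), "", sprintf("(%g)", score))))
  }
  df <- data.frame(
    Tumor_Sample_Barcode = mutations$sample,
    Hugo_Symbol = mutations$gene,
    PolyPhen = fmt(mutations$polyphen_label, mutations$polyphen_score),
    SIFT = fmt(mutations$sift_label, mutations$sift_score),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-symbol-per-line gene list (e.g. a known-driver export)
#'
#' @param path Path to the list file.
#' @return Character vector of unique, trimmed gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("gene list file not found: ", path, call. = FALSE)
  }
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write a ranking to TSV
#'
#' For an aggregate ranking the columns are `rank`, `gene`, `score`,
#' `n_patients_mutated` and, when a known-driver list was supplied at fit
#' time, `known_driver`. For a per-patient ranking the columns are `rank`,
#' `gene`, `score`, `mutated`. Rank 1 is best and scores are non-increasing.
#'
#' @param ranking An `aggregate_ranking` or `patient_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  if (inherits(ranking, "aggregate_ranking")) {
    df <- ranking$table
    keep <- intersect(c("rank", "gene", "score", "n_patients_mutated",
                        "known_driver"), colnames(df))
    df <- df[, keep, drop = FALSE]
  } else if (inherits(ranking, "patient_ranking")) {
    rp <- rank_patient(ranking)
    df <- data.frame(rank = seq_len(nrow(rp)), gene = rp$gene,
                     score = rp$rank_score,
                     mutated = rp$gene %in% ranking$mutated,
                     stringsAsFactors = FALSE)
  } else {
    stop("`ranking` must be an aggregate_ranking or patient_ranking",
         call. = FALSE)
  }
  con <- file(path, open = "wb")  # fixed EOL for byte-reproducible output
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read a ranking TSV written by [write_ranking()]
#'
#' @param path Path to the ranking TSV.
#' @return A data frame in file order.
#' @export
read_ranking <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
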