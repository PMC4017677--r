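EVIDENCE_LEVELS <- c(negative = 0, weak = 1, moderate = 2, strong = 3)

#' Construct a protein-evidence matrix
#'
#' Holds ordinal protein-detection levels (immunohistochemistry-style:
#' strong / moderate / weak / negative, with missing values) for genes
#' across samples.
#'
#' @param levels matrix (genes x samples) of levels, given either as the
#'   symbols `"strong"`, `"moderate"`, `"weak"`, `"negative"` (plus `NA`
#'   for missing) or as their ordinal codes 3/2/1/0.
#' @param genes,samples identifiers; taken from `dimnames(levels)` when
#'   omitted.
#' @return an object of class `evidence_matrix`: integer matrix of
#'   ordinal codes with `NA` for missing, with gene/sample dimnames.
#' @export
evidence_matrix <- function(levels, genes = rownames(levels),
                            samples = colnames(levels)) {
  if (is.character(levels)) {
    lv <- matrix(NA_integer_, nrow(levels), ncol(levels))
    known <- levels %in% names(EVIDENCE_LEVELS)
    if (any(!known & !is.na(levels)))
      stop("unknown evidence symbol(s): ",
           paste(unique(levels[!known & !is.na(levels)]), collapse = ", "))
    lv[known] <- EVIDENCE_LEVELS[levels[known]]
  } else {
    lv <- matrix(as.integer(levels), nrow(levels), ncol(levels))
    if (any(!is.na(lv) & (lv < 0L | lv > 3L)))
      stop("ordinal codes must lie in 0..3")
  }
  if (is.null(genes) || is.null(samples))
    stop("genes and samples must be named")
  dimnames(lv) <- list(genes, samples)
  structure(lv, class = "evidence_matrix")
}

#' Read an evidence matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids, whose
#' header row holds sample ids, and whose cells are
#' `strong`/`moderate`/`weak`/`negative`/`NA`.
#'
#' @param path file path.
#' @return an [evidence_matrix()].
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  evidence_matrix(m)
}

#' Write an evidence matrix to TSV
#' @param x an [evidence_matrix()].
#' @param path file path.
#' @export
write_evidence <- function(x, path) {
  sym <- matrix(names(EVIDENCE_LEVELS)[match(x, EVIDENCE_LEVELS)],
                nrow(x), dimnames = dimnames(x))
  df <- data.frame(gene = rownames(x), sym, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat("evidence_matrix: ", nrow(x), " genes x ", ncol(x), " samples; ",
      sum(is.na(x)), " missing cells\n", sep = "")
  invisible(x)
}

#' Median of ordinal evidence levels
#'
#' Median over the 0-3 ordinal scale with a fixed even-count tie rule:
#' when the midpoint of the two central values is integral it is used
#' directly, otherwise it is rounded *down* (so \{strong, weak\} gives
#' moderate, while \{strong, moderate\} gives moderate, not 2.5).
#'
#' @param x integer vector of ordinal codes (NAs removed by the caller).
#' @return integer ordinal code.
#' @export
ordinal_median <- function(x) {
  x <- sort(as.integer(x))
  n <- length(x)
  if (n == 0L) return(NA_integer_)
  if (n %% 2L == 1L) return(x[(n + 1L) %/% 2L])
  as.integer(floor((x[n %/% 2L] + x[n %/% 2L + 1L]) / 2))
}

#' Impute missing evidence for one sample from the cohort
#'
#' For each gene with missing evidence in `sample`, fills in the median
#' of the non-missing ordinal levels of that gene across all *other*
#' samples (see [ordinal_median()] for the tie rule).  Genes missing in
#' every other sample stay missing; measured values are never altered.
#'
#' @param matrix an [evidence_matrix()].
#' @param sample a sample id present in the matrix.
#' @return an [evidence_matrix()] with (some) missing cells of `sample`
#'   filled.
#' @export
impute_missing <- function(matrix, sample) {
  stopifnot(inherits(matrix, "evidence_matrix"))
  if (!sample %in% colnames(matrix))
    stop("unknown sample '", sample, "'")
  if (ncol(matrix) < 2L)
    stop("cannot impute from a single-sample matrix: no cohort")
  others <- matrix[, colnames(matrix) != sample, drop = FALSE]
  target <- matrix[, sample]
  fill <- which(is.na(target))
  for (g in fill) {
    vals <- others[g, ]
    vals <- vals[!is.na(vals)]
    if (length(vals)) target[g] <- ordinal_median(vals)
  }
  out <- unclass(matrix)
  out[, sample] <- target
  structure(out, class = "evidence_matrix")
}

#' Default mapping from evidence level to gene score
#'
#' Detected levels (strong/moderate/weak) map to positive scores,
#' negative evidence to a clear penalty, and still-missing (after
#' imputation) to a mild penalty — absence of measurement is weaker
#' evidence against a protein than a negative stain.  Magnitudes follow
#' the spirit of evidence-weighted network inference from protein-atlas
#' style data and are fully configurable.
#'
#' @param strong,moderate,weak,negative,missing numeric scores.
#' @return named numeric vector usable as the `mapping` of
#'   [gene_scores()].
#' @export
score_mapping <- function(strong = 20, moderate = 15, weak = 10,
                          negative = -8, missing = -2) {
  c(strong = strong, moderate = moderate, weak = weak,
    negative = negative, missing = missing)
}

#' Per-gene numeric scores for one sample
#'
#' @param matrix an [evidence_matrix()].
#' @param sample a sample id.
#' @param mapping named numeric vector with entries `strong`, `moderate`,
#'   `weak`, `negative`, `missing` (see [score_mapping()]).
#' @return named numeric vector of per-gene scores.
#' @export
gene_scores <- function(matrix, sample, mapping = score_mapping()) {
  stopifnot(inherits(matrix, "evidence_matrix"))
  need <- c("strong", "moderate", "weak", "negative", "missing")
  if (!all(need %in% names(mapping)))
    stop("mapping must define: ", paste(need, collapse = ", "))
  if (!sample %in% colnames(matrix))
    stop("unknown sample '", sample, "'")
  lv <- matrix[, sample]
  sym <- names(EVIDENCE_LEVELS)[match(lv, EVIDENCE_LEVELS)]
  sym[is.na(sym)] <- "missing"
  setNames(as.numeric(mapping[sym]), rownames(matrix))
}

#' Per-reaction scores from per-gene scores through GPR rules
#'
#' Aggregates gene scores through each reaction's gene rule: `or` nodes
#' (isozymes — any one suffices) take the maximum, `and` nodes (complex
#' subunits — all needed) the minimum.  Reactions without a gene rule
#' (spontaneous, transport) receive `spontaneous_score`.
#'
#' @param model a `gem_model`.
#' @param gene_scores named numeric vector of per-gene scores; genes
#'   referenced by rules but absent here receive `default_score`.
#' @param spontaneous_score score for reactions with no gene rule.
#' @param default_score score for rule genes not covered by
#'   `gene_scores`.
#' @return named numeric vector over all reactions of `model`.
#' @export
reaction_scores <- function(model, gene_scores, spontaneous_score = 0,
                            default_score = -2) {
  stopifnot(inherits(model, "gem_model"))
  out <- vapply(model$gpr_trees, function(tree) {
    if (is.null(tree)) return(spontaneous_score)
    eval_gpr(tree, gene_scores, default = default_score)
  }, numeric(1))
  setNames(out, model$rxns$id)
}
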