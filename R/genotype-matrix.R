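#' Sparse allele-dosage genotype matrix
#'
#' The central container of the package: a samples x variants matrix of
#' alternate-allele dosages stored in compressed sparse column form
#' ([Matrix::dgCMatrix-class]), so that memory scales with the number of
#' non-reference genotype calls rather than with `n_samples * n_variants`.
#' Missing calls are tracked separately in a sparse logical mask; their dosage
#' slots hold no stored value.
#'
#' @param dosages numeric matrix or `Matrix` sparse matrix, samples in rows,
#'   variants in columns; entries are alternate-allele counts in
#'   `0..ploidy`.
#' @param sample_ids character vector of unique sample identifiers (one per
#'   row). Defaults to rownames or `sample_<i>`.
#' @param variant_ids character vector of unique variant identifiers (one per
#'   column), conventionally `chrom:pos:ref:alt`. Defaults to colnames or
#'   `var_<j>`.
#' @param missing_mask `NULL`, a logical/pattern matrix of the same dimension,
#'   or a two-column integer matrix of (row, col) positions of missing calls.
#' @param ploidy positive integer; the maximum dosage (2 = diploid,
#'   1 = haploid).
#' @return An object of class `genotype_matrix` with fields `dosages`
#'   (`dgCMatrix`), `missing_mask` (`ngCMatrix` pattern matrix), `sample_ids`,
#'   `variant_ids`, `ploidy`.
#' @examples
#' G <- genotype_matrix(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3),
#'                      sample_ids = c("a", "b", "c"),
#'                      variant_ids = c("1:1:A:T", "1:2:C:G"))
#' dim(G)
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, variant_ids = NULL,
                            missing_mask = NULL, ploidy = 2L) {
  ploidy <- as.integer(ploidy)
  stopifnot(length(ploidy) == 1L, ploidy >= 1L)
  D <- as_dgc(dosages)
  n <- nrow(D); p <- ncol(D)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% sprintf("sample_%d", seq_len(n))
  }
  if (is.null(variant_ids)) {
    variant_ids <- colnames(dosages) %||% sprintf("var_%d", seq_len(p))
  }
  sample_ids <- as.character(sample_ids)
  variant_ids <- as.character(variant_ids)
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(dosages)")
  if (length(variant_ids) != p) stop("variant_ids length must equal ncol(dosages)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (anyDuplicated(variant_ids)) stop("duplicate variant_ids")
  M <- as_mask(missing_mask, n, p)
  if (length(D@x) && (min(D@x) < 0 || max(D@x) > ploidy)) {
    stop("dosages must lie in [0, ploidy]")
  }
  dimnames(D) <- NULL
  structure(
    list(dosages = D, missing_mask = M, sample_ids = sample_ids,
         variant_ids = variant_ids, ploidy = ploidy),
    class = "genotype_matrix"
  )
}

as_dgc <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$dosages)
  x <- methods::as(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                           "dMatrix"),
                               "generalMatrix"),
                   "CsparseMatrix")
  Matrix::drop0(x)
}

as_mask <- function(m, n, p) {
  if (is.null(m)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(n, p)))
  }
  if (is.matrix(m) && ncol(m) == 2L && !is.logical(m)) {
    M <- Matrix::sparseMatrix(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                              dims = c(n, p))
  } else {
    M <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                 "nMatrix"), "CsparseMatrix")
  }
  if (!identical(dim(M), c(n, p))) stop("missing_mask dimension mismatch")
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- n_missing(x)
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (ploidy %d)\n  %d non-zero dosages (%.2f%% dense), %d missing calls\n",
    nrow(x$dosages), ncol(x$dosages), x$ploidy, length(x$dosages@x),
    if (prod(dim(x$dosages)) > 0) 100 * length(x$dosages@x) / prod(dim(x$dosages)) else 0,
    nm))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (is.character(j)) j <- match(j, x$variant_ids)
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  sample_ids = x$sample_ids[seq_len(nrow(x$dosages))[i]],
                  variant_ids = x$variant_ids[seq_len(ncol(x$dosages))[j]],
                  missing_mask = x$missing_mask[i, j, drop = FALSE],
                  ploidy = x$ploidy)
}

#' Number of missing genotype calls
#' @param G a [genotype_matrix()]
#' @return integer count of masked (sample, variant) positions.
#' @export
n_missing <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  as.integer(Matrix::nnzero(G$missing_mask))
}

#' Per-variant alternate allele frequency
#'
#' Frequency of the alternate allele among observed (non-missing) calls,
#' i.e. `sum(dosage) / (ploidy * n_observed)` per column. Variants with no
#' observed call get `NaN`.
#'
#' @param G a [genotype_matrix()]
#' @return numeric vector, one frequency per variant, named by variant id.
#' @export
alt_allele_freq <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_obs <- nrow(G$dosages) - Matrix::colSums(G$missing_mask)
  p <- as.numeric(Matrix::colSums(G$dosages)) / (G$ploidy * n_obs)
  names(p) <- G$variant_ids
  p
}

#' Sample-to-population label mapping
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param label character vector (or factor) of population labels, parallel to
#'   `sample_id`.
#' @return Object of class `sample_labels`: list with `sample_id`, `label`
#'   (character), `k` (number of distinct labels).
#' @examples
#' sample_labels(c("a", "b", "c"), c("popA", "popA", "popB"))
#' @export
sample_labels <- function(sample_id, label) {
  sample_id <- as.character(sample_id)
  label <- as.character(label)
  if (length(sample_id) != length(label)) stop("sample_id and label lengths differ")
  if (length(sample_id) == 0L) stop("empty label set")
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in labels")
  if (anyNA(label)) stop("NA labels are not allowed")
  structure(list(sample_id = sample_id, label = label,
                 k = length(unique(label))),
            class = "sample_labels")
}

#' @export
print.sample_labels <- function(x, ...) {
  cat(sprintf("<sample_labels> %d samples, k = %d populations\n",
              length(x$sample_id), x$k))
  print(utils::head(table(x$label)))
  invisible(x)
}

# Resolve a labels argument (sample_labels object, named vector, or plain
# vector parallel to rows) into a character vector aligned with G's samples.
resolve_labels <- function(labels, sample_ids) {
  if (inherits(labels, "sample_labels")) {
    idx <- match(sample_ids, labels$sample_id)
    if (anyNA(idx)) {
      stop("labels missing for samples: ",
           paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
    }
    return(labels$label[idx])
  }
  labels <- if (is.factor(labels)) as.character(labels) else labels
  if (!is.null(names(labels)) && all(sample_ids %in% names(labels))) {
    return(as.character(labels[sample_ids]))
  }
  if (length(labels) != length(sample_ids)) {
    stop("labels length does not match number of samples")
  }
  as.character(labels)
}

#' Read a sample-to-population label table
#'
#' Two-column delimited text (sample id, population label); delimiter and
#' header are auto-detected.
#'
#' @param path file path.
#' @param sample_col,label_col column positions of the sample id and label.
#' @return a [sample_labels()] object.
#' @export
read_labels <- function(path, sample_col = 1L, label_col = 2L) {
  tab <- data.table::fread(path, header = "auto", colClasses = "character",
                           data.table = FALSE)
  if (ncol(tab) < max(sample_col, label_col)) {
    stop("label table has fewer columns than expected")
  }
  sample_labels(tab[[sample_col]], tab[[label_col]])
}

#' Write a sample-to-population label table
#' @param labels a [sample_labels()] object.
#' @param path output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "sample_labels"))
  data.table::fwrite(data.frame(sample_id = labels$sample_id,
                                population = labels$label),
                     path, sep = "\t")
  invisible(path)
}
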