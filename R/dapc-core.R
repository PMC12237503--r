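#' Exact truncated SVD of a (sparse) genotype matrix
#'
#' Computes the leading `r` right singular vectors of the dosage matrix, or of
#' the column-centered matrix when `centering = "implicit"`. Centering is
#' never materialized: the column-mean vector enters only as a rank-one
#' correction inside Gram-matrix products, so the sparse input stays sparse.
#' With implicit centering the result is classical PCA — right singular
#' vectors are PCA loadings and `singular_values^2 / (n - 1)` are covariance
#' eigenvalues.
#'
#' The solver is exact and deterministic: it eigendecomposes whichever Gram
#' matrix is smaller (samples x samples or variants x variants), which is the
#' efficient route for genotype data where one dimension is much smaller than
#' the other.
#'
#' @param G a [genotype_matrix()] with no missing entries (see
#'   [impute_missing()]), or a plain numeric matrix.
#' @param r number of components to retain; at most
#'   `min(n, p) - 1` with centering, `min(n, p)` without.
#' @param centering `"implicit"` (column-mean centering, the PCA default) or
#'   `"none"` (raw truncated SVD of the dosages).
#' @param scale if `TRUE`, additionally divide each (centered) column by its
#'   standard deviation, adegenet-style; columns with zero variance are left
#'   unscaled. Off by default.
#' @return Object of class `pc_model`: `r` (components actually returned),
#'   `loadings` (variants x r, orthonormal columns, each oriented so its
#'   largest-magnitude entry is positive), `singular_values` (non-increasing),
#'   `explained_variance_fraction`, `center` (column means, or `NULL`),
#'   `scale_` (column sds, or `NULL`), `centering_mode`, `n_fit`.
#' @export
fit_truncated_svd <- function(G, r, centering = c("implicit", "none"),
                              scale = FALSE) {
  centering <- match.arg(centering)
  X <- if (inherits(G, "genotype_matrix")) {
    if (n_missing(G) > 0L) {
      stop("genotype matrix has missing calls; run impute_missing() first")
    }
    G$dosages
  } else {
    as_dgc(G)
  }
  n <- nrow(X); p <- ncol(X)
  centered <- centering == "implicit"
  rmax <- min(n, p) - as.integer(centered)
  if (!is.numeric(r) || length(r) != 1L || r < 1 || r > rmax) {
    stop(sprintf("r must be in [1, %d] for a %d x %d matrix (centering %s)",
                 rmax, n, p, centering))
  }
  r <- as.integer(r)

  m <- if (centered) as.numeric(Matrix::colMeans(X)) else numeric(p)
  s <- NULL
  if (isTRUE(scale)) {
    css <- as.numeric(Matrix::colSums(X^2))
    v <- (css - n * m^2) / max(n - 1, 1)
    s <- sqrt(pmax(v, 0))
    s[s < 1e-12] <- 1
  }
  B <- if (is.null(s)) X else X %*% Matrix::Diagonal(x = 1 / s)
  ms <- if (is.null(s)) m else m / s

  if (n <= p) {
    K <- as.matrix(Matrix::tcrossprod(B))
    if (centered) {
      cv <- as.numeric(B %*% ms)
      K <- K - outer(cv, rep(1, n)) - outer(rep(1, n), cv) + sum(ms^2)
    }
    ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    total <- sum(ev)
    sv <- sqrt(ev[seq_len(r)])
    keep <- which(sv > max(sv[1], 0) * 1e-6 & sv > 0)  # eigenvalue ratio 1e-12
    if (length(keep) < r) {
      warning(sprintf("rank-deficient matrix: returning %d of %d requested components",
                      length(keep), r))
    }
    U <- ee$vectors[, keep, drop = FALSE]
    sv <- sv[keep]
    V <- as.matrix(Matrix::crossprod(B, U))
    if (centered) V <- V - outer(ms, colSums(U))
    V <- sweep(V, 2, sv, "/")
  } else {
    C <- as.matrix(Matrix::crossprod(B))
    if (centered) {
      dv <- as.numeric(Matrix::colSums(B))
      C <- C - outer(ms, dv) - outer(dv, ms) + n * outer(ms, ms)
    }
    ee <- eigen((C + t(C)) / 2, symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    total <- sum(ev)
    sv <- sqrt(ev[seq_len(r)])
    keep <- which(sv > max(sv[1], 0) * 1e-6 & sv > 0)  # eigenvalue ratio 1e-12
    if (length(keep) < r) {
      warning(sprintf("rank-deficient matrix: returning %d of %d requested components",
                      length(keep), r))
    }
    V <- ee$vectors[, keep, drop = FALSE]
    sv <- sv[keep]
  }
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(V))) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(r = length(sv), loadings = V, singular_values = sv,
         explained_variance_fraction = if (total > 0) sv^2 / total else rep(0, length(sv)),
         center = if (centered) m else NULL,
         scale_ = s, centering_mode = centering, n_fit = n),
    class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("<pc_model> r = %d components (%s centering%s), %.1f%% variance explained\n",
              x$r, x$centering_mode, if (is.null(x$scale_)) "" else ", scaled",
              100 * sum(x$explained_variance_fraction)))
  invisible(x)
}

#' Project samples onto retained principal components
#'
#' Scores are `(G - center) %*% loadings` with the centering (and optional
#' scaling) applied implicitly, so sparse inputs are never densified.
#'
#' @param pc a `pc_model` from [fit_truncated_svd()].
#' @param G a [genotype_matrix()] (no missing entries) or numeric matrix with
#'   the same variant set and order as at fit time.
#' @return numeric matrix, samples x r, rownames = sample ids when available.
#' @export
transform_pcs <- function(pc, G) {
  stopifnot(inherits(pc, "pc_model"))
  ids <- NULL
  X <- if (inherits(G, "genotype_matrix")) {
    if (n_missing(G) > 0L) {
      stop("genotype matrix has missing calls; run impute_missing() first")
    }
    ids <- G$sample_ids
    G$dosages
  } else {
    ids <- rownames(G)
    as_dgc(G)
  }
  if (ncol(X) != nrow(pc$loadings)) {
    stop(sprintf("variant dimension mismatch: matrix has %d columns, model expects %d",
                 ncol(X), nrow(pc$loadings)))
  }
  V <- pc$loadings
  if (!is.null(pc$scale_)) V <- V / pc$scale_
  S <- as.matrix(X %*% V)
  if (!is.null(pc$center)) {
    ms <- if (is.null(pc$scale_)) pc$center else pc$center / pc$scale_
    S <- sweep(S, 2, as.numeric(crossprod(ms, pc$loadings)), "-")
  }
  rownames(S) <- ids
  colnames(S) <- sprintf("PC%d", seq_len(ncol(S)))
  S
}

#' Fisher linear discriminant analysis on PC scores
#'
#' Finds at most `k - 1` discriminant axes maximizing between-class over
#' pooled within-class scatter (solved by Cholesky whitening of the pooled
#' within-class covariance; axes satisfy `w' S_w w = 1`). Class priors default
#' to empirical frequencies. If the within-class covariance is numerically
#' singular, a ridge `1e-6 * tr(S_w)/r * I` is added — only then.
#'
#' @param scores numeric matrix, samples x r.
#' @param labels class labels: a [sample_labels()] object, a named vector, or
#'   a vector parallel to the rows of `scores`. Every class needs >= 2
#'   samples and there must be >= 2 classes.
#' @param priors `NULL` for empirical class frequencies, or a named/ordered
#'   non-negative vector over classes (normalized internally).
#' @return Object of class `da_model`: `k`, `class_labels` (sorted),
#'   `discriminant_axes` (r x a, a <= min(k-1, r)), `axis_eigenvalues`,
#'   `class_means` (k x r), `class_priors`, `pooled_within_scatter` (r x r
#'   covariance, symmetric).
#' @export
fit_lda <- function(scores, labels, priors = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores); r <- ncol(scores)
  if (r < 1L) stop("scores must have at least one column")
  y <- resolve_labels(labels, rownames(scores) %||% as.character(seq_len(n)))
  classes <- sort(unique(y))
  k <- length(classes)
  if (k < 2L) stop("supervised fit requires k >= 2 classes")
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2L)) {
    stop("class(es) with a single sample make the within-class scatter singular: ",
         paste(names(counts)[counts < 2L], collapse = ", "),
         " — merge classes or add samples")
  }
  agg <- vapply(classes, function(cl) colMeans(scores[y == cl, , drop = FALSE]),
                numeric(r))
  mu <- if (r == 1L) matrix(agg, ncol = 1L) else t(agg)
  Sw <- matrix(0, r, r)
  for (ci in seq_len(k)) {
    Z <- sweep(scores[y == classes[ci], , drop = FALSE], 2, mu[ci, ], "-")
    Sw <- Sw + crossprod(Z)
  }
  Sw <- Sw / (n - k)
  Sw <- (Sw + t(Sw)) / 2
  if (is.null(priors)) {
    pr <- as.numeric(counts) / n
  } else {
    pr <- if (!is.null(names(priors))) priors[classes] else priors
    if (length(pr) != k || anyNA(pr) || any(pr < 0)) stop("invalid priors")
    pr <- pr / sum(pr)
  }
  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- 1e-6 * sum(diag(Sw)) / r
    R <- chol(Sw + diag(ridge, r))
  }
  gm <- colMeans(scores)
  H <- sweep(mu, 2, gm, "-") * sqrt(as.numeric(counts))
  Sb <- crossprod(H)
  # whitened between-class scatter: R^{-T} Sb R^{-1}
  Y <- forwardsolve(t(R), Sb)
  Z <- t(forwardsolve(t(R), t(Y)))
  ee <- eigen((Z + t(Z)) / 2, symmetric = TRUE)
  a_max <- min(k - 1L, r)
  lam <- pmax(ee$values[seq_len(a_max)], 0)
  keep <- which(lam > max(lam[1], 0) * 1e-12 & lam > 0)
  W <- backsolve(R, ee$vectors[, keep, drop = FALSE])
  for (j in seq_len(ncol(W))) {
    i0 <- which.max(abs(W[, j]))
    if (W[i0, j] < 0) W[, j] <- -W[, j]
  }
  structure(
    list(k = k, class_labels = classes, discriminant_axes = W,
         axis_eigenvalues = lam[keep], class_means = mu, class_priors = pr,
         pooled_within_scatter = Sw),
    class = "da_model")
}

#' @export
print.da_model <- function(x, ...) {
  cat(sprintf("<da_model> k = %d classes, %d discriminant axes\n",
              x$k, ncol(x$discriminant_axes)))
  invisible(x)
}

# Posterior class membership under the shared-covariance Gaussian model:
# P(c | x) proportional to pi_c * exp(-0.5 * mahalanobis(x, mu_c, Sw)).
lda_posterior <- function(da, scores) {
  scores <- as.matrix(scores)
  Sw <- da$pooled_within_scatter
  r <- ncol(Sw)
  R <- tryCatch(chol(Sw), error = function(e) {
    chol(Sw + diag(1e-6 * sum(diag(Sw)) / r, r))
  })
  Wn <- t(forwardsolve(t(R), t(scores)))
  Wm <- t(forwardsolve(t(R), t(da$class_means)))
  d2 <- outer(rowSums(Wn^2), rowSums(Wm^2), "+") - 2 * tcrossprod(Wn, Wm)
  ll <- -0.5 * d2 + rep(log(da$class_priors), each = nrow(scores))
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  colnames(post) <- da$class_labels
  rownames(post) <- rownames(scores)
  post
}

#' Fit the full DAPC pipeline
#'
#' Truncated SVD on the dosage matrix followed by linear discriminant
#' analysis on the retained component scores.
#'
#' @inheritParams fit_truncated_svd
#' @param labels population labels (see [fit_lda()]).
#' @param n_pcs number of principal components retained before the DA step.
#' @param seed optional integer recorded in the model provenance (the exact
#'   solver itself is deterministic).
#' @return Object of class `dapc_model` with fields `pc_model`, `da_model`,
#'   and `provenance` (sample/variant counts, options, seed, package
#'   version).
#' @examples
#' cohort <- simulate_cohort(n_populations = 3, samples_per_population = 20,
#'                           n_snps = 200, seed = 1)
#' m <- fit_dapc(cohort$genotypes, cohort$true_labels, n_pcs = 5)
#' table(predict(m, cohort$genotypes), cohort$true_labels$label)
#' @export
fit_dapc <- function(G, labels, n_pcs, centering = c("implicit", "none"),
                     scale = FALSE, seed = NULL) {
  centering <- match.arg(centering)
  stopifnot(inherits(G, "genotype_matrix"))
  y <- resolve_labels(labels, G$sample_ids)
  pc <- fit_truncated_svd(G, r = n_pcs, centering = centering, scale = scale)
  scores <- transform_pcs(pc, G)
  da <- fit_lda(scores, y)
  structure(
    list(pc_model = pc, da_model = da,
         provenance = list(n_samples = nrow(G$dosages),
                           n_variants = ncol(G$dosages),
                           n_pcs = pc$r, centering = centering,
                           scale = isTRUE(scale), seed = seed,
                           package = "dapcr",
                           package_version = as.character(utils::packageVersion("dapcr")))),
    class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("<dapc_model> %d samples x %d variants, %d PCs -> %d classes\n",
              x$provenance$n_samples, x$provenance$n_variants,
              x$pc_model$r, x$da_model$k))
  invisible(x)
}

#' Predict population labels for new samples
#'
#' Assigns each sample to the class with the highest posterior membership
#' probability; posterior ties resolve to the first class in sorted label
#' order (deterministic).
#'
#' @param object a fitted `dapc_model`.
#' @param newdata a [genotype_matrix()] (no missing entries) or numeric
#'   dosage matrix with the training variant set and order.
#' @param type `"class"` for labels, `"prob"` for the posterior matrix.
#' @param ... unused.
#' @return character vector of labels, or a samples x k probability matrix.
#' @export
predict.dapc_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  scores <- transform_pcs(object$pc_model, newdata)
  post <- lda_posterior(object$da_model, scores)
  if (type == "prob") return(post)
  labs <- object$da_model$class_labels[apply(post, 1, which.max)]
  names(labs) <- rownames(post)
  labs
}

#' Posterior membership probabilities
#'
#' Shared-covariance Gaussian class model in PC-score space: each row is a
#' probability simplex over the k classes.
#'
#' @inheritParams predict.dapc_model
#' @param model a fitted `dapc_model`.
#' @param G new data (see [predict.dapc_model()]).
#' @return samples x k matrix of posterior probabilities (rows sum to 1).
#' @export
predict_proba <- function(model, G) {
  stopifnot(inherits(model, "dapc_model"))
  predict(model, G, type = "prob")
}

#' Discriminant-axis coordinates of samples
#'
#' Projects PC scores onto the fitted discriminant axes (the coordinates
#' shown in DAPC scatter plots).
#'
#' @param model a fitted `dapc_model`.
#' @param G a [genotype_matrix()] or dosage matrix.
#' @return samples x a matrix of discriminant coordinates.
#' @export
discriminant_coords <- function(model, G) {
  stopifnot(inherits(model, "dapc_model"))
  scores <- transform_pcs(model$pc_model, G)
  out <- scores %*% model$da_model$discriminant_axes
  colnames(out) <- sprintf("LD%d", seq_len(ncol(out)))
  out
}
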