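#' Build a cross-validation split plan
#'
#' Three schemes: plain k-fold (samples shuffled, then cut into `kcv` nearly
#' equal folds), stratified k-fold (each class split separately so per-fold
#' class counts stay within 1 of proportional allocation — the default
#' downstream, since genotype cohorts are usually imbalanced), and LOOCV
#' (every sample is its own test fold; `kcv` and `seed` are ignored). Test
#' sets are pairwise disjoint and cover all samples; every train/test pair
#' partitions the index set.
#'
#' @param n number of samples.
#' @param labels class labels (required for `"stratified"`), see [fit_lda()].
#' @param scheme `"stratified"`, `"kfold"`, or `"loocv"`.
#' @param kcv number of folds, `2 <= kcv <= n`.
#' @param seed shuffling seed; mandatory for `"kfold"` and `"stratified"` so
#'   plans are reproducible.
#' @return Object of class `split_plan`: `scheme`, `kcv`, `seed`, `n`,
#'   `folds` — a list of `list(train = ..., test = ...)` index vectors.
#' @examples
#' plan <- make_split_plan(10, scheme = "kfold", kcv = 5, seed = 1)
#' lengths(lapply(plan$folds, `[[`, "test"))
#' @export
make_split_plan <- function(n, labels = NULL,
                            scheme = c("stratified", "kfold", "loocv"),
                            kcv = 10L, seed = NULL) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  if (scheme == "loocv") {
    folds <- lapply(seq_len(n), function(i) {
      list(train = setdiff(seq_len(n), i), test = i)
    })
    return(structure(list(scheme = scheme, kcv = n, seed = NULL, n = n,
                          folds = folds), class = "split_plan"))
  }
  kcv <- as.integer(kcv)
  if (kcv < 2L || kcv > n) stop("kcv must satisfy 2 <= kcv <= n")
  if (is.null(seed)) stop("a seed is required for shuffled split plans")
  test_sets <- withr::with_seed(as.integer(seed), {
    if (scheme == "kfold") {
      idx <- sample.int(n)
      sizes <- rep(n %/% kcv, kcv) + (seq_len(kcv) <= n %% kcv)
      split(idx, rep.int(seq_len(kcv), sizes))
    } else {
      if (is.null(labels)) stop("stratified splits require labels")
      # positional: label i belongs to sample/row i of the companion matrix
      y <- if (inherits(labels, "sample_labels")) labels$label else as.character(labels)
      if (length(y) != n) stop("labels length does not match n")
      sets <- rep(list(integer(0)), kcv)
      for (cl in sort(unique(y))) {
        members <- which(y == cl)
        nc <- length(members)
        if (nc < kcv) {
          stop(sprintf("class '%s' has %d samples, fewer than kcv = %d folds — cannot stratify",
                       cl, nc, kcv))
        }
        members <- sample(members)
        sizes <- rep(nc %/% kcv, kcv)
        extra <- sample.int(kcv, nc %% kcv)  # spread remainders across folds
        sizes[extra] <- sizes[extra] + 1L
        chunks <- split(members, rep.int(seq_len(kcv), sizes))
        for (f in seq_len(kcv)) sets[[f]] <- c(sets[[f]], chunks[[f]])
      }
      sets
    }
  })
  folds <- lapply(test_sets, function(ts) {
    ts <- sort(as.integer(ts))
    list(train = setdiff(seq_len(n), ts), test = ts)
  })
  structure(list(scheme = scheme, kcv = kcv, seed = as.integer(seed), n = n,
                 folds = unname(folds)), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d folds over %d samples (seed %s)\n",
              x$scheme, x$kcv, x$n, x$seed %||% "-"))
  invisible(x)
}

#' Classification accuracy
#'
#' Fraction of positions where predicted and true labels match exactly.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return a number in `[0, 1]`.
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors have different lengths")
  }
  if (length(true_labels) == 0L) stop("empty label vectors")
  mean(as.character(true_labels) == as.character(predicted_labels))
}

#' Cross-validate a DAPC fit
#'
#' For each fold the truncated SVD and the discriminant analysis are fitted
#' on the training fold only; the held-out samples are projected with the
#' training-fold centering vector and loadings and then classified, so no
#' information leaks from test to train.
#'
#' @param G a [genotype_matrix()] with no missing entries.
#' @param labels population labels (see [fit_lda()]).
#' @param n_pcs number of retained PCs per fold (must be feasible for every
#'   training fold).
#' @param plan a [make_split_plan()] for `nrow(G)` samples.
#' @param centering,scale passed to [fit_truncated_svd()].
#' @param keep_models if `TRUE`, the per-fold `dapc_model`s are returned
#'   (useful for audits; memory scales with `kcv`).
#' @return Object of class `cv_result`: `per_fold_accuracy`, `mean_accuracy`,
#'   `sd_accuracy`, `predictions` (per-fold list of named predicted labels),
#'   `plan`, `n_pcs`, optionally `models`.
#' @export
cross_validate <- function(G, labels, n_pcs, plan,
                           centering = c("implicit", "none"), scale = FALSE,
                           keep_models = FALSE) {
  centering <- match.arg(centering)
  stopifnot(inherits(G, "genotype_matrix"), inherits(plan, "split_plan"))
  if (plan$n != nrow(G$dosages)) stop("plan was built for a different sample count")
  y <- resolve_labels(labels, G$sample_ids)
  classes <- sort(unique(y))
  acc <- numeric(length(plan$folds))
  preds <- vector("list", length(plan$folds))
  models <- if (keep_models) vector("list", length(plan$folds)) else NULL
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train
    te <- plan$folds[[f]]$test
    lost <- setdiff(classes, unique(y[tr]))
    if (length(lost)) {
      stop(sprintf("fold %d training set lost class(es) %s — use a stratified plan",
                   f, paste(lost, collapse = ", ")))
    }
    m <- fit_dapc(G[tr, ], y[tr], n_pcs = n_pcs, centering = centering,
                  scale = scale)
    ph <- predict(m, G[te, ])
    acc[f] <- accuracy(y[te], ph)
    preds[[f]] <- ph
    if (keep_models) models[[f]] <- m
  }
  structure(
    list(per_fold_accuracy = acc, mean_accuracy = mean(acc),
         sd_accuracy = stats::sd(acc), predictions = preds, plan = plan,
         n_pcs = n_pcs, models = models),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s %d-fold, n_pcs = %d: mean accuracy %.4f (sd %.4f)\n",
              x$plan$scheme, x$plan$kcv, x$n_pcs, x$mean_accuracy,
              x$sd_accuracy))
  invisible(x)
}

#' Grid search over the number of retained PCs
#'
#' Runs [cross_validate()] for every candidate and keeps the full accuracy
#' table. The winner is the candidate with the highest mean accuracy; ties go
#' to the smallest candidate (parsimony guards against overfitting).
#'
#' @inheritParams cross_validate
#' @param grid non-empty vector of candidate `n_pcs` values.
#' @return Object of class `grid_search_result`: `grid`, `table` (data frame
#'   with `n_pcs`, `mean_accuracy`, `sd_accuracy`), `best_n_pcs`,
#'   `results` (list of `cv_result`).
#' @export
grid_search_pcs <- function(G, labels, grid, plan,
                            centering = c("implicit", "none"), scale = FALSE) {
  centering <- match.arg(centering)
  grid <- as.integer(grid)
  if (length(grid) == 0L || anyNA(grid)) stop("grid must be a non-empty integer vector")
  grid <- sort(unique(grid))
  results <- lapply(grid, function(np) {
    tryCatch(
      cross_validate(G, labels, n_pcs = np, plan = plan,
                     centering = centering, scale = scale),
      error = function(e) stop(sprintf("grid value n_pcs = %d failed: %s",
                                       np, conditionMessage(e)), call. = FALSE))
  })
  tab <- data.frame(
    n_pcs = grid,
    mean_accuracy = vapply(results, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(results, `[[`, numeric(1), "sd_accuracy"))
  best <- min(grid[tab$mean_accuracy == max(tab$mean_accuracy)])
  structure(list(grid = grid, table = tab, best_n_pcs = best,
                 results = results),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> best n_pcs = %d\n", x$best_n_pcs))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Default PC grid for grid search
#'
#' `10, 20, ..., 120`, truncated to what the training folds can support.
#'
#' @param n_samples,n_variants data dimensions.
#' @param kcv fold count (training folds have about `n (kcv-1)/kcv` samples).
#' @param step,cap grid step and upper cap.
#' @return integer vector of candidate PC counts.
#' @export
default_pc_grid <- function(n_samples, n_variants, kcv = 10L, step = 10L,
                            cap = 120L) {
  n_train <- floor(n_samples * (kcv - 1) / kcv)
  rmax <- min(n_train, n_variants) - 1L
  g <- seq.int(step, min(cap, rmax), by = step)
  if (length(g) == 0L) g <- max(1L, rmax)
  as.integer(g)
}

#' The k - 1 rule for retained PCs
#'
#' For k clusters, k - 1 principal components carry all the between-group
#' information the discriminant step can use; this rule retains exactly that
#' many.
#'
#' @param k number of clusters/populations (>= 2).
#' @return `k - 1`.
#' @examples
#' k_minus_one_pcs(4)
#' @export
k_minus_one_pcs <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2) {
    stop("k must be a single number >= 2")
  }
  as.integer(k) - 1L
}

#' Mean accuracy across training-set sizes
#'
#' Convenience sweep: for each training fraction, draw a stratified training
#' subset, fit on it, and score the held-out remainder; repeated `n_reps`
#' times per fraction. A descriptive diagnostic, not a formal CV scheme.
#'
#' @inheritParams cross_validate
#' @param fractions training fractions in (0, 1).
#' @param n_reps repetitions per fraction.
#' @param seed RNG seed for the subsamples.
#' @return data frame with `fraction`, `rep`, `accuracy`.
#' @export
train_fraction_sweep <- function(G, labels, n_pcs,
                                 fractions = seq(0.5, 0.9, by = 0.1),
                                 n_reps = 3L, seed = 1L,
                                 centering = c("implicit", "none")) {
  centering <- match.arg(centering)
  stopifnot(inherits(G, "genotype_matrix"))
  y <- resolve_labels(labels, G$sample_ids)
  n <- nrow(G$dosages)
  out <- withr::with_seed(as.integer(seed), {
    rows <- list()
    for (fr in fractions) {
      for (rep_i in seq_len(n_reps)) {
        tr <- unlist(lapply(sort(unique(y)), function(cl) {
          members <- which(y == cl)
          sample(members, max(2L, round(fr * length(members))))
        }))
        te <- setdiff(seq_len(n), tr)
        m <- fit_dapc(G[tr, ], y[tr], n_pcs = n_pcs, centering = centering)
        rows[[length(rows) + 1L]] <-
          data.frame(fraction = fr, rep = rep_i,
                     accuracy = accuracy(y[te], predict(m, G[te, ])))
      }
    }
    rows
  })
  do.call(rbind, out)
}
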