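#' K-means clustering of PC scores
#'
#' Lloyd iterations from k-means++ starts, repeated `n_init` times; the run
#' with the lowest within-cluster sum of squares (SSE) wins. Deterministic
#' given `(seed, n_init)`.
#'
#' @param scores numeric matrix, samples x r (principal component scores).
#' @param k number of clusters, `2 <= k <= n`.
#' @param seed RNG seed for the restarts.
#' @param n_init number of k-means++ restarts (>= 1).
#' @return Object of class `cluster_solution`: `k`, `centroids` (k x r),
#'   `assignments` (integer 1..k, named by sample when scores have
#'   rownames), `sse`, `silhouette` (mean silhouette, `NA` when `n < 3`),
#'   `seed`, `n_init`.
#' @export
fit_kmeans <- function(scores, k, seed = 1L, n_init = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n_samples")
  if (n_init < 1L) stop("n_init must be >= 1")
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_init)) {
      init <- kmeanspp_init(scores, k)
      km <- tryCatch(
        suppressWarnings(  # Lloyd may report hitting iter.max; result still usable
          stats::kmeans(scores, centers = init, iter.max = 100L,
                        algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next  # empty-cluster restart: discard
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("all k-means restarts failed; reduce k")
  assign_ <- as.integer(best$cluster)
  names(assign_) <- rownames(scores)
  sil <- if (n >= 3L && length(unique(assign_)) >= 2L) {
    silhouette_score(scores, assign_)
  } else NA_real_
  structure(
    list(k = k, centroids = unname(best$centers), assignments = assign_,
         sse = best$tot.withinss, silhouette = as.numeric(sil),
         seed = as.integer(seed), n_init = as.integer(n_init)),
    class = "cluster_solution")
}

# k-means++ seeding: first centroid uniform, then D^2-weighted draws.
kmeanspp_init <- function(scores, k) {
  n <- nrow(scores)
  centers <- matrix(NA_real_, k, ncol(scores))
  centers[1, ] <- scores[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(scores, 2, centers[1, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- scores[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(scores, 2, centers[j, ], "-")^2))
  }
  # stats::kmeans requires distinct centers; jitter exact duplicates
  if (anyDuplicated(centers)) {
    dup <- duplicated(centers)
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::rnorm(sum(dup) * ncol(centers), sd = 1e-8)
  }
  centers
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d: SSE %.4g, mean silhouette %.3f\n",
              x$k, x$sse, x$silhouette))
  invisible(x)
}

#' Mean silhouette coefficient
#'
#' For sample i with intra-cluster mean distance `a` and smallest mean
#' distance to another cluster `b`, the silhouette is `(b - a) / max(a, b)`;
#' members of singleton clusters contribute 0 (the standard convention). The
#' mean over samples lies in `[-1, 1]`.
#'
#' @param scores numeric matrix, samples x r.
#' @param assignments integer/factor cluster assignment per sample, >= 2
#'   distinct non-empty clusters, `n >= 3`.
#' @return mean silhouette (numeric scalar) with attribute `per_sample`.
#' @export
silhouette_score <- function(scores, assignments) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 3L) stop("silhouette requires at least 3 samples")
  cl <- as.integer(factor(assignments))
  if (length(cl) != n) stop("assignments length mismatch")
  k <- max(cl)
  if (k < 2L) stop("silhouette is undefined for a single cluster")
  D <- as.matrix(stats::dist(scores))
  sizes <- tabulate(cl, k)
  # mean distance from each sample to each cluster
  md <- vapply(seq_len(k), function(c2) {
    rowSums(D[, cl == c2, drop = FALSE]) / sizes[c2]
  }, numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cl[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1L)  # exclude self
    b <- min(md[i, -ci])
    s[i] <- (b - a) / max(a, b)
  }
  structure(mean(s), per_sample = s)
}

#' Sweep candidate cluster numbers
#'
#' Fits [fit_kmeans()] for each k and tabulates SSE and mean silhouette so
#' the user can apply elbow judgement. Automated selection (rule
#' `"max_silhouette"`, the default) takes the k with the highest mean
#' silhouette, smallest k on ties; with rule `"manual"` no k is selected and
#' only the table is returned. SSE is never auto-thresholded.
#'
#' @inheritParams fit_kmeans
#' @param k_range candidate cluster counts within `[2, n_samples]`.
#' @param rule `"max_silhouette"` or `"manual"`.
#' @return Object of class `ksweep_result`: `table` (data frame `k`, `sse`,
#'   `silhouette`), `selected_k` (`NA` under `"manual"`), `selection_rule`,
#'   `solutions` (list of `cluster_solution`).
#' @export
sweep_k <- function(scores, k_range = 2:8, seed = 1L, n_init = 10L,
                    rule = c("max_silhouette", "manual")) {
  rule <- match.arg(rule)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(as.matrix(scores))
  if (any(k_range < 2L) || any(k_range > n)) {
    stop("k_range must lie within [2, n_samples]")
  }
  sols <- lapply(k_range, function(k) {
    tryCatch(fit_kmeans(scores, k, seed = seed, n_init = n_init),
             error = function(e) stop(sprintf("k = %d failed: %s", k,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  tab <- data.frame(
    k = k_range,
    sse = vapply(sols, `[[`, numeric(1), "sse"),
    silhouette = vapply(sols, `[[`, numeric(1), "silhouette"))
  selected <- if (rule == "max_silhouette") {
    min(tab$k[tab$silhouette == max(tab$silhouette)])
  } else NA_integer_
  structure(list(table = tab, selected_k = selected, selection_rule = rule,
                 solutions = sols),
            class = "ksweep_result")
}

#' @export
print.ksweep_result <- function(x, ...) {
  cat(sprintf("<ksweep_result> rule %s, selected k = %s\n",
              x$selection_rule, x$selected_k))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Turn a clustering into population labels
#'
#' Cluster indices become labels `cluster_1 ... cluster_k` consumable by
#' [fit_dapc()] and [cross_validate()] for de novo analyses.
#'
#' @param solution a `cluster_solution` from [fit_kmeans()].
#' @param sample_ids optional ids; defaults to the assignment names or
#'   `sample_<i>`.
#' @return a [sample_labels()] object.
#' @export
labels_from_clusters <- function(solution, sample_ids = NULL) {
  stopifnot(inherits(solution, "cluster_solution"))
  ids <- sample_ids %||% names(solution$assignments) %||%
    sprintf("sample_%d", seq_along(solution$assignments))
  sample_labels(ids, sprintf("cluster_%d", solution$assignments))
}

#' Heuristic PC count for de novo clustering
#'
#' Smallest number of leading components whose cumulative explained-variance
#' fraction reaches `threshold` (relative to the variance captured by the
#' fitted components), capped at `cap`. A pragmatic default the method does
#' not fix; inspect the sweep table rather than trusting it blindly.
#'
#' @param pc a `pc_model` from [fit_truncated_svd()].
#' @param threshold cumulative fraction target in (0, 1].
#' @param cap hard upper bound on the count.
#' @return integer PC count.
#' @export
choose_n_pcs <- function(pc, threshold = 0.9, cap = 120L) {
  stopifnot(inherits(pc, "pc_model"))
  f <- cumsum(pc$explained_variance_fraction) /
    sum(pc$explained_variance_fraction)
  min(which(f >= threshold)[1], cap, pc$r)
}
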