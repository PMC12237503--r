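test_that("fit_truncated_svd recovers a diagonal SVD without centering", {
  pc <- fit_truncated_svd(diag(c(3, 1)), r = 1, centering = "none")
  expect_equal(pc$singular_values, 3)
  expect_equal(abs(pc$loadings[, 1]), c(1, 0), tolerance = 1e-12)
  expect_equal(pc$explained_variance_fraction, 9 / 10)
})

test_that("implicit-centered truncated SVD reproduces classical PCA", {
  # oracle: eigendecomposition of the covariance matrix, computed directly
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(20:60, 1); p <- sample(10:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    r <- min(n, p) - 1L
    pc <- fit_truncated_svd(X, r = r)
    ee <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(pc$singular_values^2 / (n - 1), ee$values[seq_len(r)],
                 tolerance = 1e-8)
    S <- transform_pcs(pc, X)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    S_ref <- Xc %*% ee$vectors[, seq_len(r), drop = FALSE]
    sg <- sign(colSums(S * S_ref))
    expect_equal(S, sweep(S_ref, 2, sg, "*"), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # loadings orthonormal; variance fractions non-increasing, sum <= 1
    expect_equal(crossprod(pc$loadings), diag(r), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(pc$explained_variance_fraction) <= 1e-12))
    expect_lte(sum(pc$explained_variance_fraction), 1 + 1e-8)
  }
})

test_that("both Gram routes (n <= p and n > p) agree", {
  set.seed(7)
  X <- matrix(rpois(30 * 50, 1), 30, 50)
  p1 <- fit_truncated_svd(X, r = 5)           # n < p route
  Xt <- rbind(X, X[1:25, ] + matrix(rnorm(25 * 50, sd = .1), 25))  # n > p
  p3 <- fit_truncated_svd(Xt, r = 5)
  expect_equal(p1$singular_values,
               svd(scale(X, center = TRUE, scale = FALSE))$d[1:5],
               tolerance = 1e-8)
  expect_equal(p3$singular_values,
               svd(scale(Xt, center = TRUE, scale = FALSE))$d[1:5],
               tolerance = 1e-8)
  # loadings agree with the dense SVD up to sign on both routes
  V3 <- svd(scale(Xt, center = TRUE, scale = FALSE))$v[, 1:5]
  sg <- sign(colSums(p3$loadings * V3))
  expect_equal(p3$loadings, sweep(V3, 2, sg, "*"), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("svd parameter validation, rank deficiency, and scaling", {
  X <- matrix(rnorm(20 * 10), 20, 10)
  expect_error(fit_truncated_svd(X, r = 10), "r must be")
  expect_error(fit_truncated_svd(X, r = 0), "r must be")
  co <- tiny_cohort(missing_rate = 0.1)
  expect_error(fit_truncated_svd(co$genotypes, 3), "impute_missing")
  # rank-2 matrix cannot yield 4 components
  set.seed(1)
  low <- matrix(rnorm(20), 10, 2) %*% matrix(rnorm(10), 2, 5)
  expect_warning(pc <- fit_truncated_svd(low, r = 4), "rank-deficient")
  expect_lte(pc$r, 2L)
  # unit-variance scaling: scaled scores match prcomp(scale.=TRUE)
  pcs <- fit_truncated_svd(X, r = 3, scale = TRUE)
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(pcs$singular_values^2 / 19, pr$sdev[1:3]^2, tolerance = 1e-8)
})

test_that("transform_pcs is consistent and handles edge inputs", {
  co <- tiny_cohort(seed = 3)
  pc <- fit_truncated_svd(co$genotypes, r = 5)
  S <- transform_pcs(pc, co$genotypes)
  expect_identical(rownames(S), co$genotypes$sample_ids)
  # a sample equal to the column means scores zero under implicit centering
  mid <- matrix(pc$center, nrow = 1)
  expect_equal(as.numeric(transform_pcs(pc, mid)), rep(0, 5),
               tolerance = 1e-10)
  # duplicated training sample gets the training score row
  dup <- as.matrix(co$genotypes$dosages[7, , drop = FALSE])
  expect_equal(as.numeric(transform_pcs(pc, dup)), as.numeric(S[7, ]),
               tolerance = 1e-10)
  expect_error(transform_pcs(pc, matrix(0, 2, 3)), "mismatch")
})

test_that("fit_lda solves separable toy problems with the k-1 axis bound", {
  # two classes on a line
  S <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("A", "A", "B", "B")
  da <- fit_lda(S, y)
  expect_identical(ncol(da$discriminant_axes), 1L)
  post <- dapcr:::lda_posterior(da, S)
  expect_identical(da$class_labels[apply(post, 1, which.max)], y)
  # decision boundary between -1 and 1: symmetric midpoint gives 0.5/0.5
  p_mid <- dapcr:::lda_posterior(da, matrix(0, 1, 1))
  expect_equal(as.numeric(p_mid), c(0.5, 0.5), tolerance = 1e-12)

  # three well-separated blobs in 5-D: exactly 2 axes
  b <- blob_scores(k = 3, r = 5, seed = 2)
  da3 <- fit_lda(b$scores, b$labels)
  expect_identical(ncol(da3$discriminant_axes), 2L)
  expect_equal(sum(da3$class_priors), 1)
  expect_equal(da3$pooled_within_scatter, t(da3$pooled_within_scatter),
               tolerance = 1e-10)
  # axes normalized against within-class scatter: w' Sw w = 1
  W <- da3$discriminant_axes
  expect_equal(diag(t(W) %*% da3$pooled_within_scatter %*% W), rep(1, 2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fit_lda errors and regularization", {
  S <- matrix(rnorm(10), 5, 2)
  expect_error(fit_lda(S, c("A", "A", "A", "A", "B")), "single sample")
  expect_error(fit_lda(S, rep("A", 5)), "k >= 2")
  # collinear scores: ridge keeps the fit well-defined
  S2 <- cbind(rnorm(20), 0)
  da <- fit_lda(S2, rep(c("A", "B"), each = 10))
  expect_true(all(is.finite(da$discriminant_axes)))
})

test_that("permuted labels on structureless data give chance-level training accuracy", {
  set.seed(42)
  accs <- replicate(10, {
    S <- matrix(rnorm(60 * 4), 60, 4)
    y <- sample(rep(c("A", "B", "C"), each = 20))
    da <- fit_lda(S, y)
    post <- dapcr:::lda_posterior(da, S)
    mean(da$class_labels[apply(post, 1, which.max)] == y)
  })
  # training accuracy exceeds 1/3 by the optimism of refitting, but must stay
  # far below genuine separation
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.65)
})

test_that("posterior probabilities are simplex rows with sensible geometry", {
  co <- tiny_cohort(seed = 8)
  m <- fit_dapc(co$genotypes, co$true_labels, n_pcs = 6)
  post <- predict_proba(m, co$genotypes)
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(post >= 0))
  # a sample placed at a class mean is most likely that class
  da <- m$da_model
  p_at_mean <- dapcr:::lda_posterior(da, da$class_means)
  expect_identical(unname(apply(p_at_mean, 1, which.max)), seq_len(da$k))
})

test_that("predict is equivariant under label permutation", {
  co <- tiny_cohort(seed = 10)
  perm <- c(pop_1 = "zebra", pop_2 = "apple", pop_3 = "mango")
  m1 <- fit_dapc(co$genotypes, co$true_labels$label, n_pcs = 5)
  m2 <- fit_dapc(co$genotypes, unname(perm[co$true_labels$label]), n_pcs = 5)
  p1 <- predict(m1, co$genotypes)
  p2 <- predict(m2, co$genotypes)
  expect_identical(unname(perm[p1]), unname(p2))
})

test_that("dapc recovers simulated population labels across seeds", {
  for (seed in 1:3) {
    co <- simulate_cohort(n_populations = 4, samples_per_population = 25,
                          n_snps = 500, fst = 0.1, seed = seed)
    m <- fit_dapc(co$genotypes, co$true_labels, n_pcs = 10)
    expect_gte(accuracy(co$true_labels$label, predict(m, co$genotypes)), 0.95)
  }
})
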