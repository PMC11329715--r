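test_that("Grafen branch lengths give an ultrametric unit-depth tree", {
  cherry <- grafen_lengths(ape::read.tree(text = "(A,B);"))
  expect_equal(sort(cherry$edge.length), c(1, 1))

  ladder <- grafen_lengths(ape::read.tree(text = "(A,(B,(C,(D,E))));"))
  depths <- diag(phylo_covariance(ladder))
  expect_equal(unname(depths), rep(1, 5), tolerance = 1e-12)
  # hand-computed Grafen heights (heights = (tips below - 1)/(n - 1)):
  # root 1, then 3/4, 2/4, 1/4 down the ladder
  C <- phylo_covariance(ladder)
  expect_equal(unname(C["D", "E"]), 3 / 4)
  expect_equal(unname(C["C", "D"]), 2 / 4)
  expect_equal(unname(C["B", "E"]), 1 / 4)
  expect_equal(unname(C["A", "E"]), 0)

  expect_error(grafen_lengths(ape::read.tree(text = "(A);")),
               class = "vipertherm_invalid_tree")
})

test_that("phylogenetic covariance matches a path-enumeration oracle", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_covariance(star)), diag(4), tolerance = 1e-12)

  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_covariance(cherry)), diag(2), tolerance = 1e-12)

  bal <- ape::read.tree(text = "((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
  C <- phylo_covariance(bal)
  # shared root-to-MRCA path lengths enumerated by hand
  oracle <- rbind(c(1.5, 0.5, 0, 0),
                  c(0.5, 1.5, 0, 0),
                  c(0, 0, 1.5, 0.8),
                  c(0, 0, 0.8, 1.5))
  dimnames(oracle) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  expect_equal(C[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-12)
})

test_that("Blomberg's K: star-tree identity, worked example, invariances", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(1)
  for (i in 1:5) {
    expect_equal(blomberg_k(rnorm(5), star), 1, tolerance = 1e-12)
  }

  # 3-tip worked example against an explicit matrix-algebra oracle
  tr3 <- ape::read.tree(text = "((A:0.6,B:0.6):0.4,C:1);")
  y <- c(A = 2.3, B = 1.1, C = -0.7)
  C <- phylo_covariance(tr3)[c("A", "B", "C"), c("A", "B", "C")]
  yv <- unname(y)
  Ci <- solve(C)
  one <- rep(1, 3)
  a <- sum(Ci %*% yv) / sum(Ci)
  mse0 <- sum((yv - a)^2) / 2
  mse <- drop(t(yv - a) %*% Ci %*% (yv - a)) / 2
  k_oracle <- (mse0 / mse) / ((sum(diag(C)) - 3 / sum(Ci)) / 2)
  expect_equal(blomberg_k(y, tr3), k_oracle, tolerance = 1e-12)

  # affine trait transform and uniform branch rescaling leave K unchanged
  tr <- grafen_lengths(ape::stree(8, "balanced"))
  set.seed(2)
  x <- as.numeric(simulate_bm(tr))
  expect_equal(blomberg_k(3.2 * x - 7, tr), blomberg_k(x, tr),
               tolerance = 1e-10)
  tr_scaled <- tr
  tr_scaled$edge.length <- tr$edge.length * 42
  expect_equal(blomberg_k(x, tr_scaled), blomberg_k(x, tr),
               tolerance = 1e-10)

  expect_error(blomberg_k(rep(1, 8), tr), class = "vipertherm_degenerate_trait")
})

test_that("K matches the reference implementation on fixed data", {
  skip_if_not_installed("phytools")
  tr <- grafen_lengths(ape::read.tree(text = "(VA,(LA,(TY,(TO,KU))));"))
  y <- c(TO = 30.09, KU = 28.95, TY = 28.74, LA = 30.26, VA = 26.77)
  ref <- phytools::phylosig(tr, y, method = "K")
  expect_equal(blomberg_k(y, tr), as.numeric(ref), tolerance = 1e-6)
})

test_that("K permutation test behaves at both extremes", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(3)
  res <- blomberg_k_test(rnorm(5), star, n_perm = 199, seed = 3)
  expect_equal(res$p_k, 1)

  # strongly clade-structured trait on a deep tree is detected
  tr16 <- grafen_lengths(ape::stree(16, "balanced"))
  y <- c(rep(10, 8), rep(0, 8)) + rnorm(16, 0, 0.1)
  names(y) <- tr16$tip.label
  res2 <- blomberg_k_test(y, tr16, n_perm = 999, seed = 4)
  expect_lte(res2$p_k, 0.05)
  expect_gte(res2$p_k, 1 / 1000)

  expect_error(blomberg_k_test(y, tr16, n_perm = 10),
               class = "vipertherm_invalid_config")
})

test_that("lambda likelihood is exact at lambda = 1 and the optimizer is sound", {
  tr <- grafen_lengths(ape::stree(16, "balanced"))
  C <- phylo_covariance(tr)
  set.seed(5)
  y <- as.numeric(simulate_bm(tr))

  # lambda = 1 likelihood equals the untransformed Brownian-motion likelihood
  Ci <- solve(C)
  n <- 16
  a <- sum(Ci %*% y) / sum(Ci)
  s2 <- drop(t(y - a) %*% Ci %*% (y - a)) / n
  ll_bm <- -0.5 * (n * log(2 * pi * s2) + determinant(C)$modulus[1] + n)
  fit <- pagel_lambda_ml(y, tr, lambda_bounds = c(1, 1 + 1e-12))
  expect_equal(fit$loglik_at_hat, ll_bm, tolerance = 1e-8)

  # optimizer matches a 0.001-step grid-search oracle
  fit_free <- pagel_lambda_ml(y, tr)
  grid <- seq(0, fit_free$lambda_max * 0.99999, by = 0.001)
  ll <- vapply(grid, vipertherm:::lambda_loglik, numeric(1), y = y, C = C)
  expect_lt(abs(fit_free$lambda_hat - grid[which.max(ll)]), 0.01)

  # destroyed signal: permuted tips give lambda near 0 on average
  set.seed(6)
  lams <- replicate(40, {
    pagel_lambda_ml(sample(y), tr)$lambda_hat
  })
  expect_lt(mean(lams), 0.4)

  # uniform branch rescaling leaves lambda-hat unchanged
  tr_s <- tr
  tr_s$edge.length <- tr$edge.length * 17
  expect_equal(pagel_lambda_ml(y, tr_s)$lambda_hat, fit_free$lambda_hat,
               tolerance = 1e-4)
})

test_that("lambda matches the reference implementation on fixed data", {
  skip_if_not_installed("phytools")
  tr <- grafen_lengths(ape::stree(16, "balanced"))
  set.seed(8)
  y <- as.numeric(simulate_bm(tr)) + rnorm(16, 0, 0.5)
  names(y) <- tr$tip.label
  ref <- phytools::phylosig(tr, y, method = "lambda")
  fit <- pagel_lambda_ml(y, tr)
  expect_equal(fit$lambda_hat, ref$lambda, tolerance = 1e-3)
  expect_equal(fit$loglik_at_hat, ref$logL, tolerance = 1e-4)
})

test_that("likelihood-ratio test arithmetic and edge cases", {
  # chi-squared(1) critical value maps to p = 0.05
  expect_equal(pchisq(3.841459, df = 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-5)

  # iid trait on a star tree: lambda irrelevant, p must be 1 or near it
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(9)
  res <- lambda_lr_test(rnorm(5), star)
  expect_gte(res$p_lambda, 0.99)
})

test_that("phylo_signal wraps both tests and assigns Grafen lengths", {
  tr <- generate_phylogeny(c("TO", "KU", "TY", "LA", "VA"))  # no lengths
  y <- c(TO = 30.09, KU = 28.95, TY = 28.74, LA = 30.26, VA = 26.77)
  res <- phylo_signal(y, tr, n_perm = 199, seed = 10)
  expect_s3_class(res, "signal_result")
  expect_gt(res$k_stat, 0)
  expect_true(res$p_k >= 0 && res$p_k <= 1)
  expect_gte(res$lambda_hat, 0)
  expect_true(res$p_lambda >= 0 && res$p_lambda <= 1)
  # determinism under the seed
  res2 <- phylo_signal(y, tr, n_perm = 199, seed = 10)
  expect_identical(res$p_k, res2$p_k)
})
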