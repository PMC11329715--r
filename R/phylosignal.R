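#' Assign Grafen branch lengths
#'
#' Node heights proportional to the number of descendant tips, scaled so the
#' root-to-tip depth is 1; yields an ultrametric tree (the `compute.brlen`
#' Grafen method).
#'
#' @param tree an [ape::phylo], branch lengths ignored/absent.
#' @return ultrametric `phylo` with unit depth.
#' @export
grafen_lengths <- function(tree) {
  if (!inherits(tree, "phylo")) vt_stop("invalid_tree", "`tree` must be a phylo")
  if (length(tree$tip.label) < 2L) {
    vt_stop("invalid_tree", "need at least 2 tips")
  }
  ape::compute.brlen(tree, method = "Grafen")
}

#' Brownian-motion covariance of a phylogeny
#'
#' `C[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds tip depths.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix, tips in `tree$tip.label`
#'   order.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) {
    vt_stop("invalid_tree", "tree has no branch lengths; see grafen_lengths()")
  }
  ape::vcv.phylo(tree)
}

align_trait <- function(trait, tree) {
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss)) {
      vt_stop("invalid_config",
              paste0("trait missing tips: ", paste(miss, collapse = ", ")))
    }
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    vt_stop("invalid_config", "trait length must match the number of tips")
  }
  as.numeric(trait)
}

# GLS pieces shared by K and lambda: phylogenetic mean and quadratic form.
gls_pieces <- function(y, C) {
  Ci <- solve(C)
  one <- rep(1, length(y))
  denom <- as.numeric(t(one) %*% Ci %*% one)
  a_hat <- as.numeric(t(one) %*% Ci %*% y) / denom
  r <- y - a_hat
  list(Ci = Ci, a_hat = a_hat, r = r, denom = denom,
       q = as.numeric(t(r) %*% Ci %*% r))
}

#' Blomberg's K statistic
#'
#' Ratio of the observed mean-squared-error ratio (trait variance about the
#' phylogenetic mean over the phylogenetically corrected MSE) to its
#' expectation under Brownian motion on the given tree. K is about 1 under
#' Brownian evolution, below 1 when relatives resemble each other less than
#' Brownian motion predicts.
#'
#' @param trait numeric vector, named by tip label or in tip order.
#' @param tree a `phylo` with branch lengths.
#' @return K (positive scalar).
#' @export
blomberg_k <- function(trait, tree) {
  y <- align_trait(trait, tree)
  n <- length(y)
  if (n < 3L) vt_stop("invalid_tree", "need at least 3 tips for K")
  if (stats::sd(y) == 0) vt_stop("degenerate_trait", "trait is constant")
  C <- phylo_covariance(tree)
  g <- gls_pieces(y, C)
  mse0 <- sum(g$r^2) / (n - 1)
  mse <- g$q / (n - 1)
  expected <- (sum(diag(C)) - n / g$denom) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for Blomberg's K
#'
#' Shuffles trait values across tips and recomputes K; the p-value is
#' `(1 + #\{K_perm >= K_obs\}) / (n_perm + 1)`.
#'
#' @param trait,tree as in [blomberg_k()].
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `k_stat` and `p_k`.
#' @export
blomberg_k_test <- function(trait, tree, n_perm = 999, seed = 1) {
  if (n_perm < 99) vt_stop("invalid_config", "`n_perm` must be >= 99")
  y <- align_trait(trait, tree)
  k_obs <- blomberg_k(y, tree)
  k_perm <- with_stage_seed(seed, "k_permutation", {
    vapply(seq_len(n_perm), function(i) blomberg_k(sample(y), tree),
           numeric(1))
  })
  # tiny tolerance so permutation-invariant configurations (star trees)
  # count as ties despite floating-point summation order
  list(k_stat = k_obs,
       p_k = (1 + sum(k_perm >= k_obs - 1e-8)) / (n_perm + 1))
}

# Lambda-transformed covariance: off-diagonals scaled by lambda.
lambda_cov <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Profile (sigma2 and mean maximized out) log-likelihood of lambda.
lambda_loglik <- function(lambda, y, C) {
  Cl <- lambda_cov(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  n <- length(y)
  logdet <- 2 * sum(log(diag(ch)))
  Ci <- chol2inv(ch)
  one <- rep(1, n)
  a_hat <- as.numeric(t(one) %*% Ci %*% y) / as.numeric(t(one) %*% Ci %*% one)
  r <- y - a_hat
  s2 <- as.numeric(t(r) %*% Ci %*% r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

# Largest lambda keeping C(lambda) positive-definite (up to `cap`).
lambda_max_pd <- function(C, cap = 10) {
  pd <- function(l) {
    ev <- min(eigen(lambda_cov(C, l), symmetric = TRUE,
                    only.values = TRUE)$values)
    ev > 1e-10
  }
  if (pd(cap)) return(cap)
  lo <- 1
  hi <- cap
  if (!pd(lo)) return(1)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (pd(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Profiles the Gaussian likelihood of the trait over the
#' lambda-transformed Brownian covariance (off-diagonals multiplied by
#' lambda), with the phylogenetic mean and rate maximized out analytically.
#' The search runs over `[0, lambda_max]` where `lambda_max` is the largest
#' value keeping the covariance positive-definite — this can exceed 1 on
#' trees whose structure supports it.
#'
#' @param trait,tree as in [blomberg_k()].
#' @param lambda_bounds optional numeric length-2 search bounds; the upper
#'   bound is capped at the positive-definiteness limit.
#' @return list with `lambda_hat`, `loglik_at_hat`, `loglik_at_zero`,
#'   `lambda_max`.
#' @export
pagel_lambda_ml <- function(trait, tree, lambda_bounds = NULL) {
  y <- align_trait(trait, tree)
  if (length(y) < 3L) vt_stop("invalid_tree", "need at least 3 tips")
  if (stats::sd(y) == 0) vt_stop("degenerate_trait", "trait is constant")
  C <- phylo_covariance(tree)
  lmax <- lambda_max_pd(C)
  lo <- 0
  hi <- lmax * 0.99999
  if (!is.null(lambda_bounds)) {
    lo <- max(0, lambda_bounds[1])
    hi <- min(hi, lambda_bounds[2])
  }
  opt <- stats::optimize(lambda_loglik, c(lo, hi), y = y, C = C,
                         maximum = TRUE, tol = 1e-6)
  # optimize() never lands exactly on the boundary; check the ends too
  cand <- c(opt$maximum, lo, hi)
  ll <- vapply(cand, lambda_loglik, numeric(1), y = y, C = C)
  best <- which.max(ll)
  list(lambda_hat = cand[best], loglik_at_hat = ll[best],
       loglik_at_zero = lambda_loglik(0, y, C), lambda_max = lmax)
}

#' Likelihood-ratio test for Pagel's lambda
#'
#' Tests the ML lambda against lambda = 0 (no phylogenetic signal) with a
#' chi-squared(1) reference for twice the log-likelihood difference.
#'
#' @param trait,tree as in [blomberg_k()].
#' @return list with `lambda_hat`, `loglik_at_hat`, `lr_stat`, `p_lambda`.
#' @export
lambda_lr_test <- function(trait, tree) {
  fit <- pagel_lambda_ml(trait, tree)
  lr <- max(0, 2 * (fit$loglik_at_hat - fit$loglik_at_zero))
  p <- if (fit$lambda_hat == 0) 1 else stats::pchisq(lr, df = 1,
                                                     lower.tail = FALSE)
  list(lambda_hat = fit$lambda_hat, loglik_at_hat = fit$loglik_at_hat,
       lr_stat = lr, p_lambda = p)
}

#' Phylogenetic-signal tests for a population trait
#'
#' Runs Blomberg's K with a permutation test and Pagel's lambda with a
#' likelihood-ratio test on one trait over one tree. Trees without branch
#' lengths get Grafen lengths first. With only a handful of tips (the typical
#' population-level case) both tests have low power; interpret accordingly.
#'
#' @param trait named numeric vector (tip labels).
#' @param tree a `phylo`; Grafen branch lengths assigned when absent.
#' @param n_perm permutations for the K test.
#' @param seed integer seed.
#' @return list of class `signal_result` with `k_stat`, `p_k`, `lambda_hat`,
#'   `loglik_at_hat`, `p_lambda`, `n_tips`.
#' @export
phylo_signal <- function(trait, tree, n_perm = 999, seed = 1) {
  if (is.null(tree$edge.length)) tree <- grafen_lengths(tree)
  kt <- blomberg_k_test(trait, tree, n_perm = n_perm, seed = seed)
  lt <- lambda_lr_test(trait, tree)
  structure(list(k_stat = kt$k_stat, p_k = kt$p_k,
                 lambda_hat = lt$lambda_hat,
                 loglik_at_hat = lt$loglik_at_hat,
                 p_lambda = lt$p_lambda,
                 n_tips = length(tree$tip.label)),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Phylogenetic signal (n = %d tips): K = %.3f (P = %.3f), lambda = %.3f (P = %.3f)\n",
              x$n_tips, x$k_stat, x$p_k, x$lambda_hat, x$p_lambda))
  invisible(x)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Draws multivariate-normal tip values with covariance `sigma2 * C(tree)`
#' about `root_state`, via the Cholesky factor.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma2 Brownian rate.
#' @param root_state ancestral state.
#' @param n number of independent replicate traits.
#' @return matrix (tips x n), rownames = tip labels.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_state = 0, n = 1) {
  C <- phylo_covariance(tree)
  L <- chol(C)
  z <- matrix(stats::rnorm(nrow(C) * n), nrow(C), n)
  x <- root_state + sqrt(sigma2) * t(L) %*% z
  rownames(x) <- rownames(C)
  x
}
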