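test_that("build_Vm reduces to the single-variate formula at d = 1", {
  g <- toy_genotypes(n = 6, M = 10, seed = 2)
  grm <- compute_grm(g)
  vc <- variance_components(matrix(1.3), matrix(0.7))
  ph <- phenotype_table(matrix(rnorm(6), 6, 1), g$sample_id)
  V <- build_Vm(vc, grm, missing_pattern(ph))
  expect_equal(V, unname(1.3 * grm$A + 0.7 * diag(6)), tolerance = 1e-12)
})

test_that("build_Vm agrees with the brute-force stacked-record oracle", {
  n <- 5
  A <- grm_brute(toy_genotypes(n = n, M = 8, seed = 4)$dosages)
  grm <- as_grm(A)
  for (d in 2:3) {
    su <- random_psd(d, seed = d)
    se <- random_psd(d, seed = d + 10)
    set.seed(d + 20)
    mask <- matrix(runif(n * d) > 0.3, n, d)
    mask[rowSums(mask) == 0, 1] <- TRUE
    vals <- matrix(rnorm(n * d), n, d); vals[!mask] <- NA
    ph <- phenotype_table(vals, grm$sample_id, mask = mask)
    vc <- variance_components(su, se)
    expect_equal(build_Vm(vc, grm, missing_pattern(ph)),
                 vm_brute(su, se, A, mask), tolerance = 1e-12)
  }
})

test_that("residual correlation cancels exactly at maximal missingness", {
  # group X observed only for variate 1, group Y only for variate 2
  n <- 8
  A <- grm_brute(toy_genotypes(n = n, M = 10, seed = 6)$dosages)
  grm <- as_grm(A)
  mask <- cbind(rep(c(TRUE, FALSE), each = n / 2),
                rep(c(FALSE, TRUE), each = n / 2))
  vals <- matrix(rnorm(n * 2), n, 2); vals[!mask] <- NA
  ph <- phenotype_table(vals, grm$sample_id, mask = mask)
  pat <- missing_pattern(ph)
  se1 <- diag(c(1.4, 0.9))
  se2 <- se1; se2[1, 2] <- se2[2, 1] <- 0.99 * sqrt(1.4 * 0.9)
  su <- random_psd(2, seed = 9)
  V1 <- build_Vm(variance_components(su, se1), grm, pat)
  V2 <- build_Vm(variance_components(su, se2), grm, pat)
  expect_identical(V1, V2)
  # and the retained residual block is diag(I_X se1, I_Y se2)
  V0 <- build_Vm(variance_components(matrix(0, 2, 2), se1), grm, pat)
  expect_equal(V0, diag(rep(c(1.4, 0.9), each = n / 2)), tolerance = 1e-15)
})

test_that("degenerate variance-component inputs are fatal", {
  expect_error(variance_components(matrix(-1), matrix(1)),
               "positive semidefinite")
  g <- toy_genotypes(n = 4, M = 6, seed = 2)
  ph <- phenotype_table(matrix(rnorm(8), 4, 2), g$sample_id)
  vc <- variance_components(diag(2), diag(2))
  vc$sigma_e <- matrix(c(1, 2, 2, 1), 2)  # indefinite, injected after checks
  expect_error(build_Vm(vc, compute_grm(g), missing_pattern(ph)),
               "non-positive-semidefinite")
})

test_that("sigma_u = 0, sigma_e = I gives the identity covariance", {
  g <- toy_genotypes(n = 5, M = 6, seed = 3)
  ph <- phenotype_table(matrix(rnorm(10), 5, 2), g$sample_id)
  V <- build_Vm(variance_components(matrix(0, 2, 2), diag(2)),
                compute_grm(g), missing_pattern(ph))
  expect_equal(V, diag(10), tolerance = 1e-15)
})

test_that("restricted_loglik matches an independent scalar implementation", {
  n <- 10
  set.seed(8)
  y <- rnorm(n, mean = 2)
  X <- matrix(1, n, 1)
  grm <- as_grm(diag(n))
  ph <- phenotype_table(matrix(y, n, 1), grm$sample_id)
  for (su in c(0.5, 2)) for (se in c(1, 3)) {
    expect_equal(
      restricted_loglik(variance_components(matrix(su), matrix(se)), ph, grm),
      scalar_reml_loglik(y, X, diag(n), su, se), tolerance = 1e-10)
  }
})

test_that("restricted_loglik is invariant under reordering individuals", {
  g <- toy_genotypes(n = 12, M = 20, seed = 5)
  grm <- compute_grm(g)
  set.seed(21)
  vals <- matrix(rnorm(24), 12, 2); vals[3, 2] <- NA
  ph <- phenotype_table(vals, grm$sample_id)
  vc <- variance_components(random_psd(2, 1), random_psd(2, 2))
  ll <- restricted_loglik(vc, ph, grm)
  perm <- sample(12)
  ph_p <- phenotype_table(vals[perm, ], grm$sample_id[perm])
  grm_p <- as_grm(grm$A[perm, perm], grm$sample_id[perm])
  expect_equal(restricted_loglik(vc, ph_p, grm_p), ll, tolerance = 1e-9)
})

test_that("doubling both components shifts the likelihood by the closed form", {
  n <- 9
  g <- toy_genotypes(n = n, M = 15, seed = 9)
  grm <- compute_grm(g)
  set.seed(31)
  y <- rnorm(n)
  ph <- phenotype_table(matrix(y, n, 1), grm$sample_id)
  su <- 1.1; se <- 0.8
  ll1 <- restricted_loglik(variance_components(matrix(su), matrix(se)),
                           ph, grm)
  ll2 <- restricted_loglik(variance_components(matrix(2 * su),
                                               matrix(2 * se)), ph, grm)
  # brute-force y'Py at the original components
  V <- su * grm$A + se * diag(n); Vi <- solve(V)
  X <- matrix(1, n, 1)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  ypy <- as.numeric(t(y) %*% P %*% y)
  expect_equal(ll2 - ll1, -0.5 * ((n - 1) * log(2) - ypy / 2),
               tolerance = 1e-9)
})

test_that("EM-REML log-likelihood path is monotone and matches the direct evaluator", {
  g <- simulate_genotypes(n = 60, n_chr = 2, snps_per_chr = 250, seed = 14)
  grm <- compute_grm(prune_maf(g))
  set.seed(41)
  vals <- matrix(rnorm(120, sd = 2), 60, 2)
  vals[sample(120, 20)] <- NA
  vals[rowSums(!is.na(vals)) == 0, 1] <- 0
  ph <- phenotype_table(vals, grm$sample_id)
  vc <- em_reml(ph, grm, maxit = 400)
  expect_true(all(diff(vc$loglik_path) >= -1e-6))
  expect_gt(length(vc$loglik_path), 3)
  # complete-data path is monotone too
  ph2 <- phenotype_table(matrix(rnorm(120, sd = 2), 60, 2), grm$sample_id)
  vc2 <- em_reml(ph2, grm, maxit = 400)
  expect_true(all(diff(vc2$loglik_path) >= -1e-6))
})

test_that("EM-REML finds the restricted-likelihood optimum (d = 1 oracle)", {
  n <- 80
  g <- simulate_genotypes(n = n, n_chr = 2, snps_per_chr = 300, seed = 7)
  grm <- compute_grm(prune_maf(g))
  set.seed(3)
  Aw <- with(mvftest:::bend_grm(grm$A), U %*% (lam * t(U)))
  y <- as.vector(chol(2.5 * Aw + 1.5 * diag(n)) %*% rnorm(n)) + 3
  ph <- phenotype_table(matrix(y, n, 1), grm$sample_id)
  vc <- em_reml(ph, grm, tol = 1e-9)
  expect_true(vc$converged)
  # independent route: Nelder-Mead on the restricted log-likelihood
  nll <- function(par) {
    -restricted_loglik(variance_components(matrix(exp(par[1])),
                                           matrix(exp(par[2]))), ph, grm)
  }
  o <- stats::optim(c(0, 0), nll, control = list(reltol = 1e-13,
                                                 maxit = 4000))
  expect_equal(as.numeric(vc$sigma_u), exp(o$par[1]), tolerance = 1e-3)
  expect_equal(as.numeric(vc$sigma_e), exp(o$par[2]), tolerance = 1e-3)
})

test_that("complete data and an explicit all-true mask give the same fit", {
  g <- simulate_genotypes(n = 50, n_chr = 1, snps_per_chr = 300, seed = 17)
  grm <- compute_grm(prune_maf(g))
  set.seed(23)
  vals <- matrix(rnorm(100, sd = 1.5), 50, 2)
  ph1 <- phenotype_table(vals, grm$sample_id)
  ph2 <- phenotype_table(vals, grm$sample_id,
                         mask = matrix(TRUE, 50, 2))
  vc1 <- em_reml(ph1, grm)
  vc2 <- em_reml(ph2, grm)
  expect_equal(vc1$sigma_u, vc2$sigma_u, tolerance = 1e-12)
  expect_equal(vc1$sigma_e, vc2$sigma_e, tolerance = 1e-12)
})

test_that("the rotated and direct EM paths agree on complete data", {
  # force the direct path by a mask that is complete except one later-
  # restored cell: instead, compare a complete fit against the direct
  # engine invoked explicitly through one masked-but-observed copy
  n <- 40
  g <- simulate_genotypes(n = n, n_chr = 1, snps_per_chr = 250, seed = 19)
  grm <- compute_grm(prune_maf(g))
  set.seed(29)
  vals <- matrix(rnorm(2 * n, sd = 2), n, 2)
  ph <- phenotype_table(vals, grm$sample_id)
  eg <- mvftest:::bend_grm(grm$A)
  su <- random_psd(2, 31); se <- random_psd(2, 32)
  rot <- mvftest:::make_rotated_step(ph$values, matrix(1, n, 1), eg, n, 2, 1)
  dir <- mvftest:::make_direct_step(ph$values, matrix(1, n, 1), eg,
                                    missing_pattern(ph))
  s1 <- rot(su, se); s2 <- dir(su, se)
  expect_equal(s1$loglik, s2$loglik, tolerance = 1e-8)
  expect_equal(s1$su, s2$su, tolerance = 1e-8)
  expect_equal(s1$se, s2$se, tolerance = 1e-8)
})

test_that("null data on a genomic relationship matrix recover near-zero heritability", {
  n <- 200
  g <- simulate_genotypes(n = n, seed = 77)
  grm <- compute_grm(prune_maf(g))
  h2 <- numeric(20)
  for (r in 1:20) {
    set.seed(600 + r)
    ph <- phenotype_table(matrix(rnorm(n), n, 1), grm$sample_id)
    vc <- em_reml(ph, grm)
    h2[r] <- as.numeric(vc$sigma_u) /
      as.numeric(vc$sigma_u + vc$sigma_e)
  }
  expect_gte(mean(h2 < 0.2), 0.9)
})

test_that("inestimable and rank-deficient designs are fatal", {
  g <- toy_genotypes(n = 4, M = 6, seed = 2)
  grm <- compute_grm(g)
  ph <- phenotype_table(matrix(rnorm(4), 4, 1), grm$sample_id)
  expect_error(em_reml(ph, grm, covariates = cbind(1, rnorm(4), rnorm(4))),
               "inestimable")
  ph8 <- phenotype_table(matrix(rnorm(8), 4, 2), grm$sample_id)
  expect_error(em_reml(ph8, grm, covariates = matrix(1, 4, 2)),
               "rank deficient")
})
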