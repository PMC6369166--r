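test_that("build_H selects the tested effects in stacked order", {
  expect_equal(t(build_H(5, 1, 2)), matrix(c(0, 1, 0, 0, 0), 1))
  H <- build_H(2, 2, 2)
  expect_equal(t(H), rbind(c(0, 1, 0, 0), c(0, 0, 0, 1)))
  expect_equal(build_H(1, 1, 1), matrix(1))
  expect_error(build_H(2, 2, 3), "tested_index")
})

test_that("GLS reduces to OLS at V = I and to the mean for intercept-only", {
  set.seed(11)
  n <- 12
  X <- cbind(1, rnorm(n), runif(n))
  y <- rnorm(n)
  fit <- gls_fit(y, X, V = diag(n))
  expect_equal(fit$beta, unname(coef(lm(y ~ X - 1))), tolerance = 1e-10)
  fit0 <- gls_fit(y, matrix(1, n, 1), V = diag(n))
  expect_equal(fit0$beta, mean(y), tolerance = 1e-12)
})

test_that("GLS matches the textbook weighted formula on a heteroscedastic toy", {
  y <- c(1.2, 0.7, -0.4, 2.5, 3.1, 1.9)
  X <- cbind(1, c(0, 1, 2, 0, 1, 2))
  V <- diag(c(1, 1, 1, 4, 4, 4))
  fit <- gls_fit(y, X, V = V)
  Vi <- solve(V)
  beta_brute <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  expect_equal(fit$beta, as.numeric(beta_brute), tolerance = 1e-12)
  expect_equal(fit$cov_beta, solve(t(X) %*% Vi %*% X), tolerance = 1e-12)
  r <- y - X %*% beta_brute
  expect_equal(fit$quadratic_form, as.numeric(t(r) %*% Vi %*% r),
               tolerance = 1e-12)
  expect_error(gls_fit(y, cbind(X, X[, 2]), V = V), "rank deficient")
})

test_that("F statistic properties: null contrast, t^2 equivalence, flooring", {
  set.seed(13)
  n <- 10
  x <- rnorm(n)
  y <- 0.5 + 0.8 * x + rnorm(n)
  X <- cbind(1, x)
  fit <- gls_fit(y, X, V = diag(n))
  # squared OLS t statistic with the quadratic-form scale
  s2 <- fit$quadratic_form / (n - 2)
  fs <- f_statistic(fit, build_H(2, 1, 2), sigma2 = s2)
  tval <- summary(lm(y ~ x))$coefficients["x", "t value"]
  expect_equal(fs$F, tval^2, tolerance = 1e-10)
  expect_equal(fs$df1, 1)
  expect_equal(fs$df2, n - 2)
  expect_equal(fs$p, 2 * pt(-abs(tval), n - 2), tolerance = 1e-10)
  # exact-zero contrast: F = 0, p = 1
  fit0 <- fit; fit0$beta <- c(3, 0)
  fs0 <- f_statistic(fit0, build_H(2, 1, 2))
  expect_equal(fs0$F, 0)
  expect_equal(fs0$p, 1)
  expect_equal(fs0$neg_log10_p, 0)
  # p-value flooring at the smallest positive double
  fitX <- fit; fitX$beta <- c(0, 1e8); fitX$cov_beta <- diag(2) * 1e-8
  fitX$n_obs <- 1000L
  fsX <- f_statistic(fitX, build_H(2, 1, 2))
  expect_true(fsX$floored)
  expect_equal(fsX$p, .Machine$double.xmin)
})

test_that("the joint-test numerator factorizes as B1^2 x'x f(a2, r)", {
  set.seed(17)
  x <- sample(c(0, 2), 10, replace = TRUE)
  x[1:2] <- c(0, 2)  # ensure polymorphic
  B1 <- 0.7
  for (a2 in c(-0.8, 0, 0.5, 1)) for (r in c(-0.6, 0, 0.8)) {
    y <- c(x * B1, x * a2 * B1)
    Xm <- kronecker(diag(2), matrix(x))
    V <- kronecker(matrix(c(1, r, r, 1), 2), diag(10))
    fit <- gls_fit(y, Xm, V = V)
    fs <- f_statistic(fit, build_H(1, 2, 1), sigma2 = 1)
    numerator <- fs$F * fs$df1
    expect_equal(numerator, B1^2 * sum(x * x) * f_a2_r(a2, r),
                 tolerance = 1e-8)
  }
})

test_that("F is invariant to allele-coding flips", {
  g <- simulate_genotypes(n = 60, n_chr = 1, snps_per_chr = 300, seed = 23)
  gp <- prune_maf(g)
  grm <- compute_grm(gp)
  set.seed(5)
  vals <- matrix(rnorm(120, sd = 1.3), 60, 2)
  vals[sample(120, 15)] <- NA
  vals[rowSums(!is.na(vals)) == 0, 1] <- 0
  ph <- phenotype_table(vals, grm$sample_id)
  vc <- em_reml(ph, grm)
  tester <- mvftest:::make_snp_tester(ph, grm, vc, "multivariate")
  x <- gp$dosages[, 10]
  r1 <- tester(x, "s", "c", 1)
  r2 <- tester(2 - x, "s", "c", 1)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("F is invariant to phenotype rescaling when V is re-estimated", {
  g <- simulate_genotypes(n = 80, n_chr = 1, snps_per_chr = 300, seed = 29)
  gp <- prune_maf(g)
  grm <- compute_grm(gp)
  set.seed(7)
  Aw <- with(mvftest:::bend_grm(grm$A), U %*% (lam * t(U)))
  y <- as.vector(chol(1.5 * Aw + diag(80)) %*% rnorm(80))
  run <- function(scale) {
    ph <- phenotype_table(matrix(scale * y, 80, 1), grm$sample_id)
    vc <- em_reml(ph, grm)
    expect_equal(vc$n_iter > 0, TRUE)
    tester <- mvftest:::make_snp_tester(ph, grm, vc, "univariate")
    tester(gp$dosages[, 25], "s", "c", 1)
  }
  r1 <- run(1); r3 <- run(3)
  expect_equal(r1$F, r3$F, tolerance = 1e-6)
})

test_that("the d = 1 multivariate path equals the univariate path exactly", {
  g <- simulate_genotypes(n = 50, n_chr = 1, snps_per_chr = 200, seed = 31)
  gp <- prune_maf(g)
  grm <- compute_grm(gp)
  set.seed(9)
  ph <- phenotype_table(matrix(rnorm(50, sd = 2), 50, 1), grm$sample_id)
  res <- gwa_scan(gp, ph, grm, scan_config(test = "both"), snps = 1:10)
  mv <- res[res$test == "multivariate", ]
  uv <- res[grepl("univariate", res$test), ]
  expect_identical(mv$F, uv$F)
  expect_identical(mv$p, uv$p)
  expect_identical(mv$df2, uv$df2)
})

test_that("a multivariate scan masked down to one variate reproduces the univariate scan", {
  g <- simulate_genotypes(n = 40, n_chr = 1, snps_per_chr = 200, seed = 37)
  gp <- prune_maf(g)
  grm <- compute_grm(gp)
  set.seed(15)
  vals <- cbind(rnorm(40, sd = 2), NA_real_)
  mask <- cbind(rep(TRUE, 40), rep(FALSE, 40))
  ph2 <- phenotype_table(vals, grm$sample_id, c("y1", "y2"), mask)
  ph1 <- phenotype_table(vals[, 1, drop = FALSE], grm$sample_id, "y1")
  expect_message(
    res2 <- gwa_scan(gp, ph2, grm, scan_config(test = "multivariate"),
                     snps = 1:8),
    "dropping variate")
  res1 <- gwa_scan(gp, ph1, grm, scan_config(test = "multivariate"),
                   snps = 1:8)
  expect_equal(res2$F, res1$F, tolerance = 1e-12)
  expect_equal(res2$p, res1$p, tolerance = 1e-12)
})

test_that("monomorphic SNPs yield NA rows and the scan continues", {
  g <- toy_genotypes(n = 30, M = 5, seed = 41, values = c(0, 2))
  dos <- g$dosages; dos[, 3] <- 2  # constant column
  g <- genotype_matrix(dos, g$snp_id, g$chrom, g$pos, g$sample_id)
  grm <- compute_grm(g)
  set.seed(19)
  ph <- phenotype_table(matrix(rnorm(30), 30, 1), g$sample_id)
  res <- gwa_scan(g, ph, grm, scan_config(test = "multivariate"))
  expect_equal(nrow(res), 5L)
  expect_true(is.na(res$F[res$snp_id == "s3"]))
  expect_true(all(!is.na(res$F[res$snp_id != "s3"])))
})

test_that("exact-REML mode runs and broadly agrees with the null-model approximation", {
  g <- simulate_genotypes(n = 40, n_chr = 1, snps_per_chr = 150, seed = 43)
  gp <- prune_maf(g)
  grm <- compute_grm(gp)
  set.seed(27)
  ph <- phenotype_table(matrix(rnorm(40, sd = 1.5), 40, 1), grm$sample_id)
  approx <- gwa_scan(gp, ph, grm, scan_config(test = "univariate"),
                     snps = 1:4)
  exact <- gwa_scan(gp, ph, grm,
                    scan_config(test = "univariate", exact_reml = TRUE),
                    snps = 1:4)
  expect_equal(nrow(exact), 4L)
  expect_equal(exact$F, approx$F, tolerance = 0.2)
})
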