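#' Contrast matrix selecting the tested fixed effects
#'
#' Builds the indicator matrix `H` ((p*d) x d) that extracts the tested
#' effect of every variate from the stacked fixed-effect vector, whose
#' ordering is variate-major: `[mu_1 B_1 mu_2 B_2 ...]` when each variate
#' carries an intercept and a SNP effect.  With `p_per_variate = 5`, `d = 1`
#' and `tested_index = 2`, `t(H) = [0 1 0 0 0]`.
#'
#' @param p_per_variate number of fixed effects per variate.
#' @param d number of variates.
#' @param tested_index which effect (within a variate) is tested.
#' @return the `(p_per_variate*d) x d` contrast matrix.
#' @export
build_H <- function(p_per_variate, d, tested_index) {
  if (tested_index < 1L || tested_index > p_per_variate)
    stop("tested_index must lie in 1..p_per_variate")
  H <- matrix(0, p_per_variate * d, d)
  for (j in seq_len(d)) H[(j - 1L) * p_per_variate + tested_index, j] <- 1
  H
}

#' Generalized least squares fit under a known covariance
#'
#' Computes `B_hat = (X'V^-1 X)^-1 X'V^-1 y` through Cholesky factorization
#' (no explicit inverse of `V`), together with the coefficient covariance
#' `(X'V^-1 X)^-1` and the residual quadratic form
#' `(y - X B_hat)' V^-1 (y - X B_hat)`.
#'
#' @param y observed response vector.
#' @param X design matrix (full column rank).
#' @param V covariance matrix (positive definite); alternatively pass a
#'   pre-computed upper-triangular `cholV = chol(V)`.
#' @param cholV optional Cholesky factor of `V`.
#' @return an object of class `FixedEffectFit` with `beta`, `cov_beta`,
#'   `quadratic_form`, `n_obs`, `p`.
#' @export
gls_fit <- function(y, X, V = NULL, cholV = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  rk <- qr(X)$rank
  if (rk < ncol(X)) {
    cn <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
    stop("design matrix is rank deficient (rank ", rk, " < ", ncol(X),
         "); columns: ", paste(cn, collapse = ", "))
  }
  if (is.null(cholV)) {
    if (is.null(V)) stop("either V or cholV must be supplied")
    cholV <- tryCatch(chol(V), error = function(e)
      stop("singular covariance matrix V"))
  }
  # whitened regression: L' z = y, L' W = X with cholV = L' (upper)
  z <- backsolve(cholV, y, transpose = TRUE)
  W <- backsolve(cholV, X, transpose = TRUE)
  K <- crossprod(W)
  cK <- tryCatch(chol((K + t(K)) / 2), error = function(e)
    stop("singular X'V^-1X"))
  cov_beta <- chol2inv(cK)
  beta <- cov_beta %*% crossprod(W, z)
  r <- z - W %*% beta
  qf <- sum(r^2)
  structure(list(beta = as.numeric(beta), cov_beta = cov_beta,
                 quadratic_form = qf, n_obs = length(y), p = ncol(X)),
            class = "FixedEffectFit")
}

#' F statistic for a set of tested fixed effects
#'
#' `F = (H'B)' [H'(X'V^-1X)^-1 H]^-1 (H'B) / (f * sigma2)` with `f` the
#' number of tested effects (columns of `H`).  The reference distribution is
#' `F(f, df2)` with `df2 = n_obs - p` by default, i.e. the total observed
#' records minus all fixed effects; the denominator scale `sigma2` is fixed
#' at 1 when `V` comes from REML estimates of the variance components.
#' p-values below the smallest positive double are floored there.
#'
#' @param fit a [gls_fit()] result.
#' @param H contrast matrix from [build_H()].
#' @param sigma2 denominator scale (default 1).
#' @param df2 denominator degrees of freedom (default `n_obs - p`).
#' @return a list with `F`, `df1`, `df2`, `p`, `neg_log10_p`.
#' @export
f_statistic <- function(fit, H, sigma2 = 1, df2 = NULL) {
  H <- as.matrix(H)
  if (nrow(H) != fit$p) stop("H does not match the fitted effects")
  f <- ncol(H)
  df2 <- df2 %||% (fit$n_obs - fit$p)
  hb <- crossprod(H, fit$beta)
  Mh <- crossprod(H, fit$cov_beta %*% H)
  Mi <- tryCatch(solve((Mh + t(Mh)) / 2), error = function(e)
    stop("singular H'(X'V^-1X)^-1H"))
  Fval <- as.numeric(crossprod(hb, Mi %*% hb)) / (f * sigma2)
  Fval <- max(Fval, 0)
  p <- stats::pf(Fval, f, df2, lower.tail = FALSE)
  floored <- FALSE
  if (p < .Machine$double.xmin) {
    p <- .Machine$double.xmin
    floored <- TRUE
  }
  list(F = Fval, df1 = f, df2 = df2, p = p, neg_log10_p = -log10(p),
       floored = floored)
}

# Closure performing per-SNP F tests for a fixed phenotype table, GRM and
# (null-model) variance components.  Used by gwa_scan() and the power grid.
# `variate_label` tags the result rows.
make_snp_tester <- function(ph, grm, vc, label) {
  pattern <- missing_pattern(ph)
  d <- pattern$d; n <- pattern$n
  obs <- pattern$obs_records
  V <- build_Vm(vc, grm, pattern)
  cholV <- chol(V)
  N <- nrow(V)
  function(x, snp_id, chrom, pos) {
    Xm_full <- matrix(0, n * d, 2L * d)
    for (j in seq_len(d)) {
      rows <- (j - 1L) * n + seq_len(n)
      Xm_full[rows, 2L * j - 1L] <- 1
      Xm_full[rows, 2L * j] <- x
    }
    Xm <- Xm_full[obs, , drop = FALSE]
    # SNP constant on the analysed (observed) samples -> untestable
    degenerate <- any(vapply(seq_len(d), function(j) {
      stats::var(x[pattern$observed[[j]]]) == 0
    }, TRUE))
    if (degenerate) {
      return(test_result_row(snp_id, chrom, pos, label, NA_real_, d,
                             N - 2L * d, NA_real_, NA_real_))
    }
    fit <- gls_fit(as.vector(ph$values)[obs], Xm, cholV = cholV)
    H <- build_H(2L, d, 2L)
    fs <- f_statistic(fit, H, sigma2 = 1)
    test_result_row(snp_id, chrom, pos, label, fs$F, fs$df1, fs$df2, fs$p,
                    fs$neg_log10_p)
  }
}

#' Genome-wide association scan
#'
#' Aligns genotypes, phenotypes and GRM by sample identifier, fits the null
#' model (intercept per variate, no SNP) once by [em_reml()], and then tests
#' every SNP by plugging its dosages into the fixed-effect design of each
#' requested test while reusing the null-model variance components (the
#' "population parameters previously determined" approximation).  The
#' multivariate test evaluates all `d` SNP effects jointly (`f = d`);
#' univariate tests are run per variate on that variate's observed
#' individuals with their own univariate null fit.  SNPs with constant
#' dosage on the analysed samples are reported with `F = NA`.
#'
#' @param g a [genotype_matrix()].
#' @param ph a [phenotype_table()].
#' @param grm a `GRM` covering the samples.
#' @param cfg a [scan_config()].
#' @param snps optional subset of SNPs to test (ids or column indices).
#' @return data frame of per-SNP, per-test results (see [write_results()]).
#' @export
gwa_scan <- function(g, ph, grm, cfg = scan_config(), snps = NULL) {
  common <- intersect(intersect(g$sample_id, ph$sample_id), grm$sample_id)
  n_drop <- max(length(g$sample_id), length(ph$sample_id),
                length(grm$sample_id)) - length(common)
  if (length(common) < 2L) stop("fewer than 2 samples shared across inputs")
  if (n_drop > 0L)
    message("gwa_scan: ", n_drop, " sample(s) dropped in the id inner join")
  g <- subset_samples(g, match(common, g$sample_id))
  grm <- subset_grm(grm, common)
  variates <- cfg$variates %||% ph$variate_names
  ph <- subset_phenotypes(ph, common, variates)
  obs_count <- colSums(ph$mask)
  if (any(obs_count == 0L)) {
    message("gwa_scan: dropping variate(s) without observed records: ",
            paste(ph$variate_names[obs_count == 0L], collapse = ", "))
    ph <- subset_phenotypes(ph, seq_along(ph$sample_id),
                            ph$variate_names[obs_count > 0L])
    variates <- ph$variate_names
  }
  # rows without any observation among the selected variates were dropped
  grm <- subset_grm(grm, ph$sample_id)
  d <- length(variates)
  idx <- if (is.null(snps)) seq_along(g$snp_id)
         else if (is.character(snps)) match(snps, g$snp_id)
         else as.integer(snps)
  if (anyNA(idx)) stop("unknown SNP id(s) requested")

  run_one <- function(ph_k, grm_k, label) {
    if (cfg$exact_reml) {
      return(run_exact(ph_k, grm_k, label))
    }
    vc <- em_reml(ph_k, grm_k, tol = cfg$reml_tol, maxit = cfg$reml_maxit)
    if (!vc$converged)
      stop("null-model REML did not converge for test '", label,
           "'; inspect the emitted messages")
    tester <- make_snp_tester(ph_k, grm_k, vc, label)
    keep <- match(ph_k$sample_id, g$sample_id)
    do.call(rbind, lapply(idx, function(s) {
      tester(g$dosages[keep, s], g$snp_id[s], g$chrom[s], g$pos[s])
    }))
  }
  run_exact <- function(ph_k, grm_k, label) {
    keep <- match(ph_k$sample_id, g$sample_id)
    do.call(rbind, lapply(idx, function(s) {
      x <- g$dosages[keep, s]
      pat <- missing_pattern(ph_k)
      dk <- pat$d
      if (any(vapply(seq_len(dk), function(j)
        stats::var(x[pat$observed[[j]]]) == 0, TRUE))) {
        return(test_result_row(g$snp_id[s], g$chrom[s], g$pos[s], label,
                               NA_real_, dk, length(pat$obs_records) - 2L * dk,
                               NA_real_, NA_real_))
      }
      vc <- em_reml(ph_k, grm_k, covariates = cbind(1, x),
                    tol = cfg$reml_tol, maxit = cfg$reml_maxit)
      if (!vc$converged)
        stop("exact-REML fit did not converge at SNP ", g$snp_id[s])
      tester <- make_snp_tester(ph_k, grm_k, vc, label)
      tester(x, g$snp_id[s], g$chrom[s], g$pos[s])
    }))
  }

  out <- list()
  if (cfg$test %in% c("both", "multivariate")) {
    out$mv <- run_one(ph, grm, "multivariate")
  }
  if (cfg$test %in% c("both", "univariate")) {
    for (v in variates) {
      keep_v <- which(ph$mask[, v])
      ph_v <- subset_phenotypes(ph, keep_v, v)
      grm_v <- subset_grm(grm, ph_v$sample_id)
      out[[paste0("uv_", v)]] <- run_one(ph_v, grm_v,
                                         paste0("univariate:", v))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$snp_id, g$snp_id)), , drop = FALSE]
}
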