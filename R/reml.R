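#' Variance components of the (multivariate) mixed model
#'
#' Holds the `d x d` genetic covariance `sigma_u` and residual covariance
#' `sigma_e` (scalars when `d = 1`), together with the EM iteration record.
#' The restricted log-likelihood path of a clean EM run is non-decreasing.
#'
#' @param sigma_u,sigma_e symmetric positive semidefinite `d x d` matrices.
#' @param converged logical.
#' @param n_iter iteration count.
#' @param loglik_path numeric vector of per-iteration restricted
#'   log-likelihoods.
#' @param variate_names optional labels.
#' @return an object of class `VarianceComponents`.
#' @export
variance_components <- function(sigma_u, sigma_e, converged = NA,
                                n_iter = 0L, loglik_path = numeric(0),
                                variate_names = NULL) {
  sigma_u <- as.matrix(sigma_u); sigma_e <- as.matrix(sigma_e)
  if (!all(dim(sigma_u) == dim(sigma_e)) || nrow(sigma_u) != ncol(sigma_u))
    stop("sigma_u and sigma_e must be square matrices of equal dimension")
  if (!is_psd(sigma_u) || !is_psd(sigma_e))
    stop("variance components must be symmetric positive semidefinite")
  d <- nrow(sigma_u)
  if (is.null(variate_names)) variate_names <- paste0("y", seq_len(d))
  dimnames(sigma_u) <- dimnames(sigma_e) <- list(variate_names, variate_names)
  structure(list(sigma_u = sigma_u, sigma_e = sigma_e, d = d,
                 converged = converged, n_iter = as.integer(n_iter),
                 loglik_path = loglik_path, variate_names = variate_names),
            class = "VarianceComponents")
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("VarianceComponents (d =", x$d, ")\n")
  cat("sigma_u:\n"); print(round(x$sigma_u, 4))
  cat("sigma_e:\n"); print(round(x$sigma_e, 4))
  cat("converged:", x$converged, "after", x$n_iter, "iteration(s)\n")
  invisible(x)
}

#' Phenotypic covariance of the observed stacked records
#'
#' Builds `V_m = sigma_u (x) A + sigma_e (x) I` on the full `n*d` stacked
#' record space (variate-major order) and deletes the rows and columns of
#' unobserved records.  With `d = 1` this is `V = A*sigma_u^2 + I*sigma_e^2`.
#' At maximal missingness (each individual observed for a single variate)
#' the retained residual block is diagonal per variate, so the residual
#' correlation parameter cancels from the residual term.
#'
#' @param vc a [variance_components()].
#' @param grm a [compute_grm()] result (or any `GRM`).
#' @param pattern a [missing_pattern()].
#' @return the observed-dimension covariance matrix.
#' @export
build_Vm <- function(vc, grm, pattern) {
  d <- vc$d
  if (pattern$d != d) stop("pattern and variance components disagree on d")
  n <- pattern$n
  if (nrow(grm$A) != n) stop("GRM dimension does not match the pattern")
  if (!is_psd(vc$sigma_u) || !is_psd(vc$sigma_e))
    stop("non-positive-semidefinite variance components")
  V <- kronecker(vc$sigma_u, grm$A) + kronecker(vc$sigma_e, diag(n))
  obs <- pattern$obs_records
  V[obs, obs, drop = FALSE]
}

# Stacked fixed-effect design: per-variate covariate matrix X0 replicated
# block-diagonally, restricted to observed records.  Column order is
# variate-major: [covariates of variate 1 | covariates of variate 2 | ...].
stacked_design <- function(X0, pattern) {
  Xm <- kronecker(diag(pattern$d), X0)
  Xm[pattern$obs_records, , drop = FALSE]
}

# Bend a relationship matrix for REML: floor eigenvalues at a small positive
# value so A is invertible (the VanRaden matrix with centered dosages is
# always singular along the constant vector).  Returns the eigensystem.
bend_grm <- function(A, rel_floor = 1e-6) {
  ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- pmax(ee$values, rel_floor * max(ee$values, 1e-12))
  list(U = ee$vectors, lam = lam)
}

#' EM-REML estimation of (co)variance components
#'
#' Fits the mixed model `y = X b + u + e` with `u ~ MVN(0, sigma_u (x) A)`
#' and `e ~ MVN(0, sigma_e (x) I)` on the observed records of a possibly
#' incomplete phenotype table, by the classical EM algorithm for restricted
#' maximum likelihood.  Complete tables are handled in the eigenspace of
#' `A`, which decouples the `n*d` system into `n` blocks of size `d` and
#' yields the same iterate sequence as the direct observed-record
#' computation at a fraction of the cost; incomplete tables use the direct
#' observed-record covariance.
#'
#' Convergence is declared when the largest absolute change in any
#' component, relative to the largest current component, falls below `tol`
#' (a relative criterion keeps the fit equivariant under rescaling of the
#' phenotypes).  Non-positive-semidefinite EM updates are projected back by
#' eigenvalue clipping; three consecutive projections abort with
#' `converged = FALSE`.
#'
#' @param ph a [phenotype_table()].
#' @param grm a `GRM` aligned to `ph` (same individuals, same order).
#' @param covariates optional per-variate fixed-effect design (`n x p0`,
#'   default a single intercept column).
#' @param tol relative convergence tolerance (default `1e-6`).
#' @param maxit maximum EM iterations (default 5000).
#' @param verbose print progress every 100 iterations.
#' @return a [variance_components()] with `converged`, `n_iter` and
#'   `loglik_path` filled in.
#' @export
em_reml <- function(ph, grm, covariates = NULL, tol = 1e-6, maxit = 5000L,
                    verbose = FALSE) {
  Y <- ph$values; mask <- ph$mask
  n <- nrow(Y); d <- ncol(Y)
  if (nrow(grm$A) != n || !identical(grm$sample_id, ph$sample_id))
    stop("GRM and phenotype table must cover the same individuals in order")
  X0 <- covariates %||% matrix(1, n, 1)
  X0 <- as.matrix(X0)
  if (nrow(X0) != n) stop("covariate design must have one row per individual")
  p0 <- ncol(X0); p <- d * p0
  pattern <- missing_pattern(ph)
  N <- length(pattern$obs_records)
  if (N < p + 2L)
    stop("inestimable model: ", N, " observed records for ", p,
         " fixed effects")
  complete <- all(mask)
  Xm <- stacked_design(X0, pattern)
  if (qr(Xm)$rank < p)
    stop("fixed-effect design is rank deficient on the observed records")
  eg <- bend_grm(grm$A)

  # starting values: half the per-variate sample variance for each of the
  # genetic and residual components (the equal-split matches a 0.5
  # heritability prior belief and is the conventional EM start)
  vars <- apply(Y, 2L, stats::var, na.rm = TRUE)
  vars[!is.finite(vars) | vars <= 0] <- 1
  su <- diag(vars / 2, d); se <- diag(vars / 2, d)

  step_fun <- if (complete) {
    make_rotated_step(Y, X0, eg, n, d, p0)
  } else {
    make_direct_step(Y, X0, eg, pattern)
  }

  # EM with squared-extrapolation acceleration: each cycle takes two plain
  # EM steps, extrapolates along the observed parameter trajectory, and
  # keeps the extrapolated point only when it is admissible (PSD) and does
  # not lower the restricted likelihood - so the recorded likelihood path
  # stays non-decreasing, as for plain EM.
  state <- new.env(parent = emptyenv())
  state$loglik_path <- numeric(0)
  state$n_proj <- 0L
  state$failed <- FALSE
  state$aborted <- FALSE
  # one safeguarded EM step from (su, se); records loglik at the input
  em_step <- function(su, se, record = TRUE) {
    st <- step_fun(su, se)
    if (!st$ok) {
      state$failed <- TRUE
      return(NULL)
    }
    if (record) state$loglik_path <- c(state$loglik_path, st$loglik)
    proj <- FALSE
    for (nm in c("su", "se")) {
      M <- st[[nm]]
      ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min < 0) {
        st[[nm]] <- clip_psd(M, floor = 1e-8, tol = 0)$mat
        if (ev_min < -1e-10) proj <- TRUE
      }
    }
    state$n_proj <- if (proj) state$n_proj + 1L else 0L
    if (state$n_proj >= 3L) state$aborted <- TRUE
    st
  }
  rel_delta <- function(su0, se0, su1, se1) {
    max(abs(su1 - su0), abs(se1 - se0)) / max(abs(su0), abs(se0), 1e-12)
  }
  converged <- FALSE
  iter <- 0L
  while (iter < maxit && !state$failed && !state$aborted) {
    s1 <- em_step(su, se); iter <- iter + 1L
    if (is.null(s1) || state$aborted) break
    if (rel_delta(su, se, s1$su, s1$se) < tol) {
      su <- s1$su; se <- s1$se; converged <- TRUE; break
    }
    s2 <- em_step(s1$su, s1$se); iter <- iter + 1L
    if (is.null(s2) || state$aborted) { su <- s1$su; se <- s1$se; break }
    if (rel_delta(s1$su, s1$se, s2$su, s2$se) < tol) {
      su <- s2$su; se <- s2$se; converged <- TRUE; break
    }
    # squared extrapolation (SQUAREM-style steplength)
    r_u <- s1$su - su;  r_e <- s1$se - se
    v_u <- (s2$su - s1$su) - r_u; v_e <- (s2$se - s1$se) - r_e
    rn <- sqrt(sum(r_u^2) + sum(r_e^2)); vn <- sqrt(sum(v_u^2) + sum(v_e^2))
    alpha <- if (vn > 0) -rn / vn else -1
    if (!is.finite(alpha) || alpha > -1) alpha <- -1
    accepted <- FALSE
    if (alpha < -1) {
      su_x <- su - 2 * alpha * r_u + alpha^2 * v_u
      se_x <- se - 2 * alpha * r_e + alpha^2 * v_e
      ok_psd <- min(eigen((su_x + t(su_x)) / 2, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10 &&
        min(eigen((se_x + t(se_x)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) > -1e-10
      if (ok_psd) {
        su_x <- clip_psd((su_x + t(su_x)) / 2, floor = 1e-10, tol = 0)$mat
        se_x <- clip_psd((se_x + t(se_x)) / 2, floor = 1e-10, tol = 0)$mat
        s3 <- step_fun(su_x, se_x)
        last_ll <- state$loglik_path[length(state$loglik_path)]
        if (s3$ok && s3$loglik >= last_ll) {
          state$loglik_path <- c(state$loglik_path, s3$loglik)
          iter <- iter + 1L
          st3 <- list(su = s3$su, se = s3$se)
          for (nm in c("su", "se")) {
            M <- st3[[nm]]
            ev_min <- min(eigen(M, symmetric = TRUE,
                                only.values = TRUE)$values)
            if (ev_min < 0) st3[[nm]] <- clip_psd(M, floor = 1e-8,
                                                  tol = 0)$mat
          }
          if (rel_delta(su_x, se_x, st3$su, st3$se) < tol) converged <- TRUE
          su <- st3$su; se <- st3$se
          accepted <- TRUE
        }
      }
    }
    if (!accepted) { su <- s2$su; se <- s2$se }
    if (converged) break
    if (verbose && iter %% 99L < 3L)
      message("  iter ", iter, " loglik ",
              format(state$loglik_path[length(state$loglik_path)],
                     digits = 10))
  }
  if (state$failed)
    message("em_reml: covariance became numerically singular; ",
            "declaring non-convergence")
  if (state$aborted)
    message("em_reml: 3 consecutive non-PSD updates; declaring non-convergence")
  if (!converged && !state$failed && !state$aborted && iter >= maxit)
    message("em_reml: no convergence within ", maxit, " iterations")
  variance_components(su, se, converged = converged, n_iter = iter,
                      loglik_path = state$loglik_path,
                      variate_names = ph$variate_names)
}

# One EM step on complete data in the eigenspace of A.  A = U diag(lam) U'
# turns V into n independent d x d blocks M_i = lam_i*su + se; traces and
# quadratic forms needed by the EM updates are rotation-invariant.
make_rotated_step <- function(Y, X0, eg, n, d, p0) {
  U <- eg$U; lam <- eg$lam
  Yt <- crossprod(U, Y)
  X0t <- crossprod(U, X0)
  p <- d * p0
  function(su, se) {
    Minv <- array(0, c(n, d, d))
    logdetV <- 0
    for (i in seq_len(n)) {
      Mi <- lam[i] * su + se
      ch <- tryCatch(chol(Mi), error = function(e) NULL)
      if (is.null(ch)) return(list(ok = FALSE))
      logdetV <- logdetV + 2 * sum(log(diag(ch)))
      Minv[i, , ] <- chol2inv(ch)
    }
    # GLS for the stacked block-diagonal design I_d (x) X0
    K0 <- matrix(0, p, p)
    Xty <- numeric(p)
    W <- matrix(0, n, d)
    for (j in seq_len(d)) {
      for (k in seq_len(d)) W[, j] <- W[, j] + Minv[, j, k] * Yt[, k]
    }
    for (c1 in seq_len(d)) {
      i1 <- (c1 - 1L) * p0 + seq_len(p0)
      Xty[i1] <- crossprod(X0t, W[, c1])
      for (c2 in seq_len(d)) {
        i2 <- (c2 - 1L) * p0 + seq_len(p0)
        K0[i1, i2] <- crossprod(X0t, Minv[, c1, c2] * X0t)
      }
    }
    cK <- tryCatch(chol((K0 + t(K0)) / 2), error = function(e) NULL)
    if (is.null(cK)) return(list(ok = FALSE))
    Kinv <- chol2inv(cK)
    beta <- Kinv %*% Xty
    Bmat <- matrix(beta, p0, d)
    Rt <- Yt - X0t %*% Bmat
    Pyt <- matrix(0, n, d)
    for (j in seq_len(d)) {
      for (k in seq_len(d)) Pyt[, j] <- Pyt[, j] + Minv[, j, k] * Rt[, k]
    }
    ut <- (Pyt %*% su) * lam
    TU <- crossprod(ut, ut / lam)
    et <- Pyt %*% se
    TE <- crossprod(et)
    # trace corrections: S_u[l,m] = tr(P_block(l,m) * A), S_e = tr(P_block)
    Blist <- vector("list", d)
    for (l in seq_len(d)) {
      Bl <- matrix(0, n, p)
      for (c1 in seq_len(d)) {
        i1 <- (c1 - 1L) * p0 + seq_len(p0)
        Bl[, i1] <- Minv[, l, c1] * X0t
      }
      Blist[[l]] <- Bl
    }
    Su <- matrix(0, d, d); Se <- matrix(0, d, d)
    for (l in seq_len(d)) {
      BKl <- Blist[[l]] %*% Kinv
      for (m in seq_len(d)) {
        cross <- rowSums(BKl * Blist[[m]])
        Su[l, m] <- sum(lam * Minv[, l, m]) - sum(lam * cross)
        Se[l, m] <- sum(Minv[, l, m]) - sum(cross)
      }
    }
    su_new <- (TU + n * su - su %*% Su %*% su) / n
    se_new <- (TE + n * se - se %*% Se %*% se) / n
    ypy <- sum(Rt * Pyt)
    loglik <- -0.5 * (logdetV + 2 * sum(log(diag(cK))) + ypy +
                        (n * d - p) * log(2 * pi))
    list(ok = TRUE, su = (su_new + t(su_new)) / 2,
         se = (se_new + t(se_new)) / 2, loglik = loglik)
  }
}

# One EM step on the direct observed-record covariance (arbitrary
# missingness).  Blocks of V, the trace terms, and the conditional moments
# of u and e are assembled from the per-variate observed index lists.
make_direct_step <- function(Y, X0, eg, pattern) {
  n <- pattern$n; d <- pattern$d
  obs <- pattern$observed
  lens <- lengths(obs)
  offs <- cumsum(c(0L, lens))
  recs <- lapply(seq_len(d), function(j) offs[j] + seq_len(lens[j]))
  N <- sum(lens)
  p0 <- ncol(X0); p <- d * p0
  A_work <- eg$U %*% (eg$lam * t(eg$U))
  Ainv <- eg$U %*% ((1 / eg$lam) * t(eg$U))
  Ablk <- Iblk <- vector("list", d * d)
  for (j in seq_len(d)) for (k in seq_len(d)) {
    Ablk[[(j - 1L) * d + k]] <- A_work[obs[[j]], obs[[k]], drop = FALSE]
    Iblk[[(j - 1L) * d + k]] <- outer(obs[[j]], obs[[k]], "==") * 1
  }
  Yv <- as.vector(Y)[pattern$obs_records]
  Xm <- stacked_design(X0, pattern)
  function(su, se) {
    V <- matrix(0, N, N)
    for (j in seq_len(d)) for (k in seq_len(d)) {
      V[recs[[j]], recs[[k]]] <- su[j, k] * Ablk[[(j - 1L) * d + k]] +
        se[j, k] * Iblk[[(j - 1L) * d + k]]
    }
    cholV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cholV)) return(list(ok = FALSE))
    Vinv <- chol2inv(cholV)
    VX <- Vinv %*% Xm
    K <- crossprod(Xm, VX)
    cK <- tryCatch(chol((K + t(K)) / 2), error = function(e) NULL)
    if (is.null(cK)) return(list(ok = FALSE))
    Kinv <- chol2inv(cK)
    beta <- Kinv %*% crossprod(VX, Yv)
    r <- Yv - Xm %*% beta
    Py <- Vinv %*% r
    P <- Vinv - VX %*% tcrossprod(Kinv, VX)
    Su <- matrix(0, d, d); Se <- matrix(0, d, d)
    for (l in seq_len(d)) for (m in seq_len(d)) {
      Pblk <- P[recs[[l]], recs[[m]], drop = FALSE]
      Su[l, m] <- sum(Pblk * Ablk[[(l - 1L) * d + m]])
      Se[l, m] <- sum(Pblk * Iblk[[(l - 1L) * d + m]])
    }
    T1 <- matrix(0, n, d)
    E1 <- matrix(0, n, d)
    for (l in seq_len(d)) {
      Pyl <- Py[recs[[l]]]
      T1[, l] <- A_work[, obs[[l]], drop = FALSE] %*% Pyl
      E1[obs[[l]], l] <- Pyl
    }
    Uhat <- T1 %*% su
    TU <- crossprod(Uhat, Ainv %*% Uhat)
    Ehat <- E1 %*% se
    TE <- crossprod(Ehat)
    su_new <- (TU + n * su - su %*% Su %*% su) / n
    se_new <- (TE + n * se - se %*% Se %*% se) / n
    loglik <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cK))) +
                        sum(r * Py) + (N - p) * log(2 * pi))
    list(ok = TRUE, su = (su_new + t(su_new)) / 2,
         se = (se_new + t(se_new)) / 2, loglik = loglik)
  }
}

#' Restricted log-likelihood of given variance components
#'
#' Evaluates the standard REML log-likelihood
#' `-(log|V| + log|X'V^-1 X| + y'Py + (N - p) log 2*pi) / 2` on the
#' observed records, independently of the EM machinery.
#'
#' @param vc a [variance_components()].
#' @param ph a [phenotype_table()].
#' @param grm an aligned `GRM`.
#' @param covariates optional per-variate design (`n x p0`; default
#'   intercept).
#' @return a finite scalar.
#' @export
restricted_loglik <- function(vc, ph, grm, covariates = NULL) {
  pattern <- missing_pattern(ph)
  X0 <- covariates %||% matrix(1, pattern$n, 1)
  Xm <- stacked_design(as.matrix(X0), pattern)
  p <- ncol(Xm)
  V <- build_Vm(vc, grm, pattern)
  N <- nrow(V)
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV))
    stop("singular phenotypic covariance (condition number ",
         format(kappa(V), digits = 3), ")")
  Yv <- as.vector(ph$values)[pattern$obs_records]
  Vinv <- chol2inv(cholV)
  VX <- Vinv %*% Xm
  K <- crossprod(Xm, VX)
  cK <- chol((K + t(K)) / 2)
  beta <- chol2inv(cK) %*% crossprod(VX, Yv)
  r <- Yv - Xm %*% beta
  ll <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cK))) +
                  sum(r * (Vinv %*% r)) + (N - p) * log(2 * pi))
  as.numeric(ll)
}
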