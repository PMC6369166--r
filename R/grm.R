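#' Genomic relationship matrix (VanRaden method 1)
#'
#' `A = W W' / (2 * sum(p_k (1 - p_k)))` where column `k` of `W` is the
#' dosage vector centered by twice the observed allele frequency `p_k`.
#' Monomorphic SNPs contribute nothing to `W W'` and are excluded from the
#' denominator sum.  If numerical error leaves eigenvalues below `-1e-8`
#' the matrix is repaired by clipping the offending eigenvalues at `1e-8`
#' and reconstructing (reported via a message).
#'
#' @param g a [genotype_matrix()].
#' @return an object of class `GRM` with elements `A` (n x n symmetric
#'   matrix) and `sample_id`.
#' @export
compute_grm <- function(g) {
  p <- colMeans(g$dosages) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L)
    stop("compute_grm needs at least 2 polymorphic SNPs")
  W <- sweep(g$dosages[, poly, drop = FALSE], 2L, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  A <- tcrossprod(W) / denom
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    message("compute_grm: clipped ", sum(ev < -1e-8),
            " negative eigenvalue(s) to restore positive semidefiniteness")
    A <- clip_psd(A)$mat
  }
  dimnames(A) <- list(g$sample_id, g$sample_id)
  structure(list(A = A, sample_id = g$sample_id), class = "GRM")
}

#' @export
print.GRM <- function(x, ...) {
  cat("GRM:", length(x$sample_id), "individuals; mean diagonal",
      format(mean(diag(x$A)), digits = 4), "\n")
  invisible(x)
}

# Restrict a GRM to a subset of samples (by id or index).
subset_grm <- function(grm, keep) {
  if (is.character(keep)) keep <- match(keep, grm$sample_id)
  structure(list(A = grm$A[keep, keep, drop = FALSE],
                 sample_id = grm$sample_id[keep]), class = "GRM")
}
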