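#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic multiplicative-counter derivation (splitmix-style) so that
#' independent random streams (replicates, scenarios, stages) can be re-run
#' in isolation from a single master seed.  All arithmetic stays below 2^53
#' and the result below 2^31, so it is exact in double precision and a valid
#' [set.seed()] argument.
#'
#' @param master integer master seed.
#' @param ... integer stream indices (e.g. stage, replicate, scenario).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- abs(as.double(master)) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + abs(as.double(k)) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

# Symmetrize and clip eigenvalues below `floor`; returns the repaired matrix
# and whether clipping was needed beyond `tol`.
clip_psd <- function(M, floor = 1e-8, tol = 1e-8) {
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  clipped <- min(ee$values) < -tol
  if (any(ee$values < floor)) {
    vals <- pmax(ee$values, floor)
    M <- ee$vectors %*% (vals * t(ee$vectors))
    M <- (M + t(M)) / 2
  }
  list(mat = M, clipped = clipped)
}

is_psd <- function(M, tol = 1e-8) {
  if (!isSymmetric(unname(M), tol = 1e-6)) return(FALSE)
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

# Compound-symmetry correlation matrix with off-diagonal r.
cs_matrix <- function(d, r) {
  S <- matrix(r, d, d)
  diag(S) <- 1
  S
}
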