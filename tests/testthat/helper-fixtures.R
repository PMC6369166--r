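# Fixture builders and independent oracles shared across the suite.

# Small random genotype matrix with valid metadata.
toy_genotypes <- function(n = 6, M = 8, seed = 1, values = c(0, 1, 2)) {
  set.seed(seed)
  dos <- matrix(sample(values, n * M, replace = TRUE), n, M)
  genotype_matrix(dos, snp_id = paste0("s", seq_len(M)),
                  chrom = rep("chr1", M), pos = seq_len(M) * 100,
                  sample_id = paste0("ind", seq_len(n)))
}

# Three-sample VCF with one clean biallelic site per example genotype,
# one multiallelic record (must be skipped) and one phased site.
write_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "v1", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "A", "C,G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "300", "v3", "G", "T", ".", "PASS", ".", "GT",
          "1|1", "0|1", "0|0", sep = "\t"))
  writeLines(lines, path)
  path
}

# Four samples x five SNPs PLINK text fixture.  The expected dosage matrix
# was decoded by hand once from these allele pairs (minor allele counted;
# frequency ties broken toward the lexicographically smaller allele;
# missing pair of sample i4 at s5 mean-imputed to 0).
write_plink_fixture <- function(prefix) {
  map <- c("1 s1 0 100", "1 s2 0 200", "1 s3 0 300", "1 s4 0 400",
           "1 s5 0 500")
  ped <- c(
    "1 i1 0 0 0 -9 A A A C G G T T C C",
    "1 i2 0 0 0 -9 A C C C G T T T C C",
    "1 i3 0 0 0 -9 C C A C T T T A C C",
    "1 i4 0 0 0 -9 A A A A G T T T 0 0")
  writeLines(map, paste0(prefix, ".map"))
  writeLines(ped, paste0(prefix, ".ped"))
  invisible(prefix)
}

plink_fixture_expected <- function() {
  matrix(c(0, 1, 2, 0, 0,
           1, 0, 1, 0, 0,
           2, 1, 0, 1, 0,
           0, 2, 1, 0, 0),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("i", 1:4), paste0("s", 1:5)))
}

# Element-by-element VanRaden method-1 evaluation (brute force).
grm_brute <- function(dos) {
  n <- nrow(dos); M <- ncol(dos)
  p <- colMeans(dos) / 2
  poly <- which(p > 0 & p < 1)
  denom <- 0
  for (k in poly) denom <- denom + 2 * p[k] * (1 - p[k])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in poly) s <- s + (dos[i, k] - 2 * p[k]) * (dos[j, k] - 2 * p[k])
    A[i, j] <- s / denom
  }
  A
}

# Brute-force observed-record covariance: loops over record pairs of the
# stacked (variate-major) response, no Kronecker shortcut.
vm_brute <- function(su, se, A, mask) {
  n <- nrow(mask); d <- ncol(mask)
  idx <- which(as.vector(mask))
  var_of <- function(rec) (rec - 1) %/% n + 1
  ind_of <- function(rec) (rec - 1) %% n + 1
  N <- length(idx)
  V <- matrix(0, N, N)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    ja <- var_of(idx[a]); jb <- var_of(idx[b])
    ia <- ind_of(idx[a]); ib <- ind_of(idx[b])
    V[a, b] <- su[ja, jb] * A[ia, ib] + se[ja, jb] * (ia == ib)
  }
  V
}

# Independent scalar (d = 1) REML log-likelihood with explicit inverses.
scalar_reml_loglik <- function(y, X, A, su, se) {
  n <- length(y)
  V <- su * A + se * diag(n)
  Vi <- solve(V)
  K <- t(X) %*% Vi %*% X
  beta <- solve(K, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(K)$modulus +
                       t(r) %*% Vi %*% r +
                       (n - ncol(X)) * log(2 * pi)))
}

# GRM wrapper around an arbitrary matrix for tests.
as_grm <- function(A, sample_id = paste0("ind", seq_len(nrow(A)))) {
  dimnames(A) <- list(sample_id, sample_id)
  structure(list(A = A, sample_id = sample_id), class = "GRM")
}

# Random symmetric positive-definite d x d matrix.
random_psd <- function(d, seed) {
  set.seed(seed)
  B <- matrix(rnorm(d * d), d)
  crossprod(B) + diag(d) * 0.5
}
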