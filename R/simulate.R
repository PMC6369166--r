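#' Simulation scenario
#'
#' Bundles the parameters of one power-study condition: number of variates
#' `d`, compound-symmetry correlation `r` shared by the genetic effects and
#' residuals, relative target-QTL effect `a_d` on the last variate (the
#' intermediate variates receive evenly spaced values between 1 and `a_d`),
#' missing proportion `m_prop` (at most `(d-1)/d`, at which point every
#' individual keeps exactly one variate), panel size and genome settings.
#'
#' @param d number of variates.
#' @param r phenotypic correlation, `|r| < 1`.
#' @param a_d relative effect on the last variate, in `[-1, 1]`.
#' @param m_prop missing proportion of phenotype cells.
#' @param n individuals (default 200).
#' @param n_chr chromosomes (default 5).
#' @param snps_per_chr SNPs per chromosome before pruning (default 2000).
#' @param maf_threshold MAF pruning threshold (default 0.02).
#' @param qtl_per_chr QTLs sampled per chromosome (default 4; 0 gives a
#'   null simulation).
#' @param replicates number of data sets (default 20).
#' @param seed master seed.
#' @return an object of class `SimScenario`.
#' @export
sim_scenario <- function(d = 2L, r = 0, a_d = 1, m_prop = 0, n = 200L,
                         n_chr = 5L, snps_per_chr = 2000L,
                         maf_threshold = 0.02, qtl_per_chr = 4L,
                         replicates = 20L, seed = 1L) {
  d <- as.integer(d); n <- as.integer(n)
  if (d < 1L) stop("d must be >= 1")
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (abs(a_d) > 1) stop("a_d must lie in [-1, 1]")
  max_m <- max_missing_prop(d, n)
  if (m_prop < 0 || m_prop > max_m + 1e-12)
    stop("m_prop must be <= (d*n - n)/(d*n) = ", format(max_m),
         " so that every individual keeps a record")
  structure(list(d = d, r = r, a_d = a_d, m_prop = m_prop, n = n,
                 n_chr = as.integer(n_chr),
                 snps_per_chr = as.integer(snps_per_chr),
                 maf_threshold = maf_threshold,
                 qtl_per_chr = as.integer(qtl_per_chr),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "SimScenario")
}

#' Maximum missing proportion with every individual retained
#'
#' `(d*n - n)/(d*n) = (d - 1)/d`: at this proportion each individual keeps
#' exactly one observed variate.
#'
#' @param d number of variates.
#' @param n number of individuals.
#' @return the maximal missing proportion.
#' @export
max_missing_prop <- function(d, n = 200L) (d * n - n) / (d * n)

# Evenly spaced relative effects from 1 (first variate) to a_d (last).
a_sequence <- function(d, a_d) {
  if (d == 1L) return(1)
  seq(1, a_d, length.out = d)
}

#' Simulate inbred genotypes with linkage disequilibrium
#'
#' Self-contained mosaic-haplotype generator for a fully selfing species.
#' Each chromosome carries a pool of founder haplotypes: per-site ancestral
#' allele frequencies follow a U-shaped Beta distribution (so rare variants
#' exist and MAF pruning is active), and each founder's alleles arise by
#' thresholding a latent stationary AR(1) Gaussian at the site-specific
#' frequency quantile, which gives the pool strong local allelic
#' association that decays smoothly with marker distance.  Each individual
#' is then a recombinant mosaic of founder segments (segments end with
#' probability `switch_prob` per marker interval), doubled to homozygosity
#' so dosages are in `{0, 2}`.  Chromosomes are independent.
#'
#' @param n individuals (default 200).
#' @param n_chr chromosomes (default 5).
#' @param snps_per_chr SNPs per chromosome (default 2000).
#' @param seed integer seed (deterministic output).
#' @param n_founders founder haplotypes per chromosome.
#' @param ar_phi autocorrelation of the latent AR(1) between adjacent
#'   markers (controls how fast haplotype association decays).
#' @param switch_prob per-interval probability that a mosaic segment ends.
#' @param freq_shape shape parameter of the symmetric Beta distribution of
#'   ancestral allele frequencies (smaller = more rare variants).
#' @return a [genotype_matrix()] with `n x (n_chr * snps_per_chr)` dosages.
#' @export
simulate_genotypes <- function(n = 200L, n_chr = 5L, snps_per_chr = 2000L,
                               seed = 1L, n_founders = 64L, ar_phi = 0.95,
                               switch_prob = 0.01, freq_shape = 0.4) {
  if (n < 2L) stop("n must be >= 2")
  set.seed(seed)
  S <- as.integer(snps_per_chr)
  dos <- matrix(0, n, n_chr * S)
  chrom <- rep(paste0("chr", seq_len(n_chr)), each = S)
  pos <- rep(seq_len(S) * 500, n_chr)
  for (cc in seq_len(n_chr)) {
    freq <- stats::rbeta(S, freq_shape, freq_shape)
    freq <- pmin(pmax(freq, 0.005), 0.995)
    thr <- stats::qnorm(freq)
    pool <- matrix(0L, n_founders, S)
    sd_innov <- sqrt(1 - ar_phi^2)
    for (f in seq_len(n_founders)) {
      z <- numeric(S)
      z[1L] <- stats::rnorm(1L)
      innov <- stats::rnorm(S - 1L, sd = sd_innov)
      for (k in 2L:S) z[k] <- ar_phi * z[k - 1L] + innov[k - 1L]
      pool[f, ] <- as.integer(z < thr)
    }
    for (i in seq_len(n)) {
      switches <- stats::runif(S - 1L) < switch_prob
      seg <- cumsum(c(1L, switches))
      founders <- sample.int(n_founders, seg[S], replace = TRUE)
      path <- founders[seg]
      dos[i, (cc - 1L) * S + seq_len(S)] <- 2 * pool[cbind(path, seq_len(S))]
    }
  }
  genotype_matrix(dos,
                  snp_id = paste0(chrom, "_s", rep(seq_len(S), n_chr)),
                  chrom = chrom, pos = pos,
                  sample_id = paste0("ind", seq_len(n)))
}

#' Sample the QTL positions
#'
#' Picks `qtl_per_chr` polymorphic SNPs at random on every chromosome and
#' flags one of them (uniformly) as the target QTL whose detection the
#' power study scores; the rest form the polygenic background.  The indices
#' are recorded so the relationship matrix can be built from the
#' non-QTL SNPs.
#'
#' @param g a [genotype_matrix()] (typically after [prune_maf()]).
#' @param qtl_per_chr QTLs per chromosome (default 4; 0 gives an empty
#'   architecture for null simulations).
#' @param seed integer seed.
#' @return a `QTLArchitecture` skeleton with `qtl_idx`, `target_idx`
#'   (index into `g`, `NA` when empty); effects are added by
#'   [draw_effects()].
#' @export
sample_qtls <- function(g, qtl_per_chr = 4L, seed = 1L) {
  set.seed(seed)
  qtl_per_chr <- as.integer(qtl_per_chr)
  if (qtl_per_chr == 0L) {
    return(structure(list(qtl_idx = integer(0), target_idx = NA_integer_,
                          d = NULL, effects = NULL, Sigma = NULL),
                     class = "QTLArchitecture"))
  }
  poly <- apply(g$dosages, 2L, function(x) stats::var(x) > 0)
  qtl_idx <- integer(0)
  for (cc in unique(g$chrom)) {
    cand <- which(g$chrom == cc & poly)
    if (length(cand) < qtl_per_chr)
      stop("chromosome ", cc, " has fewer than ", qtl_per_chr,
           " polymorphic SNPs")
    qtl_idx <- c(qtl_idx, sort(sample(cand, qtl_per_chr)))
  }
  target_idx <- qtl_idx[sample.int(length(qtl_idx), 1L)]
  structure(list(qtl_idx = qtl_idx, target_idx = target_idx,
                 d = NULL, effects = NULL, Sigma = NULL),
            class = "QTLArchitecture")
}

#' Draw QTL effects for a scenario
#'
#' The target-QTL effect on the first variate is drawn from `N(0, 1)` and
#' propagated to variate `j` as `a_j` times that draw, with the `a_j`
#' evenly spaced between 1 and `a_d`.  Background-QTL effect vectors are
#' i.i.d. `MVN(0, Sigma)` with `Sigma` the compound-symmetry correlation
#' matrix with off-diagonal `r`.
#'
#' @param skeleton a [sample_qtls()] result.
#' @param d number of variates.
#' @param r effect correlation, `|r| < 1`.
#' @param a_d relative target effect on the last variate, in `[-1, 1]`.
#' @param seed integer seed.
#' @return the completed `QTLArchitecture` with an `effects` matrix
#'   (`n_qtl x d`, target row flagged), `a` vector, `Sigma`.
#' @export
draw_effects <- function(skeleton, d, r, a_d, seed = 1L) {
  if (abs(a_d) > 1) stop("a_d must lie in [-1, 1]")
  if (abs(r) >= 1) stop("|r| must be < 1")
  set.seed(seed)
  d <- as.integer(d)
  Sigma <- cs_matrix(d, r)
  arch <- skeleton
  arch$d <- d
  arch$Sigma <- Sigma
  arch$a <- a_sequence(d, a_d)
  n_qtl <- length(skeleton$qtl_idx)
  if (n_qtl == 0L) {
    arch$effects <- matrix(0, 0L, d)
    return(arch)
  }
  target_row <- match(skeleton$target_idx, skeleton$qtl_idx)
  b1 <- stats::rnorm(1L)
  target_effects <- arch$a * b1
  n_bg <- n_qtl - 1L
  bg <- if (n_bg > 0L) {
    MASS::mvrnorm(n_bg, mu = rep(0, d), Sigma = Sigma)
  } else matrix(0, 0L, d)
  bg <- matrix(bg, n_bg, d)
  effects <- matrix(0, n_qtl, d)
  effects[target_row, ] <- target_effects
  effects[-target_row, ] <- bg
  arch$effects <- effects
  arch$target_row <- target_row
  arch
}

#' Simulate phenotypes at heritability 0.5
#'
#' Total genetic values are the dosage-weighted sums of all QTL effects,
#' `u[i, j] = sum_k dosage[i, qtl_k] * effect[k, j]`.  Residuals are i.i.d.
#' `MVN(0, S Sigma S)` across individuals, where `S` is the diagonal matrix
#' of the realized standard deviations of the genetic-value columns - so
#' each variate's realized narrow-sense heritability is 0.5 by
#' construction (up to sampling noise in the genetic/residual covariance).
#' With an empty architecture the phenotypes are pure `MVN(0, Sigma)` noise
#' (unit `S` fallback).
#'
#' @param g a [genotype_matrix()].
#' @param arch a completed [draw_effects()] architecture.
#' @param seed integer seed.
#' @return a [phenotype_table()] with attributes `genetic_values` (the
#'   `n x d` matrix `u`) and `S` (the residual scale matrix).
#' @export
simulate_phenotypes <- function(g, arch, seed = 1L) {
  if (is.null(arch$d)) stop("draw_effects() must be applied first")
  set.seed(seed)
  n <- nrow(g$dosages); d <- arch$d
  if (length(arch$qtl_idx) > 0L) {
    u <- g$dosages[, arch$qtl_idx, drop = FALSE] %*% arch$effects
    sds <- apply(u, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero genetic variance in a variate with non-empty QTLs; ",
           "the residual scale S is undefined")
  } else {
    u <- matrix(0, n, d)
    sds <- rep(1, d)
  }
  S <- diag(sds, d)
  e <- MASS::mvrnorm(n, mu = rep(0, d), Sigma = S %*% arch$Sigma %*% S)
  e <- matrix(e, n, d)
  y <- u + e
  ph <- phenotype_table(y, sample_id = g$sample_id,
                        variate_names = paste0("y", seq_len(d)))
  attr(ph, "genetic_values") <- u
  attr(ph, "S") <- S
  ph
}

#' Mask phenotype cells at random
#'
#' Masks exactly `round(m_prop * n * d)` cells, subject to every individual
#' retaining at least one observed variate: each individual first receives
#' one uniformly chosen protected variate, and the masked cells are then a
#' uniform draw from the unprotected cells.  At the maximal proportion
#' `(d-1)/d` every individual keeps exactly its protected variate.
#'
#' @param ph a [phenotype_table()].
#' @param m_prop missing proportion in `[0, (d-1)/d]`.
#' @param seed integer seed.
#' @return the masked [phenotype_table()] (attributes preserved).
#' @export
apply_missingness <- function(ph, m_prop, seed = 1L) {
  n <- nrow(ph$values); d <- ncol(ph$values)
  m <- round(m_prop * n * d)
  if (m_prop > max_missing_prop(d, n) + 1e-12)
    stop("m_prop exceeds (d*n - n)/(d*n) = ",
         format(max_missing_prop(d, n)),
         "; every individual must keep a record")
  if (m == 0L) return(ph)
  set.seed(seed)
  protected <- sample.int(d, n, replace = TRUE)
  eligible <- which(as.vector(vapply(seq_len(d), function(j) protected != j,
                                     logical(n))))
  masked <- sample(eligible, m)
  mask <- ph$mask
  mask[masked] <- FALSE
  out <- phenotype_table(ph$values, ph$sample_id, ph$variate_names, mask)
  attr(out, "genetic_values") <- attr(ph, "genetic_values")
  attr(out, "S") <- attr(ph, "S")
  out
}

#' Simulate one complete data set for a scenario
#'
#' Convenience pipeline: genotypes, MAF pruning, QTL sampling, effect
#' draws, phenotypes, missingness, and the GRM built from all non-QTL SNPs.
#' All stage seeds are derived deterministically from `seed` via
#' [derive_seed()], so any stage can be reproduced in isolation.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed (default: the scenario's).
#' @param genotypes optionally reuse a pruned [genotype_matrix()] together
#'   with its `skeleton` from [sample_qtls()] and `grm` (list with those
#'   names), as when many scenarios share genotype sets.
#' @return a list with `geno`, `ph`, `arch`, `grm` of class `SimDataset`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed,
                             genotypes = NULL) {
  sc <- scenario
  if (is.null(genotypes)) {
    g <- simulate_genotypes(sc$n, sc$n_chr, sc$snps_per_chr,
                            seed = derive_seed(seed, 1L))
    g <- prune_maf(g, sc$maf_threshold)
    skeleton <- sample_qtls(g, sc$qtl_per_chr, seed = derive_seed(seed, 2L))
    grm <- compute_grm(if (length(skeleton$qtl_idx) > 0L)
      subset_snps(g, -skeleton$qtl_idx) else g)
  } else {
    g <- genotypes$geno; skeleton <- genotypes$skeleton
    grm <- genotypes$grm
  }
  arch <- draw_effects(skeleton, sc$d, sc$r, sc$a_d,
                       seed = derive_seed(seed, 3L))
  ph <- simulate_phenotypes(g, arch, seed = derive_seed(seed, 4L))
  ph <- apply_missingness(ph, sc$m_prop, seed = derive_seed(seed, 5L))
  structure(list(geno = g, ph = ph, arch = arch, grm = grm,
                 scenario = sc), class = "SimDataset")
}
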