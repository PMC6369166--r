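#' Run a replicate grid of power scenarios
#'
#' For every scenario in `grid` and every replicate, simulates a data set,
#' fits the multivariate and first-variate univariate null models by
#' EM-REML, tests the target QTL with both F tests, and records the
#' difference of `-log10 p` (multivariate minus univariate).  Genotype
#' panels, QTL positions and the GRM are generated once per replicate and
#' shared by all scenarios of that replicate, mirroring a design in which
#' the same marker sets underlie every condition; effect draws, residuals
#' and missingness get scenario-specific seeds.  Replicates whose REML fit
#' fails to converge are dropped from the mean and counted.
#'
#' @param grid list of [sim_scenario()] objects sharing `n`, genome and QTL
#'   settings (they may differ in `d`, `r`, `a_d`, `m_prop`).
#' @param replicates number of data sets per scenario (default: the first
#'   scenario's `replicates`).
#' @param seed master seed (default: the first scenario's `seed`).
#' @param reml_tol,reml_maxit EM-REML settings.
#' @param verbose print per-replicate progress.
#' @return a data frame with one row per scenario (`d`, `r`, `a_d`,
#'   `m_prop`, `mean_delta`, `n_success`, `n_fail`) and an attribute
#'   `deltas` holding the per-replicate differences.
#' @export
run_grid <- function(grid, replicates = NULL, seed = NULL,
                     reml_tol = 1e-6, reml_maxit = 5000L, verbose = FALSE) {
  if (inherits(grid, "SimScenario")) grid <- list(grid)
  stopifnot(length(grid) >= 1L)
  base <- grid[[1L]]
  replicates <- as.integer(replicates %||% base$replicates)
  seed <- as.integer(seed %||% base$seed)
  stopifnot(replicates >= 1L)
  same <- vapply(grid, function(s)
    s$n == base$n && s$n_chr == base$n_chr &&
      s$snps_per_chr == base$snps_per_chr &&
      s$maf_threshold == base$maf_threshold &&
      s$qtl_per_chr == base$qtl_per_chr, TRUE)
  if (!all(same))
    stop("all scenarios in a grid must share the genome and QTL settings")
  ns <- length(grid)
  deltas <- matrix(NA_real_, replicates, ns)
  for (rep_i in seq_len(replicates)) {
    g <- simulate_genotypes(base$n, base$n_chr, base$snps_per_chr,
                            seed = derive_seed(seed, 1L, rep_i))
    g <- prune_maf(g, base$maf_threshold)
    skeleton <- sample_qtls(g, base$qtl_per_chr,
                            seed = derive_seed(seed, 2L, rep_i))
    if (length(skeleton$qtl_idx) == 0L)
      stop("run_grid needs a target QTL; use qtl_per_chr >= 1")
    grm <- compute_grm(subset_snps(g, -skeleton$qtl_idx))
    shared <- list(geno = g, skeleton = skeleton, grm = grm)
    for (s in seq_len(ns)) {
      sc <- grid[[s]]
      ds <- simulate_dataset(sc, seed = derive_seed(seed, 3L, rep_i, s),
                             genotypes = shared)
      delta <- tryCatch(
        target_delta(ds, reml_tol = reml_tol, reml_maxit = reml_maxit),
        error = function(e) NA_real_)
      deltas[rep_i, s] <- delta
      if (verbose)
        message("replicate ", rep_i, " scenario ", s, ": delta = ",
                format(delta, digits = 4))
    }
  }
  res <- data.frame(
    d = vapply(grid, `[[`, 0L, "d"),
    r = vapply(grid, `[[`, 0, "r"),
    a_d = vapply(grid, `[[`, 0, "a_d"),
    m_prop = vapply(grid, `[[`, 0, "m_prop"),
    mean_delta = colMeans(deltas, na.rm = TRUE),
    n_success = colSums(!is.na(deltas)),
    n_fail = colSums(is.na(deltas)))
  res$mean_delta[res$n_success == 0L] <- NA_real_
  attr(res, "deltas") <- deltas
  res
}

# Multivariate-minus-univariate -log10 p at the target QTL of one data set.
# Errors (non-convergence, degenerate fits) propagate to the caller, which
# records the replicate as failed.
target_delta <- function(ds, reml_tol = 1e-6, reml_maxit = 5000L) {
  ph <- ds$ph; grm <- ds$grm; g <- ds$geno
  x <- g$dosages[, ds$arch$target_idx]
  mv_vc <- em_reml(ph, grm, tol = reml_tol, maxit = reml_maxit)
  if (!mv_vc$converged) stop("multivariate REML failed to converge")
  mv <- make_snp_tester(ph, grm, mv_vc, "multivariate")(
    x, "target", g$chrom[ds$arch$target_idx], g$pos[ds$arch$target_idx])
  keep <- which(ph$mask[, 1L])
  ph1 <- subset_phenotypes(ph, keep, ph$variate_names[1L])
  grm1 <- subset_grm(grm, ph1$sample_id)
  uv_vc <- em_reml(ph1, grm1, tol = reml_tol, maxit = reml_maxit)
  if (!uv_vc$converged) stop("univariate REML failed to converge")
  uv <- make_snp_tester(ph1, grm1, uv_vc, "univariate")(
    x[keep], "target", g$chrom[ds$arch$target_idx],
    g$pos[ds$arch$target_idx])
  if (is.na(mv$F) || is.na(uv$F)) stop("degenerate target QTL")
  mv$neg_log10_p - uv$neg_log10_p
}

#' Arrange grid results as a rectangular heat-map table
#'
#' Validates that the results cover a complete `r x a_d` grid for a single
#' `d` and `m_prop` and returns the long-format table ordered by `r` then
#' `a_d`.  No interpolation is performed: only simulated cells appear.
#'
#' @param results a [run_grid()] result (or compatible data frame).
#' @return data frame `r`, `a_d`, `mean_delta`, `n_success`.
#' @export
delta_heatmap <- function(results) {
  need <- c("d", "r", "a_d", "m_prop", "mean_delta", "n_success")
  if (!all(need %in% colnames(results)))
    stop("results must come from run_grid()")
  if (length(unique(results$d)) != 1L ||
      length(unique(results$m_prop)) != 1L)
    stop("delta_heatmap needs a grid at fixed d and m_prop")
  rs <- sort(unique(results$r)); as <- sort(unique(results$a_d))
  full <- expand.grid(r = rs, a_d = as, KEEP.OUT.ATTRS = FALSE)
  key <- function(df) paste(df$r, df$a_d)
  miss <- setdiff(key(full), key(results))
  if (length(miss) > 0L)
    stop("grid is not rectangular; missing cells: ",
         paste(miss, collapse = "; "))
  if (nrow(results) != nrow(full))
    stop("duplicated grid cells in results")
  out <- results[order(results$r, results$a_d),
                 c("r", "a_d", "mean_delta", "n_success")]
  rownames(out) <- NULL
  out
}

#' Draw the mean-difference heat map
#'
#' Base-graphics `image()` of the [delta_heatmap()] table; warm colors mark
#' cells where the multivariate test beats the univariate one.
#'
#' @param results a [run_grid()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot_delta_heatmap <- function(results, ...) {
  tab <- delta_heatmap(results)
  rs <- sort(unique(tab$r)); as <- sort(unique(tab$a_d))
  z <- matrix(tab$mean_delta[order(tab$a_d, tab$r)], length(rs), length(as))
  lim <- max(abs(z), na.rm = TRUE)
  graphics::image(rs, as, z, xlab = "r", ylab = "a_d",
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(31, "Blue-Red 2"), ...)
  invisible(z)
}

#' QQ data for negative SNPs
#'
#' Selects the SNPs on the target QTL's chromosome whose squared dosage
#' correlation with every QTL is below `r2_threshold` (default 0.1) - the
#' "negative" SNPs, unlinked to any causal locus - and pairs their sorted
#' observed `-log10 p` with uniform-order-statistic expectations.  A
#' regression slope near 1 (see [qq_slope()]) indicates that the test does
#' not inflate the p-values of null SNPs.
#'
#' @param results scan results for a single test variant (e.g. the
#'   multivariate rows of a [gwa_scan()]).
#' @param g the scanned [genotype_matrix()].
#' @param arch the `QTLArchitecture` that generated the phenotypes.
#' @param r2_threshold linkage cutoff (default 0.1).
#' @return a list of class `QQData`: sorted `observed` and `expected`
#'   `-log10 p`, `r2_threshold`, `snp_id`.
#' @export
negative_snp_qq <- function(results, g, arch, r2_threshold = 0.1) {
  if (length(unique(results$test)) != 1L)
    stop("pass results for a single test variant")
  target_chrom <- g$chrom[arch$target_idx]
  on_chrom <- which(g$chrom == target_chrom)
  if (!all(g$snp_id[on_chrom] %in% results$snp_id))
    stop("scan results must cover the target QTL's chromosome")
  qtl_dos <- g$dosages[, arch$qtl_idx, drop = FALSE]
  neg <- vapply(on_chrom, function(s) {
    if (s %in% arch$qtl_idx) return(FALSE)
    x <- g$dosages[, s]
    if (stats::var(x) == 0) return(FALSE)
    r2 <- suppressWarnings(stats::cor(x, qtl_dos))^2
    max(r2, na.rm = TRUE) < r2_threshold
  }, TRUE)
  ids <- g$snp_id[on_chrom][neg]
  rows <- results[results$snp_id %in% ids & !is.na(results$p), ]
  if (nrow(rows) == 0L)
    stop("no negative SNPs at r2 < ", r2_threshold,
         "; consider raising the threshold")
  obs <- sort(-log10(rows$p))
  expd <- sort(-log10(stats::ppoints(length(obs))))
  structure(list(observed = obs, expected = expd,
                 r2_threshold = r2_threshold, snp_id = rows$snp_id),
            class = "QQData")
}

#' Through-origin slope of a QQ comparison
#' @param qq a [negative_snp_qq()] result.
#' @return `sum(obs * exp) / sum(exp^2)`.
#' @export
qq_slope <- function(qq) {
  sum(qq$observed * qq$expected) / sum(qq$expected^2)
}
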