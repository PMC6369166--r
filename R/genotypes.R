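#' Genotype matrix with map metadata
#'
#' An `n` individuals by `M` SNPs matrix of allele dosages in `{0, 1, 2}`
#' (fully inbred material carries only `{0, 2}`), together with SNP
#' identifiers, chromosome labels and 1-based physical positions.  Dosages
#' count copies of the minor allele; the coding is fixed at load time and any
#' consistent coding leaves the F statistics unchanged (only the sign of the
#' estimated SNP effect flips).
#'
#' @param dosages numeric `n x M` matrix, no missing values.
#' @param snp_id character vector of `M` SNP identifiers.
#' @param chrom character vector of `M` chromosome labels.
#' @param pos numeric vector of `M` 1-based positions, strictly increasing
#'   within each chromosome.
#' @param sample_id character vector of `n` sample identifiers.
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosages, snp_id, chrom, pos, sample_id) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); M <- ncol(dosages)
  if (n < 2L) stop("a GenotypeMatrix needs at least 2 individuals")
  if (M < 1L) stop("a GenotypeMatrix needs at least 1 SNP")
  if (anyNA(dosages)) stop("missing dosages are not allowed; impute at load time")
  if (length(snp_id) != M || length(chrom) != M || length(pos) != M)
    stop("snp_id, chrom and pos must each have one entry per SNP")
  if (length(sample_id) != n) stop("sample_id must have one entry per individual")
  if (anyDuplicated(snp_id)) stop("duplicated SNP identifiers")
  if (anyDuplicated(sample_id)) stop("duplicated sample identifiers")
  chrom <- as.character(chrom); pos <- as.numeric(pos)
  for (cc in unique(chrom)) {
    pc <- pos[chrom == cc]
    if (any(diff(pc) <= 0))
      stop("positions must be strictly increasing within chromosome ", cc)
  }
  dimnames(dosages) <- list(as.character(sample_id), as.character(snp_id))
  structure(list(dosages = dosages, snp_id = as.character(snp_id),
                 chrom = chrom, pos = pos,
                 sample_id = as.character(sample_id)),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$sample_id), "individuals x",
      length(x$snp_id), "SNPs on", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

# Subset SNP columns, keeping metadata in step.
subset_snps <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$snp_id[keep],
                  g$chrom[keep], g$pos[keep], g$sample_id)
}

# Subset individuals (rows).
subset_samples <- function(g, keep) {
  genotype_matrix(g$dosages[keep, , drop = FALSE], g$snp_id, g$chrom,
                  g$pos, g$sample_id[keep])
}

#' Read genotypes from VCF, PLINK text, or the native TSV dump
#'
#' All formats are decoded to minor-allele dosages.  For VCF and PLINK the
#' counted allele is chosen as the minor allele at load time (ties keep the
#' ALT allele for VCF and the lexicographically smaller allele for PLINK);
#' the native TSV stores dosages directly and round-trips verbatim.
#' Multiallelic VCF records are skipped with a reported count.  Missing
#' genotypes are mean-imputed per SNP with a warning.
#'
#' @param path file path (`.vcf`, PLINK `.ped` with a sibling `.map`, or the
#'   TSV written by [write_genotypes()]).
#' @param format one of `"vcf"`, `"plink"`, `"native-tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("native-tsv", "vcf", "plink")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  switch(format,
         "vcf" = read_genotypes_vcf(path),
         "plink" = read_genotypes_plink(path),
         "native-tsv" = read_genotypes_native(path))
}

read_genotypes_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("no variant records in VCF ", path)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) & alt != "."
  n_skip <- sum(!biallelic)
  if (n_skip > 0L)
    message("read_genotypes: skipped ", n_skip, " multiallelic/invalid VCF record(s)")
  if (!any(biallelic)) stop("no biallelic sites in VCF ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # count ALT alleles per genotype call
  count_alt <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dos <- t(apply(gt, 1L, function(row) vapply(row, count_alt, 0)))
  dos <- matrix(as.numeric(dos), nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos <- t(dos)  # samples x SNPs
  dos <- impute_and_flip(dos, flip = TRUE)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(dos, ids, fix[, "CHROM"], as.numeric(fix[, "POS"]),
                  colnames(gt))
}

read_genotypes_plink <- function(path) {
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) stop("PLINK .map file not found: ", map_path)
  map <- tryCatch(utils::read.table(map_path, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("failed to parse .map: ",
                                           conditionMessage(e)))
  if (ncol(map) < 4L) stop("malformed .map file (need 4 columns): ", map_path)
  ped <- tryCatch(utils::read.table(path, header = FALSE,
                                    stringsAsFactors = FALSE,
                                    colClasses = "character"),
                  error = function(e) stop("failed to parse .ped: ",
                                           conditionMessage(e)))
  M <- nrow(map)
  if (ncol(ped) != 6L + 2L * M)
    stop("malformed .ped: expected ", 6L + 2L * M, " columns for ", M,
         " SNPs, found ", ncol(ped))
  sample_id <- ped[[2L]]
  dos <- matrix(NA_real_, nrow(ped), M)
  for (k in seq_len(M)) {
    a1 <- ped[[6L + 2L * k - 1L]]
    a2 <- ped[[6L + 2L * k]]
    alle <- c(a1, a2)
    obs <- alle[alle != "0"]
    if (length(obs) == 0L) stop("SNP ", map[[2L]][k], " has no observed alleles")
    tab <- sort(table(obs))
    if (length(tab) > 2L)
      stop("SNP ", map[[2L]][k], " is not biallelic in ", path)
    # minor allele = least frequent; ties resolved lexicographically
    minor <- if (length(tab) == 1L) names(tab) else {
      cand <- names(tab)[tab == min(tab)]
      sort(cand)[1L]
    }
    cnt <- (a1 == minor) + (a2 == minor)
    cnt[a1 == "0" | a2 == "0"] <- NA_real_
    if (length(tab) == 1L) cnt[] <- ifelse(is.na(cnt), NA_real_, 0)
    dos[, k] <- cnt
  }
  dos <- impute_and_flip(dos, flip = FALSE)  # already minor-coded
  genotype_matrix(dos, map[[2L]], as.character(map[[1L]]),
                  as.numeric(map[[4L]]), sample_id)
}

read_genotypes_native <- function(path) {
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("failed to parse native TSV: ",
                                           conditionMessage(e)))
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% colnames(tab)))
    stop("native genotype TSV must have columns snp_id, chrom, pos")
  samp <- setdiff(colnames(tab), need)
  if (length(samp) < 2L) stop("native genotype TSV has fewer than 2 samples")
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  if (!is.numeric(dos)) stop("non-numeric dosages in native genotype TSV")
  if (anyNA(dos)) dos <- impute_and_flip(dos, flip = FALSE)
  if (any(dos < 0 | dos > 2)) stop("dosages outside [0, 2] in native TSV")
  genotype_matrix(dos, tab$snp_id, tab$chrom, tab$pos, samp)
}

# Mean-impute missing dosages per SNP (with a warning); optionally flip
# columns so the counted allele is the minor one.
impute_and_flip <- function(dos, flip) {
  if (anyNA(dos)) {
    n_miss <- sum(is.na(dos))
    warning("mean-imputed ", n_miss, " missing genotype call(s)")
    for (k in which(colSums(is.na(dos)) > 0L)) {
      mk <- mean(dos[, k], na.rm = TRUE)
      if (is.nan(mk)) mk <- 0
      dos[is.na(dos[, k]), k] <- mk
    }
  }
  if (flip) {
    fl <- colMeans(dos) / 2 > 0.5
    if (any(fl)) dos[, fl] <- 2 - dos[, fl, drop = FALSE]
  }
  dos
}

#' Write genotypes to the native TSV dump
#'
#' One row per SNP: `snp_id`, `chrom`, `pos`, then one dosage column per
#' sample.  [read_genotypes()] with `format = "native-tsv"` round-trips the
#' object exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(snp_id = g$snp_id, chrom = g$chrom, pos = g$pos,
                    t(g$dosages), check.names = FALSE,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write genotype TSV to ", path)
  invisible(path)
}

#' Prune SNPs by minor allele frequency
#'
#' Retains exactly the SNPs whose minor allele frequency is at or above
#' `threshold` (the genome-wide pipeline default is 0.02).
#'
#' @param g a [genotype_matrix()].
#' @param threshold allele-frequency threshold in `[0, 0.5]`.
#' @return the pruned [genotype_matrix()].
#' @export
prune_maf <- function(g, threshold = 0.02) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must lie in [0, 0.5]")
  p <- colMeans(g$dosages) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  if (!any(keep)) stop("all SNPs pruned at MAF threshold ", threshold)
  if (all(keep)) return(g)
  subset_snps(g, keep)
}
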