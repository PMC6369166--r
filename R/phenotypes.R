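#' Phenotype table with explicit missingness
#'
#' An `n` individuals by `d` variates table of real-valued phenotypes with a
#' logical mask (`TRUE` = observed).  Every individual must be observed for
#' at least one variate; vectorizing the observed cells in variate-major
#' order defines the stacked response of the mixed model.
#'
#' @param values numeric `n x d` matrix; unobserved cells may be `NA`.
#' @param sample_id `n` sample identifiers.
#' @param variate_names `d` variate labels.
#' @param mask logical `n x d` matrix; defaults to `!is.na(values)`.
#' @return an object of class `PhenotypeTable`.
#' @export
phenotype_table <- function(values, sample_id = rownames(values),
                            variate_names = colnames(values), mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); d <- ncol(values)
  if (is.null(sample_id)) sample_id <- paste0("ind", seq_len(n))
  if (is.null(variate_names)) variate_names <- paste0("y", seq_len(d))
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !all(dim(mask) == dim(values)))
    stop("mask must be a logical matrix matching values")
  if (any(is.na(values) & mask))
    stop("cells flagged observed must not be NA")
  if (any(rowSums(mask) == 0L))
    stop("every individual must have at least one observed variate")
  if (length(sample_id) != n || length(variate_names) != d)
    stop("identifier lengths do not match the value matrix")
  values[!mask] <- NA_real_
  dimnames(values) <- dimnames(mask) <- list(as.character(sample_id),
                                             as.character(variate_names))
  structure(list(values = values, mask = mask,
                 sample_id = as.character(sample_id),
                 variate_names = as.character(variate_names)),
            class = "PhenotypeTable")
}

#' @export
print.PhenotypeTable <- function(x, ...) {
  cat("PhenotypeTable:", nrow(x$values), "individuals x", ncol(x$values),
      "variates;", sum(!x$mask), "missing cell(s)\n")
  invisible(x)
}

#' Read a phenotype CSV
#'
#' First column `sample_id`, remaining columns one per variate; the literal
#' string `NA` (or an empty field) marks a missing record.
#'
#' @param path CSV file path.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read phenotype file: ", path)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("failed to parse phenotype CSV: ",
                                           conditionMessage(e)))
  if (ncol(tab) < 2L) stop("phenotype CSV needs sample_id plus >= 1 variate")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric phenotype values in ", path)
  phenotype_table(vals, sample_id = as.character(tab[[1L]]),
                  variate_names = colnames(tab)[-1L])
}

#' Write a phenotype CSV
#' @param ph a [phenotype_table()].
#' @param path output file path.
#' @export
write_phenotypes <- function(ph, path) {
  tab <- data.frame(sample_id = ph$sample_id, ph$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Restrict to a subset of individuals (indices or ids); rows losing all
# observations are not allowed downstream, but subsetting itself cannot
# create them.
subset_phenotypes <- function(ph, keep, variates = NULL) {
  if (is.character(keep)) keep <- match(keep, ph$sample_id)
  v <- if (is.null(variates)) seq_along(ph$variate_names)
       else match(variates, ph$variate_names)
  if (anyNA(v)) stop("unknown variate name(s)")
  vals <- ph$values[keep, v, drop = FALSE]
  msk <- ph$mask[keep, v, drop = FALSE]
  drop_rows <- rowSums(msk) == 0L
  if (any(drop_rows)) {
    vals <- vals[!drop_rows, , drop = FALSE]
    msk <- msk[!drop_rows, , drop = FALSE]
    keep <- keep[!drop_rows]
  }
  phenotype_table(vals, ph$sample_id[keep], ph$variate_names[v], msk)
}

#' Missingness pattern of a phenotype table
#'
#' Records, in variate-major (stacked) order, which cells of the `n x d`
#' table are observed, plus per-variate observed index lists.  The induced
#' blocks of the relationship matrix (e.g. the two-group partition when each
#' individual carries a single variate) follow from these index lists.
#'
#' @param ph a [phenotype_table()].
#' @return a list with `d`, `n`, `observed` (per-variate index list),
#'   `obs_records` (indices into the stacked `n*d` vector) of class
#'   `MissingPattern`.
#' @export
missing_pattern <- function(ph) {
  m <- ph$mask
  structure(list(d = ncol(m), n = nrow(m),
                 observed = lapply(seq_len(ncol(m)), function(j) which(m[, j])),
                 obs_records = which(as.vector(m))),
            class = "MissingPattern")
}

#' Scan configuration
#'
#' Plumbing for [gwa_scan()]: which variates to analyse, which tests to run,
#' REML settings and the seed.  The fixed-effect design is intercept-only by
#' default (one intercept per variate), matching the null model used for the
#' single variance-component fit.
#'
#' @param variates character vector of variate names (default: all).
#' @param test `"both"`, `"multivariate"` or `"univariate"`.
#' @param exact_reml refit REML per SNP instead of reusing the null-model
#'   variance components (slow; small scans only).
#' @param reml_tol,reml_maxit EM-REML convergence settings.
#' @param seed optional integer seed.
#' @return an object of class `ScanConfig`.
#' @export
scan_config <- function(variates = NULL,
                        test = c("both", "multivariate", "univariate"),
                        exact_reml = FALSE, reml_tol = 1e-6,
                        reml_maxit = 5000L, seed = NULL) {
  test <- match.arg(test)
  structure(list(variates = variates, test = test,
                 exact_reml = isTRUE(exact_reml),
                 reml_tol = reml_tol, reml_maxit = as.integer(reml_maxit),
                 seed = seed),
            class = "ScanConfig")
}

#' Read a scan configuration from YAML
#' @param path YAML file with any of the [scan_config()] fields.
#' @return a `ScanConfig`.
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  y <- yaml::read_yaml(path)
  do.call(scan_config, y[intersect(names(y), names(formals(scan_config)))])
}
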