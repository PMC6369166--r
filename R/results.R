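# Assemble one result row; F may be NA for degenerate SNPs.
test_result_row <- function(snp_id, chrom, pos, test, F, df1, df2, p,
                            neg_log10_p) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, test = test,
             F = F, df1 = df1, df2 = df2, p = p, neg_log10_p = neg_log10_p,
             stringsAsFactors = FALSE)
}

#' Write scan results to TSV
#'
#' Columns: `snp_id, chrom, pos, test, F, df1, df2, p, neg_log10_p`; one row
#' per SNP and test.
#'
#' @param results data frame as returned by [gwa_scan()].
#' @param path output file path.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("write_results needs a non-empty result data frame")
  need <- c("snp_id", "chrom", "pos", "test", "F", "df1", "df2", "p",
            "neg_log10_p")
  if (!all(need %in% colnames(results)))
    stop("result data frame is missing columns: ",
         paste(setdiff(need, colnames(results)), collapse = ", "))
  ok <- tryCatch({
    utils::write.table(results[, need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to ", path)
  invisible(path)
}

#' Read scan results written by [write_results()]
#' @param path TSV file path.
#' @return a data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("cannot read results file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
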