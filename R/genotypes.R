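# Genotype matrix container for array-style calls.
#
# Calls are AA/AB/BB/NA in a samples x SNPs character matrix, with
# per-sample quality summaries (p50GC, call rate), per-SNP clustering
# quality (GenTrain-like score) and optional per-call GC scores.

#' Construct a genotype matrix
#'
#' @param calls character matrix (samples x SNPs) with values `"AA"`,
#'   `"AB"`, `"BB"` or `NA`; row and column names are required.
#' @param samples optional data frame with `id` and `p50gc`; `call_rate`
#'   is computed from `calls` when absent.
#' @param snp_info optional data frame with `id` and `gentrain`.
#' @param gc optional numeric matrix of per-call GC scores, same shape as
#'   `calls`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples = NULL, snp_info = NULL, gc = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    abort("calls must have sample row names and SNP column names")
  bad <- !is.na(calls) & !calls %in% c("AA", "AB", "BB")
  if (any(bad)) abort("calls must be AA/AB/BB or missing")
  if (is.null(samples))
    samples <- data.frame(id = rownames(calls), p50gc = NA_real_,
                          stringsAsFactors = FALSE)
  if (is.null(samples$call_rate))
    samples$call_rate <- rowMeans(!is.na(calls))
  if (!identical(samples$id, rownames(calls)))
    abort("samples$id must match the call matrix rows")
  if (any(samples$call_rate < 0 | samples$call_rate > 1, na.rm = TRUE))
    abort("call_rate must lie in [0, 1]")
  if (is.null(snp_info))
    snp_info <- data.frame(id = colnames(calls), gentrain = NA_real_,
                           stringsAsFactors = FALSE)
  if (!identical(snp_info$id, colnames(calls)))
    abort("snp_info$id must match the call matrix columns")
  if (!is.null(gc) && !identical(dim(gc), dim(calls)))
    abort("gc must have the same shape as calls")
  structure(list(calls = calls, samples = samples, snp_info = snp_info,
                 gc = gc), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%.1f%% called)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(!is.na(x$calls))))
  invisible(x)
}

#' Write / read a genotype matrix as TSV files
#'
#' Writes `<prefix>_calls.tsv` (wide sample x SNP table), plus per-sample
#' and per-SNP score sidecars and, when present, a per-call GC table.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix path prefix for the output files.
#' @return `prefix` / a `genotype_matrix`.
#' @export
write_genotype_matrix <- function(gm, prefix) {
  wt <- function(d, suffix, rn = FALSE)
    utils::write.table(d, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE,
                       na = "NA")
  wt(gm$calls, "_calls.tsv", rn = TRUE)
  wt(gm$samples, "_samples.tsv")
  wt(gm$snp_info, "_snps.tsv")
  if (!is.null(gm$gc)) wt(gm$gc, "_gc.tsv", rn = TRUE)
  invisible(prefix)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(prefix) {
  calls <- as.matrix(utils::read.delim(paste0(prefix, "_calls.tsv"),
                                       row.names = 1, check.names = FALSE))
  samples <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                               stringsAsFactors = FALSE)
  snp_info <- utils::read.delim(paste0(prefix, "_snps.tsv"),
                                stringsAsFactors = FALSE)
  gc_path <- paste0(prefix, "_gc.tsv")
  gc <- if (file.exists(gc_path))
    as.matrix(utils::read.delim(gc_path, row.names = 1, check.names = FALSE))
  genotype_matrix(calls, samples, snp_info, gc)
}
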