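# Paper-style summary tables and arithmetic consistency checks.

#' Per-LG detection/filtering stage table
#'
#' For each linkage group: sequence length, candidates examined, Stage 1
#' survivors, average distance between surviving SNPs (floor of length /
#' survivors; the published tables truncate, so 350.93 prints as 350) and
#' exonic (Stage 2) survivors, plus a totals row whose average uses the
#' summed columns.
#'
#' @param lg_lengths named vector of LG lengths (bp).
#' @param examined,stage1_kept,stage2_kept named integer vectors of per-LG
#'   counts.
#' @return data frame, one row per LG plus `Total`.
#' @export
stage_table <- function(lg_lengths, examined, stage1_kept, stage2_kept) {
  lgs <- names(lg_lengths)
  g <- function(v, lg) if (lg %in% names(v)) unname(v[lg]) else 0L
  rows <- lapply(lgs, function(lg) {
    k1 <- g(stage1_kept, lg)
    data.frame(lg = lg, sequence_bp = unname(lg_lengths[lg]),
               examined = g(examined, lg), stage1_kept = k1,
               avg_distance_bp = if (k1 > 0)
                 as.integer(lg_lengths[[lg]] %/% k1) else NA_integer_,
               exonic_kept = g(stage2_kept, lg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot1 <- sum(out$stage1_kept)
  out <- rbind(out, data.frame(
    lg = "Total", sequence_bp = sum(out$sequence_bp),
    examined = sum(out$examined), stage1_kept = tot1,
    avg_distance_bp = if (tot1 > 0)
      as.integer(sum(out$sequence_bp) %/% tot1) else NA_integer_,
    exonic_kept = sum(out$exonic_kept)))
  rownames(out) <- NULL
  out
}

CHECK_OPS <- c("sum", "floor_div", "pct_1dp", "ratio_1dp", "ratio_2dp")

#' Recompute published summary arithmetic
#'
#' Each check is a row (`check_id`, `op`, `inputs` as a semicolon-separated
#' number list, `expected`) and is recomputed with the stated operation and
#' rounding: `sum`; `floor_div` (truncating division, as in the per-LG SNP
#' spacing columns); `pct_1dp` (100 a / b, half-up to 1 dp); `ratio_1dp` /
#' `ratio_2dp` (a / b, half-up). Division by zero yields an explicitly
#' undefined (`NA`) result rather than an error.
#'
#' @param checks data frame as above, or path to such a TSV.
#' @return the checks with `computed` and `pass` columns.
#' @export
consistency_checks <- function(checks) {
  if (is.character(checks))
    checks <- utils::read.delim(checks, stringsAsFactors = FALSE,
                                comment.char = "#")
  if (any(!checks$op %in% CHECK_OPS))
    abort("unknown rounding rule: %s",
          paste(setdiff(unique(checks$op), CHECK_OPS), collapse = ", "))
  computed <- vapply(seq_len(nrow(checks)), function(i) {
    x <- as.numeric(strsplit(checks$inputs[i], ";")[[1]])
    op <- checks$op[i]
    if (op == "sum") return(sum(x))
    if (length(x) != 2) abort("check %s needs two inputs", checks$check_id[i])
    if (x[2] == 0) return(NA_real_)
    switch(op,
           floor_div = floor(x[1] / x[2]),
           pct_1dp = round_half_up(100 * x[1] / x[2], 1),
           ratio_1dp = round_half_up(x[1] / x[2], 1),
           ratio_2dp = round_half_up(x[1] / x[2], 2))
  }, numeric(1))
  checks$computed <- computed
  checks$pass <- ifelse(is.na(computed), NA,
                        abs(computed - checks$expected) < 1e-9)
  checks
}

#' Shipped reference checks for the 8K apple array design
#'
#' The published per-LG and total summary values (SNP spacing, exonic
#' fraction, validation and evaluation proportions, array composition)
#' as a [consistency_checks()] table.
#'
#' @return data frame of checks.
#' @export
published_checks <- function() {
  path <- system.file("extdata", "reference_checks.tsv",
                      package = "snparraydesign", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
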