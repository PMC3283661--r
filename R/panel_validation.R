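# Validation-panel selection and GoldenGate-style classification.
#
# A small panel of candidates (evenly spread, region-dense, accession
# specific, candidate-gene, positive-control categories) is selected for a
# GoldenGate-style validation assay, and assay results are classified into
# failed / monomorphic / polymorphic-low-MAF / polymorphic with per
# category proportions.

#' Validation panel specification
#'
#' @param n_even SNPs spread evenly across the genome.
#' @param n_region SNPs targeted to a dense region of interest.
#' @param n_accession_specific SNPs whose minor allele is private to one
#'   accession.
#' @param region list/row with `lg`, `start`, `end` for the dense region
#'   (may be `NULL`).
#' @param end_window bp; an even-spread SNP is targeted to the first and
#'   last `end_window` of each LG.
#' @param spacing_range bp; target range for the even-spread grid spacing.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(n_even = 100, n_region = 20, n_accession_specific = 28,
                       region = NULL, end_window = 200000,
                       spacing_range = c(6e6, 8e6)) {
  if (any(c(n_even, n_region, n_accession_specific) < 0))
    abort("panel counts must be non-negative")
  if (diff(spacing_range) < 0) abort("spacing_range must be ascending")
  structure(list(n_even = n_even, n_region = n_region,
                 n_accession_specific = n_accession_specific, region = region,
                 end_window = end_window, spacing_range = spacing_range),
            class = "panel_spec")
}

#' Select SNPs evenly spread across the genome
#'
#' Grid points are placed per linkage group: one at each end (within
#' `end_window`) and interior points at uniform spacing, with the per-LG
#' counts apportioned by LG length (largest-remainder) so that the total
#' equals `n_even`. The SNP nearest each grid point is selected, never
#' twice. LG ends without any SNP inside the end window are reported as
#' warnings and their grid point dropped.
#'
#' @param snps data frame with `id`, `lg`, `pos`.
#' @param lg_lengths named vector of LG lengths (bp).
#' @param spec a [panel_spec()].
#' @return data frame of selections (`id`, `lg`, `pos`, `grid_pos`,
#'   `kind`), with attribute `warnings` (data frame of dropped ends).
#' @export
select_even_spread <- function(snps, lg_lengths, spec = panel_spec()) {
  lgs <- names(lg_lengths)
  n_lg <- length(lgs)
  # every LG gets its two ends when the budget allows; the remainder is
  # apportioned to interiors by physical length (largest remainder)
  base <- min(2, max(0, spec$n_even %/% n_lg))
  alloc <- rep(base, n_lg)
  remaining <- spec$n_even - sum(alloc)
  if (remaining > 0) {
    quota <- remaining * lg_lengths / sum(lg_lengths)
    extra <- floor(quota)
    rem <- quota - extra
    short <- remaining - sum(extra)
    if (short > 0) {
      bump <- order(-rem, -lg_lengths)[seq_len(short)]
      extra[bump] <- extra[bump] + 1
    }
    alloc <- alloc + extra
  }
  sel <- list(); warns <- list()
  taken <- character(0)
  for (k in seq_along(lgs)) {
    lg <- lgs[k]; len <- lg_lengths[[k]]; c_lg <- alloc[k]
    if (c_lg == 0) next
    d <- snps[snps$lg == lg, , drop = FALSE]
    short_lg <- len <= 2 * spec$end_window
    grid <- if (short_lg || c_lg == 1) {
      data.frame(grid_pos = 1, kind = "end")
    } else {
      n_int <- max(0, c_lg - 2)
      rbind(data.frame(grid_pos = 1, kind = "end"),
            if (n_int > 0)
              data.frame(grid_pos = round(len * seq_len(n_int) / (n_int + 1)),
                         kind = "interior"),
            data.frame(grid_pos = len, kind = "end"))
    }
    for (r in seq_len(nrow(grid))) {
      gp <- grid$grid_pos[r]
      pool <- d[!d$id %in% taken, , drop = FALSE]
      if (grid$kind[r] == "end") {
        lim <- if (gp == 1) pool$pos <= spec$end_window
               else pool$pos > len - spec$end_window
        pool <- pool[lim, , drop = FALSE]
      }
      if (!nrow(pool)) {
        warns[[length(warns) + 1]] <-
          data.frame(lg = lg, grid_pos = gp, kind = grid$kind[r],
                     note = "no_snp_available", stringsAsFactors = FALSE)
        next
      }
      pick <- pool[order(abs(pool$pos - gp), pool$pos), , drop = FALSE][1, ]
      taken <- c(taken, pick$id)
      sel[[length(sel) + 1]] <-
        data.frame(id = pick$id, lg = lg, pos = pick$pos, grid_pos = gp,
                   kind = grid$kind[r], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(sel)) do.call(rbind, sel) else
    data.frame(id = character(0), lg = character(0), pos = integer(0),
               grid_pos = numeric(0), kind = character(0))
  attr(out, "warnings") <- if (length(warns)) do.call(rbind, warns) else
    data.frame(lg = character(0), grid_pos = numeric(0), kind = character(0),
               note = character(0))
  out
}

#' Select SNPs densely and evenly over a target region
#'
#' Places a grid of `n` points over the region and selects `n` SNPs
#' maximizing evenness: with at most `exact_limit` candidates, the subset
#' minimizing the summed squared grid-point-to-SNP distance (both sorted;
#' in one dimension the order-preserving assignment is optimal) is found
#' exhaustively, otherwise each grid point greedily takes its nearest
#' unchosen SNP. With fewer than `n` SNPs in the region all are selected
#' and a `short` attribute set.
#'
#' @param snps data frame with `id`, `lg`, `pos`.
#' @param region list/row with `lg`, `start`, `end`.
#' @param n number of SNPs requested.
#' @param exact_limit candidate-count bound for the exhaustive search.
#' @return data frame of selections with attribute `short` (logical).
#' @export
select_region_dense <- function(snps, region, n, exact_limit = 12) {
  if (region$end < region$start) abort("empty region")
  d <- snps[snps$lg == region$lg & snps$pos >= region$start &
              snps$pos <= region$end, , drop = FALSE]
  d <- d[order(d$pos), , drop = FALSE]
  if (nrow(d) <= n) {
    out <- d[, c("id", "lg", "pos"), drop = FALSE]
    attr(out, "short") <- nrow(d) < n
    rownames(out) <- NULL
    return(out)
  }
  grid <- if (n == 1) (region$start + region$end) / 2
          else seq(region$start, region$end, length.out = n)
  taken <- if (nrow(d) <= exact_limit) {
    combs <- utils::combn(nrow(d), n)
    cost <- apply(combs, 2, function(idx) sum((d$pos[idx] - grid)^2))
    combs[, which.min(cost)]
  } else {
    sel <- integer(0)
    for (gp in grid) {
      pool <- setdiff(seq_len(nrow(d)), sel)
      sel <- c(sel, pool[order(abs(d$pos[pool] - gp), d$pos[pool])][1])
    }
    sel
  }
  out <- d[sort(taken), c("id", "lg", "pos"), drop = FALSE]
  attr(out, "short") <- FALSE
  rownames(out) <- NULL
  out
}

#' Find accession-specific SNPs
#'
#' A SNP is accession-specific when its minor allele (the allele with the
#' smaller summed read count across accessions; ties broken towards the
#' alternate allele) is supported by at least one read in exactly one
#' accession.
#'
#' @param ss a [snp_set()].
#' @return the accession-specific subset of `ss$snps`, with a
#'   `carrier` column naming the accession.
#' @export
find_accession_specific <- function(ss) {
  tot_ref <- rowSums(ss$reads_ref); tot_alt <- rowSums(ss$reads_alt)
  minor_is_ref <- tot_ref < tot_alt
  minor_reads <- ifelse(minor_is_ref, 1, 0) * ss$reads_ref +
    ifelse(minor_is_ref, 0, 1) * ss$reads_alt
  carriers <- rowSums(minor_reads > 0)
  keep <- which(carriers == 1)
  out <- ss$snps[keep, , drop = FALSE]
  out$carrier <- vapply(keep, function(i)
    colnames(minor_reads)[which(minor_reads[i, ] > 0)][1], character(1))
  rownames(out) <- NULL
  out
}

#' Allele-count minor allele frequency of one SNP's calls
#'
#' `(2 * minor homozygotes + heterozygotes) / (2 * called)`, with the minor
#' allele chosen so the value is at most 0.5.
#'
#' @param calls character vector of `"AA"`/`"AB"`/`"BB"`/`NA` calls.
#' @return MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) abort("MAF undefined: all calls missing")
  nb <- 2 * sum(calls == "BB") + sum(calls == "AB")
  p <- nb / (2 * length(calls))
  min(p, 1 - p)
}

#' Classify GoldenGate-style assay results
#'
#' Samples failing QC (call rate or GC score at or below the thresholds)
#' are excluded first. Each SNP is then classified over the passing
#' samples: `failed` when its call rate is below `snp_fail_call_rate` (or
#' it has no calls); `monomorphic` when MAF is below `maf_low` and the
#' heterozygote (A/B) frequency is below `ab_freq_min`; `poly_low_maf`
#' when polymorphic with MAF below `maf_low`; `polymorphic` otherwise.
#'
#' @param gm a [genotype_matrix()] with per-sample `p50gc` scores.
#' @param panel optional data frame with `id` and `category` (a SNP may
#'   appear in several categories); drives the per-category report.
#' @param sample_call_rate_min,sample_gc_min sample QC thresholds
#'   (strictly-greater to pass).
#' @param snp_fail_call_rate per-SNP call-rate threshold below which the
#'   assay is called failed.
#' @param maf_low,ab_freq_min monomorphic/low-MAF thresholds (strict `<`).
#' @return list with `samples` (id, pass), `classes` (per-SNP class, MAF,
#'   het frequency, call rate) and `table` (per-category class proportions,
#'   2 dp, plus a Total row).
#' @export
classify_goldengate <- function(gm, panel = NULL, sample_call_rate_min = 0.8,
                                sample_gc_min = 0.5, snp_fail_call_rate = 0.5,
                                maf_low = 0.05, ab_freq_min = 0.1) {
  if (!nrow(gm$calls) || !ncol(gm$calls)) abort("empty genotype matrix")
  pass <- gm$samples$call_rate > sample_call_rate_min &
    !is.na(gm$samples$p50gc) & gm$samples$p50gc > sample_gc_min
  if (!any(pass)) abort("no samples pass QC")
  calls <- gm$calls[pass, , drop = FALSE]
  n_pass <- nrow(calls)
  cls <- vapply(seq_len(ncol(calls)), function(j) {
    cj <- calls[, j]
    called <- sum(!is.na(cj))
    if (called == 0 || called / n_pass < snp_fail_call_rate) return("failed")
    maf <- compute_maf(cj)
    hetf <- sum(cj == "AB", na.rm = TRUE) / called
    if (maf < maf_low && hetf < ab_freq_min) "monomorphic"
    else if (maf < maf_low) "poly_low_maf"
    else "polymorphic"
  }, character(1))
  maf <- rep(NA_real_, ncol(calls)); hetf <- maf
  ok <- cls != "failed"
  maf[ok] <- vapply(which(ok), function(j) compute_maf(calls[, j]), numeric(1))
  hetf[ok] <- vapply(which(ok), function(j) {
    cj <- calls[, j]; sum(cj == "AB", na.rm = TRUE) / sum(!is.na(cj))
  }, numeric(1))
  classes <- data.frame(id = colnames(calls), class = cls, maf = maf,
                        het_freq = hetf,
                        call_rate = colMeans(!is.na(calls)),
                        stringsAsFactors = FALSE)
  lvls <- c("failed", "monomorphic", "poly_low_maf", "polymorphic")
  prop_row <- function(ids, label) {
    cc <- classes$class[classes$id %in% ids]
    props <- vapply(lvls, function(l) round_half_up(mean(cc == l), 2), numeric(1))
    data.frame(category = label, total = length(cc), t(props),
               stringsAsFactors = FALSE)
  }
  tab <- if (!is.null(panel)) {
    do.call(rbind, lapply(split(panel$id, panel$category),
                          function(ids) prop_row(ids, NA)))
  }
  if (!is.null(tab)) tab$category <- names(split(panel$id, panel$category))
  tab <- rbind(tab, prop_row(classes$id, "Total"))
  rownames(tab) <- NULL
  list(samples = data.frame(id = gm$samples$id, pass = pass,
                            stringsAsFactors = FALSE),
       classes = classes, table = tab)
}
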