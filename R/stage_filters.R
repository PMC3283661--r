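# Stage 1 and Stage 2 candidate filtering.
#
# Stage 1 applies eight independent rejection rules to every candidate
# call; a call is kept only if it violates none. Stage 2 keeps only
# candidates inside the merged exon space (gene-model exons union cDNA
# alignment blocks). Rules are evaluated without short-circuiting so the
# per-rule tallies are complete.

#' Stage 1 filtering parameters
#'
#' Thresholds for the eight rejection rules. Comparisons follow the rule
#' wording: "less than", "more than" and "greater than" are strict, while
#' "within" and "at least" are inclusive.
#'
#' @param end_margin bp; rule 1 rejects calls in the first or last
#'   `end_margin` bases of a linkage group.
#' @param ambiguity_window bp; rule 2 rejects calls with a non-ACGT
#'   reference base at the call or within this many bases of it.
#' @param adjacent_window bp; rule 3 rejects calls with another candidate
#'   within this distance.
#' @param cn_flank bp of flank on each side over which rule 4 averages the
#'   copy-number track (positions absent from the track count as copy 1).
#' @param cn_max rule 4 rejects when the average flank copy number is
#'   strictly greater than this.
#' @param qual_min rule 5 rejects when the best phred quality observed for
#'   a supported allele is strictly less than this.
#' @param min_reads_per_allele,accession_fraction rule 6: an accession
#'   fails the support test when any allele it carries has fewer than
#'   `min_reads_per_allele` reads; the rule fires when at least
#'   `accession_fraction` of accessions with any reads fail.
#' @param depth_sd_mult rule 7 rejects when either allele's summed read
#'   count across accessions exceeds the mean total depth of all candidates
#'   plus this many (population) standard deviations.
#' @param transversion_filter logical; rule 8 rejects A/T and C/G
#'   transversions (they need two Infinium II bead types). Set `FALSE` to
#'   disable.
#' @return a list of class `stage1_params`.
#' @export
stage1_params <- function(end_margin = 60, ambiguity_window = 60,
                          adjacent_window = 50, cn_flank = 60, cn_max = 2,
                          qual_min = 20, min_reads_per_allele = 2,
                          accession_fraction = 0.5, depth_sd_mult = 3,
                          transversion_filter = TRUE) {
  p <- list(end_margin = end_margin, ambiguity_window = ambiguity_window,
            adjacent_window = adjacent_window, cn_flank = cn_flank,
            cn_max = cn_max, qual_min = qual_min,
            min_reads_per_allele = min_reads_per_allele,
            accession_fraction = accession_fraction,
            depth_sd_mult = depth_sd_mult,
            transversion_filter = isTRUE(transversion_filter))
  num <- unlist(p[1:9])
  if (any(num <= 0)) abort("all stage-1 thresholds must be positive")
  if (accession_fraction > 1) abort("accession_fraction must be in (0, 1]")
  structure(p, class = "stage1_params")
}

#' Mean and SD of total allele depth across candidates
#'
#' Total depth of a candidate is the sum of reference and alternate reads
#' over all accessions. The SD is the population SD (denominator n), which
#' is what the depth-outlier rule compares against.
#'
#' @param ss a [snp_set()] with at least two candidates.
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
mean_sd_allele_depth <- function(ss) {
  if (n_snps(ss) < 2) abort("need at least 2 candidates for depth statistics")
  tot <- rowSums(ss$reads_ref) + rowSums(ss$reads_alt)
  c(mean = mean(tot), sd = pop_sd(tot))
}

# logical n x 8 matrix of rule violations for every candidate
stage1_rule_matrix <- function(ss, genome, copy_number = NULL,
                               params = stage1_params(), depth_stats = NULL) {
  s <- ss$snps
  lens <- lg_lengths(genome)
  if (any(!s$lg %in% names(lens)))
    abort("candidate LG absent from genome: %s",
          paste(setdiff(unique(s$lg), names(lens)), collapse = ", "))
  len <- lens[s$lg]
  if (any(s$pos < 1 | s$pos > len)) abort("candidate position outside genome")
  n <- n_snps(ss)
  M <- matrix(FALSE, n, 8, dimnames = list(s$id, paste0("rule", 1:8)))

  # rule 1: chromosome-end margin
  M[, 1] <- s$pos <= params$end_margin | s$pos > len - params$end_margin

  # rule 2: ambiguous reference base at or near the call
  amb <- ambiguity_positions(genome)
  for (lg in unique(s$lg)) {
    a <- amb[[lg]]
    if (!length(a)) next
    i <- which(s$lg == lg)
    a <- sort(a)
    # nearest ambiguous base to each candidate position
    k <- findInterval(s$pos[i], a)
    d_lo <- ifelse(k >= 1, s$pos[i] - a[pmax(k, 1)], Inf)
    d_hi <- ifelse(k < length(a), a[pmin(k + 1, length(a))] - s$pos[i], Inf)
    M[i, 2] <- pmin(d_lo, d_hi) <= params$ambiguity_window
  }

  # rule 3: another candidate within the adjacency window
  for (lg in unique(s$lg)) {
    i <- which(s$lg == lg)
    if (length(i) < 2) next
    o <- i[order(s$pos[i])]
    p <- s$pos[o]
    gap_prev <- c(Inf, diff(p)); gap_next <- c(diff(p), Inf)
    M[o, 3] <- pmin(gap_prev, gap_next) <= params$adjacent_window
  }

  # rule 4: average copy number of the flanking region
  if (!is.null(copy_number) && nrow(copy_number)) {
    fs <- pmax(1L, s$pos - params$cn_flank)
    fe <- pmin(as.integer(len), s$pos + params$cn_flank)
    flank_len <- fe - fs + 1
    wsum <- numeric(n); covered <- numeric(n)
    for (lg in unique(s$lg)) {
      segs <- copy_number[copy_number$lg == lg, , drop = FALSE]
      if (!nrow(segs)) next
      i <- which(s$lg == lg)
      for (r in seq_len(nrow(segs))) {
        ov <- pmax(0, pmin(fe[i], segs$end[r]) - pmax(fs[i], segs$start[r]) + 1)
        wsum[i] <- wsum[i] + ov * segs$cn[r]
        covered[i] <- covered[i] + ov
      }
    }
    avg_cn <- (wsum + (flank_len - covered)) / flank_len
    M[, 4] <- avg_cn > params$cn_max
  }

  # rule 5: best observed quality of a supported allele below threshold
  has_ref <- rowSums(ss$reads_ref) > 0
  has_alt <- rowSums(ss$reads_alt) > 0
  best_q <- function(q) do.call(pmax, c(asplit(q, 2), list(na.rm = TRUE)))
  bq_ref <- best_q(ss$qual_ref); bq_alt <- best_q(ss$qual_alt)
  M[, 5] <- (has_ref & !is.na(bq_ref) & bq_ref < params$qual_min) |
            (has_alt & !is.na(bq_alt) & bq_alt < params$qual_min)

  # rule 6: insufficient per-accession read support
  fail_acc <- (ss$reads_ref > 0 & ss$reads_ref < params$min_reads_per_allele) |
              (ss$reads_alt > 0 & ss$reads_alt < params$min_reads_per_allele)
  with_reads <- (ss$reads_ref + ss$reads_alt) > 0
  n_with <- rowSums(with_reads)
  M[, 6] <- n_with > 0 &
    rowSums(fail_acc) / pmax(n_with, 1) >= params$accession_fraction

  # rule 7: per-allele summed depth above mean + k * sd of total depth
  if (is.null(depth_stats)) depth_stats <- mean_sd_allele_depth(ss)
  thr <- depth_stats[["mean"]] + params$depth_sd_mult * depth_stats[["sd"]]
  M[, 7] <- rowSums(ss$reads_ref) > thr | rowSums(ss$reads_alt) > thr

  # rule 8: A/T or C/G transversion
  if (params$transversion_filter) {
    pair <- paste0(pmin(s$ref, s$alt), pmax(s$ref, s$alt))
    M[, 8] <- pair %in% c("AT", "CG")
  }
  M
}

#' Violated Stage 1 rules for a single candidate
#'
#' Evaluates all eight rules for the candidate in row `i` of `ss`, in the
#' context of the full candidate set (the adjacency and depth-outlier rules
#' depend on the whole set).
#'
#' @param ss a [snp_set()].
#' @param i row index or SNP id of the candidate.
#' @param genome assembly `DNAStringSet`.
#' @param copy_number copy-number track data frame, or `NULL` for none.
#' @param params a [stage1_params()].
#' @param depth_stats optional precomputed [mean_sd_allele_depth()] result.
#' @return integer vector of violated rule numbers (possibly empty).
#' @export
rule_flags <- function(ss, i, genome, copy_number = NULL,
                       params = stage1_params(), depth_stats = NULL) {
  if (is.character(i)) i <- match(i, ss$snps$id)
  M <- stage1_rule_matrix(ss, genome, copy_number, params, depth_stats)
  which(M[i, ])
}

#' Apply Stage 1 filtering
#'
#' Evaluates all eight rejection rules for every candidate and keeps the
#' candidates violating none. Rules are evaluated independently, so the
#' per-rule tally counts every violation even when a candidate breaks
#' several rules.
#'
#' @inheritParams rule_flags
#' @param ss a [snp_set()] of candidates.
#' @return list with elements `kept` (a `snp_set`), `outcomes` (data frame
#'   `snp_id`, `kept`, `violated_rules` as a comma string), and `tally`
#'   (named integer vector of per-rule violation counts).
#' @export
filter_stage1 <- function(ss, genome, copy_number = NULL,
                          params = stage1_params()) {
  if (n_snps(ss) == 0) {
    return(list(kept = ss,
                outcomes = data.frame(snp_id = character(0), kept = logical(0),
                                      violated_rules = character(0)),
                tally = stats::setNames(integer(8), paste0("rule", 1:8))))
  }
  M <- stage1_rule_matrix(ss, genome, copy_number, params)
  nviol <- rowSums(M)
  rules_str <- vapply(seq_len(nrow(M)), function(i)
    paste(which(M[i, ]), collapse = ","), character(1))
  list(kept = ss[nviol == 0],
       outcomes = data.frame(snp_id = ss$snps$id, kept = nviol == 0,
                             violated_rules = rules_str,
                             stringsAsFactors = FALSE),
       tally = colSums(M))
}

#' Build the merged exon space
#'
#' Takes gene-model exons and cDNA alignment blocks (each a data frame with
#' `lg`, `start`, `end`, 1-based inclusive) and merges them into a sorted,
#' disjoint interval set per linkage group. Abutting intervals (gap 0) are
#' merged.
#'
#' @param gene_models,cdna_blocks interval data frames (either may be `NULL`).
#' @param lg_lengths optional named vector; when given, intervals must lie
#'   within the stated bounds.
#' @return an object of class `exon_space`.
#' @export
build_exon_space <- function(gene_models = NULL, cdna_blocks = NULL,
                             lg_lengths = NULL) {
  iv <- rbind(gene_models[c("lg", "start", "end")],
              cdna_blocks[c("lg", "start", "end")])
  if (is.null(iv) || !nrow(iv)) {
    return(structure(list(intervals = data.frame(lg = character(0),
                                                 start = integer(0),
                                                 end = integer(0))),
                     class = "exon_space"))
  }
  if (any(iv$start > iv$end)) abort("interval with start > end")
  if (!is.null(lg_lengths)) {
    if (any(!iv$lg %in% names(lg_lengths)))
      abort("interval LG absent from assembly")
    if (any(iv$start < 1 | iv$end > lg_lengths[iv$lg]))
      abort("interval outside genome bounds")
  }
  out <- lapply(split(iv, iv$lg), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(lg = d$lg[1], start = IRanges::start(r), end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  ints <- do.call(rbind, out)
  ints <- ints[order(ints$lg, ints$start), ]
  rownames(ints) <- NULL
  structure(list(intervals = ints), class = "exon_space")
}

#' @export
print.exon_space <- function(x, ...) {
  cat(sprintf("<exon_space> %d merged intervals on %d LG(s), %d bp\n",
              nrow(x$intervals), length(unique(x$intervals$lg)),
              sum(x$intervals$end - x$intervals$start + 1)))
  invisible(x)
}

#' Exon-space membership of positions
#'
#' @param space an [build_exon_space()] result.
#' @param lg,pos parallel vectors of linkage group and position (1-based).
#'   Interval bounds are inclusive on both ends.
#' @return logical vector.
#' @export
in_exon_space <- function(space, lg, pos) {
  out <- logical(length(pos))
  for (g in unique(lg)) {
    iv <- space$intervals[space$intervals$lg == g, , drop = FALSE]
    i <- which(lg == g)
    if (!nrow(iv)) next
    k <- findInterval(pos[i], iv$start)
    out[i] <- k >= 1 & pos[i] <= iv$end[pmax(k, 1)]
  }
  out
}

#' Fraction of the genome covered by the exon space
#' @param space an `exon_space`.
#' @param lg_lengths named vector of LG lengths.
#' @return scalar coverage fraction.
#' @export
exon_coverage <- function(space, lg_lengths) {
  sum(space$intervals$end - space$intervals$start + 1) / sum(lg_lengths)
}

#' Write / read an exon space as BED
#' @param space an `exon_space`.
#' @param path BED path.
#' @return `path` / an `exon_space`.
#' @export
write_exon_space <- function(space, path) write_bed(space$intervals, path)

#' @rdname write_exon_space
#' @export
read_exon_space <- function(path) {
  build_exon_space(cdna_blocks = read_cdna_blocks(path))
}

#' Apply Stage 2 filtering (exonic restriction)
#'
#' Keeps the candidates whose position lies inside the merged exon space,
#' preserving input order.
#'
#' @param ss a [snp_set()] (normally the Stage 1 survivors).
#' @param space an [build_exon_space()] result.
#' @return the exonic subset of `ss`.
#' @export
filter_stage2 <- function(ss, space) {
  ss[in_exon_space(space, ss$snps$lg, ss$snps$pos)]
}
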