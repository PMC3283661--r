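# Synthetic-data generation with a full ground-truth ledger.
#
# The generator emulates every pipeline input: a toy multi-LG genome with
# planted ambiguity sites and copy-number segments, founder accessions
# resequenced at low Poisson coverage with base-calling error, genetic-map
# anchors, array-style genotype runs through a pedigree with crossovers,
# and lightweight trio/cluster draws for phasing. Candidates are clean by
# construction (placed away from LG ends, ambiguity, high-copy segments
# and each other, with transition alleles and good qualities); a chosen
# subset receives exactly one injected filter-rule violation each,
# recorded in the truth ledger. All randomness flows from the config seed
# through R's RNG, so outputs are byte-identical across runs.

#' Simulation configuration
#'
#' Defaults mirror the detection-panel conditions the pipeline was built
#' for: 27 accessions, one candidate SNP per 288 bp, 29% exon coverage,
#' ~5x read depth and a genetic map of 2.24 cM/Mb (1 cM per ~446 kb), on
#' a 17-LG toy genome.
#'
#' @param n_lg number of linkage groups.
#' @param lg_length bp per linkage group.
#' @param n_founders accessions in the detection panel.
#' @param snp_density candidate SNPs per bp.
#' @param exon_fraction fraction of the genome covered by exon space.
#' @param depth_lambda mean reads per accession per SNP (Poisson).
#' @param error_rate per-base read error rate.
#' @param cm_per_mb genetic-map density.
#' @param seed integer seed; every derived stage offsets it deterministically.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lg = 17, lg_length = 1e6, n_founders = 27,
                       snp_density = 1 / 288, exon_fraction = 0.29,
                       depth_lambda = 5, error_rate = 0.01,
                       cm_per_mb = 2.24, seed = 1) {
  p <- list(n_lg = n_lg, lg_length = as.integer(lg_length),
            n_founders = n_founders, snp_density = snp_density,
            exon_fraction = exon_fraction, depth_lambda = depth_lambda,
            error_rate = error_rate, cm_per_mb = cm_per_mb,
            seed = as.integer(seed))
  if (any(unlist(p[c(1:6, 8)]) <= 0)) abort("sim_config values must be positive")
  if (exon_fraction >= 1) abort("exon_fraction must be in (0, 1)")
  structure(p, class = "sim_config")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_AT_CG <- c(A = "T", T = "A", C = "G", G = "C")

#' Simulate a toy genome with annotation tracks
#'
#' Generates random ACGT linkage groups with planted ambiguity sites (for
#' the reference-ambiguity rule), non-overlapping exon intervals covering
#' about `exon_fraction` of the genome (split into gene-model and cDNA
#' sets whose union is the truth exon space), a mostly copy-1 copy-number
#' track with occasional high-copy segments, and genetic-map anchors:
#' primary (GDsnp) anchors at ~1 cM spacing with cM = pos x cm_per_mb,
#' and physically placed secondary (RosCOS) anchors between them.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome` with elements `genome`
#'   (`DNAStringSet`), `gene_models`, `cdna`, `cn`, `anchors`,
#'   `ambiguity`, `exon_space`, `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  len <- config$lg_length
  lgs <- sprintf("LG%02d", seq_len(config$n_lg))
  seqs <- character(config$n_lg)
  amb_list <- list(); exon_list <- list(); cn_list <- list(); anch_list <- list()
  for (i in seq_along(lgs)) {
    lg <- lgs[i]
    chars <- sample(ACGT, len, replace = TRUE)
    # planted ambiguity sites, well separated and away from the ends
    n_amb <- max(3L, len %/% 100000L)
    grid <- seq(500L, len - 500L, by = 500L)
    amb <- sort(sample(grid, n_amb))
    chars[amb] <- sample(c("N", "R", "Y"), n_amb, replace = TRUE)
    seqs[i] <- paste(chars, collapse = "")
    amb_list[[lg]] <- data.frame(lg = lg, pos = amb, stringsAsFactors = FALSE)
    # non-overlapping exon intervals; gap mean chosen so coverage ~ target
    elen_mean <- 1000
    gap_mean <- elen_mean * (1 / config$exon_fraction - 1)
    n_est <- ceiling(len / (elen_mean + gap_mean) * 1.7)
    elen <- round(stats::runif(n_est, 600, 1400))
    gaps <- 2 + round(stats::rexp(n_est, 1 / gap_mean))
    starts <- cumsum(gaps + c(0, elen[-n_est]))
    ends <- starts + elen - 1
    keep <- ends <= len - 200 & starts >= 1
    exon_list[[lg]] <- data.frame(lg = lg, start = as.integer(starts[keep]),
                                  end = as.integer(ends[keep]),
                                  stringsAsFactors = FALSE)
    # copy-number segments: two high-copy, one intermediate, on clear ground
    seg_grid <- seq(2000L, max(2000L, len - 3000L), by = 2500L)
    clear <- vapply(seg_grid, function(s)
      all(abs(amb - s) > 1500) && all(abs(amb - (s + 1200)) > 1500), logical(1))
    n_seg <- min(3L, sum(clear))
    seg_start <- sort(sample(seg_grid[clear], n_seg))
    cn_val <- round(c(stats::runif(2, 2.5, 5), stats::runif(1, 1.2, 1.8)), 3)
    cn_list[[lg]] <- if (n_seg > 0)
      data.frame(lg = lg, start = seg_start, end = seg_start + 999L,
                 cn = cn_val[seq_len(n_seg)], stringsAsFactors = FALSE)
    # map anchors
    cm_bp <- round(1e6 / config$cm_per_mb)
    start0 <- min(round(cm_bp / 2), floor(len * 0.4))
    prim_pos <- seq(start0, len, by = cm_bp)
    prim_pos <- prim_pos[prim_pos <= len - 1000]
    if (!length(prim_pos)) prim_pos <- round(len / 2)
    prim <- data.frame(marker_id = sprintf("GD_%s_%02d", lg, seq_along(prim_pos)),
                       kind = "GDsnp", lg = lg, pos = as.integer(prim_pos),
                       cM = prim_pos * config$cm_per_mb / 1e6,
                       stringsAsFactors = FALSE)
    sec_pos <- unique(c(round(stats::runif(1, 2e4, 8e4)),
                        round(prim_pos[-1] - cm_bp / 2),
                        len - round(stats::runif(1, 2e4, 8e4))))
    sec <- data.frame(marker_id = sprintf("ROS_%s_%02d", lg, seq_along(sec_pos)),
                      kind = "RosCOS", lg = lg, pos = as.integer(sec_pos),
                      cM = NA_real_, stringsAsFactors = FALSE)
    anch_list[[lg]] <- rbind(prim, sec)
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, lgs))
  exons <- do.call(rbind, exon_list)
  rownames(exons) <- NULL
  # split exons into gene models and cDNA blocks; union is the truth space
  to_gm <- stats::runif(nrow(exons)) < 0.8
  gene_models <- exons[to_gm, , drop = FALSE]
  gene_models$gene_id <- sprintf("gene%05d", seq_len(nrow(gene_models)))
  cdna <- exons[!to_gm, , drop = FALSE]
  dup <- gene_models[stats::runif(nrow(gene_models)) < 0.2,
                     c("lg", "start", "end"), drop = FALSE]
  cdna <- rbind(cdna[c("lg", "start", "end")], dup)
  structure(list(genome = genome, gene_models = gene_models, cdna = cdna,
                 cn = do.call(rbind, cn_list),
                 anchors = do.call(rbind, anch_list),
                 ambiguity = do.call(rbind, amb_list),
                 exon_space = build_exon_space(exons, NULL, lg_lengths(genome)),
                 config = config),
            class = "sim_genome")
}

# drop positions within `radius` of any site in `sites`
away_from <- function(pos, sites, radius) {
  if (!length(sites)) return(rep(TRUE, length(pos)))
  sites <- sort(sites)
  k <- findInterval(pos, sites)
  d_lo <- ifelse(k >= 1, pos - sites[pmax(k, 1)], Inf)
  d_hi <- ifelse(k < length(sites), sites[pmin(k + 1, length(sites))] - pos, Inf)
  pmin(d_lo, d_hi) > radius
}

#' Simulate resequencing of the detection panel and candidate SNP calls
#'
#' Draws candidate SNPs along the genome (transition alleles, founder
#' allele frequencies uniform on the binnable MAF range, diploid genotypes
#' per accession, Poisson read depth allocated binomially with read
#' error, and good allele qualities), then injects exactly one Stage 1
#' rule violation into a chosen fraction of SNPs, recording every
#' injection in the truth ledger. Non-injected SNPs are guaranteed
#' violation-free: read support is topped up to the two-read minimum and
#' depth outliers trimmed back below the rejection threshold, so the
#' ledger is the exact truth set for filter verification.
#'
#' @param config a [sim_config()].
#' @param sim a [simulate_genome()] result.
#' @param violation_fraction fraction of SNPs receiving one injected
#'   violation.
#' @param accession_specific_fraction fraction of SNPs made private to a
#'   single accession.
#' @return list with `snps` (a [snp_set()]) and `truth` (genotype matrix,
#'   allele frequencies, `violations` data frame of snp_id/rule,
#'   accession-specific ids).
#' @export
simulate_accessions_and_calls <- function(config, sim,
                                          violation_fraction = 0.02,
                                          accession_specific_fraction = 0.02) {
  set.seed(config$seed + 1000L)
  lens <- lg_lengths(sim$genome)
  acc <- sprintf("acc%02d", seq_len(config$n_founders))
  p1 <- stage1_params()
  min_gap <- p1$adjacent_window * 2 + 1
  gap_mean <- 1 / config$snp_density

  cn_track <- sim$cn
  if (is.null(cn_track))
    cn_track <- data.frame(lg = character(0), start = integer(0),
                           end = integer(0), cn = numeric(0))
  pos_list <- list()
  for (lg in names(lens)) {
    len <- lens[[lg]]
    amb <- sim$ambiguity$pos[sim$ambiguity$lg == lg]
    cn <- cn_track[cn_track$lg == lg, ]
    n_est <- ceiling(len / gap_mean * 1.6)
    gaps <- min_gap + stats::rgeom(n_est, 1 / max(1, gap_mean - min_gap))
    pos <- 150L + cumsum(gaps)
    pos <- pos[pos <= len - 150L]
    ok <- away_from(pos, amb, p1$ambiguity_window + min_gap + 10)
    cn_sites <- unlist(Map(seq, cn$start, cn$end, by = 50))
    ok <- ok & away_from(pos, cn_sites, p1$cn_flank + min_gap + 10)
    pos_list[[lg]] <- as.integer(pos[ok])
  }
  snps <- data.frame(lg = rep(names(pos_list), lengths(pos_list)),
                     pos = unlist(pos_list), stringsAsFactors = FALSE)
  n <- nrow(snps)
  nacc <- length(acc)
  seq_chars <- as.character(sim$genome)
  snps$ref <- NA_character_
  for (lg in unique(snps$lg)) {
    i <- which(snps$lg == lg)
    snps$ref[i] <- substring(seq_chars[[lg]], snps$pos[i], snps$pos[i])
  }
  snps$alt <- unname(TRANSITION[snps$ref])

  p_alt <- stats::runif(n, 0.01, 0.5)
  G <- matrix(stats::rbinom(n * nacc, 2, p_alt), n, nacc,
              dimnames = list(NULL, acc))
  mono <- rowSums(G) == 0 | rowSums(G) == 2 * nacc
  for (i in which(mono)) G[i, sample.int(nacc, 1)] <- 1L

  as_ids <- sort(sample.int(n, round(accession_specific_fraction * n)))
  for (i in as_ids) { G[i, ] <- 0L; G[i, sample.int(nacc, 1)] <- 1L }

  D <- matrix(stats::rpois(n * nacc, config$depth_lambda), n, nacc)
  cap <- ceiling(3 * config$depth_lambda)
  D[D > cap] <- cap
  e <- config$error_rate
  pa <- (G / 2) * (1 - e) + (1 - G / 2) * e
  RA <- matrix(stats::rbinom(n * nacc, as.vector(D), as.vector(pa)), n, nacc,
               dimnames = list(NULL, acc))
  RR <- D - RA
  dimnames(RR) <- dimnames(RA)

  # violation injection ----------------------------------------------------
  eligible <- setdiff(seq_len(n), as_ids)
  m <- round(violation_fraction * n)
  chosen <- sort(sample(eligible, min(m, length(eligible))))
  rule_of <- rep(1:8, length.out = length(chosen))
  viol <- data.frame(idx = chosen, rule = rule_of)

  # relocation slots for positional rules
  slot_r1 <- do.call(rbind, lapply(names(lens), function(lg) {
    len <- lens[[lg]]
    data.frame(lg = lg, pos = as.integer(c(5, 56, len - 4, len - 55)))
  }))
  slot_r2 <- do.call(rbind, lapply(seq_len(nrow(sim$ambiguity)), function(r) {
    data.frame(lg = sim$ambiguity$lg[r],
               pos = as.integer(sim$ambiguity$pos[r] + c(-60, 60)))
  }))
  high_cn <- cn_track[cn_track$cn > p1$cn_max, ]
  slot_r4 <- do.call(rbind, lapply(seq_len(nrow(high_cn)), function(r) {
    p <- seq(high_cn$start[r] + p1$cn_flank, high_cn$end[r] - p1$cn_flank,
             by = min_gap + 5)
    data.frame(lg = high_cn$lg[r], pos = as.integer(p))
  }))
  take_slot <- function(slots, k) {
    if (is.null(slots) || !nrow(slots))
      return(data.frame(lg = character(0), pos = integer(0)))
    if (k > nrow(slots)) k <- nrow(slots)
    slots[sample.int(nrow(slots), k), , drop = FALSE]
  }
  relocate <- function(rule, slots) {
    idx <- viol$idx[viol$rule == rule]
    s <- take_slot(slots, length(idx))
    idx <- idx[seq_len(nrow(s))]
    snps$lg[idx] <<- s$lg
    snps$pos[idx] <<- s$pos
    dropped <- setdiff(viol$idx[viol$rule == rule], idx)
    viol <<- viol[!viol$idx %in% dropped, ]
    idx
  }
  relocate(1, slot_r1)
  relocate(2, slot_r2)
  relocate(4, slot_r4)
  # refresh alleles at relocated positions (skip planted ambiguity bases)
  moved <- viol$idx[viol$rule %in% c(1, 2, 4)]
  for (i in moved) {
    b <- substring(seq_chars[[snps$lg[i]]], snps$pos[i], snps$pos[i])
    if (b %in% ACGT) { snps$ref[i] <- b; snps$alt[i] <- unname(TRANSITION[b]) }
  }
  # rule 3: give each chosen SNP a partner 30 bp away; both are ledgered
  r3 <- viol$idx[viol$rule == 3]
  if (length(r3)) {
    newpos <- snps$pos[r3] + 30L
    pref <- vapply(seq_along(r3), function(k)
      substring(seq_chars[[snps$lg[r3[k]]]], newpos[k], newpos[k]), character(1))
    add <- data.frame(lg = snps$lg[r3], pos = newpos, ref = pref,
                      alt = unname(TRANSITION[pref]), stringsAsFactors = FALSE)
    snps <- rbind(snps[c("lg", "pos", "ref", "alt")], add)
    G <- rbind(G, G[r3, , drop = FALSE])
    RA <- rbind(RA, RA[r3, , drop = FALSE])
    RR <- rbind(RR, RR[r3, , drop = FALSE])
    viol <- rbind(viol, data.frame(idx = n + seq_along(r3), rule = 3L))
    as_ids <- as_ids  # unchanged; indexes below old n
    n <- nrow(snps)
  }
  # rule 8: A/T or C/G transversion alleles
  for (i in viol$idx[viol$rule == 8])
    snps$alt[i] <- unname(TRANSVERSION_AT_CG[snps$ref[i]])
  # rule 5: alternate-allele qualities all below the threshold (set later,
  # after quality matrices exist); make sure the allele has support
  r5 <- viol$idx[viol$rule == 5]
  for (i in r5) if (sum(RA[i, ]) == 0) RA[i, which.max(G[i, ])] <- 2L
  # rule 6: most accessions left with single-read support for an allele
  for (i in viol$idx[viol$rule == 6]) {
    with_reads <- which(RR[i, ] + RA[i, ] > 0)
    k <- ceiling(0.75 * length(with_reads))
    hit <- with_reads[seq_len(k)]
    RR[i, hit] <- 1L; RA[i, hit] <- 0L
  }

  # clean-by-construction repair: outside each SNP's own injected rule,
  # no SNP may violate the read-support or depth-outlier rule
  not_r6 <- setdiff(seq_len(n), viol$idx[viol$rule == 6])
  fix <- function(M, rows) {
    sub <- M[rows, , drop = FALSE]
    sub[sub > 0 & sub < p1$min_reads_per_allele] <- p1$min_reads_per_allele
    M[rows, ] <- sub
    M
  }
  RR <- fix(RR, not_r6); RA <- fix(RA, not_r6)

  r7 <- viol$idx[viol$rule == 7]
  not_r7 <- setdiff(seq_len(n), r7)
  for (iter in 1:6) {
    tot <- rowSums(RR) + rowSums(RA)
    thr <- mean(tot) + p1$depth_sd_mult * pop_sd(tot)
    changed <- FALSE
    for (i in r7) {
      need <- ceiling(thr + 1 - sum(RA[i, ]))
      if (need > 0) { RA[i, 1] <- RA[i, 1] + as.integer(need); changed <- TRUE }
    }
    over_r <- not_r7[rowSums(RR[not_r7, , drop = FALSE]) > thr]
    over_a <- not_r7[rowSums(RA[not_r7, , drop = FALSE]) > thr]
    for (i in over_r) {
      excess <- ceiling(sum(RR[i, ]) - thr)
      j <- which.max(RR[i, ])
      RR[i, j] <- max(p1$min_reads_per_allele, RR[i, j] - as.integer(excess))
      changed <- TRUE
    }
    for (i in over_a) {
      excess <- ceiling(sum(RA[i, ]) - thr)
      j <- which.max(RA[i, ])
      RA[i, j] <- max(p1$min_reads_per_allele, RA[i, j] - as.integer(excess))
      changed <- TRUE
    }
    if (!changed) break
  }

  QR <- matrix(ifelse(RR > 0, round(stats::runif(n * nacc, 25, 40)), NA_real_),
               n, nacc, dimnames = dimnames(RR))
  QA <- matrix(ifelse(RA > 0, round(stats::runif(n * nacc, 25, 40)), NA_real_),
               n, nacc, dimnames = dimnames(RA))
  for (i in r5) QA[i, RA[i, ] > 0] <- round(stats::runif(sum(RA[i, ] > 0), 5, 15))

  af <- rowSums(G) / (2 * nacc)
  snps$maf <- pmin(af, 1 - af)
  snps$adt <- round(stats::runif(n, 0.5, 1), 3)

  ord <- order(snps$lg, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  snps$id <- sprintf("%s_%07d", snps$lg, snps$pos)
  idx_map <- match(seq_len(n), ord)  # old index -> new row
  ss <- snp_set(snps[c("id", "lg", "pos", "ref", "alt", "adt", "maf")],
                RR[ord, , drop = FALSE], RA[ord, , drop = FALSE],
                QR[ord, , drop = FALSE], QA[ord, , drop = FALSE])
  G <- G[ord, , drop = FALSE]
  rownames(G) <- snps$id
  truth <- list(
    genotypes = G,
    alt_freq = stats::setNames(af[ord], snps$id),
    violations = data.frame(snp_id = snps$id[idx_map[viol$idx]],
                            rule = viol$rule, stringsAsFactors = FALSE),
    accession_specific = snps$id[idx_map[as_ids]])
  list(snps = ss, truth = truth)
}

#' Simulate an Infinium-style array run through a pedigree
#'
#' Drops founder haplotypes through the pedigree with crossovers at the
#' configured genetic-map rate, then emits array-style calls with
#' configurable per-SNP failure and forced-monomorphic probabilities,
#' sporadic missing calls, and quality scores (per-sample p50GC, per-SNP
#' GenTrain-like, per-call GC). The truth ledger records every haplotype,
#' transmission and crossover.
#'
#' @param config a [sim_config()].
#' @param manifest manifest data frame or [assemble_array()] result.
#' @param pedigree data frame (`individual`, `mother`, `father`; parents
#'   must precede their children).
#' @param fail_prob per-SNP probability of a failed assay (all calls
#'   missing, low GenTrain-like score).
#' @param mono_prob per-SNP probability of a forced monomorphic assay.
#' @param review_frac fraction of working SNPs given a mid-range
#'   GenTrain-like score.
#' @param low_sample_frac fraction of samples given a failing p50GC.
#' @param missing_rate sporadic per-call missing rate on working SNPs.
#' @return list with `matrix` (a [genotype_matrix()]) and `truth`
#'   (haplotypes per individual, crossovers, per-SNP status, allele
#'   frequencies).
#' @export
simulate_array_run <- function(config, manifest, pedigree, fail_prob = 0.02,
                               mono_prob = 0.03, review_frac = 0.05,
                               low_sample_frac = 0.05, missing_rate = 0.005) {
  set.seed(config$seed + 2000L)
  man <- if (inherits(manifest, "array_manifest")) manifest$manifest else manifest
  man <- man[order(man$lg, man$pos), , drop = FALSE]
  ids <- man$id; n <- length(ids)
  p <- stats::runif(n, 0.05, 0.5)
  hasb <- !is.na(man$maf_bin)
  p[hasb] <- stats::runif(sum(hasb), pmax(0.011, man$maf_bin[hasb] - 0.089),
                          man$maf_bin[hasb])
  inds <- pedigree$individual
  haps <- list(); cross_list <- list()
  gamete <- function(hp, parent_label, child) {
    out <- integer(n)
    for (lg in unique(man$lg)) {
      i <- which(man$lg == lg)
      start <- sample(1:2, 1)
      sw <- if (length(i) > 1) {
        d <- diff(man$pos[i])
        stats::rbinom(length(d), 1, pmin(0.5, d * config$cm_per_mb / 1e8))
      } else integer(0)
      chrom <- (start - 1L + cumsum(c(0L, sw))) %% 2L + 1L
      out[i] <- hp[cbind(chrom, i)]
      for (k in which(sw == 1))
        cross_list[[length(cross_list) + 1]] <<-
          data.frame(individual = child, parent = parent_label, lg = lg,
                     after_snp = ids[i[k]], before_snp = ids[i[k + 1]],
                     stringsAsFactors = FALSE)
    }
    out
  }
  for (r in seq_len(nrow(pedigree))) {
    ind <- pedigree$individual[r]
    mo <- pedigree$mother[r]; fa <- pedigree$father[r]
    if (is.na(mo) || is.na(fa)) {
      haps[[ind]] <- rbind(stats::rbinom(n, 1, p), stats::rbinom(n, 1, p))
    } else {
      if (is.null(haps[[fa]]) || is.null(haps[[mo]]))
        abort("pedigree parents must precede their children")
      haps[[ind]] <- rbind(gamete(haps[[fa]], "father", ind),
                           gamete(haps[[mo]], "mother", ind))
    }
    colnames(haps[[ind]]) <- ids
  }
  dose <- t(vapply(inds, function(ind) colSums(haps[[ind]]), numeric(n)))
  calls <- matrix(c("AA", "AB", "BB")[dose + 1], nrow(dose), n,
                  dimnames = list(inds, ids))
  u <- stats::runif(n)
  status <- ifelse(u < fail_prob, "failed",
            ifelse(u < fail_prob + mono_prob, "monomorphic", "working"))
  gentrain <- ifelse(status == "failed", stats::runif(n, 0.05, 0.29),
              ifelse(stats::runif(n) < review_frac, stats::runif(n, 0.31, 0.59),
                     stats::runif(n, 0.61, 0.95)))
  calls[, status == "failed"] <- NA_character_
  calls[, status == "monomorphic"] <- "AA"
  sporadic <- matrix(stats::runif(length(calls)) < missing_rate,
                     nrow(calls), ncol(calls))
  sporadic[, status != "working"] <- FALSE
  calls[sporadic] <- NA_character_
  p50 <- ifelse(stats::runif(length(inds)) < low_sample_frac,
                stats::runif(length(inds), 0.3, 0.52),
                stats::runif(length(inds), 0.6, 0.95))
  gc <- matrix(stats::runif(length(calls), 0.45, 0.95), nrow(calls),
               ncol(calls), dimnames = dimnames(calls))
  gm <- genotype_matrix(calls,
                        samples = data.frame(id = inds, p50gc = p50,
                                             stringsAsFactors = FALSE),
                        snp_info = data.frame(id = ids, gentrain = gentrain,
                                              stringsAsFactors = FALSE),
                        gc = gc)
  crossovers <- if (length(cross_list)) do.call(rbind, cross_list) else
    data.frame(individual = character(0), parent = character(0),
               lg = character(0), after_snp = character(0),
               before_snp = character(0))
  list(matrix = gm,
       truth = list(haplotypes = haps, crossovers = crossovers,
                    snp_status = stats::setNames(status, ids),
                    alt_freq = stats::setNames(p, ids)))
}

#' Parental linkage phase from a simulation truth ledger
#'
#' Builds the per-cluster phase table [detect_recombination()] needs: the
#' allele string of the parent's chromosome 1 over each cluster's SNPs.
#'
#' @param truth `truth` element of [simulate_array_run()].
#' @param manifest manifest data frame.
#' @param parent_id sample id of the parent.
#' @param role `"father"` or `"mother"`.
#' @return data frame (`cluster_id`, `parent`, `phase1`, `phase2`).
#' @export
parental_phase_from_truth <- function(truth, manifest, parent_id, role) {
  man <- if (inherits(manifest, "array_manifest")) manifest$manifest else manifest
  man <- man[!is.na(man$cluster_id), , drop = FALSE]
  hp <- truth$haplotypes[[parent_id]]
  out <- lapply(split(man, man$cluster_id), function(m) {
    m <- m[order(m$pos), , drop = FALSE]
    s <- function(row) paste(c("A", "B")[hp[row, m$id] + 1], collapse = "")
    data.frame(cluster_id = m$cluster_id[1], parent = role,
               phase1 = s(1), phase2 = s(2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate parent-parent-child trios over SNP clusters
#'
#' A lightweight generator for phasing verification: random parental
#' haplotypes per cluster, whole-cluster transmission to the child, and
#' optional injected crossovers between chosen adjacent clusters. No
#' genotyping error.
#'
#' @param n_trios number of trios.
#' @param n_clusters clusters per trio (in map order).
#' @param snps_range vector of permissible SNPs-per-cluster counts.
#' @param crossovers optional list with elements `father`/`mother`, each an
#'   integer vector of cluster indexes after which the transmitted
#'   chromosome switches (applied to every trio).
#' @param p_range range of the per-SNP B-allele frequency.
#' @param informative when `TRUE`, clusters are built so that no site is
#'   heterozygous in both parents (phasing is always unambiguous) and both
#'   parents are heterozygous somewhere (transmissions are trackable);
#'   used for exact crossover-interval verification.
#' @param seed RNG seed.
#' @return list of trios; each trio is a list with `clusters` (list of
#'   [new_trio_genotypes()]), `truth` (father/mother haplotype strings and
#'   transmitted chromosome per cluster) and `parental_phase`.
#' @export
simulate_trio_clusters <- function(n_trios, n_clusters = 1,
                                   snps_range = 4:10, crossovers = NULL,
                                   p_range = c(0.15, 0.85),
                                   informative = FALSE, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_trios), function(t) {
    clusters <- list(); phase_rows <- list()
    truth <- list(father = list(), mother = list(),
                  transmitted = data.frame(cluster = integer(0),
                                           father = integer(0),
                                           mother = integer(0)))
    t_f <- sample(1:2, 1); t_m <- sample(1:2, 1)
    xo_f <- crossovers$father %||% integer(0)
    xo_m <- crossovers$mother %||% integer(0)
    for (cidx in seq_len(n_clusters)) {
      if (cidx > 1) {
        if ((cidx - 1) %in% xo_f) t_f <- 3L - t_f
        if ((cidx - 1) %in% xo_m) t_m <- 3L - t_m
      }
      k <- if (length(snps_range) == 1) snps_range else sample(snps_range, 1)
      pb <- stats::runif(k, p_range[1], p_range[2])
      if (informative) {
        # alternate father- and mother-informative sites: one parent
        # heterozygous, the other homozygous at every site
        f1 <- stats::rbinom(k, 1, pb); f2 <- f1
        m1 <- stats::rbinom(k, 1, pb); m2 <- m1
        fsites <- seq(1, k, by = 2)
        msites <- if (k >= 2) seq(2, k, by = 2) else integer(0)
        f2[fsites] <- 1L - f1[fsites]
        m2[msites] <- 1L - m1[msites]
        fh <- rbind(f1, f2); mh <- rbind(m1, m2)
      } else {
        fh <- rbind(stats::rbinom(k, 1, pb), stats::rbinom(k, 1, pb))
        mh <- rbind(stats::rbinom(k, 1, pb), stats::rbinom(k, 1, pb))
      }
      ch <- rbind(fh[t_f, ], mh[t_m, ])
      gt <- function(h) c("AA", "AB", "BB")[colSums(h) + 1]
      cl_id <- sprintf("t%03d_cl%02d", t, cidx)
      snp_id <- sprintf("%s_s%02d", cl_id, seq_len(k))
      clusters[[cidx]] <- new_trio_genotypes(cl_id, snp_id,
                                             gt(fh), gt(mh), gt(ch))
      hs <- function(h, row) paste(c("A", "B")[h[row, ] + 1], collapse = "")
      truth$father[[cl_id]] <- c(hs(fh, 1), hs(fh, 2))
      truth$mother[[cl_id]] <- c(hs(mh, 1), hs(mh, 2))
      truth$transmitted <- rbind(truth$transmitted,
                                 data.frame(cluster = cidx, father = t_f,
                                            mother = t_m))
      phase_rows[[length(phase_rows) + 1]] <- data.frame(
        cluster_id = cl_id, parent = c("father", "mother"),
        phase1 = c(hs(fh, 1), hs(mh, 1)), phase2 = c(hs(fh, 2), hs(mh, 2)),
        stringsAsFactors = FALSE)
    }
    list(clusters = clusters, truth = truth,
         parental_phase = do.call(rbind, phase_rows))
  })
}
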