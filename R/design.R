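# Stage 3: array design.
#
# Focal points are designated on the genetic map (primary anchors with
# known cM positions, gaps > 3 cM filled with physically placed secondary
# anchors, chromosome ends targeted), then clusters of exonic SNPs are
# selected in +/-50 kb windows around each focal point: two SNPs per MAF
# bin, at least 2 kb apart, at most ten per cluster including the focal
# SNP. Candidate-gene clusters relax the spacing rule and instead maximize
# the minimum pairwise distance. The design is fully deterministic.

#' Array design parameters
#'
#' @param focal_interval_cM target spacing of focal points (cM); informational.
#' @param gap_threshold_cM genetic gaps larger than this are filled with
#'   secondary anchors.
#' @param end_window bp; each linkage group end within this window is
#'   targeted for a focal point.
#' @param window_halfwidth bp; cluster members must lie within this
#'   distance of their focal point.
#' @param per_bin SNPs chosen per MAF bin per cluster.
#' @param cluster_max maximum SNPs per cluster, counting the focal SNP.
#' @param min_spacing bp; minimum distance between cluster SNPs.
#' @param gene_max_snps maximum SNPs per candidate-gene cluster.
#' @param adt_min minimum assay-design score retained (scores strictly
#'   below are discarded).
#' @return a list of class `design_params`.
#' @export
design_params <- function(focal_interval_cM = 1, gap_threshold_cM = 3,
                          end_window = 200000, window_halfwidth = 50000,
                          per_bin = 2, cluster_max = 10, min_spacing = 2000,
                          gene_max_snps = 4, adt_min = 0.7) {
  p <- list(focal_interval_cM = focal_interval_cM,
            gap_threshold_cM = gap_threshold_cM, end_window = end_window,
            window_halfwidth = window_halfwidth, per_bin = per_bin,
            cluster_max = cluster_max, min_spacing = min_spacing,
            gene_max_snps = gene_max_snps, adt_min = adt_min)
  if (any(unlist(p) <= 0)) abort("all design parameters must be positive")
  if (per_bin * 5 > cluster_max)
    abort("per_bin x 5 must not exceed cluster_max")
  structure(p, class = "design_params")
}

MAF_BINS <- c(0.1, 0.2, 0.3, 0.4, 0.5)

#' MAF bin of a minor allele frequency
#'
#' Bins are labelled 0.1, 0.2, 0.3, 0.4, 0.5 and cover the MAF ranges
#' 0.01-0.1, 0.101-0.2, and so on: half-open on the left at 3-decimal
#' precision. Frequencies below 0.01 are unbinnable and return `NA`.
#'
#' @param maf numeric vector in `[0, 0.5]`.
#' @return numeric vector of bin labels (`NA` for unbinnable).
#' @export
maf_bin <- function(maf) {
  if (any(is.na(maf))) abort("missing MAF is not binnable; supply MAF")
  if (any(maf < 0 | maf > 0.5)) abort("MAF outside [0, 0.5]")
  m <- round(maf, 3)
  bin <- ceiling(round(m * 10, 6)) / 10
  bin[m < 0.01] <- NA_real_
  bin
}

#' Designate focal points on the genetic map
#'
#' All primary anchors (with known cM positions) become focal points. For
#' every consecutive same-LG pair whose genetic gap exceeds
#' `gap_threshold_cM`, secondary anchors inside the gap are added, closest
#' to the gap midpoint first, until no sub-gap exceeds the threshold or
#' anchors run out. Secondary anchors receive cM positions by
#' piecewise-linear interpolation between primary anchors (clamped at LG
#' ends). Each LG end additionally receives a focal point within
#' `end_window` when any anchor lies there. Unfillable gaps and uncovered
#' ends are reported, not guessed.
#'
#' @param primary anchor data frame (see [read_anchors()]); cM required.
#' @param secondary anchor data frame; cM interpolated from `primary`.
#' @param lg_lengths named vector of LG lengths (bp).
#' @param params a [design_params()].
#' @return list with `focal_points` (anchor columns plus `window_start`,
#'   `window_end`) and `gaps` (data frame of unresolved gaps/ends).
#' @export
designate_focal_points <- function(primary, secondary = NULL, lg_lengths,
                                   params = design_params()) {
  if (is.null(secondary))
    secondary <- primary[0, , drop = FALSE]
  if (any(is.na(primary$cM))) abort("primary anchors must carry cM")
  all_lg <- unique(c(primary$lg, secondary$lg))
  if (any(!all_lg %in% names(lg_lengths)))
    abort("anchor LG absent from lg_lengths: %s",
          paste(setdiff(all_lg, names(lg_lengths)), collapse = ", "))
  fp_list <- list(); gap_list <- list()
  for (lg in all_lg) {
    len <- lg_lengths[[lg]]
    prim <- primary[primary$lg == lg, , drop = FALSE]
    prim <- prim[order(prim$cM, prim$pos), , drop = FALSE]
    sec <- secondary[secondary$lg == lg, , drop = FALSE]
    if (nrow(sec)) {
      sec$cM <- if (nrow(prim) >= 2) {
        stats::approx(prim$pos, prim$cM, xout = sec$pos, rule = 2,
                      ties = "ordered")$y
      } else if (nrow(prim) == 1) rep(prim$cM[1], nrow(sec)) else sec$cM
    }
    focal <- prim
    used <- rep(FALSE, nrow(sec))
    # fill genetic gaps midpoint-first
    if (nrow(prim) >= 2) {
      queue <- Map(c, prim$cM[-nrow(prim)], prim$cM[-1])
      while (length(queue)) {
        g <- queue[[1]]; queue <- queue[-1]
        if (g[2] - g[1] <= params$gap_threshold_cM) next
        cand <- which(!used & !is.na(sec$cM) & sec$cM > g[1] & sec$cM < g[2])
        if (!length(cand)) {
          gap_list[[length(gap_list) + 1]] <-
            data.frame(lg = lg, from_cM = g[1], to_cM = g[2],
                       note = "no_secondary_anchor", stringsAsFactors = FALSE)
          next
        }
        mid <- (g[1] + g[2]) / 2
        pick <- cand[order(abs(sec$cM[cand] - mid), sec$pos[cand])][1]
        used[pick] <- TRUE
        focal <- rbind(focal, sec[pick, names(focal), drop = FALSE])
        queue <- c(queue, list(c(g[1], sec$cM[pick]), c(sec$cM[pick], g[2])))
      }
    }
    # chromosome ends
    for (side in c("start", "end")) {
      inside <- if (side == "start") focal$pos <= params$end_window
                else focal$pos > len - params$end_window
      if (any(inside)) next
      pool <- rbind(prim[0, , drop = FALSE], sec[!used, , drop = FALSE])
      hit <- if (side == "start") which(pool$pos <= params$end_window)
             else which(pool$pos > len - params$end_window)
      if (length(hit)) {
        pick <- hit[order(if (side == "start") pool$pos[hit] else -pool$pos[hit])][1]
        used[match(pool$marker_id[pick], sec$marker_id)] <- TRUE
        focal <- rbind(focal, pool[pick, names(focal), drop = FALSE])
      } else {
        gap_list[[length(gap_list) + 1]] <-
          data.frame(lg = lg, from_cM = NA_real_, to_cM = NA_real_,
                     note = paste0("no_anchor_near_lg_", side),
                     stringsAsFactors = FALSE)
      }
    }
    focal <- focal[order(focal$pos), , drop = FALSE]
    focal$window_start <- pmax(1L, as.integer(focal$pos - params$window_halfwidth))
    focal$window_end <- pmin(as.integer(len),
                             as.integer(focal$pos + params$window_halfwidth))
    fp_list[[lg]] <- focal
  }
  fps <- do.call(rbind, fp_list)
  rownames(fps) <- NULL
  gaps <- if (length(gap_list)) do.call(rbind, gap_list) else
    data.frame(lg = character(0), from_cM = numeric(0), to_cM = numeric(0),
               note = character(0))
  list(focal_points = fps, gaps = gaps)
}

# feasibility of a candidate subset: per-bin cap and pairwise spacing
# (pairwise min distance in 1D equals the min adjacent gap after sorting)
cluster_min_dist <- function(pos) {
  if (length(pos) < 2) return(Inf)
  min(diff(sort(pos)))
}

# lexicographic key for deterministic tie-breaks over position sets
pos_key <- function(pos) paste(sprintf("%012d", sort(pos)), collapse = "")

#' Select a SNP cluster around a focal point
#'
#' Within the focal window, candidates are binned by MAF and up to
#' `per_bin` SNPs per bin are selected subject to the minimum spacing and
#' the cluster-size cap (the focal SNP, when the anchor is itself an
#' assayed SNP, occupies one slot and participates in spacing). With at
#' most twelve window candidates the selection is exact, maximizing
#' (member count, number of MAF bins represented, minimum pairwise
#' distance); larger windows use a deterministic greedy rule: bins in
#' descending label order, within a bin the candidate farthest from the
#' already selected SNPs first (ties broken by higher design score, then
#' lower position).
#'
#' @param focal one row of `focal_points` from [designate_focal_points()].
#' @param candidates data frame of window candidates (columns `id`, `lg`,
#'   `pos`, `maf`, optionally `ref`, `alt`, `adt`); all must lie in the
#'   focal window and carry MAF.
#' @param params a [design_params()].
#' @param focal_is_snp logical; whether the anchor is itself an assayed SNP
#'   (default: anchors of kind `GDsnp`).
#' @param exhaustive_limit window sizes up to this use the exact search.
#' @return an object of class `snp_cluster`: list with `anchor`, `source`,
#'   `focal_is_snp` and `members` (selected candidates with `bin`, sorted
#'   by position). Empty windows yield a memberless cluster flagged
#'   `singleton = TRUE`.
#' @export
select_cluster <- function(focal, candidates, params = design_params(),
                           focal_is_snp = identical(focal$kind, "GDsnp"),
                           exhaustive_limit = 12) {
  cand <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (nrow(cand)) {
    if (any(is.na(cand$maf))) abort("window candidates must carry MAF")
    if (any(cand$pos < focal$window_start | cand$pos > focal$window_end))
      abort("candidate outside the focal window")
    cand$bin <- maf_bin(cand$maf)
    cand <- cand[!is.na(cand$bin), , drop = FALSE]
  }
  if (is.null(cand$adt)) cand$adt <- NA_real_
  max_members <- params$cluster_max - as.integer(isTRUE(focal_is_snp))
  focal_pos <- if (isTRUE(focal_is_snp)) focal$pos else numeric(0)
  sel <- if (!nrow(cand)) integer(0)
         else if (nrow(cand) <= exhaustive_limit)
           select_exact(cand, focal_pos, params, max_members)
         else select_greedy(cand, focal_pos, params, max_members)
  members <- cand[sel, , drop = FALSE]
  members <- members[order(members$pos), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(cluster_id = NA_character_, anchor = focal,
                 source = "focal_window", focal_is_snp = isTRUE(focal_is_snp),
                 members = members, singleton = nrow(members) == 0),
            class = "snp_cluster")
}

select_exact <- function(cand, focal_pos, params, max_members) {
  n <- nrow(cand)
  best <- integer(0); best_score <- c(-1, -1, -1); best_key <- ""
  for (k in seq(min(n, max_members), 1)) {
    found <- FALSE
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      if (any(table(cand$bin[idx]) > params$per_bin)) next
      p <- c(cand$pos[idx], focal_pos)
      md <- cluster_min_dist(p)
      if (md < params$min_spacing) next
      score <- c(k, length(unique(cand$bin[idx])), min(md, .Machine$integer.max))
      key <- pos_key(cand$pos[idx])
      better <- isTRUE(score[1] > best_score[1]) ||
        (score[1] == best_score[1] && score[2] > best_score[2]) ||
        (score[1] == best_score[1] && score[2] == best_score[2] &&
           score[3] > best_score[3]) ||
        (all(score == best_score) && key < best_key)
      if (better) { best <- idx; best_score <- score; best_key <- key }
      found <- TRUE
    }
    if (found) break  # larger member counts dominate; stop at first feasible size
  }
  best
}

select_greedy <- function(cand, focal_pos, params, max_members) {
  sel <- integer(0)
  sel_pos <- focal_pos
  adt <- ifelse(is.na(cand$adt), -Inf, cand$adt)
  for (b in sort(unique(cand$bin), decreasing = TRUE)) {
    taken <- 0L
    while (taken < params$per_bin && length(sel) < max_members) {
      elig <- setdiff(which(cand$bin == b), sel)
      if (length(sel_pos)) {
        d <- vapply(cand$pos[elig], function(p) min(abs(p - sel_pos)), numeric(1))
        elig <- elig[d >= params$min_spacing]
        d <- d[d >= params$min_spacing]
      } else d <- rep(Inf, length(elig))
      if (!length(elig)) break
      pick <- elig[order(-d, -adt[elig], cand$pos[elig])][1]
      sel <- c(sel, pick)
      sel_pos <- c(sel_pos, cand$pos[pick])
      taken <- taken + 1L
    }
  }
  sel
}

#' Build candidate-gene SNP clusters
#'
#' For each gene, up to `gene_max_snps` exonic SNPs inside the gene body
#' are chosen to lie as far from each other as possible (maximizing the
#' minimum pairwise distance); the 2 kb spacing rule does not apply. Genes
#' with at most 20 SNPs are solved exhaustively, larger ones by greedy
#' farthest-point selection. Genes without SNPs emit no cluster.
#'
#' @param genes data frame with `gene_id`, `lg`, `start`, `end`.
#' @param candidates data frame of (exonic) candidates with `id`, `lg`,
#'   `pos` and optionally `maf`, `adt`.
#' @param params a [design_params()].
#' @return list of `snp_cluster` objects with source `candidate_gene`.
#' @export
design_gene_clusters <- function(genes, candidates, params = design_params()) {
  out <- list()
  cand_all <- as.data.frame(candidates, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(genes))) {
    g <- genes[r, ]
    cand <- cand_all[cand_all$lg == g$lg & cand_all$pos >= g$start &
                       cand_all$pos <= g$end, , drop = FALSE]
    if (!nrow(cand)) next
    k <- min(params$gene_max_snps, nrow(cand))
    sel <- if (nrow(cand) <= k) seq_len(nrow(cand))
           else if (nrow(cand) <= 20) maxmin_exact(cand$pos, k)
           else maxmin_greedy(cand$pos, k)
    members <- cand[sel, , drop = FALSE]
    members$bin <- if (is.null(members$maf) || all(is.na(members$maf)))
      NA_real_ else ifelse(is.na(members$maf), NA_real_, suppressWarnings(maf_bin_safe(members$maf)))
    members <- members[order(members$pos), , drop = FALSE]
    rownames(members) <- NULL
    anchor <- data.frame(marker_id = g$gene_id, kind = "candidate_gene",
                         lg = g$lg, pos = as.integer(floor((g$start + g$end) / 2)),
                         cM = NA_real_, window_start = as.integer(g$start),
                         window_end = as.integer(g$end), stringsAsFactors = FALSE)
    out[[length(out) + 1]] <-
      structure(list(cluster_id = NA_character_, anchor = anchor,
                     source = "candidate_gene", focal_is_snp = FALSE,
                     members = members, singleton = FALSE),
                class = "snp_cluster")
  }
  out
}

# maf_bin that tolerates NA entries (gene clusters do not require MAF)
maf_bin_safe <- function(maf) {
  out <- rep(NA_real_, length(maf))
  ok <- !is.na(maf)
  if (any(ok)) out[ok] <- maf_bin(maf[ok])
  out
}

# exact max-min-distance subset of size k (positions; n <= 20)
maxmin_exact <- function(pos, k) {
  combs <- utils::combn(length(pos), k)
  best <- NULL; best_d <- -Inf; best_key <- ""
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    d <- cluster_min_dist(pos[idx])
    key <- pos_key(pos[idx])
    if (d > best_d || (d == best_d && key < best_key)) {
      best <- idx; best_d <- d; best_key <- key
    }
  }
  best
}

maxmin_greedy <- function(pos, k) {
  sel <- c(which.min(pos), which.max(pos))
  while (length(sel) < k) {
    rest <- setdiff(seq_along(pos), sel)
    d <- vapply(pos[rest], function(p) min(abs(p - pos[sel])), numeric(1))
    sel <- c(sel, rest[order(-d, pos[rest])][1])
  }
  sel
}

#' Discard SNPs below the assay-design score threshold
#'
#' Scores strictly below `adt_min` are discarded; a missing score is an
#' error rather than a silent default.
#'
#' @param x a [snp_set()] or a data frame with an `adt` column.
#' @param adt_min threshold (default 0.7).
#' @return the kept subset, same type as `x`.
#' @export
apply_adt_filter <- function(x, adt_min = 0.7) {
  adt <- if (inherits(x, "snp_set")) x$snps$adt else x$adt
  if (is.null(adt) || any(is.na(adt)))
    abort("assay-design score missing; cannot apply the score filter")
  keep <- adt >= adt_min
  if (inherits(x, "snp_set")) x[keep] else x[keep, , drop = FALSE]
}

#' Apply the assay-design score filter to cluster members
#'
#' Convenience wrapper running [apply_adt_filter()] over the members of a
#' list of clusters; emptied clusters are flagged `singleton`.
#'
#' @param clusters list of `snp_cluster` objects.
#' @param adt_min threshold (default 0.7).
#' @return the filtered cluster list.
#' @export
filter_cluster_adt <- function(clusters, adt_min = 0.7) {
  lapply(clusters, function(cl) {
    if (nrow(cl$members)) cl$members <- apply_adt_filter(cl$members, adt_min)
    cl$singleton <- nrow(cl$members) == 0
    cl
  })
}

#' Assemble the array manifest
#'
#' Combines focal-window clusters, candidate-gene clusters and validated
#' extra SNPs into a single manifest, de-duplicated by genomic position
#' with source precedence GDsnp > focal_window > candidate_gene >
#' validated. Cluster ids are assigned per linkage group in anchor-position
#' order, and the manifest is sorted by (lg, pos).
#'
#' @param focal_clusters list of `snp_cluster` objects from
#'   [select_cluster()].
#' @param gene_clusters list from [design_gene_clusters()].
#' @param validated_extras optional data frame (`id`, `lg`, `pos`,
#'   optionally `ref`, `alt`, `maf`) of previously validated SNPs added
#'   without a cluster.
#' @return an object of class `array_manifest`: list with `manifest` (data
#'   frame `id`, `lg`, `pos`, `ref`, `alt`, `cluster_id`, `focal_flag`,
#'   `maf_bin`, `source`), `totals` (named counts by source plus `total`)
#'   and `n_clusters`.
#' @export
assemble_array <- function(focal_clusters, gene_clusters = list(),
                           validated_extras = NULL) {
  clusters <- c(focal_clusters, gene_clusters)
  if (length(clusters)) {
    ord <- order(vapply(clusters, function(cl) cl$anchor$lg, character(1)),
                 vapply(clusters, function(cl) cl$anchor$pos, numeric(1)))
    clusters <- clusters[ord]
    lgs <- vapply(clusters, function(cl) cl$anchor$lg, character(1))
    ordinal <- stats::ave(seq_along(lgs), lgs, FUN = seq_along)
    for (i in seq_along(clusters))
      clusters[[i]]$cluster_id <- sprintf("%s_c%03d", lgs[i], ordinal[i])
  }
  rows <- list()
  for (cl in clusters) {
    if (cl$focal_is_snp) {
      rows[[length(rows) + 1]] <- data.frame(
        id = cl$anchor$marker_id, lg = cl$anchor$lg, pos = cl$anchor$pos,
        ref = NA_character_, alt = NA_character_, cluster_id = cl$cluster_id,
        focal_flag = TRUE, maf_bin = NA_real_, source = "GDsnp",
        stringsAsFactors = FALSE)
    }
    if (nrow(cl$members)) {
      m <- cl$members
      rows[[length(rows) + 1]] <- data.frame(
        id = m$id, lg = m$lg, pos = m$pos,
        ref = m$ref %||% NA_character_, alt = m$alt %||% NA_character_,
        cluster_id = cl$cluster_id, focal_flag = FALSE,
        maf_bin = m$bin %||% NA_real_,
        source = if (cl$source == "candidate_gene") "candidate_gene"
                 else "focal_window",
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(validated_extras) && nrow(validated_extras)) {
    v <- validated_extras
    rows[[length(rows) + 1]] <- data.frame(
      id = v$id, lg = v$lg, pos = v$pos,
      ref = v$ref %||% NA_character_, alt = v$alt %||% NA_character_,
      cluster_id = NA_character_, focal_flag = FALSE,
      maf_bin = if (is.null(v$maf)) NA_real_ else maf_bin_safe(v$maf),
      source = "validated", stringsAsFactors = FALSE)
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), lg = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               cluster_id = character(0), focal_flag = logical(0),
               maf_bin = numeric(0), source = character(0))
  # de-duplicate by genomic position, keeping the highest-precedence source
  prec <- c(GDsnp = 1, focal_window = 2, candidate_gene = 3, validated = 4)
  man <- man[order(man$lg, man$pos, prec[man$source]), , drop = FALSE]
  man <- man[!duplicated(paste(man$lg, man$pos)), , drop = FALSE]
  if (anyDuplicated(man$id)) abort("duplicate SNP ids in manifest")
  rownames(man) <- NULL
  totals <- vapply(names(prec), function(s) sum(man$source == s), integer(1))
  totals <- c(totals, total = nrow(man))
  structure(list(manifest = man, totals = totals,
                 n_clusters = length(unique(stats::na.omit(man$cluster_id)))),
            class = "array_manifest")
}

#' @export
print.array_manifest <- function(x, ...) {
  cat(sprintf("<array_manifest> %d SNPs in %d clusters\n",
              x$totals[["total"]], x$n_clusters))
  print(x$totals)
  invisible(x)
}

#' Per-LG design summary
#'
#' For each linkage group: number of SNPs, number of clusters, average
#' physical distance between focal points (LG length / clusters, kb, 1 dp)
#' and average genetic distance (cM length / clusters, 2 dp), plus a
#' totals row. LGs without clusters report `NA` spacings.
#'
#' @param manifest manifest data frame or [assemble_array()] result.
#' @param lg_lengths named vector of physical LG lengths (bp).
#' @param cm_lengths named vector of genetic LG lengths (cM).
#' @return data frame, one row per LG plus `Total`.
#' @export
design_summary <- function(manifest, lg_lengths, cm_lengths = NULL) {
  man <- if (inherits(manifest, "array_manifest")) manifest$manifest else manifest
  lgs <- names(lg_lengths)
  row_for <- function(lg, len, cm) {
    d <- man[man$lg == lg, , drop = FALSE]
    ncl <- length(unique(stats::na.omit(d$cluster_id)))
    data.frame(lg = lg, n_snps = nrow(d), n_clusters = ncl,
               phys_kb_per_cluster =
                 if (ncl) round_half_up(len / 1000 / ncl, 1) else NA_real_,
               cM_per_cluster =
                 if (ncl && !is.na(cm)) round_half_up(cm / ncl, 2) else NA_real_,
               stringsAsFactors = FALSE)
  }
  cm <- if (is.null(cm_lengths)) stats::setNames(rep(NA_real_, length(lgs)), lgs)
        else cm_lengths
  out <- do.call(rbind, Map(row_for, lgs, lg_lengths, cm[lgs]))
  tot_cl <- length(unique(stats::na.omit(man$cluster_id)))
  out <- rbind(out, data.frame(
    lg = "Total", n_snps = nrow(man), n_clusters = tot_cl,
    phys_kb_per_cluster =
      if (tot_cl) round_half_up(sum(lg_lengths) / 1000 / tot_cl, 1) else NA_real_,
    cM_per_cluster = if (tot_cl && !any(is.na(cm)))
      round_half_up(sum(cm) / tot_cl, 2) else NA_real_))
  rownames(out) <- NULL
  out
}

MANIFEST_SOURCES <- c("GDsnp", "focal_window", "candidate_gene", "validated")

#' Write / read an array manifest TSV
#'
#' The manifest is written sorted by (lg, pos) regardless of input order;
#' `read_manifest` is its exact inverse and rejects unknown source tags.
#'
#' @param x manifest data frame or [assemble_array()] result.
#' @param path TSV path.
#' @return `path` / a manifest data frame.
#' @export
write_manifest <- function(x, path) {
  man <- if (inherits(x, "array_manifest")) x$manifest else x
  man <- man[order(man$lg, man$pos), , drop = FALSE]
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                           colClasses = c(pos = "integer"))
  need <- c("id", "lg", "pos", "ref", "alt", "cluster_id", "focal_flag",
            "maf_bin", "source")
  if (!all(need %in% names(man)))
    abort("manifest must have columns: %s", paste(need, collapse = ", "))
  if (any(!man$source %in% MANIFEST_SOURCES))
    abort("unknown source tag: %s",
          paste(setdiff(unique(man$source), MANIFEST_SOURCES), collapse = ", "))
  man$focal_flag <- as.logical(man$focal_flag)
  man$maf_bin <- as.numeric(man$maf_bin)
  if (!is.character(man$cluster_id)) man$cluster_id <- as.character(man$cluster_id)
  if (!is.character(man$ref)) man$ref <- as.character(man$ref)
  if (!is.character(man$alt)) man$alt <- as.character(man$alt)
  man[need]
}
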