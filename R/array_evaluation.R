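# Infinium-style array evaluation: sample and SNP QC gates, polymorphism
# classification, segregation typing in families and per-LG summaries.

#' Array evaluation parameters
#'
#' @param p50gc_min samples with p50GC strictly below this are removed.
#' @param gentrain_retain SNPs with a GenTrain-like score strictly above
#'   this are retained outright.
#' @param gentrain_review_low scores in `[gentrain_review_low,
#'   gentrain_retain]` are kept but flagged for review; below fail.
#' @param hq_maf_min,hq_callrate_min,hq_gc50_min high-quality marker
#'   thresholds (all strictly-greater).
#' @param max_missing SNPs with more than this many missing calls among
#'   passing samples are flagged.
#' @return list of class `eval_params`.
#' @export
eval_params <- function(p50gc_min = 0.54, gentrain_retain = 0.6,
                        gentrain_review_low = 0.3, hq_maf_min = 0.05,
                        hq_callrate_min = 0.95, hq_gc50_min = 0.4,
                        max_missing = 20) {
  if (gentrain_review_low >= gentrain_retain)
    abort("gentrain_review_low must be below gentrain_retain")
  structure(list(p50gc_min = p50gc_min, gentrain_retain = gentrain_retain,
                 gentrain_review_low = gentrain_review_low,
                 hq_maf_min = hq_maf_min, hq_callrate_min = hq_callrate_min,
                 hq_gc50_min = hq_gc50_min, max_missing = max_missing),
            class = "eval_params")
}

#' Sample and SNP QC gates
#'
#' Samples with `p50gc < p50gc_min` are removed (equality retained).
#' SNPs are split on the GenTrain-like score: strictly above
#' `gentrain_retain` retained; in `[gentrain_review_low, gentrain_retain]`
#' retained but flagged for review; below (or missing) failed. SNPs with
#' more than `max_missing` missing calls among passing samples are
#' additionally flagged.
#'
#' @param gm a [genotype_matrix()] with `p50gc` and `gentrain` scores.
#' @param params an [eval_params()].
#' @return list with `samples` (id, pass) and `snps` (id, status in
#'   retained/review/failed, n_missing, missing_flag).
#' @export
qc_gates <- function(gm, params = eval_params()) {
  pass <- !is.na(gm$samples$p50gc) & gm$samples$p50gc >= params$p50gc_min
  g <- gm$snp_info$gentrain
  status <- ifelse(is.na(g), "failed",
            ifelse(g > params$gentrain_retain, "retained",
            ifelse(g >= params$gentrain_review_low, "review", "failed")))
  n_missing <- colSums(is.na(gm$calls[pass, , drop = FALSE]))
  list(samples = data.frame(id = gm$samples$id, pass = pass,
                            stringsAsFactors = FALSE),
       snps = data.frame(id = gm$snp_info$id, status = status,
                         n_missing = as.integer(n_missing),
                         missing_flag = n_missing > params$max_missing,
                         stringsAsFactors = FALSE))
}

#' Classify SNPs after QC gates
#'
#' Over the QC-passing samples: a gate-failed or uncalled SNP is `failed`;
#' a SNP with a single observed genotype class is `monomorphic`; a SNP
#' with two or more classes and MAF above zero is `polymorphic`. Flags:
#' `low_maf` for polymorphic SNPs with MAF at or below `hq_maf_min`, and
#' `high_quality` for polymorphic SNPs with MAF, call rate and mean 50%GC
#' strictly above their thresholds.
#'
#' @param gm a [genotype_matrix()].
#' @param params an [eval_params()].
#' @param gates optional precomputed [qc_gates()] result.
#' @return data frame (id, label, maf, call_rate, mean_gc, low_maf,
#'   high_quality).
#' @export
classify_snps <- function(gm, params = eval_params(), gates = NULL) {
  if (is.null(gates)) gates <- qc_gates(gm, params)
  pass <- gates$samples$pass
  calls <- gm$calls[pass, , drop = FALSE]
  n_pass <- nrow(calls)
  res <- lapply(seq_len(ncol(calls)), function(j) {
    if (gates$snps$status[j] == "failed")
      return(list(label = "failed", maf = NA_real_, cr = NA_real_,
                  gc = NA_real_))
    cj <- calls[, j]
    called <- sum(!is.na(cj))
    if (called == 0)
      return(list(label = "failed", maf = NA_real_, cr = 0, gc = NA_real_))
    maf <- compute_maf(cj)
    cr <- called / n_pass
    gc <- if (!is.null(gm$gc))
      mean(gm$gc[pass, j][!is.na(cj)], na.rm = TRUE) else NA_real_
    nclass <- length(unique(cj[!is.na(cj)]))
    label <- if (nclass >= 2 && maf > 0) "polymorphic" else "monomorphic"
    list(label = label, maf = maf, cr = cr, gc = gc)
  })
  label <- vapply(res, `[[`, character(1), "label")
  maf <- vapply(res, `[[`, numeric(1), "maf")
  cr <- vapply(res, `[[`, numeric(1), "cr")
  gc <- vapply(res, `[[`, numeric(1), "gc")
  poly <- label == "polymorphic"
  data.frame(id = colnames(calls), label = label, maf = maf, call_rate = cr,
             mean_gc = gc,
             low_maf = poly & maf <= params$hq_maf_min,
             high_quality = poly & maf > params$hq_maf_min &
               cr > params$hq_callrate_min &
               (!is.na(gc) & gc > params$hq_gc50_min),
             stringsAsFactors = FALSE)
}

#' Segregation class of a marker from its parental calls
#'
#' A marker heterozygous in one parent and homozygous in the other is a
#' pseudo-testcross marker (segregates 1:1 in the F1); heterozygous in
#' both parents is `both_het`; anything else is uninformative. Symmetric
#' in the parents.
#'
#' @param p1_call,p2_call parental calls (`"AA"`/`"AB"`/`"BB"`),
#'   vectorized; missing calls are an error.
#' @return character vector of class labels.
#' @export
classify_segregation <- function(p1_call, p2_call) {
  if (any(is.na(p1_call)) || any(is.na(p2_call)))
    abort("segregation class undefined for missing parental calls")
  h1 <- p1_call == "AB"; h2 <- p2_call == "AB"
  ifelse(h1 & h2, "both_het", ifelse(xor(h1, h2), "pseudo_testcross",
                                     "uninformative"))
}

#' Per-LG array evaluation summary
#'
#' Joins per-SNP classification labels onto the manifest and reports, per
#' linkage group and in total: attempted SNPs, successful beadtypes
#' (non-failed), polymorphic count and percentage (1 dp), polymorphic
#' count with MAF > 0.05, high-quality count, attempted and polymorphic
#' clusters and the polymorphic-cluster percentage (1 dp).
#'
#' @param manifest manifest data frame or [assemble_array()] result.
#' @param labels a [classify_snps()] result.
#' @return data frame, one row per LG plus `Total`.
#' @export
evaluation_summary <- function(manifest, labels) {
  man <- if (inherits(manifest, "array_manifest")) manifest$manifest else manifest
  d <- merge(man, labels, by = "id", all.x = TRUE)
  d$label[is.na(d$label)] <- "failed"
  summarize <- function(dd, name) {
    succ <- sum(dd$label != "failed")
    poly <- sum(dd$label == "polymorphic")
    cl <- unique(stats::na.omit(dd$cluster_id))
    poly_cl <- unique(stats::na.omit(dd$cluster_id[dd$label == "polymorphic"]))
    data.frame(lg = name, attempted = nrow(dd), successful = succ,
               polymorphic = poly,
               pct_polymorphic =
                 if (succ) round_half_up(100 * poly / succ, 1) else NA_real_,
               maf_gt_0.05 = sum(dd$label == "polymorphic" &
                                   !is.na(dd$maf) & dd$maf > 0.05),
               high_quality = sum(dd$high_quality, na.rm = TRUE),
               clusters = length(cl), polymorphic_clusters = length(poly_cl),
               pct_polymorphic_clusters = if (length(cl))
                 round_half_up(100 * length(poly_cl) / length(cl), 1)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }
  per_lg <- do.call(rbind, lapply(split(d, d$lg), function(dd)
    summarize(dd, dd$lg[1])))
  out <- rbind(per_lg, summarize(d, "Total"))
  rownames(out) <- NULL
  out
}
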