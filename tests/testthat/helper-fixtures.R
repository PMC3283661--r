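# Fixture builders and independent oracles shared across the suite.

# deterministic toy genome: repeated ACGT pattern, optional ambiguity sites
tiny_genome <- function(lengths = c(LG01 = 10000), ambiguity = list()) {
  seqs <- vapply(names(lengths), function(lg) {
    chars <- rep(c("A", "C", "G", "T"), length.out = lengths[[lg]])
    for (p in ambiguity[[lg]]) chars[p] <- "N"
    paste(chars, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(seqs)
}

# snp_set with benign default evidence: 4 accessions, 5+5 reads, quality 30
make_ss <- function(df, n_acc = 4, reads = 5, qual = 30) {
  n <- nrow(df)
  acc <- sprintf("a%02d", seq_len(n_acc))
  m <- function(v) matrix(v, n, n_acc, dimnames = list(df$id, acc))
  if (is.null(df$ref)) df$ref <- "A"
  if (is.null(df$alt)) df$alt <- "G"
  snp_set(df, m(reads), m(reads), m(qual), m(qual))
}

# brute-force exon-space membership: scan every interval
brute_member <- function(intervals, lg, pos) {
  vapply(seq_along(pos), function(i) {
    any(intervals$lg == lg[i] & intervals$start <= pos[i] &
          intervals$end >= pos[i])
  }, logical(1))
}

# independent cluster-selection oracle: enumerate all subsets with combn,
# score (size, bins represented, min pairwise distance incl. focal SNP)
oracle_cluster <- function(cand, focal_pos, params, max_members) {
  n <- nrow(cand)
  bins <- maf_bin(cand$maf)
  keepable <- which(!is.na(bins))
  best <- c(0, 0, Inf)
  feas_min_dist <- function(pos) {
    pts <- sort(c(pos, focal_pos))
    if (length(pts) < 2) Inf else min(diff(pts))
  }
  for (k in seq_len(min(length(keepable), max_members))) {
    sets <- utils::combn(keepable, k)
    for (j in seq_len(ncol(sets))) {
      idx <- sets[, j]
      if (max(table(bins[idx])) > params$per_bin) next
      md <- feas_min_dist(cand$pos[idx])
      if (md < params$min_spacing) next
      sc <- c(k, length(unique(bins[idx])), md)
      if (sc[1] > best[1] ||
          (sc[1] == best[1] && sc[2] > best[2]) ||
          (sc[1] == best[1] && sc[2] == best[2] && sc[3] > best[3]))
        best <- sc
    }
  }
  best
}

cluster_objective <- function(cl, focal_pos) {
  pos <- cl$members$pos
  pts <- sort(c(pos, focal_pos))
  c(nrow(cl$members), length(unique(stats::na.omit(cl$members$bin))),
    if (length(pts) < 2) Inf else min(diff(pts)))
}

# brute-force max-min-distance subset (distance matrix route)
oracle_maxmin <- function(pos, k) {
  sets <- utils::combn(length(pos), k)
  best <- -Inf
  for (j in seq_len(ncol(sets))) {
    p <- pos[sets[, j]]
    d <- min(as.vector(stats::dist(p)))
    if (d > best) best <- d
  }
  best
}

# independent trio-cluster enumerator for small clusters: build each
# parent's compatible haplotype pairs site by site, then check every
# father-pair x mother-pair x transmission combination against the child
oracle_trio <- function(father, mother, child) {
  pairs_for <- function(g) {
    acc <- list(list(h1 = character(0), h2 = character(0)))
    for (call in g) {
      opts <- if (is.na(call)) list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B"))
              else if (call == "AA") list(c("A", "A"))
              else if (call == "BB") list(c("B", "B"))
              else list(c("A", "B"), c("B", "A"))
      acc <- unlist(lapply(acc, function(a) lapply(opts, function(o)
        list(h1 = c(a$h1, o[1]), h2 = c(a$h2, o[2])))), recursive = FALSE)
    }
    acc
  }
  fp <- pairs_for(father); mp <- pairs_for(mother)
  configs <- list()
  for (f in fp) for (m in mp) for (tf in 1:2) for (tm in 1:2) {
    cf <- if (tf == 1) f$h1 else f$h2
    cm <- if (tm == 1) m$h1 else m$h2
    ok <- TRUE
    for (s in seq_along(child)) {
      if (is.na(child[s])) next
      if (paste(sort(c(cf[s], cm[s])), collapse = "") != child[s]) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      fpair <- sort(c(paste(f$h1, collapse = ""), paste(f$h2, collapse = "")))
      mpair <- sort(c(paste(m$h1, collapse = ""), paste(m$h2, collapse = "")))
      # configurations are distinguished by the parent pairs and by which
      # haplotype each parent transmitted (ordered father-then-mother)
      key <- paste(paste(fpair, collapse = "|"), paste(mpair, collapse = "|"),
                   paste(cf, collapse = ""), paste(cm, collapse = ""),
                   sep = "::")
      configs[[key]] <- list(father = fpair, mother = mpair,
                             child = c(paste(cf, collapse = ""),
                                       paste(cm, collapse = "")))
    }
  }
  configs
}

# quick per-site uniqueness check: a site is unresolvable only when both
# parents and the child are all heterozygous (no missing calls)
sites_all_unique <- function(father, mother, child) {
  !any(father == "AB" & mother == "AB" & child == "AB") &&
    !any(is.na(father) | is.na(mother) | is.na(child))
}

# turn allele-dose vectors into call strings
dose_calls <- function(d) c("AA", "AB", "BB")[d + 1]

# minimal genetic-map anchor row
anchor <- function(id, lg, pos, cM = NA_real_, kind = "GDsnp")
  data.frame(marker_id = id, kind = kind, lg = lg, pos = as.integer(pos),
             cM = cM, stringsAsFactors = FALSE)

# random focal window with n binnable candidates
make_window <- function(focal_pos = 50000, lg = "LG01", n = 10,
                        lg_len = 1000000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- anchor("f", lg, focal_pos, 1)
  f$window_start <- max(1L, f$pos - 50000L)
  f$window_end <- min(lg_len, f$pos + 50000L)
  cand <- data.frame(
    id = sprintf("c%02d", seq_len(n)), lg = lg,
    pos = sort(sample(seq(f$window_start, f$window_end), n)),
    ref = "A", alt = "G",
    adt = round(runif(n, 0.5, 1), 2), maf = round(runif(n, 0.01, 0.5), 3),
    stringsAsFactors = FALSE)
  list(focal = f, cand = cand)
}
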