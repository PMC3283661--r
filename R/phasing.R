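# Trio-based phasing of SNP clusters.
#
# Clusters span at most ~100 kb and are treated as non-recombining blocks:
# each child haplotype is a whole-cluster copy of one parental haplotype.
# With A/B coded calls, every site constrains the four parental haplotype
# slots (father transmitted/untransmitted, mother transmitted/
# untransmitted) independently, so a trio is phased by per-site
# enumeration followed by combination of the per-site solutions. Missing
# calls are wildcards and surface as dots in the haplotype strings.

#' Assemble trio genotypes for one cluster
#'
#' @param gm a [genotype_matrix()].
#' @param manifest manifest data frame (provides `cluster_id` and `pos`).
#' @param cluster_id cluster to extract.
#' @param father,mother,child sample ids.
#' @return object of class `trio_genotypes`.
#' @export
trio_genotypes <- function(gm, manifest, cluster_id, father, mother, child) {
  man <- if (inherits(manifest, "array_manifest")) manifest$manifest else manifest
  m <- man[!is.na(man$cluster_id) & man$cluster_id == cluster_id, , drop = FALSE]
  m <- m[order(m$pos), , drop = FALSE]
  ids <- intersect(m$id, colnames(gm$calls))
  if (!length(ids)) abort("cluster %s has no SNPs in the matrix", cluster_id)
  structure(list(cluster_id = cluster_id, snp_id = ids,
                 pos = m$pos[match(ids, m$id)],
                 father = gm$calls[father, ids],
                 mother = gm$calls[mother, ids],
                 child = gm$calls[child, ids]),
            class = "trio_genotypes")
}

#' Construct trio genotypes directly from call vectors
#' @param cluster_id cluster label.
#' @param snp_id SNP ids in map order.
#' @param father,mother,child call vectors (`"AA"`/`"AB"`/`"BB"`/`NA`).
#' @param pos optional positions.
#' @return object of class `trio_genotypes`.
#' @export
new_trio_genotypes <- function(cluster_id, snp_id, father, mother, child,
                               pos = seq_along(snp_id)) {
  stopifnot(length(father) == length(snp_id),
            length(mother) == length(snp_id),
            length(child) == length(snp_id))
  structure(list(cluster_id = cluster_id, snp_id = snp_id, pos = pos,
                 father = father, mother = mother, child = child),
            class = "trio_genotypes")
}

# ordered allele pairs compatible with a genotype call (NA = wildcard)
ordered_pairs <- function(call) {
  switch(ifelse(is.na(call), "missing", call),
         AA = list(c("A", "A")),
         BB = list(c("B", "B")),
         AB = list(c("A", "B"), c("B", "A")),
         missing = list(c("A", "A"), c("A", "B"), c("B", "A"), c("B", "B")))
}

# all (father-transmitted, father-untransmitted, mother-transmitted,
# mother-untransmitted) allele 4-tuples consistent with one site
site_solutions <- function(gf, gm_, gc) {
  child_ok <- function(a, b) {
    if (is.na(gc)) return(TRUE)
    paste(sort(c(a, b)), collapse = "") ==
      switch(gc, AA = "AA", AB = "AB", BB = "BB")
  }
  sol <- list()
  for (f in ordered_pairs(gf)) for (m in ordered_pairs(gm_)) {
    if (child_ok(f[1], m[1]))
      sol[[length(sol) + 1]] <- c(f, m)
  }
  unique(sol)
}

#' Phase one SNP cluster in a parent-parent-child trio
#'
#' Enumerates, per site, every assignment of the four parental haplotype
#' slots consistent with the three genotypes (the child receiving one
#' haplotype from each parent), then combines sites. When the
#' configuration is unique it is returned outright; otherwise the
#' combination minimizing the number of distinct haplotypes is returned,
#' unresolved slots are masked with dots, and the result is flagged
#' ambiguous. Haplotypes are labelled H1, H2, ... in order of first
#' appearance walking father, mother, then child.
#'
#' @param trio a [trio_genotypes()] / [new_trio_genotypes()] object with at
#'   most ~25 SNPs.
#' @param max_combinations cap on global combinations enumerated during
#'   distinct-haplotype minimization.
#' @return object of class `cluster_haplotypes`: `haplotypes` (named H1..),
#'   `assignment` (two labels per individual), `transmitted` (per-parent
#'   label), `ambiguous_sites`, `ambiguous`.
#' @export
phase_trio_cluster <- function(trio, max_combinations = 4096) {
  k <- length(trio$snp_id)
  sols <- vector("list", k)
  for (s in seq_len(k)) {
    sols[[s]] <- site_solutions(trio$father[s], trio$mother[s], trio$child[s])
    if (!length(sols[[s]]))
      abort("Mendelian inconsistency at SNP %s", trio$snp_id[s])
  }
  n_sol <- lengths(sols)
  ambiguous_sites <- trio$snp_id[n_sol > 1]
  # representative configuration: unique when every site is unique,
  # otherwise the combination with fewest distinct haplotypes
  chosen <- vapply(sols, function(s) s[[1]], character(4))
  if (any(n_sol > 1) && prod(n_sol) <= max_combinations) {
    grids <- do.call(expand.grid, lapply(n_sol, seq_len))
    best <- NULL; best_n <- Inf; best_key <- ""
    for (r in seq_len(nrow(grids))) {
      cfg <- vapply(seq_len(k), function(s) sols[[s]][[grids[r, s]]],
                    character(4))
      haps <- apply(cfg, 1, paste, collapse = "")
      nd <- length(unique(haps))
      key <- paste(haps, collapse = "|")
      if (nd < best_n || (nd == best_n && key < best_key)) {
        best <- cfg; best_n <- nd; best_key <- key
      }
    }
    chosen <- best
  }
  # mask slots that differ across per-site solutions
  masked <- chosen
  for (s in which(n_sol > 1)) {
    slot_vals <- vapply(sols[[s]], identity, character(4))
    for (slot in 1:4)
      if (length(unique(slot_vals[slot, ])) > 1) masked[slot, s] <- "."
  }
  if (k == 1) masked <- matrix(masked, nrow = 4)
  haps <- apply(masked, 1, paste, collapse = "")
  names(haps) <- c("FT", "FU", "MT", "MU")
  # label by first appearance walking father, mother, child (position-major
  # strings; each parent's pair visited in lexicographic order)
  walk <- c(sort(haps[c("FT", "FU")]), sort(haps[c("MT", "MU")]),
            haps["FT"], haps["MT"])
  uniq <- unique(unname(walk))
  labels <- stats::setNames(paste0("H", seq_along(uniq)), uniq)
  hap_strings <- stats::setNames(uniq, labels[uniq])
  lab <- function(h) unname(labels[h])
  structure(list(
    cluster_id = trio$cluster_id, snp_id = trio$snp_id,
    haplotypes = hap_strings,
    assignment = list(father = lab(sort(haps[c("FT", "FU")])),
                      mother = lab(sort(haps[c("MT", "MU")])),
                      child = lab(unname(haps[c("FT", "MT")]))),
    slots = stats::setNames(lab(haps), names(haps)),
    transmitted = c(father = lab(haps[["FT"]]), mother = lab(haps[["MT"]])),
    ambiguous_sites = ambiguous_sites,
    ambiguous = length(ambiguous_sites) > 0), class = "cluster_haplotypes")
}

#' @export
print.cluster_haplotypes <- function(x, ...) {
  cat(sprintf("<cluster_haplotypes> %s: %d SNPs, %d haplotypes%s\n",
              x$cluster_id, length(x$snp_id), length(x$haplotypes),
              if (x$ambiguous) " (ambiguous)" else ""))
  for (h in names(x$haplotypes)) cat(" ", h, x$haplotypes[[h]], "\n")
  invisible(x)
}

#' Detect recombination between adjacent phased clusters
#'
#' Tracks, for each parent, which parental chromosome (phase 1 or 2) was
#' transmitted to the child in each cluster, and emits an event wherever
#' the phase switches between consecutive informative clusters. Ambiguous
#' clusters and clusters where the parent is homozygous never generate
#' events. Inter-cluster phase requires a supplied parental linkage phase
#' (`parental_phase`); without one the minimum-switch (parsimony)
#' assignment for a single trio is degenerate, yields no events, and the
#' result is marked `method = "parsimony"`.
#'
#' @param phasings list of [phase_trio_cluster()] results in map order.
#' @param parental_phase optional data frame with `cluster_id`, `parent`
#'   (`"father"`/`"mother"`) and `phase1` (the haplotype string of
#'   parental chromosome 1 in that cluster).
#' @return data frame of events (`parent`, `from_cluster`, `to_cluster`)
#'   with attribute `method` (`"supplied_phase"` or `"parsimony"`).
#' @export
detect_recombination <- function(phasings, parental_phase = NULL) {
  empty <- data.frame(parent = character(0), from_cluster = character(0),
                      to_cluster = character(0), stringsAsFactors = FALSE)
  if (is.null(parental_phase)) {
    attr(empty, "method") <- "parsimony"
    return(empty)
  }
  events <- list()
  for (parent in c("father", "mother")) {
    slots <- if (parent == "father") c("FT", "FU") else c("MT", "MU")
    phase_seq <- vapply(phasings, function(ph) {
      if (ph$ambiguous) return(NA_integer_)
      two <- unname(ph$haplotypes[ph$slots[slots]])
      if (two[1] == two[2]) return(NA_integer_)  # homozygous: untrackable
      p1 <- parental_phase$phase1[parental_phase$cluster_id == ph$cluster_id &
                                    parental_phase$parent == parent]
      if (!length(p1)) return(NA_integer_)
      trans <- unname(ph$haplotypes[ph$transmitted[[parent]]])
      if (trans == p1[1]) 1L else if (two[two != trans][1] == p1[1]) 2L
      else NA_integer_
    }, integer(1))
    inf <- which(!is.na(phase_seq))
    if (length(inf) >= 2) {
      for (i in seq_len(length(inf) - 1)) {
        a <- inf[i]; b <- inf[i + 1]
        if (phase_seq[a] != phase_seq[b])
          events[[length(events) + 1]] <- data.frame(
            parent = parent,
            from_cluster = phasings[[a]]$cluster_id,
            to_cluster = phasings[[b]]$cluster_id,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(events)) do.call(rbind, events) else empty
  attr(out, "method") <- "supplied_phase"
  out
}
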