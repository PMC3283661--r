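# Readers/writers for the auxiliary on-disk tracks: copy-number BED,
# gene-model GFF3, cDNA alignment-block BED, genetic-map anchor TSV and
# pedigree TSV. Coordinates are 1-based inclusive internally; BED I/O
# converts to/from 0-based half-open.

ANCHOR_KINDS <- c("GDsnp", "RosCOS", "SSR", "candidate_gene")

#' Read a copy-number track from BED
#'
#' BED4 with the region's average copy number in the name column. Intervals
#' are converted to 1-based inclusive and must be non-overlapping per LG.
#'
#' @param path BED file.
#' @return data frame with columns `lg`, `start`, `end`, `cn`.
#' @export
read_copy_number <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(lg = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   cn = suppressWarnings(as.numeric(gr$name)),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$cn)) || any(df$cn < 0))
    abort("copy-number values must be non-negative numbers")
  check_disjoint(df, "copy-number")
  df[order(df$lg, df$start), ]
}

check_disjoint <- function(df, what) {
  for (lg in unique(df$lg)) {
    d <- df[df$lg == lg, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      abort("%s intervals overlap on %s", what, lg)
  }
  invisible(TRUE)
}

#' Write a copy-number track to BED
#'
#' @param track data frame with `lg`, `start`, `end`, `cn` (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_copy_number <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", track$lg,
                     as.integer(track$start) - 1L, as.integer(track$end),
                     format(track$cn, trim = TRUE, digits = 15)), path)
  invisible(path)
}

#' Read exon intervals from a GFF3 gene-model file
#'
#' Keeps features of type `exon` (all features if none are typed `exon`).
#'
#' @param path GFF3 file.
#' @return data frame with `lg`, `start`, `end` (1-based inclusive).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(gr$type == "exon")) gr <- gr[gr$type == "exon"]
  data.frame(lg = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read cDNA alignment blocks from BED
#'
#' @param path BED file of aligned blocks (any strand; coordinates are
#'   projected to the forward strand, which BED intervals already are).
#' @return data frame with `lg`, `start`, `end` (1-based inclusive).
#' @export
read_cdna_blocks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(lg = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write exon intervals as GFF3
#' @param exons data frame with `lg`, `start`, `end` and optional `gene_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exons_gff3 <- function(exons, path) {
  ids <- exons$gene_id %||% sprintf("exon%06d", seq_len(nrow(exons)))
  writeLines(c("##gff-version 3",
               sprintf("%s\tsnparraydesign\texon\t%d\t%d\t.\t+\t.\tID=%s",
                       exons$lg, as.integer(exons$start),
                       as.integer(exons$end), ids)), path)
  invisible(path)
}

#' Write intervals as BED
#' @param df data frame with `lg`, `start`, `end` (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d", df$lg, as.integer(df$start) - 1L,
                     as.integer(df$end)), path)
  invisible(path)
}

#' Read genetic-map anchors from TSV
#'
#' Columns: `marker_id`, `kind` (one of GDsnp, RosCOS, SSR, candidate_gene),
#' `lg`, `pos`, `cM` (may be NA for physically placed anchors). GDsnp
#' anchors must carry a cM position.
#'
#' @param path TSV file.
#' @return data frame of anchors.
#' @export
read_anchors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("marker_id", "kind", "lg", "pos", "cM")
  if (!all(need %in% names(df)))
    abort("anchor table must have columns: %s", paste(need, collapse = ", "))
  if (any(!df$kind %in% ANCHOR_KINDS))
    abort("unknown anchor kind: %s",
          paste(setdiff(unique(df$kind), ANCHOR_KINDS), collapse = ", "))
  if (any(df$kind == "GDsnp" & is.na(df$cM)))
    abort("GDsnp anchors must carry a cM position")
  df$pos <- as.integer(df$pos)
  df
}

#' Write genetic-map anchors to TSV
#' @param anchors anchor data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pedigree from TSV
#'
#' Columns `individual`, `mother`, `father` (`NA` for unknown parents).
#' Fails if any individual is its own ancestor.
#'
#' @param path TSV file.
#' @return data frame pedigree.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("individual", "mother", "father")
  if (!all(need %in% names(df)))
    abort("pedigree must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$individual)) abort("duplicate individuals in pedigree")
  parent_of <- function(id) {
    r <- df[df$individual == id, ]
    if (!nrow(r)) character(0) else stats::na.omit(c(r$mother, r$father))
  }
  for (id in df$individual) {
    seen <- character(0); frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier) abort("%s is its own ancestor", id)
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(lapply(frontier, parent_of)), seen)
    }
  }
  df
}

#' Write a pedigree to TSV
#' @param pedigree pedigree data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
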