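# Candidate SNP container.
#
# A `snp_set` holds biallelic SNP candidates together with per-accession
# read evidence: a data frame of per-SNP fields plus aligned matrices of
# reference/alternate read counts and phred-scale allele qualities
# (one row per SNP, one column per accession). Qualities are NA wherever
# the corresponding read count is zero.

#' Construct a candidate SNP set
#'
#' @param snps data frame with columns `id`, `lg`, `pos`, `ref`, `alt` and
#'   optionally `adt` (Assay Design Tool score in `[0, 1]`) and `maf`
#'   (minor allele frequency in `[0, 0.5]`); missing optional columns are
#'   filled with `NA`.
#' @param reads_ref,reads_alt integer matrices (SNP x accession) of read
#'   counts supporting the reference/alternate allele.
#' @param qual_ref,qual_alt numeric matrices of phred-scale allele
#'   qualities, `NA` where the matching read count is zero. Optional.
#' @return an object of class `snp_set`.
#' @export
snp_set <- function(snps, reads_ref, reads_alt, qual_ref = NULL, qual_alt = NULL) {
  need <- c("id", "lg", "pos", "ref", "alt")
  if (!all(need %in% names(snps)))
    abort("snps must have columns: %s", paste(need, collapse = ", "))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(snps$adt)) snps$adt <- NA_real_
  if (is.null(snps$maf)) snps$maf <- NA_real_
  snps <- snps[c(need, "adt", "maf")]
  snps$pos <- as.integer(snps$pos)
  rownames(snps) <- NULL
  if (anyDuplicated(snps$id)) abort("duplicate SNP ids")
  if (any(!is_acgt(snps$ref)) || any(!is_acgt(snps$alt)))
    abort("alleles must be one of A/C/G/T")
  if (any(snps$ref == snps$alt)) abort("ref and alt alleles must differ")
  reads_ref <- as.matrix(reads_ref); reads_alt <- as.matrix(reads_alt)
  if (!identical(dim(reads_ref), dim(reads_alt)) ||
      nrow(reads_ref) != nrow(snps))
    abort("read-count matrices must be SNP x accession and match snps")
  if (any(reads_ref < 0) || any(reads_alt < 0)) abort("negative read counts")
  if (is.null(colnames(reads_ref))) abort("read matrices need accession names")
  if (is.null(qual_ref)) qual_ref <- matrix(NA_real_, nrow(reads_ref), ncol(reads_ref),
                                            dimnames = dimnames(reads_ref))
  if (is.null(qual_alt)) qual_alt <- matrix(NA_real_, nrow(reads_alt), ncol(reads_alt),
                                            dimnames = dimnames(reads_alt))
  rownames(reads_ref) <- rownames(reads_alt) <- snps$id
  rownames(qual_ref) <- rownames(qual_alt) <- snps$id
  structure(list(snps = snps, reads_ref = reads_ref, reads_alt = reads_alt,
                 qual_ref = qual_ref, qual_alt = qual_alt),
            class = "snp_set")
}

#' @export
`[.snp_set` <- function(x, i, ...) {
  structure(list(snps = x$snps[i, , drop = FALSE],
                 reads_ref = x$reads_ref[i, , drop = FALSE],
                 reads_alt = x$reads_alt[i, , drop = FALSE],
                 qual_ref = x$qual_ref[i, , drop = FALSE],
                 qual_alt = x$qual_alt[i, , drop = FALSE]),
            class = "snp_set")
}

#' Number of candidates in a SNP set
#' @param x a `snp_set`.
#' @return integer count.
#' @export
n_snps <- function(x) nrow(x$snps)

#' Accession names carried by a SNP set
#' @param x a `snp_set`.
#' @return character vector.
#' @export
accessions <- function(x) colnames(x$reads_ref)

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("<snp_set> %d candidates x %d accessions on %d LG(s)\n",
              n_snps(x), length(accessions(x)), length(unique(x$snps$lg))))
  invisible(x)
}

#' Read candidate SNPs from VCF
#'
#' Reads biallelic SNP records with per-sample allele depths (`AD`) and,
#' when present, per-allele qualities (`QR`/`QA` FORMAT fields) and `MAF`
#' and `ADT` INFO fields. Multi-allelic records and indels are rejected;
#' the number rejected is attached as attribute `n_rejected`.
#'
#' @param path VCF file.
#' @param accession_order optional character vector giving the column order
#'   to impose on the evidence matrices (must be a permutation of the VCF
#'   sample names).
#' @return a [snp_set()] with attribute `n_rejected`.
#' @export
read_snp_candidates <- function(path, accession_order = NULL) {
  if (!file.exists(path)) abort("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- !is.na(ref) & !is.na(alt) & is_acgt(ref) & is_acgt(alt)
  n_rejected <- sum(!ok)
  fmt <- v@gt[, "FORMAT"]
  no_ad <- !grepl("(^|:)AD(:|$)", fmt)
  if (any(no_ad & ok)) {
    bad <- which(no_ad & ok)[1]
    abort("per-sample allele-depth (AD) field missing for record %s:%s",
          fix[bad, "CHROM"], fix[bad, "POS"])
  }
  grab <- function(el, as_num = FALSE) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = as_num)
    m[ok, , drop = FALSE]
  }
  ad <- grab("AD")
  rr <- matrix(suppressWarnings(as.integer(sub(",.*", "", ad))),
               nrow(ad), ncol(ad), dimnames = dimnames(ad))
  ra <- matrix(suppressWarnings(as.integer(sub(".*,", "", ad))),
               nrow(ad), ncol(ad), dimnames = dimnames(ad))
  rr[is.na(rr)] <- 0L; ra[is.na(ra)] <- 0L
  has_q <- grepl("(^|:)QR(:|$)", fmt[1])
  qr <- if (has_q) grab("QR", TRUE) else NULL
  qa <- if (has_q) grab("QA", TRUE) else NULL
  info_num <- function(tag) {
    val <- suppressWarnings(as.numeric(vcfR::extract.info(v, tag)))
    val[ok]
  }
  ids <- fix[ok, "ID"]
  lg <- fix[ok, "CHROM"]; pos <- as.integer(fix[ok, "POS"])
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- sprintf("%s_%07d", lg[miss_id], pos[miss_id])
  snps <- data.frame(id = ids, lg = lg, pos = pos,
                     ref = ref[ok], alt = alt[ok],
                     adt = info_num("ADT"), maf = info_num("MAF"),
                     stringsAsFactors = FALSE)
  ss <- snp_set(snps, rr, ra, qr, qa)
  if (!is.null(accession_order)) {
    if (!setequal(accession_order, accessions(ss)))
      abort("accession_order must be a permutation of the VCF sample names")
    ss$reads_ref <- ss$reads_ref[, accession_order, drop = FALSE]
    ss$reads_alt <- ss$reads_alt[, accession_order, drop = FALSE]
    ss$qual_ref <- ss$qual_ref[, accession_order, drop = FALSE]
    ss$qual_alt <- ss$qual_alt[, accession_order, drop = FALSE]
  }
  attr(ss, "n_rejected") <- n_rejected
  ss
}

#' Write candidate SNPs to VCF
#'
#' Emits a VCF v4.2 file with `AD`, `QR`, `QA` FORMAT fields and `MAF`,
#' `ADT` INFO fields; the exact inverse of [read_snp_candidates()].
#'
#' @param ss a [snp_set()].
#' @param path output path.
#' @param lg_lengths optional named vector used for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_candidate_vcf <- function(ss, path, lg_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=snparraydesign",
           '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency in the detection panel">',
           '##INFO=<ID=ADT,Number=1,Type=Float,Description="Assay design score">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele read depths (ref,alt)">',
           '##FORMAT=<ID=QR,Number=1,Type=Float,Description="Reference allele quality">',
           '##FORMAT=<ID=QA,Number=1,Type=Float,Description="Alternate allele quality">')
  if (!is.null(lg_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(lg_lengths), as.integer(lg_lengths)))
  acc <- accessions(ss)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", acc), collapse = "\t"))
  s <- ss$snps
  info <- paste0(ifelse(is.na(s$maf), "", sprintf("MAF=%.6g", s$maf)),
                 ifelse(is.na(s$maf) | is.na(s$adt), "", ";"),
                 ifelse(is.na(s$adt), "", sprintf("ADT=%.6g", s$adt)))
  info[info == ""] <- "."
  fq <- function(q) ifelse(is.na(q), ".", format(q, trim = TRUE))
  cells <- matrix("", n_snps(ss), length(acc))
  for (j in seq_along(acc)) {
    cells[, j] <- paste0(ss$reads_ref[, j], ",", ss$reads_alt[, j], ":",
                         fq(ss$qual_ref[, j]), ":", fq(ss$qual_alt[, j]))
  }
  body <- do.call(paste, c(list(s$lg, s$pos, s$id, s$ref, s$alt, ".", "PASS",
                                info, "AD:QR:QA"),
                           asplit(cells, 2), list(sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}
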