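# Stage 1 rejection rules and Stage 2 exonic restriction.

genome10k <- tiny_genome(c(LG01 = 10000), ambiguity = list(LG01 = 5000))

clean_pair <- function(pos = c(2000L, 8000L)) {
  make_ss(data.frame(id = paste0("s", seq_along(pos)), lg = "LG01", pos = pos,
                     ref = "A", alt = "G"))
}

test_that("depth statistics use the population SD over total depth", {
  ss <- make_ss(data.frame(id = c("a", "b", "c"), lg = "LG01",
                           pos = c(1000L, 2000L, 3000L)), n_acc = 1,
                reads = 5)  # 5 + 5 per candidate
  expect_equal(mean_sd_allele_depth(ss), c(mean = 10, sd = 0))
  ss2 <- ss[1:2]
  ss2$reads_ref[, 1] <- c(2L, 4L); ss2$reads_alt[, 1] <- c(2L, 4L)
  expect_equal(mean_sd_allele_depth(ss2), c(mean = 6, sd = 2))
  expect_error(mean_sd_allele_depth(ss[1]), "at least 2")
})

test_that("positional rules fire exactly at their boundaries", {
  at <- function(pos) {
    ss <- make_ss(data.frame(id = c("probe", "far"), lg = "LG01",
                             pos = c(pos, 2000L)))
    filter_stage1(ss, genome10k)$outcomes$violated_rules[1]
  }
  expect_equal(at(30L), "1")    # deep inside the end margin
  expect_equal(at(60L), "1")    # 60th base is still within the margin
  expect_equal(at(61L), "")     # 61st base is out
  expect_equal(at(9940L), "")   # len - 60 is out of the tail margin
  expect_equal(at(9941L), "1")  # len - 59 is within it
})

test_that("the ambiguity rule scans a +/-60 bp window", {
  ss <- make_ss(data.frame(id = paste0("s", 1:3), lg = "LG01",
                           pos = c(4940L, 4939L, 5060L)))
  M <- snparraydesign:::stage1_rule_matrix(ss, genome10k)
  expect_equal(unname(M[, 2]), c(TRUE, FALSE, TRUE))
})

test_that("adjacent candidates within 50 bp reject each other", {
  ss <- make_ss(data.frame(id = paste0("s", 1:4), lg = "LG01",
                           pos = c(2000L, 2040L, 4000L, 4051L)))
  fs <- filter_stage1(ss, genome10k)
  expect_equal(fs$outcomes$violated_rules, c("3", "3", "", ""))
})

test_that("flanking copy number above two rejects; missing track means copy 1", {
  cn <- data.frame(lg = "LG01", start = 1900L, end = 2200L, cn = 3)
  ss <- clean_pair(c(2000L, 8000L))
  fs <- filter_stage1(ss, genome10k, cn)
  expect_equal(fs$outcomes$violated_rules, c("4", ""))
  expect_equal(filter_stage1(ss, genome10k, NULL)$tally[["rule4"]], 0)
  # length-weighted averaging: under half the flank at copy 3 -> mean < 2
  cn2 <- data.frame(lg = "LG01", start = 2001L, end = 2060L, cn = 3)
  expect_equal(filter_stage1(ss, genome10k, cn2)$outcomes$violated_rules[1], "")
})

test_that("allele-quality and read-support rules follow their wording", {
  ss <- clean_pair()
  ss$qual_alt[1, ] <- 15          # best alt quality below 20
  fs <- filter_stage1(ss, genome10k)
  expect_equal(fs$outcomes$violated_rules, c("5", ""))
  ss <- clean_pair()
  ss$qual_alt[1, 1] <- 19; ss$qual_alt[1, 2:4] <- 30  # one good accession saves it
  expect_equal(filter_stage1(ss, genome10k)$outcomes$violated_rules[1], "")
  # rule 6: half the accessions with a single-read allele
  ss <- clean_pair()
  ss$reads_ref[1, 1:2] <- 1L
  expect_equal(filter_stage1(ss, genome10k)$outcomes$violated_rules[1], "6")
  ss$reads_ref[1, 1:2] <- c(1L, 2L)  # only a quarter fail: below half
  expect_equal(filter_stage1(ss, genome10k)$outcomes$violated_rules[1], "")
})

test_that("depth outliers beyond mean + 3 SD of total depth are rejected", {
  df <- data.frame(id = paste0("s", 1:21), lg = "LG01",
                   pos = seq(1000L, 9000L, length.out = 21))
  ss <- make_ss(df, n_acc = 1, reads = 5)
  ss$reads_alt[21, 1] <- 195L  # total 200 vs a field of 10s
  fs <- filter_stage1(ss, genome10k)
  expect_equal(fs$tally[["rule7"]], 1)
  expect_true(grepl("7", fs$outcomes$violated_rules[21]))
})

test_that("A/T and C/G transversions are rejected unless disabled", {
  ss <- make_ss(data.frame(id = paste0("s", 1:4), lg = "LG01",
                           pos = c(1000L, 3000L, 5500L, 8000L),
                           ref = c("A", "C", "G", "A"),
                           alt = c("T", "G", "C", "G")))
  fs <- filter_stage1(ss, genome10k)
  expect_equal(fs$outcomes$violated_rules, c("8", "8", "8", ""))
  loose <- stage1_params(transversion_filter = FALSE)
  expect_equal(filter_stage1(ss, genome10k, params = loose)$tally[["rule8"]], 0)
})

test_that("stage 1 output partitions the input and tallies every violation", {
  tal <- filter_stage1(clean_pair()[0], genome10k)$tally
  expect_equal(as.integer(tal), rep(0L, 8))
  ss <- clean_pair()
  fs <- filter_stage1(ss, genome10k)
  expect_identical(fs$kept$snps$id, ss$snps$id)  # nothing violated
  expect_true(all(fs$outcomes$kept == (fs$outcomes$violated_rules == "")))
})

test_that("rule evaluation is order-independent", {
  cfg <- sim_config(n_lg = 1, lg_length = 1e5, seed = 21)
  sg <- simulate_genome(cfg)
  sim <- simulate_accessions_and_calls(cfg, sg, violation_fraction = 0.05)
  fs1 <- filter_stage1(sim$snps, sg$genome, sg$cn)
  set.seed(99)
  perm <- sample(n_snps(sim$snps))
  fs2 <- filter_stage1(sim$snps[perm], sg$genome, sg$cn)
  o1 <- fs1$outcomes[order(fs1$outcomes$snp_id), ]
  o2 <- fs2$outcomes[order(fs2$outcomes$snp_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("injected violations are recovered exactly from a small simulation", {
  cfg <- sim_config(n_lg = 1, lg_length = 2e5, seed = 9)
  sg <- simulate_genome(cfg)
  sim <- simulate_accessions_and_calls(cfg, sg, violation_fraction = 0.03)
  fs <- filter_stage1(sim$snps, sg$genome, sg$cn)
  led <- sim$truth$violations
  expect_true(all(fs$tally[paste0("rule", sort(unique(led$rule)))] > 0))
  for (i in seq_len(nrow(fs$outcomes))) {
    expected <- sort(led$rule[led$snp_id == fs$outcomes$snp_id[i]])
    got <- if (fs$outcomes$violated_rules[i] == "") integer(0)
           else as.integer(strsplit(fs$outcomes$violated_rules[i], ",")[[1]])
    expect_identical(got, as.integer(expected))
  }
})

test_that("exon spaces merge overlapping and abutting intervals", {
  sp <- build_exon_space(data.frame(lg = "LG01", start = 100L, end = 200L),
                         data.frame(lg = "LG01", start = c(150L, 201L),
                                    end = c(300L, 350L)))
  expect_equal(sp$intervals,
               data.frame(lg = "LG01", start = 100L, end = 350L))
  expect_equal(nrow(build_exon_space()$intervals), 0)
  expect_error(build_exon_space(data.frame(lg = "L", start = 10L, end = 5L)),
               "start > end")
})

test_that("exon membership matches brute force on random intervals", {
  set.seed(42)
  iv <- data.frame(lg = sample(c("LG01", "LG02"), 100, TRUE),
                   start = sample.int(50000, 100))
  iv$end <- iv$start + sample.int(500, 100)
  sp <- build_exon_space(iv)
  lg <- sample(c("LG01", "LG02"), 2000, TRUE)
  pos <- sample.int(51000, 2000, replace = TRUE)
  expect_identical(in_exon_space(sp, lg, pos), brute_member(iv, lg, pos))
})

test_that("stage 2 keeps exonic SNPs in order with inclusive bounds", {
  sp <- build_exon_space(data.frame(lg = "LG01", start = 1000L, end = 2000L))
  ss <- make_ss(data.frame(id = paste0("s", 1:4), lg = "LG01",
                           pos = c(999L, 1000L, 2000L, 2001L)))
  kept <- filter_stage2(ss, sp)
  expect_identical(kept$snps$id, c("s2", "s3"))
  expect_equal(n_snps(filter_stage2(ss, build_exon_space())), 0)
})

test_that("stage 1 and stage 2 are independent commuting predicates", {
  cfg <- sim_config(n_lg = 1, lg_length = 1e5, seed = 31)
  sg <- simulate_genome(cfg)
  sim <- simulate_accessions_and_calls(cfg, sg, violation_fraction = 0.05)
  sp <- build_exon_space(sg$gene_models, sg$cdna)
  a <- filter_stage2(filter_stage1(sim$snps, sg$genome, sg$cn)$kept, sp)
  pre <- filter_stage2(sim$snps, sp)
  # rule 3/7 statistics are defined over the full candidate set, so the
  # commuted order applies stage 1 verdicts from the full set
  keep_ids <- filter_stage1(sim$snps, sg$genome, sg$cn)$outcomes
  expect_identical(a$snps$id,
                   intersect(pre$snps$id, keep_ids$snp_id[keep_ids$kept]))
})
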