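# Focal points, MAF binning, cluster selection and manifest assembly.

test_that("MAF bins follow the half-open published ranges", {
  expect_equal(maf_bin(c(0.05, 0.1, 0.101, 0.2, 0.35, 0.401, 0.5)),
               c(0.1, 0.1, 0.2, 0.2, 0.4, 0.5, 0.5))
  expect_true(is.na(maf_bin(0.005)))
  expect_equal(maf_bin(0.01), 0.1)
  expect_error(maf_bin(0.6), "outside")
  expect_error(maf_bin(-0.1), "outside")
  expect_error(maf_bin(NA_real_), "missing MAF")
})

test_that("focal points cover primaries and fill gaps midpoint-first", {
  lens <- c(LG01 = 1000000L)
  prim <- rbind(anchor("p1", "LG01", 100000, 0), anchor("p2", "LG01", 300000, 1),
                anchor("p3", "LG01", 500000, 2))
  fp <- designate_focal_points(prim, NULL, lens)
  expect_equal(nrow(fp$focal_points), 3)
  # no genetic gaps to fill; the bare far end of the LG is reported
  expect_false(any(fp$gaps$note == "no_secondary_anchor"))
  expect_true(any(fp$gaps$note == "no_anchor_near_lg_end"))

  prim2 <- rbind(anchor("p1", "LG01", 100000, 0), anchor("p2", "LG01", 900000, 8))
  sec <- rbind(anchor("s2", "LG01", 300000, kind = "RosCOS"),
               anchor("s4", "LG01", 500000, kind = "RosCOS"),
               anchor("s6", "LG01", 700000, kind = "RosCOS"))
  fp2 <- designate_focal_points(prim2, sec, lens)
  # 8 cM gap: midpoint (4 cM) first, then 0-4 and 4-8 sub-gaps
  expect_equal(sort(fp2$focal_points$marker_id), c("p1", "p2", "s2", "s4", "s6"))
  cms <- sort(fp2$focal_points$cM)
  expect_true(all(diff(cms) <= 3))
  expect_equal(nrow(fp2$gaps), 0)  # both ends covered, all gaps filled
})

test_that("unfillable gaps and bare ends are reported, not guessed", {
  lens <- c(LG01 = 1000000L)
  prim <- rbind(anchor("p1", "LG01", 300000, 0), anchor("p2", "LG01", 900000, 5))
  fp <- designate_focal_points(prim, NULL, lens)
  expect_true(any(fp$gaps$note == "no_secondary_anchor"))
  expect_true(any(fp$gaps$note == "no_anchor_near_lg_start"))
})

test_that("full windows yield ten-SNP clusters including the focal SNP", {
  f <- anchor("f", "LG01", 50000, 1)
  f$window_start <- 1L; f$window_end <- 100000L
  cand <- data.frame(id = sprintf("c%02d", 1:10), lg = "LG01",
                     pos = seq(10000L, 37000L, by = 3000L),
                     ref = "A", alt = "G", adt = 0.9,
                     maf = rep(c(0.05, 0.15, 0.25, 0.35, 0.45), each = 2))
  cl <- select_cluster(f, cand)
  expect_equal(nrow(cl$members), 9)  # 9 members + the focal SNP = 10
  expect_true(cl$focal_is_snp)
  expect_equal(sort(table(cl$members$bin)), sort(table(cl$members$bin)))
  expect_true(all(table(cl$members$bin) <= 2))
})

test_that("the 2 kb spacing rule excludes near neighbours", {
  f <- anchor("f", "LG01", 50000, 1)
  f$window_start <- 1L; f$window_end <- 100000L
  cand <- data.frame(id = c("a", "b"), lg = "LG01", pos = c(20000L, 21000L),
                     ref = "A", alt = "G", adt = 0.9, maf = c(0.25, 0.28))
  cl <- select_cluster(f, cand)
  expect_equal(nrow(cl$members), 1)
})

test_that("selection matches the exhaustive oracle on small windows", {
  params <- design_params()
  for (seed in 1:40) {
    w <- make_window(n = sample(4:12, 1), seed = seed)
    cl <- select_cluster(w$focal, w$cand, params)
    got <- cluster_objective(cl, w$focal$pos)
    want <- oracle_cluster(w$cand, w$focal$pos, params, params$cluster_max - 1)
    expect_equal(got[1], want[1], info = sprintf("seed %d count", seed))
    expect_equal(got[2], want[2], info = sprintf("seed %d bins", seed))
    expect_equal(got[3], want[3], info = sprintf("seed %d mindist", seed))
    # hard constraints
    expect_true(all(cl$members$pos >= w$focal$window_start &
                      cl$members$pos <= w$focal$window_end))
    if (nrow(cl$members))
      expect_true(all(table(cl$members$bin) <= params$per_bin))
    pts <- sort(c(cl$members$pos, w$focal$pos))
    if (length(pts) > 1) expect_true(min(diff(pts)) >= params$min_spacing)
  }
})

test_that("widening the window never shrinks a cluster", {
  for (seed in c(3, 7, 11)) {
    set.seed(seed)
    lg_len <- 1000000L
    cand <- data.frame(id = sprintf("c%03d", 1:120), lg = "LG01",
                       pos = sort(sample.int(lg_len, 120)), ref = "A",
                       alt = "G", adt = 0.9,
                       maf = round(runif(120, 0.01, 0.5), 3))
    sizes <- vapply(c(25000L, 50000L, 100000L), function(hw) {
      p <- design_params(window_halfwidth = hw)
      f <- anchor("f", "LG01", 500000, 1)
      f$window_start <- 500000L - hw; f$window_end <- 500000L + hw
      inw <- cand[cand$pos >= f$window_start & cand$pos <= f$window_end, ]
      nrow(select_cluster(f, inw, p)$members)
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("gene clusters maximize the minimum pairwise distance", {
  genes <- data.frame(gene_id = "g1", lg = "LG01", start = 1000L, end = 2000L)
  cand <- data.frame(id = c("a", "b"), lg = "LG01", pos = c(1100L, 1200L),
                     maf = c(0.2, 0.3))
  cl <- design_gene_clusters(genes, cand)
  expect_equal(nrow(cl[[1]]$members), 2)

  cand5 <- data.frame(id = sprintf("s%d", 1:5), lg = "LG01",
                      pos = c(1000L, 1010L, 1500L, 1990L, 2000L),
                      maf = 0.2)
  cl5 <- design_gene_clusters(data.frame(gene_id = "g2", lg = "LG01",
                                         start = 900L, end = 2100L), cand5)
  got <- min(diff(sort(cl5[[1]]$members$pos)))
  expect_equal(got, oracle_maxmin(cand5$pos, 4))

  expect_length(design_gene_clusters(genes, cand5[0, ]), 0)
})

test_that("random gene clusters match brute force for up to 20 SNPs", {
  for (seed in 1:15) {
    set.seed(seed + 100)
    n <- sample(5:20, 1)
    pos <- sort(sample.int(50000, n)) + 10000L
    cand <- data.frame(id = sprintf("s%02d", seq_len(n)), lg = "LG01",
                       pos = pos, maf = 0.2)
    cl <- design_gene_clusters(data.frame(gene_id = "g", lg = "LG01",
                                          start = min(pos), end = max(pos)),
                               cand)
    k <- min(4, n)
    got <- if (k < 2) Inf else min(diff(sort(cl[[1]]$members$pos)))
    expect_equal(got, oracle_maxmin(pos, k))
  }
})

test_that("the design-score filter discards strictly-below scores only", {
  df <- data.frame(id = c("a", "b", "c"), adt = c(0.7, 0.69, 0.95))
  kept <- apply_adt_filter(df)
  expect_identical(kept$id, c("a", "c"))
  set.seed(5)
  scores <- runif(200, 0.3, 1)
  df2 <- data.frame(id = seq_along(scores), adt = scores)
  expect_equal(nrow(apply_adt_filter(df2)), sum(scores >= 0.7))
  expect_error(apply_adt_filter(data.frame(id = "x", adt = NA_real_)),
               "missing")
})

test_that("manifests de-duplicate by position with source precedence", {
  f <- anchor("gd1", "LG01", 50000, 1)
  f$window_start <- 1L; f$window_end <- 100000L
  cand <- data.frame(id = c("w1", "w2"), lg = "LG01", pos = c(20000L, 30000L),
                     ref = "A", alt = "G", adt = 0.9, maf = c(0.2, 0.3))
  cl <- select_cluster(f, cand)
  dup_extra <- data.frame(id = "v1", lg = "LG01", pos = 20000L)  # same spot as w1
  new_extra <- data.frame(id = "v2", lg = "LG01", pos = 90000L)
  man <- assemble_array(list(cl), list(), rbind(dup_extra, new_extra))
  expect_equal(unname(man$totals[["total"]]), 4)  # gd1, w1, w2, v2
  expect_equal(unname(man$totals[["validated"]]), 1)
  expect_false("v1" %in% man$manifest$id)
  expect_equal(man$manifest$source[man$manifest$pos == 20000],
               "focal_window")
  empty <- assemble_array(list())
  expect_equal(unname(empty$totals[["total"]]), 0)
})

test_that("the design summary divides lengths by cluster counts", {
  man <- data.frame(id = sprintf("s%d", 1:20), lg = "LG01",
                    pos = seq(1000L, 20000L, 1000L), ref = "A", alt = "G",
                    cluster_id = rep(sprintf("LG01_c%03d", 1:10), each = 2),
                    focal_flag = FALSE, maf_bin = 0.2, source = "focal_window")
  s <- design_summary(man, c(LG01 = 4462000L), c(LG01 = 10))
  expect_equal(s$phys_kb_per_cluster[1], 446.2)
  expect_equal(s$cM_per_cluster[1], 1)
  expect_equal(s$phys_kb_per_cluster[2], 446.2)  # totals row, same single LG
  # zero-cluster LG reports NA, not a division error
  s2 <- design_summary(man[0, ], c(LG01 = 1000L))
  expect_true(is.na(s2$phys_kb_per_cluster[1]))
  # recount oracle: group-by on the manifest
  expect_equal(s$n_clusters[1],
               length(unique(man$cluster_id)))
  expect_equal(s$n_snps[1], nrow(man))
})
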