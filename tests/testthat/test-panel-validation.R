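# Validation-panel selection and GoldenGate-style classification.

test_that("allele-count MAF follows its closed form", {
  expect_equal(compute_maf(c("AA", "AB", "BB")), 0.5)
  expect_equal(compute_maf(c(rep("AA", 9), "AB")), 0.05)
  expect_equal(compute_maf(c("BB", "BB")), 0)   # folded to the minor side
  expect_error(compute_maf(c(NA_character_, NA)), "missing")
})

test_that("MAF estimates concentrate around the true frequency", {
  set.seed(7)
  n <- 148
  for (p in c(0.1, 0.3)) {
    se <- sqrt(p * (1 - p) / (2 * n))
    hits <- replicate(300, {
      calls <- dose_calls(rbinom(n, 2, p))
      abs(compute_maf(calls) - p) <= 3 * se
    })
    expect_gte(mean(hits), 0.99)
  }
})

test_that("even spread hits every LG end and the requested total", {
  set.seed(11)
  lens <- setNames(rep(36000000L, 17), sprintf("LG%02d", 1:17))
  snps <- do.call(rbind, lapply(names(lens), function(lg)
    data.frame(id = sprintf("%s_%04d", lg, 1:1800), lg = lg,
               pos = sort(sample.int(lens[[lg]], 1800)))))
  sel <- select_even_spread(snps, lens, panel_spec(n_even = 100))
  expect_equal(nrow(sel), 100)
  expect_equal(anyDuplicated(sel$id), 0)
  expect_equal(sum(sel$kind == "end"), 34)  # both ends of all 17 LGs
  expect_true(all(sel$pos[sel$kind == "end" & sel$grid_pos == 1] <= 200000))
  # realized spacing between consecutive picks stays near the 6-8 Mb target
  sp <- unlist(lapply(split(sel$pos, sel$lg), function(p) diff(sort(p))))
  expect_true(mean(sp) > 5e6 && mean(sp) < 9e6)
})

test_that("selections sit close to their grid points on a dense LG", {
  lens <- c(LG01 = 10000000L)
  snps <- data.frame(id = sprintf("s%04d", 1:1000), lg = "LG01",
                     pos = seq(5000L, 9995000L, length.out = 1000))
  sel <- select_even_spread(snps, lens, panel_spec(n_even = 5))
  expect_equal(nrow(sel), 5)
  interior <- sel[sel$kind == "interior", ]
  grid_gap <- 10000000 / (nrow(interior) + 1)
  expect_true(all(abs(interior$pos - interior$grid_pos) < grid_gap / 2))
})

test_that("short LGs degrade to a single end selection", {
  lens <- c(LG01 = 300000L)
  snps <- data.frame(id = c("a", "b"), lg = "LG01", pos = c(150000L, 250000L))
  sel <- select_even_spread(snps, lens, panel_spec(n_even = 1))
  expect_equal(nrow(sel), 1)
  expect_equal(sel$kind, "end")
})

test_that("region-dense selection is even and matches brute force when small", {
  region <- list(lg = "LG16", start = 100000L, end = 1500000L)
  set.seed(3)
  snps <- data.frame(id = sprintf("s%03d", 1:200), lg = "LG16",
                     pos = sort(sample(region$start:region$end, 200)))
  sel <- select_region_dense(snps, region, 20)
  expect_equal(nrow(sel), 20)
  spacing <- diff(sel$pos)
  target <- (region$end - region$start) / 19
  expect_lt(abs(mean(spacing) - target) / target, 0.25)
  # n = 1 picks the SNP nearest the midpoint
  one <- select_region_dense(snps, region, 1)
  mid <- (region$start + region$end) / 2
  expect_equal(abs(one$pos - mid), min(abs(snps$pos - mid)))
  # exhaustive agreement for <= 10 candidates: sum of squared distances
  small <- snps[seq(1, 200, by = 22), ]
  n <- 4
  grid <- seq(region$start, region$end, length.out = n)
  combs <- combn(nrow(small), n)
  costs <- apply(combs, 2, function(idx)
    sum((sort(small$pos[idx]) - grid)^2))
  best <- sort(small$pos[combs[, which.min(costs)]])
  expect_equal(select_region_dense(small, region, n)$pos, best)
  # fewer SNPs than requested: all returned, flagged short
  few <- snps[1:3, ]
  out <- select_region_dense(few, region, 10)
  expect_equal(nrow(out), 3)
  expect_true(attr(out, "short"))
})

test_that("accession-specific SNPs have a private minor allele", {
  df <- data.frame(id = c("s1", "s2", "s3"), lg = "LG01",
                   pos = c(1000L, 2000L, 3000L), ref = "A", alt = "G")
  ss <- make_ss(df, n_acc = 4, reads = 5)
  ss$reads_alt[1, ] <- c(3L, 0L, 0L, 0L)  # private to a01
  ss$reads_alt[2, ] <- c(3L, 2L, 0L, 0L)  # two carriers
  ss$reads_alt[3, ] <- c(9L, 9L, 9L, 5L)  # minor allele is ref, all carry it
  out <- find_accession_specific(ss)
  expect_identical(out$id, "s1")
  expect_identical(out$carrier, "a01")
})

test_that("simulated private alleles are recovered from read evidence", {
  cfg <- sim_config(n_lg = 1, lg_length = 1e5, depth_lambda = 30,
                    error_rate = 0, seed = 13)
  sg <- simulate_genome(cfg)
  sim <- simulate_accessions_and_calls(cfg, sg, violation_fraction = 0,
                                       accession_specific_fraction = 0.05)
  found <- find_accession_specific(sim$snps)$id
  # genotype-level oracle: minor allele carried by exactly one accession
  G <- sim$truth$genotypes
  af <- rowSums(G) / (2 * ncol(G))
  carriers <- ifelse(af <= 0.5, rowSums(G > 0), rowSums(G < 2))
  want <- rownames(G)[carriers == 1]
  expect_setequal(found, want)
  expect_true(all(sim$truth$accession_specific %in% found))
})

gg_matrix <- function(n_fail = 46, n_mono = 25, n_poly = 73, n_samples = 148) {
  n <- n_fail + n_mono + n_poly
  ids <- sprintf("snp%03d", seq_len(n))
  calls <- matrix("AA", n_samples, n, dimnames = list(
    sprintf("ind%03d", seq_len(n_samples)), ids))
  status <- rep(c("failed", "mono", "poly"), c(n_fail, n_mono, n_poly))
  calls[, status == "failed"] <- NA_character_
  for (j in which(status == "poly"))
    calls[, j] <- dose_calls(rbinom(n_samples, 2, 0.3))
  genotype_matrix(calls, samples = data.frame(
    id = rownames(calls), p50gc = 0.9, stringsAsFactors = FALSE))
}

test_that("a 144-SNP panel with 73 polymorphic reports 0.51", {
  set.seed(17)
  gm <- gg_matrix()
  # 46 failed assays pull every sample's call rate to ~0.68
  res <- classify_goldengate(gm, sample_call_rate_min = 0.5)
  tot <- res$table[res$table$category == "Total", ]
  expect_equal(tot$total, 144)
  expect_equal(tot$polymorphic, 0.51)
  expect_equal(tot$failed, 0.32)
  expect_equal(table(res$classes$class)[["failed"]], 46)
})

test_that("classification equals a literal per-SNP re-implementation", {
  set.seed(23)
  n_samples <- 60; n <- 50
  calls <- matrix(NA_character_, n_samples, n,
                  dimnames = list(sprintf("i%02d", 1:n_samples),
                                  sprintf("s%02d", 1:n)))
  for (j in seq_len(n)) {
    p <- runif(1, 0, 0.5)
    calls[, j] <- dose_calls(rbinom(n_samples, 2, p))
    miss <- runif(n_samples) < runif(1, 0, 0.2)
    calls[miss, j] <- NA
  }
  calls[, 1:5] <- NA_character_  # a few failed assays
  p50 <- runif(n_samples, 0.3, 1)
  gm <- genotype_matrix(calls, samples = data.frame(
    id = rownames(calls), p50gc = p50, stringsAsFactors = FALSE))
  res <- classify_goldengate(gm)
  # independent oracle, written from the definitions
  pass <- rowMeans(!is.na(calls)) > 0.8 & p50 > 0.5
  for (j in seq_len(n)) {
    cj <- calls[pass, j]
    called <- sum(!is.na(cj))
    want <- if (called / sum(pass) < 0.5) "failed" else {
      nb <- 2 * sum(cj == "BB", na.rm = TRUE) + sum(cj == "AB", na.rm = TRUE)
      maf <- min(nb / (2 * called), 1 - nb / (2 * called))
      hetf <- sum(cj == "AB", na.rm = TRUE) / called
      if (maf < 0.05 && hetf < 0.1) "monomorphic"
      else if (maf < 0.05) "poly_low_maf" else "polymorphic"
    }
    expect_equal(res$classes$class[j], want, info = paste("snp", j))
  }
})

test_that("classification is invariant to sample and SNP order", {
  set.seed(29)
  gm <- gg_matrix(n_fail = 5, n_mono = 5, n_poly = 20, n_samples = 40)
  res1 <- classify_goldengate(gm)
  sp <- sample(nrow(gm$calls)); mp <- sample(ncol(gm$calls))
  gm2 <- genotype_matrix(gm$calls[sp, mp],
                         samples = gm$samples[sp, ],
                         snp_info = gm$snp_info[mp, ])
  res2 <- classify_goldengate(gm2)
  c1 <- res1$classes[order(res1$classes$id), ]
  c2 <- res2$classes[order(res2$classes$id), ]
  rownames(c1) <- rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("category proportions sum to one within rounding", {
  set.seed(31)
  gm <- gg_matrix()
  panel <- data.frame(id = colnames(gm$calls)[1:120],
                      category = rep(c("even", "gene", "region"), 40))
  res <- classify_goldengate(gm, panel, sample_call_rate_min = 0.5)
  sums <- rowSums(res$table[c("failed", "monomorphic", "poly_low_maf",
                              "polymorphic")])
  expect_true(all(abs(sums - 1) <= 0.02 + 1e-9))
})
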