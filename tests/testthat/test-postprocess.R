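test_that("region merging follows the distance threshold", {
  # 0.5 Mbp apart: one region
  r <- rbind(scan_row("a", "1", 1e6, 1e-12, 1e-10, mp = c(1e-12, 1e-10, 0.5)),
             scan_row("b", "1", 1.5e6, 1e-9, 1e-9, mp = c(1e-9, 1e-9, 0.5)))
  reg <- group_regions(r)
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start_bp, reg$end_bp), c(1e6, 1.5e6))
  expect_equal(reg$n_snps, 2L)
  expect_equal(reg$lead_snp, "a")
  expect_equal(reg$stage, 2L)

  # 1.5 Mbp apart: two regions
  r2 <- rbind(scan_row("a", "1", 1e6, 1e-12), scan_row("b", "1", 2.5e6, 1e-9))
  expect_equal(nrow(group_regions(r2)), 2L)

  # different chromosomes never merge
  r3 <- rbind(scan_row("a", "1", 1e6, 1e-12), scan_row("b", "2", 1e6, 1e-9))
  expect_equal(nrow(group_regions(r3)), 2L)
})

test_that("chained SNPs merge transitively like single-linkage clustering", {
  bp <- c(1.0e6, 1.9e6, 2.8e6)
  r <- do.call(rbind, lapply(seq_along(bp), function(i)
    scan_row(letters[i], "1", bp[i], 1e-10)))
  reg <- group_regions(r)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_snps, 3L)
  expect_equal(max(single_linkage_oracle(bp, 1e6)), 1L)

  # random positions: cluster count matches the brute-force oracle
  set.seed(61)
  for (i in 1:10) {
    bp <- sort(sample.int(2e7, 12))
    rr <- do.call(rbind, lapply(seq_along(bp), function(k)
      scan_row(paste0("s", k), "1", bp[k], 1e-10)))
    expect_equal(nrow(group_regions(rr)), max(single_linkage_oracle(bp, 1e6)))
  }
})

test_that("region merging is idempotent and order-independent", {
  set.seed(62)
  bp <- sort(sample.int(1e7, 8))
  r <- do.call(rbind, lapply(seq_along(bp), function(k)
    scan_row(paste0("s", k), "1", bp[k], 1e-10)))
  reg1 <- group_regions(r)
  perm <- sample(nrow(r))
  reg2 <- group_regions(r[perm, ])
  rownames(reg1) <- rownames(reg2) <- NULL
  expect_equal(reg1, reg2)
  # merging the merged regions again changes nothing: regions on the same
  # chromosome are separated by at least the gap
  expect_true(all(diff(reg1$start_bp) >= 1e6 | diff(reg1$start_bp) < 0))
})

test_that("non-significant SNPs are excluded and significance is strict", {
  r <- rbind(scan_row("a", "1", 1e6, 1e-8),     # exactly alpha: not significant
             scan_row("b", "1", 2e6, 0.5))
  expect_equal(nrow(group_regions(r, alpha = 1e-8)), 0L)
})

test_that("trait attribution flags marginally significant traits", {
  a <- attribute_traits(c(1e-12, 1e-9, 0.3), 2, trait_alpha = 1e-8)
  expect_equal(a$mask, c(TRUE, TRUE, FALSE))
  expect_false(a$forced)
  # no trait marginally significant: the two smallest p-values are forced
  b <- attribute_traits(c(0.2, 0.01, 0.3), 2, trait_alpha = 1e-8)
  expect_equal(b$mask, c(TRUE, TRUE, FALSE))
  expect_true(b$forced)
})

test_that("simulated two-trait SNPs are attributed to the right traits", {
  set.seed(63)
  hits <- 0L
  for (r in 1:200) {
    st <- sim_setting(n = 4000, p = 3, rho = 0.2, h2_trait1 = 0.02,
                      effect_ratio = 1, affected_traits = c(1L, 3L))
    dat <- simulate_dataset(st)
    adj <- adjust_phenotypes(dat$Y)
    S <- estimate_error_covariance(adj)$S
    fit <- grouped_gls(center_genotype(dat$x)$x, adj$values, S)
    mp <- marginal_pvalues(fit$beta_hat, fit$cov_beta)
    a <- attribute_traits(mp, 2, trait_alpha = 1e-8)
    if (identical(unname(a$mask), c(TRUE, FALSE, TRUE))) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("pairwise tables count shared regions per trait pair", {
  r1 <- data.frame(chrom = "1", start_bp = 1, end_bp = 2, n_snps = 4L,
                   lead_snp = "a", min_p = 1e-10, stage = 3L,
                   trait.t1 = TRUE, trait.t2 = TRUE, trait.t3 = TRUE)
  pw <- pairwise_region_table(r1)
  expect_equal(pw$regions["t1", "t2"], 1L)
  expect_equal(pw$regions["t2", "t3"], 1L)
  expect_equal(pw$snps["t1", "t3"], 4L)
  expect_true(is.na(pw$regions["t1", "t1"]))

  empty <- r1[0, ]
  pw0 <- pairwise_region_table(empty)
  expect_true(all(pw0$regions == 0L, na.rm = TRUE))

  # random masks against exhaustive pair counting
  set.seed(64)
  regs <- do.call(rbind, lapply(1:5, function(i) {
    m <- runif(3) > 0.4
    data.frame(chrom = "1", start_bp = i, end_bp = i, n_snps = i,
               lead_snp = "x", min_p = 1e-10, stage = 2L,
               trait.t1 = m[1], trait.t2 = m[2], trait.t3 = m[3])
  }))
  pw2 <- pairwise_region_table(regs)
  m <- as.matrix(regs[, c("trait.t1", "trait.t2", "trait.t3")])
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(pw2$regions[a, b], sum(m[, a] & m[, b]))
    expect_equal(pw2$snps[a, b], sum(regs$n_snps[m[, a] & m[, b]]))
  }
  expect_equal(pw2$regions, t(pw2$regions))
})

test_that("scans are deterministic and chunking does not change results", {
  set.seed(65)
  st <- sim_setting(n = 300, p = 3, rho = 0.2)
  fx <- write_fixture(st, tempfile(), n_variants = 23)
  one <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno, chunk_size = 1000L)
  small <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno, chunk_size = 4L)
  expect_identical(one$results, small$results)
  # two half-range scans concatenate to the single pass
  h1 <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno, variant_range = c(1L, 11L))
  h2 <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno, variant_range = c(12L, 23L))
  both <- rbind(h1$results, h2$results)
  rownames(both) <- rownames(one$results) <- NULL
  expect_identical(one$results, both)
  # every variant is accounted for in results or the skip log
  expect_setequal(c(one$results$id, one$skipped$id), read_bim(fx$bim)$id)
})

test_that("an end-to-end scan flags the pleiotropic SNP and only it", {
  set.seed(66)
  st <- sim_setting(n = 5e4, p = 3, rho = 0.2, h2_trait1 = 0.05,
                    effect_ratio = 1, affected_traits = 1:2)
  fx <- write_fixture(st, tempfile(), n_variants = 8)
  sc <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno)
  causal <- sc$results$id == fx$causal_id
  expect_lt(sc$results$p2[causal], 1e-8)
  expect_true(all(sc$results$p1[!causal] > 1e-8))
  reg <- group_regions(sc$results)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$lead_snp, fx$causal_id)
  expect_equal(reg$stage, 2L)
  expect_equal(unlist(reg[paste0("trait.trait", 1:3)], use.names = FALSE),
               c(TRUE, TRUE, FALSE))
})

test_that("null scans are calibrated and empty filters warn", {
  set.seed(67)
  st <- sim_setting(n = 2000, p = 3, rho = 0.2)
  fx <- write_fixture(st, tempfile(), n_variants = 400)
  sc <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno)
  frac <- mean(sc$results$p1 < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(sc$results)))
  # all variants filtered out: empty results plus a warning
  expect_warning(
    sc0 <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno, maf_min = 0.6),
    "no variants")
  expect_equal(nrow(sc0$results), 0L)
})
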