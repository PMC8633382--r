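test_that("simulated traits have the designed variance structure", {
  set.seed(51)
  # no effect: pure correlated noise with unit trait variances
  st0 <- sim_setting(n = 2e4, p = 3, rho = 0.5)
  d0 <- simulate_dataset(st0)
  expect_equal(d0$beta, rep(0, 3))
  v <- apply(d0$Y, 2, stats::var)
  expect_true(all(abs(v - 1) < 0.05))
  cors <- stats::cor(d0$Y)[lower.tri(diag(3))]
  expect_true(all(abs(cors - 0.5) < 0.05))

  # effect size: beta_1 = sqrt(h2 / (2 f (1 - f)))
  st1 <- sim_setting(n = 1e5, p = 3, rho = 0.2, h2_trait1 = 0.01,
                     maf_range = c(0.25, 0.25))
  d1 <- simulate_dataset(st1)
  expect_equal(d1$beta[1], sqrt(0.01 / 0.375), tolerance = 1e-12)
  expect_equal(d1$beta[2:3], c(0, 0))
  # genotype variance close to 2 f (1 - f); binomial-kurtosis SE at n = 1e5
  expect_lt(abs(stats::var(d1$x) - 0.375), 3 * 0.002)
  # trait-1 variance 1 (h2 from the SNP + 1 - h2 from errors)
  expect_lt(abs(stats::var(d1$Y[, 1]) - 1), 0.05)

  expect_error(sim_setting(n = 100, h2_trait1 = 1), "h2")
})

test_that("identical seeds reproduce studies and fixtures exactly", {
  st <- sim_setting(n = 500, p = 3, rho = 0.2)
  set.seed(7); a <- type1_study(st, 500, alphas = 0.05)
  set.seed(7); b <- type1_study(st, 500, alphas = 0.05)
  expect_identical(a, b)
  set.seed(8); f1 <- write_fixture(st, tempfile(), n_variants = 5)
  set.seed(8); f2 <- write_fixture(st, tempfile(), n_variants = 5)
  expect_identical(f1$dosage, f2$dosage)
})

test_that("sufficient-statistic decomposition reproduces the pipeline S", {
  # the batch sampler draws (x'x, beta-hat, S) from their exact joint law;
  # verify the algebra on raw data: with z = u'E_c and M = E_c'E_c - zz',
  # (n-1)S = x'x bb' + sqrt(x'x)(bz' + zb') + zz' + M and
  # beta-hat = b + z/sqrt(x'x)
  set.seed(52)
  n <- 300
  beta <- c(0.2, 0.1, 0)
  x <- rbinom(n, 2, 0.3)
  E <- matrix(rnorm(n * 3), n, 3) %*% chol(rho_cov(rep(1, 3), 0.4))
  Y <- outer(as.numeric(x), beta) + E
  Yc <- scale(Y, scale = FALSE)
  xc <- x - mean(x)
  xtx <- sum(xc^2)
  S_pipe <- crossprod(Yc) / (n - 1)
  bhat_pipe <- drop(crossprod(Yc, xc)) / xtx

  u <- xc / sqrt(xtx)
  Ec <- scale(E, scale = FALSE)
  z <- drop(crossprod(Ec, u))
  M <- crossprod(Ec) - tcrossprod(z)
  S_dec <- (xtx * tcrossprod(beta) + sqrt(xtx) * (tcrossprod(beta, z) +
            tcrossprod(z, beta)) + tcrossprod(z) + M) / (n - 1)
  expect_equal(S_dec, S_pipe, tolerance = 1e-10)
  expect_equal(beta + z / sqrt(xtx), bhat_pipe, tolerance = 1e-10)
})

test_that("batch and full engines agree on rejection rates", {
  st <- sim_setting(n = 1000, p = 3, rho = 0.5)
  set.seed(53)
  rb <- type1_study(st, 4000, alphas = 0.05, engine = "batch")
  rf <- type1_study(st, 1500, alphas = 0.05, engine = "full")
  se <- sqrt(0.05 * 0.95 * (1 / 4000 + 1 / 1500))
  expect_lt(abs(rb$rate - rf$rate), 4 * se)
})

test_that("null p-values are calibrated at moderate levels", {
  st <- sim_setting(n = 3000, p = 3, rho = 0.2)
  set.seed(54)
  r <- type1_study(st, 1e4, alphas = c(1.0, 0.5, 0.05))
  expect_equal(r$rate[1], 1.0)
  expect_lt(abs(r$rate[2] - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_lt(abs(r$rate[3] - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4))
  expect_true(all(r$ci_low <= r$rate & r$rate <= r$ci_high))
})

test_that("power is near alpha with no effect and rises with effect size", {
  set.seed(55)
  grid <- data.frame(n = 3000, rho = 0.2, h2 = c(0, 0.01), effect_ratio = 1)
  # stage-1 target: under no effect the rejection rate is the nominal level
  pw1 <- power_study(grid, n_reps = 4000, alpha = 0.05, target_stage = 1L)
  expect_lt(abs(pw1$power[1] - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
  # stage-2 target: the IU test is conservative under the complete null
  # (every component null true), so the rate sits at or below alpha
  pw2 <- power_study(grid, n_reps = 4000, alpha = 0.05, target_stage = 2L)
  expect_lt(pw2$power[1], 0.05 + 3 * sqrt(0.05 * 0.95 / 4000))
  expect_gt(pw2$power[2], pw2$power[1])
})

test_that("fixtures round-trip and honor injected missingness patterns", {
  set.seed(56)
  masks <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, TRUE))
  st <- sim_setting(n = 100, p = 3, rho = 0.2,
                    missing_pattern_spec = list(masks = masks,
                                                probs = c(0.7, 0.3)))
  fx <- write_fixture(st, tempfile(), n_variants = 50)
  back <- read_genotype_block(fx$bed, 100, 1:50)
  expect_equal(unname(back), unname(fx$dosage + 0))
  fam <- read_fam(fx$fam)
  Y <- read_table_aligned(fx$pheno, fam)
  groups <- find_missing_patterns(!is.na(Y))
  pats <- vapply(groups, function(g) paste(g$trait_mask + 0L, collapse = ""),
                 "")
  expect_setequal(pats, c("111", "101"))
})

test_that("a fixture scan recovers the injected effect within 3 SE", {
  set.seed(57)
  st <- sim_setting(n = 5000, p = 3, rho = 0.2, h2_trait1 = 0.01,
                    effect_ratio = 1, affected_traits = 1:3)
  fx <- write_fixture(st, tempfile(), n_variants = 10, n_covariates = 2)
  sc <- run_scan(fx$bed, fx$bim, fx$fam, fx$pheno, covar = fx$covar)
  row <- sc$results[sc$results$id == fx$causal_id, ]
  bh <- unlist(row[paste0("beta.trait", 1:3)])
  # recompute the sampling SE for the causal SNP
  fam <- read_fam(fx$fam)
  Y <- read_table_aligned(fx$pheno, fam)
  Z <- read_table_aligned(fx$covar, fam)
  adj <- adjust_phenotypes(Y, Z)
  S <- estimate_error_covariance(adj)$S
  g <- read_genotype_block(fx$bed, st$n, match(fx$causal_id,
                                               read_bim(fx$bim)$id))
  fit <- grouped_gls(center_genotype(drop(g))$x, adj$values, S)
  se <- sqrt(diag(fit$cov_beta))
  expect_true(all(abs(bh - fx$beta) < 3 * se))
})
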