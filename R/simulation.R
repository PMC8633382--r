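# Monte Carlo engine for the type-I-error and power studies, and the
# synthetic-fixture generator used throughout the test suite.
#
# Study design: per replicate, one SNP with allele frequency f drawn from
# maf_law (default Uniform(0.01, 0.5)), dosages Binomial(2, f), and traits
#   y_ji = x_i beta_j + e_ji,  e_i ~ MVN(0, Sigma)
# with Sigma_jj = 1 - h2_j and Sigma_jj' = rho * sqrt((1-h2_j)(1-h2_j')),
# so each trait has total phenotypic variance 1 and "percent variance
# explained" is exact. beta_1 = sqrt(h2_trait1 / (2f(1-f))); other affected
# traits get effect_ratio * beta_1.

#' Simulation setting
#'
#' @param n Sample size.
#' @param p Number of traits.
#' @param rho Homogeneous error correlation, in (-1/(p-1), 1).
#' @param h2_trait1 Proportion of trait-1 phenotypic variance explained by
#'   the SNP, in `[0, 1)`.
#' @param effect_ratio Ratio beta_other / beta_1 for the other affected
#'   traits (effect_ratio = 0.5 means beta_1 is twice beta_2 = beta_3).
#' @param affected_traits Integer indices of traits with non-zero effects
#'   (must include 1 when `h2_trait1 > 0`); default `1` when h2 > 0, none
#'   otherwise.
#' @param maf_range Support of the uniform allele-frequency law, default
#'   `c(0.01, 0.5)`.
#' @param missing_pattern_spec Optional list with `masks` (k x p logical
#'   matrix of observed-trait patterns) and `probs` (length-k pattern
#'   probabilities) used by [simulate_dataset()] and [write_fixture()].
#' @return A `sim_setting` list.
#' @export
sim_setting <- function(n, p = 3L, rho = 0.2, h2_trait1 = 0,
                        effect_ratio = 1, affected_traits = NULL,
                        maf_range = c(0.01, 0.5),
                        missing_pattern_spec = NULL) {
  stopifnot(n >= 2, p >= 1, h2_trait1 >= 0, h2_trait1 < 1,
            rho > -1 / max(p - 1, 1), rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (is.null(affected_traits)) {
    affected_traits <- if (h2_trait1 > 0) 1L else integer(0)
  }
  if (h2_trait1 > 0 && !(1L %in% affected_traits)) {
    stop("trait 1 must be affected when h2_trait1 > 0")
  }
  if (!is.null(missing_pattern_spec)) {
    stopifnot(is.matrix(missing_pattern_spec$masks),
              ncol(missing_pattern_spec$masks) == p,
              length(missing_pattern_spec$probs) ==
                nrow(missing_pattern_spec$masks))
  }
  structure(list(n = as.integer(n), p = as.integer(p), rho = rho,
                 h2_trait1 = h2_trait1, effect_ratio = effect_ratio,
                 affected_traits = as.integer(affected_traits),
                 maf_range = maf_range,
                 missing_pattern_spec = missing_pattern_spec),
            class = "sim_setting")
}

# relative effect profile: beta = sqrt(h2 / varx) * profile
.effect_profile <- function(setting) {
  prof <- numeric(setting$p)
  prof[setting$affected_traits] <- setting$effect_ratio
  if (1L %in% setting$affected_traits) prof[1L] <- 1
  prof
}

#' Simulate one dataset (single SNP, p traits)
#'
#' @param setting A [sim_setting()].
#' @return List with `x` (dosage vector, `NA` under injected missingness
#'   patterns never applies to genotypes), `Y` (n x p trait matrix with `NA`
#'   per the missing-pattern spec), `f` (drawn allele frequency), `beta`
#'   (true effect vector), and `Sigma` (error covariance).
#' @export
simulate_dataset <- function(setting) {
  stopifnot(inherits(setting, "sim_setting"))
  n <- setting$n; p <- setting$p
  f <- runif(1, setting$maf_range[1], setting$maf_range[2])
  x <- rbinom(n, 2L, f)
  varx <- 2 * f * (1 - f)
  prof <- .effect_profile(setting)
  beta <- if (setting$h2_trait1 > 0) sqrt(setting$h2_trait1 / varx) * prof
          else numeric(p)
  h2 <- setting$h2_trait1 * prof^2
  d <- 1 - h2
  Sigma <- rho_cov(d, setting$rho)
  E <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
  Y <- outer(x, beta) + E
  spec <- setting$missing_pattern_spec
  if (!is.null(spec)) {
    pat <- sample.int(nrow(spec$masks), n, replace = TRUE, prob = spec$probs)
    Y[!spec$masks[pat, , drop = FALSE]] <- NA_real_
  }
  list(x = x, Y = Y, f = f, beta = beta, Sigma = Sigma)
}

# covariance with given variances d and homogeneous correlation rho
rho_cov <- function(d, rho) {
  p <- length(d)
  S <- rho * sqrt(outer(d, d))
  diag(S) <- d
  S
}

# Batch sufficient-statistic sampler: returns B x length(stages) matrix of
# stage p-values, distributionally identical to running simulate_dataset()
# through the full pipeline (see the methods vignette for the derivation).
.mc_seq_batch <- function(setting, B, stages = 1:2) {
  p <- setting$p
  zs <- lapply(stages, function(s) {
    m <- vapply(build_contrasts(p, s), function(K) K - 1L,
                integer(p - s + 1L))
    if (!is.matrix(m)) m <- matrix(m, nrow = p - s + 1L)
    m
  })
  out <- .mc_seq_batch_cpp(setting$n, as.integer(B), p, setting$rho,
                           setting$h2_trait1, .effect_profile(setting),
                           setting$maf_range[1], setting$maf_range[2], zs)
  colnames(out) <- paste0("p", stages)
  out
}

# Full-pipeline replicate engine (raw data -> adjust -> S -> GLS -> test);
# slower, used to cross-validate the batch sampler and for settings with
# missing-value patterns.
.mc_seq_full <- function(setting, B, stages = 1:2) {
  out <- matrix(NA_real_, B, length(stages),
                dimnames = list(NULL, paste0("p", stages)))
  for (r in seq_len(B)) {
    dat <- simulate_dataset(setting)
    adj <- adjust_phenotypes(dat$Y)
    groups <- find_missing_patterns(adj$observed)
    S <- estimate_error_covariance(adj)$S
    cg <- center_genotype(dat$x)
    if (!is.null(cg$skip)) next
    fit <- gls_fit(accumulate_group_stats(cg$x, adj, groups), S)
    for (k in seq_along(stages)) {
      out[r, k] <- stage_pvalue(fit$beta_hat, fit$cov_beta, stages[k])$p
    }
  }
  out
}

#' Monte Carlo type-I error study
#'
#' Simulates `n_reps` independent datasets under `setting` and reports the
#' empirical rejection rate of the target stage at each nominal level, with
#' a normal-approximation 95% confidence interval and the rate on the
#' -log10 scale. `target = "stage1"` is the global test of any effect
#' (null when all beta = 0); `target = "stage2"` is two-trait pleiotropy
#' (null when at most one beta differs from zero). Stage-2 rejection is by
#' the stage-2 p-value alone; requiring stage-1 significance as well could
#' only lower the rate.
#'
#' @param setting A [sim_setting()].
#' @param n_reps Number of Monte Carlo replicates.
#' @param alphas Nominal significance levels.
#' @param target `"stage1"` or `"stage2"`.
#' @param engine `"batch"` (compiled sufficient-statistic sampler, for large
#'   replicate counts) or `"full"` (raw-data pipeline; required when the
#'   setting has missing-value patterns).
#' @return Data.frame per alpha: `alpha`, `rate`, `ci_low`, `ci_high`,
#'   `neglog10_rate`, `n_reps`.
#' @export
type1_study <- function(setting, n_reps, alphas = c(0.05, 0.01),
                        target = c("stage1", "stage2"),
                        engine = c("batch", "full")) {
  target <- match.arg(target)
  engine <- match.arg(engine)
  if (n_reps < 10 / min(alphas)) {
    warning("n_reps is small for the smallest alpha; rate estimate is noisy")
  }
  stage <- if (target == "stage1") 1L else 2L
  if (engine == "batch") {
    if (!is.null(setting$missing_pattern_spec)) {
      stop("batch engine does not support missing-value patterns; use engine='full'")
    }
    pv <- .mc_seq_batch(setting, n_reps, stages = stage)[, 1L]
  } else {
    pv <- .mc_seq_full(setting, n_reps, stages = stage)[, 1L]
  }
  pv <- pv[!is.na(pv)]
  res <- lapply(alphas, function(a) {
    rate <- mean(pv < a)
    se <- sqrt(rate * (1 - rate) / length(pv))
    data.frame(alpha = a, rate = rate,
               ci_low = max(rate - 1.96 * se, 0),
               ci_high = min(rate + 1.96 * se, 1),
               neglog10_rate = -log10(max(rate, .Machine$double.xmin)),
               n_reps = length(pv))
  })
  do.call(rbind, res)
}

#' Monte Carlo power study over a settings grid
#'
#' @param grid Data.frame of settings, columns among `n`, `rho`, `h2`,
#'   `effect_ratio` (defaults: the study grid n in \{3000, 5000, 10000\},
#'   rho in \{0.2, 0.5, 0.8\}, ratio in \{1, 0.5\}, h2 up to 0.01). All
#'   traits are affected.
#' @param n_reps Replicates per grid cell.
#' @param alpha Rejection level for the target stage (default 0.05).
#' @param target_stage Stage whose rejection defines power (default 2,
#'   i.e. detecting at least two affected traits).
#' @param p Number of traits (default 3).
#' @return `grid` with `power` and `mc_se` columns appended.
#' @export
power_study <- function(grid = NULL, n_reps = 1e4, alpha = 0.05,
                        target_stage = 2L, p = 3L) {
  if (is.null(grid)) {
    grid <- expand.grid(n = c(3000L, 5000L, 10000L), rho = c(0.2, 0.5, 0.8),
                        h2 = c(0.0025, 0.005, 0.01), effect_ratio = c(1, 0.5))
  }
  grid$power <- NA_real_
  grid$mc_se <- NA_real_
  for (i in seq_len(nrow(grid))) {
    st <- sim_setting(n = grid$n[i], p = p, rho = grid$rho[i],
                      h2_trait1 = grid$h2[i],
                      effect_ratio = grid$effect_ratio[i],
                      affected_traits = seq_len(p))
    pv <- .mc_seq_batch(st, n_reps, stages = target_stage)[, 1L]
    grid$power[i] <- mean(pv < alpha)
    grid$mc_se[i] <- sqrt(grid$power[i] * (1 - grid$power[i]) / n_reps)
  }
  grid
}

#' Write a synthetic PLINK fixture with known effects
#'
#' Generates `n_variants` independent variants (allele frequencies from the
#' setting's MAF law), makes the `causal_index` variant causal with the
#' setting's effect vector, and writes bed/bim/fam plus a tab-delimited
#' phenotype file (FID/IID keyed). Optional covariates with real effects on
#' every trait are written to `<prefix>.covar.tsv` and added to the traits,
#' so a scan must adjust for them. Missing-value patterns from the setting
#' are injected into the phenotypes.
#'
#' @param setting A [sim_setting()].
#' @param out_prefix Output path prefix.
#' @param n_variants Number of variants (default 50).
#' @param causal_index Index of the causal variant (default the middle one).
#' @param n_covariates Number of standard-normal covariates with unit
#'   effects to add (default 0).
#' @param chrom Chromosome label for all variants (default "1").
#' @param bp_step Base-pair spacing between consecutive variants (default
#'   10000, starting at 10001).
#' @return List with the file paths, `beta` (true effects), `causal_id`,
#'   and the simulated `dosage` matrix (samples x variants).
#' @export
write_fixture <- function(setting, out_prefix, n_variants = 50L,
                          causal_index = NULL, n_covariates = 0L,
                          chrom = "1", bp_step = 10000L) {
  stopifnot(inherits(setting, "sim_setting"), n_variants >= 1L)
  n <- setting$n; p <- setting$p
  if (is.null(causal_index)) causal_index <- max(1L, n_variants %/% 2L)
  f <- runif(n_variants, setting$maf_range[1], setting$maf_range[2])
  G <- vapply(f, function(ff) rbinom(n, 2L, ff), integer(n))
  varx <- 2 * f[causal_index] * (1 - f[causal_index])
  prof <- .effect_profile(setting)
  beta <- if (setting$h2_trait1 > 0) sqrt(setting$h2_trait1 / varx) * prof
          else numeric(p)
  d <- 1 - setting$h2_trait1 * prof^2
  E <- matrix(rnorm(n * p), n, p) %*% chol(rho_cov(d, setting$rho))
  Y <- outer(as.numeric(G[, causal_index]), beta) + E
  covar_path <- NULL
  if (n_covariates > 0L) {
    Z <- matrix(rnorm(n * n_covariates), n, n_covariates,
                dimnames = list(NULL, paste0("cov", seq_len(n_covariates))))
    Y <- Y + Z %*% matrix(1, n_covariates, p)
    covar_path <- paste0(out_prefix, ".covar.tsv")
    write.table(data.frame(FID = paste0("F", seq_len(n)),
                           IID = paste0("I", seq_len(n)), Z),
                covar_path, quote = FALSE, sep = "\t", row.names = FALSE)
  }
  spec <- setting$missing_pattern_spec
  if (!is.null(spec)) {
    pat <- sample.int(nrow(spec$masks), n, replace = TRUE, prob = spec$probs)
    Y[!spec$masks[pat, , drop = FALSE]] <- NA_real_
  }
  colnames(Y) <- paste0("trait", seq_len(p))
  fam <- data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                    stringsAsFactors = FALSE)
  bim <- data.frame(chrom = chrom, id = paste0("snp", seq_len(n_variants)),
                    cm = 0, bp = 10001L + bp_step * (seq_len(n_variants) - 1L),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  write_plink(G, bim, fam, out_prefix)
  pheno_path <- paste0(out_prefix, ".pheno.tsv")
  write.table(data.frame(FID = fam$fid, IID = fam$iid, Y),
              pheno_path, quote = FALSE, sep = "\t", row.names = FALSE)
  list(bed = paste0(out_prefix, ".bed"), bim = paste0(out_prefix, ".bim"),
       fam = paste0(out_prefix, ".fam"), pheno = pheno_path,
       covar = covar_path, beta = beta,
       causal_id = bim$id[causal_index], dosage = G, f = f)
}
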