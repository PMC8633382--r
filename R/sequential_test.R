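# Sequential Wald intersection-union test for "the SNP affects at least s
# traits". Stage s tests the composite null that at most s - 1 effects are
# non-zero: every subset of p - s + 1 effects constrained to zero is one
# component null; the IU p-value comes from the minimum Wald statistic,
# chi-square with df = p - s + 1 under the null. Stage 1 is the global test
# beta = 0 (df = p). Stage-2 component nulls correspond to removing one row
# of the p x p identity contrast.

P_FLOOR <- 1e-300

#' Component-null zero sets for one stage of the sequential test
#'
#' @param p Number of traits.
#' @param stage Stage s in 1..p.
#' @return List of integer vectors; each is a subset of traits of size
#'   `p - stage + 1` constrained to zero under one component null. There are
#'   `choose(p, stage - 1)` of them; stage 1 has the single set `1:p`.
#' @export
build_contrasts <- function(p, stage) {
  stopifnot(p >= 1L)
  if (stage < 1L || stage > p) {
    stop(sprintf("stage must be in 1..%d, got %s", p, stage))
  }
  if (stage == 1L) return(list(seq_len(p)))
  keep <- utils::combn(p, stage - 1L, simplify = FALSE)
  lapply(keep, function(k) setdiff(seq_len(p), k))
}

#' Wald statistic for a zero-constrained subset of effects
#'
#' `w = beta_K' (cov_KK)^{-1} beta_K` for `K = zero_set`; with the full set
#' this is the global statistic `beta' cov^{-1} beta`.
#'
#' @param beta_hat Effect vector.
#' @param cov_beta Sampling covariance of `beta_hat` (positive definite).
#' @param zero_set Integer trait subset constrained to zero.
#' @return Non-negative scalar.
#' @export
wald_statistic <- function(beta_hat, cov_beta, zero_set) {
  bK <- beta_hat[zero_set]
  cK <- cov_beta[zero_set, zero_set, drop = FALSE]
  sol <- tryCatch(solve(cK, bK), error = function(e) NULL)
  if (is.null(sol)) {
    stop(structure(class = c("pleio_singular_error", "error", "condition"),
                   list(message = "singular covariance block in Wald statistic",
                        call = sys.call(-1))))
  }
  drop(crossprod(bK, sol))
}

#' Stage-wise IU p-value
#'
#' @inheritParams wald_statistic
#' @param stage Stage s.
#' @return List with `w_min` (minimum Wald statistic over the stage's
#'   component nulls), `p` (upper chi-square tail at `w_min` with
#'   df = p - stage + 1), `df`, and `zero_set` (the argmin component null;
#'   ties resolved to the first set in enumeration order — the p-value is
#'   unaffected since the minimum is well-defined).
#' @export
stage_pvalue <- function(beta_hat, cov_beta, stage) {
  p <- length(beta_hat)
  zsets <- build_contrasts(p, stage)
  w <- vapply(zsets, function(K) wald_statistic(beta_hat, cov_beta, K), 0)
  i <- which.min(w)
  df <- p - stage + 1L
  list(w_min = w[i], p = pchisq(w[i], df = df, lower.tail = FALSE),
       df = df, zero_set = zsets[[i]])
}

#' Sequential stage p-values with early stopping
#'
#' Computes the stage-1 p-value, then stage 2, and so on, stopping after the
#' first stage whose p-value exceeds `early_stop_p` (that stage's p-value is
#' still recorded; later stages are reported as absent, not as 1). The
#' declared pleiotropy order at level alpha is the largest s with all of
#' p_1..p_s below alpha (see [pleiotropy_order()]); the sequential gating
#' controls the error rate without further within-locus multiplicity
#' adjustment.
#'
#' @inheritParams wald_statistic
#' @param max_stage Highest stage to test (default p, capped at 15 since the
#'   number of component nulls at stage s is `choose(p, s - 1)`).
#' @param early_stop_p Threshold above which later stages are skipped
#'   (default 1 = never skip; 0.01 is a practical choice).
#' @return List with `stage_p` (named numeric, only the tested stages),
#'   `stage_w`, `stages_tested`, and `neglog10_p` (with p-values floored at
#'   1e-300).
#' @export
sequential_pvalues <- function(beta_hat, cov_beta, max_stage = length(beta_hat),
                               early_stop_p = 1) {
  p <- length(beta_hat)
  stopifnot(max_stage >= 1L, max_stage <= p)
  if (p > 15L) stop("sequential test limited to p <= 15 traits")
  stage_p <- numeric(0)
  stage_w <- numeric(0)
  for (s in seq_len(max_stage)) {
    r <- stage_pvalue(beta_hat, cov_beta, s)
    stage_p[paste0("p", s)] <- r$p
    stage_w[paste0("w", s)] <- r$w_min
    if (r$p > early_stop_p) break
  }
  pf <- pmax(stage_p, P_FLOOR)
  list(stage_p = stage_p, stage_w = stage_w,
       stages_tested = length(stage_p), neglog10_p = -log10(pf))
}

#' Declared pleiotropy order at a significance level
#'
#' @param stage_p Named stage p-values from [sequential_pvalues()].
#' @param alpha Significance level (strict inequality).
#' @return Largest s such that stages 1..s all have p < alpha (0 if stage 1
#'   is not significant).
#' @export
pleiotropy_order <- function(stage_p, alpha) {
  sig <- unname(stage_p < alpha)
  as.integer(sum(cumprod(sig)))
}

#' Single-trait marginal Wald p-values
#'
#' Per trait j: upper chi-square(1) tail at `beta_j^2 / cov_jj`; used for
#' trait attribution in region summaries.
#'
#' @inheritParams wald_statistic
#' @return Numeric p-vector of two-sided p-values.
#' @export
marginal_pvalues <- function(beta_hat, cov_beta) {
  w <- beta_hat^2 / diag(cov_beta)
  pchisq(w, df = 1, lower.tail = FALSE)
}
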