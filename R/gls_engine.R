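# Per-SNP multi-trait GLS/SUR estimation. Balanced data reduce to the closed
# form beta_j = x'y_j / x'x with cov(beta) = S / x'x; unbalanced data combine
# per-pattern-group sufficient statistics under the block-diagonal error
# covariance with blocks S[mask_g, mask_g].

#' Center a genotype vector, mean-imputing missing calls
#'
#' Missing dosages are replaced by the mean dosage over the analyzed samples
#' and the vector is then mean-centered, so imputed entries become exactly 0
#' and contribute nothing to x'x or x'y. Imputing (rather than treating
#' genotype missingness as extra patterns) keeps the pattern count bounded;
#' post-filter genotype missingness is at most 5% by construction.
#'
#' @param dosage Numeric dosage vector in \{0, 1, 2, NA\}.
#' @param analyzed Optional integer indices of samples in the analysis;
#'   default all.
#' @return List with `x` (centered vector over analyzed samples),
#'   `n_imputed`, and `skip` (`NULL`, or a string reason when the SNP is
#'   monomorphic or all-missing and must be skipped).
#' @export
center_genotype <- function(dosage, analyzed = NULL) {
  if (is.null(analyzed)) analyzed <- seq_along(dosage)
  d <- dosage[analyzed]
  miss <- is.na(d)
  if (all(miss)) {
    return(list(x = NULL, n_imputed = length(d), skip = "all genotypes missing"))
  }
  m <- mean(d[!miss])
  d[miss] <- m
  x <- d - mean(d)
  if (sum(x^2) <= 0) {
    return(list(x = NULL, n_imputed = sum(miss), skip = "monomorphic"))
  }
  list(x = x, n_imputed = sum(miss), skip = NULL)
}

#' Accumulate per-group sufficient statistics for one SNP
#'
#' @param x Centered genotype vector aligned to the analyzed samples.
#' @param adjusted An `adj_pheno` object (values aligned to the same samples).
#' @param groups Pattern groups from [find_missing_patterns()].
#' @return List per group: `xtx` (sum of squared x over members), `xty`
#'   (named vector, one entry per observed trait), `trait_mask`, `size`.
#' @export
accumulate_group_stats <- function(x, adjusted, groups) {
  Y <- adjusted$values
  lapply(groups, function(g) {
    ix <- g$member_indices
    xs <- x[ix]
    yg <- Y[ix, g$trait_mask, drop = FALSE]
    list(xtx = sum(xs^2),
         xty = as.vector(crossprod(yg, xs)),
         trait_mask = g$trait_mask,
         size = g$size)
  })
}

#' GLS estimate of per-trait SNP effects and their sampling covariance
#'
#' Solves the normal equations `A beta = b` with
#' `A = sum_g xtx_g E_g' S_g^{-1} E_g` and `b = sum_g E_g' S_g^{-1} xty_g`,
#' where `S_g = S[mask_g, mask_g]` and `E_g` selects the traits observed in
#' group g. With a single complete group this reduces exactly to per-trait
#' OLS slopes `x'y_j / x'x` with `cov(beta) = S / x'x`.
#'
#' @param stats Group statistics from [accumulate_group_stats()].
#' @param S Error covariance matrix (p x p) from
#'   [estimate_error_covariance()].
#' @return List with `beta_hat` (p-vector), `cov_beta` (p x p), `n_used`.
#'   Errors of class `pleio_singular_error` signal a SNP whose normal
#'   equations cannot be solved (e.g. a trait observed in no retained group).
#' @export
gls_fit <- function(stats, S) {
  S <- as.matrix(S)
  p <- ncol(S)
  stopifnot(length(stats) >= 1L)
  A <- matrix(0, p, p)
  b <- numeric(p)
  n_used <- 0L
  for (g in stats) {
    K <- which(g$trait_mask)
    Sg_inv <- chol2inv(chol(S[K, K, drop = FALSE]))
    A[K, K] <- A[K, K] + g$xtx * Sg_inv
    b[K] <- b[K] + Sg_inv %*% g$xty
    n_used <- n_used + g$size
  }
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stop(structure(class = c("pleio_singular_error", "error", "condition"),
                   list(message = "singular GLS normal equations",
                        call = sys.call(-1))))
  }
  cov_beta <- chol2inv(ch)
  beta_hat <- drop(cov_beta %*% b)
  names(beta_hat) <- colnames(S)
  dimnames(cov_beta) <- dimnames(S)
  list(beta_hat = beta_hat, cov_beta = cov_beta, n_used = n_used)
}
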