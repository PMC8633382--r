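# Phenotype adjustment, variant filtering, error-covariance estimation, and
# missing-value-pattern grouping.

#' Covariate-adjust and center phenotypes
#'
#' Each trait is optionally log-transformed, regressed on an intercept plus
#' the covariates by least squares over that trait's observed rows (rows with
#' a missing covariate count as unobserved for every trait), and replaced by
#' its mean-centered residual. Adjustment is per trait over each trait's own
#' observed rows, which uses all available data under unbalanced designs.
#'
#' @param raw_traits Numeric matrix (samples x traits), `NA` for missing.
#'   Column names are used as trait names.
#' @param covariates Optional numeric matrix (samples x covariates);
#'   categorical covariates must be pre-expanded to indicator columns. An
#'   intercept is always added.
#' @param transforms Optional character vector per trait, `"identity"`
#'   (default) or `"log"`.
#' @return An object of class `adj_pheno`: list with `values` (residual
#'   matrix, `NA` where unobserved), `observed` (logical mask), and
#'   `trait_names`.
#' @export
adjust_phenotypes <- function(raw_traits, covariates = NULL, transforms = NULL) {
  raw_traits <- as.matrix(raw_traits)
  n <- nrow(raw_traits); p <- ncol(raw_traits)
  trait_names <- colnames(raw_traits)
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(p))
  if (is.null(transforms)) transforms <- rep("identity", p)
  stopifnot(length(transforms) == p,
            all(transforms %in% c("identity", "log")))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n, is.numeric(covariates))
    cov_ok <- stats::complete.cases(covariates)
  } else {
    cov_ok <- rep(TRUE, n)
  }
  values <- matrix(NA_real_, n, p, dimnames = list(NULL, trait_names))
  observed <- matrix(FALSE, n, p)
  for (j in seq_len(p)) {
    y <- raw_traits[, j]
    obs <- !is.na(y) & cov_ok
    if (transforms[j] == "log") {
      if (any(y[obs] <= 0)) {
        stop(sprintf("trait '%s': log transform of non-positive value",
                     trait_names[j]))
      }
      y[obs] <- log(y[obs])
    }
    X <- cbind(`(Intercept)` = rep(1, n), covariates)[obs, , drop = FALSE]
    if (sum(obs) <= ncol(X) + 1L) {
      stop(sprintf("trait '%s': too few complete cases (%d) for %d covariates",
                   trait_names[j], sum(obs), ncol(X) - 1L))
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop(sprintf("rank-deficient covariate matrix; collinear column(s): %s",
                   paste(bad, collapse = ", ")))
    }
    r <- qr.resid(qrX, y[obs])
    values[obs, j] <- r - mean(r)
    observed[obs, j] <- TRUE
  }
  structure(list(values = values, observed = observed,
                 trait_names = trait_names),
            class = "adj_pheno")
}

#' Per-variant allele frequency and call rate
#'
#' @param dosage Samples x variants dosage matrix (`NA` missing).
#' @return Data.frame with columns `af` (A1 allele frequency over non-missing
#'   samples), `call_rate`, and `n_obs`.
#' @export
variant_stats <- function(dosage) {
  dosage <- as.matrix(dosage)
  n_obs <- colSums(!is.na(dosage))
  af <- colMeans(dosage, na.rm = TRUE) / 2
  data.frame(af = af, call_rate = n_obs / nrow(dosage), n_obs = n_obs)
}

#' Variant filter on minor-allele frequency and call rate
#'
#' Thresholds are inclusive: a variant is kept iff
#' `min(af, 1 - af) >= maf_min` and `call_rate >= call_rate_min`.
#'
#' @param stats Data.frame from [variant_stats()] (columns `af`, `call_rate`).
#' @param maf_min Minimum minor-allele frequency (default 0.001).
#' @param call_rate_min Minimum call rate (default 0.95).
#' @return Logical keep mask.
#' @export
filter_variants <- function(stats, maf_min = 0.001, call_rate_min = 0.95) {
  maf <- pmin(stats$af, 1 - stats$af)
  keep <- !is.na(maf) & maf >= maf_min & stats$call_rate >= call_rate_min
  if (!any(keep)) message("no variants pass the MAF/call-rate filter")
  keep
}

#' Partition samples by missing-value pattern
#'
#' Samples sharing the same set of observed traits form one group; the GLS
#' engine combines per-group sufficient statistics. Groups smaller than
#' `min_group_size` are excluded from analysis (their sample count is
#' reported); dropping small groups (e.g. n < 50) bounds the computational
#' cost of highly fragmented data.
#'
#' @param mask Logical samples x traits matrix, `TRUE` where observed.
#' @param min_group_size Minimum group size retained (default 1).
#' @return List of groups, each a list with `trait_mask` (logical p-vector),
#'   `member_indices`, and `size`; attribute `n_dropped` counts samples in
#'   excluded groups (including fully-missing rows).
#' @export
find_missing_patterns <- function(mask, min_group_size = 1L) {
  mask <- as.matrix(mask)
  stopifnot(is.logical(mask))
  any_obs <- rowSums(mask) > 0L
  if (!any(any_obs)) stop("every sample is missing all traits")
  key <- do.call(paste0, lapply(seq_len(ncol(mask)), function(j) mask[, j] + 0L))
  key[!any_obs] <- NA_character_
  split_idx <- split(which(any_obs), key[any_obs])
  groups <- lapply(split_idx, function(ix) {
    list(trait_mask = mask[ix[1L], ], member_indices = ix, size = length(ix))
  })
  sizes <- vapply(groups, `[[`, 0L, "size")
  small <- sizes < min_group_size
  n_dropped <- sum(!any_obs) + sum(sizes[small])
  if (any(small)) {
    message(sum(sizes[small]), " sample(s) in ", sum(small),
            " group(s) below min_group_size dropped")
  }
  groups <- unname(groups[!small])
  # deterministic order: by first member index
  ord <- order(vapply(groups, function(g) g$member_indices[1L], 0L))
  structure(groups[ord], n_dropped = n_dropped)
}

#' Estimate the error covariance from adjusted phenotypes
#'
#' Computes the trait-by-trait covariance of the adjusted phenotypes,
#' `S[j, j'] = sum_i y_ij y_ij' / (n_jj' - 1)` over pairwise-complete
#' samples. Because single SNPs explain only a small fraction of trait
#' variance, S approximates the residual covariance R from above (S - R-hat
#' is positive semi-definite), so it is computed once and reused for every
#' SNP; inference is at most slightly conservative. If the pairwise-complete
#' matrix is not positive definite, eigenvalues are clipped at
#' `1e-8 * max(eigenvalue)` and the repair is reported.
#'
#' @param adjusted An `adj_pheno` object from [adjust_phenotypes()].
#' @return List with `S` (p x p positive-definite matrix) and `n_pairs`
#'   (p x p joint-observation counts).
#' @export
estimate_error_covariance <- function(adjusted) {
  stopifnot(inherits(adjusted, "adj_pheno"))
  Y <- adjusted$values
  obs <- adjusted$observed
  Y0 <- ifelse(obs, Y, 0)
  n_pairs <- crossprod(obs)
  if (any(n_pairs < 3L)) {
    bad <- which(n_pairs < 3L, arr.ind = TRUE)
    bad <- bad[bad[, 1L] <= bad[, 2L], , drop = FALSE]
    stop("trait pair(s) jointly observed in < 3 samples: ",
         paste(sprintf("(%s,%s)", adjusted$trait_names[bad[, 1L]],
                       adjusted$trait_names[bad[, 2L]]), collapse = ", "))
  }
  S <- crossprod(Y0) / (n_pairs - 1)
  if (any(diag(S) <= 0)) stop("trait with zero residual variance")
  ev <- eigen(S, symmetric = TRUE)
  floor_ev <- 1e-8 * max(ev$values)
  if (min(ev$values) < floor_ev) {
    vals <- pmax(ev$values, floor_ev)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    S <- (S + t(S)) / 2
    message("error covariance not positive definite; eigenvalues clipped")
  }
  dimnames(S) <- list(adjusted$trait_names, adjusted$trait_names)
  list(S = S, n_pairs = n_pairs)
}
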