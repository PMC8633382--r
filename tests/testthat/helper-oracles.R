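# Independent oracles and fixture helpers shared across test files.

# Observation-level GLS: stacks one row per observed (sample, trait) cell and
# solves the full Omega-inverse-weighted normal equations, with Omega block
# diagonal per sample (block = S restricted to that sample's observed traits).
# Deliberately brute-force and independent of the grouped-sufficient-statistic
# path it checks.
brute_force_gls <- function(x, Y, S) {
  p <- ncol(Y)
  Xs <- NULL
  ys <- NULL
  blocks <- list()
  for (i in seq_len(nrow(Y))) {
    O <- which(!is.na(Y[i, ]))
    if (!length(O)) next
    E <- matrix(0, length(O), p)
    E[cbind(seq_along(O), O)] <- 1
    Xs <- rbind(Xs, x[i] * E)
    ys <- c(ys, Y[i, O])
    blocks[[length(blocks) + 1L]] <- S[O, O, drop = FALSE]
  }
  N <- length(ys)
  Om <- matrix(0, N, N)
  at <- 1L
  for (b in blocks) {
    k <- nrow(b)
    Om[at:(at + k - 1L), at:(at + k - 1L)] <- b
    at <- at + k
  }
  OiX <- solve(Om, Xs)
  A <- t(Xs) %*% OiX
  beta <- solve(A, t(OiX) %*% ys)
  list(beta_hat = drop(beta), cov_beta = solve(A))
}

# explicit-inverse quadratic form (oracle for wald_statistic)
quadform_oracle <- function(beta, cov, K) {
  drop(t(beta[K]) %*% solve(cov[K, K, drop = FALSE]) %*% beta[K])
}

# exhaustive stage p-value: enumerate every size-(p-s+1) subset, explicit
# inverses, independent chi-square tail
stage_pvalue_oracle <- function(beta, cov, stage) {
  p <- length(beta)
  sets <- utils::combn(p, p - stage + 1L, simplify = FALSE)
  w <- vapply(sets, function(K) quadform_oracle(beta, cov, K), 0)
  stats::pchisq(min(w), df = p - stage + 1L, lower.tail = FALSE)
}

random_pd <- function(p) {
  M <- matrix(rnorm(p * p), p)
  crossprod(M) + diag(p) * 0.5
}

# random small unbalanced instance; every trait observed in >= 2 samples so
# the normal equations stay well posed
random_instance <- function(n_max = 30L, p_max = 4L) {
  repeat {
    n <- sample(6:n_max, 1L)
    p <- sample(2:p_max, 1L)
    mask <- matrix(runif(n * p) > 0.3, n, p)
    mask[rowSums(mask) == 0L, 1L] <- TRUE
    if (all(colSums(mask) >= 2L)) break
  }
  x <- rnorm(n)
  x <- x - mean(x)
  Y <- matrix(rnorm(n * p), n, p)
  Y[!mask] <- NA_real_
  list(x = x, Y = Y, S = random_pd(p), n = n, p = p)
}

# run the grouped-GLS path of the package on a raw (x, Y, S) instance
grouped_gls <- function(x, Y, S) {
  adj <- structure(list(values = Y, observed = !is.na(Y),
                        trait_names = colnames(S)),
                   class = "adj_pheno")
  groups <- find_missing_patterns(!is.na(Y))
  gls_fit(accumulate_group_stats(x, adj, groups), S)
}

# single-linkage clustering by brute force: merge any two SNPs closer than
# gap, transitively, via repeated pairwise sweeps
single_linkage_oracle <- function(bp, gap) {
  id <- seq_along(bp)
  repeat {
    changed <- FALSE
    for (i in seq_along(bp)) for (j in seq_along(bp)) {
      if (id[i] != id[j] && abs(bp[i] - bp[j]) < gap) {
        id[id == id[j]] <- id[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(id, unique(id))
}

# minimal scan-results row builder for region tests
scan_row <- function(id, chrom, bp, p1, p2 = NA, mp = c(1, 1, 1)) {
  df <- data.frame(id = id, chrom = chrom, bp = bp, p1 = p1, p2 = p2)
  for (j in seq_along(mp)) df[[paste0("mp.trait", j)]] <- mp[j]
  df
}
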