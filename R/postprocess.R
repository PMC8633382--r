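# Genome-scan driver and post-GWAS region utilities.

#' Multi-trait pleiotropy scan over a PLINK fileset
#'
#' Streams variants in blocks, and for each SNP passing the MAF/call-rate
#' filter: centers the genotype (mean-imputing missing calls), accumulates
#' missing-pattern group statistics, fits the GLS effect estimates with the
#' shared error covariance, and computes the sequential IU p-values plus the
#' single-trait marginal p-values. Per-SNP failures are recorded and the
#' scan continues; output is deterministic given fixed inputs and identical
#' whether the scan is run in one pass or in chunks.
#'
#' @param bed,bim,fam Paths to the PLINK files.
#' @param pheno Path to the phenotype table (FID/IID keyed, header).
#' @param covar Optional covariate table path.
#' @param traits Optional trait column names (default: all phenotype
#'   columns).
#' @param transforms Optional per-trait transform vector passed to
#'   [adjust_phenotypes()].
#' @param maf_min,call_rate_min Variant filters (defaults 0.001 and 0.95,
#'   inclusive).
#' @param min_group_size Smallest missing-pattern group retained (default 1).
#' @param max_stage Highest pleiotropy stage tested (default: number of
#'   traits).
#' @param early_stop_p Early-stop threshold for the sequential test
#'   (default 1; 0.01 saves time in large scans).
#' @param chunk_size Variants decoded per block (default 512).
#' @param variant_range Optional 1-based index range `c(first, last)` into
#'   the .bim order, for chunked/parallel runs.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>.results.tsv`, `<prefix>.skipped.tsv` and `<prefix>.log.json`.
#' @return List with `results` (data.frame: id, chrom, bp, af, n_used,
#'   beta.<trait>, p1..p<max_stage> with `NA` for untested stages,
#'   mp.<trait> marginal p-values), `skipped` (id + reason), and `log`.
#' @export
run_scan <- function(bed, bim, fam, pheno, covar = NULL, traits = NULL,
                     transforms = NULL, maf_min = 0.001, call_rate_min = 0.95,
                     min_group_size = 1L, max_stage = NULL, early_stop_p = 1,
                     chunk_size = 512L, variant_range = NULL,
                     out_prefix = NULL) {
  bim_df <- read_bim(bim)
  fam_df <- read_fam(fam)
  n <- nrow(fam_df)
  Yraw <- read_table_aligned(pheno, fam_df, value_columns = traits)
  if (ncol(Yraw) < 2L) stop("at least two traits are required")
  Z <- if (!is.null(covar)) read_table_aligned(covar, fam_df) else NULL
  adj <- adjust_phenotypes(Yraw, Z, transforms)
  groups <- find_missing_patterns(adj$observed, min_group_size)
  S <- estimate_error_covariance(adj)$S
  p <- ncol(Yraw)
  if (is.null(max_stage)) max_stage <- p
  stopifnot(max_stage >= 1L, max_stage <= p)

  idx_all <- if (is.null(variant_range)) seq_len(nrow(bim_df))
             else seq.int(variant_range[1L], variant_range[2L])
  rows <- vector("list", length(idx_all))
  skipped <- list()
  n_filtered <- 0L
  trait_nm <- adj$trait_names
  for (start in seq.int(1L, length(idx_all), by = chunk_size)) {
    block_idx <- idx_all[seq.int(start, min(start + chunk_size - 1L,
                                            length(idx_all)))]
    G <- read_genotype_block(bed, n, block_idx)
    st <- variant_stats(G)
    keep <- filter_variants(st, maf_min, call_rate_min)
    for (k in seq_along(block_idx)) {
      i <- block_idx[k]
      vid <- bim_df$id[i]
      if (!keep[k]) {
        n_filtered <- n_filtered + 1L
        skipped[[length(skipped) + 1L]] <-
          data.frame(id = vid, reason = "maf/call-rate filter")
        next
      }
      cg <- center_genotype(G[, k])
      if (!is.null(cg$skip)) {
        skipped[[length(skipped) + 1L]] <- data.frame(id = vid, reason = cg$skip)
        next
      }
      row <- tryCatch({
        fit <- gls_fit(accumulate_group_stats(cg$x, adj, groups), S)
        seqr <- sequential_pvalues(fit$beta_hat, fit$cov_beta, max_stage,
                                   early_stop_p)
        pv <- rep(NA_real_, max_stage)
        pv[seq_len(seqr$stages_tested)] <- seqr$stage_p
        mp <- marginal_pvalues(fit$beta_hat, fit$cov_beta)
        as.data.frame(c(list(id = vid, chrom = bim_df$chrom[i],
                             bp = bim_df$bp[i], af = st$af[k],
                             n_used = fit$n_used),
                        setNames(as.list(fit$beta_hat),
                                 paste0("beta.", trait_nm)),
                        setNames(as.list(pv), paste0("p", seq_len(max_stage))),
                        setNames(as.list(mp), paste0("mp.", trait_nm))))
      }, pleio_singular_error = function(e) {
        skipped[[length(skipped) + 1L]] <<- data.frame(id = vid,
                                                       reason = e$message)
        NULL
      })
      if (!is.null(row)) rows[[match(i, idx_all)]] <- row
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(results)) {
    warning("no variants passed filtering")
    results <- data.frame()
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(id = character(), reason = character())
  log <- list(n_samples = n, n_traits = p, n_variants = length(idx_all),
              n_tested = nrow(results), n_skipped = nrow(skipped),
              n_filtered = n_filtered,
              n_groups = length(groups),
              n_dropped_samples = attr(groups, "n_dropped"),
              maf_min = maf_min, call_rate_min = call_rate_min,
              min_group_size = min_group_size, max_stage = max_stage,
              early_stop_p = early_stop_p)
  if (!is.null(out_prefix)) {
    write.table(results, paste0(out_prefix, ".results.tsv"), quote = FALSE,
                sep = "\t", row.names = FALSE)
    write.table(skipped, paste0(out_prefix, ".skipped.tsv"), quote = FALSE,
                sep = "\t", row.names = FALSE)
    jsonlite::write_json(log, paste0(out_prefix, ".log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, skipped = skipped, log = log)
}

#' Merge significant SNPs into non-overlapping genomic regions
#'
#' Per chromosome, significant SNPs (stage-1 p-value below `alpha`, strict)
#' are sorted by position and merged transitively whenever consecutive
#' positions differ by less than `gap_bp` (single-linkage clustering).
#' Region bounds are the min/max member positions (1-based, closed); the
#' lead SNP minimizes the region's smallest stage p-value (ties broken by
#' smaller bp). A region's pleiotropy order is the maximum order attained by
#' any member SNP, and its trait mask is the union of member masks from
#' [attribute_traits()]. The merge is idempotent and independent of input
#' row order.
#'
#' @param results Scan results data.frame from [run_scan()].
#' @param gap_bp Merge distance threshold in bp (default 1e6, i.e. 1 Mbp).
#' @param alpha Significance level (default 1e-8, strict inequality).
#' @param trait_alpha Marginal-p threshold for trait attribution (default
#'   `alpha`).
#' @return Data.frame of regions: `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `lead_snp`, `min_p`, `stage` (pleiotropy order), and one logical
#'   `trait.<name>` column per trait.
#' @export
group_regions <- function(results, gap_bp = 1e6, alpha = 1e-8,
                          trait_alpha = alpha) {
  stage_cols <- grep("^p[0-9]+$", names(results), value = TRUE)
  mp_cols <- grep("^mp\\.", names(results), value = TRUE)
  trait_nm <- sub("^mp\\.", "", mp_cols)
  if (!nrow(results)) return(.empty_regions(trait_nm))
  ord_of_row <- function(i) {
    pv <- unlist(results[i, stage_cols])
    pleiotropy_order(pv[!is.na(pv)], alpha)
  }
  orders <- vapply(seq_len(nrow(results)), ord_of_row, 0L)
  sig <- orders >= 1L
  if (!any(sig)) return(.empty_regions(trait_nm))
  sigres <- results[sig, , drop = FALSE]
  sigord <- orders[sig]
  out <- list()
  for (ch in unique(sigres$chrom)) {
    rows <- which(sigres$chrom == ch)
    rows <- rows[order(sigres$bp[rows])]
    bp <- sigres$bp[rows]
    new_region <- c(TRUE, diff(bp) >= gap_bp)
    rid <- cumsum(new_region)
    for (r in unique(rid)) {
      members <- rows[rid == r]
      mp <- as.matrix(sigres[members, mp_cols, drop = FALSE])
      morder <- sigord[members]
      masks <- t(vapply(seq_along(members), function(k) {
        attribute_traits(mp[k, ], morder[k], trait_alpha)$mask
      }, logical(length(trait_nm))))
      minp <- vapply(members, function(i) {
        pv <- unlist(sigres[i, stage_cols])
        min(pv, na.rm = TRUE)
      }, 0)
      lead <- members[order(minp, sigres$bp[members])][1L]
      reg <- data.frame(chrom = ch, start_bp = min(sigres$bp[members]),
                        end_bp = max(sigres$bp[members]),
                        n_snps = length(members),
                        lead_snp = sigres$id[lead], min_p = min(minp),
                        stage = max(morder), stringsAsFactors = FALSE)
      for (j in seq_along(trait_nm)) {
        reg[[paste0("trait.", trait_nm[j])]] <- any(masks[, j])
      }
      out[[length(out) + 1L]] <- reg
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_bp), , drop = FALSE]
}

.empty_regions <- function(trait_nm) {
  reg <- data.frame(chrom = character(), start_bp = integer(),
                    end_bp = integer(), n_snps = integer(),
                    lead_snp = character(), min_p = numeric(),
                    stage = integer(), stringsAsFactors = FALSE)
  for (nm in trait_nm) reg[[paste0("trait.", nm)]] <- logical()
  reg
}

#' Attribute traits to a significant SNP
#'
#' Flags traits whose marginal p-value is below `trait_alpha`. If fewer than
#' the SNP's declared pleiotropy order are flagged, the `order` traits with
#' the smallest marginal p-values are flagged instead and the result is
#' marked `forced`. The rule is an output convention for trait-sharing
#' tables (the stage test itself does not identify which traits drive it).
#'
#' @param marginal_p Numeric vector of single-trait p-values.
#' @param order Declared pleiotropy order of the SNP.
#' @param trait_alpha Marginal significance threshold.
#' @return List with `mask` (logical per trait) and `forced` (logical).
#' @export
attribute_traits <- function(marginal_p, order, trait_alpha = 1e-8) {
  mask <- marginal_p < trait_alpha
  forced <- FALSE
  if (sum(mask) < order) {
    mask <- rep(FALSE, length(marginal_p))
    mask[order(marginal_p)[seq_len(order)]] <- TRUE
    forced <- TRUE
  }
  list(mask = mask, forced = forced)
}

#' Pairwise trait-sharing counts over regions
#'
#' @param regions Region data.frame from [group_regions()] (with
#'   `trait.<name>` columns and `n_snps`).
#' @return List with `regions` and `snps`: symmetric p x p matrices whose
#'   (j, j') cell counts regions (resp. their member SNPs) whose trait mask
#'   contains both j and j'; diagonals are `NA`. Attribute `totals` gives
#'   per-trait totals of regions and SNPs involved in any sharing.
#' @export
pairwise_region_table <- function(regions) {
  trait_cols <- grep("^trait\\.", names(regions), value = TRUE)
  trait_nm <- sub("^trait\\.", "", trait_cols)
  p <- length(trait_nm)
  cnt_reg <- matrix(0L, p, p, dimnames = list(trait_nm, trait_nm))
  cnt_snp <- cnt_reg
  for (i in seq_len(nrow(regions))) {
    on <- which(unlist(regions[i, trait_cols]))
    if (length(on) < 2L) next
    for (a in on) for (b in on) if (a != b) {
      cnt_reg[a, b] <- cnt_reg[a, b] + 1L
      cnt_snp[a, b] <- cnt_snp[a, b] + regions$n_snps[i]
    }
  }
  totals <- data.frame(trait = trait_nm,
                       regions = vapply(seq_len(p), function(j)
                         .trait_total(regions, trait_cols, j), 0L),
                       snps = vapply(seq_len(p), function(j)
                         .trait_total(regions, trait_cols, j,
                                      weights = regions$n_snps), 0L))
  diag(cnt_reg) <- NA_integer_
  diag(cnt_snp) <- NA_integer_
  structure(list(regions = cnt_reg, snps = cnt_snp), totals = totals)
}

# regions (optionally SNP-weighted) where trait j is shared with >= 1 other
.trait_total <- function(regions, trait_cols, j, weights = NULL) {
  if (!nrow(regions)) return(0L)
  m <- as.matrix(regions[, trait_cols, drop = FALSE])
  hit <- m[, j] & rowSums(m) >= 2L
  if (is.null(weights)) sum(hit) else as.integer(sum(weights[hit]))
}
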