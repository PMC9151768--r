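#' Prepare an editing matrix for edQTL mapping
#'
#' Drops sites detected in fewer than `min_detection` of donors, then
#' imputes remaining missing values by k-nearest predictive mean matching
#' (PMM): each incomplete site is regressed on the most-correlated complete
#' sites, every donor gets a predicted value, and each missing entry copies
#' the observed value of one of the `k` donors with the nearest predictions
#' (sampled uniformly). A median-imputation fallback is available.
#'
#' @param editing site x donor matrix with NAs.
#' @param min_detection minimum fraction of donors with an observed value.
#' @param method "pmm" or "median".
#' @param k PMM donor-candidate neighbourhood size.
#' @param n_predictors number of complete predictor sites per regression.
#' @param min_observed sites with fewer observed values are dropped (and
#'   reported via the `dropped` attribute).
#' @param seed integer seed (PMM draws are stochastic).
#' @return complete matrix; attributes `dropped_detection` and
#'   `dropped_sparse` list removed sites.
#' @export
prepare_editing_for_qtl <- function(editing, min_detection = 0.5,
                                    method = c("pmm", "median"), k = 5L,
                                    n_predictors = 5L, min_observed = 3L,
                                    seed = 1L) {
  method <- match.arg(method)
  stop_if_not(min_detection > 0 && min_detection <= 1,
              "min_detection must lie in (0, 1]")
  editing <- as.matrix(editing)
  obs_frac <- rowMeans(!is.na(editing))
  drop1 <- rownames(editing)[obs_frac < min_detection]
  editing <- editing[obs_frac >= min_detection, , drop = FALSE]
  nobs <- rowSums(!is.na(editing))
  drop2 <- rownames(editing)[nobs < min_observed]
  editing <- editing[nobs >= min_observed, , drop = FALSE]

  if (anyNA(editing)) {
    complete <- which(rowSums(is.na(editing)) == 0L)
    incomplete <- which(rowSums(is.na(editing)) > 0L)
    with_local_seed(seed, {
      for (s in incomplete) {
        y <- editing[s, ]
        miss <- is.na(y)
        if (method == "median" || length(complete) == 0L) {
          editing[s, miss] <- stats::median(y, na.rm = TRUE)
          next
        }
        cors <- abs(stats::cor(y, t(editing[complete, , drop = FALSE]),
                               use = "pairwise.complete.obs"))[1, ]
        cors[is.na(cors)] <- 0
        pred_sites <- complete[order(cors, decreasing = TRUE)][
          seq_len(min(n_predictors, length(complete)))]
        Xp <- cbind(1, t(editing[pred_sites, , drop = FALSE]))
        fit <- stats::lm.fit(Xp[!miss, , drop = FALSE], y[!miss])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        yhat <- as.numeric(Xp %*% beta)
        for (j in which(miss)) {
          dist <- abs(yhat[!miss] - yhat[j])
          cand <- order(dist)[seq_len(min(k, sum(!miss)))]
          donor_pool <- which(!miss)[cand]
          editing[s, j] <- y[sample(donor_pool, 1L)]
        }
      }
    })
  }
  attr(editing, "dropped_detection") <- drop1
  attr(editing, "dropped_sparse") <- drop2
  editing
}

#' Map cis editing quantitative trait loci
#'
#' For every SNP-site pair within `window` bp on the same chromosome, fits
#' `editing ~ dosage + covariates` across donors and reports the additive
#' effect, standard error, t and p. Benjamini-Hochberg FDR is applied across
#' all pairs of all chromosomes jointly; pairs below `fdr` are flagged
#' significant. Monomorphic SNPs are skipped and reported.
#'
#' @param editing site x donor matrix (complete; see
#'   [prepare_editing_for_qtl()]).
#' @param site_pos data.frame: site_id, chrom, pos (one row per editing row).
#' @param genotypes a `GenotypeMatrix` (donor columns must match the editing
#'   columns).
#' @param covariates data.frame of per-donor covariates (e.g. sex, age,
#'   RIN, death type); factors are expanded to dummy contrasts.
#' @param window maximum |SNP - site| distance in bp.
#' @param fdr significance threshold on BH-adjusted p.
#' @return data.frame of `EdqtlPair` rows: snp_id, site_id, distance, beta,
#'   se, t, p, fdr, significant; attribute `skipped` names monomorphic SNPs.
#' @export
map_cis_edqtl <- function(editing, site_pos, genotypes, covariates = NULL,
                          window = 1e6, fdr = 0.05) {
  editing <- as.matrix(editing)
  stop_if_not(nrow(site_pos) == nrow(editing),
              "site_pos must describe every editing row")
  donors <- colnames(editing)
  stop_if_not(!is.null(donors) && all(donors %in% colnames(genotypes$dosage)),
              "donors must be aligned between editing and genotypes")
  dos <- genotypes$dosage[, donors, drop = FALSE]
  snps <- genotypes$snps
  mono <- apply(dos, 1L, function(z) stats::sd(z) == 0)
  Xc <- matrix(1, nrow = length(donors), ncol = 1)
  if (!is.null(covariates)) {
    stop_if_not(nrow(covariates) == length(donors), "one covariate row per donor")
    stop_if_not(!anyNA(covariates), "covariates must be complete")
    Xc <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  rows <- list()
  for (si in seq_len(nrow(site_pos))) {
    near <- which(snps$chrom == site_pos$chrom[si] &
                    abs(snps$pos - site_pos$pos[si]) <= window)
    for (vi in near) {
      if (mono[vi]) next
      X <- cbind(dosage = dos[vi, ], Xc)
      fit <- stats::lm.fit(X, editing[si, ])
      dfree <- length(donors) - fit$rank
      rss <- sum(fit$residuals^2)
      sigma2 <- rss / dfree
      R <- qr.R(fit$qr)
      xtxi <- chol2inv(R)
      # dosage is pivot-tracked: locate its column after pivoting
      pcol <- match(1L, fit$qr$pivot)
      se <- sqrt(sigma2 * xtxi[pcol, pcol])
      beta <- fit$coefficients["dosage"]
      tval <- beta / se
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps$snp_id[vi], site_id = site_pos$site_id[si],
        distance = snps$pos[vi] - site_pos$pos[si],
        beta = unname(beta), se = se, t = unname(tval),
        p = 2 * stats::pt(abs(tval), dfree, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  stop_if_not(length(rows) > 0, "no testable SNP-site pairs in the cis window")
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr
  attr(out, "skipped") <- snps$snp_id[mono]
  out
}

#' Select the max-edQTL per site
#'
#' For every site with at least one significant pair, keeps the single most
#' significant SNP-site pair: minimum p, ties broken by larger |beta|, then
#' smaller |distance|, then lexicographic SNP id.
#'
#' @param pairs output of [map_cis_edqtl()].
#' @return one row per site with a significant pair.
#' @export
select_max_edqtl <- function(pairs) {
  sig <- pairs[isTRUE_vec(pairs$significant, nrow(pairs)), , drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  ord <- order(sig$site_id, sig$p, -abs(sig$beta), abs(sig$distance), sig$snp_id)
  sig <- sig[ord, , drop = FALSE]
  out <- sig[!duplicated(sig$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP-site distance profile of max-edQTLs
#'
#' Histogram of |SNP - site| distances plus the fraction of pairs within a
#' radius (default 200 kb).
#'
#' @param pairs data.frame with a `distance` column (bp, signed).
#' @param bin_width histogram bin width in bp.
#' @param radius reporting radius in bp.
#' @return list: `histogram` (data.frame bin_start, bin_end, count) and
#'   `fraction_within`.
#' @export
distance_profile <- function(pairs, bin_width = 50000L, radius = 200000L) {
  stop_if_not(nrow(pairs) > 0, "no pairs to profile")
  d <- abs(pairs$distance)
  brk <- seq(0, max(d) + bin_width, by = bin_width)
  h <- hist(d, breaks = brk, plot = FALSE)
  list(histogram = data.frame(bin_start = utils::head(brk, -1),
                              bin_end = brk[-1], count = h$counts),
       fraction_within = mean(d <= radius))
}

#' Cell-type annotation of max-edQTLs and effect-size comparison
#'
#' Joins specificity labels onto max-edQTL pairs and compares |beta|
#' between cell-type-associated (specific or enriched) and unannotated
#' sites with a two-sided Mann-Whitney test.
#'
#' @param max_pairs output of [select_max_edqtl()].
#' @param labels data.frame from [classify_specificity()] (site_id, label).
#' @return list: `pairs` (with `annotation` column: the label, or
#'   "unannotated") and `beta_test` (n per group, median |beta|, p; p is NA
#'   with a note when a group has < 2 members).
#' @export
annotate_edqtl_celltype <- function(max_pairs, labels) {
  ann <- labels$label[match(max_pairs$site_id, labels$site_id)]
  ann[is.na(ann)] <- "unannotated"
  max_pairs$annotation <- ann
  assoc <- category_base(ann) %in% c("specific", "enriched")
  a <- abs(max_pairs$beta[assoc]); u <- abs(max_pairs$beta[!assoc])
  bt <- if (length(a) < 2L || length(u) < 2L) {
    list(n_associated = length(a), n_unannotated = length(u),
         median_beta_associated = stats::median(a),
         median_beta_unannotated = stats::median(u),
         p = NA_real_, note = "skipped: group with < 2 members")
  } else {
    list(n_associated = length(a), n_unannotated = length(u),
         median_beta_associated = stats::median(a),
         median_beta_unannotated = stats::median(u),
         p = stats::wilcox.test(a, u, exact = FALSE)$p.value, note = "")
  }
  list(pairs = max_pairs, beta_test = bt)
}
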