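#' Cohen's d effect size
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, with the pooled standard deviation
#' weighted by degrees of freedom.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return Cohen's d; positive when `a` has the larger mean.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stop_if_not(length(a) >= 2 && length(b) >= 2, "each group needs >= 2 values")
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  stop_if_not(sp > 0, "pooled SD is zero: Cohen's d undefined")
  (mean(a) - mean(b)) / sp
}

#' Differential editing between two cell types
#'
#' Per site, fits `editing ~ cell type + covariates` across the samples of
#' the two contrasted cell types. Donor as a repeated measure is handled by
#' estimating one consensus intra-donor correlation (the average over sites
#' of the within-donor residual correlation after an ordinary least squares
#' fit) and refitting by generalized least squares under a
#' compound-symmetry covariance (`donor = "gls"`, the default); a
#' fixed-effect donor term (`"fixed"`) and no donor adjustment (`"none"`)
#' are available. Two-sided p values are Benjamini-Hochberg adjusted across
#' all sites of the contrast.
#'
#' Sites with zero residual variance are flagged degenerate and assigned
#' p = 1 rather than raising an error.
#'
#' @param sm a `SiteMatrix` (complete, i.e. after imputation, for the
#'   samples of the contrast).
#' @param contrast character(2): the two cell types; the reported change in
#'   editing is `mean(contrast[1]) - mean(contrast[2])`.
#' @param covariates sample-metadata columns used as fixed covariates
#'   (default age and PMI).
#' @param donor donor handling: "gls", "fixed" or "none".
#' @param adar_covariates optional additional metadata columns (e.g. ADAR1
#'   and ADAR2 expression) for the ADAR-adjusted secondary model.
#' @param fdr_threshold significance threshold on the adjusted p value.
#' @return data.frame: site_id, delta, t, p, fdr, cohens_d, degenerate,
#'   significant; attribute `rho` carries the consensus correlation.
#' @export
differential_editing <- function(sm, contrast,
                                 covariates = c("age", "PMI"),
                                 donor = c("gls", "fixed", "none"),
                                 adar_covariates = NULL,
                                 fdr_threshold = 0.05) {
  donor <- match.arg(donor)
  stop_if_not(length(contrast) == 2L, "contrast must name two cell types")
  keep <- sm$samples$cell_type %in% contrast
  stop_if_not(sum(sm$samples$cell_type == contrast[1]) >= 3 &&
                sum(sm$samples$cell_type == contrast[2]) >= 3,
              "need >= 3 samples per group")
  sub <- sm[, keep]
  meta <- sub$samples
  y <- sub$level
  grp <- factor(meta$cell_type, levels = rev(contrast))  # coef = group1 - group2
  covs <- c(covariates, adar_covariates)
  for (cv in covs) stop_if_not(!anyNA(meta[[cv]]), "covariate '%s' incomplete", cv)
  mm_df <- data.frame(grp = grp, meta[covs], check.names = FALSE)
  X <- stats::model.matrix(stats::reformulate(c("grp", covs)), data = mm_df)
  if (donor == "fixed") {
    Xd <- stats::model.matrix(~ factor(meta$donor))[, -1, drop = FALSE]
    X <- cbind(X, Xd)
  }
  coef_idx <- 2L  # the cell-type term

  fit_all <- function(Xw, Yw) {
    n <- nrow(Xw); p <- ncol(Xw)
    qr_x <- qr(Xw)
    coefs <- qr.coef(qr_x, t(Yw))
    res <- t(Yw) - Xw %*% coefs
    rss <- colSums(res^2)
    xtxi <- chol2inv(qr.R(qr_x))
    se2 <- xtxi[coef_idx, coef_idx]
    sigma2 <- rss / (n - p)
    tstat <- coefs[coef_idx, ] / sqrt(se2 * sigma2)
    list(beta = coefs[coef_idx, ], t = tstat, sigma2 = sigma2,
         df = n - p, res = t(res))
  }

  ols <- fit_all(X, y)
  rho <- 0
  if (donor == "gls") {
    # consensus within-donor correlation by moment matching. The naive
    # correlation of OLS residual pairs is biased (residuals inherit
    # hat-matrix structure), so match the observed mean pair product to its
    # expectation under compound symmetry: with M = I - H and Boff the
    # within-donor pair indicator,
    #   E[mean_d e_i e_j]   = sigma^2 (a + rho b) / D
    #   E[RSS / (n - p)]    = sigma^2 (1 + rho c / (n - p))
    # where a, b, c are the corresponding traces; solve the linear equation.
    dn <- meta$donor
    paired <- names(which(table(dn) == 2L))
    if (length(paired) >= 3L && nrow(y) >= 2L) {
      i1 <- match(paired, dn)
      i2 <- length(dn) + 1L - match(paired, rev(dn))
      D <- length(paired)
      n <- nrow(X); p <- ncol(X)
      Q <- qr.Q(qr(X))
      M <- diag(n) - tcrossprod(Q)
      Boff <- matrix(0, n, n)
      Boff[cbind(i1, i2)] <- 1; Boff[cbind(i2, i1)] <- 1
      MBM <- M %*% Boff %*% M
      a <- sum(M[cbind(i1, i2)])
      b <- sum(MBM[cbind(i1, i2)])
      cc <- sum(diag(M %*% Boff))
      m_s <- rowMeans(ols$res[, i1, drop = FALSE] * ols$res[, i2, drop = FALSE])
      s2_s <- ols$sigma2
      r_obs <- mean(m_s) / mean(s2_s)
      denom <- b - r_obs * D * cc / (n - p)
      rho <- if (abs(denom) > 1e-12) (r_obs * D - a) / denom else 0
      if (!is.finite(rho)) rho <- 0
      rho <- max(min(rho, 0.95), -0.45)
    }
  }
  if (donor == "gls" && abs(rho) > 1e-8) {
    # whiten per donor block under compound symmetry
    W <- diag(nrow(X))
    for (d in unique(meta$donor)) {
      idx <- which(meta$donor == d)
      m <- length(idx)
      R <- matrix(rho, m, m); diag(R) <- 1
      e <- eigen(R, symmetric = TRUE)
      Rinv_half <- e$vectors %*% diag(1 / sqrt(e$values), m) %*% t(e$vectors)
      W[idx, idx] <- Rinv_half
    }
    fit <- fit_all(W %*% X, y %*% t(W))
  } else {
    fit <- fit_all(X, y)
  }

  degenerate <- fit$sigma2 < 1e-20 | !is.finite(fit$t)
  p <- 2 * stats::pt(abs(fit$t), df = fit$df, lower.tail = FALSE)
  p[degenerate] <- 1
  m1 <- rowMeans(y[, meta$cell_type == contrast[1], drop = FALSE])
  m2 <- rowMeans(y[, meta$cell_type == contrast[2], drop = FALSE])
  d <- vapply(seq_len(nrow(y)), function(s) {
    a <- y[s, meta$cell_type == contrast[1]]
    b <- y[s, meta$cell_type == contrast[2]]
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) 0 else (mean(a) - mean(b)) / sp
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(site_id = sub$sites$site_id,
                    delta = m1 - m2, t = as.numeric(fit$t), p = p, fdr = fdr,
                    cohens_d = d, degenerate = degenerate,
                    significant = fdr < fdr_threshold & !degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  attr(out, "rho") <- rho
  out
}

#' Classify sites as cell-type specific, enriched or shared
#'
#' A site detected in exactly one cell type, with re-query evidence
#' (covered-unedited or insufficient-coverage) recorded for the remaining
#' cell types, is `specific:<cell type>`. A site detected in two or more
#' cell types with at least one pairwise contrast at FDR < `fdr_threshold`
#' is `enriched:<cell type>`, where the direction is the cell type with the
#' higher mean in the significant contrasts it wins. All other multi-cell
#' sites are `shared`.
#'
#' @param sites data.frame with site_id and `detected_in` (comma-separated
#'   cell types), e.g. from [apply_filter_cascade()].
#' @param requery data.frame from [requery_other_celltypes()].
#' @param diff_results list of [differential_editing()] results (one per
#'   contrast).
#' @param fdr_threshold significance cutoff.
#' @param cell_types the full cell-type universe; single-cell-type sites
#'   need re-query evidence for every other member. Defaults to the union
#'   of cell types seen in `sites` and the contrasts.
#' @return data.frame: site_id, label, n_detected, evidence.
#' @export
classify_specificity <- function(sites, requery, diff_results,
                                 fdr_threshold = 0.05, cell_types = NULL) {
  det <- strsplit(sites$detected_in, ",")
  n_det <- lengths(det)
  if (is.null(cell_types)) {
    cell_types <- unique(c(unlist(det),
                           unlist(lapply(diff_results, attr, "contrast"))))
  }
  label <- character(nrow(sites))
  evidence <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cts <- det[[i]]
    if (n_det[i] == 1L) {
      rq <- requery[requery$site_id == sites$site_id[i], , drop = FALSE]
      others <- setdiff(cell_types, cts)
      missing <- setdiff(others, rq$cell_type)
      if (length(missing) > 0L) {
        stop(sprintf("site %s lacks re-query evidence for: %s",
                     sites$site_id[i], paste(missing, collapse = ", ")),
             call. = FALSE)
      }
      label[i] <- paste0("specific:", cts)
      evidence[i] <- paste(paste(rq$cell_type, rq$label, sep = "="),
                           collapse = ";")
    } else {
      wins <- character(0); fdrs <- numeric(0)
      for (dr in diff_results) {
        con <- attr(dr, "contrast")
        if (!all(con %in% cts)) next
        row <- dr[dr$site_id == sites$site_id[i], , drop = FALSE]
        if (nrow(row) == 0L || row$degenerate) next
        if (row$fdr < fdr_threshold) {
          winner <- if (row$delta > 0) con[1] else con[2]
          wins <- c(wins, winner); fdrs <- c(fdrs, row$fdr)
        }
      }
      if (length(wins) > 0L) {
        tab <- sort(table(wins), decreasing = TRUE)
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1L) top <- wins[which.min(fdrs)]
        label[i] <- paste0("enriched:", top[1])
        evidence[i] <- paste(sprintf("%s(fdr=%.3g)", wins, fdrs), collapse = ";")
      } else {
        label[i] <- "shared"
      }
    }
  }
  data.frame(site_id = sites$site_id, label = label, n_detected = n_det,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Partition per-site editing variance across known factors
#'
#' Per site, fits a linear mixed model treating categorical factors as
#' random grouping effects and continuous factors as fixed covariates, and
#' reports the fraction of variance attributable to each factor: random
#' effects contribute their variance component, each continuous covariate
#' contributes the variance of its fitted term, and the residual takes the
#' remainder. Fractions are non-negative and sum to 1, and are invariant to
#' affine rescaling of continuous covariates.
#'
#' @param sm a `SiteMatrix` with complete levels.
#' @param categorical sample-metadata columns treated as grouping factors.
#' @param continuous sample-metadata columns treated as fixed covariates.
#' @param cond_max condition-number bound on the continuous design;
#'   collinear factor pairs raise an error.
#' @return data.frame: site_id plus one fraction column per factor and
#'   `residual`.
#' @importFrom lme4 lmer VarCorr lmerControl
#' @export
variance_partition <- function(sm, categorical = c("cell_type", "donor"),
                               continuous = c("age", "pH", "PMI",
                                              "ADAR1", "ADAR2", "ADAR3"),
                               cond_max = 1e8) {
  meta <- sm$samples
  for (f in c(categorical, continuous))
    stop_if_not(!is.null(meta[[f]]) && !anyNA(meta[[f]]),
                "factor '%s' missing or incomplete", f)
  Z <- scale(as.matrix(meta[continuous]))
  if (length(continuous) >= 2L) {
    cn <- kappa(crossprod(Z) / (nrow(Z) - 1), exact = TRUE)
    if (!is.finite(cn) || cn > cond_max) {
      cm <- stats::cor(Z)
      diag(cm) <- 0
      worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
      stop(sprintf("collinear continuous factors: %s and %s",
                   continuous[worst[1]], continuous[worst[2]]), call. = FALSE)
    }
  }
  dat <- data.frame(meta[c(categorical, continuous)])
  form <- stats::as.formula(paste(
    "y ~", paste(c(continuous, sprintf("(1 | %s)", categorical)),
                 collapse = " + ")))
  out <- matrix(NA_real_, nrow(sm$sites), length(categorical) + length(continuous) + 1L,
                dimnames = list(NULL, c(categorical, continuous, "residual")))
  for (s in seq_len(nrow(sm$sites))) {
    dat$y <- sm$level[s, ]
    # exact-fit degenerate case: one categorical factor explains y perfectly
    done <- FALSE
    for (cf in categorical) {
      gm <- stats::ave(dat$y, dat[[cf]])
      if (stats::var(dat$y) > 0 && sum((dat$y - gm)^2) < 1e-24) {
        out[s, ] <- 0; out[s, cf] <- 1
        done <- TRUE; break
      }
    }
    if (done) next
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) { out[s, ] <- c(rep(0, length(categorical) + length(continuous)), 1); next }
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- stats::setNames(vc$vcov[match(categorical, vc$grp)], categorical)
    re_var[is.na(re_var)] <- 0
    resid_var <- vc$vcov[vc$grp == "Residual"]
    fe <- lme4::fixef(fit)
    fx_var <- vapply(continuous, function(cv) {
      b <- fe[[cv]]
      if (is.null(b) || is.na(b)) 0 else stats::var(b * dat[[cv]])
    }, numeric(1))
    tot <- sum(re_var) + sum(fx_var) + resid_var
    out[s, ] <- c(re_var, fx_var, resid_var) / tot
  }
  data.frame(site_id = sm$sites$site_id, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Association of editing levels with ADAR expression
#'
#' Per site, regresses the editing level on one ADAR enzyme's expression,
#' adjusting for donor as a fixed effect, with Benjamini-Hochberg FDR across
#' sites. Constant-editing sites are flagged degenerate (slope 0, p = 1).
#'
#' @param sm a `SiteMatrix` with complete levels.
#' @param expression numeric vector of ADAR expression, one value per sample.
#' @param adjust_donor include donor fixed effects?
#' @return data.frame: site_id, slope, t, p, fdr, degenerate.
#' @export
adar_association <- function(sm, expression, adjust_donor = TRUE) {
  stop_if_not(length(expression) == nrow(sm$samples),
              "need one expression value per sample")
  stop_if_not(stats::sd(expression) > 0, "constant expression: association undefined")
  X <- cbind(1, expression)
  if (adjust_donor && length(unique(sm$samples$donor)) > 1L) {
    X <- cbind(X, stats::model.matrix(~ factor(sm$samples$donor))[, -1, drop = FALSE])
  }
  qr_x <- qr(X)
  stop_if_not(qr_x$rank == ncol(X), "expression collinear with donor structure")
  n <- nrow(X); p <- ncol(X)
  coefs <- qr.coef(qr_x, t(sm$level))
  res <- t(sm$level) - X %*% coefs
  sigma2 <- colSums(res^2) / (n - p)
  se2 <- chol2inv(qr.R(qr_x))[2, 2]
  tstat <- coefs[2, ] / sqrt(se2 * sigma2)
  degenerate <- sigma2 < 1e-20 | !is.finite(tstat)
  pval <- 2 * stats::pt(abs(tstat), n - p, lower.tail = FALSE)
  pval[degenerate] <- 1
  slope <- coefs[2, ]; slope[degenerate & !is.finite(slope)] <- 0
  slope[apply(sm$level, 1L, stats::sd) == 0] <- 0
  data.frame(site_id = sm$sites$site_id, slope = slope,
             t = as.numeric(tstat), p = pval,
             fdr = stats::p.adjust(pval, "BH"),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Gene-level editing density with outlier calls
#'
#' Density is the number of editing sites on the gene divided by
#' log2(gene length + 1). Outliers lie beyond the 99% interval around the
#' grand mean of densities: normal-theory bounds `mean +/- z(0.995) * SD`
#' by default, or the empirical [0.5%, 99.5%] quantiles.
#'
#' @param site_gene character vector of gene ids, one entry per site
#'   (NA entries are dropped).
#' @param genes data.frame with gene_id and either `length` or start/end.
#' @param method "normal" or "quantile" outlier bounds.
#' @return data.frame: gene_id, n_sites, length, density, outlier.
#' @export
gene_editing_density <- function(site_gene, genes, method = c("normal", "quantile")) {
  method <- match.arg(method)
  len <- genes$length %||% (genes$end - genes$start + 1L)
  stop_if_not(all(len > 0), "gene length must be positive")
  cnt <- table(factor(site_gene[!is.na(site_gene)], levels = genes$gene_id))
  density <- as.numeric(cnt) / log2(len + 1)
  if (method == "normal") {
    z <- stats::qnorm(0.995)
    lo <- mean(density) - z * stats::sd(density)
    hi <- mean(density) + z * stats::sd(density)
  } else {
    q <- stats::quantile(density, c(0.005, 0.995))
    lo <- q[1]; hi <- q[2]
  }
  data.frame(gene_id = genes$gene_id, n_sites = as.integer(cnt),
             length = len, density = density,
             outlier = density < lo | density > hi,
             stringsAsFactors = FALSE)
}

#' Fisher overlap enrichment of two sets against a background
#'
#' One-sided (over-representation) Fisher's exact test on the 2x2 table
#' formed by membership in A and B within the background universe, with the
#' sample odds ratio from the table (capped when a margin is empty).
#'
#' @param setA,setB character vectors, subsets of `background`.
#' @param background character vector: the universe.
#' @param or_cap reported odds ratio when the table estimate is infinite.
#' @return list with `odds_ratio`, `p`, and `table`.
#' @export
overlap_enrichment <- function(setA, setB, background, or_cap = 1e6) {
  stop_if_not(length(background) > 0, "background must be non-empty")
  setA <- unique(setA); setB <- unique(setB); background <- unique(background)
  stop_if_not(all(setA %in% background) && all(setB %in% background),
              "setA and setB must be subsets of the background")
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  cc <- length(setdiff(setB, setA))
  d <- length(background) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b == 0 || cc == 0) {
    if (a == 0) 0 else or_cap
  } else (a * d) / (b * cc)
  list(odds_ratio = or, p = p, table = tab)
}

#' Permutation test of genomic region overlap
#'
#' Compares the observed number of query regions overlapping any target
#' region with a null built by redrawing the query regions uniformly at
#' random, preserving each region's length and per-chromosome counts.
#' `p = (1 + #{perm >= observed}) / (n_perm + 1)`; the z-score uses the
#' permutation mean and SD.
#'
#' @param query,target interval data.frames (chrom, start, end).
#' @param genome a `GenomeBundle` (chromosome lengths bound the sampling).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: observed, perm_mean, perm_sd, z, p, n_perm.
#' @export
permutation_region_overlap <- function(query, target, genome,
                                       n_perm = 1000L, seed = 1L) {
  lens <- nchar(genome$chromosomes)
  stop_if_not(all(query$chrom %in% names(lens)) &&
                all(target$chrom %in% names(lens)), "unknown chromosome")
  w <- query$end - query$start + 1L
  stop_if_not(all(w <= lens[query$chrom]),
              "query region longer than its chromosome")
  count_overlaps <- function(qs, qe, qc) {
    tot <- 0L
    for (cn in unique(qc)) {
      ti <- target[target$chrom == cn, , drop = FALSE]
      qi <- which(qc == cn)
      if (nrow(ti) == 0L || length(qi) == 0L) next
      tot <- tot + sum(IRanges::countOverlaps(
        IRanges::IRanges(qs[qi], qe[qi]),
        IRanges::IRanges(ti$start, ti$end)) > 0L)
    }
    tot
  }
  obs <- count_overlaps(query$start, query$end, query$chrom)
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      smax <- lens[query$chrom] - w + 1L
      s <- 1L + floor(stats::runif(length(w)) * smax)
      count_overlaps(s, s + w - 1L, query$chrom)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  sdv <- stats::sd(perm)
  list(observed = obs, perm_mean = mean(perm), perm_sd = sdv,
       z = if (sdv > 0) (obs - mean(perm)) / sdv else NA_real_,
       p = p, n_perm = n_perm)
}
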