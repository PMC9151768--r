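#' CPM filter and log2 transform of a count matrix
#'
#' Counts per million are computed against per-sample library sizes; genes
#' with CPM >= `min_cpm` in at least `min_fraction` of samples (inclusive)
#' are retained and returned as log2(CPM + 1).
#'
#' @param counts gene x sample count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction fraction of samples required at threshold.
#' @return log2(CPM + 1) matrix of the retained genes.
#' @export
cpm_filter_log <- function(counts, min_cpm = 1, min_fraction = 0.5) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  stop_if_not(all(libsize > 0), "zero library size")
  cpm <- sweep(counts, 2L, libsize, "/") * 1e6
  keep <- rowMeans(cpm >= min_cpm) >= min_fraction
  log2(cpm[keep, , drop = FALSE] + 1)
}

#' Cell-type fraction estimation by non-negative least squares
#'
#' Per sample, solves `min || S f - b ||` subject to `f >= 0` over the genes
#' shared between the bulk profile and the signature matrix (both on the
#' log2-CPM scale), then sums the excitatory and inhibitory neuronal
#' estimates into one neuronal fraction and normalizes fractions to sum
#' to 1.
#'
#' @param bulk gene x sample matrix (log2-CPM).
#' @param signature gene x cell-type matrix; neuronal columns named in
#'   `neuronal_cols` are summed post-fit.
#' @param neuronal_cols signature columns combined into "neuronal" (set
#'   NULL to skip).
#' @return data.frame: sample_id, one fraction column per (combined) cell
#'   type, residual_norm.
#' @export
estimate_fractions_nnls <- function(bulk, signature,
                                    neuronal_cols = c("excitatory", "inhibitory")) {
  bulk <- as.matrix(bulk); signature <- as.matrix(signature)
  shared <- intersect(rownames(bulk), rownames(signature))
  stop_if_not(length(shared) >= 10L,
              "need >= 10 shared genes between bulk and signature (got %d)",
              length(shared))
  S <- signature[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  out <- lapply(seq_len(ncol(B)), function(j) {
    fit <- pracma::lsqnonneg(S, B[, j])
    f <- fit$x
    names(f) <- colnames(S)
    if (!is.null(neuronal_cols) && all(neuronal_cols %in% names(f))) {
      f <- c(f[setdiff(names(f), neuronal_cols)],
             neuronal = sum(f[neuronal_cols]))
    }
    tot <- sum(f)
    if (tot > 0) f <- f / tot
    c(f, residual_norm = sqrt(fit$resid.norm))
  })
  res <- as.data.frame(do.call(rbind, out))
  data.frame(sample_id = colnames(B) %||% sprintf("S%03d", seq_len(ncol(B))),
             res, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Variance explained by a single predictor
#'
#' R-squared of the ordinary least squares regression of `response` on
#' `predictor`.
#'
#' @param response,predictor numeric vectors (>= 3 samples).
#' @return R-squared in [0, 1].
#' @export
variance_explained <- function(response, predictor) {
  ok <- stats::complete.cases(response, predictor)
  stop_if_not(sum(ok) >= 3, "need >= 3 complete samples")
  stop_if_not(stats::sd(predictor[ok]) > 0, "constant predictor")
  fit <- stats::lm(response[ok] ~ predictor[ok])
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate answer here
  suppressWarnings(summary(fit)$r.squared)
}

#' Detection saturation across sample-fraction thresholds
#'
#' At each threshold t of the grid, retains the sites detected in at least
#' `t * n` samples and reports the retained count and the fraction of
#' retained sites whose category is cell-type-associated.
#'
#' @param detection site x sample logical matrix.
#' @param category character vector per site; values in `associated`
#'   count as cell-type-associated.
#' @param grid thresholds in [0, 1].
#' @param associated category values treated as cell-type-associated.
#' @return a `SaturationCurve` data.frame: threshold, n_retained,
#'   frac_associated.
#' @export
detection_saturation <- function(detection, category,
                                 grid = seq(0, 1, by = 0.1),
                                 associated = c("specific", "enriched")) {
  detection <- as.matrix(detection)
  stop_if_not(nrow(detection) > 0 && ncol(detection) > 0, "empty detection matrix")
  stop_if_not(length(category) == nrow(detection),
              "one category per site required")
  stop_if_not(all(grid >= 0 & grid <= 1), "grid must lie in [0, 1]")
  n <- ncol(detection)
  ndet <- rowSums(detection)
  is_assoc <- category_base(category) %in% associated
  out <- lapply(sort(grid), function(t) {
    keep <- ndet >= t * n
    data.frame(threshold = t, n_retained = sum(keep),
               frac_associated = if (any(keep)) mean(is_assoc[keep]) else NA_real_)
  })
  res <- do.call(rbind, out)
  class(res) <- c("SaturationCurve", "data.frame")
  res
}

category_base <- function(x) sub(":.*$", "", x)

#' Fold enrichment of site categories at 90% vs 10% detection
#'
#' For each category c: `FE(c) = share of c among sites detected in >=
#' hi * n samples / share of c among sites detected in >= lo * n samples`
#' (share ratio; a count-ratio alternative divides raw counts).
#' Significance by site-label permutation.
#'
#' @param detection site x sample logical matrix.
#' @param category character vector per site.
#' @param hi,lo detection-fraction thresholds (defaults 0.9 and 0.1).
#' @param definition "share" (default) or "count" ratio.
#' @param n_perm label permutations for the empirical p value.
#' @param seed integer seed.
#' @return data.frame: category, n_hi, n_lo, fold_enrichment (NA when the
#'   category is absent at the low threshold), p.
#' @export
fold_enrichment_90_10 <- function(detection, category, hi = 0.9, lo = 0.1,
                                  definition = c("share", "count"),
                                  n_perm = 1000L, seed = 1L) {
  definition <- match.arg(definition)
  detection <- as.matrix(detection)
  n <- ncol(detection)
  ndet <- rowSums(detection)
  in_hi <- ndet >= hi * n
  in_lo <- ndet >= lo * n
  stop_if_not(any(in_hi) && any(in_lo),
              "a threshold retains no sites: fold enrichment undefined")
  cats <- sort(unique(category))
  fe_of <- function(cat_vec) {
    vapply(cats, function(cc) {
      nh <- sum(cat_vec[in_hi] == cc); nl <- sum(cat_vec[in_lo] == cc)
      if (nl == 0L) return(NA_real_)
      if (definition == "share") (nh / sum(in_hi)) / (nl / sum(in_lo))
      else nh / nl
    }, numeric(1))
  }
  obs <- fe_of(category)
  perm_ge <- rep(0L, length(cats))
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      fe_b <- fe_of(sample(category))
      perm_ge <- perm_ge + as.integer(!is.na(fe_b) & !is.na(obs) & fe_b >= obs)
    }
  })
  data.frame(category = cats,
             n_hi = vapply(cats, function(cc) sum(category[in_hi] == cc), integer(1)),
             n_lo = vapply(cats, function(cc) sum(category[in_lo] == cc), integer(1)),
             fold_enrichment = unname(obs),
             p = ifelse(is.na(obs), NA_real_, (1 + perm_ge) / (n_perm + 1)),
             stringsAsFactors = FALSE)
}
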