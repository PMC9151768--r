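#' Assign nuclei to marker-defined pseudo-bulk pools
#'
#' Deterministic marker logic, applied in order of precedence:
#' RBFOX3+ & SOX6+ -> MGE-GABA; RBFOX3+ & SOX6- -> GLU; RBFOX3- & SOX10+ ->
#' OLIG; RBFOX3- & GFAP+ -> astrocyte; RBFOX3- & CLDN5+ -> endothelial;
#' RBFOX3- & microglia-marker+ -> microglia; anything else is unassigned.
#' Marker "presence" is a logical (callers with counts should threshold
#' first; any nonzero count counts as present via [marker_presence()]).
#'
#' @param markers data.frame with a nucleus id column and logical (or
#'   count) columns RBFOX3, SOX6, SOX10, GFAP, CLDN5, MICROGLIA.
#' @param id_col name of the nucleus id column.
#' @return data.frame: nucleus id, pool, evidence string.
#' @export
assign_pools <- function(markers, id_col = "nucleus_id") {
  need <- c("RBFOX3", "SOX6", "SOX10", "GFAP", "CLDN5", "MICROGLIA")
  stop_if_not(all(need %in% names(markers)),
              "marker table needs columns: %s", paste(need, collapse = ", "))
  m <- lapply(markers[need], marker_presence)
  pool <- rep("unassigned", nrow(markers))
  rules <- list(
    `MGE-GABA`  = m$RBFOX3 & m$SOX6,
    GLU         = m$RBFOX3 & !m$SOX6,
    OLIG        = !m$RBFOX3 & m$SOX10,
    astrocyte   = !m$RBFOX3 & m$GFAP,
    endothelial = !m$RBFOX3 & m$CLDN5,
    microglia   = !m$RBFOX3 & m$MICROGLIA)
  for (lab in names(rules)) {
    pool[pool == "unassigned" & rules[[lab]]] <- lab
  }
  evidence <- apply(do.call(cbind, m), 1L, function(z)
    paste0(need, ifelse(z, "+", "-"), collapse = ","))
  data.frame(nucleus_id = markers[[id_col]], pool = pool,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' @rdname assign_pools
#' @param x logical or numeric marker values; numeric values above
#'   `min_count` count as present.
#' @param min_count minimum count for presence (default: any nonzero).
#' @export
marker_presence <- function(x, min_count = 1) {
  if (is.logical(x)) x else x >= min_count
}

#' Quantify a site list in pseudo-bulk pools
#'
#' Re-quantifies FANS-derived sites in pooled pileups. A site's level in a
#' replicate is reported only with coverage at or above the threshold (and
#' at least `min_edited` edited reads); otherwise missing. In sweep mode one
#' `SiteMatrix` is returned per coverage threshold, which by nesting gives
#' monotone non-increasing site counts as the threshold rises.
#'
#' @param pool_samples list of pool replicate samples (with `pileup`).
#' @param sites FANS site table (chrom, pos, strand, site_id).
#' @param min_coverage coverage threshold (single value, or ignored when
#'   `sweep = TRUE`).
#' @param min_edited minimum edited reads for a non-missing call; 0 by
#'   default — pool re-quantification is supervised measurement, so only
#'   the coverage threshold gates a value.
#' @param sweep return one matrix per threshold in `sweep_range`?
#' @param sweep_range thresholds explored in sweep mode.
#' @return a `SiteMatrix`, or a named list of them in sweep mode.
#' @export
pool_quantify <- function(pool_samples, sites, min_coverage = 10L,
                          min_edited = 0L, sweep = FALSE,
                          sweep_range = 3:20) {
  if (sweep) {
    out <- lapply(sweep_range, function(th)
      quantify_supervised(pool_samples, sites, min_coverage = th,
                          min_edited = min_edited))
    names(out) <- as.character(sweep_range)
    return(out)
  }
  quantify_supervised(pool_samples, sites, min_coverage = min_coverage,
                      min_edited = min_edited)
}

#' Validate FANS sites against pseudo-bulk editing levels
#'
#' A site is validated when the median pooled editing level across
#' replicates lies within 50% of the FANS median:
#' `|pool - FANS| <= concordance * FANS` (relative rule, default 0.5). An
#' absolute interpretation (`|pool - FANS| <= concordance`) is available.
#' Sites with FANS median 0 validate only at pool median 0 (the limit of
#' the relative rule) and are flagged. Sites with no replicate passing the
#' coverage threshold are reported unvalidated with `pool_median = NA`.
#'
#' @param fans_median named numeric vector (site_id -> FANS median level).
#' @param pool_sm a `SiteMatrix` of pooled replicates (from
#'   [pool_quantify()]): missing entries are below coverage.
#' @param concordance the 50% rule constant.
#' @param rule "relative" or "absolute".
#' @return data.frame: site_id, fans_median, pool_median, n_replicates,
#'   pool_coverage (median), validated, zero_flag.
#' @export
validate_sites <- function(fans_median, pool_sm, concordance = 0.5,
                           rule = c("relative", "absolute")) {
  rule <- match.arg(rule)
  ids <- pool_sm$sites$site_id
  stop_if_not(all(ids %in% names(fans_median)),
              "every pooled site needs a FANS median")
  fm <- fans_median[ids]
  pm <- apply(pool_sm$level, 1L, function(z)
    if (all(is.na(z))) NA_real_ else stats::median(z, na.rm = TRUE))
  nrep <- rowSums(!is.na(pool_sm$level))
  pcov <- apply(pool_sm$coverage, 1L, stats::median)
  zero <- fm == 0
  validated <- !is.na(pm) & if (rule == "relative") {
    ifelse(zero, pm == 0, abs(pm - fm) <= concordance * fm)
  } else {
    abs(pm - fm) <= concordance
  }
  data.frame(site_id = ids, fans_median = unname(fm), pool_median = pm,
             n_replicates = nrep, pool_coverage = pcov,
             validated = validated, zero_flag = zero & rule == "relative",
             stringsAsFactors = FALSE)
}

#' Positional (TSS-distance) bias of validated sites
#'
#' Tests whether snRNA-seq-validated sites sit farther from the
#' transcription start site than non-validated sites (two-sided
#' Mann-Whitney / Wilcoxon rank-sum), overall and within coverage bins:
#' high = first coverage quintile, medium = second to fourth, low = fifth.
#'
#' @param validated logical vector per site.
#' @param tss_dist numeric TSS distance per site.
#' @param coverage numeric pool coverage per site (defines the quintiles).
#' @return data.frame with one row per comparison (overall, high, medium,
#'   low): n_validated, n_other, median TSS distances, p (NA with a skip
#'   note when a group has < 2 sites).
#' @export
tss_bias_test <- function(validated, tss_dist, coverage) {
  stop_if_not(length(validated) == length(tss_dist) &&
                length(validated) == length(coverage),
              "inputs must have one entry per site")
  q <- stats::quantile(coverage, probs = seq(0, 1, 0.2), na.rm = TRUE)
  bin <- cut(coverage, breaks = unique(q), include.lowest = TRUE,
             labels = FALSE)
  nb <- max(bin, na.rm = TRUE)
  grp <- rep("medium", length(coverage))
  grp[bin == nb] <- "high"   # first quintile by coverage rank = highest coverage
  grp[bin == 1L] <- "low"
  one <- function(sel, label) {
    v <- tss_dist[sel & validated]; o <- tss_dist[sel & !validated]
    if (length(v) < 2L || length(o) < 2L) {
      return(data.frame(comparison = label, n_validated = length(v),
                        n_other = length(o), median_validated = stats::median(v),
                        median_other = stats::median(o), p = NA_real_,
                        note = "skipped: group with < 2 sites",
                        stringsAsFactors = FALSE))
    }
    p <- stats::wilcox.test(v, o, exact = FALSE)$p.value
    data.frame(comparison = label, n_validated = length(v),
               n_other = length(o), median_validated = stats::median(v),
               median_other = stats::median(o), p = p, note = "",
               stringsAsFactors = FALSE)
  }
  rbind(one(rep(TRUE, length(validated)), "overall"),
        one(grp == "high", "high-coverage"),
        one(grp == "medium", "medium-coverage"),
        one(grp == "low", "low-coverage"))
}
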