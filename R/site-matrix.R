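#' SiteMatrix: editing levels, coverage and edited counts per site and sample
#'
#' A `SiteMatrix` bundles an ordered site table with site x sample matrices
#' of editing levels (edited / coverage, `NA` where a site fails the
#' per-sample calling thresholds), total coverage and edited-read counts,
#' plus per-sample metadata (cell type, donor, covariates).
#'
#' @param sites data.frame with at least site_id, chrom, pos, strand.
#' @param level,coverage,edited site x sample numeric matrices sharing
#'   dimensions and column order with `samples$sample_id`.
#' @param samples data.frame with at least sample_id, cell_type, donor.
#' @return an object of class `SiteMatrix`.
#' @export
new_site_matrix <- function(sites, level, coverage, edited, samples) {
  stop_if_not(nrow(sites) == nrow(level), "sites and level disagree in rows")
  stop_if_not(all(dim(level) == dim(coverage)) && all(dim(level) == dim(edited)),
              "matrices must share dimensions")
  stop_if_not(ncol(level) == nrow(samples), "one matrix column per sample")
  ok <- is.na(level) | (level >= 0 & level <= 1)
  stop_if_not(all(ok), "editing levels must lie in [0,1] or be NA")
  structure(list(sites = sites, level = level, coverage = coverage,
                 edited = edited, samples = samples),
            class = "SiteMatrix")
}

#' @export
print.SiteMatrix <- function(x, ...) {
  cat(sprintf("SiteMatrix: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x$sites), nrow(x$samples),
              100 * mean(is.na(x$level))))
  invisible(x)
}

#' @export
dim.SiteMatrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a SiteMatrix by site and/or sample
#' @param x a `SiteMatrix`.
#' @param i site index (logical/integer).
#' @param j sample index (logical/integer).
#' @param ... ignored.
#' @export
`[.SiteMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  new_site_matrix(x$sites[i, , drop = FALSE],
                  x$level[i, j, drop = FALSE],
                  x$coverage[i, j, drop = FALSE],
                  x$edited[i, j, drop = FALSE],
                  x$samples[j, , drop = FALSE])
}

sample_metadata <- function(samples) {
  df <- data.frame(sample_id = vapply(samples, `[[`, "", "sample_id"),
                   cell_type = vapply(samples, `[[`, "", "cell_type"),
                   donor = vapply(samples, `[[`, "", "donor"),
                   mapped_bases = vapply(samples, `[[`, 0, "mapped_bases"),
                   stringsAsFactors = FALSE)
  cov_names <- unique(unlist(lapply(samples, function(s) names(s$covariates))))
  for (nm in cov_names) {
    df[[nm]] <- sapply(samples, function(s) s$covariates[[nm]] %||% NA)
  }
  rownames(df) <- NULL
  df
}

# strand-aware edited / unedited counts from one pileup for given positions
pileup_site_counts <- function(pileup, sites) {
  key <- site_key(pileup$chrom, pileup$pos)
  idx <- match(site_key(sites$chrom, sites$pos), key)
  edited <- ifelse(sites$strand == "+", pileup$G[idx], pileup$C[idx])
  coverage <- pileup$coverage[idx]
  edited[is.na(idx)] <- 0L
  coverage[is.na(idx)] <- 0L
  list(edited = as.integer(edited), coverage = as.integer(coverage))
}

#' Supervised quantification of a known site list
#'
#' Quantifies editing at given positions in every sample: the level is the
#' strand-aware edited-read fraction (G on '+', C on '-', complemented from
#' the reference pileup). A site is called in a sample only with total
#' coverage of at least `min_coverage` reads and at least `min_edited`
#' edited reads; otherwise its level is `NA` for that sample, while the
#' observed coverage is still recorded (the re-query step needs it).
#'
#' @param samples list of `SimulatedSample` (or any objects with `pileup`
#'   and metadata fields).
#' @param sites data.frame with chrom, pos, strand (site_id added if absent).
#' @param min_coverage,min_edited per-sample calling thresholds.
#' @param genome optional `GenomeBundle`; when supplied, site positions are
#'   validated against chromosome bounds.
#' @return a `SiteMatrix`.
#' @export
quantify_supervised <- function(samples, sites, min_coverage = 10L,
                                min_edited = 3L, genome = NULL) {
  if (is.null(sites$site_id))
    sites$site_id <- site_key(sites$chrom, sites$pos, sites$strand)
  if (!is.null(genome)) {
    lens <- nchar(genome$chromosomes)
    bad <- !(sites$chrom %in% names(lens)) | sites$pos < 1L |
      sites$pos > lens[sites$chrom]
    if (any(bad)) stop(sprintf("site(s) outside genome: %s",
                               paste(sites$site_id[bad], collapse = ", ")),
                       call. = FALSE)
  }
  meta <- sample_metadata(samples)
  n <- nrow(sites); m <- length(samples)
  level <- cov <- ed <- matrix(NA_real_, n, m,
                               dimnames = list(sites$site_id, meta$sample_id))
  for (k in seq_len(m)) {
    cnt <- pileup_site_counts(samples[[k]]$pileup, sites)
    cov[, k] <- cnt$coverage
    ed[, k] <- cnt$edited
    lv <- ifelse(cnt$coverage > 0, cnt$edited / cnt$coverage, NA_real_)
    lv[cnt$coverage < min_coverage | cnt$edited < min_edited] <- NA_real_
    level[, k] <- lv
  }
  new_site_matrix(sites, level, cov, ed, meta)
}

#' Median imputation of missing editing levels within cell-type groups
#'
#' Replaces each missing level by the median of the observed levels of the
#' same site within the same cell type. Observed values are untouched, so
#' the per-site group median is invariant under imputation.
#'
#' @param sm a `SiteMatrix`.
#' @param group sample-metadata column defining the imputation groups.
#' @return the `SiteMatrix` with missing levels imputed.
#' @export
impute_missing_median <- function(sm, group = "cell_type") {
  g <- sm$samples[[group]]
  lv <- sm$level
  for (gg in unique(g)) {
    j <- which(g == gg)
    sub <- lv[, j, drop = FALSE]
    miss <- is.na(sub)
    if (!any(miss)) next
    med <- apply(sub, 1L, stats::median, na.rm = TRUE)
    allmiss <- rowSums(!miss) == 0L & rowSums(miss) > 0L
    if (any(allmiss)) {
      stop(sprintf("site(s) missing in every sample of group '%s': %s",
                   gg, paste(utils::head(sm$sites$site_id[allmiss], 5),
                             collapse = ", ")), call. = FALSE)
    }
    sub[miss] <- med[row(sub)[miss]]
    lv[, j] <- sub
  }
  sm$level <- lv
  sm
}
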