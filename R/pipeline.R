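#' End-to-end cell-type editing pipeline on pileup samples
#'
#' Convenience wrapper chaining the calling stages: de novo candidate
#' calling, the quality filter cascade, re-query of single-cell-type sites
#' in the remaining cell types, per-contrast covariate-adjusted differential
#' editing (with per-cell-type median imputation of the contrast submatrix),
#' and specificity/enrichment classification.
#'
#' @param samples list of samples (e.g. from [simulate_pileups()]).
#' @param genome a `GenomeBundle`.
#' @param k detection-rate rule: minimum detecting samples per cell type.
#' @param covariates covariate columns for the differential models.
#' @param donor donor handling passed to [differential_editing()].
#' @param fdr_threshold significance threshold.
#' @return list: `matrix` (retained `SiteMatrix`), `report` (FilterReport),
#'   `requery`, `diff` (list of per-contrast results), `labels`
#'   (classification table).
#' @export
run_celltype_pipeline <- function(samples, genome, k = 8L,
                                  covariates = c("age", "PMI"),
                                  donor = "gls", fdr_threshold = 0.05) {
  cand <- call_denovo(samples, genome)
  res <- apply_filter_cascade(cand, genome, k = k)
  sm <- res$matrix
  single <- !grepl(",", sm$sites$detected_in)
  requery <- requery_other_celltypes(sm[single, ], samples)

  cts <- unique(sm$samples$cell_type)
  contrasts <- utils::combn(cts, 2, simplify = FALSE)
  diffs <- list()
  for (con in contrasts) {
    both <- vapply(strsplit(sm$sites$detected_in, ","), function(z)
      all(con %in% z), logical(1))
    if (sum(both) == 0L) next
    sub <- sm[both, sm$samples$cell_type %in% con]
    sub <- impute_missing_median(sub)
    diffs[[paste(con, collapse = "_vs_")]] <-
      differential_editing(sub, con, covariates = covariates, donor = donor,
                           fdr_threshold = fdr_threshold)
  }
  labels <- classify_specificity(sm$sites, requery, diffs,
                                 fdr_threshold = fdr_threshold,
                                 cell_types = cts)
  list(matrix = sm, report = res$report, requery = requery, diff = diffs,
       labels = labels)
}
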