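#' Simulate pseudo-bulk pools from single-nucleus data
#'
#' Emulates pooling single-nucleus reads by marker-defined cell identity:
#' per-site coverage scales linearly with the number of nuclei in the pool
#' and decays towards the transcription start site according to a 3' coverage
#' bias (single-nucleus libraries sample transcript 3' ends preferentially).
#' Editing rates are inherited from the pool's cell-type truth.
#'
#' Coverage model: `cov ~ Poisson(n_nuclei * coverage_per_nucleus *
#' exp(-bias * d3))` where `d3` is the site's distance from the transcript
#' 3' end as a fraction of gene length (0 at the 3' end, 1 at the TSS).
#' `bias = 0` gives position-independent coverage.
#'
#' @param truth a `TruthTable` (sites must carry gene_id/tss_dist).
#' @param genome the matching `GenomeBundle`.
#' @param pools data.frame with columns pool (cell type), replicate and
#'   n_nuclei; defaults to the three cell types x 3 replicates of 500 nuclei.
#' @param coverage_per_nucleus expected reads contributed per nucleus at an
#'   unbiased site.
#' @param bias 3' coverage bias strength (>= 0).
#' @param error_rate uniform miscall probability.
#' @param seed integer seed.
#' @return list of `SimulatedSample` objects (one per pool replicate) whose
#'   `cell_type` is the pool label and `donor` the replicate id.
#' @export
simulate_pseudobulk_pools <- function(truth, genome, pools = NULL,
                                      coverage_per_nucleus = 0.05,
                                      bias = 2, error_rate = 0.001,
                                      seed = 1L) {
  if (is.null(pools)) {
    pools <- expand.grid(pool = CELL_TYPES,
                         replicate = sprintf("R%d", 1:3),
                         stringsAsFactors = FALSE)
    pools$n_nuclei <- 500L
  }
  stop_if_not(all(pools$n_nuclei > 0), "pool sizes must be positive")
  stop_if_not(bias >= 0, "bias must be >= 0")
  st <- truth$sites
  stop_if_not(all(!is.na(st$gene_id)), "truth sites must lie in genes")

  genes <- genome$genes
  glen <- stats::setNames(genes$end - genes$start + 1L, genes$gene_id)
  d3 <- 1 - st$tss_dist / glen[st$gene_id]   # 0 at 3' end, 1 at TSS
  d3 <- pmin(pmax(d3, 0), 1)

  with_local_seed(seed, {
    out <- vector("list", nrow(pools))
    for (k in seq_len(nrow(pools))) {
      ct <- pools$pool[k]
      rate <- if (ct %in% CELL_TYPES) st[[paste0("rate_", ct)]] else rep(0, nrow(st))
      mu <- pools$n_nuclei[k] * coverage_per_nucleus * exp(-bias * d3)
      n <- nrow(st)
      ref <- genome_base(genome, st$chrom, st$pos)
      altb <- ifelse(st$strand == "+", "G", "C")
      cov <- stats::rpois(n, mu)
      counts <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
      for (i in seq_len(n)) {
        if (cov[i] == 0L) next
        counts[i, ] <- stats::rmultinom(
          1, cov[i], base_probs(ref[i], altb[i], clip01(rate[i]), error_rate))[, 1]
      }
      pu <- data.frame(chrom = st$chrom, pos = st$pos, strand = st$strand,
                       ref = ref, as.data.frame(counts), coverage = cov,
                       stringsAsFactors = FALSE)
      sid <- paste(ct, pools$replicate[k], sep = "_pool_")
      out[[k]] <- structure(list(
        sample_id = sid, cell_type = ct, donor = pools$replicate[k],
        covariates = list(n_nuclei = pools$n_nuclei[k]),
        pileup = pu, mapped_bases = as.numeric(sum(cov)) * 100,
        adar_scale = 1), class = "SimulatedSample")
      names(out)[k] <- sid
    }
    attr(out, "design") <- data.frame(sample_id = names(out),
                                      cell_type = pools$pool,
                                      donor = pools$replicate,
                                      stringsAsFactors = FALSE)
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Simulate bulk expression as mixtures of cell-type signatures
#'
#' Bulk expression is `signature %*% fractions` per sample plus Gaussian
#' noise, floored at zero — the generative model non-negative least squares
#' deconvolution assumes.
#'
#' @param signature gene x cell-type numeric matrix.
#' @param fractions sample x cell-type matrix; rows must be non-negative and
#'   sum to 1 (tolerance 1e-8).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return gene x sample matrix of bulk expression.
#' @export
simulate_bulk_mixtures <- function(signature, fractions, noise_sd = 0,
                                   seed = 1L) {
  signature <- as.matrix(signature); fractions <- as.matrix(fractions)
  stop_if_not(ncol(signature) == ncol(fractions),
              "signature and fractions must share cell-type columns")
  stop_if_not(all(fractions >= 0), "fractions must be non-negative")
  bad <- abs(rowSums(fractions) - 1) > 1e-8
  if (any(bad)) stop(sprintf("fractions of %d sample(s) do not sum to 1", sum(bad)),
                     call. = FALSE)
  with_local_seed(seed, {
    bulk <- signature %*% t(fractions)
    if (noise_sd > 0) bulk <- bulk + stats::rnorm(length(bulk), 0, noise_sd)
    bulk[bulk < 0] <- 0
    colnames(bulk) <- rownames(fractions) %||% sprintf("S%03d", seq_len(nrow(fractions)))
    bulk
  })
}
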