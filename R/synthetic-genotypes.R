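#' Simulate donor genotypes and plant cis-edQTL effects
#'
#' Draws SNP dosages at Hardy-Weinberg proportions for a donor panel and
#' plants additive genotype effects on a subset of truth sites: a donor's
#' true editing rate at an edQTL site is `base + beta * dosage`, clipped to
#' [0, 1]. Each causal SNP is placed within `max_dist` of its site on the
#' same chromosome.
#'
#' @param truth a `TruthTable`.
#' @param genome the matching `GenomeBundle`.
#' @param n_donors donor panel size.
#' @param n_snps total SNPs to simulate (causal SNPs included).
#' @param n_edqtl number of sites given a genotype effect.
#' @param maf_range minor allele frequency range, within [0.05, 0.5].
#' @param beta additive effect per dosage unit (editing-level units).
#' @param max_dist maximum SNP-site distance for planted effects (bp).
#' @param seed integer seed.
#' @return list with `genotypes` (a `GenotypeMatrix`: `snps` data.frame and
#'   `dosage` SNP x donor matrix), `truth` (input truth with an `edqtl`
#'   data.frame of snp_id, site_id, beta added) and `rates` (site x donor
#'   matrix of true rates for the edQTL sites, base + beta * dosage clipped).
#' @export
simulate_genotypes_and_edqtl <- function(truth, genome, n_donors = 150L,
                                         n_snps = 200L, n_edqtl = 20L,
                                         maf_range = c(0.05, 0.5),
                                         beta = 0.08, max_dist = 100000L,
                                         seed = 1L) {
  stop_if_not(maf_range[1] >= 0.05 && maf_range[2] <= 0.5,
              "MAF range must lie within [0.05, 0.5]")
  st <- truth$sites
  editable <- st[st$class != "null", , drop = FALSE]
  stop_if_not(n_edqtl <= nrow(editable),
              "requested %d edQTL sites but only %d non-null truth sites",
              n_edqtl, nrow(editable))
  with_local_seed(seed, {
    donors <- sprintf("D%03d", seq_len(n_donors))
    lens <- nchar(genome$chromosomes)

    causal_sites <- editable[sample.int(nrow(editable), n_edqtl), , drop = FALSE]
    causal_pos <- vapply(seq_len(n_edqtl), function(i) {
      p <- causal_sites$pos[i] +
        sample(seq(-max_dist, max_dist), 1L)
      min(max(p, 1L), lens[[causal_sites$chrom[i]]])
    }, integer(1))
    n_rand <- n_snps - n_edqtl
    rand_chrom <- sample(names(lens), n_rand, replace = TRUE)
    rand_pos <- vapply(rand_chrom, function(cc) sample.int(lens[[cc]], 1L),
                       integer(1), USE.NAMES = FALSE)
    snps <- data.frame(
      snp_id = sprintf("snp%04d", seq_len(n_snps)),
      chrom = c(causal_sites$chrom, rand_chrom),
      pos = c(causal_pos, rand_pos),
      maf = stats::runif(n_snps, maf_range[1], maf_range[2]),
      stringsAsFactors = FALSE)

    dosage <- t(vapply(snps$maf, function(m) stats::rbinom(n_donors, 2L, m),
                       integer(n_donors)))
    dimnames(dosage) <- list(snps$snp_id, donors)

    edqtl <- data.frame(snp_id = snps$snp_id[seq_len(n_edqtl)],
                        site_id = causal_sites$site_id,
                        beta = beta, stringsAsFactors = FALSE)

    # true per-donor rates at edQTL sites: base (mean across cell types with
    # non-zero truth, i.e. the site's bulk-level rate) + beta * dosage
    rate_cols <- paste0("rate_", CELL_TYPES)
    base <- apply(as.matrix(causal_sites[, rate_cols]), 1L, function(r) {
      nz <- r[r > 0]
      if (length(nz) == 0) 0 else mean(nz)
    })
    rates <- clip01(matrix(base, n_edqtl, n_donors) +
                      beta * dosage[seq_len(n_edqtl), , drop = FALSE])
    dimnames(rates) <- list(causal_sites$site_id, donors)
    clipped <- rowSums(rates == 0 | rates == 1) == n_donors
    if (any(clipped)) {
      warning(sprintf("%d edQTL site(s) fully clipped to [0,1] bounds", sum(clipped)))
      edqtl$clipped <- clipped
    }

    geno <- structure(list(snps = snps, dosage = dosage),
                      class = "GenotypeMatrix")
    truth$edqtl <- edqtl
    list(genotypes = geno, truth = truth, rates = rates)
  })
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d donors (MAF %.2f-%.2f)\n",
              nrow(x$snps), ncol(x$dosage), min(x$snps$maf), max(x$snps$maf)))
  invisible(x)
}
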