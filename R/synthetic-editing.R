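#' Simulate ground-truth editing rates per cell type
#'
#' Places editing sites on adenosines of the annotated transcript strand
#' (A on '+', T on the reference for '-' sites) and assigns each site a class
#' and a true editing rate per cell type. Sites are placed at "clean"
#' positions: outside blacklist and homopolymer intervals, more than 5 bp
#' from splice sites, and away from SNPs with minor allele frequency above
#' 0.05 — the truth models genuine editing, which the downstream filter
#' cascade is designed to retain.
#'
#' Classes: `specific:<cell type>` (non-zero rate in exactly one cell type),
#' `enriched` (one cell type edited `delta` above the other two),
#' `shared-equal` (identical rate everywhere) and `null` (rate zero
#' everywhere; such positions should never survive calling).
#'
#' @param genome a `GenomeBundle`.
#' @param n_sites number of sites to place.
#' @param class_props named numeric vector of class proportions summing to 1.
#' @param rate_fn function(n) drawing base editing rates; defaults to
#'   Beta(2, 3) truncated below at `min_rate`.
#' @param delta true editing-level difference for `enriched` sites.
#' @param min_rate smallest base rate the generator emits for edited classes.
#' @param in_genes place sites only within gene bodies (needed for
#'   TSS-distance analyses).
#' @param seed integer seed.
#' @return a `TruthTable`: list with `sites` (data.frame with site_id, chrom,
#'   pos, strand, gene_id, tss_dist, class and one `rate_<cell type>` column
#'   per cell type) and `edqtl` (empty until
#'   [simulate_genotypes_and_edqtl()] fills it).
#' @export
simulate_editing_truth <- function(genome, n_sites = 300L,
                                   class_props = c("specific:MGE-GABA" = 0.15,
                                                   "specific:GLU" = 0.15,
                                                   "specific:OLIG" = 0.15,
                                                   "enriched" = 0.2,
                                                   "shared-equal" = 0.2,
                                                   "null" = 0.15),
                                   rate_fn = NULL, delta = 0.2,
                                   min_rate = 0.05, in_genes = TRUE,
                                   seed = 1L) {
  stop_if_not(abs(sum(class_props) - 1) < 1e-8, "class proportions must sum to 1")
  stop_if_not(delta > 0 && delta < 1, "delta must be in (0,1)")
  if (is.null(rate_fn)) {
    rate_fn <- function(n) {
      r <- stats::rbeta(n, 2, 3)
      while (any(bad <- r < min_rate)) r[bad] <- stats::rbeta(sum(bad), 2, 3)
      r
    }
  }
  with_local_seed(seed, {
    cand <- clean_adenosines(genome, in_genes = in_genes)
    stop_if_not(nrow(cand) >= n_sites,
                "requested %d sites but only %d clean adenosines available",
                n_sites, nrow(cand))
    cand <- cand[sample.int(nrow(cand), n_sites), , drop = FALSE]
    cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
    rownames(cand) <- NULL

    # class counts match proportions within rounding
    cum <- round(cumsum(class_props) * n_sites)
    counts <- diff(c(0L, cum))
    labels <- rep(names(class_props), counts)
    labels <- sample(labels)  # decouple class from genomic order

    rates <- matrix(0, nrow = n_sites, ncol = length(CELL_TYPES),
                    dimnames = list(NULL, CELL_TYPES))
    enriched_in <- rep(NA_character_, n_sites)
    for (i in seq_len(n_sites)) {
      cls <- labels[i]
      if (startsWith(cls, "specific:")) {
        ct <- sub("^specific:", "", cls)
        rates[i, ct] <- rate_fn(1)
      } else if (cls == "enriched") {
        ct <- CELL_TYPES[1L + (i %% length(CELL_TYPES))]
        base <- min(rate_fn(1), 1 - delta - 0.01)
        base <- max(base, min_rate)
        rates[i, ] <- base
        rates[i, ct] <- base + delta
        enriched_in[i] <- ct
      } else if (cls == "shared-equal") {
        rates[i, ] <- rate_fn(1)
      } # null: all zero
    }
    sites <- data.frame(
      site_id = sprintf("site%05d", seq_len(n_sites)),
      cand, class = labels, enriched_in = enriched_in,
      stringsAsFactors = FALSE)
    colnames(rates) <- paste0("rate_", CELL_TYPES)
    sites <- cbind(sites, as.data.frame(rates))
    structure(list(sites = sites, edqtl = NULL),
              class = "TruthTable", seed = as.integer(seed), delta = delta)
  })
}

# adenosine positions (transcript-strand) passing the placement filters
clean_adenosines <- function(genome, in_genes = TRUE) {
  out <- list()
  genes <- genome$genes
  for (cn in names(genome$chromosomes)) {
    s <- strsplit(genome$chromosomes[[cn]], "")[[1]]
    g <- genes[genes$chrom == cn, , drop = FALSE]
    if (in_genes && nrow(g) == 0L) next
    for (gi in seq_len(if (in_genes) nrow(g) else 1L)) {
      if (in_genes) {
        rng <- g$start[gi]:g$end[gi]
        strand <- g$strand[gi]
        gid <- g$gene_id[gi]; tss <- g$tss[gi]
      } else {
        rng <- seq_along(s); strand <- "+"; gid <- NA_character_; tss <- NA_integer_
      }
      want <- if (strand == "+") "A" else "T"
      pos <- rng[s[rng] == want]
      if (length(pos) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, pos = pos, strand = strand, gene_id = gid,
        tss_dist = if (is.na(tss)) NA_integer_ else abs(pos - tss),
        stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, out)
  if (is.null(cand)) return(cand)
  bad <- in_intervals(cand$chrom, cand$pos, genome$blacklist_intervals) |
    in_intervals(cand$chrom, cand$pos, genome$homopolymer_intervals) |
    dist_to_nearest_pos(cand$chrom, cand$pos, genome$splice_sites) <= 5
  snps <- genome$snps[genome$snps$maf > 0.05, , drop = FALSE]
  bad <- bad | site_key(cand$chrom, cand$pos) %in% site_key(snps$chrom, snps$pos)
  cand[!bad, , drop = FALSE]
}

#' @export
print.TruthTable <- function(x, ...) {
  cat(sprintf("TruthTable: %d sites\n", nrow(x$sites)))
  print(table(x$sites$class))
  if (!is.null(x$edqtl)) cat(sprintf("  edQTL effects: %d\n", nrow(x$edqtl)))
  invisible(x)
}

# multinomial base probabilities for a pileup position: reads are edited
# (ref -> alt) with probability p, then each sequenced base is miscalled
# uniformly to one of the other three bases with probability eps
base_probs <- function(ref, alt, p, eps) {
  bases <- c("A", "C", "G", "T")
  pr <- stats::setNames(rep(eps / 3, 4), bases)
  pr[ref] <- pr[ref] + (1 - p) * (1 - 4 * eps / 3)
  pr[alt] <- pr[alt] + p * (1 - 4 * eps / 3)
  pr
}

#' Simulate per-sample pileup tables from an editing truth table
#'
#' Draws per-site coverage from a Poisson distribution and base counts from a
#' multinomial in which reads are edited with the sample's cell-type truth
#' rate (times an optional per-sample ADAR scaling factor) and sequencing
#' errors are uniform base miscalls at rate `error_rate`. Minus-strand sites
#' are emitted as T>C on the reference; the quantification layer complements.
#'
#' @param truth a `TruthTable`.
#' @param genome the `GenomeBundle` the truth was built on.
#' @param design data.frame with columns sample_id, cell_type, donor;
#'   defaults to 3 cell types x `n_donors` donors.
#' @param n_donors donors for the default design.
#' @param mean_coverage Poisson mean of per-site coverage.
#' @param error_rate uniform base miscall probability, in [0, 0.05].
#' @param background optional data.frame (chrom, pos, strand) of extra
#'   positions carrying no true editing (error-level mismatches only), e.g.
#'   `alu_adenosine_positions(genome)` for Alu editing index work.
#' @param adar_scale optional numeric vector (one per sample) scaling all
#'   true rates of that sample; default 1.
#' @param read_length nominal read length used to derive mapped-base counts.
#' @param seed integer seed.
#' @return list of `SimulatedSample` objects, each with `sample_id`,
#'   `cell_type`, `donor`, `covariates`, `pileup` (chrom, pos, strand, ref,
#'   A, C, G, T, coverage), `mapped_bases` and `adar_scale`.
#' @export
simulate_pileups <- function(truth, genome, design = NULL, n_donors = 9L,
                             mean_coverage = 50, error_rate = 0.001,
                             background = NULL, adar_scale = NULL,
                             read_length = 100L, seed = 1L) {
  stop_if_not(mean_coverage > 0, "mean coverage must be positive")
  stop_if_not(error_rate >= 0 && error_rate <= 0.05,
              "error rate must lie in [0, 0.05]")
  if (is.null(design)) {
    design <- expand.grid(donor = sprintf("D%02d", seq_len(n_donors)),
                          cell_type = CELL_TYPES, stringsAsFactors = FALSE)
    design$sample_id <- paste(design$cell_type, design$donor, sep = "_")
  }
  stop_if_not(all(c("sample_id", "cell_type", "donor") %in% names(design)),
              "design needs sample_id, cell_type, donor columns")
  if (is.null(adar_scale)) adar_scale <- rep(1, nrow(design))
  stop_if_not(length(adar_scale) == nrow(design),
              "adar_scale must have one entry per sample")

  with_local_seed(seed, {
    donors <- unique(design$donor)
    covar <- data.frame(
      donor = donors,
      age = round(stats::runif(length(donors), 30, 85)),
      PMI = round(stats::runif(length(donors), 5, 40), 1),
      pH = round(stats::runif(length(donors), 6, 7), 2),
      sex = sample(c("M", "F"), length(donors), replace = TRUE),
      RIN = round(stats::runif(length(donors), 6, 9), 1),
      stringsAsFactors = FALSE)

    st <- truth$sites
    pos_tab <- data.frame(chrom = st$chrom, pos = st$pos, strand = st$strand,
                          stringsAsFactors = FALSE)
    rate_cols <- paste0("rate_", CELL_TYPES)
    if (!is.null(background) && nrow(background) > 0L) {
      bg <- background[!site_key(background$chrom, background$pos) %in%
                         site_key(pos_tab$chrom, pos_tab$pos), , drop = FALSE]
    } else bg <- NULL

    samples <- vector("list", nrow(design))
    for (k in seq_len(nrow(design))) {
      ct <- design$cell_type[k]
      rate <- if (ct %in% CELL_TYPES) st[[paste0("rate_", ct)]] else rep(0, nrow(st))
      rate <- clip01(rate * adar_scale[k])
      all_pos <- rbind(pos_tab, if (!is.null(bg))
        bg[, c("chrom", "pos", "strand")])
      p_edit <- c(rate, rep(0, if (is.null(bg)) 0L else nrow(bg)))
      pu <- draw_pileup(genome, all_pos, p_edit, mean_coverage, error_rate)
      cv <- covar[covar$donor == design$donor[k], , drop = FALSE]
      samples[[k]] <- structure(list(
        sample_id = design$sample_id[k],
        cell_type = ct,
        donor = design$donor[k],
        covariates = as.list(cv[, setdiff(names(cv), "donor")]),
        pileup = pu,
        mapped_bases = as.numeric(sum(pu$coverage)) * read_length,
        adar_scale = adar_scale[k]
      ), class = "SimulatedSample")
    }
    names(samples) <- design$sample_id
    attr(samples, "design") <- design
    attr(samples, "covariates") <- covar
    attr(samples, "seed") <- as.integer(seed)
    samples
  })
}

draw_pileup <- function(genome, pos_tab, p_edit, mean_coverage, error_rate) {
  n <- nrow(pos_tab)
  ref <- genome_base(genome, pos_tab$chrom, pos_tab$pos)
  alt <- ifelse(pos_tab$strand == "+", "G", "C")
  cov <- stats::rpois(n, mean_coverage)
  counts <- matrix(0L, nrow = n, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(n)) {
    if (cov[i] == 0L) next
    pr <- base_probs(ref[i], alt[i], p_edit[i], error_rate)
    counts[i, ] <- stats::rmultinom(1, cov[i], pr)[, 1]
  }
  data.frame(chrom = pos_tab$chrom, pos = pos_tab$pos,
             strand = pos_tab$strand, ref = ref,
             as.data.frame(counts), coverage = cov,
             stringsAsFactors = FALSE)
}

#' @export
print.SimulatedSample <- function(x, ...) {
  cat(sprintf("SimulatedSample %s (%s, donor %s): %d pileup rows, %.3g mapped bases\n",
              x$sample_id, x$cell_type, x$donor, nrow(x$pileup), x$mapped_bases))
  invisible(x)
}
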