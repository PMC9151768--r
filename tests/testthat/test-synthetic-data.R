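test_that("genome generation is deterministic and structurally sound", {
  g1 <- build_synthetic_genome(c(chr1 = 50000L), n_genes = 5L, seed = 1L)
  g2 <- build_synthetic_genome(c(chr1 = 50000L), n_genes = 5L, seed = 1L)
  expect_identical(serialize(g1, NULL, version = 2),
                   serialize(g2, NULL, version = 2))
  g3 <- build_synthetic_genome(c(chr1 = 50000L), n_genes = 5L, seed = 2L)
  expect_false(identical(g1$chromosomes, g3$chromosomes))

  # every splice site coincides with an exon boundary (exhaustive)
  g <- small_genome()
  boundaries <- c(g$exons$start, g$exons$end)
  expect_true(all(g$splice_sites$pos %in% boundaries))

  # intervals lie within chromosome bounds; exons sorted, non-overlapping
  lens <- nchar(g$chromosomes)
  for (iv in list(g$alu_intervals, g$l1_intervals, g$blacklist_intervals,
                  g$homopolymer_intervals)) {
    expect_true(all(iv$start >= 1 & iv$end <= lens[iv$chrom]))
    expect_true(all(iv$start <= iv$end))
  }
  for (gid in unique(g$exons$gene_id)) {
    ex <- g$exons[g$exons$gene_id == gid, ]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(utils::head(ex$end, -1) < ex$start[-1]))
  }
})

test_that("degenerate genome configs behave as specified", {
  g0 <- build_synthetic_genome(c(chr1 = 20000L), n_genes = 2L,
                               repeat_density = 0, seed = 3L)
  expect_identical(nrow(g0$alu_intervals), 0L)
  expect_error(build_synthetic_genome(c(chr1 = 12000L), n_genes = 10L, seed = 1L),
               "cannot place")
})

test_that("editing truth respects class proportions, placement and rates", {
  g <- small_genome()
  tr <- simulate_editing_truth(
    g, n_sites = 100L,
    class_props = c("specific:GLU" = 0.5, "shared-equal" = 0.5), seed = 5L)
  n_spec <- sum(tr$sites$class == "specific:GLU")
  expect_true(abs(n_spec - 50L) <= 1L)

  # sites sit on transcript-strand adenosines
  chrom_seq <- g$chromosomes[["chr1"]]
  base <- substring(chrom_seq, tr$sites$pos, tr$sites$pos)
  expect_true(all(ifelse(tr$sites$strand == "+", base == "A", base == "T")))

  # specific sites: exactly one cell type with nonzero rate
  rates <- as.matrix(tr$sites[, paste0("rate_", c("MGE-GABA", "GLU", "OLIG"))])
  spec <- startsWith(tr$sites$class, "specific:")
  expect_true(all(rowSums(rates[spec, ] > 0) == 1L))
  expect_true(all(rates >= 0 & rates <= 1))

  # enriched sites carry an exact pre-clipping difference delta
  tr2 <- simulate_editing_truth(g, n_sites = 60L,
                                class_props = c(enriched = 1), delta = 0.2,
                                seed = 6L)
  r2 <- as.matrix(tr2$sites[, paste0("rate_", c("MGE-GABA", "GLU", "OLIG"))])
  gap <- apply(r2, 1L, function(z) max(z) - min(z))
  expect_equal(gap, rep(0.2, nrow(r2)), tolerance = 1e-12)

  expect_error(simulate_editing_truth(g, n_sites = 1e6L, seed = 1L),
               "clean adenosines")
})

test_that("base editing rates follow the requested distribution", {
  g <- big_genome()
  tr <- simulate_editing_truth(g, n_sites = 10000L,
                               class_props = c("shared-equal" = 1),
                               rate_fn = function(n) stats::rbeta(n, 2, 3),
                               seed = 7L)
  r <- tr$sites$rate_GLU
  se <- sqrt(2 * 3 / ((2 + 3)^2 * 6)) / sqrt(length(r))  # Beta(2,3) SE of mean
  expect_lt(abs(mean(r) - 0.4), 3 * se)
})

test_that("pileups conserve counts and reproduce binomial sampling theory", {
  g <- small_genome()
  tr <- simulate_editing_truth(g, n_sites = 80L, seed = 8L)
  ss <- simulate_pileups(tr, g, n_donors = 3L, mean_coverage = 40,
                         error_rate = 0.001, seed = 9L)
  for (s in ss) {
    pu <- s$pileup
    expect_true(all(pu$coverage == pu$A + pu$C + pu$G + pu$T))
    expect_true(all(pu$A >= 0 & pu$C >= 0 & pu$G >= 0 & pu$T >= 0))
  }
  expect_identical(
    serialize(simulate_pileups(tr, g, n_donors = 3L, seed = 9L), NULL),
    serialize(simulate_pileups(tr, g, n_donors = 3L, seed = 9L), NULL))

  # rate 0 with no error -> zero edited; rate 1 -> fully edited
  tr0 <- simulate_editing_truth(g, n_sites = 40L,
                                class_props = c("null" = 1), seed = 10L)
  s0 <- simulate_pileups(tr0, g, n_donors = 1L, error_rate = 0, seed = 11L)
  for (s in s0) {
    ed <- ifelse(s$pileup$strand == "+", s$pileup$G, s$pileup$C)
    expect_true(all(ed == 0L))
  }
  tr1 <- simulate_editing_truth(g, n_sites = 40L,
                                class_props = c("shared-equal" = 1),
                                rate_fn = function(n) rep(1, n), seed = 12L)
  s1 <- simulate_pileups(tr1, g, n_donors = 1L, error_rate = 0, seed = 13L)
  for (s in s1) {
    ed <- ifelse(s$pileup$strand == "+", s$pileup$G, s$pileup$C)
    expect_true(all(ed == s$pileup$coverage))
  }
})

test_that("pooled empirical editing rate matches the planted rate", {
  g <- big_genome()
  tr <- simulate_editing_truth(g, n_sites = 5000L,
                               class_props = c("shared-equal" = 1),
                               rate_fn = function(n) rep(0.3, n), seed = 14L)
  s <- simulate_pileups(tr, g, design = data.frame(
    sample_id = "x", cell_type = "GLU", donor = "d1"),
    mean_coverage = 50, error_rate = 0, seed = 15L)[[1]]
  ed <- ifelse(s$pileup$strand == "+", s$pileup$G, s$pileup$C)
  p_hat <- sum(ed) / sum(s$pileup$coverage)
  se <- sqrt(0.3 * 0.7 / sum(s$pileup$coverage))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("hyper-edited read generation matches its configuration", {
  g <- small_genome()
  # edit fraction 1: every adenosine of the read becomes G
  hr1 <- simulate_hyperedited_reads(g, n_reads = 5L, n_background = 0L,
                                    edit_fraction = 1, error_rate = 0,
                                    seed = 16L)
  expect_false(any(grepl("A", hr1$reads$seq[hr1$reads$hyper])))
  # background-only set records no truth clusters
  hr0 <- simulate_hyperedited_reads(g, n_reads = 0L, n_background = 10L,
                                    seed = 17L)
  expect_identical(nrow(hr0$clusters), 0L)
  expect_error(simulate_hyperedited_reads(g, n_reads = 5L, edit_fraction = 0,
                                          seed = 1L),
               "contradictory")
  # mean edited-A fraction ~ Binomial(n_A, 0.6)
  hr <- simulate_hyperedited_reads(g, n_reads = 60L, n_background = 0L,
                                   error_rate = 0, seed = 18L)
  frac <- vapply(seq_len(nrow(hr$reads)), function(i) {
    ref <- substring(g$chromosomes[[hr$reads$true_chrom[i]]],
                     hr$reads$true_start[i], hr$reads$true_start[i] + 99L)
    rd <- if (hr$reads$strand[i] == "+") ref else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    n_a <- lengths(regmatches(rd, gregexpr("A", rd)))
    n_e <- hr$clusters$n_sites[i]
    n_e / n_a
  }, numeric(1))
  n_a_mean <- 25  # ~ a quarter of a 100-bp read
  se <- sqrt(0.6 * 0.4 / (n_a_mean * length(frac)))
  expect_lt(abs(mean(frac) - 0.6), 3 * se)
})

test_that("genotypes follow Hardy-Weinberg and edQTL effects are additive", {
  g <- small_genome()
  tr <- simulate_editing_truth(g, n_sites = 30L,
                               class_props = c("shared-equal" = 1),
                               rate_fn = function(n) rep(0.3, n), seed = 19L)
  ge <- simulate_genotypes_and_edqtl(tr, g, n_donors = 10000L, n_snps = 2L,
                                     n_edqtl = 1L, maf_range = c(0.5, 0.5),
                                     beta = 0.1, seed = 20L)
  dos <- ge$genotypes$dosage[1, ]
  freq <- table(factor(dos, levels = 0:2)) / length(dos)
  exp_freq <- c(0.25, 0.5, 0.25)
  se <- sqrt(exp_freq * (1 - exp_freq) / length(dos))
  expect_true(all(abs(as.numeric(freq) - exp_freq) < 3 * se))

  # beta = 0.1, base 0.3 -> dosage-2 donors at exactly 0.5
  r <- ge$rates[1, ]
  expect_true(all(r[dos == 2] == 0.5))
  expect_true(all(r[dos == 0] == 0.3))

  # beta = 0 -> rates independent of dosage
  ge0 <- simulate_genotypes_and_edqtl(tr, g, n_donors = 200L, n_snps = 2L,
                                      n_edqtl = 1L, beta = 0, seed = 21L)
  expect_identical(length(unique(ge0$rates[1, ])), 1L)
  expect_error(
    simulate_genotypes_and_edqtl(tr, g, maf_range = c(0.01, 0.5), seed = 1L),
    "MAF range")
})

test_that("pseudo-bulk coverage scales with pool size and 3' bias", {
  g <- small_genome()
  tr <- simulate_editing_truth(g, n_sites = 150L, seed = 22L)
  pools <- data.frame(pool = "GLU", replicate = c("a", "b"),
                      n_nuclei = c(1L, 1000L))
  ps <- simulate_pseudobulk_pools(tr, g, pools = pools, bias = 0,
                                  coverage_per_nucleus = 0.05, seed = 23L)
  ratio <- mean(ps[[2]]$pileup$coverage) / max(mean(ps[[1]]$pileup$coverage), 1e-9)
  expect_gt(ratio, 500)  # ~1:1000 scaling up to Poisson noise

  # zero bias: coverage uncorrelated with TSS distance (1,000 sites)
  trb <- simulate_editing_truth(big_genome(), n_sites = 1000L, seed = 27L)
  p0 <- simulate_pseudobulk_pools(trb, big_genome(), bias = 0, seed = 24L)
  r0 <- cor(p0[[1]]$pileup$coverage, trb$sites$tss_dist)
  expect_lt(abs(r0), 0.1)
  # positive bias: 3'-proximal (TSS-distal) sites get more coverage
  p2 <- simulate_pseudobulk_pools(trb, big_genome(), bias = 3, seed = 24L)
  r2 <- cor(p2[[1]]$pileup$coverage, trb$sites$tss_dist)
  expect_gt(r2, 0.3)

  # pooled rates inherit the cell-type truth (binomial CI at pooled depth)
  glu <- simulate_pseudobulk_pools(tr, g, bias = 0,
                                   coverage_per_nucleus = 0.2, seed = 25L)
  s <- glu[[which(attr(glu, "design")$cell_type == "GLU")[1]]]
  ed <- ifelse(s$pileup$strand == "+", s$pileup$G, s$pileup$C)
  rate <- tr$sites$rate_GLU
  ok <- s$pileup$coverage >= 30 & rate > 0.05 & rate < 0.95
  phat <- ed[ok] / s$pileup$coverage[ok]
  ci_ok <- abs(phat - rate[ok]) <=
    4 * sqrt(rate[ok] * (1 - rate[ok]) / s$pileup$coverage[ok]) + 0.01
  expect_gt(mean(ci_ok), 0.95)
})

test_that("bulk mixtures follow the linear mixing model", {
  set.seed(26)
  sig <- matrix(rexp(40 * 3, 0.2), 40, 3,
                dimnames = list(sprintf("g%02d", 1:40), c("a", "b", "c")))
  f1 <- matrix(c(1, 0, 0), 1, dimnames = list("s1", colnames(sig)))
  expect_equal(as.numeric(simulate_bulk_mixtures(sig, f1, 0)),
               unname(sig[, 1]))
  f2 <- matrix(c(0.5, 0.5, 0), 1, dimnames = list("s1", colnames(sig)))
  expect_equal(as.numeric(simulate_bulk_mixtures(sig, f2, 0)),
               unname((sig[, 1] + sig[, 2]) / 2))
  # noise SD recovered
  fr <- matrix(rep(1 / 3, 3), 1, dimnames = list("s1", colnames(sig)))
  reps <- replicate(200, as.numeric(
    simulate_bulk_mixtures(sig, fr, 0.1, seed = sample.int(1e6, 1))))
  clean <- as.numeric(sig %*% t(fr))
  resid <- sweep(reps, 1, clean)
  resid <- resid[clean > 1, ]  # avoid the zero floor
  se <- 0.1 / sqrt(2 * length(resid))
  expect_lt(abs(sd(resid) - 0.1), 3 * se)
  bad <- matrix(c(0.5, 0.4, 0.2), 1, dimnames = list("s1", colnames(sig)))
  expect_error(simulate_bulk_mixtures(sig, bad, 0), "sum to 1")
})
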