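# shared toy design: two cell types x 9 paired donors
diff_fixture <- function(n_sites, delta_sites = integer(0), delta = 0.2,
                         noise = 0.05, seed = 51L) {
  withr::with_seed(seed, {
    donors <- sprintf("D%02d", 1:9)
    ct <- rep(c("MGE-GABA", "GLU"), each = 9)
    meta <- data.frame(sample_id = paste(ct, rep(donors, 2), sep = "_"),
                       cell_type = ct, donor = rep(donors, 2),
                       age = rep(runif(9, 30, 80), 2),
                       PMI = rep(runif(9, 5, 40), 2),
                       stringsAsFactors = FALSE)
    base <- matrix(rbeta(n_sites, 2, 3), n_sites, 18)
    y <- base + matrix(rnorm(n_sites * 18, 0, noise), n_sites, 18)
    y[delta_sites, ct == "MGE-GABA"] <- y[delta_sites, ct == "MGE-GABA"] + delta
    y <- pmin(pmax(y, 0), 1)
    sm <- new_site_matrix(
      data.frame(site_id = sprintf("s%05d", seq_len(n_sites)), chrom = "chr1",
                 pos = seq_len(n_sites), strand = "+", stringsAsFactors = FALSE),
      y, matrix(50, n_sites, 18), matrix(25L, n_sites, 18), meta)
    sm
  })
}

test_that("Cohen's d matches the textbook formula", {
  expect_equal(cohens_d(c(0.4, 0.6), c(0.4, 0.6)), 0)
  a <- c(0.1, 0.2, 0.35); b <- a + 0.1
  expect_equal(cohens_d(b, a), 0.1 / sd(a))   # shift case, positive sign
  set.seed(52)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(9)
    sp <- sqrt((6 * var(x) + 8 * var(y)) / 14)
    expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  }
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
  expect_error(cohens_d(1, c(1, 2)), ">= 2 values")
})

test_that("differential editing handles degenerate and shifted sites", {
  sm <- diff_fixture(10, delta_sites = 1:3, noise = 0.03, seed = 53L)
  sm$level[10, ] <- 0.3   # identical groups
  dr <- differential_editing(sm, c("MGE-GABA", "GLU"))
  expect_true(dr$degenerate[10])
  expect_equal(dr$delta[10], 0)
  expect_false(dr$significant[10])
  expect_equal(dr$p[10], 1)
  # deltas and effect sizes share sign, FDR >= p
  expect_true(all(sign(dr$cohens_d) == sign(dr$delta) | dr$delta == 0))
  expect_true(all(dr$fdr >= dr$p - 1e-12))
  expect_true(all(dr$significant[1:3]))
  expect_gt(min(dr$delta[1:3]), 0.1)
})

test_that("differential editing is calibrated on label-permuted data", {
  sm <- diff_fixture(1000, seed = 101L)
  dr <- differential_editing(sm, c("MGE-GABA", "GLU"))
  # nominal type-I error within 2 binomial SE of alpha
  alpha <- 0.05
  frac <- mean(dr$p < alpha)
  expect_lt(abs(frac - alpha), 2 * sqrt(alpha * (1 - alpha) / 1000))
  expect_identical(sum(dr$significant), 0L)
})

test_that("BH adjustment matches brute-force step-up exactly", {
  set.seed(55)
  for (n in c(10, 500, 10000)) {
    p <- runif(n)^2
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("specificity classification applies the label rules", {
  sites <- data.frame(
    site_id = c("a", "b", "c"),
    detected_in = c("OLIG", "MGE-GABA,GLU,OLIG", "MGE-GABA,GLU,OLIG"),
    stringsAsFactors = FALSE)
  requery <- data.frame(
    site_id = c("a", "a"), cell_type = c("MGE-GABA", "GLU"),
    coverage = c(50L, 4L), edited = c(0L, 0L),
    label = c("covered-unedited", "insufficient-coverage"),
    stringsAsFactors = FALSE)
  mk_dr <- function(con, fdrs, deltas) {
    structure(data.frame(site_id = c("b", "c"), delta = deltas,
                         fdr = fdrs, degenerate = FALSE,
                         stringsAsFactors = FALSE), contrast = con)
  }
  drs <- list(
    mk_dr(c("MGE-GABA", "GLU"), c(0.001, 0.9), c(0.15, 0.01)),
    mk_dr(c("MGE-GABA", "OLIG"), c(0.5, 0.8), c(0.05, 0.01)),
    mk_dr(c("GLU", "OLIG"), c(0.7, 0.6), c(0.02, 0.01)))
  lab <- classify_specificity(sites, requery, drs)
  expect_identical(lab$label, c("specific:OLIG", "enriched:MGE-GABA", "shared"))
  # labels partition sites: exactly one label each
  expect_identical(anyDuplicated(lab$site_id), 0L)
  expect_true(all(nzchar(lab$label)))
  # conflicting/missing evidence errors
  expect_error(classify_specificity(sites, requery[1, , drop = FALSE], drs),
               "lacks re-query evidence")
})

test_that("variance partitioning attributes variance to the right factors", {
  withr::with_seed(56, {
    meta <- data.frame(sample_id = sprintf("s%02d", 1:27),
                       cell_type = rep(c("MGE-GABA", "GLU", "OLIG"), each = 9),
                       donor = rep(sprintf("D%d", 1:9), 3),
                       age = rep(runif(9, 30, 80), 3),
                       pH = rep(runif(9, 6, 7), 3),
                       PMI = rep(runif(9, 5, 40), 3),
                       ADAR1 = runif(27), ADAR2 = runif(27), ADAR3 = runif(27),
                       stringsAsFactors = FALSE)
    # zero-noise cell-type site: fraction exactly 1
    ctm <- c("MGE-GABA" = 0.2, GLU = 0.5, OLIG = 0.8)
    y1 <- matrix(ctm[meta$cell_type], 1)
    sm1 <- new_site_matrix(data.frame(site_id = "z", chrom = "chr1", pos = 1L,
                                      strand = "+"),
                           y1, y1 * 0 + 50, y1 * 0 + 10L, meta)
    vp1 <- variance_partition(sm1)
    expect_equal(vp1$cell_type, 1)
    expect_equal(vp1$residual, 0)

    # planted age effect explaining ~50% of variance, recovered within 0.1
    ag <- scale(meta$age)[, 1]
    n <- 120
    Y <- t(vapply(seq_len(n), function(i) 0.5 + 0.1 * ag + rnorm(27, 0, 0.1),
                  numeric(27)))
    sm2 <- new_site_matrix(data.frame(site_id = sprintf("v%03d", 1:n),
                                      chrom = "chr1", pos = 1:n, strand = "+"),
                           Y, Y * 0 + 50, Y * 0 + 10L, meta)
    vp2 <- variance_partition(sm2)
    expect_lt(abs(mean(vp2$age) - 0.5), 0.1)
    expect_true(all(abs(rowSums(as.matrix(vp2[, -1])) - 1) < 1e-6))
    expect_true(all(as.matrix(vp2[, -1]) >= -1e-12))

    # pure noise: median cell-type fraction stays small
    Y0 <- matrix(rnorm(n * 27, 0.5, 0.1), n, 27)
    sm0 <- sm2; sm0$level <- pmin(pmax(Y0, 0), 1)
    vp0 <- variance_partition(sm0)
    expect_lte(median(vp0$cell_type), 0.05)

    # affine rescaling of continuous covariates leaves fractions unchanged
    meta2 <- meta; meta2$age <- meta$age * 12 + 100
    sm3 <- sm2; sm3$samples <- meta2
    vp3 <- variance_partition(sm3)
    expect_equal(vp3$age, vp2$age, tolerance = 1e-4)

    # collinear continuous factors are refused with the pair named
    meta4 <- meta; meta4$ADAR2 <- 2 * meta4$ADAR1 + 3
    sm4 <- sm2; sm4$samples <- meta4
    expect_error(variance_partition(sm4), "collinear.*ADAR")
  })
})

test_that("ADAR association recovers slopes and stays calibrated", {
  withr::with_seed(57, {
    meta <- data.frame(sample_id = sprintf("s%02d", 1:27),
                       cell_type = rep(c("MGE-GABA", "GLU", "OLIG"), each = 9),
                       donor = rep(sprintf("D%d", 1:9), 3),
                       stringsAsFactors = FALSE)
    expr <- runif(27, 5, 15)
    n <- 200
    Y <- t(vapply(seq_len(n), function(i) 0.01 * expr + rnorm(27, 0, 0.001),
                  numeric(27)))
    sm <- new_site_matrix(data.frame(site_id = sprintf("a%03d", 1:n),
                                     chrom = "chr1", pos = 1:n, strand = "+"),
                          pmin(pmax(Y, 0), 1), Y * 0 + 50, Y * 0 + 10L, meta)
    aa <- adar_association(sm, expr)
    expect_true(all(abs(aa$slope - 0.01) / 0.01 < 0.1))
    expect_true(all(aa$fdr[!aa$degenerate] < 0.05))

    # permuted expression: few significant calls
    aa0 <- adar_association(sm, sample(expr))
    expect_lte(mean(aa0$fdr < 0.05), 0.07)

    # constant site: degenerate, slope 0, p ~ 1
    smc <- sm; smc$level[1, ] <- 0.4
    ac <- adar_association(smc, expr)
    expect_true(ac$degenerate[1])
    expect_equal(ac$slope[1], 0)
    expect_equal(ac$p[1], 1)
    expect_error(adar_association(sm, rep(1, 27)), "constant expression")
  })
})

test_that("gene editing density and outliers follow the definition", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:1000),
                      length = rep(1023L, 1000))
  site_gene <- rep(genes$gene_id[1], 31)
  gd <- gene_editing_density(site_gene, genes)
  expect_equal(gd$density[1], 31 / log2(1024))
  expect_equal(gd$density[2], 0)
  # one gene at 100x the background density is an outlier
  set.seed(58)
  bg_counts <- rpois(999, 5)
  site_gene2 <- c(rep(genes$gene_id[1], 500),
                  rep(genes$gene_id[-1], bg_counts))
  gd2 <- gene_editing_density(site_gene2, genes)
  z <- qnorm(0.995)
  expect_true(gd2$outlier[1])
  expect_identical(gd2$outlier,
                   gd2$density > mean(gd2$density) + z * sd(gd2$density) |
                     gd2$density < mean(gd2$density) - z * sd(gd2$density))
  expect_error(gene_editing_density("g001", data.frame(gene_id = "g001",
                                                       length = 0L)),
               "positive")
})

test_that("Fisher overlap enrichment matches the hypergeometric oracle", {
  bg <- sprintf("x%05d", 1:10000)
  # table (30, 70, 170, 9730): |A| = 100, |B| = 200
  A <- bg[1:100]; B <- bg[c(1:30, 101:270)]
  oe <- overlap_enrichment(A, B, bg)
  p_oracle <- sum(dhyper(30:100, 200, 9800, 100))
  expect_lt(abs(oe$p - p_oracle), 1e-10)
  expect_equal(oe$odds_ratio, (30 * 9730) / (70 * 170))

  # independence construction: OR ~ 1
  A2 <- bg[1:1000]; B2 <- bg[c(1:100, 1001:1900)]  # |A2 n B2| = |A||B|/N
  oe2 <- overlap_enrichment(A2, B2, bg)
  expect_equal(oe2$odds_ratio, 1, tolerance = 0.01)

  # A = B = half of the background: capped OR, maximal significance
  A3 <- bg[1:5000]
  oe3 <- overlap_enrichment(A3, A3, bg)
  expect_identical(oe3$odds_ratio, 1e6)
  expect_lt(oe3$p, 1e-100)
  expect_error(overlap_enrichment(A, B, character(0)), "non-empty")
})

test_that("permutation region overlap hits its degenerate limits", {
  g <- small_genome()
  q <- data.frame(chrom = "chr1", start = seq(1000L, 40000L, by = 1000L))
  q$end <- q$start + 199L
  # identity: observed is maximal
  po <- permutation_region_overlap(q, q, g, n_perm = 200L, seed = 61L)
  expect_equal(po$p, 1 / 201)
  expect_identical(po$observed, nrow(q))
  # targets covering the whole genome: every permutation ties, p = 1
  whole <- data.frame(chrom = "chr1", start = 1L, end = 60000L)
  po2 <- permutation_region_overlap(q, whole, g, n_perm = 100L, seed = 62L)
  expect_equal(po2$p, 1)
  expect_error(permutation_region_overlap(
    data.frame(chrom = "chr1", start = 1L, end = 70000L), q, g),
    "longer than its chromosome")
})
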