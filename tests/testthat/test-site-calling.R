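test_that("supervised quantification applies the coverage and edited-read rules", {
  pu <- rbind(
    pileup_row("chr1", 100L, "+", "A", A = 4L, G = 5L),            # cov 9
    pileup_row("chr1", 200L, "+", "A", A = 40L, G = 0L),           # cov 40, ed 0
    pileup_row("chr1", 300L, "+", "A", A = 10L, G = 10L),          # cov 20, ed 10
    pileup_row("chr1", 400L, "-", "T", T = 12L, C = 6L))           # minus strand
  s <- fake_sample(pu)
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                      strand = c("+", "+", "+", "-"),
                      stringsAsFactors = FALSE)
  sm <- quantify_supervised(list(s), sites)
  expect_true(is.na(sm$level[1, 1]))          # fails 10-read minimum
  expect_true(is.na(sm$level[2, 1]))          # fails 3-edited minimum
  expect_identical(sm$coverage[2, 1], 40)     # but coverage is recorded
  expect_equal(sm$level[3, 1], 0.5)
  expect_equal(sm$level[4, 1], 6 / 18)        # complemented on minus strand
  expect_true(all(sm$level >= 0 & sm$level <= 1, na.rm = TRUE))

  g <- small_genome()
  bad <- data.frame(chrom = "chr1", pos = 10^9L, strand = "+")
  expect_error(quantify_supervised(list(s), bad, genome = g), "outside genome")
})

test_that("de novo calling types candidates and flags multi-allelic events", {
  pu <- rbind(
    pileup_row("chr1", 100L, "+", "A", A = 45L, G = 5L),
    pileup_row("chr1", 200L, "+", "A", A = 30L, G = 5L, C = 4L),
    pileup_row("chr1", 300L, "+", "A", A = 99L, G = 1L),
    pileup_row("chr1", 400L, "-", "T", T = 40L, C = 8L),
    pileup_row("chr1", 500L, "+", "C", C = 44L, T = 6L))
  cand <- call_denovo(list(fake_sample(pu)))
  ids <- cand$sites$pos
  expect_true(100L %in% ids)
  expect_equal(cand$level[cand$sites$pos == 100L, 1], 0.1)
  expect_true(cand$sites$multi_allelic[cand$sites$pos == 200L])
  expect_false(300L %in% ids)                 # ratio 1% below 5%
  expect_identical(cand$sites$type[cand$sites$pos == 400L], "A>G")
  expect_identical(cand$sites$type[cand$sites$pos == 500L], "C>T")
  expect_true(cand$sites$provisional[cand$sites$pos == 500L])
  expect_false(cand$sites$provisional[cand$sites$pos == 100L])
})

test_that("filter cascade matches the brute-force oracle on boundary cases", {
  toy <- make_boundary_table(200L, seed = 31L)
  cand <- toy_candidates(toy$sites, toy$coverage, toy$edited, toy$cell_type,
                         toy$multi_allelic)
  res <- apply_filter_cascade(cand, toy$genome, k = 8L)
  keep_oracle <- oracle_cascade(toy$sites, toy$coverage, toy$edited,
                                toy$cell_type, toy$genome, toy$multi_allelic,
                                k = 8L)
  expect_identical(sort(res$matrix$sites$pos), sort(toy$sites$pos[keep_oracle]))
  # conservation: input = retained + sum(removed)
  expect_identical(attr(res$report, "input"),
                   attr(res$report, "retained") + sum(res$report$removed))
})

test_that("cascade rules fire in order and on the stated boundaries", {
  base_cov <- matrix(60L, 4, 9); base_ed <- matrix(6L, 4, 9)  # all detected
  sites <- data.frame(chrom = "chrT", pos = c(100L, 200L, 300L, 400L),
                      strand = "+", stringsAsFactors = FALSE)
  genome <- annotation_bundle(
    blacklist = data.frame(chrom = "chrT", start = 99L, end = 101L),
    splice = data.frame(chrom = "chrT", pos = 203L),          # 3 bp from 200
    snps = data.frame(chrom = "chrT", pos = c(300L, 400L), maf = c(0.10, 0.01)))
  cand <- toy_candidates(sites, base_cov, base_ed, rep("GLU", 9),
                         multi_allelic = c(TRUE, FALSE, FALSE, FALSE))
  res <- apply_filter_cascade(cand, genome, k = 8L)
  rpt <- res$report
  # site 1 is blacklisted AND multi-allelic: counted once, under rule 1
  expect_identical(rpt$removed[rpt$rule == "multi-allelic"], 1L)
  expect_identical(rpt$removed[rpt$rule == "blacklist/homopolymer"], 0L)
  expect_identical(rpt$removed[rpt$rule == "splice-adjacent"], 1L)
  expect_identical(rpt$removed[rpt$rule == "snp"], 1L)
  # MAF 0.01 site survives everything
  expect_identical(res$matrix$sites$pos, 400L)
  expect_error(apply_filter_cascade(cand, genome, k = 10L), "exceeds group size")
})

test_that("detection-rate rule requires k of n within one cell type", {
  # detected in 7 of 9 MGE-GABA samples only -> removed
  cov <- matrix(0L, 1, 18); ed <- matrix(0L, 1, 18)
  cov[1, 1:7] <- 50L; ed[1, 1:7] <- 10L
  sites <- data.frame(chrom = "chrT", pos = 100L, strand = "+")
  cand <- toy_candidates(sites, cov, ed,
                         rep(c("MGE-GABA", "GLU"), each = 9))
  res <- apply_filter_cascade(cand, annotation_bundle(), k = 8L)
  expect_identical(nrow(res$matrix$sites), 0L)
  expect_identical(res$report$removed[res$report$rule == "detection-rate"], 1L)
  # an 8th detecting sample rescues it
  cov[1, 8] <- 50L; ed[1, 8] <- 10L
  cand2 <- toy_candidates(sites, cov, ed, rep(c("MGE-GABA", "GLU"), each = 9))
  res2 <- apply_filter_cascade(cand2, annotation_bundle(), k = 8L)
  expect_identical(res2$matrix$sites$detected_in, "MGE-GABA")
})

test_that("cascade retains true sites and rejects error-only positions", {
  g <- small_genome()
  tr <- simulate_editing_truth(g, n_sites = 120L, seed = 32L)
  ss <- simulate_pileups(tr, g, n_donors = 9L, mean_coverage = 50,
                         error_rate = 0.001, seed = 33L)
  cand <- call_denovo(ss, g)
  res <- apply_filter_cascade(cand, g, k = 8L)
  got <- paste(res$matrix$sites$chrom, res$matrix$sites$pos)
  st <- tr$sites
  rates <- as.matrix(st[, paste0("rate_", c("MGE-GABA", "GLU", "OLIG"))])
  strong <- apply(rates, 1, max) >= 0.1
  expect_gte(mean(paste(st$chrom, st$pos)[strong] %in% got), 0.95)
  nulls <- paste(st$chrom, st$pos)[st$class == "null"]
  expect_identical(sum(nulls %in% got), 0L)
  # recovered sites are detected in their truly edited cell types
  idx <- match(got, paste(st$chrom, st$pos))
  spec_glu <- which(st$class[idx] == "specific:GLU")
  expect_true(all(res$matrix$sites$detected_in[spec_glu] == "GLU"))
})

test_that("re-query labels the zero classes from pooled counts", {
  mk <- function(cov, ed) {
    pu <- pileup_row("chr1", 100L, "+", "A", A = cov - ed, G = ed)
    fake_sample(pu, id = paste0("s", cov, ed), cell_type = "GLU", donor = "d9")
  }
  sm <- list(sites = data.frame(site_id = "x", chrom = "chr1", pos = 100L,
                                strand = "+", detected_in = "MGE-GABA",
                                stringsAsFactors = FALSE))
  expect_identical(
    requery_other_celltypes(sm, list(mk(50L, 0L)))$label, "covered-unedited")
  expect_identical(
    requery_other_celltypes(sm, list(mk(4L, 0L)))$label, "insufficient-coverage")
  expect_identical(
    requery_other_celltypes(sm, list(mk(12L, 2L)))$label, "covered-unedited")
  expect_identical(
    requery_other_celltypes(sm, list(mk(12L, 3L)))$label, "insufficient-coverage")
})

test_that("median imputation fills gaps without moving group medians", {
  meta_ct <- rep(c("MGE-GABA", "GLU"), each = 3)
  lv <- rbind(c(0.1, 0.3, NA, 0.5, 0.5, 0.5),
              c(0.1, 0.2, 0.9, NA, 0.4, 0.6),
              c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
  sm <- toy_candidates(data.frame(chrom = "chr1", pos = 1:3, strand = "+"),
                       matrix(50, 3, 6), matrix(25, 3, 6), meta_ct)
  sm$level <- lv
  imp <- impute_missing_median(sm)
  expect_equal(imp$level[1, 3], 0.2)   # median of {0.1, 0.3}
  expect_equal(imp$level[2, 4], 0.5)   # median of {0.4, 0.6}, not the mean path
  expect_identical(imp$level[3, ], lv[3, ])  # untouched without missingness
  for (cc in unique(meta_ct)) {
    j <- meta_ct == cc
    expect_equal(apply(imp$level[, j], 1, median),
                 apply(sm$level[, j], 1, median, na.rm = TRUE))
  }
  # median, not mean: observed {0.1, 0.2, 0.9} imputes 0.2
  sm2 <- toy_candidates(data.frame(chrom = "chr1", pos = 1L, strand = "+"),
                        matrix(50, 1, 4), matrix(25, 1, 4), rep("GLU", 4))
  sm2$level <- matrix(c(0.1, 0.2, 0.9, NA), 1)
  expect_equal(impute_missing_median(sm2)$level[1, 4], 0.2)
  # all-missing within a group is an error
  sm3 <- sm
  sm3$level[1, 1:3] <- NA
  expect_error(impute_missing_median(sm3), "every sample of group")
})

test_that("annotation assigns region precedence, repeats, catalog and recoding", {
  g <- small_genome()
  # an intronic Alu position: independent axes
  alu <- g$alu_intervals
  intr <- NULL
  for (i in seq_len(nrow(alu))) {
    gi <- g$genes[g$genes$start <= alu$start[i] & g$genes$end >= alu$end[i], ]
    if (nrow(gi) == 0) next
    ex <- g$exons[g$exons$gene_id == gi$gene_id[1], ]
    mid <- alu$start[i]:alu$end[i]
    inx <- mid[!in_any(mid, ex)]
    if (length(inx)) { intr <- data.frame(chrom = alu$chrom[i], pos = inx[1],
                                          strand = "+"); break }
  }
  ann <- annotate_sites(intr, g)
  expect_identical(ann$region, "intron")
  expect_identical(ann$repeat_class, "Alu")

  # catalog: exact match only
  cat_tbl <- data.frame(chrom = intr$chrom, pos = intr$pos, strand = "+")
  a1 <- annotate_sites(intr, g, catalog = cat_tbl)
  expect_identical(a1$catalog_status, "known")
  off <- intr; off$pos <- off$pos + 1L
  a2 <- annotate_sites(off, g, catalog = cat_tbl)
  expect_identical(a2$catalog_status, "not-in-catalog")
})

test_that("recoding flags agree with an independent translation oracle", {
  g <- small_genome()
  # every CDS adenosine (transcript strand) of each gene, vs Biostrings
  checked <- 0L
  for (gid in unique(g$cds$gene_id)) {
    cds <- g$cds[g$cds$gene_id == gid, ]
    cds <- cds[order(cds$start), ]
    strand <- g$genes$strand[g$genes$gene_id == gid]
    chrom <- cds$chrom[1]
    gpos <- unlist(Map(seq, cds$start, cds$end))
    txt <- paste(substring(g$chromosomes[[chrom]], cds$start, cds$end),
                 collapse = "")
    if (strand == "-") {
      txt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(txt)))
      gpos <- rev(gpos)
    }
    a_idx <- which(strsplit(txt, "")[[1]] == "A")
    a_idx <- utils::head(a_idx, 25L)
    for (ai in a_idx) {
      edited_txt <- txt
      substr(edited_txt, ai, ai) <- "G"
      n3 <- (nchar(txt) %/% 3) * 3
      p_ref <- Biostrings::translate(Biostrings::DNAString(substr(txt, 1, n3)))
      p_alt <- Biostrings::translate(Biostrings::DNAString(substr(edited_txt, 1, n3)))
      expected <- as.character(p_ref) != as.character(p_alt)
      site <- data.frame(chrom = chrom, pos = gpos[ai], strand = strand)
      ann <- annotate_sites(site, g)
      if (ann$region != "CDS") next   # UTR-overlapping codons out of scope here
      checked <- checked + 1L
      expect_identical(ann$recoding, expected)
    }
  }
  expect_gt(checked, 30L)
})
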