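# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_genome <- function() cached("small_genome",
  build_synthetic_genome(c(chr1 = 60000L), n_genes = 5L, seed = 11L))

big_genome <- function() cached("big_genome",
  build_synthetic_genome(c(chr1 = 300000L, chr2 = 300000L),
                         n_genes = 12L, seed = 12L))

# a bare annotation bundle with hand-placed layers; enough structure for the
# filter cascade, which only consults the annotation fields
annotation_bundle <- function(chrom_len = 1e6L,
                              blacklist = empty_iv(), homopolymer = empty_iv(),
                              splice = data.frame(chrom = character(),
                                                  pos = integer()),
                              snps = data.frame(chrom = character(),
                                                pos = integer(),
                                                maf = numeric())) {
  structure(list(chromosomes = c(chrT = strrep("A", 10L)),  # unused by cascade
                 blacklist_intervals = blacklist,
                 homopolymer_intervals = homopolymer,
                 splice_sites = splice, snps = snps),
            class = "GenomeBundle")
}

empty_iv <- function() data.frame(chrom = character(), start = integer(),
                                  end = integer(), stringsAsFactors = FALSE)

# assemble a candidate SiteMatrix directly from coverage / edited matrices
toy_candidates <- function(sites, coverage, edited, cell_type,
                           multi_allelic = rep(FALSE, nrow(sites))) {
  meta <- data.frame(sample_id = sprintf("s%02d", seq_along(cell_type)),
                     cell_type = cell_type,
                     donor = sprintf("d%02d", seq_along(cell_type)),
                     stringsAsFactors = FALSE)
  sites$site_id <- sites$site_id %||% sprintf("toy%05d", seq_len(nrow(sites)))
  sites$multi_allelic <- multi_allelic
  level <- ifelse(coverage > 0, edited / coverage, NA_real_)
  sm <- new_site_matrix(sites, level, coverage, edited, meta)
  sm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent brute-force oracle for the filter cascade ----------------
# evaluates the six predicates with plain loops, no shared code with the
# package implementation
oracle_cascade <- function(sites, coverage, edited, cell_type, genome,
                           multi_allelic, k = 8L, min_cov = 10, min_ed = 3,
                           min_ratio = 0.05, maf_max = 0.05, splice_dist = 5) {
  n <- nrow(sites)
  keep <- logical(n)
  in_iv <- function(chrom, pos, iv) {
    if (is.null(iv) || nrow(iv) == 0) return(FALSE)
    any(iv$chrom == chrom & iv$start <= pos & iv$end >= pos)
  }
  for (i in seq_len(n)) {
    if (multi_allelic[i]) next
    det <- logical(length(cell_type))
    for (j in seq_along(cell_type)) {
      cv <- coverage[i, j]; ee <- edited[i, j]
      det[j] <- cv >= min_cov && ee >= min_ed && cv > 0 && ee / cv >= min_ratio
    }
    if (!any(det)) next
    if (in_iv(sites$chrom[i], sites$pos[i], genome$blacklist_intervals)) next
    if (in_iv(sites$chrom[i], sites$pos[i], genome$homopolymer_intervals)) next
    sn <- genome$snps
    if (nrow(sn) > 0 &&
        any(sn$chrom == sites$chrom[i] & sn$pos == sites$pos[i] &
              sn$maf > maf_max)) next
    sp <- genome$splice_sites
    if (nrow(sp) > 0 &&
        any(sp$chrom == sites$chrom[i] &
              abs(sp$pos - sites$pos[i]) <= splice_dist)) next
    pass6 <- FALSE
    for (cc in unique(cell_type)) {
      if (sum(det[cell_type == cc]) >= k) pass6 <- TRUE
    }
    if (!pass6) next
    keep[i] <- TRUE
  }
  keep
}

# enumerated toy table spanning every cascade rule boundary
make_boundary_table <- function(n_sites, seed) {
  withr::with_seed(seed, {
    n_samp <- 9L
    cell_type <- rep("MGE-GABA", n_samp)
    pos <- seq(100L, by = 100L, length.out = n_sites)
    sites <- data.frame(chrom = "chrT", pos = pos, strand = "+",
                        stringsAsFactors = FALSE)
    # annotation layers straddling the boundaries
    bl <- sample(c(TRUE, FALSE), n_sites, TRUE, prob = c(0.1, 0.9))
    hp <- sample(c(TRUE, FALSE), n_sites, TRUE, prob = c(0.1, 0.9))
    splice_d <- sample(c(4L, 5L, 6L, 1000L), n_sites, TRUE,
                       prob = c(0.1, 0.1, 0.1, 0.7))
    maf <- sample(c(0.04, 0.06, NA), n_sites, TRUE, prob = c(0.15, 0.15, 0.7))
    genome <- annotation_bundle(
      blacklist = data.frame(chrom = "chrT", start = pos[bl] - 1L,
                             end = pos[bl] + 1L),
      homopolymer = data.frame(chrom = "chrT", start = pos[hp] - 2L,
                               end = pos[hp]),
      splice = data.frame(chrom = "chrT",
                          pos = pos + splice_d),
      snps = data.frame(chrom = "chrT", pos = pos[!is.na(maf)],
                        maf = maf[!is.na(maf)]))
    # per-sample counts drawn from the boundary grid:
    # coverage 9/10/11 with edited 2/3, and coverage 1000 with edited
    # 49/50/51 (ratios 4.9% / 5.0% / 5.1%)
    n_det <- sample(c(7L, 8L, 9L), n_sites, TRUE)
    coverage <- matrix(0L, n_sites, n_samp)
    edited <- matrix(0L, n_sites, n_samp)
    for (i in seq_len(n_sites)) {
      for (j in seq_len(n_samp)) {
        if (j <= n_det[i]) {
          if (runif(1) < 0.5) {
            coverage[i, j] <- sample(c(9L, 10L, 11L), 1L)
            edited[i, j] <- sample(c(2L, 3L), 1L)
          } else {
            coverage[i, j] <- 1000L
            edited[i, j] <- sample(c(49L, 50L, 51L), 1L)
          }
        } else {
          coverage[i, j] <- sample(c(0L, 5L), 1L)
          edited[i, j] <- 0L
        }
      }
    }
    multi <- sample(c(TRUE, FALSE), n_sites, TRUE, prob = c(0.05, 0.95))
    list(sites = sites, coverage = coverage, edited = edited,
         cell_type = cell_type, multi_allelic = multi, genome = genome)
  })
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    v <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

# fake sample object wrapping a pileup table
fake_sample <- function(pileup, id = "s1", cell_type = "MGE-GABA",
                        donor = "d1", mapped_bases = 1e6) {
  structure(list(sample_id = id, cell_type = cell_type, donor = donor,
                 covariates = list(age = 50, PMI = 20), pileup = pileup,
                 mapped_bases = mapped_bases, adar_scale = 1),
            class = "SimulatedSample")
}

pileup_row <- function(chrom, pos, strand, ref, A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(chrom = chrom, pos = pos, strand = strand, ref = ref,
             A = A, C = C, G = G, T = T, coverage = A + C + G + T,
             stringsAsFactors = FALSE)
}

in_any <- function(pos, iv) {
  vapply(pos, function(p) any(iv$start <= p & iv$end >= p), logical(1))
}
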