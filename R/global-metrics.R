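#' Alu editing index (AEI)
#'
#' The AEI is the ratio of the total number of A-to-G edited reads to the
#' total read coverage over all adenosines within Alu elements, computed
#' strand-aware: on '+' intervals adenosines are reference A and edited
#' reads are G; on '-' intervals adenosines are reference T and edited reads
#' are C.
#'
#' @param pileup a pileup data.frame (chrom, pos, strand, ref, A, C, G, T,
#'   coverage), or a `SimulatedSample`.
#' @param alu_intervals interval data.frame (chrom, start, end, strand).
#' @return the AEI, a number in [0, 1].
#' @export
compute_aei <- function(pileup, alu_intervals) {
  if (inherits(pileup, "SimulatedSample")) pileup <- pileup$pileup
  stop_if_not(!is.null(alu_intervals$strand), "Alu intervals need a strand column")
  tot_ed <- 0; tot_cov <- 0
  for (str in c("+", "-")) {
    ivl <- alu_intervals[alu_intervals$strand == str, , drop = FALSE]
    if (nrow(ivl) == 0L) next
    want_ref <- if (str == "+") "A" else "T"
    ed_col <- if (str == "+") "G" else "C"
    sel <- pileup$ref == want_ref & in_intervals(pileup$chrom, pileup$pos, ivl)
    tot_ed <- tot_ed + sum(pileup[[ed_col]][sel])
    tot_cov <- tot_cov + sum(pileup$coverage[sel])
  }
  stop_if_not(tot_cov > 0, "no Alu adenosine coverage: AEI undefined")
  tot_ed / tot_cov
}

#' Normalized hyper-editing rate
#'
#' Hyper-editing sites per million mapped bases:
#' `n_sites / mapped_bases * 1e6`.
#'
#' @param n_sites number of hyper-editing sites detected in a sample.
#' @param mapped_bases total mapped bases of the sample (> 0).
#' @return the normalized rate.
#' @export
normalized_he_rate <- function(n_sites, mapped_bases) {
  stop_if_not(all(mapped_bases > 0), "mapped_bases must be positive")
  n_sites / mapped_bases * 1e6
}

# --- hyper-editing detection ------------------------------------------------

# unique ungapped alignment of a transformed read against transformed
# chromosomes; seeds at three offsets, verification by Hamming distance
transformed_align <- function(tread, tgenome, k = 16L, max_mm_frac = 0.05) {
  L <- nchar(tread)
  offsets <- unique(pmin(c(1L, 1L + k, 1L + 2L * k), L - k + 1L))
  cand <- list()
  for (cn in names(tgenome)) {
    g <- tgenome[[cn]]
    for (off in offsets) {
      seed <- substr(tread, off, off + k - 1L)
      hits <- gregexpr(seed, g, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (h in hits) {
        s <- h - off + 1L
        if (s < 1L || s + L - 1L > nchar(g)) next
        cand[[paste(cn, s)]] <- c(cn = cn, start = s)
      }
    }
  }
  if (length(cand) == 0L) return(NULL)
  ok <- list()
  for (cd in cand) {
    s <- as.integer(cd["start"])
    ref <- substr(tgenome[[cd["cn"]]], s, s + L - 1L)
    mm <- hamming(tread, ref)
    if (mm <= max_mm_frac * L) ok[[paste(cd["cn"], s)]] <- list(chrom = cd[["cn"]], start = s, mm = mm)
  }
  if (length(ok) == 0L) return(NULL)
  if (length(ok) > 1L) return("ambiguous")
  ok[[1L]]
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Detect hyper-editing by transformed alignment
#'
#' Reads withheld from (or failing) ordinary alignment are aligned after
#' erasing the editing signal: for the plus-strand pass both reads and
#' genome have A converted to G; the minus-strand pass aligns the
#' reverse-complemented read against a T-to-C transformed genome. Alignment
#' uses exact k-mer seeding with ungapped verification and must be unique
#' (ambiguous reads are discarded and counted). Original sequences are then
#' restored and A>G mismatches called. A read counts as hyper-edited with at
#' least `min_sites` A>G sites, with A>G accounting for at least
#' `min_fraction` of all its mismatches, while at most
#' `max_mismatch_fraction` of all bases mismatch (screening out generally
#' hyper-mutated or mis-placed reads).
#' Per-strand site runs separated by more than `max_gap` bp are split into
#' clusters; each cluster is extended on both ends by its mean inter-site
#' distance and overlapping clusters are merged (idempotent). Finally,
#' sites at SNPs with minor allele frequency above 0.05 are dropped.
#'
#' @param reads data.frame with read_id and seq columns.
#' @param genome a `GenomeBundle`.
#' @param min_sites minimum A>G sites per hyper-edited read.
#' @param min_fraction minimum fraction of the read's mismatches that are
#'   A>G on the aligned strand.
#' @param max_mismatch_fraction maximum fraction of mismatched bases.
#' @param k seed k-mer length.
#' @param max_gap maximum intra-cluster gap between neighbouring sites (bp).
#' @param min_cluster_sites minimum member sites per reported cluster.
#' @param maf_max SNP allele-frequency cutoff for site removal.
#' @return list with `sites` (chrom, pos, strand), `clusters` (a
#'   `HyperCluster` data.frame: chrom, strand, start, end, n_sites,
#'   mean_spacing, site positions and supporting reads as comma strings)
#'   and `report` (aligned / ambiguous / hyper-edited read counts).
#' @export
detect_hyperediting <- function(reads, genome, min_sites = 5L,
                                min_fraction = 0.6,
                                max_mismatch_fraction = 0.9,
                                k = 16L, max_gap = 100L,
                                min_cluster_sites = 3L, maf_max = 0.05) {
  tg_plus <- vapply(genome$chromosomes, function(s) chartr("A", "G", s),
                    character(1))
  tg_minus <- vapply(genome$chromosomes, function(s) chartr("T", "C", s),
                     character(1))
  n_amb <- 0L; n_aligned <- 0L
  site_rows <- list(); read_of_site <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads$seq[i]
    hit <- transformed_align(chartr("A", "G", rd), tg_plus, k = k)
    strand <- "+"
    if (is.null(hit)) {
      hit <- transformed_align(chartr("T", "C", revcomp(rd)), tg_minus, k = k)
      strand <- "-"
    }
    if (is.null(hit)) next
    if (identical(hit, "ambiguous")) { n_amb <- n_amb + 1L; next }
    n_aligned <- n_aligned + 1L
    L <- nchar(rd)
    ref <- substr(genome$chromosomes[[hit$chrom]], hit$start, hit$start + L - 1L)
    qry <- if (strand == "+") rd else revcomp(rd)
    rv <- strsplit(ref, "")[[1]]; qv <- strsplit(qry, "")[[1]]
    mism <- rv != qv
    if (strand == "+") {
      edited <- which(rv == "A" & qv == "G")
    } else {
      edited <- which(rv == "T" & qv == "C")
    }
    n_mism <- sum(mism)
    if (length(edited) >= min_sites && n_mism > 0L &&
        length(edited) / n_mism >= min_fraction &&
        n_mism / L <= max_mismatch_fraction) {
      gpos <- hit$start + edited - 1L
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        chrom = hit$chrom, pos = gpos, strand = strand,
        read_id = reads$read_id[i], stringsAsFactors = FALSE)
    }
  }
  report <- data.frame(aligned = n_aligned, ambiguous = n_amb,
                       hyper_reads = length(site_rows))
  if (length(site_rows) == 0L) {
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   strand = character(), stringsAsFactors = FALSE),
                clusters = empty_hypercluster(), report = report))
  }
  raw <- do.call(rbind, site_rows)
  snps <- genome$snps[genome$snps$maf > maf_max, , drop = FALSE]
  raw <- raw[!site_key(raw$chrom, raw$pos) %in% site_key(snps$chrom, snps$pos), ,
             drop = FALSE]
  sites <- unique(raw[, c("chrom", "pos", "strand")])
  sites <- sites[order(sites$chrom, sites$strand, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  clusters <- cluster_he_sites(raw, max_gap = max_gap,
                               min_cluster_sites = min_cluster_sites)
  list(sites = sites, clusters = clusters, report = report)
}

empty_hypercluster <- function() {
  structure(data.frame(chrom = character(), strand = character(),
                       start = integer(), end = integer(), n_sites = integer(),
                       mean_spacing = numeric(), sites = character(),
                       reads = character(), stringsAsFactors = FALSE),
            class = c("HyperCluster", "data.frame"))
}

#' Cluster hyper-editing sites with boundary extension
#'
#' Groups per-strand site runs separated by at most `max_gap` bp, extends
#' each cluster's [min, max] span by its mean inter-site distance on both
#' ends, and merges overlapping clusters. E.g. sites {100, 110, 130} have
#' mean spacing 15 and yield the extended cluster [85, 145].
#'
#' @param raw data.frame with chrom, pos, strand and read_id columns (one
#'   row per supporting read x site).
#' @param max_gap maximum distance between neighbouring member sites.
#' @param min_cluster_sites clusters with fewer sites are dropped.
#' @return a `HyperCluster` data.frame.
#' @export
cluster_he_sites <- function(raw, max_gap = 100L, min_cluster_sites = 3L) {
  out <- list()
  for (grp in split(raw, paste(raw$chrom, raw$strand))) {
    pos <- sort(unique(grp$pos))
    brk <- c(0L, which(diff(pos) > max_gap), length(pos))
    for (b in seq_len(length(brk) - 1L)) {
      p <- pos[(brk[b] + 1L):brk[b + 1L]]
      if (length(p) < min_cluster_sites) next
      dbar <- mean(diff(p))
      rid <- unique(grp$read_id[grp$pos %in% p])
      out[[length(out) + 1L]] <- data.frame(
        chrom = grp$chrom[1], strand = grp$strand[1],
        start = as.integer(floor(min(p) - dbar)),
        end = as.integer(ceiling(max(p) + dbar)),
        n_sites = length(p), mean_spacing = dbar,
        sites = paste(p, collapse = ","),
        reads = paste(rid, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_hypercluster())
  cl <- do.call(rbind, out)
  cl <- merge_he_clusters(cl)
  structure(cl, class = c("HyperCluster", "data.frame"))
}

#' Merge overlapping hyper-editing clusters
#'
#' Merges clusters (per chromosome and strand) whose extended coordinates
#' overlap, pooling member sites and supporting reads. Idempotent:
#' re-running on its own output changes nothing.
#'
#' @param cl a `HyperCluster` data.frame.
#' @return merged `HyperCluster` data.frame.
#' @export
merge_he_clusters <- function(cl) {
  if (nrow(cl) <= 1L) return(cl)
  res <- list()
  for (grp in split(cl, paste(cl$chrom, cl$strand))) {
    grp <- grp[order(grp$start), , drop = FALSE]
    cur <- grp[1L, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1L]) {
      if (grp$start[i] <= cur$end) {
        pos <- sort(unique(c(as.integer(strsplit(cur$sites, ",")[[1]]),
                             as.integer(strsplit(grp$sites[i], ",")[[1]]))))
        cur$end <- max(cur$end, grp$end[i])
        cur$start <- min(cur$start, grp$start[i])
        cur$n_sites <- length(pos)
        cur$mean_spacing <- if (length(pos) > 1L) mean(diff(pos)) else 0
        cur$sites <- paste(pos, collapse = ",")
        cur$reads <- paste(sort(unique(c(strsplit(cur$reads, ",")[[1]],
                                         strsplit(grp$reads[i], ",")[[1]]))),
                           collapse = ",")
      } else {
        res[[length(res) + 1L]] <- cur
        cur <- grp[i, , drop = FALSE]
      }
    }
    res[[length(res) + 1L]] <- cur
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("HyperCluster", "data.frame"))
}

# --- local sequence context -------------------------------------------------

#' Nucleotide frequency and enrichment around editing sites
#'
#' Extracts the sequence `flank` bp either side of each edited adenosine (on
#' the site strand; minus-strand contexts are reverse-complemented), tabulates
#' per-position nucleotide frequencies and reports log2 enrichment against
#' the genome-wide adenosine context background. Counts receive a
#' pseudocount of 1 per cell and log-ratios are capped at +/- `cap`.
#'
#' @param sites data.frame with chrom, pos, strand.
#' @param genome a `GenomeBundle`.
#' @param flank flank width in bp (default 4: a 9-base window).
#' @param cap absolute cap on log2 enrichment values.
#' @param max_background number of genome-wide adenosine contexts sampled
#'   for the background (all used if fewer).
#' @return list with `freq` and `enrichment` (4 x (2*flank+1) matrices,
#'   positions -flank..+flank) and `skipped` (sites too close to a
#'   chromosome end).
#' @export
motif_profile <- function(sites, genome, flank = 4L, cap = 8,
                          max_background = 20000L) {
  ctx <- site_contexts(sites$chrom, sites$pos, sites$strand, genome, flank)
  skipped <- attr(ctx, "skipped")
  stop_if_not(length(ctx) > 0L, "no site context could be extracted")
  obs <- context_counts(ctx, flank)

  # background: genome-wide adenosine contexts (both strands)
  bg_sites <- list()
  for (cn in names(genome$chromosomes)) {
    v <- strsplit(genome$chromosomes[[cn]], "")[[1]]
    pa <- which(v == "A"); pt <- which(v == "T")
    bg_sites[[cn]] <- data.frame(
      chrom = cn, pos = c(pa, pt),
      strand = rep(c("+", "-"), c(length(pa), length(pt))),
      stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, bg_sites)
  if (nrow(bg) > max_background) {
    idx <- round(seq(1L, nrow(bg), length.out = max_background))
    bg <- bg[idx, , drop = FALSE]
  }
  bctx <- site_contexts(bg$chrom, bg$pos, bg$strand, genome, flank)
  bgc <- context_counts(bctx, flank)

  f_obs <- sweep(obs, 2L, colSums(obs), "/")
  pobs <- sweep(obs + 1, 2L, colSums(obs + 1), "/")
  pbg <- sweep(bgc + 1, 2L, colSums(bgc + 1), "/")
  enr <- log2(pobs / pbg)
  enr[enr > cap] <- cap; enr[enr < -cap] <- -cap
  list(freq = f_obs, enrichment = enr, skipped = skipped)
}

site_contexts <- function(chrom, pos, strand, genome, flank) {
  lens <- nchar(genome$chromosomes)
  ok <- pos - flank >= 1L & pos + flank <= lens[chrom]
  ctx <- character(sum(ok))
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    s <- substr(genome$chromosomes[[chrom[i]]], pos[i] - flank, pos[i] + flank)
    ctx[j] <- if (strand[i] == "+") s else revcomp(s)
  }
  structure(ctx, skipped = sum(!ok))
}

context_counts <- function(ctx, flank) {
  w <- 2L * flank + 1L
  m <- matrix(0L, 4L, w, dimnames = list(c("A", "C", "G", "T"),
                                         as.character(-flank:flank)))
  chars <- do.call(rbind, strsplit(ctx, ""))
  for (j in seq_len(w)) {
    tb <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    m[, j] <- as.integer(tb)
  }
  m
}
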