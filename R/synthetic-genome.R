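#' Build a small synthetic genome with gene and repeat annotation
#'
#' Generates random chromosome sequences together with the annotation layers
#' the editing pipeline consumes: multi-exon gene models (TSS, exons, CDS,
#' UTRs, splice sites), A-rich Alu-like repeat intervals, L1-like intervals,
#' blacklist regions, homopolymer runs and common SNPs with allele
#' frequencies. All coordinates are 1-based and intervals are closed.
#'
#' Alu-like intervals are rewritten to be adenosine-rich on their annotated
#' strand (with homopolymer runs suppressed inside them) so that Alu editing
#' index denominators are non-zero. Homopolymer intervals are obtained by
#' scanning the final sequence for runs of length >= `homopolymer_min`,
#' so they reflect the sequence actually emitted.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (>= 10 kb).
#' @param n_genes number of genes per chromosome.
#' @param repeat_density approximate fraction of each chromosome covered by
#'   Alu-like repeats; 0 gives no Alu intervals.
#' @param l1_density approximate fraction covered by L1-like repeats.
#' @param blacklist_density approximate fraction covered by blacklist regions.
#' @param snp_rate expected SNPs per base.
#' @param homopolymer_min run length from which a mononucleotide run is
#'   recorded as a homopolymer interval.
#' @param seed integer seed; the bundle is byte-identical for a fixed seed.
#' @return an object of class `GenomeBundle`: a list with elements
#'   `chromosomes` (named character vector), `genes`, `exons`, `cds`, `utr5`,
#'   `utr3`, `splice_sites`, `alu_intervals`, `l1_intervals`,
#'   `blacklist_intervals`, `homopolymer_intervals`, `snps`.
#' @export
build_synthetic_genome <- function(chrom_lengths = c(chr1 = 200000L),
                                   n_genes = 8L,
                                   repeat_density = 0.15,
                                   l1_density = 0.03,
                                   blacklist_density = 0.01,
                                   snp_rate = 1 / 1000,
                                   homopolymer_min = 5L,
                                   seed = 1L) {
  stop_if_not(all(chrom_lengths >= 10000L), "chromosome lengths must be >= 10 kb")
  stop_if_not(!is.null(names(chrom_lengths)) && all(nzchar(names(chrom_lengths))),
              "chrom_lengths must be named")
  with_local_seed(seed, {
    chroms <- list(); genes <- list(); exons <- list(); cds <- list()
    utr5 <- list(); utr3 <- list(); splice <- list()
    alu <- list(); l1 <- list(); black <- list(); snps <- list()
    hp_all <- list()
    gi <- 0L
    for (cn in names(chrom_lengths)) {
      L <- as.integer(chrom_lengths[[cn]])
      seq_v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

      # --- gene placement: non-overlapping bodies separated by >= 500 bp
      gene_len <- sample(3000:6000, n_genes, replace = TRUE)
      need <- sum(gene_len) + 500L * (n_genes + 1L)
      if (need > L) {
        stop(sprintf("cannot place %d genes of total span %d on '%s' (length %d)",
                     n_genes, need, cn, L), call. = FALSE)
      }
      slack <- L - sum(gene_len) - 500L * (n_genes + 1L)
      gaps <- 500L + floor(slack * diff(c(0, sort(stats::runif(n_genes)))))
      starts <- cumsum(gaps) + c(0L, cumsum(gene_len))[seq_len(n_genes)]
      for (g in seq_len(n_genes)) {
        gi <- gi + 1L
        gid <- sprintf("gene%03d", gi)
        gs <- as.integer(starts[g]); ge <- gs + gene_len[g] - 1L
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(3:4, 1L)
        ex_len <- sample(250:500, n_ex, replace = TRUE)
        intron_tot <- gene_len[g] - sum(ex_len)
        intron_len <- 100L + floor((intron_tot - 100L * (n_ex - 1L)) *
                                     diff(c(0, sort(stats::runif(n_ex - 2L)), 1)))
        ex_start <- gs + cumsum(c(0L, ex_len[-n_ex] + intron_len))
        ex_end <- ex_start + ex_len - 1L
        ex_end[n_ex] <- ge
        ex_len[n_ex] <- ex_end[n_ex] - ex_start[n_ex] + 1L
        tss <- if (strand == "+") gs else ge
        genes[[gid]] <- data.frame(gene_id = gid, chrom = cn, strand = strand,
                                   start = gs, end = ge, tss = tss,
                                   stringsAsFactors = FALSE)
        exons[[gid]] <- data.frame(gene_id = gid, chrom = cn,
                                   start = ex_start, end = ex_end,
                                   stringsAsFactors = FALSE)
        # internal exon boundaries are splice sites
        sp <- sort(c(ex_end[-n_ex], ex_start[-1L]))
        splice[[gid]] <- data.frame(chrom = cn, pos = sp, stringsAsFactors = FALSE)
        # UTRs at transcript ends; CDS is the remaining exonic sequence
        u5_len <- 100L; u3_len <- 200L
        if (strand == "+") {
          u5 <- c(gs, gs + u5_len - 1L)
          u3 <- c(ex_end[n_ex] - u3_len + 1L, ex_end[n_ex])
        } else {
          u5 <- c(ex_end[n_ex] - u5_len + 1L, ex_end[n_ex])
          u3 <- c(gs, gs + u3_len - 1L)
        }
        utr5[[gid]] <- data.frame(gene_id = gid, chrom = cn, start = u5[1],
                                  end = u5[2], stringsAsFactors = FALSE)
        utr3[[gid]] <- data.frame(gene_id = gid, chrom = cn, start = u3[1],
                                  end = u3[2], stringsAsFactors = FALSE)
        cds_df <- data.frame(gene_id = gid, chrom = cn,
                             start = ex_start, end = ex_end,
                             stringsAsFactors = FALSE)
        # clip UTR spans out of the CDS intervals
        for (u in list(u5, u3)) {
          keep <- cds_df$end >= u[1] & cds_df$start <= u[2]
          for (i in which(keep)) {
            if (cds_df$start[i] >= u[1] && cds_df$end[i] <= u[2]) {
              cds_df$start[i] <- NA_integer_
            } else if (cds_df$start[i] >= u[1]) {
              cds_df$start[i] <- u[2] + 1L
            } else if (cds_df$end[i] <= u[2]) {
              cds_df$end[i] <- u[1] - 1L
            }
          }
        }
        cds_df <- cds_df[!is.na(cds_df$start) & cds_df$start <= cds_df$end, ,
                         drop = FALSE]
        cds[[gid]] <- cds_df
      }

      gene_df <- do.call(rbind, genes[names(genes) %in% sprintf("gene%03d", (gi - n_genes + 1L):gi)])

      # --- repeat intervals inside gene introns and intergenic space
      place_intervals <- function(total_len, unit_len, avoid) {
        out <- empty_intervals()
        placed <- 0L; tries <- 0L
        while (placed < total_len && tries < 10000L) {
          tries <- tries + 1L
          w <- as.integer(round(unit_len * stats::runif(1, 0.8, 1.2)))
          s <- sample.int(L - w, 1L)
          e <- s + w - 1L
          block <- rbind(avoid, out)
          clash <- nrow(block) > 0L &&
            any(block$chrom == cn & block$start <= e & block$end >= s)
          if (!clash) {
            out <- rbind(out, data.frame(chrom = cn, start = s, end = e,
                                         stringsAsFactors = FALSE))
            placed <- placed + w
          }
        }
        out
      }
      exon_df <- do.call(rbind, exons[gene_df$gene_id])
      alu_c <- place_intervals(as.integer(repeat_density * L), 300L, exon_df[, c("chrom", "start", "end")])
      if (nrow(alu_c) > 0L) {
        # strand follows the containing gene, else random
        alu_c$strand <- vapply(seq_len(nrow(alu_c)), function(i) {
          hit <- gene_df$start <= alu_c$start[i] & gene_df$end >= alu_c$end[i]
          if (any(hit)) gene_df$strand[which(hit)[1]] else sample(c("+", "-"), 1L)
        }, character(1))
        # rewrite to be A-rich on the annotated strand, runs capped at 4
        for (i in seq_len(nrow(alu_c))) {
          w <- alu_c$end[i] - alu_c$start[i] + 1L
          rich <- if (alu_c$strand[i] == "+") c(A = 0.45, C = 0.2, G = 0.15, T = 0.2) else
            c(A = 0.2, C = 0.15, G = 0.2, T = 0.45)
          s <- character(w); run <- 0L; last <- ""
          draw <- sample(names(rich), w, replace = TRUE, prob = rich)
          for (j in seq_len(w)) {
            b <- draw[j]
            if (b == last && run >= 4L) {
              b <- sample(setdiff(c("A", "C", "G", "T"), last), 1L)
            }
            run <- if (b == last) run + 1L else 1L
            last <- b; s[j] <- b
          }
          seq_v[alu_c$start[i]:alu_c$end[i]] <- s
        }
      } else alu_c$strand <- character(0)
      l1_c <- place_intervals(as.integer(l1_density * L), 800L,
                              rbind(exon_df[, c("chrom", "start", "end")],
                                    alu_c[, c("chrom", "start", "end")]))
      black_c <- place_intervals(as.integer(blacklist_density * L), 400L,
                                 rbind(exon_df[, c("chrom", "start", "end")],
                                       alu_c[, c("chrom", "start", "end")]))

      # --- homopolymer intervals: scan the final sequence for runs
      r <- rle(seq_v)
      ends <- cumsum(r$lengths)
      keep <- r$lengths >= homopolymer_min
      hp_c <- data.frame(chrom = rep(cn, sum(keep)),
                         start = (ends - r$lengths + 1L)[keep],
                         end = ends[keep], stringsAsFactors = FALSE)

      # --- SNPs with MAFs straddling the 0.05 filter boundary
      n_snp <- stats::rpois(1L, snp_rate * L)
      sp <- sort(sample.int(L, min(n_snp, L)))
      snp_c <- data.frame(chrom = rep(cn, length(sp)), pos = sp,
                          maf = stats::runif(length(sp), 0.01, 0.5),
                          stringsAsFactors = FALSE)

      chroms[[cn]] <- paste(seq_v, collapse = "")
      alu[[cn]] <- alu_c; l1[[cn]] <- l1_c; black[[cn]] <- black_c
      snps[[cn]] <- snp_c
      hp_all[[cn]] <- hp_c
    }

    bundle <- structure(list(
      chromosomes = unlist(chroms),
      genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
      exons = do.call(rbind, c(exons, list(make.row.names = FALSE))),
      cds = do.call(rbind, c(cds, list(make.row.names = FALSE))),
      utr5 = do.call(rbind, c(utr5, list(make.row.names = FALSE))),
      utr3 = do.call(rbind, c(utr3, list(make.row.names = FALSE))),
      splice_sites = do.call(rbind, c(splice, list(make.row.names = FALSE))),
      alu_intervals = do.call(rbind, c(alu, list(make.row.names = FALSE))),
      l1_intervals = do.call(rbind, c(l1, list(make.row.names = FALSE))),
      blacklist_intervals = do.call(rbind, c(black, list(make.row.names = FALSE))),
      homopolymer_intervals = do.call(rbind, c(hp_all, list(make.row.names = FALSE))),
      snps = do.call(rbind, c(snps, list(make.row.names = FALSE)))
    ), class = "GenomeBundle", seed = as.integer(seed))
    rownames(bundle$genes) <- NULL
    bundle
  })
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf("GenomeBundle: %d chromosome(s), %s bp total\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  cat(sprintf("  genes: %d | Alu: %d | L1: %d | blacklist: %d | homopolymer: %d | SNPs: %d\n",
              nrow(x$genes), nrow(x$alu_intervals), nrow(x$l1_intervals),
              nrow(x$blacklist_intervals), nrow(x$homopolymer_intervals),
              nrow(x$snps)))
  invisible(x)
}

# reference base at 1-based positions
genome_base <- function(genome, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    substr(genome$chromosomes[[chrom[i]]], pos[i], pos[i])
  }, character(1))
}

#' Adenosine positions within Alu intervals
#'
#' All positions inside Alu intervals whose reference base is the adenosine
#' of the interval's annotated strand (A on '+', T on '-'). These are the
#' positions over which the Alu editing index is defined; they also serve
#' as background positions for [simulate_pileups()].
#'
#' @param genome a `GenomeBundle`.
#' @return data.frame: chrom, pos, strand.
#' @export
alu_adenosine_positions <- function(genome) {
  ivl <- genome$alu_intervals
  if (is.null(ivl) || nrow(ivl) == 0L) return(
    data.frame(chrom = character(), pos = integer(), strand = character(),
               stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(ivl)), function(i) {
    s <- substr(genome$chromosomes[[ivl$chrom[i]]], ivl$start[i], ivl$end[i])
    want <- if (ivl$strand[i] == "+") "A" else "T"
    rel <- which(strsplit(s, "")[[1]] == want)
    if (length(rel) == 0L) return(NULL)
    data.frame(chrom = ivl$chrom[i], pos = ivl$start[i] + rel - 1L,
               strand = ivl$strand[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
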