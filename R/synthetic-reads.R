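#' Simulate hyper-edited and background reads
#'
#' Hyper-edited reads are drawn from non-overlapping genomic windows; each
#' adenosine on the read's transcript strand is converted to guanosine with
#' probability `edit_fraction`, emulating dense A-to-G hyper-editing that
#' defeats ordinary alignment. Background reads carry only error-level
#' miscalls. Ground-truth cluster intervals (the span of the edited
#' adenosines of each hyper-edited read, on the reference) are recorded for
#' recovery testing.
#'
#' @param genome a `GenomeBundle`.
#' @param n_reads number of hyper-edited reads.
#' @param read_length read length (>= 50).
#' @param edit_fraction per-adenosine editing probability within a
#'   hyper-edited read (default 0.6).
#' @param n_background number of unedited background reads.
#' @param error_rate uniform miscall probability applied to every read.
#' @param motif plant the editing sequence context (G depleted at -1,
#'   enriched at +1 around edited adenosines)? Applied by rewriting the read
#'   base following each edited position to G with probability 0.6 and the
#'   preceding base away from G; the genome is untouched so the planted
#'   context shows up as additional mismatches.
#' @param seed integer seed.
#' @return list with `reads` (read_id, seq, hyper flag and, for truth
#'   bookkeeping, true_chrom/true_start/strand), `clusters` (ground-truth
#'   chrom, start, end, strand, n_sites) and `sites` (chrom, pos, strand).
#' @export
simulate_hyperedited_reads <- function(genome, n_reads = 60L,
                                       read_length = 100L,
                                       edit_fraction = 0.6,
                                       n_background = 60L,
                                       error_rate = 0.001,
                                       motif = FALSE,
                                       seed = 1L) {
  stop_if_not(read_length >= 50L, "read length must be >= 50")
  if (n_reads > 0L && edit_fraction <= 0)
    stop("contradictory config: hyper-edited reads requested with zero cluster density",
         call. = FALSE)
  with_local_seed(seed, {
    chroms <- names(genome$chromosomes)
    lens <- nchar(genome$chromosomes)

    # non-overlapping windows for hyper reads so truth clusters stay distinct
    win <- empty_intervals()
    tries <- 0L
    while (nrow(win) < n_reads && tries < 50L * max(n_reads, 1L)) {
      tries <- tries + 1L
      cc <- sample(chroms, 1L)
      s <- sample.int(lens[[cc]] - read_length + 1L, 1L)
      e <- s + read_length - 1L
      clash <- nrow(win) > 0L &&
        any(win$chrom == cc & win$start <= e + read_length & win$end >= s - read_length)
      if (!clash) win <- rbind(win, data.frame(chrom = cc, start = s, end = e,
                                               stringsAsFactors = FALSE))
    }
    stop_if_not(nrow(win) == n_reads,
                "could not place %d non-overlapping read windows", n_reads)

    reads <- list(); clusters <- list(); sites <- list()
    make_read <- function(cc, s, strand, hyper, id) {
      ref <- substr(genome$chromosomes[[cc]], s, s + read_length - 1L)
      rd <- if (strand == "+") ref else revcomp(ref)
      v <- strsplit(rd, "")[[1]]
      edited_rel <- integer(0)
      if (hyper) {
        a_idx <- which(v == "A")
        edited_rel <- a_idx[stats::runif(length(a_idx)) < edit_fraction]
        v[edited_rel] <- "G"
        if (motif && length(edited_rel) > 0L) {
          after <- edited_rel + 1L; after <- after[after <= read_length]
          sel <- after[stats::runif(length(after)) < 0.6]
          v[setdiff(sel, edited_rel)] <- "G"
          before <- edited_rel - 1L; before <- before[before >= 1L]
          gg <- before[v[before] == "G"]
          v[setdiff(gg, edited_rel)] <- sample(c("C", "T"), length(setdiff(gg, edited_rel)),
                                               replace = TRUE)
        }
      }
      miss <- which(stats::runif(read_length) < error_rate)
      for (j in miss) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1L)
      # genome coordinates of the edited adenosines
      gpos <- if (strand == "+") s + edited_rel - 1L else s + read_length - edited_rel
      list(read = data.frame(read_id = id, seq = paste(v, collapse = ""),
                             hyper = hyper, true_chrom = cc, true_start = s,
                             strand = strand, stringsAsFactors = FALSE),
           gpos = sort(gpos))
    }

    rid <- 0L
    for (i in seq_len(n_reads)) {
      rid <- rid + 1L
      strand <- sample(c("+", "-"), 1L)
      r <- make_read(win$chrom[i], win$start[i], strand, TRUE,
                     sprintf("hyper%04d", rid))
      reads[[length(reads) + 1L]] <- r$read
      if (length(r$gpos) > 0L) {
        clusters[[length(clusters) + 1L]] <- data.frame(
          chrom = win$chrom[i], start = min(r$gpos), end = max(r$gpos),
          strand = strand, n_sites = length(r$gpos), stringsAsFactors = FALSE)
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = win$chrom[i], pos = r$gpos, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(n_background)) {
      rid <- rid + 1L
      cc <- sample(chroms, 1L)
      s <- sample.int(lens[[cc]] - read_length + 1L, 1L)
      r <- make_read(cc, s, sample(c("+", "-"), 1L), FALSE,
                     sprintf("bg%04d", rid))
      reads[[length(reads) + 1L]] <- r$read
    }
    structure(list(reads = do.call(rbind, reads),
                   clusters = if (length(clusters)) do.call(rbind, clusters) else
                     data.frame(chrom = character(), start = integer(),
                                end = integer(), strand = character(),
                                n_sites = integer(), stringsAsFactors = FALSE),
                   sites = if (length(sites)) do.call(rbind, sites) else NULL),
              seed = as.integer(seed), read_length = as.integer(read_length))
  })
}
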