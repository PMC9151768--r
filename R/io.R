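# File interchange: FASTA via Biostrings, BED with 0-based half-open
# conversion at the boundary, everything else as TSV.

#' Write and read genome sequences as FASTA
#'
#' @param genome a `GenomeBundle` (or any named character vector of
#'   sequences).
#' @param path output file.
#' @return `write_genome_fasta` returns the path invisibly;
#'   `read_genome_fasta` returns a named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "GenomeBundle")) genome$chromosomes else genome
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write and read interval tables as BED
#'
#' Internal intervals are 1-based closed; BED files are 0-based half-open.
#' Conversion happens here and only here.
#'
#' @param intervals data.frame with chrom, start, end (extra columns kept
#'   as BED name/score/strand when present).
#' @param path file path.
#' @return `read_bed` returns a 1-based closed interval data.frame.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$chrom,
                   start = intervals$start - 1L,
                   end = intervals$end,
                   stringsAsFactors = FALSE)
  if (!is.null(intervals$name)) df$name <- intervals$name
  if (!is.null(intervals$strand)) {
    if (is.null(df$name)) df$name <- "."
    df$score <- 0L
    df$strand <- intervals$strand
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  if (ncol(df) >= 6L) names(df)[6] <- "strand"
  df$start <- df$start + 1L
  df
}

#' Write and read pileup tables as TSV
#'
#' Columns: chrom, pos (1-based), strand, ref, A, C, G, T, coverage.
#'
#' @param pileup pileup data.frame or a `SimulatedSample`.
#' @param path file path.
#' @return `read_pileup_tsv` returns the pileup data.frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  if (inherits(pileup, "SimulatedSample")) pileup <- pileup$pileup
  utils::write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write annotated sites as a VCF-like table
#'
#' CHROM POS ID REF ALT QUAL FILTER INFO with region / repeat / catalog
#' keys in INFO; a convenience text surface for downstream tools, not a
#' validated VCF.
#'
#' @param sites annotated site table (from [annotate_sites()]).
#' @param path file path.
#' @export
write_sites_vcf <- function(sites, path) {
  info <- sprintf("STRAND=%s;REGION=%s;REPEAT=%s;CATALOG=%s",
                  sites$strand,
                  sites$region %||% ".", sites$repeat_class %||% ".",
                  sites$catalog_status %||% ".")
  ref <- ifelse(sites$strand == "+", "A", "T")
  alt <- ifelse(sites$strand == "+", "G", "C")
  df <- data.frame(CHROM = sites$chrom, POS = sites$pos,
                   ID = sites$site_id, REF = ref, ALT = alt,
                   QUAL = ".", FILTER = "PASS", INFO = info,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2-like", con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read genotype dosage tables as TSV
#'
#' Columns: snp_id, chrom, pos, maf, then one dosage column per donor.
#'
#' @param genotypes a `GenotypeMatrix`.
#' @param path file path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$snps, as.data.frame(genotypes$dosage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "maf")
  dosage <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(dosage) <- df$snp_id
  structure(list(snps = df[meta_cols], dosage = dosage),
            class = "GenotypeMatrix")
}

#' Write a truth table as TSV
#' @param truth a `TruthTable`.
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
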