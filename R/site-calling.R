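#' De novo calling of candidate editing sites from pileups
#'
#' Scans every pileup position across samples for mismatches. A position
#' becomes a candidate when at least one sample reaches the per-sample
#' thresholds (coverage >= `min_coverage`, alternate reads >= `min_edited`,
#' mismatch ratio >= `min_ratio`). Candidates are typed by transcript-strand
#' substitution (12 types); positions with two or more alternate alleles
#' each supported by >= 3 reads and >= 1% of pooled coverage are flagged
#' multi-allelic. C-to-T and G-to-A candidates are retained but tagged
#' provisional.
#'
#' @param samples list of samples with `pileup` tables.
#' @param genome optional `GenomeBundle` for position validation.
#' @param min_coverage,min_edited,min_ratio per-sample candidate thresholds.
#' @return a `SiteMatrix` whose `sites` carry ref/alt (reference strand),
#'   `type` (transcript strand, e.g. "A>G"), `multi_allelic` and
#'   `provisional` columns, plus a `detected` logical matrix recording which
#'   samples meet all thresholds.
#' @export
call_denovo <- function(samples, genome = NULL, min_coverage = 10L,
                        min_edited = 3L, min_ratio = 0.05) {
  bases <- c("A", "C", "G", "T")
  # union of positions, pooled counts
  pools <- list(); per_sample <- list()
  for (k in seq_along(samples)) {
    pu <- samples[[k]]$pileup
    pu$key <- site_key(pu$chrom, pu$pos)
    per_sample[[k]] <- pu
  }
  all_pos <- unique(do.call(rbind, lapply(per_sample, function(p)
    p[, c("chrom", "pos", "strand", "ref", "key")])))
  all_pos <- all_pos[order(all_pos$chrom, all_pos$pos), , drop = FALSE]
  rownames(all_pos) <- NULL
  n <- nrow(all_pos)
  pooled <- matrix(0L, n, 4, dimnames = list(NULL, bases))
  m <- length(samples)
  cov <- ed <- matrix(0, n, m)
  for (k in seq_len(m)) {
    pu <- per_sample[[k]]
    idx <- match(all_pos$key, pu$key)
    got <- !is.na(idx)
    cnt <- as.matrix(pu[idx[got], bases])
    pooled[got, ] <- pooled[got, ] + cnt
    cov[got, k] <- pu$coverage[idx[got]]
  }
  pooled_cov <- rowSums(pooled)
  ref <- all_pos$ref
  ref_i <- match(ref, bases)
  altcnt <- pooled
  altcnt[cbind(seq_len(n), ref_i)] <- -1L
  alt_i <- max.col(altcnt, ties.method = "first")
  alt <- bases[alt_i]
  # multi-allelic: >= 2 non-reference alleles with >= 3 reads and >= 1% of
  # pooled coverage (robust to singleton sequencing errors)
  nonref_ok <- pooled >= 3L & pooled >= 0.01 * pooled_cov
  nonref_ok[cbind(seq_len(n), ref_i)] <- FALSE
  multi <- rowSums(nonref_ok) >= 2L

  # per-sample alt counts and detection
  detected <- matrix(FALSE, n, m)
  for (k in seq_len(m)) {
    pu <- per_sample[[k]]
    idx <- match(all_pos$key, pu$key)
    got <- !is.na(idx)
    ac <- as.matrix(pu[idx[got], bases])[cbind(seq_len(sum(got)), alt_i[got])]
    ed[got, k] <- ac
    detected[got, k] <- cov[got, k] >= min_coverage & ac >= min_edited &
      ifelse(cov[got, k] > 0, ac / cov[got, k], 0) >= min_ratio
  }
  keep <- rowSums(detected) > 0L & alt != ref
  tref <- ifelse(all_pos$strand == "+", ref, comp_base(ref))
  talt <- ifelse(all_pos$strand == "+", alt, comp_base(alt))
  sites <- data.frame(
    site_id = site_key(all_pos$chrom, all_pos$pos, all_pos$strand),
    chrom = all_pos$chrom, pos = all_pos$pos, strand = all_pos$strand,
    ref = ref, alt = alt, type = paste0(tref, ">", talt),
    multi_allelic = multi,
    provisional = paste0(tref, ">", talt) %in% c("C>T", "G>A"),
    stringsAsFactors = FALSE)
  meta <- sample_metadata(samples)
  level <- ifelse(cov > 0, ed / cov, NA_real_)
  level[!detected] <- NA_real_
  dimnames(level) <- dimnames(cov) <- dimnames(ed) <-
    list(sites$site_id, meta$sample_id)
  out <- new_site_matrix(sites[keep, , drop = FALSE],
                         level[keep, , drop = FALSE],
                         cov[keep, , drop = FALSE],
                         ed[keep, , drop = FALSE], meta)
  out$detected <- detected[keep, , drop = FALSE]
  dimnames(out$detected) <- list(out$sites$site_id, meta$sample_id)
  out
}

detection_matrix <- function(sm, min_coverage = 10L, min_edited = 3L,
                             min_ratio = 0.05) {
  if (!is.null(sm$detected)) return(sm$detected)
  ratio <- ifelse(sm$coverage > 0, sm$edited / sm$coverage, 0)
  sm$coverage >= min_coverage & sm$edited >= min_edited & ratio >= min_ratio
}

#' Apply the editing-site quality filter cascade
#'
#' Applies, in order: (1) drop multi-allelic candidates; (2) require the
#' per-sample coverage / edited-read / ratio thresholds in at least one
#' sample; (3) drop sites overlapping blacklist or homopolymer intervals;
#' (4) drop sites at SNPs with minor allele frequency above `maf_max`;
#' (5) drop sites within `splice_dist` bp of an annotated splice site;
#' (6) keep sites detected in at least `k` of the n samples of some cell
#' type. A site removed by rule j is never re-counted by a later rule.
#'
#' @param cand a `SiteMatrix` from [call_denovo()] or [quantify_supervised()].
#' @param genome a `GenomeBundle` supplying the annotation layers.
#' @param k minimum number of detecting samples within a cell type.
#' @param min_coverage,min_edited,min_ratio per-sample detection thresholds
#'   (used if `cand` lacks a detection matrix).
#' @param maf_max SNP minor allele frequency above which a position is
#'   treated as a genomic variant.
#' @param splice_dist exclusion distance around splice sites (bp).
#' @return list with `matrix` (retained `SiteMatrix`; its `sites` gain a
#'   `detected_in` column of comma-separated cell types passing rule 6) and
#'   `report` (a `FilterReport` data.frame: rule, removed, plus attributes
#'   `input` and `retained`).
#' @export
apply_filter_cascade <- function(cand, genome, k = 8L, min_coverage = 10L,
                                 min_edited = 3L, min_ratio = 0.05,
                                 maf_max = 0.05, splice_dist = 5L) {
  ct <- cand$samples$cell_type
  for (cc in unique(ct)) {
    stop_if_not(k <= sum(ct == cc),
                "detection rule k=%d exceeds group size %d of cell type '%s'",
                k, sum(ct == cc), cc)
  }
  det <- detection_matrix(cand, min_coverage, min_edited, min_ratio)
  sites <- cand$sites
  n_in <- nrow(sites)
  alive <- rep(TRUE, n_in)
  removed <- integer(0)

  mark <- function(alive, fail, rule) {
    fail <- fail & alive
    removed[[rule]] <<- sum(fail)
    alive & !fail
  }
  alive <- mark(alive, isTRUE_vec(sites$multi_allelic, n_in), "multi-allelic")
  alive <- mark(alive, rowSums(det) == 0L, "thresholds")
  alive <- mark(alive,
                in_intervals(sites$chrom, sites$pos, genome$blacklist_intervals) |
                  in_intervals(sites$chrom, sites$pos, genome$homopolymer_intervals),
                "blacklist/homopolymer")
  snps <- genome$snps[genome$snps$maf > maf_max, , drop = FALSE]
  alive <- mark(alive,
                site_key(sites$chrom, sites$pos) %in% site_key(snps$chrom, snps$pos),
                "snp")
  alive <- mark(alive,
                dist_to_nearest_pos(sites$chrom, sites$pos,
                                    genome$splice_sites) <= splice_dist,
                "splice-adjacent")
  # rule 6: >= k detecting samples in at least one cell type
  cts <- unique(ct)
  det_by_ct <- vapply(cts, function(cc)
    rowSums(det[, ct == cc, drop = FALSE]) >= k, logical(n_in))
  if (n_in == 1L) det_by_ct <- matrix(det_by_ct, nrow = 1L,
                                      dimnames = list(NULL, cts))
  alive <- mark(alive, rowSums(det_by_ct) == 0L, "detection-rate")

  report <- data.frame(rule = names(removed), removed = unname(removed),
                       stringsAsFactors = FALSE)
  attr(report, "input") <- n_in
  attr(report, "retained") <- sum(alive)
  class(report) <- c("FilterReport", "data.frame")

  out <- cand[alive, ]
  if (any(alive)) {
    out$detected <- det[alive, , drop = FALSE]
    out$sites$detected_in <- apply(det_by_ct[alive, , drop = FALSE], 1L,
                                   function(z) paste(cts[z], collapse = ","))
  } else {
    out$detected <- det[alive, , drop = FALSE]
    out$sites$detected_in <- character(0)
  }
  list(matrix = out, report = report)
}

isTRUE_vec <- function(x, n) if (is.null(x)) rep(FALSE, n) else as.logical(x)

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d candidates -> %d retained\n",
              attr(x, "input"), attr(x, "retained")))
  print.data.frame(x)
  invisible(x)
}

#' Re-query sites unique to one cell type in the remaining cell types
#'
#' For sites detected in exactly one cell type, pools the reads of each
#' other cell type and labels it `covered-unedited` (coverage >= 10 with
#' fewer than 3 edited reads: the cell type truly does not edit the site) or
#' `insufficient-coverage` (the site was simply not measurable there).
#'
#' @param sm a `SiteMatrix` whose `sites` carry a single-cell-type
#'   `detected_in` column.
#' @param samples the full sample list (all cell types).
#' @param min_coverage,min_edited thresholds defining "covered" and "edited".
#' @return data.frame: site_id, cell_type, coverage, edited, label.
#' @export
requery_other_celltypes <- function(sm, samples, min_coverage = 10L,
                                    min_edited = 3L) {
  sites <- sm$sites
  stop_if_not(!is.null(sites$detected_in), "sites need a detected_in column")
  stop_if_not(all(!grepl(",", sites$detected_in)),
              "re-query applies to sites detected in exactly one cell type")
  meta <- sample_metadata(samples)
  out <- list()
  for (cc in unique(meta$cell_type)) {
    idx <- which(meta$cell_type == cc)
    pooled_ed <- pooled_cov <- integer(nrow(sites))
    for (k in idx) {
      cnt <- pileup_site_counts(samples[[k]]$pileup, sites)
      pooled_ed <- pooled_ed + cnt$edited
      pooled_cov <- pooled_cov + cnt$coverage
    }
    rel <- sites$detected_in != cc
    out[[cc]] <- data.frame(
      site_id = sites$site_id[rel], cell_type = cc,
      coverage = pooled_cov[rel], edited = pooled_ed[rel],
      label = ifelse(pooled_cov[rel] >= min_coverage & pooled_ed[rel] < min_edited,
                     "covered-unedited", "insufficient-coverage"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate editing sites with genic region, repeat class and catalog status
#'
#' Genic region is assigned with precedence CDS > 5'UTR > 3'UTR > intron >
#' downstream-TSS > intergenic ("downstream-TSS" = within `tss_window` bp of
#' a TSS but outside any assigned exonic/intronic context). Repeat class is
#' Alu, L1 or none by interval overlap. A site is `known` only on an exact
#' (chrom, pos, strand) catalog match. CDS sites additionally get a recoding
#' flag when the A-to-G change alters the encoded amino acid under the
#' standard genetic code.
#'
#' @param sites data.frame with chrom, pos, strand (site_id optional).
#' @param genome a `GenomeBundle`.
#' @param catalog optional data.frame of known sites (chrom, pos, strand).
#' @param tss_window window around the TSS for the downstream-TSS class.
#' @return the site table with `gene_id`, `region`, `repeat_class`,
#'   `catalog_status` and `recoding` columns added.
#' @export
annotate_sites <- function(sites, genome, catalog = NULL, tss_window = 1000L) {
  if (is.null(sites$site_id))
    sites$site_id <- site_key(sites$chrom, sites$pos, sites$strand)
  n <- nrow(sites)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)

  assign_region <- function(iv, label) {
    hit <- in_intervals(sites$chrom, sites$pos, iv)
    upd <- hit & region == "intergenic"
    region[upd] <<- label
    if (!is.null(iv$gene_id)) {
      for (i in which(upd & is.na(gene_id))) {
        g <- iv$gene_id[iv$chrom == sites$chrom[i] &
                          iv$start <= sites$pos[i] & iv$end >= sites$pos[i]]
        if (length(g)) gene_id[i] <<- g[1]
      }
    }
  }
  assign_region(genome$cds, "CDS")
  assign_region(genome$utr5, "5'UTR")
  assign_region(genome$utr3, "3'UTR")
  # intron: inside a gene body but no exonic assignment yet
  g <- genome$genes
  in_gene <- in_intervals(sites$chrom, sites$pos, g)
  upd <- in_gene & region == "intergenic"
  region[upd] <- "intron"
  for (i in which(upd & is.na(gene_id))) {
    gg <- g$gene_id[g$chrom == sites$chrom[i] & g$start <= sites$pos[i] &
                      g$end >= sites$pos[i]]
    if (length(gg)) gene_id[i] <- gg[1]
  }
  near_tss <- dist_to_nearest_pos(sites$chrom, sites$pos,
                                  data.frame(chrom = g$chrom, pos = g$tss)) <= tss_window
  region[near_tss & region == "intergenic"] <- "downstream-TSS"

  repeat_class <- rep("none", n)
  repeat_class[in_intervals(sites$chrom, sites$pos, genome$l1_intervals)] <- "L1"
  repeat_class[in_intervals(sites$chrom, sites$pos, genome$alu_intervals)] <- "Alu"

  status <- rep("not-in-catalog", n)
  if (!is.null(catalog) && nrow(catalog) > 0L) {
    status[site_key(sites$chrom, sites$pos, sites$strand) %in%
             site_key(catalog$chrom, catalog$pos, catalog$strand)] <- "known"
  }

  recoding <- rep(FALSE, n)
  for (i in which(region == "CDS")) {
    recoding[i] <- is_recoding(genome, gene_id[i], sites$chrom[i],
                               sites$pos[i], sites$strand[i])
  }

  sites$gene_id <- gene_id
  sites$region <- region
  sites$repeat_class <- repeat_class
  sites$catalog_status <- status
  sites$recoding <- recoding
  sites
}

# does the A>G edit change the encoded amino acid?
#' @importFrom Biostrings GENETIC_CODE
is_recoding <- function(genome, gid, chrom, pos, strand) {
  if (is.na(gid)) return(FALSE)
  cds <- genome$cds[genome$cds$gene_id == gid, , drop = FALSE]
  if (nrow(cds) == 0L) return(FALSE)
  cds <- cds[order(cds$start), , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
  seq_txt <- paste(vapply(seq_len(nrow(cds)), function(i)
    substr(genome$chromosomes[[chrom]], cds$start[i], cds$end[i]),
    character(1)), collapse = "")
  if (strand == "-") {
    seq_txt <- revcomp(seq_txt)
    gpos <- rev(gpos)
  }
  idx <- match(pos, gpos)
  if (is.na(idx)) return(FALSE)
  cod0 <- ((idx - 1L) %/% 3L) * 3L + 1L
  if (cod0 + 2L > nchar(seq_txt)) return(FALSE)
  codon <- substr(seq_txt, cod0, cod0 + 2L)
  within <- idx - cod0 + 1L
  edited <- codon
  substr(edited, within, within) <- "G"
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[codon])
  aa_alt <- unname(gc[edited])
  !is.na(aa_ref) && !is.na(aa_alt) && aa_ref != aa_alt
}
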