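# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @importFrom withr with_seed
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# interval data.frames carry chrom/start/end (1-based, closed)
empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' @importFrom IRanges IRanges findOverlaps countOverlaps reduce start end width
in_intervals <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  hit <- logical(length(pos))
  if (is.null(intervals) || nrow(intervals) == 0L) return(hit)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    ivl <- intervals[intervals$chrom == cc, , drop = FALSE]
    if (nrow(ivl) == 0L) next
    q <- IRanges::IRanges(start = pos[idx], width = 1L)
    s <- IRanges::IRanges(start = ivl$start, end = ivl$end)
    hit[idx] <- IRanges::countOverlaps(q, s) > 0L
  }
  hit
}

# distance from each position to the nearest entry of `sites` (chrom/pos);
# Inf where the chromosome has no sites
dist_to_nearest_pos <- function(chrom, pos, sites) {
  out <- rep(Inf, length(pos))
  if (is.null(sites) || nrow(sites) == 0L) return(out)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    sp <- sort(sites$pos[sites$chrom == cc])
    if (length(sp) == 0L) next
    i <- findInterval(pos[idx], sp)
    lo <- ifelse(i >= 1L, abs(pos[idx] - sp[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(sp), abs(sp[pmin(i + 1L, length(sp))] - pos[idx]), Inf)
    out[idx] <- pmin(lo, hi)
  }
  out
}

merge_closed_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(r),
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

site_key <- function(chrom, pos, strand = NULL) {
  if (is.null(strand)) paste(chrom, pos, sep = ":")
  else paste(chrom, pos, strand, sep = ":")
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

CELL_TYPES <- c("MGE-GABA", "GLU", "OLIG")
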