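#' Per-base coverage track for one chromosome strand
#'
#' Depth is stored run-length encoded, so whole-chromosome processing is
#' linear in the number of runs.
#'
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param depth numeric/integer vector or `Rle` of per-base depth
#'   (position 1 = chromosome base 1). Negative depth is rejected.
#' @param sample_id optional sample label carried into island records.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, strand, depth, sample_id = NA_character_) {
  if (!methods::is(depth, "Rle")) depth <- S4Vectors::Rle(depth)
  if (length(depth) && min(S4Vectors::runValue(depth)) < 0) {
    stop("coverage depth must be non-negative")
  }
  structure(
    list(chrom = chrom, strand = strand, depth = depth,
         sample_id = sample_id),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s): %d bp, max depth %s\n",
              x$chrom, x$strand, length(x$depth),
              if (length(x$depth)) max(x$depth) else 0))
  invisible(x)
}

#' Build coverage tracks from a stranded bedGraph interval set
#'
#' @param gr GRanges with a `score` column (from [read_bedgraph()]);
#'   intervals may be unstranded, in which case `strand` labels them.
#' @param strand strand label for the resulting tracks.
#' @param seqlengths named vector of chromosome lengths; defaults to the
#'   maximum covered position per chromosome.
#' @param sample_id optional sample label.
#' @return Named list of `coverage_track`, one per chromosome.
#' @export
coverage_from_bedgraph <- function(gr, strand, seqlengths = NULL,
                                   sample_id = NA_character_) {
  chroms <- if (!is.null(seqlengths)) names(seqlengths) else
    unique(as.character(GenomicRanges::seqnames(gr)))
  out <- list()
  for (chrom in chroms) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    len <- if (!is.null(seqlengths)) seqlengths[[chrom]] else
      max(GenomicRanges::end(sub))
    depth <- S4Vectors::Rle(0, len)
    if (length(sub)) {
      ir <- IRanges::IRanges(GenomicRanges::start(sub),
                             pmin(GenomicRanges::end(sub), len))
      depth <- as(IRanges::coverage(ir, width = len, weight = sub$score),
                  "Rle")
    }
    out[[chrom]] <- coverage_track(chrom, strand, depth, sample_id)
  }
  out
}

#' Detect islands of expression
#'
#' An island is a maximal run of positions whose depth is strictly above
#' `depth_threshold`; only islands at least `min_length` bp long (one
#' read length by default) are kept. Islands are pairwise disjoint,
#' sorted, and maximal: the positions flanking each island have depth at
#' or below the threshold.
#'
#' @param track `coverage_track` (typically masked with
#'   [mask_coverage()] first).
#' @param depth_threshold strict depth cutoff (default 2: qualifying
#'   positions have depth > 2).
#' @param min_length minimum island length in bp (default 100).
#' @return GRanges of islands with metadata `mean_depth`, `max_depth`,
#'   `sample_id`.
#' @export
find_islands <- function(track, depth_threshold = 2, min_length = 100L) {
  stopifnot(inherits(track, "coverage_track"),
            depth_threshold > 0, min_length > 0L)
  # linear scan over the run-length encoding
  rl <- S4Vectors::runLength(track$depth)
  rv <- as.numeric(S4Vectors::runValue(track$depth))
  above <- rv > depth_threshold
  if (!any(above)) return(GenomicRanges::GRanges())
  grp <- rle(above)
  run_end <- cumsum(rl)
  run_start <- run_end - rl + 1L
  g_last <- cumsum(grp$lengths)
  g_first <- g_last - grp$lengths + 1L
  sel <- which(grp$values)
  isl_start <- run_start[g_first[sel]]
  isl_end <- run_end[g_last[sel]]
  keep <- (isl_end - isl_start + 1L) >= min_length
  if (!any(keep)) return(GenomicRanges::GRanges())
  sel <- sel[keep]
  isl_start <- isl_start[keep]; isl_end <- isl_end[keep]
  cw <- c(0, cumsum(rl * rv))
  mean_depth <- (cw[g_last[sel] + 1L] - cw[g_first[sel]]) /
    (isl_end - isl_start + 1L)
  max_depth <- vapply(seq_along(sel), function(k) {
    max(rv[g_first[sel[k]]:g_last[sel[k]]])
  }, numeric(1))
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(isl_start, isl_end),
    strand = track$strand
  )
  gr$mean_depth <- mean_depth
  gr$max_depth <- max_depth
  gr$sample_id <- track$sample_id
  gr
}

#' Mean depth of a track over an interval
#'
#' @param track `coverage_track`.
#' @param start,end 1-based inclusive interval bounds within the track.
#' @return Arithmetic mean depth over the interval.
#' @export
island_mean_depth <- function(track, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  if (end < start) stop("empty interval")
  if (start < 1L || end > length(track$depth)) {
    stop("interval outside track")
  }
  mean(as.numeric(S4Vectors::window(track$depth, start, end)))
}

#' Depth vector of a track over an interval
#' @inheritParams island_mean_depth
#' @return Numeric vector of per-base depth.
#' @export
track_depth <- function(track, start, end) {
  as.numeric(S4Vectors::window(track$depth, start, end))
}
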