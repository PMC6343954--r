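#' Build the strand-aware exclusion mask from annotated gene models
#'
#' Each gene contributes its span (or exon union, in `exon_union` mode)
#' extended by `flank` bp on both sides, clipped at position 1; intervals
#' are merged per (chromosome, strand). The mask is strand-specific: with
#' dUTP-stranded coverage, removing transcription against same-strand
#' gene models only is what leaves antisense transcription observable.
#' `span` mode masks annotated intron interiors too and drives the
#' intergenic/antisense discovery pass; `exon_union` mode masks exons
#' only, so a second pass can recover intronic transcription.
#'
#' @param annotation `lnc_annotation` from [read_gtf()].
#' @param flank extension in bp (default 1000).
#' @param mode `"span"` or `"exon_union"`.
#' @return GRanges of merged mask intervals, strand-tagged
#'   (class `strand_mask`).
#' @export
build_mask <- function(annotation, flank = 1000L, mode = c("span", "exon_union")) {
  mode <- match.arg(mode)
  stopifnot(flank >= 0L)
  src <- if (mode == "span") annotation$genes else annotation$exons
  if (length(src) == 0L) {
    m <- GenomicRanges::GRanges()
    class(m) <- c(class(m))
    attr(m, "mask_mode") <- mode
    return(m)
  }
  ext <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(src, IRanges::width(src) + 2L * flank, fix = "center")
  ))
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(ext))
  m <- GenomicRanges::reduce(GenomicRanges::granges(ext))
  attr(m, "mask_mode") <- mode
  m
}

#' Zero coverage depth over masked positions
#'
#' Positions of the track that fall inside a same-strand, same-chromosome
#' mask interval are set to depth 0; all other positions are unchanged.
#' Masking is idempotent.
#'
#' @param track a `coverage_track` (see [coverage_track()]).
#' @param mask GRanges mask from [build_mask()] (or any strand-tagged
#'   GRanges).
#' @return The masked `coverage_track`.
#' @export
mask_coverage <- function(track, mask) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(mask) == 0L) return(track)
  keep <- as.character(GenomicRanges::seqnames(mask)) == track$chrom &
    as.character(GenomicRanges::strand(mask)) %in% c(track$strand, "*")
  mask <- mask[keep]
  if (length(mask) == 0L) return(track)
  n <- length(track$depth)
  s <- pmax(1L, GenomicRanges::start(mask))
  e <- pmin(n, GenomicRanges::end(mask))
  ok <- s <= e
  if (any(ok)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = s[ok], end = e[ok]))
    unmasked <- IRanges::coverage(ir, width = n) == 0L
    track$depth <- track$depth * unmasked
  }
  track
}
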