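#' Read a bedGraph coverage file
#'
#' bedGraph intervals are 0-based half-open on disk; the returned GRanges
#' uses the 1-based inclusive convention, with depth in the `score`
#' metadata column. Import is delegated to rtracklayer.
#'
#' @param path bedGraph file.
#' @return GRanges with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a run-length coverage list as bedGraph
#'
#' Zero-depth runs are omitted, matching the usual sparse bedGraph
#' convention.
#'
#' @param rle_list named `RleList` of per-chromosome depth.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(rle_list, path) {
  gr <- GenomicRanges::bindAsGRanges(score = methods::as(rle_list, "RleList"))
  gr <- gr[gr$score > 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read de-novo splice junctions (STAR SJ.out.tab format)
#'
#' Nine whitespace-separated columns: chromosome, intron start and end
#' (1-based, first and last intron base), strand code (0 undefined, 1 `+`,
#' 2 `-`), splice motif, annotated flag, unique-read support, multi-read
#' support, maximum overhang.
#'
#' @param path junction file.
#' @return GRanges of introns with metadata `unique_reads` (integer),
#'   `multi_reads`, and `annotated` (logical). Undefined strand becomes `*`.
#' @export
read_sj_tab <- function(path) {
  stopifnot(file.exists(path))
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = c(
      "character", rep("integer", 8L))),
    error = function(e) stop("malformed SJ.out.tab file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(df) && ncol(df) != 9L) {
    stop("malformed SJ.out.tab file '", path, "': expected 9 columns, got ",
         ncol(df))
  }
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  strand <- c("*", "+", "-")[df[[4]] + 1L]
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]], end = df[[3]]),
    strand = strand
  )
  gr$unique_reads <- df[[7]]
  gr$multi_reads <- df[[8]]
  gr$annotated <- df[[6]] == 1L
  gr
}

#' Write splice junctions in STAR SJ.out.tab format
#'
#' @param junctions GRanges of introns with `unique_reads` and `annotated`
#'   metadata (as returned by [read_sj_tab()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sj_tab <- function(junctions, path) {
  strand_code <- match(as.character(GenomicRanges::strand(junctions)),
                       c("*", "+", "-")) - 1L
  multi <- if (!is.null(junctions$multi_reads)) junctions$multi_reads else 0L
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(junctions)),
    start = GenomicRanges::start(junctions),
    end = GenomicRanges::end(junctions),
    strand = strand_code,
    motif = 1L,
    annotated = as.integer(isTRUE_vec(junctions$annotated, length(junctions))),
    unique_reads = junctions$unique_reads,
    multi_reads = multi,
    overhang = 30L
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else as.logical(x)
}

#' Read transcription start sites from a BED6 file
#'
#' BED is 0-based half-open on disk; positions come back 1-based. Each
#' record is reduced to its single TSS base (the start of the BED
#' interval on `+`, the end on `-`).
#'
#' @param path BED6 file of TSS tags.
#' @return GRanges of width-1 TSS positions, strand-tagged.
#' @export
read_tss_bed <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "BED")
  pos <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                GenomicRanges::end(gr), GenomicRanges::start(gr))
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(start = pos, width = 1L),
    strand = GenomicRanges::strand(gr)
  )
}

#' Read or write a plain feature-by-sample count matrix
#'
#' Tab-separated, header row of sample ids, first column feature ids.
#'
#' @param path TSV file.
#' @return Numeric matrix with feature rownames.
#' @export
read_counts_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_counts_tsv
#' @param mat numeric matrix (features x samples).
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample, condition, and optional extra columns)
#'
#' @param path TSV with at least `sample` and `condition` columns.
#' @return data.frame.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "condition") %in% names(df)))
  df
}

#' @rdname read_sample_info
#' @param info sample metadata data.frame.
#' @export
write_sample_info <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
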