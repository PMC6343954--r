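#' Build a transcript-candidate set from exon ranges
#'
#' The candidate container pairs an exon-level GRanges (metadata
#' `gene_id`) with a per-candidate summary table. Exons of one candidate
#' must share one chromosome and strand and be pairwise disjoint.
#'
#' @param exons GRanges with a `gene_id` metadata column.
#' @param extra optional data.frame of per-candidate columns keyed by
#'   `gene_id`.
#' @return An object of class `lnc_candidates`: list with `exons`
#'   (GRanges) and `info` (data.frame with one row per candidate:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `n_exons`, `length`).
#' @export
candidates_from_exons <- function(exons, extra = NULL) {
  stopifnot(methods::is(exons, "GRanges"), !is.null(exons$gene_id))
  exons <- BiocGenerics::sort(exons)
  by_gene <- S4Vectors::split(GenomicRanges::granges(exons), exons$gene_id)
  red <- GenomicRanges::reduce(by_gene)
  if (!identical(sum(IRanges::width(red)), sum(IRanges::width(by_gene)))) {
    stop("candidate exons must be pairwise disjoint within a gene")
  }
  spans <- BiocGenerics::unlist(range(by_gene), use.names = FALSE)
  strands <- vapply(as.list(by_gene), function(g) {
    s <- unique(as.character(GenomicRanges::strand(g)))
    if (length(s) != 1L) stop("candidate exons must share one strand")
    s
  }, character(1))
  info <- data.frame(
    gene_id = names(by_gene),
    chrom = as.character(GenomicRanges::seqnames(spans)),
    strand = unname(strands),
    start = GenomicRanges::start(spans),
    end = GenomicRanges::end(spans),
    n_exons = unname(lengths(by_gene)),
    length = unname(sum(IRanges::width(by_gene))),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    info <- merge(info, extra, by = "gene_id", all.x = TRUE, sort = FALSE)
  }
  info <- info[order(info$chrom, info$start, info$end, info$gene_id), ]
  rownames(info) <- NULL
  structure(list(exons = exons, info = info), class = "lnc_candidates")
}

#' @export
print.lnc_candidates <- function(x, ...) {
  cat("lnc_candidates:", nrow(x$info), "candidates,",
      length(x$exons), "exons\n")
  if ("class" %in% names(x$info)) {
    print(table(x$info$class))
  }
  invisible(x)
}

#' Exons of one candidate
#' @param candidates `lnc_candidates` object.
#' @param gene_id candidate identifier.
#' @return Sorted GRanges of the candidate's exons.
#' @export
candidate_exons <- function(candidates, gene_id) {
  BiocGenerics::sort(candidates$exons[candidates$exons$gene_id == gene_id])
}

#' Subset a candidate set
#' @param candidates `lnc_candidates` object.
#' @param gene_ids identifiers to keep.
#' @return `lnc_candidates` restricted to `gene_ids`.
#' @export
subset_candidates <- function(candidates, gene_ids) {
  info <- candidates$info[candidates$info$gene_id %in% gene_ids, ,
                          drop = FALSE]
  rownames(info) <- NULL
  structure(list(
    exons = candidates$exons[candidates$exons$gene_id %in% gene_ids],
    info = info
  ), class = "lnc_candidates")
}
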