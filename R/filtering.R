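#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param count read-pair count (non-negative).
#' @param transcript_length transcript length in bp (positive).
#' @param library_size total counted read pairs of the sample (positive).
#' @return `count * 1e9 / (transcript_length * library_size)`.
#' @export
compute_fpkm <- function(count, transcript_length, library_size) {
  if (any(transcript_length <= 0)) stop("transcript length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count * 1e9 / (as.numeric(transcript_length) * as.numeric(library_size))
}

#' Coverage-based read-pair quantification of candidates
#'
#' Approximates the number of sequenced read pairs supporting each
#' candidate as the summed exonic depth divided by twice the read length
#' (two mates per pair).
#'
#' @param candidates `lnc_candidates`.
#' @param tracks_by_sample nested list: sample -> strand -> chromosome ->
#'   `coverage_track` (unmasked).
#' @param read_length read length in bp.
#' @return Matrix of counts (candidates x samples).
#' @export
quantify_candidates <- function(candidates, tracks_by_sample,
                                read_length = 100L) {
  samples <- names(tracks_by_sample)
  info <- candidates$info
  counts <- matrix(0, nrow = nrow(info), ncol = length(samples),
                   dimnames = list(info$gene_id, samples))
  for (i in seq_len(nrow(info))) {
    ex <- candidate_exons(candidates, info$gene_id[i])
    for (s in samples) {
      track <- tracks_by_sample[[s]][[info$strand[i]]][[info$chrom[i]]]
      if (is.null(track)) next
      tot <- sum(vapply(seq_along(ex), function(k) {
        island_mean_depth(track, GenomicRanges::start(ex)[k],
                          GenomicRanges::end(ex)[k]) *
          IRanges::width(ex)[k]
      }, numeric(1)))
      counts[i, s] <- round(tot / (2 * read_length))
    }
  }
  counts
}

#' Classify candidates by genomic context
#'
#' Priority antisense > intronic > intergenic: a candidate is antisense
#' when at least one exonic bp overlaps an annotated exon on the opposite
#' strand; intronic when its span lies inside an annotated intron (either
#' strand by default) with no opposite-strand exon overlap; intergenic
#' otherwise. A candidate overlapping a same-strand annotated exon (which
#' the mask normally precludes) is left unclassified. The closest gene is
#' the host gene for antisense/intronic candidates (distance 0) and the
#' gene with minimal genomic gap otherwise, ties broken by the
#' lexicographically smaller gene id.
#'
#' @param candidates `lnc_candidates`.
#' @param annotation `lnc_annotation`.
#' @param intronic_same_strand_only restrict intronic containment to
#'   same-strand host genes.
#' @return `candidates` with `class`, `closest_gene_id` and `distance`
#'   columns filled in.
#' @export
classify_context <- function(candidates, annotation,
                             intronic_same_strand_only = FALSE) {
  info <- candidates$info
  n <- nrow(info)
  cls <- character(n); closest <- character(n); dist <- integer(n)
  genes <- annotation$genes
  exons <- annotation$exons
  for (i in seq_len(n)) {
    ex <- candidate_exons(candidates, info$gene_id[i])
    span <- range(GenomicRanges::granges(ex))
    same <- as.character(GenomicRanges::strand(exons)) ==
      info$strand[i]
    same_chr <- as.character(GenomicRanges::seqnames(exons)) ==
      info$chrom[i]
    opp_exons <- exons[!same & same_chr]
    same_exons <- exons[same & same_chr]
    ov_opp <- GenomicRanges::findOverlaps(
      GenomicRanges::granges(ex), GenomicRanges::granges(opp_exons),
      ignore.strand = TRUE)
    ov_same <- IRanges::overlapsAny(
      GenomicRanges::granges(ex), GenomicRanges::granges(same_exons),
      ignore.strand = TRUE)
    if (length(ov_opp)) {
      cls[i] <- "antisense"
      host <- sort(unique(opp_exons$gene_id[S4Vectors::subjectHits(ov_opp)]))
      closest[i] <- host[1]
      dist[i] <- 0L
      next
    }
    if (any(ov_same)) {
      cls[i] <- "unclassified"
      closest[i] <- NA_character_
      dist[i] <- NA_integer_
      next
    }
    host_genes <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                          info$chrom[i]]
    if (intronic_same_strand_only) {
      host_genes <- host_genes[as.character(GenomicRanges::strand(host_genes)) ==
                                 info$strand[i]]
    }
    inside <- which(GenomicRanges::start(host_genes) <= info$start[i] &
                      GenomicRanges::end(host_genes) >= info$end[i])
    if (length(inside)) {
      # contained in a gene body, no exon overlap on either strand checked
      # above for opposite; verify no same-strand-host exon overlap
      host_ids <- sort(host_genes$gene_id[inside])
      cls[i] <- "intronic"
      closest[i] <- host_ids[1]
      dist[i] <- 0L
      next
    }
    cls[i] <- "intergenic"
    gchr <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                    info$chrom[i]]
    if (length(gchr) == 0L) {
      closest[i] <- NA_character_
      dist[i] <- NA_integer_
    } else {
      d <- GenomicRanges::distance(span, GenomicRanges::granges(gchr),
                                   ignore.strand = TRUE)
      dmin <- min(d, na.rm = TRUE)
      cand <- sort(gchr$gene_id[which(d == dmin)])
      closest[i] <- cand[1]
      dist[i] <- as.integer(dmin)
    }
  }
  candidates$info$class <- cls
  candidates$info$closest_gene_id <- closest
  candidates$info$distance <- dist
  candidates
}

#' Spliced transcript sequences of candidates
#'
#' Concatenates the exon sequence in genomic order and reverse-complements
#' for minus-strand candidates.
#'
#' @param candidates `lnc_candidates`.
#' @param genome `DNAStringSet` named by chromosome.
#' @return Named character vector of transcript sequences.
#' @export
candidate_sequences <- function(candidates, genome) {
  info <- candidates$info
  out <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    ex <- candidate_exons(candidates, info$gene_id[i])
    chrom_seq <- genome[[info$chrom[i]]]
    parts <- Biostrings::extractAt(
      chrom_seq,
      IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex))
    )
    seqc <- do.call(Biostrings::xscat, as.list(parts))
    if (info$strand[i] == "-") {
      seqc <- Biostrings::reverseComplement(seqc)
    }
    out[i] <- as.character(seqc)
  }
  names(out) <- info$gene_id
  out
}

#' Apply the length, coding, consistency and expression filters
#'
#' A candidate is kept when (in this order of flagging) its length is at
#' least 200 bp, its coding probability is below the model cutoff, it is
#' present in all replicates of at least one condition, and its mean FPKM
#' strictly exceeds 0.5 in at least one condition. The filters are
#' conjunctive, so the kept set does not depend on their order; each
#' discarded candidate carries the first failing flag.
#'
#' @param candidates `lnc_candidates` with `present_<condition>` columns
#'   (from [merge_samples()]) and a `coding_prob` column.
#' @param counts candidate x sample count matrix.
#' @param library_sizes named vector of per-sample total read pairs.
#' @param sample_info data.frame with `sample` and `condition`.
#' @param params [assembly_params()].
#' @return List with `kept` (`lnc_candidates`), and `report` (data.frame
#'   of all candidates with `filter_flag`, `max_condition_fpkm`, `kept`).
#' @export
apply_filters <- function(candidates, counts, library_sizes, sample_info,
                          params = assembly_params()) {
  info <- candidates$info
  conditions <- unique(sample_info$condition)
  fpkm <- counts * 1e9 /
    outer(info$length[match(rownames(counts), info$gene_id)],
          library_sizes[colnames(counts)])
  cond_mean <- matrix(NA_real_, nrow = nrow(counts),
                      ncol = length(conditions),
                      dimnames = list(rownames(counts), conditions))
  for (cn in conditions) {
    cols <- sample_info$sample[sample_info$condition == cn]
    cond_mean[, cn] <- rowMeans(fpkm[, cols, drop = FALSE])
  }
  max_fpkm <- apply(cond_mean, 1L, max)
  max_fpkm <- max_fpkm[match(info$gene_id, rownames(counts))]

  flag <- rep("", nrow(info))
  ok_len <- info$length >= params$min_transcript_length
  ok_coding <- info$coding_prob < params$coding_cutoff
  pres_cols <- grep("^present_", names(info), value = TRUE)
  ok_pres <- if (length(pres_cols)) {
    apply(as.data.frame(info[, pres_cols, drop = FALSE]), 1L, any)
  } else rep(TRUE, nrow(info))
  ok_fpkm <- !is.na(max_fpkm) & max_fpkm > params$min_fpkm
  flag[!ok_fpkm] <- "min_fpkm"
  flag[!ok_pres] <- "replicate_consistency"
  flag[!ok_coding] <- "coding_potential"
  flag[!ok_len] <- "min_length"
  kept <- ok_len & ok_coding & ok_pres & ok_fpkm
  report <- data.frame(
    gene_id = info$gene_id,
    length = info$length,
    coding_prob = info$coding_prob,
    max_condition_fpkm = max_fpkm,
    filter_flag = flag,
    kept = kept,
    stringsAsFactors = FALSE
  )
  list(kept = subset_candidates(candidates, info$gene_id[kept]),
       report = report)
}
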