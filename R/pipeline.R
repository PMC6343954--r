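#' Run the full novel-lncRNA discovery pipeline on in-memory inputs
#'
#' Stages, in order: build the strand-aware exclusion masks (gene spans
#' plus flank for the intergenic/antisense pass, exon unions for the
#' intronic pass); per sample and strand, mask coverage, detect islands
#' of expression, filter junctions, cluster islands through junctions,
#' derive consensus introns, subtract them from the island hulls and
#' refine boundaries with the smoothed z-score detector; reconcile
#' junction-free islands across samples through the monoexonic
#' intersection/top-decile path; merge per-sample candidates into a
#' non-redundant gene-level set with per-condition presence; classify
#' genomic context and assign closest genes; score coding potential;
#' quantify expression from coverage and apply the length / coding /
#' consistency / FPKM filters.
#'
#' @param annotation `lnc_annotation` of known gene models.
#' @param tracks_by_sample nested list sample -> strand (`+`/`-`) ->
#'   chromosome -> `coverage_track` (raw, unmasked).
#' @param junctions_by_sample list sample -> GRanges of junctions.
#' @param genome `DNAStringSet` named by chromosome.
#' @param coding_model `coding_model` from [train_coding_model()].
#' @param sample_info data.frame with `sample` and `condition`.
#' @param library_sizes named per-sample totals of counted read pairs;
#'   when `NULL`, derived from the coverage-based candidate counts.
#' @param params [assembly_params()].
#' @return List with `candidates` (final `lnc_candidates`, named),
#'   `all_candidates` (pre-filter merged set), `report` (filter report),
#'   `counts` (candidate x sample), `stage_counts` (named counts per
#'   stage).
#' @export
run_lncrna_pipeline <- function(annotation, tracks_by_sample,
                                junctions_by_sample, genome, coding_model,
                                sample_info,
                                library_sizes = NULL,
                                params = assembly_params()) {
  samples <- sample_info$sample
  mask_span <- build_mask(annotation, params$flank_bp, "span")
  mask_exon <- build_mask(annotation, params$flank_bp, "exon_union")
  gene_spans <- annotation$genes

  per_sample_exons <- list()
  singletons <- list()
  mono_tracks <- list()
  n_islands <- 0L; n_clusters <- 0L; n_sample_cands <- 0L

  for (s in samples) {
    jx_raw <- junctions_by_sample[[s]]
    jx_span <- filter_junctions(jx_raw, params, mask = mask_span,
                                novel_only = TRUE)
    jx_exon <- filter_junctions(jx_raw, params, mask = mask_exon,
                                novel_only = TRUE)
    cand_i <- 0L
    for (strand in c("+", "-")) {
      singles <- list()
      masked_tracks <- list()
      for (ch in names(tracks_by_sample[[s]][[strand]])) {
        track <- tracks_by_sample[[s]][[strand]][[ch]]
        m1 <- mask_coverage(track, mask_span)
        masked_tracks[[ch]] <- m1
        isl1 <- find_islands(m1, params$depth_threshold,
                             params$min_island_length)
        n_islands <- n_islands + length(isl1)
        jx_here <- jx_span[
          as.character(GenomicRanges::strand(jx_span)) == strand &
            as.character(GenomicRanges::seqnames(jx_span)) == ch]
        clu1 <- cluster_islands(isl1, jx_here,
                                tol = params$junction_tolerance_bp)
        clusters <- cluster_list(isl1, jx_here, clu1)
        n_clusters <- n_clusters + clu1$n_clusters
        for (cl in clusters) {
          if (length(cl$junctions) == 0L) {
            if (length(cl$islands) == 1L) {
              singles[[length(singles) + 1L]] <- cl$islands
            }
            next
          }
          introns <- consensus_introns(cl$junctions,
                                       params$consensus_fraction,
                                       params$z_min_intron)
          exons <- subtract_introns(cl$islands, introns)
          exons <- refine_exons(exons, m1, params)
          if (length(exons) == 0L) next
          cand_i <- cand_i + 1L
          exons$sample_id <- s
          exons$cand_key <- sprintf("c%04d", cand_i)
          per_sample_exons[[length(per_sample_exons) + 1L]] <- exons
          n_sample_cands <- n_sample_cands + 1L
        }

        # intronic pass: exon-union mask, same-strand gene bodies only
        m2 <- mask_coverage(track, mask_exon)
        isl2 <- find_islands(m2, params$depth_threshold,
                             params$min_island_length)
        if (length(isl2)) {
          spans_here <- gene_spans[
            as.character(GenomicRanges::strand(gene_spans)) == strand &
              as.character(GenomicRanges::seqnames(gene_spans)) == ch]
          isl2 <- isl2[IRanges::overlapsAny(
            GenomicRanges::ranges(isl2), GenomicRanges::ranges(spans_here))]
        }
        if (length(isl2)) {
          jx2 <- jx_exon[
            as.character(GenomicRanges::strand(jx_exon)) == strand &
              as.character(GenomicRanges::seqnames(jx_exon)) == ch]
          clu2 <- cluster_islands(isl2, jx2,
                                  tol = params$junction_tolerance_bp)
          clusters2 <- cluster_list(isl2, jx2, clu2)
          for (cl in clusters2) {
            if (length(cl$junctions) == 0L) next  # needs novel splicing
            introns <- consensus_introns(cl$junctions,
                                         params$consensus_fraction,
                                         params$z_min_intron)
            exons <- subtract_introns(cl$islands, introns)
            exons <- refine_exons(exons, m2, params)
            if (length(exons) == 0L) next
            if (is_retained_intron(exons, annotation,
                                   params$junction_tolerance_bp)) next
            cand_i <- cand_i + 1L
            exons$sample_id <- s
            exons$cand_key <- sprintf("c%04d", cand_i)
            per_sample_exons[[length(per_sample_exons) + 1L]] <- exons
            n_sample_cands <- n_sample_cands + 1L
          }
        }
      }
      sgl <- if (length(singles))
        suppressWarnings(do.call(c, singles)) else GenomicRanges::GRanges()
      singletons[[s]] <- if (is.null(singletons[[s]])) sgl else
        suppressWarnings(c(singletons[[s]], sgl))
      if (is.null(mono_tracks[[s]])) mono_tracks[[s]] <- list()
      mono_tracks[[s]][[strand]] <- masked_tracks
    }
  }

  # monoexonic path across samples; the Pr(>) population pools strands
  n_mono <- 0L
  if (length(samples) >= 2L) {
    res <- monoexonic_candidates(singletons, mono_tracks,
                                 params$monoexonic_pr_cutoff)
    if (length(res$kept)) {
      for (k in seq_along(res$kept)) {
        n_mono <- n_mono + 1L
        reg <- GenomicRanges::granges(res$kept[k])
        for (s in samples) {
          ex <- reg
          ex$sample_id <- s
          ex$cand_key <- sprintf("mono_%03d", k)
          per_sample_exons[[length(per_sample_exons) + 1L]] <- ex
        }
      }
    }
  }

  if (length(per_sample_exons) == 0L) {
    empty <- structure(list(exons = GenomicRanges::GRanges(),
                            info = data.frame(gene_id = character(0))),
                       class = "lnc_candidates")
    return(list(candidates = empty, all_candidates = empty,
                report = data.frame(),
                counts = matrix(0, 0, length(samples)),
                stage_counts = c(islands = n_islands,
                                 clusters = n_clusters,
                                 sample_candidates = n_sample_cands,
                                 monoexonic = n_mono,
                                 merged = 0L, kept = 0L)))
  }

  pooled <- suppressWarnings(do.call(c, per_sample_exons))
  merged <- merge_samples(pooled, sample_info, id_prefix = "LNC")
  merged <- classify_context(merged, annotation)

  seqs <- candidate_sequences(merged, genome)
  merged$info$coding_prob <- coding_probability(seqs, coding_model)

  counts <- quantify_candidates(merged, tracks_by_sample,
                                params$read_length_bp)
  if (is.null(library_sizes)) {
    library_sizes <- pmax(1, colSums(counts))
  }
  flt <- apply_filters(merged, counts, library_sizes, sample_info, params)
  final <- flt$kept
  if (nrow(final$info)) {
    classified <- final$info$class %in% c("antisense", "intergenic",
                                          "intronic")
    final$info$name <- NA_character_
    final$info$name[classified] <- make_name(
      final$info$closest_gene_id[classified],
      final$info$class[classified],
      final$info$chrom[classified],
      final$info$start[classified],
      final$info$end[classified],
      final$info$strand[classified])
  }
  list(candidates = final, all_candidates = merged, report = flt$report,
       counts = counts,
       stage_counts = c(islands = n_islands, clusters = n_clusters,
                        sample_candidates = n_sample_cands,
                        monoexonic = n_mono,
                        merged = nrow(merged$info),
                        kept = nrow(final$info)))
}

# a candidate spanning an entire annotated intron whose both ends sit
# within tol bp of the flanking exon boundaries is a retained intron
is_retained_intron <- function(exons, annotation, tol = 10L) {
  span <- range(GenomicRanges::granges(exons))
  strand <- as.character(GenomicRanges::strand(span))
  ex <- annotation$exons
  sel <- as.character(GenomicRanges::strand(ex)) == strand &
    as.character(GenomicRanges::seqnames(ex)) ==
      as.character(GenomicRanges::seqnames(span))
  ex <- ex[sel]
  if (length(ex) < 2L) return(FALSE)
  introns <- introns_of(local({g <- ex; g$type <- "coding"; g}))
  if (length(introns) == 0L) return(FALSE)
  any(abs(GenomicRanges::start(introns) - GenomicRanges::start(span)) <= tol &
        abs(GenomicRanges::end(introns) - GenomicRanges::end(span)) <= tol)
}

#' Match recovered candidates against planted truth
#'
#' A candidate matches a planted feature when they are on the same strand
#' and their exonic overlap is at least `min_reciprocal` of both exonic
#' lengths. Reports gene-level recall and precision, the class-label
#' agreement among matched pairs, and how many planted coding-like decoys
#' survive into the final set.
#'
#' @param candidates final `lnc_candidates` (with `class` column).
#' @param truth `lnc_candidates` of planted lncRNAs with `class` info.
#' @param decoys optional `lnc_candidates` of planted decoys.
#' @param min_reciprocal reciprocal exonic-overlap fraction.
#' @return List with `recall`, `precision`, `class_agreement`,
#'   `decoy_removal`, `matches` (data.frame).
#' @export
evaluate_recovery <- function(candidates, truth, decoys = NULL,
                              min_reciprocal = 0.5) {
  match_sets <- function(a, b) {
    # exonic-overlap matches between candidate sets a and b
    out <- list()
    for (ga in unique(a$info$gene_id)) {
      exa <- candidate_exons(a, ga)
      wa <- sum(IRanges::width(exa))
      for (gb in unique(b$info$gene_id)) {
        exb <- candidate_exons(b, gb)
        if (as.character(GenomicRanges::strand(exb))[1] !=
            as.character(GenomicRanges::strand(exa))[1]) next
        ov <- sum(IRanges::width(suppressWarnings(GenomicRanges::intersect(
          GenomicRanges::granges(exa), GenomicRanges::granges(exb)))))
        if (ov == 0) next
        wb <- sum(IRanges::width(exb))
        if (ov / wa >= min_reciprocal && ov / wb >= min_reciprocal) {
          out[[length(out) + 1L]] <- data.frame(
            candidate = ga, truth = gb, overlap = ov,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(candidate = character(0), truth = character(0),
                 overlap = numeric(0))
  }
  m <- match_sets(candidates, truth)
  recall <- length(unique(m$truth)) / nrow(truth$info)
  precision <- if (nrow(candidates$info)) {
    length(unique(m$candidate)) / nrow(candidates$info)
  } else NA_real_
  agree <- NA_real_
  if (nrow(m)) {
    cand_class <- candidates$info$class[match(m$candidate,
                                              candidates$info$gene_id)]
    truth_class <- truth$info$class[match(m$truth, truth$info$gene_id)]
    agree <- mean(cand_class == truth_class)
  }
  decoy_removal <- NA_real_
  if (!is.null(decoys) && nrow(decoys$info)) {
    md <- match_sets(candidates, decoys)
    decoy_removal <- 1 - length(unique(md$truth)) / nrow(decoys$info)
  }
  list(recall = recall, precision = precision, class_agreement = agree,
       decoy_removal = decoy_removal, matches = m)
}
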