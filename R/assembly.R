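#' Filter de-novo splice junctions
#'
#' A junction is kept when its unique-read support is strictly above 2
#' (default), its intron length lies strictly between 20 and 100,000 bp,
#' and it does not intersect the same-strand exclusion mask. Annotated
#' junctions can additionally be excluded so only novel splicing remains.
#'
#' @param junctions GRanges of introns from [read_sj_tab()].
#' @param params [assembly_params()].
#' @param mask optional strand-tagged GRanges mask from [build_mask()].
#' @param novel_only drop junctions flagged as annotated.
#' @return The retained junctions.
#' @export
filter_junctions <- function(junctions, params = assembly_params(),
                             mask = NULL, novel_only = FALSE) {
  if (length(junctions) == 0L) return(junctions)
  w <- IRanges::width(junctions)
  keep <- junctions$unique_reads >= params$sj_min_unique_reads &
    w >= params$sj_min_length & w <= params$sj_max_length
  if (novel_only && !is.null(junctions$annotated)) {
    keep <- keep & !junctions$annotated
  }
  out <- junctions[keep]
  if (!is.null(mask) && length(mask) && length(out)) {
    hit <- IRanges::overlapsAny(out, mask)
    out <- out[!hit]
  }
  out
}

# islands whose edge lies within tol bp of a genomic point, same chromosome
attach_islands <- function(point, chrom_j, st, en, chrom_i, tol) {
  which(chrom_i == chrom_j & st - tol <= point & en + tol >= point)
}

# path-compressed union-find over n nodes
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Cluster islands of expression through splice junctions
#'
#' Islands are nodes; a junction whose donor end falls within (or abuts,
#' within a small tolerance) one island and whose acceptor end falls in
#' another joins the two with an edge, and co-overlapping islands (e.g.
#' across samples) share an edge. Clusters are the connected components
#' of this graph; unconnected islands form singleton clusters.
#'
#' @param islands GRanges of islands (one strand; disjoint within each
#'   sample).
#' @param junctions GRanges of filtered junctions.
#' @param tol attachment tolerance in bp for junction ends overshooting
#'   island edges.
#' @param overlap_edges also connect islands that overlap one another.
#' @return An `island_clustering`: list with `membership` (cluster id per
#'   island, ids numbered in genomic span order), `junction_cluster`
#'   (cluster id per junction, `NA` when not attached at both ends),
#'   `span_chrom`/`span_start`/`span_end` (covering interval per cluster)
#'   and `n_clusters`. Use [cluster_list()] to materialise per-cluster
#'   islands and junctions.
#' @export
cluster_islands <- function(islands, junctions, tol = 10L,
                            overlap_edges = TRUE) {
  n <- length(islands)
  if (n == 0L) {
    return(structure(list(membership = integer(0),
                          junction_cluster = integer(0),
                          spans = GenomicRanges::GRanges(),
                          n_clusters = 0L),
                     class = "island_clustering"))
  }
  edges <- matrix(integer(0), ncol = 2L)
  if (overlap_edges && n > 1L) {
    ov <- GenomicRanges::findOverlaps(islands, drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov)) {
      edges <- rbind(edges, cbind(S4Vectors::queryHits(ov),
                                  S4Vectors::subjectHits(ov)))
    }
  }
  st <- GenomicRanges::start(islands)
  en <- GenomicRanges::end(islands)
  chrom <- as.character(GenomicRanges::seqnames(islands))
  jx_members <- vector("list", length(junctions))
  if (length(junctions)) {
    j_st <- GenomicRanges::start(junctions)
    j_en <- GenomicRanges::end(junctions)
    j_chrom <- as.character(GenomicRanges::seqnames(junctions))
    for (j in seq_along(junctions)) {
      d <- attach_islands(j_st[j] - 1L, j_chrom[j], st, en, chrom, tol)
      if (length(d) == 0L) next
      acc <- attach_islands(j_en[j] + 1L, j_chrom[j], st, en, chrom, tol)
      if (length(acc) == 0L) next
      jx_members[[j]] <- unique(c(d, acc))
      pairs <- expand.grid(d = d, a = acc)
      pairs <- pairs[pairs$d != pairs$a, , drop = FALSE]
      if (nrow(pairs)) {
        edges <- rbind(edges, cbind(pairs$d, pairs$a))
      }
    }
  }
  comp <- union_find(n, edges)
  span_chrom <- vapply(split(chrom, comp), `[`, "", 1L)
  span_start <- vapply(split(st, comp), min, 0L)
  span_end <- vapply(split(en, comp), max, 0L)
  ord <- order(span_chrom, span_start, span_end)
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  membership <- relabel[comp]
  junction_cluster <- rep(NA_integer_, length(junctions))
  for (j in seq_along(jx_members)) {
    m <- jx_members[[j]]
    if (length(m)) junction_cluster[j] <- membership[m[1]]
  }
  structure(list(membership = membership,
                 junction_cluster = junction_cluster,
                 span_chrom = span_chrom[ord],
                 span_start = unname(span_start[ord]),
                 span_end = unname(span_end[ord]),
                 n_clusters = length(ord)),
            class = "island_clustering")
}

#' Materialise clusters as per-cluster islands and junctions
#'
#' @param islands,junctions the inputs given to [cluster_islands()].
#' @param clustering the resulting `island_clustering`.
#' @return List of clusters, span-ordered; each holds `islands`
#'   (GRanges, sorted), `junctions` (GRanges attached at both ends) and
#'   `span` (GRanges).
#' @export
cluster_list <- function(islands, junctions, clustering) {
  st <- GenomicRanges::start(islands)
  lapply(seq_len(clustering$n_clusters), function(k) {
    idx <- which(clustering$membership == k)
    idx <- idx[order(st[idx])]
    jsel <- which(!is.na(clustering$junction_cluster) &
                    clustering$junction_cluster == k)
    list(islands = islands[idx],
         junctions = if (length(junctions)) junctions[jsel] else
           GenomicRanges::GRanges(),
         span = GenomicRanges::GRanges(
           clustering$span_chrom[k],
           IRanges::IRanges(clustering$span_start[k],
                            clustering$span_end[k])))
  })
}

#' Consensus introns of a junction set
#'
#' The union of the junction intervals is broken at every junction start
#' and end into atomic segments. A segment enters the consensus when the
#' number of junctions containing it, relative to the number of junctions
#' overlapping the segment's contiguous union block, exceeds
#' `consensus_fraction` (strict majority by default). Adjacent accepted
#' segments are merged and introns shorter than `min_intron` are dropped.
#'
#' @param junctions GRanges of junction introns (one cluster).
#' @param consensus_fraction strict-majority fraction.
#' @param min_intron minimum intron length retained.
#' @return GRanges of disjoint consensus introns (possibly empty).
#' @export
consensus_introns <- function(junctions, consensus_fraction = 0.5,
                              min_intron = 20L) {
  if (length(junctions) == 0L) return(GenomicRanges::GRanges())
  jx <- GenomicRanges::granges(junctions)
  segs <- GenomicRanges::disjoin(jx)
  blocks <- GenomicRanges::reduce(jx)
  contain <- GenomicRanges::countOverlaps(segs, jx, type = "within")
  seg_block <- GenomicRanges::findOverlaps(segs, blocks, select = "first")
  denom <- GenomicRanges::countOverlaps(blocks, jx)[seg_block]
  keep <- contain / denom > consensus_fraction
  merged <- GenomicRanges::reduce(segs[keep])
  merged[IRanges::width(merged) >= min_intron]
}

#' Reconstruct an exon chain by subtracting introns from grouped islands
#'
#' The covering hull of the cluster's islands is cut by the consensus
#' introns; resulting pieces with no island support at all are discarded.
#'
#' @param islands GRanges of the cluster's islands.
#' @param introns GRanges of disjoint introns.
#' @return Sorted GRanges of exons (empty when subtraction consumes the
#'   whole hull).
#' @export
subtract_introns <- function(islands, introns) {
  if (length(islands) == 0L) return(GenomicRanges::GRanges())
  hull <- range(GenomicRanges::granges(islands))
  if (length(introns) == 0L) return(hull)
  exons <- GenomicRanges::setdiff(hull, GenomicRanges::granges(introns))
  if (length(exons)) {
    supported <- IRanges::overlapsAny(exons, islands)
    exons <- exons[supported]
  }
  BiocGenerics::sort(exons)
}

#' Smoothed z-score breakpoint detector
#'
#' A rolling mean and standard deviation are maintained over the trailing
#' `z_window` positions of an influence-free filtered signal: positions
#' flagged as breakpoints do not update the statistics. A position is
#' flagged DROP when the rolling mean exceeds its depth by more than
#' `z_drop_threshold` floored standard deviations, PEAK for the converse.
#' Maximal DROP runs at least `z_min_intron` long in the interior become
#' candidate introns; a qualifying DROP run touching the segment's end
#' trims the transcript end.
#'
#' @param y numeric vector of per-base depth over one segment.
#' @param params [assembly_params()] (window, threshold, minimum intron,
#'   standard-deviation floor).
#' @return List with `flags` (integer per position: -1 drop, 0 none,
#'   1 peak), `introns` (IRanges, segment-local coordinates), `peaks`
#'   (IRanges of peak runs), and `trim_right` (new right boundary, or
#'   `length(y)` when no trailing drop run).
#' @export
zscore_breakpoints <- function(y, params = assembly_params()) {
  n <- length(y)
  w <- params$z_window
  empty <- list(flags = integer(n), introns = IRanges::IRanges(),
                peaks = IRanges::IRanges(), trim_right = n)
  if (n <= w) return(empty)
  thr <- params$z_drop_threshold
  floor_sd <- params$z_sd_floor
  flags <- integer(n)
  filt <- as.numeric(y)
  run_sum <- sum(filt[1:w])
  run_sumsq <- sum(filt[1:w]^2)
  for (i in (w + 1L):n) {
    m <- run_sum / w
    varw <- max(0, run_sumsq / w - m^2)
    s <- max(sqrt(varw), floor_sd)
    if (m - y[i] > thr * s) {
      flags[i] <- -1L
      filt[i] <- filt[i - 1L]
    } else if (y[i] - m > thr * s) {
      flags[i] <- 1L
      filt[i] <- filt[i - 1L]
    } else {
      filt[i] <- y[i]
    }
    # advance trailing window [i-w+1, i]
    run_sum <- run_sum + filt[i] - filt[i - w]
    run_sumsq <- run_sumsq + filt[i]^2 - filt[i - w]^2
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop_runs <- IRanges::IRanges(starts[r$values == -1L],
                                ends[r$values == -1L])
  peak_runs <- IRanges::IRanges(starts[r$values == 1L],
                                ends[r$values == 1L])
  drop_runs <- drop_runs[IRanges::width(drop_runs) >= params$z_min_intron]
  trim_right <- n
  if (length(drop_runs) && IRanges::end(drop_runs)[length(drop_runs)] == n) {
    trim_right <- IRanges::start(drop_runs)[length(drop_runs)] - 1L
    drop_runs <- drop_runs[-length(drop_runs)]
  }
  list(flags = flags, introns = drop_runs, peaks = peak_runs,
       trim_right = trim_right)
}

#' Refine candidate exons with the z-score detector
#'
#' Each exon longer than the smoothing window is scanned for coverage
#' drops; interior drop runs become additional introns (splitting the
#' exon) and a trailing drop run trims the exon end.
#'
#' @param exons GRanges exon chain of one candidate.
#' @param track `coverage_track` of the candidate's chromosome strand.
#' @param params [assembly_params()].
#' @return Refined, sorted GRanges of exons.
#' @export
refine_exons <- function(exons, track, params = assembly_params()) {
  if (length(exons) == 0L) return(exons)
  pieces <- list()
  for (i in seq_along(exons)) {
    s <- GenomicRanges::start(exons)[i]
    e <- GenomicRanges::end(exons)[i]
    y <- track_depth(track, s, e)
    res <- zscore_breakpoints(y, params)
    keep <- IRanges::IRanges(1L, res$trim_right)
    if (length(res$introns)) {
      keep <- IRanges::setdiff(keep, res$introns)
    }
    keep <- keep[IRanges::width(keep) > 0L]
    if (length(keep)) {
      pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(exons))[i],
        ranges = IRanges::shift(keep, s - 1L),
        strand = as.character(GenomicRanges::strand(exons))[i]
      )
    }
  }
  if (length(pieces) == 0L) return(GenomicRanges::GRanges())
  BiocGenerics::sort(suppressWarnings(do.call(c, pieces)))
}

#' Monoexonic candidate selection across samples
#'
#' Junction-free islands are reconciled across samples: a candidate
#' region is the intersection, across all samples, of co-overlapping
#' singleton islands (groups missing any sample are discarded). The
#' length-normalised coverage `c` of each region (mean per-base depth,
#' averaged over samples) is then ranked within the whole monoexonic
#' population and only regions in the strict top decile survive:
#' Pr(>) = #\{c' > c\}/N must be below `pr_cutoff`.
#'
#' @param singletons_by_sample named list (sample id -> strand-tagged
#'   GRanges of junction-free islands).
#' @param tracks_by_sample nested list (sample id -> strand -> named
#'   list of `coverage_track` per chromosome).
#' @param pr_cutoff upper-tail probability cutoff (default 0.1).
#' @return List with `regions` (all candidate regions, metadata `c` and
#'   `pr`) and `kept` (the surviving regions).
#' @export
monoexonic_candidates <- function(singletons_by_sample, tracks_by_sample,
                                  pr_cutoff = 0.1) {
  samples <- names(singletons_by_sample)
  stopifnot(length(samples) >= 2L)
  pool <- list()
  for (s in samples) {
    gr <- singletons_by_sample[[s]]
    if (length(gr)) {
      gr$sample_id <- s
      pool[[length(pool) + 1L]] <- gr
    }
  }
  if (length(pool) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(list(regions = empty, kept = empty))
  }
  pool <- suppressWarnings(do.call(c, pool))
  groups <- GenomicRanges::reduce(GenomicRanges::granges(pool))
  hits <- GenomicRanges::findOverlaps(pool, groups)
  grp_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  regions <- list()
  for (g in seq_along(groups)) {
    members <- pool[grp_of == g]
    present <- unique(members$sample_id)
    if (!all(samples %in% present)) next
    region <- NULL
    for (s in samples) {
      rs <- GenomicRanges::reduce(
        GenomicRanges::granges(members[members$sample_id == s]))
      region <- if (is.null(region)) rs else
        GenomicRanges::intersect(region, rs)
    }
    if (length(region) == 0L) next
    if (length(region) > 1L) {
      region <- region[which.max(IRanges::width(region))]
    }
    regions[[length(regions) + 1L]] <- region
  }
  if (length(regions) == 0L) {
    empty <- GenomicRanges::GRanges()
    return(list(regions = empty, kept = empty))
  }
  regions <- BiocGenerics::sort(suppressWarnings(do.call(c, regions)))
  cvals <- vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    strand <- as.character(GenomicRanges::strand(regions))[i]
    s <- GenomicRanges::start(regions)[i]
    e <- GenomicRanges::end(regions)[i]
    mean(vapply(samples, function(sm) {
      island_mean_depth(tracks_by_sample[[sm]][[strand]][[chrom]], s, e)
    }, numeric(1)))
  }, numeric(1))
  pr <- vapply(cvals, function(ci) mean(cvals > ci), numeric(1))
  regions$c <- cvals
  regions$pr <- pr
  list(regions = regions, kept = regions[pr < pr_cutoff])
}

#' Merge per-sample candidates into a non-redundant gene-level set
#'
#' Same-strand candidates with overlapping exonic bp are unioned into a
#' single gene-level model (exon union); each merged gene records, per
#' condition, whether it was contributed by every replicate of that
#' condition, and genes present in no complete condition are dropped.
#' Gene identifiers are assigned in sorted genomic order, so the merged
#' output is independent of sample order.
#'
#' @param exons GRanges of per-sample candidate exons with metadata
#'   `sample_id` and `cand_key` (a per-sample candidate identifier).
#' @param sample_info data.frame with `sample` and `condition` columns.
#' @param id_prefix prefix of assigned gene identifiers.
#' @param drop_inconsistent drop genes present in no complete condition.
#' @return `lnc_candidates` with logical `present_<condition>` columns
#'   and a `consistent` flag.
#' @export
merge_samples <- function(exons, sample_info, id_prefix = "LNC",
                          drop_inconsistent = TRUE) {
  stopifnot(!is.null(exons$sample_id), !is.null(exons$cand_key))
  conditions <- unique(sample_info$condition)
  if (length(exons) == 0L) {
    info <- data.frame(gene_id = character(0))
    return(structure(list(exons = exons, info = info),
                     class = "lnc_candidates"))
  }
  keys <- paste(exons$sample_id, exons$cand_key, sep = "\r")
  ukeys <- unique(keys)
  node <- match(keys, ukeys)
  ov <- GenomicRanges::findOverlaps(exons)
  edges <- cbind(node[S4Vectors::queryHits(ov)],
                 node[S4Vectors::subjectHits(ov)])
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(ukeys), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  comp_of_exon <- comp[node]

  merged <- list()
  for (cid in sort(unique(comp))) {
    sel <- comp_of_exon == cid
    mex <- GenomicRanges::reduce(GenomicRanges::granges(exons[sel]))
    sams <- unique(exons$sample_id[sel])
    presence <- vapply(conditions, function(cn) {
      reps <- sample_info$sample[sample_info$condition == cn]
      all(reps %in% sams)
    }, logical(1))
    merged[[length(merged) + 1L]] <- list(exons = mex, presence = presence)
  }
  spans <- suppressWarnings(do.call(c, lapply(merged, function(m) {
    range(m$exons)
  })))
  ord <- order(as.character(GenomicRanges::seqnames(spans)),
               GenomicRanges::start(spans), GenomicRanges::end(spans),
               as.character(GenomicRanges::strand(spans)))
  merged <- merged[ord]
  all_exons <- list()
  rows <- list()
  for (i in seq_along(merged)) {
    gid <- sprintf("%s%04d", id_prefix, i)
    mex <- merged[[i]]$exons
    mex$gene_id <- gid
    all_exons[[i]] <- mex
    pres <- merged[[i]]$presence
    row <- data.frame(gene_id = gid, consistent = any(pres),
                      stringsAsFactors = FALSE)
    for (cn in conditions) {
      row[[paste0("present_", cn)]] <- pres[[cn]]
    }
    rows[[i]] <- row
  }
  extra <- do.call(rbind, rows)
  out <- candidates_from_exons(suppressWarnings(do.call(c, all_exons)),
                               extra = extra)
  if (drop_inconsistent) {
    out <- subset_candidates(out, out$info$gene_id[out$info$consistent])
  }
  out
}
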