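# Independent oracles and small fixture builders used across tests.

# position-by-position island scan: strict depth > threshold, runs >= min_len
naive_islands <- function(depth, threshold, min_len) {
  above <- depth > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

# transitive-closure connected components (Floyd-Warshall style)
warshall_components <- function(n, edges) {
  reach <- diag(TRUE, n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      reach[edges[k, 1], edges[k, 2]] <- TRUE
      reach[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  for (k in seq_len(n)) {
    reach <- reach | (outer(reach[, k], reach[k, ]))
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# exhaustive ORF scan over all (frame, ATG, stop) triples
orf_oracle <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, by = 3L, length.out = (n - frame) %/% 3L)
    if (length(starts) == 0L) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    for (a in which(codons == "ATG")) {
      for (j in a:length(codons)) {        # linear scan to the first stop
        if (is_stop[j]) {
          best <- max(best, (j - a + 1L) * 3L)
          break
        }
      }
    }
  }
  best
}

# two-sided Fisher p by explicit enumeration with binomial coefficients
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0L, k - n_):min(k, m)
  tot <- choose(m + n_, k)
  probs <- choose(m, support) * choose(n_, k - support) / tot
  p_obs <- choose(m, a) * choose(n_, k - a) / tot
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# random coverage track with 0/depth runs
random_track <- function(len, p_on = 0.3, depth = 5L, chrom = "chrT",
                         strand = "+") {
  v <- ifelse(stats::runif(len) < p_on, depth, 0L)
  coverage_track(chrom, strand, v)
}

# small annotation: genes given as list(gene_id, chrom, strand, exon starts/ends)
toy_annotation <- function(genes) {
  ex <- do.call(c, lapply(genes, function(g) {
    gr <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$starts, g$ends), strand = g$strand)
    gr$gene_id <- g$gene_id
    gr
  }))
  ex$biotype <- "protein_coding"
  sp <- BiocGenerics::unlist(range(S4Vectors::split(
    GenomicRanges::granges(ex), ex$gene_id)), use.names = FALSE)
  sp$gene_id <- sort(unique(ex$gene_id))
  sp$biotype <- "protein_coding"
  lncislands:::new_annotation(sp, ex)
}

# candidate set from a list of exon GRanges
toy_candidates <- function(...) {
  exl <- list(...)
  ex <- suppressWarnings(do.call(c, lapply(seq_along(exl), function(i) {
    g <- exl[[i]]
    g$gene_id <- sprintf("cand%02d", i)
    g
  })))
  candidates_from_exons(ex)
}

gr <- function(chrom, starts, ends, strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strand)
}

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
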