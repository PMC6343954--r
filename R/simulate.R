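# Codon-usage bias shared by simulated coding sequence. The bias is
# deliberately asymmetric under reverse complement (A-rich, T-poor
# codons): real coding sequence is strand-asymmetric too, which is what
# lets hexamer usage separate sense coding sequence from its antisense
# complement as well as from random background.
.sim_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b)[, 3:1], 1L, paste0, collapse = "")
  sense <- setdiff(all3, c("TAA", "TAG", "TGA"))
  comp <- vapply(strsplit(sense, ""), function(ch) {
    c(A = sum(ch == "A"), T = sum(ch == "T"))
  }, numeric(2))
  w <- 3^comp["A", ] * 0.3^comp["T", ]
  list(codons = sense, weights = w / sum(w))
}

random_coding_orf <- function(n_codons) {
  cb <- .sim_codons()
  body <- sample(cb$codons, n_codons, replace = TRUE, prob = cb$weights)
  paste0("ATG", paste0(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulated training sequences for the coding-potential model
#'
#' Coding sequences carry a codon-biased open reading frame over ~90% of
#' their length; noncoding sequences are uniform random DNA.
#'
#' @param n sequences per class.
#' @param len_range transcript length range.
#' @return List with character vectors `coding` and `noncoding`.
#' @export
simulate_training_sets <- function(n = 120L, len_range = c(500L, 1500L)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  coding <- vapply(lens, function(L) {
    orf_nt <- 3L * max(20L, (floor(0.9 * L) %/% 3L) - 2L)
    flank <- max(0L, L - orf_nt - 6L)
    left <- flank %/% 2L
    paste0(if (left > 0) random_dna(left) else "",
           random_coding_orf(orf_nt %/% 3L - 2L),
           random_dna(max(0L, L - left - orf_nt)))
  }, character(1))
  noncoding <- vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                      random_dna, character(1))
  list(coding = coding, noncoding = noncoding)
}

exon_chain <- function(chrom, strand, start, exon_widths, intron_widths) {
  starts <- integer(length(exon_widths))
  pos <- start
  for (i in seq_along(exon_widths)) {
    starts[i] <- pos
    pos <- pos + exon_widths[i] +
      if (i < length(exon_widths)) intron_widths[i] else 0L
  }
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts, width = exon_widths),
    strand = strand
  )
}

rand_between <- function(lo, hi) sample(lo:hi, 1L)

# number of exons for a planted multiexonic lncRNA: biexonic-skewed
sample_lnc_exon_count <- function() {
  sample(c(2L, 3L, 4L), 1L, prob = c(0.6875, 0.1875, 0.125))
}

#' Simulate a reference genome, annotation and planted lncRNA truth
#'
#' Lays out multi-exon coding genes and planted novel lncRNAs of each
#' genomic-context class on a small genome. Chromosomes are tiled into
#' 20 kb blocks; coding genes sit well inside their block so that every
#' planted intergenic feature is over 1000 bp away from any annotated
#' gene span. Antisense lncRNAs overlap host-gene exons on the opposite
#' strand; intronic lncRNAs sit deep inside a long host intron on the
#' same strand; monoexonic features occupy intergenic space. Coding genes
#' and decoy transcripts carry codon-biased open reading frames written
#' into the genome sequence.
#'
#' @param config [simulation_config()].
#' @return List with `genome` (DNAStringSet), `annotation`
#'   (`lnc_annotation`), `truth` (`lnc_candidates` of planted lncRNAs;
#'   info columns `class`, `monoexonic`, `host_gene`), `decoys`
#'   (`lnc_candidates`), `expression` (per-feature data.frame: id, type,
#'   base_mean, lfc), `seqlengths`.
#' @export
simulate_reference <- function(config = simulation_config()) {
  set.seed(config$seed)
  block <- 20000L
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqlengths <- stats::setNames(rep(config$chrom_length, length(chroms)),
                                chroms)
  blocks <- do.call(rbind, lapply(chroms, function(ch) {
    nb <- config$chrom_length %/% block
    data.frame(chrom = ch, b0 = (seq_len(nb) - 1L) * block)
  }))
  need <- config$n_coding_genes + config$n_intergenic +
    config$n_monoexonic + config$n_decoys
  if (need > nrow(blocks)) stop("genome too small for requested features")
  if (config$n_coding_genes < config$n_antisense + config$n_intronic) {
    stop("need at least one coding gene per antisense/intronic feature")
  }
  blocks <- blocks[sample(nrow(blocks)), ]
  take_blocks <- function(n) {
    if (n == 0L) return(blocks[integer(0), , drop = FALSE])
    out <- blocks[seq_len(n), , drop = FALSE]
    blocks <<- blocks[-seq_len(n), , drop = FALSE]
    out
  }
  gene_blocks <- take_blocks(config$n_coding_genes)
  ig_blocks <- take_blocks(config$n_intergenic)
  mono_blocks <- take_blocks(config$n_monoexonic)
  decoy_blocks <- take_blocks(config$n_decoys)

  gene_role <- rep("plain", config$n_coding_genes)
  gene_role[seq_len(config$n_antisense)] <- "antisense_host"
  gene_role[config$n_antisense + seq_len(config$n_intronic)] <-
    "intronic_host"

  ann_exons <- list()
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_coding_genes))
  truth_exons <- list(); truth_rows <- list()
  lnc_i <- 0L
  new_truth <- function(exons, class, monoexonic, host) {
    lnc_i <<- lnc_i + 1L
    id <- sprintf("NOVEL_T%03d", lnc_i)
    exons$gene_id <- id
    truth_exons[[length(truth_exons) + 1L]] <<- exons
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      gene_id = id, class = class, monoexonic = monoexonic,
      host_gene = host, stringsAsFactors = FALSE)
    id
  }

  for (i in seq_len(config$n_coding_genes)) {
    ch <- gene_blocks$chrom[i]; b0 <- gene_blocks$b0[i]
    strand <- sample(c("+", "-"), 1L)
    gstart <- b0 + 7000L + rand_between(0L, 1000L)
    if (gene_role[i] == "intronic_host") {
      ew <- c(rand_between(200L, 300L), rand_between(200L, 300L))
      iw <- rand_between(6000L, 6500L)
      gex <- exon_chain(ch, strand, gstart, ew, iw)
      # plant the intronic lncRNA deep inside the single long intron
      intron_start <- GenomicRanges::end(gex)[1] + 1L
      lew <- c(rand_between(300L, 400L), rand_between(250L, 350L))
      liw <- rand_between(250L, 350L)
      lstart <- intron_start + 2000L + rand_between(0L, 400L)
      lex <- exon_chain(ch, strand, lstart, lew, liw)
      new_truth(lex, "intronic", FALSE, gene_ids[i])
    } else if (gene_role[i] == "antisense_host") {
      ew <- c(rand_between(500L, 700L), rand_between(500L, 700L))
      iw <- rand_between(400L, 800L)
      gex <- exon_chain(ch, strand, gstart, ew, iw)
      anti_strand <- if (strand == "+") "-" else "+"
      lew <- c(rand_between(250L, 350L), rand_between(200L, 300L))
      liw <- rand_between(250L, 350L)
      lstart <- GenomicRanges::start(gex)[1] + 50L
      lex <- exon_chain(ch, anti_strand, lstart, lew, liw)
      new_truth(lex, "antisense", FALSE, gene_ids[i])
    } else {
      ne <- rand_between(3L, 5L)
      ew <- vapply(seq_len(ne), function(k) rand_between(150L, 400L),
                   integer(1))
      iw <- vapply(seq_len(ne - 1L), function(k) rand_between(300L, 800L),
                   integer(1))
      gex <- exon_chain(ch, strand, gstart, ew, iw)
    }
    gex$gene_id <- gene_ids[i]
    ann_exons[[i]] <- gex
  }

  for (i in seq_len(config$n_intergenic)) {
    ch <- ig_blocks$chrom[i]; b0 <- ig_blocks$b0[i]
    strand <- sample(c("+", "-"), 1L)
    ne <- sample_lnc_exon_count()
    ew <- vapply(seq_len(ne), function(k) rand_between(200L, 400L),
                 integer(1))
    iw <- if (ne > 1L) vapply(seq_len(ne - 1L), function(k)
      rand_between(300L, 700L), integer(1)) else integer(0)
    lex <- exon_chain(ch, strand, b0 + 9000L + rand_between(0L, 1000L),
                      ew, iw)
    new_truth(lex, "intergenic", FALSE, NA_character_)
  }

  for (i in seq_len(config$n_monoexonic)) {
    ch <- mono_blocks$chrom[i]; b0 <- mono_blocks$b0[i]
    strand <- sample(c("+", "-"), 1L)
    lex <- exon_chain(ch, strand, b0 + 9000L + rand_between(0L, 1000L),
                      rand_between(400L, 800L), integer(0))
    new_truth(lex, "intergenic", TRUE, NA_character_)
  }

  decoy_exons <- list(); decoy_ids <- character(config$n_decoys)
  for (i in seq_len(config$n_decoys)) {
    ch <- decoy_blocks$chrom[i]; b0 <- decoy_blocks$b0[i]
    strand <- sample(c("+", "-"), 1L)
    ew <- c(rand_between(450L, 600L), rand_between(500L, 700L))
    iw <- rand_between(300L, 500L)
    dex <- exon_chain(ch, strand, b0 + 9000L + rand_between(0L, 1000L),
                      ew, iw)
    decoy_ids[i] <- sprintf("DECOY%03d", i)
    dex$gene_id <- decoy_ids[i]
    decoy_exons[[i]] <- dex
  }

  # genome sequence with planted open reading frames
  genome_chars <- lapply(seqlengths, function(len) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  plant <- function(exons, strand, transcript) {
    ch <- as.character(GenomicRanges::seqnames(exons))[1]
    tchars <- strsplit(transcript, "")[[1]]
    if (strand == "-") {
      tchars <- rev(c(A = "T", C = "G", G = "C", T = "A")[tchars])
    }
    off <- 0L
    for (k in seq_along(exons)) {
      w <- IRanges::width(exons)[k]
      idx <- GenomicRanges::start(exons)[k]:GenomicRanges::end(exons)[k]
      genome_chars[[ch]][idx] <<- tchars[(off + 1L):(off + w)]
      off <- off + w
    }
  }
  for (i in seq_len(config$n_coding_genes)) {
    gex <- ann_exons[[i]]
    strand <- as.character(GenomicRanges::strand(gex))[1]
    L <- sum(IRanges::width(gex))
    orf_nt <- 3L * max(20L, ((L - 60L) %/% 3L))
    left <- (L - orf_nt) %/% 2L
    tx <- paste0(random_dna(left), random_coding_orf(orf_nt %/% 3L - 2L),
                 random_dna(L - left - orf_nt))
    plant(BiocGenerics::sort(gex), strand, tx)
  }
  for (i in seq_len(config$n_decoys)) {
    dex <- decoy_exons[[i]]
    strand <- as.character(GenomicRanges::strand(dex))[1]
    L <- sum(IRanges::width(dex))
    orf_nt <- 3L * max(20L, (floor(0.85 * L) %/% 3L))
    left <- max(0L, (L - orf_nt) %/% 2L)
    tx <- paste0(random_dna(left), random_coding_orf(orf_nt %/% 3L - 2L),
                 random_dna(L - left - orf_nt))
    plant(BiocGenerics::sort(dex), strand, tx)
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste0,
                                            character(1), collapse = ""))
  names(genome) <- chroms

  ann_gr <- suppressWarnings(do.call(c, ann_exons))
  annotation <- new_annotation(
    genes = local({
      sp <- BiocGenerics::unlist(range(S4Vectors::split(
        GenomicRanges::granges(ann_gr), ann_gr$gene_id)), use.names = FALSE)
      sp$gene_id <- names(S4Vectors::split(GenomicRanges::granges(ann_gr),
                                           ann_gr$gene_id))
      sp$biotype <- "protein_coding"
      sp
    }),
    exons = ann_gr
  )
  truth <- if (length(truth_exons)) {
    candidates_from_exons(suppressWarnings(do.call(c, truth_exons)),
                          extra = do.call(rbind, truth_rows))
  } else {
    structure(list(exons = GenomicRanges::GRanges(),
                   info = data.frame(gene_id = character(0),
                                     class = character(0),
                                     monoexonic = logical(0),
                                     host_gene = character(0),
                                     stringsAsFactors = FALSE)),
              class = "lnc_candidates")
  }
  decoys <- if (length(decoy_exons)) {
    candidates_from_exons(suppressWarnings(do.call(c, decoy_exons)))
  } else {
    structure(list(exons = GenomicRanges::GRanges(),
                   info = data.frame(gene_id = character(0),
                                     stringsAsFactors = FALSE)),
              class = "lnc_candidates")
  }

  # expression programme: lncRNAs and decoys ~10x below coding genes
  feats <- data.frame(
    id = c(gene_ids, truth$info$gene_id, decoy_ids),
    type = c(rep("coding", length(gene_ids)),
             rep("lncRNA", nrow(truth$info)),
             rep("decoy", length(decoy_ids))),
    stringsAsFactors = FALSE
  )
  feats$base_mean <- ifelse(feats$type == "coding",
                            stats::rlnorm(nrow(feats), log(300), 0.4),
                            stats::rlnorm(nrow(feats), log(300 *
                              config$lnc_coding_ratio), 0.4))
  feats$lfc <- 0
  de_pick <- stats::runif(nrow(feats)) < 0.3
  feats$lfc[de_pick] <- stats::rnorm(sum(de_pick), 0, 1)
  # antisense features: a configured fraction flips sign against the host
  tinfo <- truth$info
  anti <- tinfo$gene_id[tinfo$class == "antisense"]
  for (aid in anti) {
    host <- tinfo$host_gene[tinfo$gene_id == aid]
    host_lfc <- sample(c(-1, 1), 1L) * stats::runif(1, 1, 2)
    feats$lfc[feats$id == host] <- host_lfc
    flip <- stats::runif(1) < config$antisense_flip_fraction
    feats$lfc[feats$id == aid] <-
      (if (flip) -1 else 1) * sign(host_lfc) * stats::runif(1, 0.8, 1.6)
  }

  list(genome = genome, annotation = annotation, truth = truth,
       decoys = decoys, expression = feats, seqlengths = seqlengths,
       config = config)
}

#' Simulate per-sample coverage, splice junctions and counts
#'
#' Every planted feature (lncRNAs, decoys and annotated coding genes)
#' produces plateau coverage over its exons on its strand: the per-exon
#' depth is drawn as `max(3, rpois(1, target))` around a per-feature
#' target from `depth_range`, so an expressed feature always clears the
#' island depth floor. Multiexonic features emit one splice junction per
#' intron with support drawn from `junction_support_range`. Sparse
#' background noise runs (all shorter than the minimum island length)
#' are added on both strands. Counts are negative binomial around the
#' expression programme of the reference, with the condition-2 effect
#' given by each feature's log2 fold change; a synthetic differential
#' expression table (estimated fold change and adjusted p-value) is
#' derived from the same programme.
#'
#' @param ref output of [simulate_reference()].
#' @param config [simulation_config()] (defaults to the one in `ref`).
#' @return List with `samples` (data.frame sample/condition), `tracks`
#'   (sample -> strand -> chromosome -> `coverage_track`), `junctions`
#'   (sample -> GRanges), `counts` (feature x sample matrix),
#'   `library_sizes`, `de` (data.frame id, lfc, padj), `tss` (GRanges).
#' @export
simulate_evidence <- function(ref, config = ref$config) {
  set.seed(config$seed + 1L)
  conditions <- paste0("cond", seq_len(config$n_conditions))
  samples <- data.frame(
    sample = unlist(lapply(conditions, function(cn)
      paste0(cn, "_rep", seq_len(config$n_samples_per_condition)))),
    condition = rep(conditions, each = config$n_samples_per_condition),
    stringsAsFactors = FALSE
  )
  chroms <- names(ref$seqlengths)

  # feature table: exons + strand + id + type
  feat_exons <- c(
    local({g <- ref$truth$exons; g$type <- "lncRNA"; g}),
    local({g <- ref$decoys$exons; g$type <- "decoy"; g}),
    local({g <- ref$annotation$exons; g$type <- "coding"; g})
  )
  ids <- unique(feat_exons$gene_id)
  target <- stats::setNames(
    stats::runif(length(ids), config$depth_range[1], config$depth_range[2]),
    ids)
  # coding genes are sequenced deeper, mirroring their higher expression
  coding_ids <- unique(ref$annotation$exons$gene_id)
  target[coding_ids] <- target[coding_ids] / config$lnc_coding_ratio / 2

  tracks <- list(); junctions <- list()
  all_introns <- introns_of(feat_exons)
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample[si]
    tracks[[s]] <- list(`+` = list(), `-` = list())
    for (strand in c("+", "-")) {
      for (ch in chroms) {
        sel <- feat_exons[
          as.character(GenomicRanges::strand(feat_exons)) == strand &
            as.character(GenomicRanges::seqnames(feat_exons)) == ch]
        depth <- S4Vectors::Rle(0L, ref$seqlengths[[ch]])
        if (length(sel)) {
          w <- vapply(seq_along(sel), function(k) {
            max(3L, stats::rpois(1L, target[[sel$gene_id[k]]]))
          }, integer(1))
          cov <- IRanges::coverage(
            IRanges::IRanges(GenomicRanges::start(sel),
                             GenomicRanges::end(sel)),
            width = ref$seqlengths[[ch]], weight = w)
          depth <- methods::as(cov, "Rle")
        }
        n_noise <- stats::rpois(1L, config$noise_runs_per_100kb *
                                  ref$seqlengths[[ch]] / 1e5)
        if (n_noise > 0L) {
          nw <- sample(20:80, n_noise, replace = TRUE)
          ns <- sample.int(ref$seqlengths[[ch]] - 100L, n_noise)
          nd <- sample(3:6, n_noise, replace = TRUE)
          noise <- methods::as(IRanges::coverage(
            IRanges::IRanges(ns, width = nw),
            width = ref$seqlengths[[ch]], weight = nd), "Rle")
          depth <- depth + noise
        }
        tracks[[s]][[strand]][[ch]] <- coverage_track(ch, strand, depth, s)
      }
    }
    jx <- all_introns
    if (length(jx)) {
      jx$unique_reads <- as.integer(round(stats::runif(
        length(jx), config$junction_support_range[1],
        config$junction_support_range[2])))
      jx$multi_reads <- 0L
      jx$annotated <- jx$type == "coding"
      deep <- jx$type == "coding"
      jx$unique_reads[deep] <- jx$unique_reads[deep] * 5L
    }
    junctions[[s]] <- jx
  }

  # counts and synthetic DE programme
  expr <- ref$expression
  mu <- outer(expr$base_mean, rep(1, nrow(samples)))
  cond2 <- samples$condition != conditions[1]
  mu[, cond2] <- mu[, cond2] * 2^expr$lfc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   nrow = nrow(expr),
                   dimnames = list(expr$id, samples$sample))
  de <- data.frame(
    id = expr$id,
    lfc = expr$lfc + stats::rnorm(nrow(expr), 0, 0.15),
    padj = ifelse(abs(expr$lfc) > 0.5,
                  stats::runif(nrow(expr), 0, 0.01),
                  stats::runif(nrow(expr), 0.2, 1)),
    stringsAsFactors = FALSE
  )

  # CAGE-style TSS at feature 5' ends with positional jitter
  tss_src <- c(ref$truth$exons, ref$annotation$exons)
  by_id <- S4Vectors::split(GenomicRanges::granges(tss_src),
                            tss_src$gene_id)
  spans <- BiocGenerics::unlist(range(by_id), use.names = FALSE)
  keep <- stats::runif(length(spans)) < 0.9
  spans <- spans[keep]
  five <- ifelse(as.character(GenomicRanges::strand(spans)) == "-",
                 GenomicRanges::end(spans), GenomicRanges::start(spans))
  pos <- pmax(1L, five + as.integer(round(stats::rnorm(length(spans), 0, 30))))
  tss <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(spans),
    IRanges::IRanges(pos, width = 1L),
    strand = GenomicRanges::strand(spans))

  list(samples = samples, tracks = tracks, junctions = junctions,
       counts = counts, library_sizes = colSums(counts), de = de,
       tss = tss)
}

# introns implied by each feature's exon chain (with gene_id, type)
introns_of <- function(exons) {
  out <- list()
  for (id in unique(exons$gene_id)) {
    ex <- BiocGenerics::sort(exons[exons$gene_id == id])
    if (length(ex) < 2L) next
    gaps <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(ex)[-1],
      IRanges::IRanges(GenomicRanges::end(ex)[-length(ex)] + 1L,
                       GenomicRanges::start(ex)[-1] - 1L),
      strand = GenomicRanges::strand(ex)[-1])
    gaps$gene_id <- id
    gaps$type <- ex$type[1]
    out[[length(out) + 1L]] <- gaps
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, out))
}

#' Write a complete synthetic data set to a directory
#'
#' Emits every file the pipeline consumes: `genome.fa`, `annotation.gtf`,
#' `truth.gtf` + `truth_info.tsv` (planted lncRNAs with class labels),
#' `decoys.gtf`, per-sample stranded bedGraphs and `SJ.out.tab` files,
#' `counts.tsv`, `samples.tsv`, `de.tsv`, `tss.bed`, and coding/noncoding
#' training FASTAs for the coding-potential model.
#'
#' @param config [simulation_config()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a list with `ref`, `evidence` and `paths`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- simulate_reference(config)
  ev <- simulate_evidence(ref, config)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(ref$genome, p("genome.fa"))
  ann_cand <- candidates_from_exons(ref$annotation$exons)
  write_gtf(ann_cand, p("annotation.gtf"), source = "synthetic")
  write_gtf(ref$truth, p("truth.gtf"), source = "synthetic")
  write_gtf(ref$decoys, p("decoys.gtf"), source = "synthetic")
  utils::write.table(ref$truth$info, p("truth_info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  strand_tag <- c(`+` = "plus", `-` = "minus")
  rows <- list()
  for (si in seq_len(nrow(ev$samples))) {
    s <- ev$samples$sample[si]
    row <- list(sample = s, condition = ev$samples$condition[si])
    for (strand in c("+", "-")) {
      rl <- methods::as(lapply(ev$tracks[[s]][[strand]],
                               function(t) t$depth), "RleList")
      f <- p(sprintf("%s.%s.bedGraph", s, strand_tag[[strand]]))
      write_bedgraph(rl, f)
      row[[paste0("bedgraph_", strand_tag[[strand]])]] <- basename(f)
    }
    fj <- p(sprintf("%s.SJ.out.tab", s))
    write_sj_tab(ev$junctions[[s]], fj)
    row$sj <- basename(fj)
    rows[[si]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  samples_df <- do.call(rbind, rows)
  names(samples_df) <- c("sample", "condition", "bedgraph_plus",
                         "bedgraph_minus", "sj")
  utils::write.table(samples_df, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts_tsv(ev$counts, p("counts.tsv"))
  utils::write.table(ev$de, p("de.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rtracklayer::export(ev$tss, p("tss.bed"), format = "BED")
  tr <- simulate_training_sets()
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      tr$coding, sprintf("coding%03d", seq_along(tr$coding)))),
    p("training_coding.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      tr$noncoding, sprintf("noncoding%03d", seq_along(tr$noncoding)))),
    p("training_noncoding.fa"))
  invisible(list(ref = ref, evidence = ev, dir = dir,
                 samples = samples_df))
}
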