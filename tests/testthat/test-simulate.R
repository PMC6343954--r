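small_cfg <- function(seed = 5L, ...) {
  simulation_config(seed = seed, n_chromosomes = 1L, chrom_length = 3e5,
                    n_coding_genes = 6L, n_antisense = 1L, n_intergenic = 3L,
                    n_intronic = 1L, n_monoexonic = 1L, n_decoys = 2L, ...)
}

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$truth$info, r2$truth$info)
  e1 <- simulate_evidence(r1, cfg)
  e2 <- simulate_evidence(r2, cfg)
  expect_identical(e1$counts, e2$counts)
  s <- e1$samples$sample[1]
  expect_identical(
    as.integer(e1$tracks[[s]][["+"]][["chr1"]]$depth),
    as.integer(e2$tracks[[s]][["+"]][["chr1"]]$depth))
})

test_that("requesting zero lncRNAs yields an empty truth set", {
  cfg <- simulation_config(seed = 3L, n_chromosomes = 1L,
                           chrom_length = 3e5, n_coding_genes = 5L,
                           n_antisense = 0L, n_intergenic = 0L,
                           n_intronic = 0L, n_monoexonic = 0L,
                           n_decoys = 1L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$truth$info), 0L)
  expect_equal(n_planted(cfg), 0L)
})

test_that("planted features respect the masking geometry by construction", {
  ref <- simulate_reference(small_cfg())
  tinfo <- ref$truth$info
  genes <- ref$annotation$genes
  for (i in which(tinfo$class == "intergenic")) {
    span <- gr(tinfo$chrom[i], tinfo$start[i], tinfo$end[i],
               tinfo$strand[i])
    same <- genes[as.character(GenomicRanges::strand(genes)) ==
                    tinfo$strand[i]]
    if (length(same) == 0L) next
    d <- min(GenomicRanges::distance(span, same, ignore.strand = TRUE),
             na.rm = TRUE)
    expect_gte(d, 1001L)
  }
  # antisense features overlap opposite-strand annotated exons
  for (i in which(tinfo$class == "antisense")) {
    ex <- candidate_exons(ref$truth, tinfo$gene_id[i])
    opp <- ref$annotation$exons[
      as.character(GenomicRanges::strand(ref$annotation$exons)) !=
        tinfo$strand[i]]
    expect_true(any(IRanges::overlapsAny(GenomicRanges::ranges(ex),
                                         GenomicRanges::ranges(opp))))
  }
  # intronic features sit inside a host-gene span without exon overlap
  for (i in which(tinfo$class == "intronic")) {
    ex <- candidate_exons(ref$truth, tinfo$gene_id[i])
    host <- genes[genes$gene_id == tinfo$host_gene[i]]
    expect_gte(min(GenomicRanges::start(ex)), GenomicRanges::start(host))
    expect_lte(max(GenomicRanges::end(ex)), GenomicRanges::end(host))
    hex <- ref$annotation$exons[
      ref$annotation$exons$gene_id == tinfo$host_gene[i]]
    expect_false(any(IRanges::overlapsAny(GenomicRanges::ranges(ex),
                                          GenomicRanges::ranges(hex))))
  }
  # planted lncRNAs are at least 200 bp long
  expect_true(all(tinfo$length >= 200L))
})

test_that("noiseless evidence puts islands exactly on planted exons", {
  cfg <- small_cfg(noise_runs_per_100kb = 0)
  ref <- simulate_reference(cfg)
  ev <- simulate_evidence(ref, cfg)
  s <- ev$samples$sample[1]
  mask <- build_mask(ref$annotation)
  found <- list()
  for (strand in c("+", "-")) {
    tr <- mask_coverage(ev$tracks[[s]][[strand]][["chr1"]], mask)
    isl <- find_islands(tr)
    if (length(isl)) found[[strand]] <- isl
  }
  found <- suppressWarnings(do.call(c, unname(found)))
  # every unmasked planted exon (lncRNA or decoy, away from gene bodies)
  # is recovered as an island on its own strand
  planted <- c(ref$truth$exons, ref$decoys$exons)
  planted <- planted[!IRanges::overlapsAny(planted, mask)]
  hits <- GenomicRanges::findOverlaps(planted, found, type = "equal")
  expect_equal(length(hits), length(planted))
})

test_that("monoexonic features emit no junctions", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  ev <- simulate_evidence(ref, cfg)
  mono_ids <- ref$truth$info$gene_id[ref$truth$info$monoexonic]
  jx <- ev$junctions[[ev$samples$sample[1]]]
  expect_false(any(jx$gene_id %in% mono_ids))
})

test_that("simulated counts are centred on the configured programme", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  ev <- simulate_evidence(ref, cfg)
  cond2 <- ev$samples$condition != "cond1"
  mu <- outer(ref$expression$base_mean, rep(1, nrow(ev$samples)))
  mu[, cond2] <- mu[, cond2] * 2^ref$expression$lfc
  # pooled mean over all features and samples within a few percent
  expect_lt(abs(mean(ev$counts) / mean(mu) - 1), 0.05)
  # lncRNAs are expressed about tenfold below coding genes
  med_coding <- stats::median(ref$expression$base_mean[
    ref$expression$type == "coding"])
  med_lnc <- stats::median(ref$expression$base_mean[
    ref$expression$type == "lncRNA"])
  expect_lt(med_lnc / med_coding, 0.3)
})

test_that("the dataset writer round-trips through the file readers", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, dir)
  ann <- read_gtf(file.path(dir, "annotation.gtf"))
  expect_equal(length(ann$genes), cfg$n_coding_genes)
  truth <- read_gtf(file.path(dir, "truth.gtf"))
  expect_equal(length(truth$genes), n_planted(cfg))
  sj <- read_sj_tab(file.path(dir, "cond1_rep1.SJ.out.tab"))
  expect_gt(length(sj), 0L)
  bg <- read_bedgraph(file.path(dir, "cond1_rep1.plus.bedGraph"))
  s <- "cond1_rep1"
  tr <- coverage_from_bedgraph(bg, "+", seqlengths = c(chr1 = cfg$chrom_length))
  expect_identical(as.integer(tr$chr1$depth),
                   as.integer(sim$evidence$tracks[[s]][["+"]][["chr1"]]$depth))
  cm <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_identical(dim(cm), dim(sim$evidence$counts))
})
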