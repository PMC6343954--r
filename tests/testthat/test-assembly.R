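make_jx <- function(chrom, starts, ends, strand = "+", support = 5L,
                    annotated = FALSE) {
  j <- gr(chrom, starts, ends, strand)
  j$unique_reads <- rep(as.integer(support), length.out = length(j))
  j$annotated <- rep(annotated, length.out = length(j))
  j
}

test_that("junction filters are strict at the printed thresholds", {
  p <- assembly_params()
  # support > 2: 2 rejected, 3 and 4 kept
  for (sup in 2:4) {
    j <- make_jx("c", 101, 200, support = sup)
    expect_equal(length(filter_junctions(j, p)), if (sup > 2) 1L else 0L)
  }
  # intron length bounds: (20, 100000) exclusive on both sides
  for (w in c(20L, 21L, 22L)) {
    j <- make_jx("c", 101, 100 + w)
    expect_equal(length(filter_junctions(j, p)), if (w > 20) 1L else 0L)
  }
  for (w in c(99999L, 100000L, 100001L)) {
    j <- make_jx("c", 101, 100 + w)
    expect_equal(length(filter_junctions(j, p)), if (w < 100000) 1L else 0L)
  }
  # same-strand mask removes junctions; opposite strand does not
  j <- make_jx("c", 101, 200)
  mask_plus <- gr("c", 150, 160, "+")
  mask_minus <- gr("c", 150, 160, "-")
  expect_equal(length(filter_junctions(j, p, mask = mask_plus)), 0L)
  expect_equal(length(filter_junctions(j, p, mask = mask_minus)), 1L)
  # annotated junctions drop under novel_only
  ja <- make_jx("c", 101, 200, annotated = TRUE)
  expect_equal(length(filter_junctions(ja, p, novel_only = TRUE)), 0L)
})

test_that("junction-linked islands cluster; chains are transitive", {
  islands <- gr("c", c(1, 301), c(150, 450))
  jx <- make_jx("c", 151, 300)
  clu <- cluster_islands(islands, jx)
  cl <- cluster_list(islands, jx, clu)
  expect_equal(length(cl), 1L)
  expect_equal(length(cl[[1]]$islands), 2L)
  expect_equal(length(cl[[1]]$junctions), 1L)

  # chain A-B, B-C collapses into one cluster; D stays a singleton
  islands3 <- gr("c", c(1, 301, 601, 5001), c(150, 450, 800, 5200))
  jx2 <- make_jx("c", c(151, 451), c(300, 600))
  clu2 <- cluster_islands(islands3, jx2)
  expect_equal(clu2$n_clusters, 2L)
  expect_equal(clu2$membership, c(1L, 1L, 1L, 2L))
  cl2 <- cluster_list(islands3, jx2, clu2)
  expect_equal(length(cl2[[1]]$islands), 3L)
  expect_equal(length(cl2[[2]]$islands), 1L)
  expect_equal(length(cl2[[2]]$junctions), 0L)
})

test_that("consensus introns follow the segment-frequency rule", {
  # single junction: the intron is the junction
  one <- make_jx("c", 151, 300)
  ci <- consensus_introns(one)
  expect_equal(GenomicRanges::start(ci), 151L)
  expect_equal(GenomicRanges::end(ci), 300L)
  # duplicated junction: idempotent
  two <- make_jx("c", c(151, 151), c(300, 300))
  expect_equal(as.character(GenomicRanges::granges(consensus_introns(two))),
               as.character(GenomicRanges::granges(ci)))
  # [101,200] x2 and [101,300] x1: segment [101,200] kept at 3/3,
  # [201,300] dropped at 1/3
  mix <- make_jx("c", c(101, 101, 101), c(200, 200, 300))
  cm <- consensus_introns(mix)
  expect_equal(length(cm), 1L)
  expect_equal(GenomicRanges::start(cm), 101L)
  expect_equal(GenomicRanges::end(cm), 200L)
  # consensus introns shorter than the minimum are discarded
  short <- make_jx("c", 101, 115)
  expect_equal(length(consensus_introns(short, min_intron = 20L)), 0L)
})

test_that("intron subtraction reconstructs exon chains", {
  islands <- gr("c", c(1, 301), c(150, 450))
  introns <- gr("c", 151, 300)
  ex <- subtract_introns(islands, introns)
  expect_equal(GenomicRanges::start(ex), c(1L, 301L))
  expect_equal(GenomicRanges::end(ex), c(150L, 450L))
  # intron strictly inside one island splits it
  ex2 <- subtract_introns(gr("c", 1, 450), introns)
  expect_equal(GenomicRanges::start(ex2), c(1L, 301L))
  expect_equal(GenomicRanges::end(ex2), c(150L, 450L))
  # random cases against a position-set oracle
  set.seed(10)
  for (rep in 1:20) {
    isl_starts <- sort(sample(seq(1, 900, by = 100), 3))
    islands_r <- gr("c", isl_starts, isl_starts + sample(30:80, 3))
    intr_starts <- sort(sample(1:900, 2))
    introns_r <- IRanges::reduce(IRanges::IRanges(
      intr_starts, intr_starts + sample(20:60, 2)))
    introns_gr <- GenomicRanges::GRanges("c", introns_r, "+")
    got <- subtract_introns(islands_r, introns_gr)
    pos <- rep(FALSE, 1100)
    hull <- range(c(GenomicRanges::start(islands_r),
                    GenomicRanges::end(islands_r)))
    pos[hull[1]:hull[2]] <- TRUE
    for (k in seq_along(introns_r)) {
      pos[IRanges::start(introns_r)[k]:IRanges::end(introns_r)[k]] <- FALSE
    }
    oracle <- naive_islands(as.integer(pos), 0L, 1L)
    # keep only oracle pieces with island support
    sup <- vapply(seq_len(nrow(oracle)), function(k) {
      any(GenomicRanges::start(islands_r) <= oracle$end[k] &
            GenomicRanges::end(islands_r) >= oracle$start[k])
    }, logical(1))
    oracle <- oracle[sup, , drop = FALSE]
    expect_equal(GenomicRanges::start(got), oracle$start)
    expect_equal(GenomicRanges::end(got), oracle$end)
  }
})

test_that("z-score detector finds sustained drops but ignores short dips", {
  p <- assembly_params()
  # constant signal: no breakpoints
  res <- zscore_breakpoints(rep(50, 300), p)
  expect_equal(length(res$introns), 0L)
  expect_equal(res$trim_right, 300L)
  # sustained dip of 25 bp becomes an intron containing the drop position
  k <- 150L
  y <- rep(50, 300); y[k:(k + 24L)] <- 0
  res2 <- zscore_breakpoints(y, p)
  expect_equal(length(res2$introns), 1L)
  expect_lte(IRanges::start(res2$introns), k)
  expect_gte(IRanges::end(res2$introns), k)
  # 10 bp dip is below the minimum intron length
  y3 <- rep(50, 300); y3[150:159] <- 0
  expect_equal(length(zscore_breakpoints(y3, p)$introns), 0L)
  # drop run touching the segment end trims instead of splitting
  y4 <- rep(50, 300); y4[260:300] <- 0
  res4 <- zscore_breakpoints(y4, p)
  expect_equal(res4$trim_right, 259L)
  expect_equal(length(res4$introns), 0L)
})

test_that("segments not longer than the window pass through untouched", {
  p <- assembly_params()
  for (len in c(30L, 31L, 32L)) {
    y <- c(rep(50, len %/% 2), rep(0, len - len %/% 2))
    res <- zscore_breakpoints(y, p)
    if (len <= p$z_window) {
      expect_equal(length(res$introns) + length(res$peaks), 0L)
      expect_equal(res$trim_right, len)
    } else {
      expect_equal(length(res$flags), len)  # scored, not passed through
    }
  }
})

two_sample_tracks <- function(len, depths_by_region, regions) {
  # identical coverage in both samples over the given regions
  v <- rep(0L, len)
  for (k in seq_along(regions)) {
    v[regions[[k]][1]:regions[[k]][2]] <- depths_by_region[k]
  }
  tr <- coverage_track("c", "+", v)
  list(s1 = list(`+` = list(c = tr)), s2 = list(`+` = list(c = tr)))
}

test_that("monoexonic regions are cross-sample intersections", {
  tracks <- two_sample_tracks(1000, 5L, list(c(1, 250)))
  singles <- list(
    s1 = gr("c", 1, 200),
    s2 = gr("c", 51, 250)
  )
  res <- monoexonic_candidates(singles, tracks)
  expect_equal(length(res$regions), 1L)
  expect_equal(GenomicRanges::start(res$regions), 51L)
  expect_equal(GenomicRanges::end(res$regions), 200L)
  expect_equal(length(res$kept), 1L)

  # islands that do not co-occur across samples are discarded
  singles2 <- list(s1 = gr("c", 1, 200), s2 = gr("c", 501, 700))
  res2 <- monoexonic_candidates(singles2,
                                two_sample_tracks(1000, 5L,
                                                  list(c(1, 700))))
  expect_equal(length(res2$regions), 0L)
})

test_that("only the strict top decile of monoexonic candidates survives", {
  n <- 100L
  regions <- lapply(seq_len(n), function(i) c(i * 500L + 1L, i * 500L + 100L))
  depths <- 3L + seq_len(n)  # distinct length-normalised coverages
  tracks <- two_sample_tracks(60000L, depths, regions)
  singles <- list(
    s1 = gr("c", vapply(regions, `[`, 1L, 1L),
            vapply(regions, `[`, 1L, 2L)),
    s2 = gr("c", vapply(regions, `[`, 1L, 1L),
            vapply(regions, `[`, 1L, 2L))
  )
  res <- monoexonic_candidates(singles, tracks, pr_cutoff = 0.1)
  # independent sort-based oracle: keep c where #{c' > c} / N < 0.1
  cvals <- res$regions$c
  expected_keep <- sort(cvals[vapply(cvals, function(ci)
    mean(cvals > ci) < 0.1, logical(1))])
  expect_equal(sort(res$kept$c), expected_keep)
  expect_equal(length(res$kept), sum(vapply(cvals, function(ci)
    mean(cvals > ci), numeric(1)) < 0.1))
})

test_that("sample merging unions overlaps and enforces replicate presence", {
  info <- data.frame(
    sample = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
    condition = rep(c("A", "B"), each = 4),
    stringsAsFactors = FALSE
  )
  mk <- function(sample, starts, ends, key = "c1") {
    g <- gr("c", starts, ends)
    g$sample_id <- sample
    g$cand_key <- key
    g
  }
  # candidate seen in all four replicates of A only
  ex <- do.call(c, lapply(c("a1", "a2", "a3", "a4"),
                          mk, starts = c(1, 301), ends = c(150, 450)))
  merged <- merge_samples(ex, info)
  expect_equal(nrow(merged$info), 1L)
  expect_true(merged$info$present_A)
  expect_false(merged$info$present_B)

  # 3/4 replicates of A and none of B: dropped
  ex2 <- do.call(c, lapply(c("a1", "a2", "a3"),
                           mk, starts = c(1, 301), ends = c(150, 450)))
  merged2 <- merge_samples(ex2, info)
  expect_equal(nrow(merged2$info), 0L)

  # overlapping same-strand candidates union their exons
  ex3 <- c(
    do.call(c, lapply(info$sample, mk, starts = c(1, 301),
                      ends = c(150, 450))),
    do.call(c, lapply(info$sample, mk, starts = c(101, 301),
                      ends = c(180, 500), key = "c2"))
  )
  merged3 <- merge_samples(ex3, info)
  expect_equal(nrow(merged3$info), 1L)
  mex <- candidate_exons(merged3, merged3$info$gene_id[1])
  expect_equal(GenomicRanges::start(mex), c(1L, 301L))
  expect_equal(GenomicRanges::end(mex), c(180L, 500L))
})
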