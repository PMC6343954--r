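test_that("FPKM follows the closed form and is linear in counts", {
  expect_equal(compute_fpkm(0, 1000, 1e7), 0)
  expect_equal(compute_fpkm(10, 1000, 1e7), 1)
  set.seed(16)
  for (rep in 1:10) {
    cnt <- sample(1:500, 1); len <- sample(200:5000, 1)
    lib <- sample(1e5:1e7, 1)
    expect_equal(compute_fpkm(2 * cnt, len, lib),
                 2 * compute_fpkm(cnt, len, lib))
    expect_equal(compute_fpkm(cnt, len, lib),
                 cnt * 1e9 / (as.numeric(len) * lib))
  }
  expect_error(compute_fpkm(1, 0, 1e6), "length")
  expect_error(compute_fpkm(1, 100, 0), "library")
})

toy_filter_setup <- function(lengths, coding_prob, fpkm_target,
                             present = TRUE) {
  n <- length(lengths)
  exl <- lapply(seq_len(n), function(i) {
    gr("chr1", i * 100000, i * 100000 + lengths[i] - 1L)
  })
  cands <- do.call(toy_candidates, exl)
  cands$info$coding_prob <- coding_prob
  cands$info$present_A <- present
  cands$info$present_B <- FALSE
  info <- data.frame(sample = c("s1", "s2"), condition = c("A", "A"))
  lib <- c(s1 = 1e6, s2 = 1e6)
  # counts chosen so mean FPKM in condition A equals fpkm_target
  counts <- matrix(
    rep(fpkm_target * lengths * 1e6 / 1e9, 2),
    ncol = 2, dimnames = list(cands$info$gene_id, info$sample))
  list(cands = cands, counts = counts, lib = lib, info = info)
}

test_that("length, coding, consistency and expression filters are strict", {
  p <- assembly_params()
  # transcript length at 199 / 200 / 201
  st <- toy_filter_setup(c(199L, 200L, 201L), 0.1, 5)
  res <- apply_filters(st$cands, st$counts, st$lib, st$info, p)
  expect_equal(res$report$kept, c(FALSE, TRUE, TRUE))
  expect_equal(res$report$filter_flag[1], "min_length")

  # mean FPKM exactly at 0.5 fails the strict threshold
  for (f in c(0.49, 0.5, 0.51)) {
    st <- toy_filter_setup(c(1000L, 1000L), 0.1, f)
    res <- apply_filters(st$cands, st$counts, st$lib, st$info, p)
    expect_equal(unique(res$report$kept), f > 0.5)
    if (f <= 0.5) expect_equal(unique(res$report$filter_flag), "min_fpkm")
  }

  # coding probability at the cutoff is coding (kept only when below)
  for (cp in c(0.43, 0.44, 0.45)) {
    st <- toy_filter_setup(1000L, cp, 5)
    res <- apply_filters(st$cands, st$counts, st$lib, st$info, p)
    expect_equal(res$report$kept, cp < 0.44)
  }

  # present in no complete condition
  st <- toy_filter_setup(1000L, 0.1, 5, present = FALSE)
  res <- apply_filters(st$cands, st$counts, st$lib, st$info, p)
  expect_false(res$report$kept)
  expect_equal(res$report$filter_flag, "replicate_consistency")

  # a candidate passing everything carries no flag
  st <- toy_filter_setup(1000L, 0.1, 5)
  res <- apply_filters(st$cands, st$counts, st$lib, st$info, p)
  expect_true(res$report$kept)
  expect_equal(res$report$filter_flag, "")
})

context_fixture <- function() {
  toy_annotation(list(
    list(gene_id = "gPlus", chrom = "chr1", strand = "+",
         starts = c(10001, 15001), ends = c(10600, 15600)),
    list(gene_id = "gFar", chrom = "chr1", strand = "+",
         starts = 40001, ends = 41000)
  ))
}

test_that("genomic context classification partitions candidates", {
  ann <- context_fixture()
  cands <- toy_candidates(
    gr("chr1", 10101, 10400, "-"),      # overlaps gPlus exon, opposite strand
    gr("chr1", 11001, 11400, "+"),      # inside gPlus intron, same strand
    gr("chr1", 46001, 46500, "+"),      # 5 kb downstream of gFar
    gr("chr1", 11001, 11400, "-")       # inside gPlus intron, opposite strand
  )
  out <- classify_context(cands, ann)
  byid <- function(res, id, col) res$info[[col]][res$info$gene_id == id]
  expect_equal(byid(out, "cand01", "class"), "antisense")
  expect_equal(byid(out, "cand02", "class"), "intronic")
  expect_equal(byid(out, "cand03", "class"), "intergenic")
  expect_equal(byid(out, "cand04", "class"), "intronic")
  expect_equal(byid(out, "cand01", "closest_gene_id"), "gPlus")
  expect_equal(byid(out, "cand01", "distance"), 0L)
  expect_equal(byid(out, "cand03", "closest_gene_id"), "gFar")
  expect_equal(byid(out, "cand03", "distance"), 5000L)
  # same-strand-only intronic containment demotes the opposite-strand case
  out2 <- classify_context(cands, ann, intronic_same_strand_only = TRUE)
  expect_equal(byid(out2, "cand04", "class"), "intergenic")
  # every candidate receives exactly one class
  expect_true(all(out$info$class %in%
                    c("antisense", "intergenic", "intronic", "unclassified")))
})

test_that("closest gene matches a brute-force all-pairs scan", {
  set.seed(17)
  genes <- lapply(1:30, function(i) {
    s <- i * 20000L + sample(0:5000, 1)
    list(gene_id = sprintf("g%02d", i), chrom = "chr1",
         strand = sample(c("+", "-"), 1), starts = s, ends = s + 2000L)
  })
  ann <- toy_annotation(genes)
  for (rep in 1:10) {
    s <- sample(8000:580000, 1)
    cand <- toy_candidates(gr("chr1", s, s + 400L, "+"))
    out <- classify_context(cand, ann)
    if (out$info$class[1] != "intergenic") next
    spans <- ann$genes
    dists <- vapply(seq_along(spans), function(k) {
      gs <- GenomicRanges::start(spans)[k]; ge <- GenomicRanges::end(spans)[k]
      if (ge < s) s - ge - 1L else if (gs > s + 400L) gs - (s + 400L) - 1L
      else 0L
    }, numeric(1))
    best <- min(dists)
    ids <- sort(spans$gene_id[dists == best])
    expect_equal(out$info$distance[1], as.integer(best))
    expect_equal(out$info$closest_gene_id[1], ids[1])
  }
})

test_that("candidate sequences are spliced and strand-corrected", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  cands <- toy_candidates(gr("chr1", c(1, 9), c(4, 12), "+"),
                          gr("chr1", 1, 4, "-"))
  seqs <- candidate_sequences(cands, genome)
  expect_equal(unname(seqs["cand01"]), "ACGTACGT")
  expect_equal(unname(seqs["cand02"]), "ACGT")  # revcomp of ACGT is ACGT
  cands2 <- toy_candidates(gr("chr1", 2, 5, "-"))
  expect_equal(unname(candidate_sequences(cands2, genome)[1]), "TACG")
})
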