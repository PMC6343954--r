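test_that("tau has its analytic values and scale invariance", {
  expect_equal(tau(c(5, 0, 0, 0)), 1)
  expect_equal(tau(rep(3.7, 6)), 0)
  set.seed(18)
  for (rep in 1:20) {
    x <- stats::runif(sample(2:12, 1), 0, 50)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(tau(k * x), tau(x))
    expect_equal(tau(x), sum(1 - x / max(x)) / (length(x) - 1))
    expect_gte(tau(x), 0); expect_lte(tau(x), 1)
  }
  expect_error(tau(c(0, 0, 0)), "all-zero")
  expect_error(tau(c(-1, 2)), "non-negative")
  expect_error(tau(5), "two")
})

test_that("tau rises as expression concentrates in one tissue", {
  base <- rep(1, 5)
  taus <- vapply(c(1, 2, 5, 20, 100), function(boost) {
    x <- base; x[1] <- boost; tau(x)
  }, numeric(1))
  expect_true(all(diff(taus) >= 0))
})

test_that("subtype specificity applies strict tau and expression floors", {
  groups <- rep(c("n1", "n2", "n3", "n4"), each = 2)
  mk_row <- function(means) {
    # per-sample values whose log2(x+1) group means equal `means`
    rep(2^means - 1, each = 2)
  }
  mat <- rbind(
    ubiquitous = mk_row(c(4, 4, 4, 4)),
    specific_strong = mk_row(c(6, 0.1, 0.1, 0.1)),
    specific_weak = mk_row(c(2.5, 0.01, 0.01, 0.01)),
    at_floor = mk_row(c(3, 0, 0, 0))
  )
  colnames(mat) <- paste0("s", 1:8)
  res <- subtype_specific(mat, groups)
  expect_false(res$specific[res$feature == "ubiquitous"])
  expect_true(res$specific[res$feature == "specific_strong"])
  # tau passes but the best mean (2.5) misses the strict >3 floor
  expect_false(res$specific[res$feature == "specific_weak"])
  # best mean exactly 3 is excluded (strict)
  expect_false(res$specific[res$feature == "at_floor"])
  # tau exactly at the threshold is excluded: profile engineered to 0.8
  prof <- c(1, rep(1 - 0.8, 4) / 1)  # tau = 0.8 for (1, .2, .2, .2, .2)
  expect_equal(tau(c(1, .2, .2, .2, .2)), 0.8)
  mat2 <- matrix(rep(2^c(5, 5 * .2, 5 * .2, 5 * .2, 5 * .2) - 1, each = 2),
                 nrow = 1, byrow = TRUE)
  colnames(mat2) <- paste0("s", 1:10)
  rownames(mat2) <- "edge"
  res2 <- subtype_specific(mat2, rep(paste0("g", 1:5), each = 2))
  expect_equal(res2$tau, 0.8)
  expect_false(res2$specific)
})

test_that("Fisher enrichment matches hand-computed tables", {
  flat <- enrichment_2x2(10, 10, 10, 10)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)
  diag <- enrichment_2x2(5, 0, 0, 5)
  expect_equal(diag$p_value, 2 / 252)
  expect_equal(diag$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
  expect_error(enrichment_2x2(0, 0, 3, 4), "margin")
})

test_that("Fisher p is invariant under table transposition", {
  set.seed(19)
  for (rep in 1:25) {
    cells <- sample(0:15, 4, replace = TRUE)
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    p1 <- enrichment_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    p2 <- enrichment_2x2(cells[1], cells[3], cells[2], cells[4])$p_value
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("Fisher p agrees with the reference implementation", {
  set.seed(20)
  for (rep in 1:50) {
    cells <- sample(0:20, 4, replace = TRUE)
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    ours <- enrichment_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-7)
  }
})

tss_fixture <- function() {
  cands <- toy_candidates(
    gr("chr1", 10001, 11000, "+"),
    gr("chr1", 50001, 51000, "-"),
    gr("chr1", 90001, 91000, "+")
  )
  tss <- gr("chr1",
            c(10001, 49851, 51000, 90101, 200000),
            c(10001, 49851, 51000, 90101, 200000),
            c("+", "-", "-", "+", "+"))
  list(cands = cands, tss = tss)
}

test_that("TSS distances are strand-oriented and summarised after trimming", {
  fx <- tss_fixture()
  res <- tss_proximity(fx$cands, fx$tss, window = 100)
  d <- res$per_candidate
  expect_equal(d$distance[d$gene_id == "cand01"], 0)      # exactly at 5' end
  # minus-strand candidate: 5' end is the span end; TSS at 51000 sits on it
  expect_equal(d$distance[d$gene_id == "cand02"], 0)
  expect_equal(d$distance[d$gene_id == "cand03"], 100)
  expect_equal(res$fraction_within, 1)

  # a TSS 150 bp upstream on + is distance -150 and outside the window
  res2 <- tss_proximity(toy_candidates(gr("chr1", 10001, 11000, "+")),
                        gr("chr1", 9851, 9851, "+"), window = 100)
  expect_equal(res2$per_candidate$distance, -150)
  expect_equal(res2$fraction_within, 0)

  # record order does not change the summary
  perm <- fx$tss[c(3, 5, 1, 4, 2)]
  res3 <- tss_proximity(fx$cands, perm, window = 100)
  expect_equal(res3$median_distance, res$median_distance)
  expect_equal(sort(res3$per_candidate$distance),
               sort(res$per_candidate$distance))
})

test_that("TSS assignment equals a brute-force nearest scan", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 8
    starts <- sort(sample(seq(1000, 500000, by = 3000), n))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    cands <- do.call(toy_candidates, lapply(seq_len(n), function(i) {
      gr("chr1", starts[i], starts[i] + 800, strands[i])
    }))
    tpos <- sample(1:500000, 40)
    tstr <- sample(c("+", "-"), 40, replace = TRUE)
    tss <- gr("chr1", tpos, tpos, tstr)
    res <- tss_proximity(cands, tss)
    for (i in seq_len(nrow(cands$info))) {
      row <- cands$info[i, ]
      five <- if (row$strand == "-") row$end else row$start
      cand_t <- tpos[tstr == row$strand]
      signed <- (cand_t - five) * (if (row$strand == "-") -1 else 1)
      expect_equal(res$per_candidate$distance[i],
                   signed[which.min(abs(signed))])
    }
  }
})

test_that("neighbour correlation is Pearson on log2 values", {
  expr <- rbind(
    lnc1 = c(1, 4, 9, 20, 33),
    geneA = c(1, 4, 9, 20, 33),
    lnc2 = c(2, 8, 1, 30, 7),
    geneB = c(30, 5, 22, 1, 16)
  )
  colnames(expr) <- paste0("s", 1:5)
  pairs <- data.frame(
    gene_id = c("lnc1", "lnc2"),
    closest_gene_id = c("geneA", "geneB"),
    distance = c(100, 20000)
  )
  res <- neighbor_correlation(pairs, expr)
  expect_equal(res$per_pair$correlation[1], 1)
  expect_lt(res$per_pair$correlation[2], 0)
  manual <- stats::cor(log2(expr["lnc2", ] + 1), log2(expr["geneB", ] + 1))
  expect_equal(res$per_pair$correlation[2], manual)
  expect_error(neighbor_correlation(pairs, expr[, 1:2]), "3 samples")
})

test_that("antisense concordance counts opposite-sign fold changes", {
  pairs <- data.frame(
    lnc_id = sprintf("l%02d", 1:10),
    sense_gene_id = sprintf("g%02d", 1:10),
    lfc_lnc = c(1.2, 1.2, -0.8, 2.0, -1.0, 0.0, 0.5, -0.3, 1.1, -2.2),
    lfc_sense = c(-0.8, 0.3, 0.9, -1.5, -2.0, 1.0, 0.4, 0.2, 0.8, 1.9),
    padj_lnc = c(0.01, 0.5, 0.01, 0.001, 0.2, 0.01, 0.6, 0.04, 0.3, 0.01),
    padj_sense = c(0.02, 0.3, 0.2, 0.004, 0.1, 0.02, 0.5, 0.01, 0.2, 0.03)
  )
  res <- antisense_concordance(pairs)
  # opposite pairs: rows 1, 3, 4, 8, 10 -> fraction 0.5; zero LFC is not
  expect_equal(res$fraction_opposite, 0.5)
  expect_equal(sort(res$significant_opposite$lnc_id),
               c("l01", "l04", "l08", "l10"))
  sub <- pairs[c(1, 2, 5, 6, 7, 9), ]  # 1 opposite of 6
  expect_equal(antisense_concordance(sub)$fraction_opposite, 1 / 6)
})
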