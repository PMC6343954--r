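#' Tau tissue/subtype specificity index
#'
#' For a profile of mean expression values over N tissues,
#' `tau = sum(1 - x_i / max(x)) / (N - 1)`: 0 for a uniform profile, 1
#' when a single tissue carries all expression. Scale-invariant.
#'
#' @param x non-negative numeric profile of length >= 2 with at least one
#'   positive value.
#' @return tau in `[0, 1]`.
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau needs at least two tissues")
  if (any(is.na(x)) || any(x < 0)) stop("tau requires non-negative values")
  mx <- max(x)
  if (mx == 0) stop("tau is undefined for an all-zero profile")
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Subtype-specific features
#'
#' Expression is averaged per subtype (after a `log2(x + 1)` transform by
#' default); a feature is subtype-specific when its tau strictly exceeds
#' `tau_cutoff` and its best subtype mean strictly exceeds
#' `min_mean_log2`.
#'
#' @param mat features x samples expression matrix (non-negative).
#' @param subtypes character vector of subtype labels per sample (>= 2
#'   distinct values).
#' @param tau_cutoff strict tau threshold (default 0.8).
#' @param min_mean_log2 strict floor on the best subtype mean (default 3).
#' @param log2_transform transform values with `log2(x + 1)` before
#'   averaging.
#' @return data.frame per feature: `tau`, `best_subtype`, `best_mean`,
#'   `specific`.
#' @export
subtype_specific <- function(mat, subtypes, tau_cutoff = 0.8,
                             min_mean_log2 = 3, log2_transform = TRUE) {
  stopifnot(ncol(mat) == length(subtypes),
            length(unique(subtypes)) >= 2L)
  vals <- if (log2_transform) log2(mat + 1) else mat
  groups <- unique(subtypes)
  means <- vapply(groups, function(g) {
    rowMeans(vals[, subtypes == g, drop = FALSE])
  }, numeric(nrow(mat)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L)
  taus <- apply(means, 1L, tau)
  best <- apply(means, 1L, which.max)
  best_mean <- means[cbind(seq_len(nrow(means)), best)]
  data.frame(
    feature = rownames(mat),
    tau = taus,
    best_subtype = groups[best],
    best_mean = best_mean,
    specific = taus > tau_cutoff & best_mean > min_mean_log2,
    stringsAsFactors = FALSE
  )
}

#' Two-sided Fisher exact enrichment of a 2x2 table
#'
#' The two-sided p-value sums all hypergeometric point probabilities not
#' exceeding that of the observed table (with a small relative
#' tolerance); the odds ratio is `(a*d)/(b*c)` with the Haldane
#' correction (0.5 added to every cell) when any cell is zero.
#'
#' @param a,b,c,d the table cells: `a` specific among the class of
#'   interest, `b` non-specific in the class, `c` specific among the
#'   reference class, `d` non-specific in the reference.
#' @return List with `odds_ratio` and `p_value`.
#' @export
enrichment_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("degenerate margin in 2x2 table")
  }
  m <- a + c           # first column margin
  n_ <- b + d          # second column margin
  k <- a + b           # first row margin
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(odds_ratio = or, p_value = p)
}

#' TSS proximity of candidate 5-prime ends
#'
#' For each candidate, the nearest same-strand TSS is located and the
#' signed, strand-oriented distance to the candidate's 5-prime end is
#' reported (upstream of the transcript negative). The summary counts the
#' fraction of candidates with a TSS within `window` bp and reports the
#' median and mean distance after removing outliers beyond 1.5 IQR of the
#' quartiles.
#'
#' @param candidates `lnc_candidates`.
#' @param tss GRanges of width-1, strand-tagged TSS positions.
#' @param window proximity window in bp (default 100).
#' @return List with `per_candidate` (data.frame `gene_id`, `distance`),
#'   `fraction_within`, `median_distance`, `mean_distance`,
#'   `distances_trimmed`.
#' @export
tss_proximity <- function(candidates, tss, window = 100L) {
  info <- candidates$info
  dist <- rep(NA_real_, nrow(info))
  for (i in seq_len(nrow(info))) {
    five <- if (info$strand[i] == "-") info$end[i] else info$start[i]
    sel <- as.character(GenomicRanges::strand(tss)) == info$strand[i] &
      as.character(GenomicRanges::seqnames(tss)) == info$chrom[i]
    pos <- GenomicRanges::start(tss[sel])
    if (length(pos) == 0L) next
    signed <- (pos - five) * if (info$strand[i] == "-") -1 else 1
    dist[i] <- signed[which.min(abs(signed))]
  }
  have <- !is.na(dist)
  d <- dist[have]
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  trimmed <- d[d >= q[1] - 1.5 * iqr & d <= q[2] + 1.5 * iqr]
  list(
    per_candidate = data.frame(gene_id = info$gene_id, distance = dist,
                               stringsAsFactors = FALSE),
    fraction_within = mean(abs(d) <= window),
    median_distance = stats::median(trimmed),
    mean_distance = mean(trimmed),
    distances_trimmed = trimmed
  )
}

#' Expression correlation with the closest genomic neighbour
#'
#' Pearson correlation on `log2(x + 1)`-transformed expression across
#' samples between each (typically intergenic) candidate and its closest
#' gene, plus the Spearman association between neighbour distance and
#' correlation.
#'
#' @param pairs data.frame with `gene_id`, `closest_gene_id`, `distance`.
#' @param expr expression matrix covering candidates and neighbours
#'   (rownames = feature ids; >= 3 samples).
#' @return List with `per_pair` (adds `correlation`) and `association`
#'   (`rho`, `p_value` of Spearman distance-correlation test).
#' @export
neighbor_correlation <- function(pairs, expr) {
  if (ncol(expr) < 3L) stop("need at least 3 samples for correlations")
  vals <- log2(expr + 1)
  cor_i <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_id[i]; b <- pairs$closest_gene_id[i]
    if (a %in% rownames(vals) && b %in% rownames(vals)) {
      cor_i[i] <- stats::cor(vals[a, ], vals[b, ])
    }
  }
  pairs$correlation <- cor_i
  ok <- !is.na(cor_i) & !is.na(pairs$distance)
  assoc <- if (sum(ok) >= 3L) {
    ct <- suppressWarnings(stats::cor.test(pairs$distance[ok], cor_i[ok],
                                           method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  list(per_pair = pairs, association = assoc)
}

#' Antisense/sense fold-change concordance
#'
#' The fraction of antisense lncRNA / sense gene pairs whose log2 fold
#' changes have opposite signs (a zero fold change counts as
#' non-opposite), and the subset where both members are significant
#' (adjusted p < `alpha`) with opposite signs.
#'
#' @param pairs data.frame with columns `lnc_id`, `sense_gene_id`,
#'   `lfc_lnc`, `lfc_sense`, `padj_lnc`, `padj_sense`.
#' @param alpha significance cutoff on the adjusted p-values.
#' @return List with `fraction_opposite` and `significant_opposite`
#'   (data.frame subset).
#' @export
antisense_concordance <- function(pairs, alpha = 0.05) {
  opposite <- pairs$lfc_lnc * pairs$lfc_sense < 0
  sig <- opposite & pairs$padj_lnc < alpha & pairs$padj_sense < alpha
  list(
    fraction_opposite = mean(opposite),
    significant_opposite = pairs[which(sig), , drop = FALSE]
  )
}
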