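# Fickett TESTCODE lookup tables: probability that a window of given
# positional asymmetry / composition is coding, with the published
# per-base weights. Position bins are (>=1.9, >=1.8, ..., >=1.1, <1.1),
# content bins (>=0.33, >=0.31, ..., >=0.19, <0.19).
.fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_position_breaks <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1)
.fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickett_content_breaks <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21,
                             0.19, 0.17)

fickett_bin <- function(value, breaks) {
  # first bin whose lower bound the value reaches; last bin otherwise
  hit <- which(value >= breaks)
  if (length(hit)) hit[1] else length(breaks) + 1L
}

#' Fickett TESTCODE statistic
#'
#' Computes the classic positional-asymmetry / composition statistic from
#' the published lookup tables. For each base the position parameter is
#' `max(c1,c2,c3)/(min(c1,c2,c3)+1)` over the three codon positions and
#' the content parameter is the base frequency; both are converted to
#' coding probabilities by table lookup and combined with the published
#' weights. Case-insensitive; deterministic.
#'
#' @param sequence a single DNA string (A/C/G/T/N).
#' @return The Fickett score (higher = more coding-like).
#' @export
fickett_score <- function(sequence) {
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(s)
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    hit <- s == base
    idx <- which(hit)
    phase_counts <- tabulate(((idx - 1L) %% 3L) + 1L, nbins = 3L)
    pos_param <- max(phase_counts) / (min(phase_counts) + 1)
    content <- sum(hit) / n
    pb <- fickett_bin(pos_param, .fickett_position_breaks)
    cb <- fickett_bin(content, .fickett_content_breaks)
    score <- score +
      .fickett_position_prob[[base]][pb] * .fickett_position_weight[[base]] +
      .fickett_content_prob[[base]][cb] * .fickett_content_weight[[base]]
  }
  score
}

#' Longest open reading frame on the sense strand
#'
#' Scans the three forward frames for the longest ATG..(TAA|TAG|TGA) open
#' reading frame; the stop codon is included in the length. Transcripts
#' are stranded, so only the sense strand is considered.
#'
#' @param sequence a single DNA string.
#' @return List with `orf_length` (nt, 0 when no complete ORF) and
#'   `orf_coverage` (fraction of the transcript).
#' @export
longest_orf <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  best <- 0L
  if (n >= 6L) {
    chars <- strsplit(s, "")[[1]]
    for (frame in 0:2) {
      starts <- seq.int(1L + frame, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      if (!any(is_atg) || !any(is_stop)) next
      # for each ATG, the first stop codon at or after it
      stops <- which(is_stop)
      atg_idx <- which(is_atg)
      pos <- findInterval(atg_idx - 1L, stops) + 1L
      stop_idx <- ifelse(pos <= length(stops), stops[pos], NA_integer_)
      ok <- !is.na(stop_idx)
      if (any(ok)) {
        len <- (stop_idx[ok] - atg_idx[ok] + 1L) * 3L
        best <- max(best, max(len))
      }
    }
  }
  list(orf_length = as.integer(best),
       orf_coverage = if (n > 0L) best / n else 0)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  grid <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  # first factor varies fastest in expand.grid; reorder for lexicographic
  apply(grid[, 6:1], 1L, paste0, collapse = "")
}

sequence_hexamers <- function(sequence, step = 3L) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n < 6L) return(character(0))
  starts <- seq.int(1L, n - 5L, by = step)
  substring(s, starts, starts + 5L)
}

#' Train a hexamer usage table
#'
#' In-frame (step 3) hexamer frequencies are tabulated for a coding and a
#' noncoding sequence set; the table maps each of the 4096 hexamers to
#' `log((f_coding + p) / (f_noncoding + p))` where `f` are relative
#' frequencies and `p` a pseudocount.
#'
#' @param coding,noncoding character vectors (or `DNAStringSet`) of
#'   training sequences.
#' @param pseudocount smoothing constant added to both relative
#'   frequencies.
#' @return Named numeric vector over all 4096 hexamers.
#' @export
train_hexamer_table <- function(coding, noncoding, pseudocount = 1e-4) {
  coding <- as.character(coding); noncoding <- as.character(noncoding)
  if (length(coding) == 0L || length(noncoding) == 0L) {
    stop("both training classes must be non-empty")
  }
  hx <- all_hexamers()
  freq_of <- function(seqs) {
    counts <- table(factor(unlist(lapply(seqs, sequence_hexamers)),
                           levels = hx))
    as.numeric(counts) / max(1L, sum(counts))
  }
  f_c <- freq_of(coding)
  f_n <- freq_of(noncoding)
  stats::setNames(log((f_c + pseudocount) / (f_n + pseudocount)), hx)
}

#' Mean hexamer log-ratio of a sequence
#'
#' Averages the table values of the in-frame (step 3) hexamers of the
#' sequence; hexamers containing unknown letters are skipped.
#'
#' @param sequence a single DNA string.
#' @param hexamer_table named vector from [train_hexamer_table()].
#' @return Mean log-ratio (0 for sequences with no scorable hexamer).
#' @export
hexamer_bias <- function(sequence, hexamer_table) {
  hx <- sequence_hexamers(sequence)
  vals <- hexamer_table[hx]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(0)
  mean(vals)
}

#' Coding features of a transcript sequence
#'
#' @param sequence a single DNA string (sense strand).
#' @param hexamer_table named vector from [train_hexamer_table()].
#' @return data.frame row: `orf_length`, `orf_coverage`, `fickett`,
#'   `hexamer`.
#' @export
coding_features <- function(sequence, hexamer_table) {
  orf <- longest_orf(sequence)
  data.frame(
    orf_length = orf$orf_length,
    orf_coverage = orf$orf_coverage,
    fickett = fickett_score(sequence),
    hexamer = hexamer_bias(sequence, hexamer_table)
  )
}

#' Train the coding-potential logistic model
#'
#' Fits a logistic regression of coding status on ORF length, ORF
#' coverage, Fickett score and hexamer bias by maximum likelihood.
#' Training is deterministic given the input sets.
#'
#' @param coding,noncoding character vectors (or `DNAStringSet`) of
#'   labelled training sequences (at least a handful per class).
#' @param pseudocount pseudocount for the hexamer table.
#' @param cutoff probability cutoff below which a transcript is called
#'   noncoding.
#' @return Object of class `coding_model`: list with `hexamer_table`,
#'   `coefficients` (intercept + 4 slopes) and `cutoff`.
#' @export
train_coding_model <- function(coding, noncoding, pseudocount = 1e-4,
                               cutoff = 0.44) {
  coding <- as.character(coding); noncoding <- as.character(noncoding)
  if (length(coding) == 0L || length(noncoding) == 0L) {
    stop("both training classes must be non-empty")
  }
  tbl <- train_hexamer_table(coding, noncoding, pseudocount)
  feats <- do.call(rbind, lapply(c(coding, noncoding), coding_features,
                                 hexamer_table = tbl))
  feats$label <- rep(c(1L, 0L), c(length(coding), length(noncoding)))
  fit <- suppressWarnings(stats::glm(
    label ~ orf_length + orf_coverage + fickett + hexamer,
    data = feats, family = stats::binomial()
  ))
  structure(list(
    hexamer_table = tbl,
    coefficients = stats::coef(fit),
    cutoff = cutoff
  ), class = "coding_model")
}

#' Coding probability of transcript sequences
#'
#' Applies the logistic model to the four coding features of each
#' sequence.
#'
#' @param sequences character vector (or `DNAStringSet`).
#' @param model `coding_model` from [train_coding_model()], or a list
#'   with `coefficients` (length 5: intercept, orf_length, orf_coverage,
#'   fickett, hexamer), `hexamer_table` and `cutoff`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
coding_probability <- function(sequences, model) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) return(numeric(0))
  feats <- do.call(rbind, lapply(sequences, coding_features,
                                 hexamer_table = model$hexamer_table))
  eta <- model$coefficients[1] +
    as.matrix(feats[, c("orf_length", "orf_coverage", "fickett",
                        "hexamer")]) %*% model$coefficients[-1]
  as.numeric(stats::plogis(eta))
}

#' @rdname coding_probability
#' @return `is_noncoding()`: logical vector, `TRUE` when the probability
#'   is below the model cutoff.
#' @export
is_noncoding <- function(sequences, model) {
  coding_probability(sequences, model) < model$cutoff
}
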