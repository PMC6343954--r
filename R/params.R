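#' Assembly and filtering parameters
#'
#' Bundles every tunable threshold of the discovery pipeline. Defaults are
#' the working values of the method: splice junctions need more than 2
#' uniquely mapped supporting reads and an intron length strictly between
#' 20 and 100,000 bp; gene models are extended by a 1000 bp flank before
#' masking; islands of expression need depth strictly greater than 2 over
#' at least 100 bp (one read length); the smoothed z-score detector uses a
#' 31 bp window, a drop threshold of 5 and a minimum intron of 20 bp;
#' transcripts shorter than 200 bp are discarded, the expression floor is
#' 0.5 FPKM (strict) in the best condition, and monoexonic candidates must
#' sit in the top decile (Pr(>) < 0.1) of their population.
#'
#' @param sj_min_unique_reads minimum unique read support (kept iff
#'   `unique_reads >= sj_min_unique_reads`, i.e. strictly more than 2 with
#'   the default of 3).
#' @param sj_min_length minimum intron length in bp (inclusive).
#' @param sj_max_length maximum intron length in bp (inclusive).
#' @param flank_bp gene-model extension applied on each side before masking.
#' @param mask_mode `"span"` masks whole gene spans (intergenic/antisense
#'   discovery); `"exon_union"` masks only exon unions so that intronic
#'   transcription remains visible.
#' @param depth_threshold island depth threshold, strict (`depth > threshold`).
#' @param min_island_length minimum island length in bp.
#' @param z_window smoothing window of the z-score detector (odd, bp).
#' @param z_drop_threshold number of (floored) standard deviations a
#'   position must fall below the rolling mean to be flagged as a drop.
#' @param z_min_intron minimum length of a drop run to be called an intron.
#' @param z_sd_floor floor applied to the rolling standard deviation so
#'   flat signals do not produce zero-variance blowups.
#' @param consensus_fraction strict-majority fraction for consensus-intron
#'   segments.
#' @param junction_tolerance_bp tolerance when attaching junction ends to
#'   island edges.
#' @param min_transcript_length minimum reconstructed transcript length.
#' @param min_fpkm expression floor; candidates must exceed this mean FPKM
#'   in at least one condition (strict `>`).
#' @param monoexonic_pr_cutoff upper-tail probability cutoff for the
#'   monoexonic length-normalised coverage filter (strict `<`).
#' @param coding_cutoff logistic-probability cutoff below which a
#'   transcript is called noncoding (CPAT-style mouse default).
#' @param read_length_bp sequencing read length; informs the default
#'   island length and coverage-based quantification.
#'
#' @return An object of class `assembly_params` (a validated list).
#' @export
assembly_params <- function(sj_min_unique_reads = 3L,
                            sj_min_length = 21L,
                            sj_max_length = 99999L,
                            flank_bp = 1000L,
                            mask_mode = c("span", "exon_union"),
                            depth_threshold = 2,
                            min_island_length = 100L,
                            z_window = 31L,
                            z_drop_threshold = 5,
                            z_min_intron = 20L,
                            z_sd_floor = 1,
                            consensus_fraction = 0.5,
                            junction_tolerance_bp = 10L,
                            min_transcript_length = 200L,
                            min_fpkm = 0.5,
                            monoexonic_pr_cutoff = 0.1,
                            coding_cutoff = 0.44,
                            read_length_bp = 100L) {
  mask_mode <- match.arg(mask_mode)
  p <- list(
    sj_min_unique_reads = as.integer(sj_min_unique_reads),
    sj_min_length = as.integer(sj_min_length),
    sj_max_length = as.integer(sj_max_length),
    flank_bp = as.integer(flank_bp),
    mask_mode = mask_mode,
    depth_threshold = depth_threshold,
    min_island_length = as.integer(min_island_length),
    z_window = as.integer(z_window),
    z_drop_threshold = z_drop_threshold,
    z_min_intron = as.integer(z_min_intron),
    z_sd_floor = z_sd_floor,
    consensus_fraction = consensus_fraction,
    junction_tolerance_bp = as.integer(junction_tolerance_bp),
    min_transcript_length = as.integer(min_transcript_length),
    min_fpkm = min_fpkm,
    monoexonic_pr_cutoff = monoexonic_pr_cutoff,
    coding_cutoff = coding_cutoff,
    read_length_bp = as.integer(read_length_bp)
  )
  stopifnot(
    p$sj_min_unique_reads >= 0L,
    p$sj_min_length > 0L,
    p$sj_max_length >= p$sj_min_length,
    p$flank_bp >= 0L,
    p$min_island_length > 0L,
    p$z_window > 0L,
    p$z_window %% 2L == 1L,
    p$z_drop_threshold > 0,
    p$z_min_intron > 0L,
    p$consensus_fraction > 0,
    p$consensus_fraction < 1,
    p$junction_tolerance_bp >= 0L,
    p$min_transcript_length > 0L,
    p$coding_cutoff > 0,
    p$coding_cutoff < 1
  )
  structure(p, class = "assembly_params")
}

#' Synthetic-data simulation configuration
#'
#' Defines the study conditions emulated by the generator: a small
#' two-chromosome genome carrying annotated multi-exon coding genes and
#' planted novel lncRNAs of each genomic-context class, profiled in two
#' conditions with three replicates each from dUTP-stranded libraries.
#' Planted lncRNAs are expressed roughly tenfold lower than coding genes
#' and their exon count is skewed towards biexonic structures. Coding-like
#' decoy transcripts (long, codon-biased open reading frames) are planted
#' alongside to exercise the coding-potential filter.
#'
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_coding_genes annotated multi-exon coding genes (split evenly
#'   across chromosomes).
#' @param n_antisense,n_intergenic,n_intronic,n_monoexonic planted novel
#'   lncRNAs per genomic-context class (monoexonic features are placed in
#'   intergenic space).
#' @param n_decoys planted coding-like decoy transcripts.
#' @param depth_range per-feature target plateau coverage (uniform draw).
#' @param junction_support_range unique-read support per junction per
#'   sample (uniform draw).
#' @param n_conditions,n_samples_per_condition experimental design.
#' @param noise_runs_per_100kb sparse low-depth background runs per strand,
#'   all shorter than the minimum island length.
#' @param lnc_coding_ratio expression of lncRNAs relative to coding genes.
#' @param antisense_flip_fraction fraction of planted antisense lncRNAs
#'   whose condition effect has the opposite sign to their sense gene.
#' @param dispersion negative-binomial dispersion of simulated counts.
#' @param read_length_bp read length assumed by the evidence simulator.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 7L,
                              n_chromosomes = 2L,
                              chrom_length = 1e6,
                              n_coding_genes = 40L,
                              n_antisense = 6L,
                              n_intergenic = 15L,
                              n_intronic = 6L,
                              n_monoexonic = 3L,
                              n_decoys = 10L,
                              depth_range = c(8, 20),
                              junction_support_range = c(5, 15),
                              n_conditions = 2L,
                              n_samples_per_condition = 3L,
                              noise_runs_per_100kb = 5,
                              lnc_coding_ratio = 0.1,
                              antisense_flip_fraction = 0.4,
                              dispersion = 0.1,
                              read_length_bp = 100L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_coding_genes = as.integer(n_coding_genes),
    n_antisense = as.integer(n_antisense),
    n_intergenic = as.integer(n_intergenic),
    n_intronic = as.integer(n_intronic),
    n_monoexonic = as.integer(n_monoexonic),
    n_decoys = as.integer(n_decoys),
    depth_range = as.numeric(depth_range),
    junction_support_range = as.numeric(junction_support_range),
    n_conditions = as.integer(n_conditions),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    noise_runs_per_100kb = noise_runs_per_100kb,
    lnc_coding_ratio = lnc_coding_ratio,
    antisense_flip_fraction = antisense_flip_fraction,
    dispersion = dispersion,
    read_length_bp = as.integer(read_length_bp)
  )
  stopifnot(
    cfg$n_chromosomes >= 1L,
    cfg$chrom_length >= 1e5,
    length(cfg$depth_range) == 2L,
    cfg$depth_range[1] >= 3,
    cfg$n_conditions >= 1L,
    cfg$n_samples_per_condition >= 1L,
    cfg$lnc_coding_ratio > 0
  )
  structure(cfg, class = "simulation_config")
}

#' Number of planted lncRNAs in a simulation configuration
#' @param config a [simulation_config()].
#' @return Integer count over all classes.
#' @export
n_planted <- function(config) {
  config$n_antisense + config$n_intergenic + config$n_intronic +
    config$n_monoexonic
}
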