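#' Run the whole discovery pipeline from files on disk
#'
#' File-based driver around [run_lncrna_pipeline()]: reads the
#' annotation GTF, genome FASTA, per-sample stranded bedGraphs and
#' SJ.out.tab files listed in a samples table, trains the
#' coding-potential model from the supplied training FASTAs, executes
#' every stage in order, and writes the final GTF, a per-candidate
#' filter report and a machine-readable run manifest (parameter
#' snapshot, input digests, per-stage feature counts). Output is
#' deterministic: re-running on identical inputs reproduces the GTF
#' byte for byte.
#'
#' @param config named list or path to a YAML file with keys
#'   `annotation_gtf`, `genome_fasta`, `samples_tsv` (columns `sample`,
#'   `condition`, `bedgraph_plus`, `bedgraph_minus`, `sj`; file paths
#'   relative to the table's directory), `training_coding_fasta`,
#'   `training_noncoding_fasta`, optional `counts_tsv` (library sizes
#'   are its column sums) and optional `params` (overrides for
#'   [assembly_params()]).
#' @param out_dir output directory.
#' @return Invisibly, the [run_lncrna_pipeline()] result with an added
#'   `paths` element.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  required <- c("annotation_gtf", "genome_fasta", "samples_tsv",
                "training_coding_fasta", "training_noncoding_fasta")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop("config is missing keys: ", paste(missing_keys, collapse = ", "))
  }
  inputs <- unlist(config[required])
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) {
    stop("missing input file(s): ", paste(absent, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  params <- do.call(assembly_params, as.list(config$params))
  annotation <- read_gtf(config$annotation_gtf)
  genome <- Biostrings::readDNAStringSet(config$genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqlengths <- stats::setNames(Biostrings::width(genome), names(genome))
  samples_df <- utils::read.table(config$samples_tsv, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
  base <- dirname(config$samples_tsv)
  resolve <- function(f) ifelse(file.exists(f), f, file.path(base, f))

  message("reading evidence for ", nrow(samples_df), " samples")
  tracks <- list(); junctions <- list()
  input_files <- inputs
  for (i in seq_len(nrow(samples_df))) {
    s <- samples_df$sample[i]
    tracks[[s]] <- list()
    for (strand in c("+", "-")) {
      col <- if (strand == "+") "bedgraph_plus" else "bedgraph_minus"
      f <- resolve(samples_df[[col]][i])
      input_files <- c(input_files, f)
      gr <- read_bedgraph(f)
      tracks[[s]][[strand]] <- coverage_from_bedgraph(
        gr, strand, seqlengths = seqlengths, sample_id = s)
    }
    fj <- resolve(samples_df$sj[i])
    input_files <- c(input_files, fj)
    junctions[[s]] <- read_sj_tab(fj)
  }

  coding_model <- train_coding_model(
    as.character(Biostrings::readDNAStringSet(config$training_coding_fasta)),
    as.character(Biostrings::readDNAStringSet(
      config$training_noncoding_fasta)),
    cutoff = params$coding_cutoff)

  library_sizes <- NULL
  if (!is.null(config$counts_tsv) && file.exists(config$counts_tsv)) {
    library_sizes <- colSums(read_counts_tsv(config$counts_tsv))
    input_files <- c(input_files, config$counts_tsv)
  }

  res <- run_lncrna_pipeline(annotation, tracks, junctions, genome,
                             coding_model, samples_df,
                             library_sizes = library_sizes,
                             params = params)
  for (nm in names(res$stage_counts)) {
    message(sprintf("stage %-18s %d", nm, res$stage_counts[[nm]]))
  }

  gtf_path <- file.path(out_dir, "novel_lncRNAs.gtf")
  write_gtf(res$candidates, gtf_path)
  report_path <- file.path(out_dir, "filter_report.tsv")
  utils::write.table(res$report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    parameters = unclass(params),
    inputs = as.list(tools::md5sum(unique(input_files))),
    stage_counts = as.list(res$stage_counts),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)), manifest_path)
  }
  res$paths <- list(gtf = gtf_path, report = report_path,
                    manifest = manifest_path)
  invisible(res)
}
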