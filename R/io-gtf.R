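#' Read gene models from a GTF file
#'
#' Parses a 9-column GTF into one gene model per `gene_id`: a gene span
#' plus the merged union of its exon records. Coordinates are kept in the
#' 1-based inclusive convention used by `GRanges`. The RefSeq dialect
#' accepts either a `gene_id` or a `gene` attribute key (first match
#' wins); the ENSEMBL dialect requires `gene_id`.
#'
#' @param path GTF file.
#' @param dialect `"ensembl"` or `"refseq"`.
#' @return An object of class `lnc_annotation`: a list with `genes`
#'   (GRanges of gene spans, metadata `gene_id`, `biotype`) and `exons`
#'   (GRanges with metadata `gene_id`), both sorted.
#' @export
read_gtf <- function(path, dialect = c("ensembl", "refseq")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_annotation(GenomicRanges::GRanges(), GenomicRanges::GRanges()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- line_no[which(nf != 9L)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated columns")
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  strand <- m[, 7]
  bad_strand <- !(strand %in% c("+", "-", "."))
  if (any(bad_strand)) {
    stop("unknown strand symbol '", strand[which(bad_strand)[1]],
         "' at GTF line ", line_no[which(bad_strand)[1]])
  }
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1]]
    stop("malformed GTF line ", bad, ": non-integer coordinates")
  }
  keys <- if (dialect == "refseq") c("gene_id", "gene") else "gene_id"
  gene_id <- rep(NA_character_, nrow(m))
  for (k in keys) {
    hit <- is.na(gene_id)
    if (!any(hit)) break
    gene_id[hit] <- gtf_attribute(m[hit, 9], k)
  }
  if (anyNA(gene_id)) {
    bad <- line_no[which(is.na(gene_id))[1]]
    stop("malformed GTF line ", bad, ": no gene identifier attribute")
  }
  biotype <- gtf_attribute(m[, 9], "gene_biotype")
  bt2 <- gtf_attribute(m[, 9], "biotype")
  biotype[is.na(biotype)] <- bt2[is.na(biotype)]
  biotype[is.na(biotype)] <- "unknown"

  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = ifelse(strand == ".", "*", strand)
  )
  gr$gene_id <- gene_id
  gr$feature <- m[, 3]
  gr$biotype <- biotype

  ex <- gr[gr$feature == "exon"]
  # genes without explicit exon rows contribute their own row as one exon
  no_exon <- setdiff(gene_id, ex$gene_id)
  if (length(no_exon)) {
    ex <- c(ex, gr[gr$gene_id %in% no_exon & gr$feature != "transcript"])
  }
  ex_by_gene <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(ex), ex$gene_id)
  )
  exons <- BiocGenerics::unlist(ex_by_gene, use.names = FALSE)
  exons$gene_id <- rep(names(ex_by_gene), lengths(ex_by_gene))

  span_by_gene <- BiocGenerics::unlist(range(ex_by_gene), use.names = FALSE)
  genes <- span_by_gene
  genes$gene_id <- names(ex_by_gene)
  bt_map <- tapply(biotype, gene_id, function(x) x[1])
  genes$biotype <- unname(bt_map[genes$gene_id])

  new_annotation(genes, exons)
}

new_annotation <- function(genes, exons) {
  if (length(genes)) genes <- BiocGenerics::sort(genes)
  if (length(exons)) exons <- BiocGenerics::sort(exons)
  structure(list(genes = genes, exons = exons), class = "lnc_annotation")
}

#' @export
print.lnc_annotation <- function(x, ...) {
  cat("lnc_annotation:", length(x$genes), "gene models,",
      length(x$exons), "merged exons\n")
  invisible(x)
}

gtf_attribute <- function(attrs, key) {
  pat <- paste0('(^|; ?)', key, ' "([^"]*)"')
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(g) {
    if (length(g) >= 3L) g[3] else NA_character_
  }, character(1))
}

#' Write transcript candidates as a three-level GTF
#'
#' Emits one `gene`, one `transcript` and one `exon` row per exon for each
#' candidate, 1-based inclusive coordinates, attributes `gene_id` and
#' `transcript_id` (the transcript id is `<gene_id>.t1`; the pipeline
#' works at the gene level so there is exactly one transcript per gene).
#' Re-reading the file with [read_gtf()] reproduces identical intervals.
#'
#' @param candidates an `lnc_candidates` object (see [candidates_from_exons()]).
#' @param path output file.
#' @param source source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(candidates, path, source = "lncislands") {
  stopifnot(inherits(candidates, "lnc_candidates"))
  con <- try(file(path, open = "wt"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open '", path, "' for writing")
  on.exit(close(con))
  info <- candidates$info
  ex <- candidates$exons
  rows <- character(0)
  for (i in seq_len(nrow(info))) {
    gid <- info$gene_id[i]
    e <- ex[ex$gene_id == gid]
    e <- BiocGenerics::sort(e)
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    strand <- as.character(GenomicRanges::strand(e))[1]
    gs <- min(GenomicRanges::start(e)); ge <- max(GenomicRanges::end(e))
    a_gene <- sprintf('gene_id "%s";', gid)
    a_tx <- sprintf('gene_id "%s"; transcript_id "%s.t1";', gid, gid)
    rows <- c(rows,
      paste(chrom, source, "gene", gs, ge, ".", strand, ".", a_gene,
            sep = "\t"),
      paste(chrom, source, "transcript", gs, ge, ".", strand, ".", a_tx,
            sep = "\t"),
      paste(chrom, source, "exon",
            GenomicRanges::start(e), GenomicRanges::end(e), ".", strand, ".",
            sprintf('%s exon_number "%d";', a_tx,
                    seq_along(e)),
            sep = "\t"))
  }
  writeLines(rows, con)
  invisible(path)
}
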