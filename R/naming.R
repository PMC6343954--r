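#' Construct the display name of a novel lncRNA
#'
#' Names follow the scheme
#' `<closest or sense gene>_LNCRNA[_IG|_IN]:<chr>:<start>-<end>(<strand>)`
#' with 1-based inclusive coordinates: intergenic candidates carry the
#' `IG` tag, intronic candidates an `IN` tag, and antisense candidates no
#' tag (the prefixed gene is then the sense gene on the opposite strand).
#' The strand is rendered as ASCII `+`/`-`.
#'
#' @param gene_id closest (or sense) gene identifier.
#' @param class one of `"antisense"`, `"intergenic"`, `"intronic"`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive span of the candidate.
#' @param strand `"+"` or `"-"`.
#' @return A single name string.
#' @seealso [parse_name()] for the inverse.
#' @export
make_name <- function(gene_id, class, chrom, start, end, strand) {
  stopifnot(length(class) == length(gene_id))
  if (any(!class %in% c("antisense", "intergenic", "intronic"))) {
    stop("cannot name an unclassified candidate")
  }
  tag <- c(antisense = "", intergenic = "_IG", intronic = "_IN")[class]
  sprintf("%s_LNCRNA%s:%s:%d-%d(%s)", gene_id, tag, chrom,
          as.integer(start), as.integer(end), strand)
}

#' Parse a lncRNA display name back into its parts
#'
#' Accepts the unicode minus sign as equivalent to ASCII `-` in the
#' strand field.
#'
#' @param name name string produced by [make_name()].
#' @return data.frame with columns `gene_id`, `class`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
parse_name <- function(name) {
  name <- gsub("\u2212", "-", name)
  pat <- "^(.*)_LNCRNA(_IG|_IN)?:([^:]+):([0-9]+)-([0-9]+)\\(([+-])\\)$"
  m <- regexec(pat, name)
  parts <- regmatches(name, m)
  if (any(lengths(parts) == 0L)) {
    stop("unparseable lncRNA name: ", name[which(lengths(parts) == 0L)[1]])
  }
  p <- do.call(rbind, parts)
  class <- c("_IG" = "intergenic", "_IN" = "intronic")[p[, 3]]
  class[is.na(class)] <- "antisense"
  data.frame(
    gene_id = p[, 2],
    class = unname(class),
    chrom = p[, 4],
    start = as.integer(p[, 5]),
    end = as.integer(p[, 6]),
    strand = p[, 7],
    stringsAsFactors = FALSE
  )
}
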