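#' Read variant records from VCF
#'
#' Parses a VCF into a variant table with 0-based positions; all other
#' fields (ID, QUAL, FILTER, INFO, and any genotype columns) are carried
#' through untouched so that [write_vcf()] reproduces them.
#'
#' @param path Path to a VCF file (optionally gzipped).
#' @return A data.frame with columns `seq_id`, `pos` (0-based), `id`,
#'   `ref`, `alt`, `qual`, `filter`, `info`; the header lines are the
#'   `"meta"` attribute and genotype columns (FORMAT + samples), when
#'   present, the `"gt"` attribute.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # vcfR does not accept completely variant-free files gracefully in all
  # versions; probe first
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  meta <- lines[startsWith(lines, "##")]
  if (length(body) == 0L) {
    df <- data.frame(seq_id = character(0), pos = integer(0),
                     id = character(0), ref = character(0),
                     alt = character(0), qual = character(0),
                     filter = character(0), info = character(0),
                     stringsAsFactors = FALSE)
    attr(df, "meta") <- meta
    return(df)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  df <- data.frame(
    seq_id = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    id = fix$ID, ref = fix$REF, alt = fix$ALT,
    qual = fix$QUAL, filter = fix$FILTER, info = fix$INFO,
    stringsAsFactors = FALSE)
  attr(df, "meta") <- v@meta
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) > 0L) attr(df, "gt") <- gt
  df
}

#' Write variant records as VCF
#'
#' Inverse of [read_vcf()]: positions go back to 1-based, pass-through
#' fields and header lines are emitted unchanged.
#'
#' @param variants Data.frame as returned by [read_vcf()] (or with at
#'   least `seq_id`, `pos`, `ref`, `alt`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  meta <- attr(variants, "meta")
  if (is.null(meta) || length(meta) == 0L) {
    meta <- "##fileformat=VCFv4.2"
  }
  gt <- attr(variants, "gt")
  miss <- function(x, default = ".") {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- default
    x
  }
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                    "FILTER", "INFO",
                    if (!is.null(gt)) colnames(gt)), collapse = "\t")
  lines <- c(meta, header)
  if (nrow(variants) > 0L) {
    fields <- cbind(
      variants$seq_id,
      as.character(variants$pos + 1L),
      miss(variants$id %||% "."),
      variants$ref,
      miss(variants$alt %||% "."),
      miss(variants$qual %||% "."),
      miss(variants$filter %||% "."),
      miss(variants$info %||% "."))
    if (!is.null(gt)) fields <- cbind(fields, apply(gt, 2L, miss))
    lines <- c(lines, apply(fields, 1L, paste, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
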