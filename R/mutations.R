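#' Read base-pair substitutions from a TSV or VCF file
#'
#' Only single-base substitutions are in scope: records whose REF or ALT is
#' not a single A/C/G/T base (indels, MNVs, multi-allelic sites) are
#' rejected with a logged tally, available as `attr(x, "rejected")`.
#'
#' TSV input requires columns `chrom`, `pos` (1-based), `ref`, `alt`;
#' optional columns `qual`, `mutant_read_fraction` (or `fraction`),
#' `strain`, `lineage`, `condition` are carried through. For VCF input the
#' mutant-read fraction is taken from the INFO field named by
#' `fraction_field` (VCF dialects differ in where they record it).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param fraction_field INFO key holding the mutant-read fraction in VCF
#'   input.
#' @return a data frame with columns `chrom`, `pos` (0-based internal
#'   coordinate), `ref`, `alt`, `qual`, `mutant_read_fraction`, `strain`,
#'   `lineage`, `condition`; attribute `rejected` counts skipped records.
#' @export
read_mutations <- function(path, format = c("auto", "tsv", "vcf"),
                           fraction_field = "AF") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("mutation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "vcf") "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) return(empty_mutations())
    frac <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = fraction_field)))
    df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     qual = suppressWarnings(as.numeric(fix$QUAL)),
                     mutant_read_fraction = frac,
                     strain = NA_character_, lineage = NA_character_,
                     condition = NA_character_, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(empty_mutations())
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stopf("mutation TSV '%s' lacks column(s): %s", path,
            paste(miss, collapse = ", "))
    if (!"mutant_read_fraction" %in% names(df) && "fraction" %in% names(df))
      df$mutant_read_fraction <- df$fraction
    for (col in c("qual", "mutant_read_fraction"))
      if (!col %in% names(df)) df[[col]] <- NA_real_
    for (col in c("strain", "lineage", "condition"))
      if (!col %in% names(df)) df[[col]] <- NA_character_
    df <- df[c("chrom", "pos", "ref", "alt", "qual", "mutant_read_fraction",
               "strain", "lineage", "condition")]
    df$pos <- as.integer(df$pos)
  }
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  ok <- df$ref %in% DNA_BASES & df$alt %in% DNA_BASES & df$ref != df$alt
  rejected <- sum(!ok)
  if (rejected > 0L)
    uvma_log(sprintf("%d non-BPS record(s) rejected from '%s'", rejected, path),
             level = "WARN")
  df <- df[ok, , drop = FALSE]
  df$pos <- df$pos - 1L  # to 0-based internal coordinates
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

empty_mutations <- function() {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), qual = numeric(),
                   mutant_read_fraction = numeric(), strain = character(),
                   lineage = character(), condition = character(),
                   stringsAsFactors = FALSE)
  attr(df, "rejected") <- 0L
  df
}

#' Write a mutation table to TSV
#'
#' Positions are written 1-based; [read_mutations()] converts back, so a
#' write/read round trip reproduces all fields.
#'
#' @param muts a mutation data frame (0-based `pos`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mutations <- function(muts, path) {
  out <- muts
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the variant-call quality filters
#'
#' Keeps exactly the calls with Phred quality at or above `min_qual` and
#' mutant-read fraction at or above `min_fraction` (strictly smaller values
#' are removed; equality is kept). The defaults are the thresholds used to
#' retain only mutations that are dominant or fixed in a sequenced
#' population. Order is preserved and the operation is idempotent.
#'
#' @param calls mutation data frame with `qual` and `mutant_read_fraction`.
#' @param min_qual minimum Phred-scaled quality (default 100).
#' @param min_fraction minimum mutant-read fraction (default 0.90).
#' @return the filtered data frame.
#' @export
filter_calls <- function(calls, min_qual = 100, min_fraction = 0.90) {
  if (min_qual < 0 || min_fraction < 0)
    stopf("filter thresholds must be non-negative")
  if (nrow(calls) == 0L) return(calls)
  keep <- calls$qual >= min_qual & calls$mutant_read_fraction >= min_fraction
  keep[is.na(keep)] <- FALSE
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
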