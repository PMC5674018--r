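#' Construct a feature annotation
#'
#' Holds the coding (CDS) and RNA-gene intervals used for substitution
#' classification and codon usage. Intervals are 0-based half-open on the
#' reference (plus) strand; file readers convert from the 1-based inclusive
#' convention of GFF3/BED name columns.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector of "+"/"-".
#' @param type character vector; "cds" or "rna".
#' @param id feature identifiers.
#' @return a data frame of class `"uvma_annotation"` with columns
#'   `start`, `end`, `strand`, `type`, `id`.
#' @export
annotation <- function(start, end, strand, type, id = NULL) {
  n <- length(start)
  if (is.null(id)) id <- sprintf("feat_%04d", seq_len(n))
  stopifnot(length(end) == n, length(strand) == n, length(type) == n,
            length(id) == n)
  type <- tolower(type)
  if (!all(type %in% c("cds", "rna")))
    stopf("feature type must be 'cds' or 'rna'")
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(end <= start)) stopf("features must have end > start")
  ann <- data.frame(start = as.integer(start), end = as.integer(end),
                    strand = strand, type = type, id = as.character(id),
                    stringsAsFactors = FALSE)
  class(ann) <- c("uvma_annotation", "data.frame")
  ann
}

#' Validate an annotation against a genome
#'
#' Checks that features lie within genome bounds and that every CDS length
#' is divisible by 3.
#'
#' @param ann an `"uvma_annotation"`.
#' @param g an `"uvma_genome"`.
#' @return invisibly `TRUE`; errors otherwise, naming the offending feature.
#' @export
validate_annotation <- function(ann, g) {
  stopifnot(inherits(ann, "uvma_annotation"), inherits(g, "uvma_genome"))
  out <- ann$start < 0L | ann$end > g$length
  if (any(out))
    stopf("feature(s) outside genome bounds: %s",
          paste(ann$id[out], collapse = ", "))
  cds <- ann[ann$type == "cds", , drop = FALSE]
  badframe <- (cds$end - cds$start) %% 3L != 0L
  if (any(badframe))
    stopf("CDS length not divisible by 3: %s",
          paste(cds$id[badframe], collapse = ", "))
  invisible(TRUE)
}

#' Total coding length L_CDS
#'
#' @param ann an `"uvma_annotation"`.
#' @return total CDS length in bp.
#' @export
cds_length <- function(ann) {
  stopifnot(inherits(ann, "uvma_annotation"))
  sum(ann$end[ann$type == "cds"] - ann$start[ann$type == "cds"])
}

# Feature types mapped into the two internal classes.
.RNA_GFF_TYPES <- c("rrna", "trna", "ncrna", "rna", "rna_gene")

#' Read an annotation from GFF3 or BED
#'
#' GFF3 feature types `CDS`, `rRNA`, `tRNA` and `ncRNA` are kept; other
#' types (gene, exon, ...) are ignored. For BED (which carries no type
#' column) the name field is inspected: names containing "rRNA", "tRNA" or
#' "ncRNA" become RNA genes, everything else a CDS.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return an `"uvma_annotation"`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  gr <- if (format == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  if (length(gr) == 0L) stopf("annotation '%s' contains no features", path)
  start0 <- GenomicRanges::start(gr) - 1L  # 1-based closed -> 0-based half-open
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (format == "bed") {
    nm <- if ("name" %in% names(meta)) as.character(meta$name)
          else sprintf("feat_%04d", seq_along(gr))
    type <- ifelse(grepl("rrna|trna|ncrna", tolower(nm)), "rna", "cds")
    id <- nm
  } else {
    rawtype <- tolower(as.character(meta$type))
    keep <- rawtype %in% c("cds", .RNA_GFF_TYPES)
    if (!any(keep)) stopf("annotation '%s' has no CDS or RNA-gene features", path)
    gr <- gr[keep]; meta <- meta[keep, , drop = FALSE]
    start0 <- start0[keep]; end0 <- end0[keep]; strand <- strand[keep]
    rawtype <- rawtype[keep]
    type <- ifelse(rawtype == "cds", "cds", "rna")
    id <- if ("ID" %in% names(meta)) as.character(meta$ID)
          else sprintf("feat_%04d", seq_along(type))
    id[is.na(id)] <- sprintf("feat_%04d", which(is.na(id)))
  }
  annotation(start0, end0, strand, type, id)
}

#' Write an annotation to GFF3
#'
#' @param ann an `"uvma_annotation"`.
#' @param path output path.
#' @param seqname sequence identifier to record.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(ann, path, seqname = "genome") {
  stopifnot(inherits(ann, "uvma_annotation"))
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  S4Vectors::mcols(gr)$type <- ifelse(ann$type == "cds", "CDS", "ncRNA")
  S4Vectors::mcols(gr)$ID <- ann$id
  S4Vectors::mcols(gr)$phase <- ifelse(ann$type == "cds", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
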