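#' Construct a genome object
#'
#' A genome is a single chromosome-scale DNA sequence with an identifier and
#' a circularity flag. All package-internal coordinates are 0-based
#' half-open; conversion from 1-based file formats happens at the I/O
#' boundary.
#'
#' @param seq character scalar over A/C/G/T/N (case-insensitive).
#' @param id sequence identifier.
#' @param circular logical; bacterial chromosomes are circular, so context
#'   windows wrap around the origin. Linear contigs drop incomplete windows.
#' @return an object of class `"uvma_genome"` with fields `id`, `seq`
#'   (uppercase), `length` and `circular`.
#' @export
#' @examples
#' g <- genome("ACGTACGT")
#' g$length
genome <- function(seq, id = "genome", circular = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stopf("genome sequence must be a non-empty character scalar")
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stopf("genome sequence contains non-ACGTN characters: %s",
          paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  structure(
    list(id = as.character(id), seq = seq, length = nchar(seq),
         circular = isTRUE(circular)),
    class = "uvma_genome"
  )
}

#' @export
print.uvma_genome <- function(x, ...) {
  cat(sprintf("<uvma_genome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads the first record of a FASTA file; additional records are reported
#' and ignored (the analyses operate on a single chromosome coordinate
#' frame). The sequence is uppercased.
#'
#' @param path path to a FASTA file.
#' @param circular logical, passed to [genome()].
#' @return an `"uvma_genome"` object.
#' @export
read_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) stopf("FASTA file '%s' contains no records", path)
  if (length(set) > 1L)
    uvma_log(sprintf("FASTA '%s' has %d records; using the first (%s)",
                     path, length(set), names(set)[1]), level = "WARN")
  id <- sub("\\s.*$", "", names(set)[1])
  genome(as.character(set[[1]]), id = id, circular = circular)
}

#' Write a genome to a FASTA file
#'
#' @param g an `"uvma_genome"` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "uvma_genome"))
  set <- Biostrings::DNAStringSet(setNames(g$seq, g$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Split a genome into a character vector of single bases (workhorse for
# context windows; callers should split once and reuse).
genome_bases <- function(g) strsplit(g$seq, "", fixed = TRUE)[[1]]

# Bases at 0-based positions `pos0 + offset` for a vector of positions and a
# scalar offset, honouring circular wrap. Returns NA outside a linear contig.
bases_at <- function(bases, pos0, offset, circular, L = length(bases)) {
  i <- pos0 + offset
  if (circular) {
    bases[(i %% L) + 1L]
  } else {
    out <- rep(NA_character_, length(i))
    ok <- i >= 0L & i < L
    out[ok] <- bases[i[ok] + 1L]
    out
  }
}
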