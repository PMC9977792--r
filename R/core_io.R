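# Core I/O and coordinate conventions.
#
# All coordinates in this package are 1-based, fully inclusive (GenBank
# convention). BED6 export converts to 0-based half-open at the boundary and
# the conversion is covered by round-trip tests. Minus-strand extraction
# returns the reverse complement of the plus-strand slice.

#' Construct a genome sequence record
#'
#' A `genome_sequence` is a named nucleotide sequence over \{A,C,G,T,N\}.
#' The sequence is normalized to upper case on construction.
#'
#' @param id Non-empty sequence identifier.
#' @param seq Nucleotide string.
#' @return An object of class `genome_sequence` with fields `id`, `seq`,
#'   `length`.
#' @export
genome_sequence <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_format("sequence id must be a non-empty string")
  seq <- toupper(seq)
  check_dna(seq, paste0("sequence '", id, "'"))
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (%d bp)\n", x$id, x$length))
  invisible(x)
}

as_genome_sequence <- function(x, id = "seq") {
  if (inherits(x, "genome_sequence")) return(x)
  genome_sequence(id, as.character(x))
}

#' Construct a genomic interval
#'
#' 1-based, inclusive coordinates; `interval_length()` is `end - start + 1`.
#'
#' @param seq_id Sequence identifier the interval lives on.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param seq_len Optional length of the parent sequence; when given,
#'   `end <= seq_len` is enforced.
#' @return An object of class `interval`.
#' @export
interval <- function(seq_id, start, end, strand = "+", seq_len = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop_validation(sprintf("invalid interval [%s, %s]: need 1 <= start <= end",
                            start, end))
  if (!strand %in% c("+", "-")) stop_validation("strand must be '+' or '-'")
  if (!is.null(seq_len) && end > seq_len)
    stop_validation(sprintf("interval end %d exceeds sequence length %d",
                            end, as.integer(seq_len)))
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "interval")
}

#' Length of a genomic interval in bp
#'
#' @param iv An [interval()].
#' @return Integer width `end - start + 1`.
#' @examples
#' interval_length(interval("CP044356", 173741, 174626)) # 886
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "interval"))
  iv$end - iv$start + 1L
}

#' Extract the sequence of an interval
#'
#' Minus-strand intervals return the reverse complement of the plus-strand
#' slice.
#'
#' @param genome A [genome_sequence()].
#' @param iv An [interval()].
#' @return Nucleotide string.
#' @export
extract_interval <- function(genome, iv) {
  genome <- as_genome_sequence(genome)
  if (iv$end > genome$length)
    stop_validation("interval extends beyond the sequence")
  s <- substr(genome$seq, iv$start, iv$end)
  if (iv$strand == "-") revcomp(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' `N` maps to `N`; any other character outside \{A,C,G,T,N\} is an error.
#' The operation is an involution: `revcomp(revcomp(s)) == s`.
#'
#' @param seq Nucleotide string (possibly empty).
#' @return The reverse complement.
#' @examples
#' revcomp("TACA") # "TGTA"
#' @export
revcomp <- function(seq) {
  check_dna(toupper(seq))
  seq <- toupper(seq)
  if (!nzchar(seq)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a FASTA file into genome sequences
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A list of [genome_sequence()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_format(paste("malformed FASTA:", conditionMessage(e))))
  if (length(set) == 0L) stop_format(paste("empty FASTA file:", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop_format("FASTA record with empty header")
  lapply(seq_along(set), function(i) genome_sequence(ids[i], as.character(set[[i]])))
}

#' Write genome sequences to FASTA
#'
#' @param seqs A [genome_sequence()] or list thereof.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## GFF3 / BED output --------------------------------------------------------

# Build the GRanges (parent + 5 child segments) for one annotated element.
element_granges <- function(el, idx) {
  lay <- el$layout
  iv <- el$interval
  segs <- c(tir5 = lay$tir5_len, utr5 = lay$utr5_len, orf = lay$orf_len,
            utr3 = lay$utr3_len, tir3 = lay$tir3_len)
  if (sum(segs) != interval_length(iv))
    stop_validation(sprintf(
      "element %s: segment lengths sum to %d but the element spans %d bp",
      el$id %||% idx, sum(segs), interval_length(iv)))
  so <- c(tir5 = "terminal_inverted_repeat", utr5 = "five_prime_UTR",
          orf = "CDS", utr3 = "three_prime_UTR",
          tir3 = "terminal_inverted_repeat")
  pid <- el$id %||% sprintf("te%03d", idx)
  starts <- iv$start + cumsum(c(0L, unname(segs[-5L])))
  ends <- starts + unname(segs) - 1L
  keep <- segs > 0L           # zero-length (unknown) TIRs are not emitted
  gr <- GenomicRanges::GRanges(
    seqnames = iv$seq_id,
    ranges = IRanges::IRanges(start = c(iv$start, starts[keep]),
                              end = c(iv$end, ends[keep])),
    strand = iv$strand)
  n_child <- sum(keep)
  S4Vectors::mcols(gr)$source <- "tc1scout"
  S4Vectors::mcols(gr)$type <- c("transposable_element", unname(so[keep]))
  S4Vectors::mcols(gr)$ID <- c(pid, paste0(pid, ".", names(segs)[keep]))
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    c(list(character(0)), rep(list(pid), n_child)))
  S4Vectors::mcols(gr)$phase <- ifelse(S4Vectors::mcols(gr)$type == "CDS", 0L,
                                       NA_integer_)
  gr
}

#' Write annotated elements as GFF3
#'
#' Each element is emitted as one `transposable_element` parent feature plus
#' child features for the five layout segments (zero-length segments, i.e.
#' unknown TIRs, are omitted). Coordinates are 1-based inclusive.
#'
#' @param elements List of elements; each a list with `interval` (an
#'   [interval()]), `layout` (an [element_layout()]) and optional `id`.
#' @param path Output path.
#' @param seq_lengths Optional named vector of sequence lengths used to
#'   validate coordinates.
#' @return `path`, invisibly.
#' @export
write_gff <- function(elements, path, seq_lengths = NULL) {
  if (length(elements) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  grl <- lapply(seq_along(elements), function(i) {
    el <- elements[[i]]
    if (!is.null(seq_lengths)) {
      sl <- seq_lengths[[el$interval$seq_id]]
      if (!is.null(sl) && el$interval$end > sl)
        stop_validation(sprintf("element %d: end %d outside sequence %s (%d bp)",
                                i, el$interval$end, el$interval$seq_id, sl))
    }
    element_granges(el, i)
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED6
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention (delegated to rtracklayer).
#'
#' @param ivs List of [interval()] objects.
#' @param path Output path.
#' @param names Feature names (defaults to `feat<i>`).
#' @param scores Numeric scores (defaults to 0).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(ivs, path, names = NULL, scores = NULL) {
  if (inherits(ivs, "interval")) ivs <- list(ivs)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(ivs, function(x) x$seq_id, ""),
    ranges = IRanges::IRanges(start = vapply(ivs, function(x) x$start, 1L),
                              end = vapply(ivs, function(x) x$end, 1L)),
    strand = vapply(ivs, function(x) x$strand, ""))
  S4Vectors::mcols(gr)$name <- names %||% sprintf("feat%d", seq_along(ivs))
  S4Vectors::mcols(gr)$score <- scores %||% rep(0, length(ivs))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
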