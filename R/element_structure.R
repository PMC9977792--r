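# The three-point evidence rule for calling a TIR-order element: identical
# terminal inverted repeats at both ends, TA target-site-duplication excision
# sites spanning the boundaries, and a transposase ORF between the TIRs --
# plus element boundary inference from homolog presence/absence groups.

tir_pair <- function(tir5, tir3, length, identity) {
  structure(list(tir5 = tir5, tir3 = tir3, length = as.integer(length),
                 identity = identity),
            class = "tir_pair")
}

#' @export
print.tir_pair <- function(x, ...) {
  cat(sprintf("<tir_pair> %d bp, identity %.3f\n", x$length, x$identity))
  invisible(x)
}

#' Detect terminal inverted repeats of an element region
#'
#' Returns the longest prefix `P` with `min_len <= |P| <= max_len` whose
#' ungapped identity to the reverse complement of the equal-length suffix is
#' at least `min_identity`. With `min_identity = 1` this is the longest exact
#' terminal inverted repeat; in that exact mode any window containing `N` is
#' excluded as evidence ("identical TIRs" is an exact claim).
#'
#' @param element_region Nucleotide string spanning the candidate element.
#' @param min_len,max_len TIR length bounds (defaults 10 and 250 bp, spanning
#'   the 26/141/169-bp TIRs of known Tc1 family members).
#' @param min_identity Identity threshold (1.0 for discovery; 0.8 is a
#'   reasonable choice for degenerate-copy scanning).
#' @param seq_id Sequence id used for the returned intervals.
#' @return A `tir_pair` (intervals are 1-based within `element_region`), or
#'   `NULL` when no qualifying pair exists.
#' @export
detect_tirs <- function(element_region, min_len = 10L, max_len = 250L,
                        min_identity = 1.0, seq_id = "region") {
  element_region <- toupper(element_region)
  check_dna(element_region, "element region")
  n <- nchar(element_region)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (!(min_len <= max_len && max_len <= n %/% 2L))
    stop_validation("need min_len <= max_len <= floor(region length / 2)")
  chars <- seq_chars(element_region)
  idx <- seq_len(max_len)
  # column i compares prefix base i with the complement of suffix base i
  eq <- chars[idx] == complement_chr(chars[n - idx + 1L])
  has_n <- chars[idx] == "N" | chars[n - idx + 1L] == "N"
  cum_id <- cumsum(eq) / idx
  ok <- cum_id >= min_identity
  if (min_identity >= 1) ok <- ok & !cumsum(has_n)
  hits <- which(ok)
  hits <- hits[hits >= min_len]
  if (length(hits) == 0L) return(NULL)
  l <- max(hits)
  tir_pair(interval(seq_id, 1L, l),
           interval(seq_id, n - l + 1L, n),
           l, cum_id[l])
}

#' Check excision sites / target-site duplication at element boundaries
#'
#' The boundary 4-mers span each junction: 2 bp of flank plus the 2 terminal
#' element bases (so the two printed Tc1 sites `TACA|` and `|TGTA`, and the
#' IS630 `TA|TA` sites, are both satisfied). `excision_ok` requires the two
#' 4-mers to be reverse complements of one another and the flank-side
#' dinucleotide on each side to equal the target-site duplication `tsd`.
#'
#' @param genome A [genome_sequence()].
#' @param element An [interval()] with at least 2 bp of flank on each side.
#' @param tsd Target-site-duplication dinucleotide (default `"TA"`).
#' @return List with `excision_ok`, `flank5_4mer`, `flank3_4mer`.
#' @export
check_excision_sites <- function(genome, element, tsd = "TA") {
  genome <- as_genome_sequence(genome)
  tsd <- toupper(tsd)
  if (element$start < 3L || element$end > genome$length - 2L)
    stop_flank("element too close to the sequence edge for a 2-bp flank")
  f5 <- substr(genome$seq, element$start - 2L, element$start + 1L)
  f3 <- substr(genome$seq, element$end - 1L, element$end + 2L)
  ok <- identical(f5, revcomp(f3)) &&
    identical(substr(f5, 1L, 2L), tsd) &&
    identical(substr(f3, 3L, 4L), tsd)
  list(excision_ok = ok, flank5_4mer = f5, flank3_4mer = f3)
}

#' Construct an element layout
#'
#' The five-segment anatomy (5'TIR, 5'UTR, ORF, 3'UTR, 3'TIR) of one element.
#' Unknown TIRs are represented as zero-length segments, never as absent
#' fields, so the segment-sum invariant
#' `layout_total_length(x) == interval_length(element)` is universal.
#'
#' @param tir5_len,utr5_len,orf_len,utr3_len,tir3_len Segment lengths in bp.
#' @param element Optional [interval()] of the whole element.
#' @param excision_ok,flank5_4mer,flank3_4mer Optional excision-site
#'   evidence as returned by [check_excision_sites()].
#' @return An `element_layout`.
#' @export
element_layout <- function(tir5_len, utr5_len, orf_len, utr3_len, tir3_len,
                           element = NULL, excision_ok = NA,
                           flank5_4mer = NA_character_,
                           flank3_4mer = NA_character_) {
  lens <- c(tir5_len, utr5_len, orf_len, utr3_len, tir3_len)
  if (any(lens < 0L)) stop_validation("segment lengths must be non-negative")
  if (!is.null(element) && sum(lens) != interval_length(element))
    stop_validation(sprintf("segments sum to %d but element spans %d bp",
                            sum(lens), interval_length(element)))
  structure(list(tir5_len = as.integer(tir5_len),
                 utr5_len = as.integer(utr5_len),
                 orf_len = as.integer(orf_len),
                 utr3_len = as.integer(utr3_len),
                 tir3_len = as.integer(tir3_len),
                 element = element, excision_ok = excision_ok,
                 flank5_4mer = flank5_4mer, flank3_4mer = flank3_4mer),
            class = "element_layout")
}

#' @export
print.element_layout <- function(x, ...) {
  cat(sprintf("<element_layout> TIR %d | UTR %d | ORF %d | UTR %d | TIR %d = %d bp (excision_ok: %s)\n",
              x$tir5_len, x$utr5_len, x$orf_len, x$utr3_len, x$tir3_len,
              layout_total_length(x), x$excision_ok))
  invisible(x)
}

#' Total element length implied by a layout
#'
#' @param layout An [element_layout()].
#' @return Sum of the five segment lengths in bp.
#' @examples
#' layout_total_length(element_layout(169, 245, 3468, 1608, 169)) # 5659
#' @export
layout_total_length <- function(layout) {
  stopifnot(inherits(layout, "element_layout"))
  layout$tir5_len + layout$utr5_len + layout$orf_len + layout$utr3_len +
    layout$tir3_len
}

#' Assemble the five-segment layout of an element
#'
#' UTR lengths are derived by subtraction from the element interval, the TIR
#' pair and the ORF interval; the segment-sum invariant holds by
#' construction. Excision-site evidence is filled in by
#' [check_excision_sites()] (recorded as `NA` when the element sits at the
#' sequence edge).
#'
#' @param genome A [genome_sequence()].
#' @param element Element [interval()] (genome coordinates).
#' @param tir A `tir_pair` from [detect_tirs()], or `NULL` for unknown TIRs
#'   (zero-length segments).
#' @param orf An `orf_call` with a genome-coordinate interval strictly inside
#'   the element, between the TIRs.
#' @param tsd Target-site duplication dinucleotide.
#' @return An [element_layout()].
#' @export
annotate_layout <- function(genome, element, tir, orf, tsd = "TA") {
  genome <- as_genome_sequence(genome)
  tlen <- if (is.null(tir)) 0L else tir$length
  ost <- orf$interval$start; oen <- orf$interval$end
  if (ost < element$start || oen > element$end)
    stop_validation("ORF is not contained in the element")
  utr5 <- ost - element$start - tlen
  utr3 <- element$end - oen - tlen
  if (utr5 < 0L || utr3 < 0L)
    stop_validation("ORF overlaps a terminal inverted repeat")
  exc <- tryCatch(check_excision_sites(genome, element, tsd),
                  tc1scout_flank_error = function(e)
                    list(excision_ok = NA, flank5_4mer = NA_character_,
                         flank3_4mer = NA_character_))
  element_layout(tlen, utr5, oen - ost + 1L, utr3, tlen, element = element,
                 excision_ok = exc$excision_ok,
                 flank5_4mer = exc$flank5_4mer, flank3_4mer = exc$flank3_4mer)
}

## Boundary inference from homolog presence/absence -------------------------

boundary_call <- function(iv, support_with, support_without) {
  structure(list(interval = iv, support_with = as.integer(support_with),
                 support_without = as.integer(support_without)),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat(sprintf("<boundary_call> %d-%d (%d bp), support %d with / %d without\n",
              x$interval$start, x$interval$end, interval_length(x$interval),
              x$support_with, x$support_without))
  invisible(x)
}

# Longest subject-gap run of a global alignment, in pattern coordinates.
longest_deletion_run <- function(rep_seq, other_seq) {
  aln <- align_global_nt(rep_seq, other_seq)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  r <- rle(sa == "-")
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  best <- gi[which.max(r$lengths[gi])]
  cols <- starts[best]:ends[best]
  # pattern coordinate of the first gapped column
  pstart <- sum(pa[seq_len(starts[best] - 1L)] != "-") + 1L
  plen <- sum(pa[cols] != "-")
  if (plen == 0L) return(NULL)
  c(start = pstart, end = pstart + plen - 1L)
}

#' Infer an insertion interval from homolog presence/absence groups
#'
#' Locates the maximal contiguous segment of a representative "with" region
#' that is present in every with-group homolog and absent (as one alignment
#' gap) from every without-group homolog -- the way an element's boundaries
#' can be fixed without knowing its TIRs. Coordinates are reported on the
#' first with-group region.
#'
#' @param with_group Non-empty list/vector of region sequences carrying the
#'   segment.
#' @param without_group Non-empty list/vector of homologous regions lacking
#'   it.
#' @param tolerance Maximum disagreement (bp) between the gap endpoints
#'   implied by different without-group regions (default 2).
#' @param min_support_frac Fraction of segment columns that must align to
#'   residues for a with-group region to count as supporting.
#' @return A `boundary_call` with the interval and support counts.
#' @export
infer_insertion_interval <- function(with_group, without_group, tolerance = 2L,
                                     min_support_frac = 0.9) {
  wg <- lapply(with_group, function(x) as_genome_sequence(x)$seq)
  wo <- lapply(without_group, function(x) as_genome_sequence(x)$seq)
  if (length(wg) == 0L)
    stop_validation("with-group is empty")
  if (length(wo) == 0L)
    stop_ambiguous("without-group is empty: no absence evidence for a boundary")
  rep_seq <- wg[[1L]]
  runs <- lapply(wo, function(w) longest_deletion_run(rep_seq, w))
  if (any(vapply(runs, is.null, TRUE)))
    stop_ambiguous("a without-group region shows no deletion against the representative")
  starts <- vapply(runs, `[`, 1, "start")
  ends <- vapply(runs, `[`, 1, "end")
  if (diff(range(starts)) > tolerance || diff(range(ends)) > tolerance)
    stop_ambiguous(sprintf(
      "without-group regions disagree on the deleted interval beyond +/-%d bp",
      tolerance))
  cstart <- as.integer(round(stats::median(starts)))
  cend <- as.integer(round(stats::median(ends)))
  support_with <- 1L
  if (length(wg) > 1L) {
    for (w in wg[-1L]) {
      aln <- align_global_nt(rep_seq, w)
      pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
      sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
      ppos <- cumsum(pa != "-")
      cols <- which(ppos >= cstart & ppos <= cend & pa != "-")
      if (length(cols) && mean(sa[cols] != "-") >= min_support_frac)
        support_with <- support_with + 1L
    }
  }
  boundary_call(interval("with_rep", cstart, cend), support_with, length(wo))
}
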