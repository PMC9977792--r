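# Genome-wide placement of a reference element: full-length copy counting
# under the strict >90%-coverage rule, solo-TIR scanning, and copy-vs-copy
# divergence reporting.

copy_hit <- function(iv, coverage, identity) {
  structure(list(interval = iv, coverage = coverage, identity = identity,
                 full_length = coverage > 0.90),
            class = "copy_hit")
}

#' @export
print.copy_hit <- function(x, ...) {
  cat(sprintf("<copy_hit> %s:%d-%d(%s) coverage %.3f identity %.3f%s\n",
              x$interval$seq_id, x$interval$start, x$interval$end,
              x$interval$strand, x$coverage, x$identity,
              if (x$full_length) " [full-length]" else ""))
  invisible(x)
}

# Seed positions of shared k-mers between a reference and a genome string.
# Returns data.frame(gpos, rpos) of genome/reference k-mer start positions.
kmer_seeds <- function(genome_seq, ref_seq, k) {
  ng <- nchar(genome_seq); nr <- nchar(ref_seq)
  if (ng < k || nr < k) return(data.frame(gpos = integer(0), rpos = integer(0)))
  rk <- substring(ref_seq, 1:(nr - k + 1L), k:nr)
  gk <- substring(genome_seq, 1:(ng - k + 1L), k:ng)
  m <- match(gk, rk)
  hit <- which(!is.na(m))
  data.frame(gpos = hit, rpos = m[hit])
}

# Split seed hits into loci: same-strand hits within a gap of
# chain_gap_frac * reference length belong to one locus.
cluster_seeds <- function(seeds, nr, chain_gap_frac) {
  seeds <- seeds[order(seeds$gpos), , drop = FALSE]
  gap <- max(50L, as.integer(chain_gap_frac * nr))
  grp <- cumsum(c(1L, diff(seeds$gpos) > gap))
  split(seeds, grp)
}

#' Locate copies of a reference element in a genome
#'
#' Seed-and-extend on both strands: shared k-mer seeds are chained into loci
#' (same-strand seeds within a gap of `chain_gap_frac` of the reference
#' length form one locus, tolerating internal indels without double
#' counting), and each locus is resolved by local alignment of the reference
#' against the locus window. `coverage` is the aligned reference span over
#' the reference length, and the full-length flag applies the strict rule:
#' homologs covering more than 90% of the reference count as one full-length
#' copy, so exactly 90.0% does not qualify.
#'
#' @param genome A [genome_sequence()] (or plain string).
#' @param reference_element Reference element nucleotide string (>= 50 bp).
#' @param min_identity Minimum alignment identity to report a hit (default
#'   0.8 -- autonomous family members diverge by up to ~20% at the DNA
#'   level).
#' @param k Seed k-mer size.
#' @param min_coverage Minimum reference coverage to report a hit (default
#'   0.05, so isolated TIR matches are left to [find_solo_tirs()]).
#' @param chain_gap_frac Chaining gap as a fraction of reference length.
#' @return List of `copy_hit` objects sorted by coordinate.
#' @export
find_copies <- function(genome, reference_element, min_identity = 0.8,
                        k = 12L, min_coverage = 0.05, chain_gap_frac = 0.2) {
  genome <- as_genome_sequence(genome)
  ref <- toupper(as_genome_sequence(reference_element, "ref")$seq)
  nr <- nchar(ref)
  if (nr < 50L) stop_validation("reference element must be >= 50 bp")
  hits <- list()
  for (std in c("+", "-")) {
    rs <- if (std == "+") ref else revcomp(ref)
    seeds <- kmer_seeds(genome$seq, rs, k)
    if (nrow(seeds) == 0L) next
    for (cl in cluster_seeds(seeds, nr, chain_gap_frac)) {
      d <- cl$gpos - cl$rpos
      wstart <- max(1L, min(d) + 1L - 30L)
      wend <- min(genome$length, max(d) + nr + 30L)
      window <- substr(genome$seq, wstart, wend)
      aln <- align_local_nt(rs, window)
      cov <- IRanges::width(Biostrings::pattern(aln)@range) / nr
      idn <- Biostrings::pid(aln, type = "PID1") / 100
      if (cov < min_coverage || idn < min_identity) next
      srange <- Biostrings::subject(aln)@range
      iv <- interval(genome$id, wstart + IRanges::start(srange) - 1L,
                     wstart + IRanges::end(srange) - 1L, std)
      hits[[length(hits) + 1L]] <- copy_hit(iv, cov, idn)
    }
  }
  if (length(hits) == 0L) return(list())
  # resolve overlapping calls (e.g. a palindromic-TIR echo on the other
  # strand): keep the higher-coverage hit
  st <- vapply(hits, function(h) h$interval$start, 1L)
  en <- vapply(hits, function(h) h$interval$end, 1L)
  cov <- vapply(hits, function(h) h$coverage, 1)
  keep <- rep(TRUE, length(hits))
  ord <- order(-cov)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (b in ord[-seq_len(i)]) {
      if (!keep[b]) next
      ov <- min(en[a], en[b]) - max(st[a], st[b]) + 1L
      if (ov > 0L && ov > 0.5 * min(en[a] - st[a] + 1L, en[b] - st[b] + 1L))
        keep[b] <- FALSE
    }
  }
  hits <- hits[keep]
  hits[order(vapply(hits, function(h) h$interval$start, 1L))]
}

#' Census table of copy hits
#'
#' @param hits List of `copy_hit` objects from [find_copies()].
#' @return A data.frame (seq_id, start, end, strand, coverage, identity,
#'   full_length).
#' @export
census_table <- function(hits) {
  if (length(hits) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      full_length = logical(0)))
  data.frame(
    seq_id = vapply(hits, function(h) h$interval$seq_id, ""),
    start = vapply(hits, function(h) h$interval$start, 1L),
    end = vapply(hits, function(h) h$interval$end, 1L),
    strand = vapply(hits, function(h) h$interval$strand, ""),
    coverage = round(vapply(hits, function(h) h$coverage, 1), 4),
    identity = round(vapply(hits, function(h) h$identity, 1), 4),
    full_length = vapply(hits, function(h) h$full_length, TRUE))
}

#' Find solo TIRs
#'
#' Matches to the TIR sequence or its reverse complement that are not
#' contained in any excluded interval (typically the copy hits from
#' [find_copies()], so that the TIRs of intact elements are not reported as
#' solo).
#'
#' @param genome A [genome_sequence()].
#' @param tir_seq TIR nucleotide string (>= 10 bp).
#' @param min_identity Match identity threshold (mismatches allowed, no
#'   indels).
#' @param exclude List of [interval()]s (or `copy_hit`s) to exclude.
#' @return List of [interval()]s sorted by coordinate.
#' @export
find_solo_tirs <- function(genome, tir_seq, min_identity = 0.9,
                           exclude = list()) {
  genome <- as_genome_sequence(genome)
  tir_seq <- toupper(tir_seq)
  if (nchar(tir_seq) < 10L) stop_validation("TIR must be >= 10 bp")
  max_mm <- floor((1 - min_identity) * nchar(tir_seq))
  excl <- lapply(exclude, function(x) if (inherits(x, "copy_hit")) x$interval else x)
  subj <- Biostrings::DNAString(genome$seq)
  out <- list()
  for (std in c("+", "-")) {
    pat <- if (std == "+") tir_seq else revcomp(tir_seq)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
    for (i in seq_along(m)) {
      st <- IRanges::start(m)[i]; en <- IRanges::end(m)[i]
      inside <- any(vapply(excl, function(iv)
        st >= iv$start && en <= iv$end, TRUE))
      if (inside) next
      out[[length(out) + 1L]] <- interval(genome$id, st, en, std)
    }
  }
  if (length(out) == 0L) return(list())
  # a near-palindromic TIR can match at the same spot on both strands
  key <- vapply(out, function(iv) paste0(iv$start, "-", iv$end), "")
  out <- out[!duplicated(key)]
  out[order(vapply(out, function(iv) iv$start, 1L))]
}

## Copy-vs-copy divergence ---------------------------------------------------

copy_diff <- function(n_snps, indels, aa_consequence = NULL) {
  structure(list(n_snps = as.integer(n_snps), indels = indels,
                 aa_consequence = aa_consequence),
            class = "copy_diff")
}

#' @export
print.copy_diff <- function(x, ...) {
  cat(sprintf("<copy_diff> %d SNPs, %d indel(s)%s\n", x$n_snps,
              nrow(x$indels),
              if (!is.null(x$aa_consequence)) paste0("; ", x$aa_consequence) else ""))
  invisible(x)
}

# Codon-wise translation with stops as "*" and N-containing codons as "X".
translate_raw <- function(nt) {
  aa <- Biostrings::GENETIC_CODE[codon_split(nt)]
  aa[is.na(aa)] <- "X"
  aa[codon_split(nt) %in% STOP_CODONS] <- "*"
  paste0(aa, collapse = "")
}

# Residues lost by an in-frame deletion inside the ORF, derived by local
# translation comparison around the gap (robust to alignment gap-wander,
# which can shift the reported gap by a base or two within repeats).
indel_aa_consequence <- function(a, pa, sa, apos, orf, pos, len) {
  d <- len %/% 3L
  generic <- sprintf("in-frame deletion of %d aa", d)
  w1 <- orf$start + 3L * max(0L, (pos - orf$start) %/% 3L - 2L)
  w2 <- min(orf$end, w1 + ((pos + len - 1L - w1) %/% 3L + 3L) * 3L - 1L)
  if ((w2 - w1 + 1L) %% 3L != 0L || w2 <= w1) return(generic)
  a_sub <- substr(a, w1, w2)
  cols <- which(apos >= w1 & apos <= w2)
  b_sub <- paste0(sa[cols][sa[cols] != "-"], collapse = "")
  if (nchar(b_sub) %% 3L != 0L || nchar(a_sub) - nchar(b_sub) != len)
    return(generic)
  ta <- translate_raw(a_sub); tb <- translate_raw(b_sub)
  diffs <- which(seq_chars(substr(ta, 1L, nchar(tb))) != seq_chars(tb))
  k <- if (length(diffs)) diffs[1L] else nchar(tb) + 1L
  removed <- substr(ta, k, k + d - 1L)
  rest <- paste0(substr(ta, 1L, k - 1L), substr(ta, k + d, nchar(ta)))
  if (identical(rest, tb)) sprintf("deletion of %d aa (%s)", d, removed)
  else generic
}

#' Compare two copies of an element
#'
#' One global alignment of the two copies; mismatch columns count as SNPs
#' (columns within `gap_buffer` bp of a gap are excluded, avoiding
#' edge-wander artifacts) and each gap run collapses to one indel record.
#' Indels are reported in copy-A coordinates: a gap in copy B is a deletion
#' (`del`), a gap in copy A an insertion (`ins`).
#'
#' @param copy_a,copy_b Nucleotide strings (copy A is the reference for
#'   positions).
#' @param orf Optional [interval()] of the ORF in copy-A coordinates; when
#'   given, in-frame codon-aligned deletions are annotated with the deleted
#'   residues (e.g. `"deletion of 1 aa (M)"`).
#' @param gap_buffer SNP exclusion zone around gaps in bp (default 1).
#' @return A `copy_diff` with `n_snps`, `indels` (data.frame pos, length,
#'   type) and `aa_consequence`.
#' @export
compare_copies <- function(copy_a, copy_b, orf = NULL, gap_buffer = 1L) {
  a <- toupper(as_genome_sequence(copy_a, "a")$seq)
  b <- toupper(as_genome_sequence(copy_b, "b")$seq)
  if (!nzchar(a) || !nzchar(b)) stop_validation("copies must be non-empty")
  aln <- align_global_nt(a, b)
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  ncol <- length(pa)
  gapcol <- pa == "-" | sa == "-"
  near_gap <- gapcol
  if (gap_buffer > 0L && any(gapcol)) {
    gi <- which(gapcol)
    for (off in seq_len(gap_buffer)) {
      near_gap[pmax(gi - off, 1L)] <- TRUE
      near_gap[pmin(gi + off, ncol)] <- TRUE
    }
  }
  snp <- !gapcol & !near_gap & pa != sa
  apos <- cumsum(pa != "-")

  runs <- rle(ifelse(pa == "-", "ins", ifelse(sa == "-", "del", "m")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- which(runs$values != "m")
  indels <- data.frame(pos = integer(0), length = integer(0),
                       type = character(0), stringsAsFactors = FALSE)
  for (i in idx) {
    type <- runs$values[i]
    len <- runs$lengths[i]
    pos <- if (type == "del") apos[starts[i]]       # first deleted base, A coords
           else max(1L, apos[starts[i]])            # A base preceding insertion
    indels <- rbind(indels, data.frame(pos = pos, length = len, type = type,
                                       stringsAsFactors = FALSE))
  }
  aa_cons <- NULL
  if (!is.null(orf) && nrow(indels)) {
    msgs <- character(0)
    for (i in seq_len(nrow(indels))) {
      if (indels$type[i] != "del" || indels$length[i] %% 3L != 0L) next
      pos <- indels$pos[i]; len <- indels$length[i]
      if (pos < orf$start || pos + len - 1L > orf$end) next
      msgs <- c(msgs, indel_aa_consequence(a, pa, sa, apos, orf, pos, len))
    }
    if (length(msgs)) aa_cons <- paste(msgs, collapse = "; ")
  }
  copy_diff(sum(snp), indels, aa_cons)
}
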