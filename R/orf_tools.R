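# ORF detection, translation, and frameshift repair by minimal insertion
# removal.

orf_call <- function(iv, frame, start_codon, protein, length_nt) {
  structure(list(interval = iv, frame = frame, start_codon = start_codon,
                 protein = protein, length_nt = length_nt,
                 length_aa = length_nt %/% 3L - 1L),
            class = "orf_call")
}

#' @export
print.orf_call <- function(x, ...) {
  cat(sprintf("<orf_call> %s:%d-%d(%s) %d nt / %d aa, start %s\n",
              x$interval$seq_id, x$interval$start, x$interval$end,
              x$interval$strand, x$length_nt, x$length_aa, x$start_codon))
  invisible(x)
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code (table 1). The input must be a multiple of 3 and end
#' in a stop codon; the stop is not included in the protein, so the protein
#' has `nchar(orf_nt)/3 - 1` residues. An internal stop is an error.
#'
#' @param orf_nt Nucleotide string.
#' @return Amino-acid string.
#' @examples
#' translate_orf("ATGTAA") # "M"
#' @export
translate_orf <- function(orf_nt) {
  orf_nt <- toupper(orf_nt)
  check_dna(orf_nt, "ORF")
  n <- nchar(orf_nt)
  if (n < 6L || n %% 3L != 0L)
    stop_validation("ORF length must be a multiple of 3 and >= 6")
  codons <- codon_split(orf_nt)
  if (!codons[length(codons)] %in% STOP_CODONS)
    stop_validation("ORF does not end in a stop codon")
  body <- codons[-length(codons)]
  if (any(body %in% STOP_CODONS))
    stop_validation(sprintf("internal stop codon at codon %d",
                            which(body %in% STOP_CODONS)[1L]))
  aa <- Biostrings::GENETIC_CODE[body]
  aa[is.na(aa)] <- "X"          # codons containing N
  paste0(aa, collapse = "")
}

# All stop-codon start positions (frame-agnostic) in a string.
stop_positions <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(integer(0))
  tri <- substring(seq, 1:(n - 2L), 3:n)
  which(tri %in% STOP_CODONS)
}

# Maximal ORFs on one strand of `seq` (coordinates on that strand). For each
# in-frame stop, the ORF runs from the leftmost qualifying start codon since
# the previous stop.
scan_orfs_one_strand <- function(seq, min_aa, start_codons) {
  n <- nchar(seq)
  res <- list()
  if (n < 6L) return(res)
  tri <- substring(seq, 1:(n - 2L), 3:n)
  for (f in 0:2) {
    pos <- seq.int(1L + f, n - 2L, by = 3L)
    cods <- tri[pos]
    is_stop <- cods %in% STOP_CODONS
    is_start <- cods %in% start_codons
    first_start <- NA_integer_
    for (ci in seq_along(cods)) {
      if (is_stop[ci]) {
        if (!is.na(first_start)) {
          st <- pos[first_start]; en <- pos[ci] + 2L
          if ((en - st + 1L) %/% 3L - 1L >= min_aa)
            res[[length(res) + 1L]] <- list(start = st, end = en,
                                            start_codon = cods[first_start],
                                            frame = f)
        }
        first_start <- NA_integer_
      } else if (is.na(first_start) && is_start[ci]) {
        first_start <- ci
      }
    }
  }
  res
}

#' Find open reading frames
#'
#' All maximal ORFs on both strands: for each in-frame stop, the ORF runs
#' from the leftmost qualifying start codon since the previous stop to that
#' stop (stop codon included in `length_nt`, excluded from the protein).
#' Results are sorted by length descending, ties by coordinate ascending.
#'
#' @param seq Nucleotide string or [genome_sequence()].
#' @param min_aa Minimum protein length in residues (>= 1).
#' @param start_codons Set of permitted start codons. `ATG` is the default;
#'   alternative starts (e.g. `TGG`) are supported but never assumed.
#' @param strands Strands to scan.
#' @return List of `orf_call` objects.
#' @export
find_orfs <- function(seq, min_aa = 50L, start_codons = "ATG",
                      strands = c("+", "-")) {
  g <- as_genome_sequence(seq, id = "query")
  stopifnot(min_aa >= 1L)
  start_codons <- toupper(start_codons)
  calls <- list()
  for (std in strands) {
    s <- if (std == "+") g$seq else revcomp(g$seq)
    hits <- scan_orfs_one_strand(s, min_aa, start_codons)
    for (h in hits) {
      iv <- if (std == "+") interval(g$id, h$start, h$end, "+")
            else interval(g$id, g$length - h$end + 1L, g$length - h$start + 1L, "-")
      nt <- substr(s, h$start, h$end)
      calls[[length(calls) + 1L]] <-
        orf_call(iv, h$frame, h$start_codon, translate_orf(nt), nchar(nt))
    }
  }
  if (length(calls) == 0L) return(list())
  len <- vapply(calls, function(x) x$length_nt, 1L)
  st <- vapply(calls, function(x) x$interval$start, 1L)
  calls[order(-len, st)]
}

## Frameshift repair --------------------------------------------------------

repair_result <- function(success, removed = list(), repaired_seq = NULL,
                          repaired_orf = NULL, message = NULL) {
  structure(list(success = success, removed_segments = removed,
                 total_removed = if (length(removed))
                   sum(vapply(removed, `[[`, 1L, "length")) else 0L,
                 repaired_seq = repaired_seq, repaired_orf = repaired_orf,
                 message = message),
            class = "repair_result")
}

#' @export
print.repair_result <- function(x, ...) {
  if (!x$success) {
    cat("<repair_result> FAILED:", x$message %||% "no removal restores an ORF", "\n")
  } else {
    cat(sprintf("<repair_result> removed %d segment(s), %d bp total\n",
                length(x$removed_segments), x$total_removed))
    for (s in x$removed_segments)
      cat(sprintf("  - pos %d, %d bp (%s)\n", s$position, s$length, s$sequence))
  }
  invisible(x)
}

apply_removals <- function(seq, segs) {
  if (length(segs) == 0L) return(seq)
  chars <- seq_chars(seq)
  drop <- unlist(lapply(segs, function(s) s$position:(s$position + s$length - 1L)))
  chars_to_seq(chars[-drop])
}

#' Repair a frameshift-broken ORF by minimal insertion removal
#'
#' Finds the removal set of minimal total length (primary criterion), fewest
#' segments (secondary), leftmost positions (tertiary), lexicographic segment
#' sequences (final tie-break) such that the region, after removal, carries a
#' single forward-strand ORF covering at least `min_coverage` of it.
#'
#' The search is exact for removal sets of one or two segments whose restored
#' stop codon is read from contiguous original bases (the restored terminal
#' stop never spans a removal junction -- the generative situation for both a
#' single multi-bp insertion and separate single-base insertions). Candidate
#' segments are anchored by reading-frame arithmetic between each start codon
#' near the region 5' end and each stop codon near its 3' end, using
#' per-frame stop-position indexes; every surviving candidate is then
#' verified by a full ORF re-scan of the repaired sequence.
#'
#' @param region Nucleotide string spanning the broken ORF (forward
#'   orientation).
#' @param max_insert_len Bound on the total removed length (default 50 bp).
#' @param reference_protein Optional protein; a candidate repair is only
#'   accepted if the restored protein aligns to it end-to-end with identity
#'   at least `min_identity`.
#' @param min_coverage Fraction of the repaired region the restored ORF must
#'   span (default 0.9).
#' @param max_segments 1 or 2 removal segments (default 2).
#' @param start_codons Permitted start codons.
#' @param min_identity Identity threshold for the reference-protein check.
#' @return A `repair_result`; `success = FALSE` (not an exception) when no
#'   removal within bounds restores an ORF. An intact region returns an empty
#'   removal set.
#' @export
repair_frameshifts <- function(region, max_insert_len = 50L,
                               reference_protein = NULL, min_coverage = 0.9,
                               max_segments = 2L, start_codons = "ATG",
                               min_identity = 0.8) {
  region <- toupper(region)
  check_dna(region, "region")
  n <- nchar(region)
  max_insert_len <- as.integer(max_insert_len)
  stopifnot(max_insert_len >= 1L)
  if (!max_segments %in% 1:2)
    stop_spec("the repair search supports max_segments of 1 or 2")

  accept <- function(segs) {
    rep_seq <- apply_removals(region, segs)
    orfs <- find_orfs(rep_seq, min_aa = 2L, start_codons = start_codons,
                      strands = "+")
    if (length(orfs) == 0L) return(NULL)
    orf <- orfs[[1L]]
    if (orf$length_nt < min_coverage * nchar(rep_seq)) return(NULL)
    if (!is.null(reference_protein)) {
      if (min_identity >= 1) {
        # exact recovery requested: global PID of 100 means equality
        if (!identical(orf$protein, reference_protein)) return(NULL)
      } else {
        la <- nchar(orf$protein); lb <- nchar(reference_protein)
        if (min(la, lb) / max(la, lb) < min_identity) return(NULL)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(orf$protein),
          Biostrings::AAString(reference_protein),
          type = "global",
          substitutionMatrix = get_substitution_matrix("BLOSUM62"),
          gapOpening = 10, gapExtension = 0.5)
        if (Biostrings::pid(aln, type = "PID1") < 100 * min_identity) return(NULL)
      }
    }
    list(segs = segs, seq = rep_seq, orf = orf)
  }

  sol0 <- accept(list())
  if (!is.null(sol0)) return(repair_result(TRUE, list(), sol0$seq, sol0$orf))

  stops_all <- stop_positions(region)
  by_cls <- lapply(0:2, function(r) stops_all[stops_all %% 3L == r])
  first_stop_ge <- function(pos) {
    cls <- by_cls[[(pos %% 3L) + 1L]]
    i <- findInterval(pos - 1L, cls) + 1L
    if (i > length(cls)) NA_integer_ else cls[i]
  }
  last_stop_lt <- function(pos, cls_of) {
    cls <- by_cls[[(cls_of %% 3L) + 1L]]
    i <- findInterval(pos - 1L, cls)
    if (i >= 1L && cls[i] == pos) i <- i - 1L
    if (i < 1L) NA_integer_ else cls[i]
  }

  # candidate start codons near the 5' end; terminal stops near the 3' end
  max_start <- max(3L, floor((1 - min_coverage) * n) + 3L)
  cand_starts <- integer(0)
  for (sc in toupper(start_codons)) {
    m <- gregexpr(sc, region, fixed = TRUE)[[1L]]
    cand_starts <- c(cand_starts, m[m > 0 & m <= max_start])
  }
  cand_starts <- sort(unique(cand_starts))
  if (length(cand_starts) == 0L)
    return(repair_result(FALSE,
      message = "no start codon near the region 5' end"))
  t_lo <- floor(min_coverage * (n - max_insert_len))
  Ts <- stops_all[stops_all >= t_lo]

  exact_ref <- !is.null(reference_protein) && min_identity >= 1
  nref <- if (exact_ref) nchar(reference_protein) else NA_integer_
  if (exact_ref) {
    # exact recovery pins the removal junctions: complete codons before the
    # first removal must already translate to the reference prefix, and
    # complete codons after the last removal to the reference suffix
    ref_chars <- seq_chars(reference_protein)
    GEN <- Biostrings::GENETIC_CODE
    aa_at <- unname(GEN[substring(region, 1:(n - 2L), 3:n)])
    prefix_pmax <- function(s) {
      i <- 0L
      while (i < nref) {
        cs <- s + 3L * i
        if (cs + 2L > n) break
        aa <- GEN[[substr(region, cs, cs + 2L)]]
        if (is.null(aa) || is.na(aa) || aa != ref_chars[i + 1L]) break
        i <- i + 1L
      }
      s + 3L * i + 2L
    }
    suffix_jmin <- function(Tpos) {
      i <- 0L
      while (i < nref) {
        cs <- Tpos - 3L * (i + 1L)
        if (cs < 1L) break
        aa <- GEN[[substr(region, cs, cs + 2L)]]
        if (is.null(aa) || is.na(aa) || aa != ref_chars[nref - i]) break
        i <- i + 1L
      }
      Tpos - 3L * i - 3L
    }
  }

  seg <- function(p, k) list(position = p, length = k,
                             sequence = substr(region, p, p + k - 1L))

  # Valid removal positions for one segment of length k, read from codon
  # origin `base` (obstruction stop `stf`, suffix backstop B, target stop
  # Tpos). Vectorized over the position window.
  cand_ps <- function(lo, base, stf, hi, Tpos, B, k) {
    p_hi <- min(hi, Tpos + 2L)
    p_lo <- max(lo, if (is.na(B)) lo else B - k - 1L)
    if (p_lo > p_hi) return(integer(0))
    p <- p_lo:p_hi
    rem <- (p - base) %% 3L
    keep <- if (is.na(stf)) rep(TRUE, length(p)) else stf > p - rem - 3L
    pad <- (3L - rem) %% 3L
    j2 <- p + k + pad
    keep <- keep & j2 <= Tpos & (j2 %% 3L) == (Tpos %% 3L)
    if (!is.na(B)) keep <- keep & j2 > B
    jr <- which(keep & rem > 0L)
    if (length(jr)) {
      over <- p[jr] + k + pad[jr] - 1L > n
      keep[jr[over]] <- FALSE
      jr <- jr[!over]
      if (length(jr)) {
        jc <- paste0(substring(region, p[jr] - rem[jr], p[jr] - 1L),
                     substring(region, p[jr] + k, p[jr] + k + pad[jr] - 1L))
        keep[jr[jc %in% STOP_CODONS]] <- FALSE
      }
    }
    p[keep]
  }

  # Per-start bookkeeping (obstruction stop, admissible terminal stops and
  # their backstops) and a cache of the filtered first-removal positions for
  # each (start, k1) pair, reused across the total-length iteration.
  smeta <- lapply(cand_starts, function(s) {
    st1 <- first_stop_ge(s)
    TsS <- Ts[Ts >= s + 3L]
    Bs <- vapply(TsS, function(Tpos) {
      b <- last_stop_lt(Tpos, Tpos); if (is.na(b)) 0L else b
    }, 1L)
    list(s = s, st1 = st1, hi1 = if (is.na(st1)) n else st1 + 2L,
         TsS = TsS, Bs = Bs,
         pmax = if (exact_ref) prefix_pmax(s) else n)
  })
  Tjmin <- if (exact_ref) vapply(Ts, suffix_jmin, 1L) else
    stats::setNames(rep(0L, length(Ts)), NULL)
  p1cache <- new.env(parent = emptyenv())
  # exact mode: positions q (codon starts of the post-first-removal reading,
  # q == delta mod 3 with delta = s + k1) whose codon does NOT translate to
  # the reference residue (q - delta)/3 + 1; sorted, for run lookups
  mismcache <- new.env(parent = emptyenv())
  get_mism <- function(delta) {
    key <- as.character(delta)
    got <- mismcache[[key]]
    if (!is.null(got)) return(got)
    q0 <- ((delta - 1L) %% 3L) + 1L
    q <- seq.int(q0, n - 2L, by = 3L)
    idx <- (q - delta) %/% 3L + 1L
    ok <- idx >= 1L & idx <= nref
    ok[ok] <- !is.na(aa_at[q[ok]]) & aa_at[q[ok]] == ref_chars[idx[ok]]
    got <- q[!ok]
    mismcache[[key]] <- got
    got
  }
  first_mism_ge <- function(delta, from) {
    mm <- get_mism(delta)
    i <- findInterval(from - 1L, mm) + 1L
    if (i > length(mm)) NA_integer_ else mm[i]
  }
  get_p1set <- function(sm, k1) {
    key <- paste0(sm$s, ":", k1)
    got <- p1cache[[key]]
    if (!is.null(got)) return(got)
    p1v <- (sm$s + 1L):sm$hi1
    rem1 <- (p1v - sm$s) %% 3L
    keep <- if (is.na(sm$st1)) rep(TRUE, length(p1v)) else
      sm$st1 > p1v - rem1 - 3L
    pad1 <- (3L - rem1) %% 3L
    j2v <- p1v + k1 + pad1
    keep <- keep & j2v <= n - 2L
    jr <- which(keep & rem1 > 0L)
    if (length(jr)) {
      jc <- paste0(substring(region, p1v[jr] - rem1[jr], p1v[jr] - 1L),
                   substring(region, p1v[jr] + k1,
                             p1v[jr] + k1 + pad1[jr] - 1L))
      bad <- jc %in% STOP_CODONS
      if (exact_ref) {
        ridx <- (p1v[jr] - sm$s - rem1[jr]) %/% 3L + 1L
        jaa <- unname(Biostrings::GENETIC_CODE[jc])
        bad <- bad | is.na(jaa) | ridx < 1L | ridx > nref |
          jaa != ref_chars[pmin(pmax(ridx, 1L), nref)]
      }
      keep[jr[bad]] <- FALSE
    }
    if (exact_ref) {
      # complete codons before the first removal must match the reference
      keep <- keep & p1v <= sm$pmax
    }
    st2v <- rep(NA_integer_, length(p1v))
    for (cls in 0:2) {
      ii <- which(keep & (j2v %% 3L) == cls)
      if (!length(ii)) next
      cl <- by_cls[[cls + 1L]]
      pos <- findInterval(j2v[ii] - 1L, cl) + 1L
      st2v[ii] <- ifelse(pos > length(cl), NA_integer_,
                         cl[pmin(pos, length(cl))])
    }
    keep <- keep & !is.na(st2v)
    got <- list(p1 = p1v[keep], j2 = j2v[keep], st2 = st2v[keep])
    p1cache[[key]] <- got
    got
  }

  # Enumerate removal sets in ascending total length L and accept the first
  # verified one: L is then the provable minimum. When an exact reference
  # protein is required, the admissible total for a (start, terminal stop)
  # pair is fixed by arithmetic and all other totals are skipped.
  for (L in seq_len(max_insert_len)) {
    Lcands <- list()
    seen <- new.env(parent = emptyenv())
    push_cand <- function(segs, s, Tpos) {
      orf_len <- Tpos + 2L - s + 1L - L
      if (orf_len < min_coverage * (n - L)) return(invisible())
      key <- paste(vapply(segs, function(x) paste0(x$position, ":", x$length),
                          ""), collapse = ";")
      if (!is.null(seen[[key]])) return(invisible())
      seen[[key]] <- TRUE
      Lcands[[length(Lcands) + 1L]] <<- segs
      invisible()
    }
    for (sm in smeta) {
      s <- sm$s
      for (ti in seq_along(sm$TsS)) {
        Tpos <- sm$TsS[ti]
        B <- if (sm$Bs[ti] == 0L) NA_integer_ else sm$Bs[ti]
        if ((Tpos - s - L) %% 3L != 0L) next      # frame arithmetic
        if (exact_ref) {
          if (Tpos + 2L - s + 1L - L != 3L * (nref + 1L)) next
          jmin <- Tjmin[match(Tpos, Ts)]
          B <- max(B, jmin - 1L, na.rm = TRUE)    # last junction >= jmin
          if (B == 0L) B <- NA_integer_
        }
        hi_s <- min(sm$hi1, sm$pmax)
        # single segment of length L
        for (p in cand_ps(s + 1L, s, sm$st1, hi_s, Tpos, B, L))
          push_cand(list(seg(p, L)), s, Tpos)
        # two segments k1 + k2 = L
        if (max_segments >= 2L && L >= 2L) {
          for (k1 in seq_len(L - 1L)) {
            k2 <- L - k1
            ps <- get_p1set(sm, k1)
            ok <- which(ps$st2 + k2 + 2L >= (if (is.na(B)) 0L else B) &
                        Tpos >= ps$j2 + 3L)
            for (i1 in ok) {
              j2 <- ps$j2[i1]; st2 <- ps$st2[i1]
              if ((Tpos - j2 - k2) %% 3L != 0L) next
              hi2 <- st2 + 2L
              if (exact_ref) {
                fm <- first_mism_ge(s + k1, j2)
                if (!is.na(fm)) hi2 <- min(hi2, fm + 2L)
              }
              for (p2 in cand_ps(j2, j2, st2, hi2, Tpos, B, k2))
                push_cand(list(seg(ps$p1[i1], k1), seg(p2, k2)), s, Tpos)
            }
          }
        }
      }
    }
    if (length(Lcands)) {
      nsegs <- vapply(Lcands, length, 1L)
      poskey <- vapply(Lcands, function(x)
        paste(sprintf("%09d", vapply(x, `[[`, 1L, "position")),
              collapse = ","), "")
      seqkey <- vapply(Lcands, function(x)
        paste(vapply(x, `[[`, "", "sequence"), collapse = ","), "")
      for (i in order(nsegs, poskey, seqkey)) {
        sol <- accept(Lcands[[i]])
        if (!is.null(sol))
          return(repair_result(TRUE, sol$segs, sol$seq, sol$orf))
      }
    }
  }
  repair_result(FALSE, message = sprintf(
    "no removal of total <= %d bp in <= %d segment(s) restores an ORF",
    max_insert_len, max_segments))
}
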