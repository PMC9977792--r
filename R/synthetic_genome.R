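# Synthetic genomes with planted IS630/Tc1/mariner elements.
#
# The generator states a small world with the statistical structure the
# downstream analysis assumes: elements with exact terminal inverted repeats,
# TA target-site duplication on insertion, a single intact transposase ORF
# carrying a planted D..D..E/D catalytic triad, optional between-copy
# divergence (substitutions + short indels), frameshift-breaking insertions,
# truncated copies and solo TIRs. Every construction is recorded as ground
# truth so that each detector can be tested with no sequence download.

#' Specify a planted catalytic triad
#'
#' Positions are 1-based residue offsets within the translated ORF. The
#' spacing class implied is `paste0("DD", spacing, last_residue)`; the final
#' residue sits at `d2_offset + spacing + 1`.
#'
#' @param d1_offset,d2_offset Residue positions of the first and second
#'   aspartate.
#' @param last_residue `"D"` or `"E"`.
#' @param spacing Residues strictly between the second aspartate and the
#'   final catalytic residue (34 for classical Tc1 DD34E, 40 for DD40E).
#' @return A `triad_spec` list.
#' @export
triad_spec <- function(d1_offset, d2_offset, last_residue = "E", spacing = 34L) {
  d1 <- as.integer(d1_offset); d2 <- as.integer(d2_offset)
  spacing <- as.integer(spacing)
  if (!last_residue %in% c("D", "E")) stop_spec("last_residue must be 'D' or 'E'")
  if (!(d1 < d2)) stop_spec("need d1_offset < d2_offset")
  if (spacing < 0L) stop_spec("spacing must be >= 0")
  structure(list(d1 = d1, d2 = d2, last = d2 + spacing + 1L,
                 last_residue = last_residue, spacing = spacing),
            class = "triad_spec")
}

#' Specify the anatomy of a synthetic element
#'
#' Five-segment layout: 5'TIR, 5'UTR, ORF, 3'UTR, 3'TIR; total element length
#' is `2*tir_len + utr5_len + orf_len + utr3_len`.
#'
#' @param tir_len TIR length in bp (0 permitted: unknown/absent TIRs).
#' @param utr5_len,utr3_len UTR lengths in bp.
#' @param orf_len ORF length in bp including start and stop codon; a multiple
#'   of 3, at least 6.
#' @param triad A [triad_spec()] or `NULL` for no planted triad.
#' @param tsd Target-site duplication dinucleotide (default `"TA"`).
#' @return An `element_spec` list.
#' @export
element_spec <- function(tir_len, utr5_len, orf_len, utr3_len,
                         triad = NULL, tsd = "TA") {
  tir_len <- as.integer(tir_len); utr5_len <- as.integer(utr5_len)
  orf_len <- as.integer(orf_len); utr3_len <- as.integer(utr3_len)
  if (orf_len < 6L || orf_len %% 3L != 0L)
    stop_spec("orf_len must be a multiple of 3 and >= 6")
  if (min(tir_len, utr5_len, utr3_len) < 0L)
    stop_spec("segment lengths must be non-negative")
  if (nchar(tsd) != 2L) stop_spec("tsd must be a dinucleotide")
  check_dna(tsd, "tsd")
  n_aa <- orf_len %/% 3L - 1L
  if (!is.null(triad)) {
    stopifnot(inherits(triad, "triad_spec"))
    if (triad$d1 < 2L || triad$last > n_aa)
      stop_spec(sprintf(
        "triad positions (%d, %d, %d) collide with the start/stop of a %d-aa ORF",
        triad$d1, triad$d2, triad$last, n_aa))
  }
  structure(list(tir_len = tir_len, utr5_len = utr5_len, orf_len = orf_len,
                 utr3_len = utr3_len, triad = triad, tsd = toupper(tsd),
                 n_aa = n_aa,
                 total = 2L * tir_len + utr5_len + orf_len + utr3_len),
            class = "element_spec")
}

# Random ORF of n_aa residues (+ start M, + TAA stop) with the triad and one
# internal methionine planted at recorded positions.
synth_orf <- function(n_aa, triad = NULL) {
  aa_fixed <- integer(0)
  prot <- rep(NA_character_, n_aa)
  prot[1L] <- "M"
  if (!is.null(triad)) {
    prot[triad$d1] <- "D"
    prot[triad$d2] <- "D"
    prot[triad$last] <- triad$last_residue
    aa_fixed <- c(triad$d1, triad$d2, triad$last)
  }
  met_aa <- NA_integer_
  if (n_aa >= 4L) {
    met_aa <- max(2L, n_aa %/% 2L)
    while (met_aa %in% aa_fixed) met_aa <- met_aa + 1L
    if (met_aa <= n_aa) prot[met_aa] <- "M" else met_aa <- NA_integer_
  }
  free <- which(is.na(prot))
  if (length(free)) {
    # uniform over residues then uniform over synonymous codons
    prot[free] <- sample(AA20, length(free), replace = TRUE)
  }
  protected <- c(1L, aa_fixed, met_aa[!is.na(met_aa)])
  if (!is.null(triad)) {
    # the family's conserved glycine context around the triad
    for (g in c(triad$d1 + 18L, triad$d1 + 43L, triad$last - 14L))
      if (g >= 2L && g <= n_aa && !(g %in% protected)) prot[g] <- "G"
    # a real catalytic domain has a unique triad: neutralize decoy (D,D,D/E)
    # combinations so the planted (d2, last) anchor pair is the only one
    # under the default scan parameters
    scan_set <- sort(unique(c(34L, 37L, 38L, 39L, 40L, triad$spacing)))
    for (pass in 1:20) {
      tri <- find_dde_triads(paste0(prot, collapse = ""),
                             spacing_set = scan_set,
                             last_residues = c("D", "E"),
                             d1_d2_range = c(50L, 250L))
      bad <- Filter(function(t) !(t$d2_pos == triad$d2 &&
                                  t$last_pos == triad$last), tri)
      if (length(bad) == 0L) break
      for (t in bad) {
        pos <- setdiff(c(t$last_pos, t$d2_pos, t$d1_pos), protected)[1L]
        if (!is.na(pos)) prot[pos] <- "Q"
      }
    }
  }
  codons <- vapply(prot, function(a) {
    cs <- codons_for(a)
    cs[sample.int(length(cs), 1L)]
  }, "")
  orf <- paste0(paste0(codons, collapse = ""), "TAA")
  list(orf = orf, protein = paste0(prot, collapse = ""), met_aa = met_aa)
}

#' Build one synthetic element from a spec
#'
#' The 5' and 3' TIRs are exact reverse complements; the ORF has a valid
#' start/stop, no internal stop, and carries the planted triad. Two guards
#' keep the construction's truth recoverable by the detectors: the last three
#' bases of the 5'UTR are set to an in-frame `TAA` so the maximal ORF call
#' starts exactly at the planted `ATG`, and the first base inside each TIR
#' boundary is chosen to break inverted-repeat symmetry so the planted TIR
#' length is also the longest exact one.
#'
#' @param spec An [element_spec()].
#' @param rng_seed Integer seed (optional; uses current RNG state if `NULL`).
#' @return List with `seq`, `layout` (an [element_layout()]), `triad` (a
#'   [dde_triad()] truth record or `NULL`), `protein`, `met_aa`, `segments`
#'   (the five segment strings) and `orf_start`/`orf_end` (element coords).
#' @export
build_element <- function(spec, rng_seed = NULL) {
  stopifnot(inherits(spec, "element_spec"))
  with_seed(rng_seed, {
    tir5 <- random_dna(spec$tir_len)
    utr5 <- random_dna(spec$utr5_len)
    utr3 <- random_dna(spec$utr3_len)
    o <- synth_orf(spec$n_aa, spec$triad)

    # guard 1: in-frame stop just upstream of the planted ATG
    if (spec$utr5_len >= 3L)
      utr5 <- paste0(substr(utr5, 1L, spec$utr5_len - 3L), "TAA")

    # guard 2: break TIR symmetry one base inside each boundary
    if (spec$tir_len >= 1L && spec$utr3_len >= 1L) {
      u3_last <- substr(utr3, spec$utr3_len, spec$utr3_len)
      if (spec$utr5_len > 3L) {
        bad <- complement_chr(u3_last)
        u5_first <- sample(setdiff(DNA_BASES, bad), 1L)
        utr5 <- paste0(u5_first, substr(utr5, 2L, spec$utr5_len))
      } else if (spec$utr5_len >= 1L) {
        u5_first <- substr(utr5, 1L, 1L)
        bad <- complement_chr(u5_first)
        u3_last <- sample(setdiff(DNA_BASES, bad), 1L)
        utr3 <- paste0(substr(utr3, 1L, spec$utr3_len - 1L), u3_last)
      }
    }

    tir3 <- revcomp(tir5)
    seqs <- c(tir5 = tir5, utr5 = utr5, orf = o$orf, utr3 = utr3, tir3 = tir3)
    el <- paste0(seqs, collapse = "")
    # zero-TIR elements: force revcomp-symmetric termini so the TSD excision
    # check remains the boundary evidence (the IS630 situation)
    if (spec$tir_len < 2L) {
      el <- paste0(spec$tsd, substr(el, 3L, nchar(el) - 2L), revcomp(spec$tsd))
    }
    stopifnot(nchar(el) == spec$total)
    orf_start <- spec$tir_len + spec$utr5_len + 1L
    orf_end <- orf_start + spec$orf_len - 1L
    triad <- NULL
    if (!is.null(spec$triad))
      triad <- dde_triad(spec$triad$d1, spec$triad$d2, spec$triad$last,
                         spec$triad$last_residue)
    list(seq = el,
         layout = element_layout(spec$tir_len, spec$utr5_len, spec$orf_len,
                                 spec$utr3_len, spec$tir_len),
         triad = triad, protein = o$protein, met_aa = o$met_aa,
         segments = as.list(seqs), orf_start = orf_start, orf_end = orf_end,
         tsd = spec$tsd)
  })
}

#' Specify what to plant into a background genome
#'
#' @param n_full Number of full-length copies.
#' @param partial Numeric vector of coverage fractions in (0,1), one
#'   truncated copy each.
#' @param n_solo_tir Number of solo (element-less) TIR copies.
#' @param divergence `NULL`, or `list(n_snps =, indel_lengths =)` applied to
#'   copy 2 (requires `n_full >= 2`). A 3-bp indel deletes the planted
#'   internal methionine codon in frame; other lengths delete from the 3'UTR.
#' @param frameshift_insertions `NULL`, or a list of `list(at =, seq =)`
#'   insertions applied inside the ORF of the last full copy (`at` is a
#'   1-based nt offset within the ORF, or `NULL` for a seeded draw from the
#'   central 20--60% of the ORF).
#' @return A `plant_plan` list.
#' @export
plant_plan <- function(n_full = 1L, partial = numeric(0), n_solo_tir = 0L,
                       divergence = NULL, frameshift_insertions = NULL) {
  n_full <- as.integer(n_full); n_solo_tir <- as.integer(n_solo_tir)
  if (length(partial) && any(partial <= 0 | partial >= 1))
    stop_spec("partial coverage fractions must lie in (0, 1)")
  if (!is.null(divergence)) {
    stopifnot(is.list(divergence))
    if (n_full < 2L) stop_spec("divergence needs n_full >= 2 (applied to copy 2)")
  }
  if (!is.null(frameshift_insertions)) {
    stopifnot(is.list(frameshift_insertions))
    if (!is.null(divergence) && n_full < 3L)
      stop_spec("divergence + frameshift need n_full >= 3 (distinct target copies)")
  }
  structure(list(n_full = n_full, partial = as.numeric(partial),
                 n_solo_tir = n_solo_tir, divergence = divergence,
                 frameshift_insertions = frameshift_insertions),
            class = "plant_plan")
}

#' Random background genome
#'
#' i.i.d. bases with `P(G) + P(C) = gc`; deterministic under `rng_seed`.
#'
#' @param length Genome length in bp (> 0).
#' @param gc GC fraction, strictly inside (0, 1).
#' @param rng_seed Integer seed.
#' @param id Sequence id.
#' @return A [genome_sequence()].
#' @export
random_background <- function(length, gc = 0.5, rng_seed = NULL, id = "bg1") {
  if (length <= 0) stop_spec("background length must be positive")
  if (!(gc > 0 && gc < 1)) stop_spec("gc must be strictly inside (0, 1)")
  with_seed(rng_seed, genome_sequence(id, random_dna(as.integer(length), gc)))
}

# Apply divergence to a copy sequence; returns list(seq, sub_pos, dels).
diverge_copy <- function(ref, bld, divergence) {
  n <- nchar(ref)
  chars <- seq_chars(ref)
  dels <- list()
  del_zones <- integer(0)
  for (k in divergence$indel_lengths %||% integer(0)) {
    k <- as.integer(k)
    if (k == 3L && !is.na(bld$met_aa)) {
      # in-frame deletion of the planted internal ATG codon
      pos <- bld$orf_start + (bld$met_aa - 1L) * 3L
    } else {
      utr3_start <- bld$orf_end + 1L
      utr3_len <- bld$layout$utr3_len
      if (utr3_len < k + 10L)
        stop_spec(sprintf("3'UTR too short for a %d-bp deletion", k))
      pos <- utr3_start + utr3_len %/% 2L
    }
    dels[[length(dels) + 1L]] <- list(pos = pos, len = k)
    # keep substitutions well clear of the indel (> 2 codons + gap wander)
    # so the indel's local aa consequence stays decodable
    del_zones <- c(del_zones, (pos - 12L):(pos + k + 11L))
  }
  n_snps <- as.integer(divergence$n_snps %||% 0L)
  # never touch the outermost 4 bp (keeps excision-site evidence intact)
  allowed <- setdiff(5:(n - 4L), del_zones)
  if (length(allowed) < n_snps) stop_spec("element too short for requested SNP count")
  sub_pos <- sort(sample(allowed, n_snps))
  for (p in sub_pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  # apply deletions right-to-left so positions stay valid
  for (d in rev(dels[order(vapply(dels, `[[`, 1L, "pos"))])) {
    chars <- chars[-(d$pos:(d$pos + d$len - 1L))]
  }
  list(seq = chars_to_seq(chars), sub_pos = sub_pos, dels = dels)
}

# Apply frameshift insertions (element coords derived from ORF offsets).
frameshift_copy <- function(ref, bld, insertions) {
  orf_len <- bld$layout$orf_len
  ins <- lapply(insertions, function(x) {
    at <- x$at %||% sample(seq.int(round(0.2 * orf_len), round(0.6 * orf_len)), 1L)
    list(at = as.integer(at), seq = toupper(x$seq))
  })
  ins <- ins[order(vapply(ins, `[[`, 1L, "at"))]
  if (length(ins) > 1L &&
      any(diff(vapply(ins, `[[`, 1L, "at")) < 1L))
    stop_spec("frameshift insertion offsets must be distinct")
  s <- ref
  for (x in rev(ins)) {
    pos <- bld$orf_start + x$at - 1L   # insert before this element position
    s <- paste0(substr(s, 1L, pos - 1L), x$seq, substr(s, pos, nchar(s)))
  }
  list(seq = s, insertions = ins,
       orf_len_new = orf_len + sum(nchar(vapply(ins, `[[`, "", "seq"))))
}

#' Plant elements into a background genome
#'
#' Each full insertion happens at a TA target site whose dinucleotide is
#' duplicated (flank pattern `tsd | element | tsd`); partial copies and solo
#' TIRs are inserted without duplication. Divergence (substitutions never
#' hitting the outermost 4 bp, plus short indels) is applied to copy 2;
#' frameshift insertions to the last full copy. Fully reproducible under
#' `rng_seed`.
#'
#' @param background A [genome_sequence()], or an integer length from which a
#'   background is drawn (GC fraction `gc`).
#' @param spec An [element_spec()].
#' @param plan A [plant_plan()].
#' @param rng_seed Integer seed.
#' @param gc Background GC fraction when `background` is a length.
#' @return List with `genome` (a [genome_sequence()]), `truth` (a data.frame
#'   of planted features: type, copy, start, end, strand, length, note) and
#'   `detail` (reference element build, per-copy sequences/intervals,
#'   divergence and frameshift records).
#' @export
plant_elements <- function(background, spec, plan, rng_seed = NULL, gc = 0.42) {
  stopifnot(inherits(spec, "element_spec"), inherits(plan, "plant_plan"))
  with_seed(rng_seed, {
    bg <- if (is.numeric(background)) {
      genome_sequence("synth1", random_dna(as.integer(background), gc))
    } else as_genome_sequence(background)

    bld <- build_element(spec)
    instances <- list()

    div_copy <- if (!is.null(plan$divergence)) 2L else NA_integer_
    fs_copy <- if (!is.null(plan$frameshift_insertions)) {
      if (plan$n_full == 1L) 1L else plan$n_full
    } else NA_integer_

    divergence_rec <- NULL; frameshift_rec <- NULL
    for (i in seq_len(plan$n_full)) {
      s <- bld$seq; note <- "full"
      orf_off <- c(bld$orf_start, bld$orf_end)
      if (!is.na(div_copy) && i == div_copy) {
        dv <- diverge_copy(bld$seq, bld, plan$divergence)
        s <- dv$seq; note <- "full_diverged"; divergence_rec <- dv
        for (d in dv$dels)   # shift ORF end for deletions inside the ORF
          if (d$pos >= bld$orf_start && d$pos <= bld$orf_end)
            orf_off[2L] <- orf_off[2L] - d$len
      }
      if (!is.na(fs_copy) && i == fs_copy) {
        fs <- frameshift_copy(bld$seq, bld, plan$frameshift_insertions)
        s <- fs$seq; note <- "full_frameshift"; frameshift_rec <- fs
        orf_off <- c(bld$orf_start, bld$orf_start + fs$orf_len_new - 1L)
      }
      instances[[length(instances) + 1L]] <-
        list(type = "full", copy = i, seq = s, tsd = TRUE, note = note,
             orf_off = orf_off)
    }
    for (f in plan$partial) {
      keep <- max(1L, round(f * nchar(bld$seq)))
      from5 <- sample(c(TRUE, FALSE), 1L)
      s <- if (from5) substr(bld$seq, 1L, keep)
           else substr(bld$seq, nchar(bld$seq) - keep + 1L, nchar(bld$seq))
      instances[[length(instances) + 1L]] <-
        list(type = "partial", copy = NA_integer_, seq = s, tsd = FALSE,
             note = sprintf("partial_%s_%.2f", if (from5) "5p" else "3p", f),
             retained = if (from5) c(1L, keep)
                        else c(nchar(bld$seq) - keep + 1L, nchar(bld$seq)))
    }
    for (i in seq_len(plan$n_solo_tir)) {
      if (spec$tir_len < 1L) stop_spec("cannot plant solo TIRs with tir_len 0")
      instances[[length(instances) + 1L]] <-
        list(type = "solo_tir", copy = NA_integer_, seq = bld$segments$tir5,
             tsd = FALSE, note = "solo_tir")
    }

    n_items <- length(instances)
    if (n_items == 0L) {
      return(list(genome = bg, truth = empty_truth(), detail = list(element = bld)))
    }
    # one insertion point per equal-width block, margins away from edges
    block <- bg$length %/% n_items
    if (block < 120L)
      stop_placement(sprintf("background of %d bp too short for %d placements",
                             bg$length, n_items))
    points <- vapply(seq_len(n_items), function(i) {
      lo <- (i - 1L) * block + 50L
      hi <- i * block - 50L
      sample(seq.int(lo, hi), 1L)
    }, 1L)
    ord <- sample.int(n_items)      # which instance goes at which point
    instances <- instances[ord]

    pieces <- character(0); cur <- 1L; total <- 0L
    rows <- list()
    push <- function(x) { pieces[[length(pieces) + 1L]] <<- x; total <<- total + nchar(x) }
    for (j in seq_len(n_items)) {
      p <- points[j]; inst <- instances[[j]]
      push(substr(bg$seq, cur, p - 1L))
      if (inst$tsd) {
        push(spec$tsd)
        st <- total + 1L; push(inst$seq); en <- total
        push(spec$tsd)
        cur <- p + 2L                # original site dinucleotide consumed
      } else {
        st <- total + 1L; push(inst$seq); en <- total
        cur <- p
      }
      rows[[j]] <- data.frame(type = inst$type, copy = inst$copy, start = st,
                              end = en, strand = "+", length = en - st + 1L,
                              note = inst$note, stringsAsFactors = FALSE)
      instances[[j]]$interval <- c(st, en)
    }
    push(substr(bg$seq, cur, bg$length))
    gseq <- genome_sequence(bg$id, paste0(pieces, collapse = ""))
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL

    copies <- lapply(instances, function(inst) {
      out <- list(type = inst$type, copy = inst$copy, note = inst$note,
                  interval = interval(gseq$id, inst$interval[1L], inst$interval[2L]),
                  seq = inst$seq)
      if (!is.null(inst$orf_off))
        out$orf_interval <- interval(gseq$id,
                                     inst$interval[1L] + inst$orf_off[1L] - 1L,
                                     inst$interval[1L] + inst$orf_off[2L] - 1L)
      out
    })
    list(genome = gseq, truth = truth,
         detail = list(element = bld, copies = copies,
                       divergence = divergence_rec, frameshift = frameshift_rec,
                       spec = spec, plan = plan))
  })
}

empty_truth <- function() {
  data.frame(type = character(0), copy = integer(0), start = integer(0),
             end = integer(0), strand = character(0), length = integer(0),
             note = character(0), stringsAsFactors = FALSE)
}
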