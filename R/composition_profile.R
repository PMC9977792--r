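# Amino-acid composition vectors, Pearson-correlation ranking against a
# proteome, and serine-rich category labels for unknown domains.

#' Amino-acid composition of a protein
#'
#' Fractions over the 20 standard residues (alphabetical one-letter order).
#' Ambiguous residues (B, Z, X, U, O) and gaps are excluded from both
#' numerator and denominator; the fractions always sum to 1.
#'
#' @param protein Amino-acid string.
#' @param protein_id Identifier stored with the vector.
#' @return An `aa_composition` with `freqs` (named 20-vector), `n_residues`,
#'   `protein_id`.
#' @export
aa_composition <- function(protein, protein_id = "query") {
  chars <- seq_chars(toupper(protein))
  chars <- chars[chars %in% AA20]
  if (length(chars) == 0L)
    stop_validation("no standard residues left after exclusions")
  counts <- table(factor(chars, levels = AA20))
  freqs <- as.numeric(counts) / length(chars)
  names(freqs) <- AA20
  stopifnot(abs(sum(freqs) - 1) < 1e-9)
  structure(list(protein_id = protein_id, freqs = freqs,
                 n_residues = length(chars)),
            class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  cat(sprintf("<aa_composition> %s (%d aa)\n", x$protein_id, x$n_residues))
  top <- sort(x$freqs, decreasing = TRUE)[1:4]
  cat(sprintf("  top residues: %s\n",
              paste(sprintf("%s %.2f%%", names(top), 100 * top), collapse = ", ")))
  invisible(x)
}

#' Pearson correlation of two composition vectors
#'
#' Population Pearson correlation over the 20 paired fractions. A vector
#' with zero variance (single-residue protein) has no defined correlation:
#' `NA` is returned with a classed warning.
#'
#' @param a,b [aa_composition()] objects.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
composition_pcc <- function(a, b) {
  stopifnot(inherits(a, "aa_composition"), inherits(b, "aa_composition"))
  if (stats::sd(a$freqs) == 0 || stats::sd(b$freqs) == 0) {
    warning(warningCondition("zero-variance composition vector: undefined correlation",
                             class = "tc1scout_undefined_pcc_warning"))
    return(NA_real_)
  }
  unname(stats::cor(a$freqs, b$freqs))
}

#' Rank a proteome by composition similarity to a query
#'
#' @param query An [aa_composition()].
#' @param proteome Non-empty list of [aa_composition()] objects.
#' @return A data.frame (protein_id, pcc) sorted by pcc descending, ties by
#'   protein_id ascending; a permutation of the input ids.
#' @export
rank_against_proteome <- function(query, proteome) {
  if (length(proteome) == 0L) stop_validation("proteome is empty")
  ids <- vapply(proteome, function(p) p$protein_id, "")
  pcc <- vapply(proteome, function(p)
    suppressWarnings(composition_pcc(query, p)), 1)
  df <- data.frame(protein_id = ids, pcc = pcc, stringsAsFactors = FALSE)
  df <- df[order(-df$pcc, df$protein_id, na.last = TRUE), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Serine-rich category label of a composition vector
#'
#' Labels follow the field's serine-rich protein families: SR-rich (Ser/Arg),
#' SAP-rich (Ser/Ala/Pro), PS-rich (Pro/Ser) and SP-rich (Ser/Pro). Serine
#' must be enriched (>= `primary` times its background frequency) for any
#' label; partner residues use the `partner` multiplier. When both serine
#' and proline qualify, the more abundant of the two residues leads the
#' label (SP- vs PS-rich).
#'
#' @param v An [aa_composition()].
#' @param thresholds `list(primary =, partner =)` enrichment multipliers
#'   (defaults 2 and 1.5).
#' @param background Named background frequencies per residue (e.g. from a
#'   host proteome); defaults to uniform 0.05.
#' @return One of `"SR-rich"`, `"SAP-rich"`, `"PS-rich"`, `"SP-rich"`,
#'   `"none"`.
#' @export
rich_class <- function(v, thresholds = list(primary = 2, partner = 1.5),
                       background = NULL) {
  stopifnot(inherits(v, "aa_composition"))
  bg <- rep(0.05, 20); names(bg) <- AA20
  if (!is.null(background)) bg[names(background)] <- background
  f <- v$freqs
  enr <- function(res, mult) f[[res]] >= mult * bg[[res]]
  if (!enr("S", thresholds$primary)) return("none")
  if (enr("R", thresholds$partner)) return("SR-rich")
  if (enr("A", thresholds$partner) && enr("P", thresholds$partner))
    return("SAP-rich")
  if (enr("P", thresholds$partner))
    return(if (f[["S"]] >= f[["P"]]) "SP-rich" else "PS-rich")
  "none"
}

#' Two-region composition ratio report
#'
#' Per-residue fraction ratios between two regions (e.g. an unknown domain
#' vs the transposase region of the same protein), rounded to 2 decimals.
#'
#' @param a,b [aa_composition()] objects (ratios are a / b).
#' @return A data.frame (residue, freq_a, freq_b, ratio).
#' @export
composition_ratio <- function(a, b) {
  stopifnot(inherits(a, "aa_composition"), inherits(b, "aa_composition"))
  data.frame(residue = AA20,
             freq_a = unname(a$freqs),
             freq_b = unname(b$freqs),
             ratio = round(ifelse(b$freqs > 0, a$freqs / b$freqs, NA), 2))
}
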