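# DDE/DDD catalytic-triad detection and spacing-class nomenclature, domain
# geometry, and pairwise identity/positives statistics on aligned domains.

#' Construct a DDE/DDD triad record
#'
#' @param d1_pos,d2_pos,last_pos 1-based residue positions, strictly
#'   increasing.
#' @param last_residue `"D"` or `"E"`.
#' @param evidence_score Optional conservation evidence (see
#'   [find_dde_triads()]).
#' @return A `dde_triad` with `spacing = last_pos - d2_pos - 1` and
#'   `spacing_class = paste0("DD", spacing, last_residue)`.
#' @export
dde_triad <- function(d1_pos, d2_pos, last_pos, last_residue,
                      evidence_score = NA_real_) {
  cls <- spacing_class(d1_pos, d2_pos, last_pos, last_residue)
  structure(list(d1_pos = as.integer(d1_pos), d2_pos = as.integer(d2_pos),
                 last_pos = as.integer(last_pos), last_residue = last_residue,
                 spacing = as.integer(last_pos - d2_pos - 1L),
                 spacing_class = cls, evidence_score = evidence_score),
            class = "dde_triad")
}

#' @export
print.dde_triad <- function(x, ...) {
  cat(sprintf("<dde_triad> %s at %d/%d/%d (evidence %.0f)\n", x$spacing_class,
              x$d1_pos, x$d2_pos, x$last_pos, x$evidence_score))
  invisible(x)
}

#' Spacing-class string of a catalytic triad
#'
#' The class names the number of residues strictly between the second
#' aspartate and the final catalytic residue: `DD34E` is the classical Tc1
#' motif, `DD34D` the mariner one.
#'
#' @param d1,d2,last 1-based residue positions, `d1 < d2 < last`.
#' @param last_residue `"D"` or `"E"`.
#' @return Class string, e.g. `"DD40E"`.
#' @examples
#' spacing_class(892, 1056, 1097, "E") # "DD40E"
#' @export
spacing_class <- function(d1, d2, last, last_residue) {
  if (!(d1 < d2 && d2 < last))
    stop_validation("triad positions must satisfy d1 < d2 < last")
  if (!last_residue %in% c("D", "E"))
    stop_validation("last_residue must be 'D' or 'E'")
  paste0("DD", last - d2 - 1L, last_residue)
}

#' Find candidate DDE/DDD catalytic triads in a protein
#'
#' Enumerates all (D, D, D/E) position triples whose second spacing
#' (`last - d2 - 1`) lies in `spacing_set` and whose first spacing
#' (`d2 - d1 - 1`) lies in `d1_d2_range`. Each triad is scored by the number
#' of glycines within +/-30 residues of any of the three anchors (the
#' family's conserved-glycine context); results are sorted by evidence score
#' descending, then total span ascending, then position.
#'
#' @param protein Amino-acid string.
#' @param spacing_set Admissible `last - d2 - 1` spacings. The default
#'   \{34, 37, 38, 39, 40\} covers the classical DD34E/DD34D classes, the
#'   known DD37D/DD37E/DD38E/DD39D exceptions and DD40E.
#' @param last_residues Admissible final residues.
#' @param d1_d2_range Admissible range for `d2 - d1 - 1`.
#' @return List of `dde_triad` objects (possibly empty).
#' @export
find_dde_triads <- function(protein, spacing_set = c(34L, 37L, 38L, 39L, 40L),
                            last_residues = c("D", "E"),
                            d1_d2_range = c(50L, 250L)) {
  stopifnot(nzchar(protein), length(spacing_set) >= 1L)
  chars <- seq_chars(toupper(protein))
  n <- length(chars)
  dpos <- which(chars == "D")
  lastpos <- sort(unique(unlist(lapply(last_residues, function(r) which(chars == r)))))
  gpos <- which(chars == "G")
  out <- list()
  for (d2 in dpos) {
    ls <- lastpos[(lastpos - d2 - 1L) %in% spacing_set & lastpos > d2]
    if (length(ls) == 0L) next
    d1s <- dpos[dpos < d2 &
                (d2 - dpos - 1L) >= d1_d2_range[1L] &
                (d2 - dpos - 1L) <= d1_d2_range[2L]]
    if (length(d1s) == 0L) next
    for (last in ls) {
      for (d1 in d1s) {
        anchors <- c(d1, d2, last)
        win <- unique(unlist(lapply(anchors, function(a)
          max(1L, a - 30L):min(n, a + 30L))))
        score <- sum(gpos %in% win)
        out[[length(out) + 1L]] <-
          dde_triad(d1, d2, last, chars[last], score)
      }
    }
  }
  if (length(out) == 0L) return(list())
  ev <- vapply(out, function(x) x$evidence_score, 1)
  span <- vapply(out, function(x) x$last_pos - x$d1_pos, 1L)
  d1v <- vapply(out, function(x) x$d1_pos, 1L)
  d2v <- vapply(out, function(x) x$d2_pos, 1L)
  out[order(-ev, span, d1v, d2v)]
}

#' Construct a domain span
#'
#' @param start_aa,end_aa 1-based inclusive residue coordinates.
#' @return A `domain_span` with `length_aa = end_aa - start_aa + 1`.
#' @export
domain_span <- function(start_aa, end_aa) {
  if (start_aa > end_aa) stop_validation("need start_aa <= end_aa")
  structure(list(start_aa = as.integer(start_aa), end_aa = as.integer(end_aa),
                 length_aa = as.integer(end_aa - start_aa + 1L)),
            class = "domain_span")
}

#' Length of a domain span in residues
#'
#' @param span A [domain_span()].
#' @return Inclusive length in aa.
#' @examples
#' domain_length(domain_span(892, 1097)) # 206
#' @export
domain_length <- function(span) {
  stopifnot(inherits(span, "domain_span"))
  span$length_aa
}

#' Inclusive residue span of an insert or motif
#'
#' @param region_start,region_end 1-based inclusive residue coordinates.
#' @return Integer length in aa.
#' @examples
#' insert_span(945, 994) # 50
#' @export
insert_span <- function(region_start, region_end) {
  if (region_start > region_end) stop_validation("need start <= end")
  as.integer(region_end - region_start + 1L)
}

#' Pairwise identity and positives of two aligned domains
#'
#' Columns where both sequences carry a residue (no gap) are counted as
#' `n_cols`; `n_identical` counts identical residue pairs and `n_positive`
#' counts pairs with a positive substitution score (identities included,
#' BLOSUM62 by default). Percentages follow the field's printed precision:
#' identity to 2 decimals, positives to 1.
#'
#' @param aligned_a,aligned_b Equal-length aligned amino-acid strings (gaps
#'   `-` or `.`).
#' @param substitution_matrix Matrix name from Biostrings (e.g. "BLOSUM62")
#'   or an actual scoring matrix.
#' @return A `pairwise_domain_stats` list: `n_cols`, `n_identical`,
#'   `n_positive`, `identity_pct`, `positives_pct`.
#' @export
pairwise_domain_stats <- function(aligned_a, aligned_b,
                                  substitution_matrix = "BLOSUM62") {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop_validation("aligned sequences must have equal length")
  mat <- get_substitution_matrix(substitution_matrix)
  a <- seq_chars(toupper(aligned_a))
  b <- seq_chars(toupper(aligned_b))
  res <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  a <- a[res]; b <- b[res]
  n_cols <- length(a)
  if (n_cols == 0L) stop_validation("no columns with residues in both sequences")
  n_id <- sum(a == b)
  sc <- rep(-1, n_cols)
  known <- a %in% rownames(mat) & b %in% colnames(mat)
  sc[known] <- mat[cbind(a[known], b[known])]
  n_pos <- sum(sc > 0)
  structure(list(n_cols = n_cols, n_identical = n_id, n_positive = n_pos,
                 identity_pct = round(100 * n_id / n_cols, 2),
                 positives_pct = round(100 * n_pos / n_cols, 1)),
            class = "pairwise_domain_stats")
}

#' @export
print.pairwise_domain_stats <- function(x, ...) {
  cat(sprintf("<pairwise_domain_stats> identity %.2f%% (%d/%d), positives %.1f%% (%d/%d)\n",
              x$identity_pct, x$n_identical, x$n_cols,
              x$positives_pct, x$n_positive, x$n_cols))
  invisible(x)
}
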