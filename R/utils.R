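# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions -------------------------------------------------------

tc1_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tc1scout_error")))
}

stop_format     <- function(msg) tc1_stop(msg, "tc1scout_format_error")
stop_alphabet   <- function(msg) tc1_stop(msg, "tc1scout_alphabet_error")
stop_validation <- function(msg) tc1_stop(msg, "tc1scout_validation_error")
stop_spec       <- function(msg) tc1_stop(msg, "tc1scout_spec_error")
stop_placement  <- function(msg) tc1_stop(msg, "tc1scout_placement_error")
stop_flank      <- function(msg) tc1_stop(msg, "tc1scout_flank_error")
stop_ambiguous  <- function(msg) tc1_stop(msg, "tc1scout_ambiguous_boundary_error")
stop_usage      <- function(msg) tc1_stop(msg, "tc1scout_usage_error")

## Seeded evaluation --------------------------------------------------------

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
# All generator entry points funnel randomness through this helper so that a
# single integer seed makes a whole simulation reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Sequence primitives ------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# One-letter codes of the 20 standard amino acids, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

is_dna <- function(x) !grepl("[^ACGTN]", x)

check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x)) stop_alphabet(paste(what, "must be a single string"))
  if (!is_dna(x)) stop_alphabet(paste0(what, " contains characters outside {A,C,G,T,N}"))
  invisible(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste0(x, collapse = "")

# Codon starts of a frame-0 reading of `x` (length multiple of 3 not required;
# trailing partial codon dropped).
codon_split <- function(x) {
  n <- nchar(x)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(x, starts, starts + 2L)
}

complement_chr <- function(ch) chartr("ACGTN", "TGCAN", ch)

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars_to_seq(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

# Random codon uniform over the 61 non-stop codons.
NONSTOP_CODONS <- local({
  all3 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all3, STOP_CODONS)
})

# Codons encoding a given residue (standard code), stops excluded.
codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa & !(names(gc) %in% STOP_CODONS)]
}

## Substitution matrices ----------------------------------------------------

get_substitution_matrix <- function(m) {
  if (is.matrix(m)) return(m)
  stopifnot(is.character(m), length(m) == 1L)
  e <- new.env()
  utils::data(list = m, package = "Biostrings", envir = e)
  get(m, envir = e)
}

nt_submat <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

# Shared affine-gap defaults (match 2 / mismatch -3 / open -5 / extend -2);
# Biostrings expresses gap penalties as positive costs.
align_global_nt <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = nt_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
}

align_local_nt <- function(a, b, match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = nt_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
}
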