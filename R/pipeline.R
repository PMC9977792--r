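# End-to-end discovery workflow: ORF scan -> triad filter -> TIR/excision
# validation -> layout -> census -> reports. Deterministic under a fixed
# (inputs, config, seed) triple.

#' Discovery pipeline configuration
#'
#' All thresholds of the discovery workflow in one validated object; unknown
#' keys are rejected. Every threshold is echoed into the run log.
#'
#' @param ... Overrides for: `start_codons`, `min_orf_aa`, `spacing_set`,
#'   `last_residues`, `d1_d2_range`, `tir_min`, `tir_max`,
#'   `tir_min_identity`, `tsd`, `max_flank`, `census_min_identity`,
#'   `full_length_min_coverage`, `rng_seed`, `out_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(start_codons = "ATG", min_orf_aa = 100L,
              spacing_set = c(34L, 37L, 38L, 39L, 40L),
              last_residues = c("D", "E"), d1_d2_range = c(50L, 250L),
              tir_min = 10L, tir_max = 250L, tir_min_identity = 1.0,
              tsd = "TA", max_flank = 3000L, census_min_identity = 0.8,
              full_length_min_coverage = 0.9, rng_seed = 1L, out_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop_usage(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

# Locate TIR-bracketed element boundaries around a candidate transposase ORF.
# Candidate 5' starts are positions preceded by the TSD; candidate 3' ends
# are followed by it. Pairs whose first tir_min bases are exact reverse
# complements are extended base by base; the longest TIR wins (ties: leftmost
# start, then widest span).
locate_element <- function(genome, orf_iv, cfg) {
  g <- genome$seq; L <- genome$length
  m <- cfg$tir_min
  a_lo <- max(3L, orf_iv$start - cfg$max_flank)
  a_hi <- orf_iv$start - m
  b_lo <- orf_iv$end + m
  b_hi <- min(L - 2L, orf_iv$end + cfg$max_flank)
  if (a_lo > a_hi || b_lo > b_hi) return(NULL)
  av <- a_lo:a_hi
  av <- av[substring(g, av - 2L, av - 1L) == cfg$tsd]
  bv <- b_lo:b_hi
  bv <- bv[substring(g, bv + 1L, bv + 2L) == cfg$tsd]
  if (!length(av) || !length(bv)) return(NULL)
  apref <- substring(g, av, av + m - 1L)
  bterm <- vapply(substring(g, bv - m + 1L, bv), revcomp, "")
  bmap <- split(seq_along(bv), bterm)
  best <- NULL
  for (ai in seq_along(av)) {
    bis <- bmap[[apref[ai]]]
    if (is.null(bis)) next
    a <- av[ai]
    for (bi in bis) {
      b <- bv[bi]
      l <- m
      while (l < cfg$tir_max &&
             a + l <= orf_iv$start - 1L && b - l >= orf_iv$end + 1L &&
             substr(g, a + l, a + l) ==
               complement_chr(substr(g, b - l, b - l))) {
        l <- l + 1L
      }
      cand <- list(a = a, b = b, tir_len = l)
      if (is.null(best) || l > best$tir_len ||
          (l == best$tir_len && (a < best$a || (a == best$a && b > best$b))))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  el <- interval(genome$id, best$a, best$b)
  tir <- tir_pair(interval(genome$id, best$a, best$a + best$tir_len - 1L),
                  interval(genome$id, best$b - best$tir_len + 1L, best$b),
                  best$tir_len, 1.0)
  list(element = el, tir = tir)
}

#' Run the structure-based discovery workflow on a genome
#'
#' For every ORF above `min_orf_aa` whose protein carries a candidate
#' DDE/DDD triad, the three-point evidence rule is applied: a pair of
#' identical TIRs bracketing the ORF, excision sites matching the
#' target-site duplication, and the transposase ORF itself. Candidates
#' failing TIR or excision evidence are reported separately. A copy census
#' against the longest reported element is appended.
#'
#' @param genome Path to a FASTA file, or a [genome_sequence()] / list
#'   thereof.
#' @param config A [pipeline_config()].
#' @return List with `elements` (data.frame), `failed` (data.frame),
#'   `census` (data.frame) and `files` (paths written, when
#'   `config$out_dir` is set).
#' @export
run_discover <- function(genome, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  genomes <- load_genomes(genome)
  elements <- list(); failed <- list(); layouts <- list()
  for (g in genomes) {
    orfs <- find_orfs(g, min_aa = config$min_orf_aa,
                      start_codons = config$start_codons, strands = "+")
    for (orf in orfs) {
      triads <- find_dde_triads(orf$protein, spacing_set = config$spacing_set,
                                last_residues = config$last_residues,
                                d1_d2_range = config$d1_d2_range)
      if (length(triads) == 0L) next
      triad <- triads[[1L]]
      loc <- locate_element(g, orf$interval, config)
      rec <- data.frame(
        seq_id = g$id, orf_start = orf$interval$start,
        orf_end = orf$interval$end, orf_aa = orf$length_aa,
        triad = triad$spacing_class,
        d1 = triad$d1_pos, d2 = triad$d2_pos, last = triad$last_pos,
        stringsAsFactors = FALSE)
      if (is.null(loc)) {
        rec$reason <- "no TIR pair with TSD-flanked boundaries"
        failed[[length(failed) + 1L]] <- rec
        next
      }
      lay <- annotate_layout(g, loc$element, loc$tir, orf, config$tsd)
      rec$start <- loc$element$start; rec$end <- loc$element$end
      rec$length <- interval_length(loc$element)
      rec$tir_len <- loc$tir$length
      rec$excision_ok <- lay$excision_ok
      rec$flank5 <- lay$flank5_4mer; rec$flank3 <- lay$flank3_4mer
      if (isTRUE(lay$excision_ok)) {
        elements[[length(elements) + 1L]] <- rec
        layouts[[length(layouts) + 1L]] <-
          list(id = sprintf("te%03d", length(layouts) + 1L),
               interval = loc$element, layout = lay,
               seq = extract_interval(g, loc$element), genome_id = g$id)
      } else {
        rec$reason <- "excision sites failed"
        failed[[length(failed) + 1L]] <- rec
      }
    }
  }
  bindr <- function(x) if (length(x)) do.call(rbind_fill, x) else data.frame()
  el_df <- bindr(elements); fa_df <- bindr(failed)
  cen <- data.frame()
  if (length(layouts)) {
    ref <- layouts[[which.max(vapply(layouts, function(l) nchar(l$seq), 1L))]]
    hits <- list()
    for (g in genomes)
      hits <- c(hits, find_copies(g, ref$seq,
                                  min_identity = config$census_min_identity))
    cen <- census_table(hits)
  }
  out <- list(elements = el_df, failed = fa_df, census = cen, files = character(0))
  if (!is.null(config$out_dir))
    out$files <- write_discover_outputs(out, layouts, genomes, config)
  out
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}

load_genomes <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    return(read_fasta(genome))   # format error (exit 3) when unreadable
  if (inherits(genome, "genome_sequence")) return(list(genome))
  if (is.list(genome)) return(lapply(genome, as_genome_sequence))
  stop_usage("genome must be a FASTA path or genome_sequence object(s)")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_discover_outputs <- function(res, layouts, genomes, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  files <- c(elements = file.path(od, "elements.tsv"),
             failed = file.path(od, "failed_evidence.tsv"),
             census = file.path(od, "census.tsv"),
             gff = file.path(od, "elements.gff3"),
             log = file.path(od, "run.log"),
             summary = file.path(od, "summary.json"))
  write_tsv(res$elements, files["elements"])
  write_tsv(res$failed, files["failed"])
  write_tsv(res$census, files["census"])
  lens <- stats::setNames(vapply(genomes, function(g) g$length, 1L),
                          vapply(genomes, function(g) g$id, ""))
  write_gff(layouts, files["gff"], seq_lengths = lens)
  cfg_echo <- vapply(names(unclass(config)), function(k)
    paste0(k, " = ", paste(format(config[[k]]), collapse = ",")), "")
  writeLines(c(paste("tc1scout", as.character(utils::packageVersion("tc1scout"))),
               cfg_echo,
               paste("genomes:", paste(names(lens), lens, sep = ":", collapse = " "))),
             files["log"])
  jsonlite::write_json(list(n_elements = nrow(res$elements),
                            n_failed = nrow(res$failed),
                            n_full_length = if (nrow(res$census))
                              sum(res$census$full_length) else 0L),
                       files["summary"], auto_unbox = TRUE)
  files
}

#' Simulate a genome with planted elements and write truth files
#'
#' @param out_dir Output directory (FASTA + truth GFF3 + truth TSV).
#' @param spec An [element_spec()].
#' @param plan A [plant_plan()].
#' @param background_len Background length in bp.
#' @param rng_seed Integer seed.
#' @param gc Background GC fraction.
#' @return The [plant_elements()] result, with `files` attached.
#' @export
run_simulate <- function(out_dir, spec, plan, background_len = 20000L,
                         rng_seed = 1L, gc = 0.42) {
  sim <- plant_elements(background_len, spec, plan, rng_seed = rng_seed, gc = gc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(fasta = file.path(out_dir, "genome.fa"),
             truth = file.path(out_dir, "truth.tsv"),
             element = file.path(out_dir, "element.fa"))
  write_fasta(sim$genome, files["fasta"])
  write_tsv(sim$truth, files["truth"])
  write_fasta(genome_sequence("reference_element", sim$detail$element$seq),
              files["element"])
  sim$files <- files
  sim
}

#' Copy census subcommand
#'
#' @param genome FASTA path or [genome_sequence()].
#' @param element FASTA path or element string.
#' @param out_dir Optional output directory (census TSV + BED6 + JSON).
#' @param min_identity Identity threshold for hits.
#' @return List with `census` data.frame, `hits`, `solo_tirs`.
#' @export
run_census <- function(genome, element, out_dir = NULL, min_identity = 0.8) {
  g <- load_genomes(genome)[[1L]]
  el <- if (is.character(element) && file.exists(element))
    read_fasta(element)[[1L]]$seq else as_genome_sequence(element)$seq
  hits <- find_copies(g, el, min_identity = min_identity)
  tir <- detect_tirs(el)
  solo <- if (!is.null(tir))
    find_solo_tirs(g, substr(el, 1L, tir$length), exclude = hits) else list()
  cen <- census_table(hits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(cen, file.path(out_dir, "census.tsv"))
    if (length(hits))
      write_bed6(lapply(hits, `[[`, "interval"), file.path(out_dir, "census.bed"))
    jsonlite::write_json(list(n_hits = length(hits),
                              n_full_length = sum(cen$full_length),
                              n_solo_tirs = length(solo)),
                         file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  }
  list(census = cen, hits = hits, solo_tirs = solo)
}

#' Composition profiling subcommand
#'
#' @param query Protein FASTA path or amino-acid string.
#' @param proteome Optional proteome FASTA path (enables PCC ranking and a
#'   proteome-derived background for the rich-class label).
#' @param out_dir Optional output directory.
#' @return List with `composition`, `ranking`, `label`.
#' @export
run_compose <- function(query, proteome = NULL, out_dir = NULL) {
  qseq <- if (is.character(query) && file.exists(query)) {
    r <- Biostrings::readAAStringSet(query)
    stats::setNames(as.character(r[[1L]]), names(r)[1L])
  } else stats::setNames(query, "query")
  qv <- aa_composition(qseq[[1L]], protein_id = names(qseq))
  ranking <- NULL; bg <- NULL
  if (!is.null(proteome)) {
    pr <- Biostrings::readAAStringSet(proteome)
    pv <- lapply(seq_along(pr), function(i)
      aa_composition(as.character(pr[[i]]), protein_id = names(pr)[i]))
    ranking <- rank_against_proteome(qv, pv)
    tot <- Reduce(`+`, lapply(pv, function(p) p$freqs * p$n_residues))
    bg <- tot / sum(tot)
  }
  label <- rich_class(qv, background = bg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(data.frame(residue = AA20, fraction = unname(qv$freqs)),
              file.path(out_dir, "composition.tsv"))
    if (!is.null(ranking)) write_tsv(ranking, file.path(out_dir, "pcc_ranking.tsv"))
    jsonlite::write_json(list(label = label, n_residues = qv$n_residues),
                         file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  }
  list(composition = qv, ranking = ranking, label = label)
}

#' Phylogeny subcommand
#'
#' @param alignment Aligned amino-acid FASTA path (or named character
#'   vector).
#' @param outgroup Optional outgroup id (enables rooting + clade report).
#' @param out_dir Optional output directory (newick + clade TSV).
#' @param model Distance model for [p_distance_matrix()].
#' @return List with `tree`, `rooted`, `clades`.
#' @export
run_phylo <- function(alignment, outgroup = NULL, out_dir = NULL,
                      model = "p") {
  aln <- if (is.character(alignment) && length(alignment) == 1L &&
             file.exists(alignment)) {
    s <- Biostrings::readAAStringSet(alignment)
    stats::setNames(as.character(s), names(s))
  } else alignment
  dm <- p_distance_matrix(aln, model = model)
  tree <- nj_tree(dm)
  rooted <- NULL; clades <- NULL
  if (!is.null(outgroup)) {
    rooted <- root_with_outgroup(tree, outgroup)
    clades <- ingroup_clades(tree, outgroup)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(rooted %||% tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(clades)) {
      cl <- data.frame(clade = rep(seq_along(clades),
                                   vapply(clades, length, 1L)),
                       tip = unlist(clades))
      write_tsv(cl, file.path(out_dir, "clades.tsv"))
    }
  }
  list(tree = tree, rooted = rooted, clades = clades)
}
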