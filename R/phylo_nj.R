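# Distance-based phylogeny of DDE domains: p-distances from an aligned set,
# Saitou-Nei neighbor joining with deterministic tie-breaking, outgroup
# rooting and two-clade membership reporting.

#' Pairwise p-distance matrix of an aligned set
#'
#' p-distance = mismatches / columns where both sequences carry a residue;
#' gapped columns are excluded pairwise. A Poisson correction
#' (`-log(1 - p)`) is available via `model = "poisson"`.
#'
#' @param aligned Named character vector (or list / `AAStringSet`) of
#'   equal-length gapped amino-acid strings, at least 3.
#' @param model `"p"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal and sequence names as
#'   dimnames.
#' @export
p_distance_matrix <- function(aligned, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (methods::is(aligned, "XStringSet")) {
    nm <- names(aligned)
    aligned <- as.character(aligned)
    names(aligned) <- nm
  }
  aligned <- unlist(aligned)
  n <- length(aligned)
  if (n < 3L) stop_validation("need at least 3 sequences")
  if (length(unique(nchar(aligned))) != 1L)
    stop_validation("aligned sequences must have equal length")
  ids <- names(aligned) %||% paste0("seq", seq_len(n))
  if (is.null(names(aligned))) names(aligned) <- ids
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  is_res <- !(m %in% c("-", ".")); dim(is_res) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- is_res[i, ] & is_res[j, ]
      if (!any(comp))
        stop_validation(sprintf("no comparable columns between '%s' and '%s'",
                                ids[i], ids[j]))
      p <- mean(m[i, comp] != m[j, comp])
      if (model == "poisson") {
        if (p >= 1) stop_validation(sprintf(
          "p-distance of 1 between '%s' and '%s': Poisson correction undefined",
          ids[i], ids[j]))
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

fmt_bl <- function(x) sprintf("%.10g", max(0, x))

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Deterministic: ties on Q are broken by the lowest index pair. Negative
#' branch-length estimates are clamped to zero with the deficit moved to the
#' sibling edge (their sum, the joined pair's distance, is preserved).
#'
#' @param dm Symmetric distance matrix with dimnames (or a `dist`).
#' @return An unrooted binary `phylo` tree (ape).
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop_validation("distance matrix must be square")
  if (max(abs(dm - t(dm))) > 1e-8 || any(diag(dm) != 0) || any(dm < 0))
    stop_validation("distance matrix must be symmetric, non-negative, zero-diagonal")
  n <- nrow(dm)
  if (n < 3L) stop_validation("need at least 3 taxa")
  labs <- rownames(dm) %||% paste0("t", seq_len(n))
  if (any(grepl("[(),:; ]", labs)))
    stop_validation("taxon labels must not contain newick metacharacters")
  sub <- labs
  D <- dm
  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- D[i, j]; vi <- 0 }
    if (vj < 0) { vi <- D[i, j]; vj <- 0 }
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt_bl(vi), sub[j], fmt_bl(vj))
    ks <- setdiff(seq_len(nn), c(i, j))
    dnew <- pmax(0, (D[i, ks] + D[j, ks] - D[i, j]) / 2)
    D <- D[ks, ks, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    sub <- c(sub[ks], newsub)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt_bl(v[1]),
                 sub[2], fmt_bl(v[2]), sub[3], fmt_bl(v[3]))
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup's pendant edge
#'
#' Idempotent for a fixed outgroup.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_id A leaf label.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop_validation(sprintf("unknown outgroup '%s'", outgroup_id))
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}

#' Ingroup clade membership after outgroup rooting
#'
#' Drops the outgroup and reports the tip sets of the two basal ingroup
#' clades (the clade I / clade II readout).
#'
#' @param tree A `phylo` tree (rooted or not).
#' @param outgroup_id The outgroup leaf label.
#' @return List of character vectors of tip labels, one per basal clade.
#' @export
ingroup_clades <- function(tree, outgroup_id) {
  tree <- root_with_outgroup(tree, outgroup_id)
  ing <- ape::drop.tip(tree, outgroup_id)
  ntip <- length(ing$tip.label)
  root <- ntip + 1L
  kids <- ing$edge[ing$edge[, 1] == root, 2]
  lapply(kids, function(k) {
    if (k <= ntip) ing$tip.label[k]
    else sort(ape::extract.clade(ing, k)$tip.label)
  })
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
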