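# Distance-based phylogeny: p-distances, a deterministic neighbour-joining
# implementation, bootstrap supports on reference-tree bipartitions, and
# Newick output. Trees are ape "phylo" objects throughout.

#' p-distance matrix from an alignment
#'
#' Computes `d(i, j) = 1 - identity(i, j) / 100` on the gap-stripped site
#' set (columns with a gap in any sequence are excluded before distance
#' computation).
#'
#' @param x An [msa()] with at least 3 sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (nrow(x) < 3L) stop("need at least 3 sequences")
  im <- identity_matrix(x, sites = "ungapped")
  d <- 1 - unclass(im) / 100
  attr(d, "summary") <- NULL
  diag(d) <- 0
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("distance matrix is not symmetric")
  }
  if (any(d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  d
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Neighbour-joining tree
#'
#' Standard neighbour-joining agglomeration on the Q-criterion
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j`. Ties on Q are broken toward the
#' lowest `(i, j)` index pair in the current id order, making the result
#' deterministic. Negative branch lengths are clamped to zero; the number
#' of clamped branches is reported in the `"clamped"` attribute.
#'
#' For an additive distance matrix the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param d Symmetric non-negative distance matrix (zero diagonal) with at
#'   least 3 taxa; rownames are taxon ids.
#' @return An unrooted `ape::phylo` tree (basal trichotomy) with branch
#'   lengths.
#' @export
neighbor_joining <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  # each working taxon is represented by a growing newick fragment
  frag <- labels
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  while (n > 3L) {
    r <- rowSums(d)
    best <- NULL; best_q <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt_bl(li), ",",
                       frag[j], ":", fmt_bl(lj), ")")
    others <- setdiff(seq_len(n), c(i, j))
    new_d <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- rbind(cbind(d[others, others, drop = FALSE], new_d),
               c(new_d, 0))
    frag <- c(frag[others], new_frag)
    n <- n - 1L
  }
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", frag[1L], ":", fmt_bl(l1), ",",
                frag[2L], ":", fmt_bl(l2), ",",
                frag[3L], ":", fmt_bl(l3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# Canonical nontrivial bipartitions of an unrooted tree, each encoded as a
# sorted, comma-joined string of the tip labels on the side NOT containing
# the alphabetically first tip.
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)
  out <- character(0L)
  for (p in parts) {
    side <- tree$tip.label[p]
    if (anchor %in% side) side <- setdiff(tips, side)
    k <- length(side)
    if (k >= 2L && k <= length(tips) - 2L) {
      out <- c(out, paste(sort(side), collapse = ","))
    }
  }
  unique(out)
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the reference NJ tree from the full gap-stripped site set, then
#' resamples sites with replacement `n_trials` times, rebuilds the NJ tree
#' for each replicate, and counts, for every internal edge of the
#' reference tree, the replicates containing the same bipartition.
#' Supports are integer counts out of `n_trials`, attached as internal
#' node labels, and are deterministic under a fixed seed.
#'
#' @param x An [msa()] with at least 4 sequences.
#' @param n_trials Number of bootstrap replicates (the published analysis
#'   used 1000).
#' @param seed Integer seed for site resampling.
#' @return The reference `phylo` tree with `node.label` holding supports
#'   (root label empty) and attribute `"n_trials"`.
#' @export
bootstrap_support <- function(x, n_trials = 1000L, seed = 1L) {
  stopifnot(inherits(x, "msa"), n_trials >= 1L)
  if (nrow(x) < 4L) stop("bootstrap supports undefined for fewer than 4 taxa")
  stripped <- strip_allgap_sites(x)
  # canonicalise row order so supports are invariant to leaf input order
  # (floating-point Q near-ties would otherwise depend on summation order)
  m <- unclass(stripped)[order(rownames(stripped)), , drop = FALSE]
  class(m) <- c("msa", class(m))
  stripped <- m
  ref <- neighbor_joining(p_distance_matrix(stripped))
  ref_splits <- tree_bipartitions(ref)
  counts <- stats::setNames(integer(length(ref_splits)), ref_splits)
  ncols <- ncol(stripped)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (t in seq_len(n_trials)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    rep_msa <- unclass(stripped)[, cols, drop = FALSE]
    class(rep_msa) <- c("msa", class(rep_msa))
    rep_tree <- neighbor_joining(p_distance_matrix(rep_msa))
    hit <- ref_splits %in% tree_bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  # attach supports as internal node labels in prop.part node order
  parts <- ape::prop.part(ref)
  tips <- sort(ref$tip.label)
  anchor <- tips[1L]
  labs <- character(length(parts))
  for (k in seq_along(parts)) {
    side <- ref$tip.label[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = ",")
    labs[k] <- if (key %in% names(counts)) as.character(counts[[key]]) else ""
  }
  ref$node.label <- labs
  attr(ref, "supports") <- counts
  attr(ref, "n_trials") <- as.integer(n_trials)
  ref
}

#' Serialise a tree to Newick
#'
#' Writes branch lengths and (when present) integer bootstrap supports as
#' internal node labels, compatible with standard tree viewers.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Parse a Newick string or file
#'
#' @param text Newick string (or `NULL` when reading `path`).
#' @param path Optional file path.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}
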