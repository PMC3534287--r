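# Shared helpers: independent brute-force oracles and random-input
# generators used across the suite. Oracles are deliberately naive and
# share no code with the implementation paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# Random gapped MSA; column 1 is kept gap-free so every pair shares at
# least one non-gap column and gap-stripping never empties the alignment.
random_msa <- function(n = 5L, len = 40L, gap_prob = 0.15) {
  rows <- vapply(seq_len(n), function(i) {
    chars <- sample(AA20, len, TRUE)
    gaps <- runif(len) < gap_prob
    gaps[1L] <- FALSE
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1L))
  msa(stats::setNames(rows, paste0("s", seq_len(n))))
}

# Naive per-column gap filter.
oracle_strip_gaps <- function(m) {
  mm <- unclass(m)
  keep <- vapply(seq_len(ncol(mm)), function(j) all(mm[, j] != "-"),
                 logical(1L))
  mm[, keep, drop = FALSE]
}

# Naive pairwise identity with pairwise gap exclusion.
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  num <- 0L; den <- 0L
  for (k in seq_along(av)) {
    if (av[k] != "-" && bv[k] != "-") {
      den <- den + 1L
      if (av[k] == bv[k]) num <- num + 1L
    }
  }
  100 * num / den
}

# Position-by-position motif oracle: same Y..G.D.R.F pattern and the
# greedy non-overlapping policy, written as a direct window check.
oracle_motif <- function(seq, allow_variant = TRUE) {
  chars <- strsplit(seq, "")[[1L]]
  hits <- data.frame(start = integer(0L), motif_name = character(0L))
  i <- 1L
  while (i + 9L <= length(chars)) {
    w <- chars[i:(i + 9L)]
    core_ok <- w[1L] == "Y" && w[4L] == "G"
    anchors <- c(w[6L] == "D", w[8L] == "R", w[10L] == "F")
    kind <- NULL
    if (core_ok && all(anchors)) kind <- "plant_motif"
    else if (core_ok && allow_variant && sum(!anchors) == 1L)
      kind <- "plant_motif_variant"
    if (!is.null(kind)) {
      hits <- rbind(hits, data.frame(start = i - 1L, motif_name = kind))
      i <- i + 10L
    } else i <- i + 1L
  }
  hits
}

# Exhaustive hinge oracle: score every in-window Glu with an independent
# re-statement of the profile, apply the documented tie rule.
oracle_hinge <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  len <- length(chars)
  allowed <- list("E", c("E", "K", "R"), "G", c("S", "T"),
                  c("A", "G", "S", "T", "N", "Q"),
                  c("A", "G", "S", "T", "V"), c("A", "G", "S", "T", "V"),
                  c("A", "G", "S", "T", "V"), c("A", "G", "S", "T", "V"))
  weights <- c(2, 1, 1, 1, 1, 1, 1, 1, 1)
  wstart <- len - floor(0.4 * len)          # 0-based
  cands <- which(chars == "E") - 1L
  cands <- cands[cands >= wstart & cands + 19L <= len - 1L]
  if (length(cands) == 0L) return(NULL)
  score <- vapply(cands, function(p) {
    sum(weights[vapply(seq_len(9L), function(k)
      chars[p + k] %in% allowed[[k]], logical(1L))])
  }, numeric(1L))
  tie <- abs(((len - 1L) - (cands + 16L)) - 35L)
  cands[order(-score, tie, -cands)][1L]
}

# Exhaustive two-site amplicon oracle: enumerate every forward-site /
# reverse-site pair with the reverse site fully downstream.
oracle_amplicon_count <- function(template, fwd, rvs) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  all_sites <- function(tmpl, pat) {
    n <- nchar(tmpl); k <- nchar(pat)
    which(vapply(seq_len(n - k + 1L),
                 function(i) substr(tmpl, i, i + k - 1L) == pat,
                 logical(1L)))
  }
  f <- all_sites(template, fwd)
  r <- all_sites(template, revcomp(rvs))
  sum(outer(f, r, function(fs, rs) rs >= fs + nchar(fwd)))
}

# Random planted tree with strictly positive branch lengths.
random_planted_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 0.5)
  tr
}
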