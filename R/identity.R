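# Percent-identity matrices from a multiple sequence alignment, display
# banding, and gap-column filtering.

#' Remove alignment columns containing any gap
#'
#' Retains exactly the columns where no sequence has a gap, preserving
#' column order (the site-exclusion rule used before distance and tree
#' computation).
#'
#' @param x An [msa()].
#' @return An `msa` over the ungapped column subset.
#' @export
strip_allgap_sites <- function(x) {
  stopifnot(inherits(x, "msa"))
  keep <- colSums(unclass(x) == "-") == 0L
  if (!any(keep)) stop("no ungapped sites remain after gap exclusion")
  m <- unclass(x)[, keep, drop = FALSE]
  class(m) <- c("msa", class(m))
  m
}

#' Percent identity between two aligned rows
#'
#' `100 * identical / shared`, where `shared` counts columns in which both
#' rows are non-gap; columns with a gap in either row are excluded from
#' numerator and denominator (pairwise gap exclusion).
#'
#' @param rowA,rowB Equal-length aligned sequences (strings or character
#'   vectors of residues).
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_identity("ABCD", "ABCE")  # 75
#' @export
percent_identity <- function(rowA, rowB) {
  a <- if (length(rowA) == 1L) strsplit(rowA, "", fixed = TRUE)[[1L]] else rowA
  b <- if (length(rowB) == 1L) strsplit(rowB, "", fixed = TRUE)[[1L]] else rowB
  if (length(a) != length(b)) stop("rows have unequal length")
  shared <- a != "-" & b != "-"
  if (!any(shared)) stop("zero shared non-gap columns")
  100 * sum(a[shared] == b[shared]) / sum(shared)
}

#' Pairwise percent-identity matrix
#'
#' @param x An [msa()] with at least two sequences.
#' @param sites `"all"` computes identities on the full alignment (with
#'   pairwise gap exclusion); `"ungapped"` first applies
#'   [strip_allgap_sites()].
#' @return An object of class `identity_matrix`: the symmetric percentage
#'   matrix with a `summary` attribute (`min`, `max`, `mean` over the
#'   off-diagonal upper triangle).
#' @export
identity_matrix <- function(x, sites = c("all", "ungapped")) {
  stopifnot(inherits(x, "msa"))
  sites <- match.arg(sites)
  if (nrow(x) < 2L) stop("need at least 2 sequences")
  if (sites == "ungapped") x <- strip_allgap_sites(x)
  n <- nrow(x)
  m <- diag(100, n)
  dimnames(m) <- list(rownames(x), rownames(x))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- percent_identity(unclass(x)[i, ], unclass(x)[j, ])
    }
  }
  off <- m[upper.tri(m)]
  attr(m, "summary") <- c(min = min(off), max = max(off), mean = mean(off))
  class(m) <- c("identity_matrix", class(m))
  m
}

#' @export
print.identity_matrix <- function(x, digits = 1L, ...) {
  s <- attr(x, "summary")
  m <- x
  attr(m, "summary") <- NULL
  class(m) <- "matrix"
  print(round(m, digits))
  cat(sprintf("off-diagonal identity: min %.1f, max %.1f, mean %.1f\n",
              s[["min"]], s[["max"]], s[["mean"]]))
  invisible(x)
}

#' Display band for a percent-identity value
#'
#' Bands follow the display legend on the nearest-integer value:
#' red 20-39, orange 40-59, yellow 60-79, green 80-99; below 20 is
#' `"below_range"` and 100 is `"identical"`.
#'
#' @param value Percentage(s) in \[0, 100\] (vectorised).
#' @return Character vector of band names.
#' @examples
#' band_identity(c(87, 42.9, 39.6))  # green, orange, orange
#' @export
band_identity <- function(value) {
  if (any(value < 0 | value > 100)) stop("identity out of [0, 100]")
  r <- floor(value + 0.5)  # deterministic nearest-integer
  out <- character(length(value))
  out[r < 20] <- "below_range"
  out[r >= 20 & r <= 39] <- "red"
  out[r >= 40 & r <= 59] <- "orange"
  out[r >= 60 & r <= 79] <- "yellow"
  out[r >= 80 & r <= 99] <- "green"
  out[r >= 100] <- "identical"
  out
}
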