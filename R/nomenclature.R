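# Reactive-centre-based serpin nomenclature and physico-chemical residue
# classes.

RESIDUE_CLASSES <- list(
  small = c("A", "C", "G", "S", "T"),
  medium_large_hydrophobic = c("F", "I", "L", "M", "P", "V", "W", "Y"),
  polar = c("H", "N", "Q"),
  negatively_charged = c("D", "E"),
  positively_charged = c("K", "R")
)

#' Physico-chemical class of a residue
#'
#' Partition of the 20 standard residues into five classes: small
#' (A, C, G, S, T); medium and large hydrophobic (F, I, L, M, P, V, W, Y);
#' polar (H, N, Q); negatively charged (D, E); positively charged (K, R).
#'
#' @param residue Single uppercase one-letter residue code (vectorised).
#' @return Character vector of class names.
#' @examples
#' classify_residue("R")  # "positively_charged"
#' @export
classify_residue <- function(residue) {
  vapply(as.character(residue), function(r) {
    hit <- names(RESIDUE_CLASSES)[vapply(RESIDUE_CLASSES, function(s) r %in% s,
                                         logical(1L))]
    if (length(hit) != 1L) stop("unknown residue: '", r, "'")
    hit
  }, character(1L), USE.NAMES = FALSE)
}

#' Build reactive-centre-based serpin names
#'
#' Renders names of the form `<prefix>SRP-<P2 P1 P1'>` (e.g. `OsSRP-LRS`
#' for the serpin at Os03g41419). When two or more serpins of one species
#' share a P2-P1' code, all colliding members receive numeric suffixes
#' 1..n in ascending locus-id order; unique codes stay unsuffixed.
#'
#' @param records Data frame with columns `locus_id`, `species_prefix`,
#'   `code` (3-residue P2-P1' triplet).
#' @return The input with an added `name` column, in the input row order.
#' @examples
#' make_names(data.frame(locus_id = "Os03g41419", species_prefix = "Os",
#'                       code = "LRS"))$name
#' @export
make_names <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("locus_id", "species_prefix", "code") %in% names(records)))
  if (anyDuplicated(records$locus_id)) {
    stop("duplicate locus_id: ",
         paste(unique(records$locus_id[duplicated(records$locus_id)]),
               collapse = ", "))
  }
  bad <- !grepl("^[A-Z]{3}$", records$code)
  if (any(bad)) {
    stop("invalid P2-P1' code(s): ",
         paste(records$code[bad], collapse = ", "))
  }
  key <- paste(records$species_prefix, records$code, sep = "\r")
  name <- paste0(records$species_prefix, "SRP-", records$code)
  for (k in unique(key[duplicated(key)])) {
    members <- which(key == k)
    members <- members[order(records$locus_id[members])]
    name[members] <- paste0(name[members], seq_along(members))
  }
  records$name <- name
  records
}

#' Census of P1 residues by physico-chemical class
#'
#' Counts the serpins in a reactive-centre table by the class of the P1
#' residue (the middle residue of each P2-P1' code). All five classes are
#' reported, including zero counts.
#'
#' @param table Data frame with a `code` column of P2-P1' triplets
#'   (e.g. the `locus_table` from [load_rice_fixture()], or its printed
#'   inhibitory-only subset `table3 == TRUE`).
#' @return Named integer vector over the five residue classes.
#' @export
count_by_p1_class <- function(table) {
  stopifnot(is.data.frame(table), "code" %in% names(table))
  counts <- stats::setNames(integer(length(RESIDUE_CLASSES)),
                            names(RESIDUE_CLASSES))
  if (nrow(table) > 0L) {
    cls <- classify_residue(substr(table$code, 2L, 2L))
    tab <- table(factor(cls, levels = names(RESIDUE_CLASSES)))
    counts[] <- as.integer(tab)
  }
  counts
}
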