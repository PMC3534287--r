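# Residue alphabet: the 20 standard one-letter codes plus the ambiguity code X.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_OK <- c(AA_STANDARD, "X")

#' Construct a serpin protein record
#'
#' A `serpin_record` holds one protein sequence together with its locus
#' identifier (e.g. `"Os03g41419"`), the two-letter species prefix used for
#' naming (e.g. `"Os"` for *Oryza sativa*), and a free-text description.
#'
#' @param locus_id Locus identifier; must be non-empty.
#' @param sequence Protein sequence, uppercase one-letter codes. The 20
#'   standard residues plus `X` are accepted; gaps are rejected (records hold
#'   unaligned sequences).
#' @param species_prefix Two-letter species prefix. Defaults to the first two
#'   characters of `locus_id`.
#' @param description Optional free text (FASTA header remainder).
#' @return An object of class `serpin_record`.
#' @examples
#' serpin_record("Os03g41419", "MADDVSKL")
#' @export
serpin_record <- function(locus_id, sequence,
                          species_prefix = substr(locus_id, 1L, 2L),
                          description = "") {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    stop("sequence must be non-empty for locus '", locus_id, "'")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET_OK)
  if (length(bad) > 0L) {
    stop("invalid residue(s) ", paste(sQuote(bad), collapse = ", "),
         " in sequence for locus '", locus_id,
         "' (gaps and non-standard codes are not allowed)")
  }
  structure(
    list(locus_id = locus_id,
         species_prefix = species_prefix,
         sequence = sequence,
         description = description),
    class = "serpin_record"
  )
}

#' @export
print.serpin_record <- function(x, ...) {
  cat("<serpin_record> ", x$locus_id, " (", nchar(x$sequence), " aa)\n",
      sep = "")
  invisible(x)
}

seq_chars <- function(record) {
  strsplit(record$sequence, "", fixed = TRUE)[[1L]]
}

#' Read protein sequences from a FASTA file
#'
#' Parses an unaligned protein FASTA file into a list of
#' [serpin_record()] objects. The locus identifier is the first whitespace
#' -delimited token of each header; the remainder becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A named list of `serpin_record` objects (class `serpin_set`),
#'   in file order.
#' @details Duplicate identifiers and gap characters are errors: records are
#'   unaligned sequences and identifiers must be unique within a collection.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aas)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1L), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  recs <- vector("list", length(aas))
  for (i in seq_along(aas)) {
    s <- as.character(aas[[i]])
    if (grepl("-", s, fixed = TRUE)) {
      stop("gap character in unaligned input for '", ids[i],
           "'; use read_alignment() for aligned data")
    }
    recs[[i]] <- serpin_record(ids[i], s, description = desc[i])
  }
  names(recs) <- ids
  structure(recs, class = "serpin_set")
}

#' Write serpin records to FASTA
#'
#' @param records A `serpin_set` or list of `serpin_record` objects.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) {
      paste(r$locus_id, r$description)
    } else {
      r$locus_id
    }
    cat(">", header, "\n", sep = "", file = con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` is a rectangular character matrix: one row per sequence, one
#' column per alignment site; gaps are encoded `"-"`.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return A character matrix of class `msa` with sequence ids as rownames.
#' @examples
#' msa(c(a = "AB-", b = "A-C"))
#' @export
msa <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  class(m) <- c("msa", class(m))
  m
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", nrow(x), " sequences x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

msa_strings <- function(x) {
  stats::setNames(apply(unclass(x), 1L, paste, collapse = ""), rownames(x))
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal-format alignment into an [msa()].
#' All rows must have equal length; gaps are `"-"`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An `msa` object.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  aas <- as.character(Biostrings::unmasked(aln))
  if (length(aas) == 0L) stop("empty alignment: ", path)
  # Dots sometimes encode gaps in third-party Clustal output.
  aas <- gsub(".", "-", aas, fixed = TRUE)
  msa(aas)
}

#' Write an alignment as aligned FASTA
#'
#' @param x An `msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  seqs <- msa_strings(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", seqs[[i]], "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Load the packaged rice serpin reference tables
#'
#' Returns the in-package reference data for the 14 full-length serpins of
#' rice (*Oryza sativa* cv. Nipponbare): the reactive-centre locus table,
#' the two primer tables (semi-quantitative and real-time RT-PCR), the
#' curation edit scripts, and a table of locus-assignment discrepancies in
#' the source annotations (shipped verbatim, deliberately not reconciled).
#'
#' @return A list with elements `locus_table` (14 rows: `locus_id`, `code`,
#'   `class_label`, `table3`, `name`), `primers_semiquant`,
#'   `primers_realtime` (columns `gene`, `forward`, `reverse`,
#'   `amplicon_bp`), `edit_scripts` (see [build_rice_scripts()]) and
#'   `discrepancies`.
#' @examples
#' fx <- load_rice_fixture()
#' subset(fx$locus_table, locus_id == "Os03g41419")$code  # "LRS"
#' @export
load_rice_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "serpintools",
                                 mustWork = TRUE)
  read_tsv <- function(f) {
    utils::read.delim(ext(f), stringsAsFactors = FALSE, comment.char = "#")
  }
  locus_table <- read_tsv("rice_locus_table.tsv")
  locus_table$table3 <- as.logical(locus_table$table3)
  stopifnot(nrow(locus_table) == 14L, !anyDuplicated(locus_table$locus_id))
  list(
    locus_table = locus_table,
    primers_semiquant = read_tsv("rice_primers_semiquant.tsv"),
    primers_realtime = read_tsv("rice_primers_realtime.tsv"),
    edit_scripts = build_rice_scripts(),
    discrepancies = read_tsv("rice_locus_discrepancies.tsv")
  )
}
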