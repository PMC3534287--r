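# Reactive-centre-loop annotation: hinge location, canonical P positions,
# P2-P1' code extraction, inhibitory classification and motif scanning.
#
# Coordinates are 0-based internally; all user-facing reports are 1-based.

#' Default annotation parameters
#'
#' The hinge consensus profile scores the proximal RCL (P17 through P9).
#' The conserved P17 Glu is a required anchor worth 2; P16 accepts E/K/R,
#' P15 requires G, P14 S/T, P13 any of A/G/S/T/N/Q, and P12 through P9 each
#' accept the small set A/G/S/T/V, one point each, for a maximum score of 10.
#' The ambiguity code X never scores. Class cutoffs reproduce the published
#' calls: inhibitory requires a near-consensus hinge (score >= 7) and a
#' small P1' (A/C/G/S); a serpin is called non-inhibitory when the hinge is
#' clearly degenerate (score <= 4) or when a non-small P1' combines with at
#' least two non-small residues at P12-P9; anything else is uncertain.
#'
#' @param window_frac Fraction of the sequence (C-terminal end) searched for
#'   hinge candidates. Default 0.4.
#' @param p1_target_from_cterm Preferred distance (residues) of P1 from the
#'   C-terminus, used only to break ties between equal-scoring candidates.
#' @param inhibitory_min_score Minimum hinge score for an inhibitory call.
#' @param non_inhibitory_max_score Hinge score at or below which the serpin
#'   is called non-inhibitory outright.
#' @param small_p1prime Residues counted as "small" at P1'.
#' @param hinge_small Residues counted as small within P12-P9.
#' @param motif_max_anchor_mismatch How many of the D/R/F motif anchors may
#'   mismatch in a "conservative variant" motif hit (0 disables variants).
#' @param hinge_profile Optional replacement consensus profile: a list of
#'   entries `list(label, offset, allowed, weight)` with `offset` counted
#'   from P17. `NULL` uses the default profile described above.
#' @return A list of annotation parameters.
#' @export
annotation_config <- function(window_frac = 0.4,
                              p1_target_from_cterm = 35L,
                              inhibitory_min_score = 7L,
                              non_inhibitory_max_score = 4L,
                              small_p1prime = c("A", "C", "G", "S"),
                              hinge_small = c("A", "G", "S", "T", "V"),
                              motif_max_anchor_mismatch = 1L,
                              hinge_profile = NULL) {
  stopifnot(window_frac > 0, window_frac <= 1,
            inhibitory_min_score > non_inhibitory_max_score)
  # label, offset from P17, allowed residues, weight
  default_profile <- list(
    list(label = "P17", offset = 0L, allowed = "E", weight = 2L),
    list(label = "P16", offset = 1L, allowed = c("E", "K", "R"), weight = 1L),
    list(label = "P15", offset = 2L, allowed = "G", weight = 1L),
    list(label = "P14", offset = 3L, allowed = c("S", "T"), weight = 1L),
    list(label = "P13", offset = 4L,
         allowed = c("A", "G", "S", "T", "N", "Q"), weight = 1L),
    list(label = "P12", offset = 5L,
         allowed = c("A", "G", "S", "T", "V"), weight = 1L),
    list(label = "P11", offset = 6L,
         allowed = c("A", "G", "S", "T", "V"), weight = 1L),
    list(label = "P10", offset = 7L,
         allowed = c("A", "G", "S", "T", "V"), weight = 1L),
    list(label = "P9", offset = 8L,
         allowed = c("A", "G", "S", "T", "V"), weight = 1L)
  )
  list(
    window_frac = window_frac,
    p1_target_from_cterm = as.integer(p1_target_from_cterm),
    inhibitory_min_score = as.integer(inhibitory_min_score),
    non_inhibitory_max_score = as.integer(non_inhibitory_max_score),
    small_p1prime = small_p1prime,
    hinge_small = hinge_small,
    motif_max_anchor_mismatch = as.integer(motif_max_anchor_mismatch),
    hinge_profile = if (is.null(hinge_profile)) default_profile
                    else hinge_profile
  )
}

hinge_profile_score <- function(chars, p17_index0, config) {
  score <- 0L
  for (pos in config$hinge_profile) {
    res <- chars[p17_index0 + pos$offset + 1L]
    if (res %in% pos$allowed) score <- score + pos$weight
  }
  score
}

#' Locate the RCL hinge (conserved P17 glutamate)
#'
#' Scans Glu residues in the C-terminal search window and scores each as a
#' putative P17 anchor against the hinge consensus profile, returning the
#' best-scoring candidate. Ties are broken toward the candidate whose P1
#' lies closest to `p1_target_from_cterm` residues from the C-terminus,
#' then toward the more C-terminal candidate.
#'
#' @param record A [serpin_record()].
#' @param config Parameters from [annotation_config()].
#' @return A list of class `hinge_hit` with `p17_index` (0-based),
#'   `hinge_score`, and `candidate_rank` (1 = best).
#' @export
find_hinge <- function(record, config = annotation_config()) {
  chars <- seq_chars(record)
  len <- length(chars)
  if (len < 60L) {
    stop("sequence too short for hinge search (", len, " < 60 residues)")
  }
  window_start0 <- len - floor(config$window_frac * len)  # 0-based inclusive
  cand0 <- which(chars == "E") - 1L
  # room for P17..P3': p17 + 19 must be a valid index
  cand0 <- cand0[cand0 >= window_start0 & cand0 + 19L <= len - 1L]
  if (length(cand0) == 0L) {
    stop("no hinge candidate: no suitable Glu in the C-terminal search window")
  }
  scores <- vapply(cand0, hinge_profile_score, integer(1L),
                   chars = chars, config = config)
  p1_dist <- (len - 1L) - (cand0 + 16L)
  tie_dist <- abs(p1_dist - config$p1_target_from_cterm)
  ord <- order(-scores, tie_dist, -cand0)
  best <- ord[1L]
  structure(
    list(p17_index = cand0[best],
         hinge_score = scores[best],
         candidate_rank = 1L,
         n_candidates = length(cand0)),
    class = "hinge_hit"
  )
}

P_LABELS <- c(paste0("P", 17:1), "P1'", "P2'", "P3'")

#' Assign canonical P positions from the P17 anchor
#'
#' Canonical positions are counted C-terminal from the conserved Glu at
#' P17: `index(Pk) = p17_index + (17 - k)` for k = 17..1, so P1 sits 16
#' residues after the anchor and P1' immediately follows it.
#'
#' @param record A [serpin_record()].
#' @param hinge A `hinge_hit` from [find_hinge()].
#' @return Named integer vector of class `position_map`: 0-based sequence
#'   indices for labels P17..P1, P1'..P3'.
#' @export
assign_p_positions <- function(record, hinge) {
  p17 <- hinge$p17_index
  len <- nchar(record$sequence)
  if (seq_chars(record)[p17 + 1L] != "E") {
    stop("hinge invalid for record: residue at P17 index is not Glu")
  }
  if (p17 + 19L > len - 1L) {
    stop("position map would exceed sequence end (need P17 index + 19 < ",
         len, ")")
  }
  idx <- p17 + 0:19
  structure(stats::setNames(as.integer(idx), P_LABELS),
            class = "position_map")
}

#' Extract the reactive-centre P2-P1' code
#'
#' @param record A [serpin_record()].
#' @param positions A `position_map` from [assign_p_positions()].
#' @return Three-character string: residues at P2, P1, P1'.
#' @export
reactive_centre_code <- function(record, positions) {
  chars <- seq_chars(record)
  paste0(chars[positions[["P2"]] + 1L],
         chars[positions[["P1"]] + 1L],
         chars[positions[["P1'"]] + 1L])
}

#' Classify a serpin as inhibitory, non-inhibitory or uncertain
#'
#' Applies the class cutoffs documented in [annotation_config()]. A serpin
#' whose P1' is outside the small set (A/C/G/S) is never called inhibitory
#' and carries the flag `"P1prime_not_small"`.
#'
#' @param annotation An `rcl_annotation` from [annotate_serpin()], or any
#'   list with elements `hinge`, `positions` and `record`.
#' @param config Parameters from [annotation_config()].
#' @return List with `class_label`, `class_score` (the hinge score) and
#'   `flags` (character vector).
#' @export
classify_inhibitory <- function(annotation, config = annotation_config()) {
  chars <- seq_chars(annotation$record)
  positions <- annotation$positions
  score <- annotation$hinge$hinge_score
  p1prime <- chars[positions[["P1'"]] + 1L]
  hinge_res <- chars[positions[c("P12", "P11", "P10", "P9")] + 1L]
  n_nonsmall_hinge <- sum(!hinge_res %in% config$hinge_small)
  flags <- character(0L)
  p1prime_small <- p1prime %in% config$small_p1prime
  if (!p1prime_small) flags <- c(flags, "P1prime_not_small")
  label <- if (score >= config$inhibitory_min_score && p1prime_small) {
    "inhibitory"
  } else if (score <= config$non_inhibitory_max_score ||
             (!p1prime_small && n_nonsmall_hinge >= 2L)) {
    "non_inhibitory"
  } else {
    "uncertain"
  }
  list(class_label = label, class_score = score, flags = flags)
}

#' Annotate the reactive-centre loop of a serpin
#'
#' Runs the full pipeline: hinge search, P-position assignment, P2-P1'
#' code extraction, inhibitory classification and plant-motif scan.
#'
#' @param record A [serpin_record()].
#' @param config Parameters from [annotation_config()].
#' @return An object of class `rcl_annotation`: list with `record`,
#'   `hinge`, `positions`, `code`, `class_label`, `class_score`, `flags`
#'   and `motifs`.
#' @examples
#' gs <- generate_serpin(synthetic_serpin_spec(planted_code = "LRS", seed = 1))
#' annotate_serpin(gs$record)$code
#' @export
annotate_serpin <- function(record, config = annotation_config()) {
  hinge <- find_hinge(record, config)
  positions <- assign_p_positions(record, hinge)
  ann <- list(record = record, hinge = hinge, positions = positions)
  ann$code <- reactive_centre_code(record, positions)
  cls <- classify_inhibitory(ann, config)
  ann$class_label <- cls$class_label
  ann$class_score <- cls$class_score
  ann$flags <- cls$flags
  ann$motifs <- scan_plant_motif(record, config)
  class(ann) <- "rcl_annotation"
  ann
}

#' @export
print.rcl_annotation <- function(x, ...) {
  cat("<rcl_annotation> ", x$record$locus_id,
      ": P17 at ", x$hinge$p17_index + 1L, " (1-based), code ", x$code,
      ", ", x$class_label, " (hinge score ", x$class_score, ")\n", sep = "")
  invisible(x)
}

# Plant-specific s2B-s3B motif: Y x x G x D x R x F (x = any residue).
MOTIF_LEN <- 10L
MOTIF_FIXED <- c(`1` = "Y", `4` = "G", `6` = "D", `8` = "R", `10` = "F")
MOTIF_RELAXABLE <- c(6L, 8L, 10L)  # the D, R, F anchors

#' Scan for the plant-specific structural motif
#'
#' Finds occurrences of the 10-residue motif Y-x-x-G-x-D-x-R-x-F that, in
#' plant serpins, bridges the breach tyrosine and the hydrophobic-core
#' phenylalanine between beta-strands s2B and s3B. Exact matches are
#' reported along with "conservative variant" matches in which exactly one
#' of the D/R/F anchors mismatches (Y and G must always match). The scan is
#' non-overlapping from the N-terminus; exact matches take precedence at a
#' given start position.
#'
#' @param record A [serpin_record()].
#' @param config Parameters from [annotation_config()];
#'   `motif_max_anchor_mismatch = 0` restricts to exact matches.
#' @return Data frame with columns `start` (0-based), `matched_text` and
#'   `motif_name` (`"plant_motif"` or `"plant_motif_variant"`); zero rows
#'   when nothing matches.
#' @export
scan_plant_motif <- function(record, config = annotation_config()) {
  chars <- seq_chars(record)
  len <- length(chars)
  out <- list()
  i <- 1L  # 1-based window start
  while (i + MOTIF_LEN - 1L <= len) {
    win <- chars[i:(i + MOTIF_LEN - 1L)]
    mism <- names(MOTIF_FIXED)[win[as.integer(names(MOTIF_FIXED))] !=
                                 MOTIF_FIXED]
    mism <- as.integer(mism)
    hit <- NULL
    if (length(mism) == 0L) {
      hit <- "plant_motif"
    } else if (config$motif_max_anchor_mismatch >= 1L &&
               length(mism) == 1L && mism %in% MOTIF_RELAXABLE) {
      hit <- "plant_motif_variant"
    }
    if (!is.null(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L,
        matched_text = paste(win, collapse = ""),
        motif_name = hit,
        stringsAsFactors = FALSE
      )
      i <- i + MOTIF_LEN  # non-overlapping
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) {
    data.frame(start = integer(0L), matched_text = character(0L),
               motif_name = character(0L), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Report breach and hydrophobic-core residues across an alignment
#'
#' Given alignment columns anchored on a reference sequence (the breach
#' tyrosine column and the hydrophobic-core phenylalanine column), reports
#' for each sequence the residue found there and whether it satisfies the
#' conservation expectation: Y at the breach; F, or the alternative
#' hydrophobic residues Y/L, at the core.
#'
#' @param x An [msa()].
#' @param reference_row Row id (name) of the reference sequence.
#' @param breach_col,core_col 1-based alignment column indices.
#' @return Data frame with one row per sequence: `id`, `breach_residue`,
#'   `breach_present`, `core_residue`, `core_present`, `gap_flagged`.
#'   A gap in a sequence reports the residue as `"-"`, absent, and flagged.
#' @export
check_breach_core <- function(x, reference_row, breach_col, core_col) {
  stopifnot(inherits(x, "msa"))
  if (!reference_row %in% rownames(x)) {
    stop("reference row '", reference_row, "' not in alignment")
  }
  if (breach_col < 1L || breach_col > ncol(x) ||
      core_col < 1L || core_col > ncol(x)) {
    stop("column index out of range for alignment with ", ncol(x), " columns")
  }
  if (x[reference_row, breach_col] == "-") {
    stop("gap at reference row in breach column ", breach_col)
  }
  if (x[reference_row, core_col] == "-") {
    stop("gap at reference row in core column ", core_col)
  }
  breach <- unclass(x)[, breach_col]
  core <- unclass(x)[, core_col]
  data.frame(
    id = rownames(x),
    breach_residue = breach,
    breach_present = breach == "Y",
    core_residue = core,
    core_present = core %in% c("F", "Y", "L"),
    gap_flagged = breach == "-" | core == "-",
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
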