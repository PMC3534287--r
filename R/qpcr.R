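# qPCR relative quantification: crossing-point (CP) transformation on the
# 100,000-units-at-CP-20 scale, reference-gene normalisation, detection
# calls, and in-silico amplicon prediction for primer tables.

#' Transform a crossing-point value to relative transcript abundance
#'
#' `abundance = 100000 * 2^(20 - cp)`: a CP of 20.00 is anchored
#' (arbitrarily) to 100,000 relative units, and every cycle earlier
#' doubles the abundance.
#'
#' @param cp Crossing-point value(s) in cycles; must be positive.
#' @return Relative abundance in units.
#' @examples
#' cp_to_abundance(20)  # 100000
#' cp_to_abundance(21)  # 50000
#' @export
cp_to_abundance <- function(cp) {
  if (any(!is.finite(cp)) || any(cp <= 0)) {
    stop("CP values must be positive and finite")
  }
  100000 * 2^(20 - cp)
}

#' Detection call for a mean crossing point
#'
#' A gene is called detected in a sample iff its mean CP is defined and
#' does not exceed the detection threshold (late crossing, CP > 36 by
#' default, is reported as "no expression detected").
#'
#' @param mean_cp Mean CP (may be `NA` for no signal; vectorised).
#' @param threshold Detection threshold in cycles.
#' @return Logical vector.
#' @export
detection_call <- function(mean_cp, threshold = 36) {
  !is.na(mean_cp) & mean_cp <= threshold
}

#' Summarise a CP table into relative abundances
#'
#' For each gene x sample, takes the arithmetic mean of the replicate CP
#' values (replicates beyond the detection threshold are excluded; if all
#' replicates exceed it the gene is not detected in that sample),
#' transforms via [cp_to_abundance()], and normalises to the reference
#' gene within the same sample. Log10 display values are included for
#' plotting.
#'
#' @param cp_table Data frame with columns `gene`, `sample`, `cp`
#'   (one row per technical replicate; `NA` cp = no signal).
#' @param reference_gene Housekeeping gene name (e.g. `"Actin"`); must be
#'   present in every sample.
#' @param threshold Detection threshold in cycles.
#' @return Data frame with one row per gene x sample: `gene`, `sample`,
#'   `n_replicates_used`, `mean_cp`, `detected`, `relative_units`,
#'   `log10_units`, `normalised_ratio`, `reference_detected`. When the
#'   reference gene itself is not detected in a sample, ratios for that
#'   sample are `NA` (raw units are still reported) and a warning is
#'   raised.
#' @examples
#' tb <- data.frame(gene = rep(c("g", "Actin"), each = 3),
#'                  sample = "s1", cp = c(23, 23, 23, 20, 20, 20))
#' summarise_qpcr(tb, "Actin")$normalised_ratio[1]  # 0.125
#' @export
summarise_qpcr <- function(cp_table, reference_gene = "Actin",
                           threshold = 36) {
  stopifnot(is.data.frame(cp_table),
            all(c("gene", "sample", "cp") %in% names(cp_table)))
  if (!reference_gene %in% cp_table$gene) {
    stop("reference gene '", reference_gene, "' absent from CP table")
  }
  key <- interaction(cp_table$gene, cp_table$sample, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- cp_table[key == k, , drop = FALSE]
    ok <- !is.na(sub$cp) & sub$cp <= threshold
    mean_cp <- if (any(ok)) mean(sub$cp[ok]) else NA_real_
    data.frame(gene = sub$gene[1L], sample = sub$sample[1L],
               n_replicates_used = sum(ok), mean_cp = mean_cp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$detected <- detection_call(out$mean_cp, threshold)
  out$relative_units <- NA_real_
  out$relative_units[out$detected] <- cp_to_abundance(out$mean_cp[out$detected])
  out$log10_units <- log10(out$relative_units)
  ref <- out[out$gene == reference_gene, c("sample", "relative_units",
                                           "detected")]
  names(ref) <- c("sample", "ref_units", "reference_detected")
  missing_ref <- setdiff(unique(out$sample), ref$sample)
  if (length(missing_ref) > 0L) {
    stop("reference gene '", reference_gene, "' missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  out <- merge(out, ref, by = "sample", sort = FALSE)
  if (any(!out$reference_detected)) {
    warning("reference gene not detected in sample(s): ",
            paste(unique(out$sample[!out$reference_detected]),
                  collapse = ", "),
            "; ratios set to NA, raw units still reported")
  }
  out$normalised_ratio <- ifelse(out$reference_detected & out$detected,
                                 out$relative_units / out$ref_units,
                                 NA_real_)
  out$ref_units <- NULL
  out[order(out$sample, out$gene), ]
}

#' Construct a primer pair
#'
#' @param gene Gene name.
#' @param forward,reverse Primer sequences, 5'->3', over A/C/G/T.
#' @param expected_amplicon Expected product size in bp (optional).
#' @return List of class `primer_pair`.
#' @export
primer_pair <- function(gene, forward, reverse, expected_amplicon = NA) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    stop("primer sequences must be over A/C/G/T")
  }
  structure(list(gene = gene, forward = forward, reverse = reverse,
                 expected_amplicon = as.integer(expected_amplicon)),
            class = "primer_pair")
}

match_starts <- function(template, pattern, max_mismatches) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(template),
                                   max.mismatch = max_mismatches)
  Biostrings::start(hits)
}

#' Predict the PCR product for a primer pair on a template
#'
#' Matches the forward primer on the given strand and the
#' reverse-complement of the reverse primer downstream of it. The product
#' spans the first base of the forward match through the last base of the
#' reverse-primer binding site (full product size including both primers).
#' Exactly one product is required: zero products and multiple products
#' (non-specific primers) are both errors.
#'
#' @param template DNA sequence (character scalar over A/C/G/T/N).
#' @param pair A [primer_pair()].
#' @param max_mismatches Mismatches tolerated per primer site.
#' @return List with `start` (0-based), `end` (0-based exclusive) and
#'   `length` (bp).
#' @export
find_amplicon <- function(template, pair, max_mismatches = 0L) {
  stopifnot(inherits(pair, "primer_pair"))
  template <- toupper(template)
  if (grepl("[^ACGTN]", template)) stop("template must be DNA (A/C/G/T/N)")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$reverse)))
  f_starts <- match_starts(template, pair$forward, max_mismatches)
  r_starts <- match_starts(template, rc, max_mismatches)
  products <- list()
  for (fs in f_starts) {
    for (rs in r_starts) {
      r_end <- rs + nchar(rc) - 1L               # 1-based inclusive
      if (rs >= fs + nchar(pair$forward)) {      # reverse site downstream
        products[[length(products) + 1L]] <-
          c(start = fs - 1L, end = r_end, length = r_end - fs + 1L)
      }
    }
  }
  if (length(products) == 0L) stop("no amplicon for ", pair$gene)
  if (length(products) > 1L) {
    stop("multiple amplicons (", length(products), ") for ", pair$gene,
         ": non-specific primers")
  }
  as.list(products[[1L]])
}
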