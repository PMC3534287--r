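# Synthetic serpin-like data with planted ground truth: single sequences
# with a planted hinge/RCL, sequence families simulated down a planted
# tree, qPCR tables with known expression ratios, and inputs conforming to
# the packaged curation scripts. Everything is reproducible bit-for-bit
# under a fixed seed.
#
# Background residues are drawn uniformly from the 19 non-Glu residues so
# that Glu placement (anchor and decoys) is fully controlled.

AA_NO_E <- setdiff(AA_STANDARD, "E")

# Deterministic consensus / violation residues per hinge-profile slot.
# Consensus picks avoid Glu (so the only Glu in the hinge is the P17
# anchor); violations use Trp, which is in no profile set and is non-small.
HINGE_CONSENSUS_PICK <- c(P17 = "E", P16 = "K", P15 = "G", P14 = "S",
                          P13 = "N", P12 = "A", P11 = "G", P10 = "S",
                          P9 = "T")
HINGE_VIOLATION_RESIDUE <- "W"
PLANT_MOTIF_EXACT <- "YAAGADARAF"

#' Specification for one synthetic serpin
#'
#' @param length Total sequence length in residues (>= 100; rice serpins
#'   run 340-440 aa, default 400).
#' @param hinge_quality Fraction in \[0, 1\] of the nine hinge-profile
#'   positions (P17-P9) set to consensus. Positions are degraded distal
#'   first (P9 inward); the P17 Glu anchor is the last to go, so quality 0
#'   plants no anchor at all.
#' @param planted_code P2-P1' triplet written at the canonical positions.
#' @param p17_offset_from_c_terminus Distance (residues) from the planted
#'   P17 to the last residue. The default 51 puts P1 35 residues from the
#'   C-terminus, the typical serpin RCL placement. Must be >= 19 (room for
#'   P17..P3') and leave >= 60 residues N-terminal of the hinge.
#' @param decoy_glu_count Number of decoy Glu residues planted in the
#'   C-terminal search window outside the hinge region.
#' @param include_plant_motif Plant an exact copy of the 10-residue plant
#'   motif in the N-terminal half.
#' @param degrade_positions Optional character vector of hinge labels
#'   (e.g. `c("P12", "P11")`) to violate explicitly, overriding
#'   `hinge_quality`.
#' @param seed Integer seed.
#' @return List of class `synthetic_serpin_spec`.
#' @export
synthetic_serpin_spec <- function(length = 400L,
                                  hinge_quality = 1,
                                  planted_code = "LRS",
                                  p17_offset_from_c_terminus = 51L,
                                  decoy_glu_count = 0L,
                                  include_plant_motif = FALSE,
                                  degrade_positions = NULL,
                                  seed = 1L) {
  length <- as.integer(length)
  off <- as.integer(p17_offset_from_c_terminus)
  stopifnot(length >= 100L, hinge_quality >= 0, hinge_quality <= 1,
            grepl("^[A-Z]{3}$", planted_code), off >= 19L,
            decoy_glu_count >= 0L)
  if (length - 1L - off < 60L) {
    stop("offset leaves too little sequence N-terminal of the hinge")
  }
  structure(
    list(length = length, hinge_quality = hinge_quality,
         planted_code = planted_code,
         p17_offset_from_c_terminus = off,
         decoy_glu_count = as.integer(decoy_glu_count),
         include_plant_motif = isTRUE(include_plant_motif),
         degrade_positions = degrade_positions,
         seed = as.integer(seed)),
    class = "synthetic_serpin_spec"
  )
}

#' Generate a synthetic serpin with planted ground truth
#'
#' Builds a sequence containing a hinge at the planted offset whose
#' consensus-match fraction equals the requested quality, the planted
#' P2-P1' code at the canonical positions, the requested number of decoy
#' Glu residues in the search window, and (optionally) the plant motif.
#'
#' @param spec A [synthetic_serpin_spec()].
#' @param locus_id Identifier for the generated record.
#' @return List with `record` (a [serpin_record()]) and `truth`: the
#'   planted `p17_index` (0-based; `NA` when no anchor was planted),
#'   `code`, `hinge_quality`, `violated` (labels) and `decoy_indices`.
#' @export
generate_serpin <- function(spec, locus_id = "SYN00001") {
  stopifnot(inherits(spec, "synthetic_serpin_spec"))
  with_seed(spec$seed, {
    len <- spec$length
    chars <- sample(AA_NO_E, len, replace = TRUE)
    p17 <- len - 1L - spec$p17_offset_from_c_terminus  # 0-based
    labels <- names(HINGE_CONSENSUS_PICK)
    violated <- if (!is.null(spec$degrade_positions)) {
      bad <- setdiff(spec$degrade_positions, labels)
      if (length(bad) > 0L) stop("unknown hinge label(s): ",
                                 paste(bad, collapse = ", "))
      spec$degrade_positions
    } else {
      n_sat <- round(spec$hinge_quality * length(labels))
      # degrade distal first: P9, P10, ..., P17 last
      if (n_sat < length(labels)) rev(labels)[seq_len(length(labels) - n_sat)]
      else character(0L)
    }
    for (k in seq_along(labels)) {
      lab <- labels[k]
      chars[p17 + k] <- if (lab %in% violated) HINGE_VIOLATION_RESIDUE
                        else HINGE_CONSENSUS_PICK[[lab]]
    }
    code <- strsplit(spec$planted_code, "", fixed = TRUE)[[1L]]
    chars[p17 + 16L] <- code[1L]  # P2  (0-based p17+15)
    chars[p17 + 17L] <- code[2L]  # P1
    chars[p17 + 18L] <- code[3L]  # P1'
    if (spec$include_plant_motif) {
      at <- 21L  # 1-based; N-terminal half, clear of the hinge
      motif <- strsplit(PLANT_MOTIF_EXACT, "", fixed = TRUE)[[1L]]
      chars[at:(at + MOTIF_LEN - 1L)] <- motif
    }
    decoy_idx <- integer(0L)
    if (spec$decoy_glu_count > 0L) {
      window_start0 <- len - floor(0.4 * len)
      eligible0 <- setdiff(seq(window_start0, len - 1L - 19L),
                           seq(p17, p17 + 19L))
      if (length(eligible0) < spec$decoy_glu_count) {
        stop("impossible spec: not enough room for ", spec$decoy_glu_count,
             " decoy Glu residues outside the hinge")
      }
      decoy_idx <- sort(sample(eligible0, spec$decoy_glu_count))
      chars[decoy_idx + 1L] <- "E"
    }
    anchor_planted <- !"P17" %in% violated
    list(
      record = serpin_record(locus_id, paste(chars, collapse = "")),
      truth = list(
        p17_index = if (anchor_planted) p17 else NA_integer_,
        code = spec$planted_code,
        hinge_quality = spec$hinge_quality,
        violated = violated,
        decoy_indices = decoy_idx
      )
    )
  })
}

#' Simulate a gapless protein family down a planted tree
#'
#' Draws a root sequence uniformly over the 20 residues and evolves it
#' along each branch under a uniform substitution model: each site
#' substitutes with probability `1 - exp(-b)` for branch length `b`
#' (expected substitutions per site), and a substituting site picks
#' uniformly among the other 19 residues. No indels are simulated, so the
#' tip sequences form a gapless alignment.
#'
#' @param tree An `ape::phylo` planted tree with branch lengths (rates).
#' @param n_sites Number of sites.
#' @param rate Optional scalar overriding every branch length.
#' @param seed Integer seed.
#' @return An [msa()] over the tip labels.
#' @export
generate_family <- function(tree, n_sites = 500L, rate = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(rate)) {
    stopifnot(rate >= 0)
    tree$edge.length <- rep(rate, nrow(tree$edge))
  }
  if (is.null(tree$edge.length)) stop("tree needs branch lengths (rates)")
  if (any(tree$edge.length < 0)) stop("negative substitution rates")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    seqs[[root]] <- sample(AA_STANDARD, n_sites, replace = TRUE)
    # preorder traversal: parents before children
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- tree$edge.length[match(paste(edges[, 1], edges[, 2]),
                                   paste(tree$edge[, 1], tree$edge[, 2]))]
    for (e in seq_len(nrow(edges))) {
      parent <- seqs[[edges[e, 1L]]]
      p_sub <- 1 - exp(-lens[e])
      child <- parent
      hit <- stats::runif(n_sites) < p_sub
      if (any(hit)) {
        child[hit] <- vapply(parent[hit], function(r) {
          sample(setdiff(AA_STANDARD, r), 1L)
        }, character(1L))
      }
      seqs[[edges[e, 2L]]] <- child
    }
    tips <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                   character(1L))
    msa(stats::setNames(tips, tree$tip.label))
  })
}

#' Generate a qPCR CP table with known expression ratios
#'
#' The reference gene is fixed at CP 20 (the anchor of the abundance
#' scale); each target gene's true CP is `20 - log2(ratio)` with Gaussian
#' replicate noise, run as technical triplicates per the standard design.
#'
#' @param gene_effects Named numeric vector: true abundance ratio
#'   (gene/reference) per gene; ratios must be positive.
#' @param noise_sd Replicate noise standard deviation, in cycles.
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per gene (default 3).
#' @param sample_id Sample name.
#' @param reference_gene Reference gene name.
#' @return Data frame with columns `gene`, `sample`, `replicate`, `cp`.
#' @export
generate_qpcr_table <- function(gene_effects, noise_sd = 0, seed = 1L,
                                n_replicates = 3L, sample_id = "s1",
                                reference_gene = "Actin") {
  stopifnot(is.numeric(gene_effects), !is.null(names(gene_effects)),
            all(gene_effects > 0), noise_sd >= 0)
  with_seed(seed, {
    genes <- c(names(gene_effects), reference_gene)
    true_cp <- c(20 - log2(gene_effects), 20)
    rows <- lapply(seq_along(genes), function(i) {
      noise <- if (genes[i] == reference_gene) 0
               else stats::rnorm(n_replicates, 0, noise_sd)
      data.frame(gene = genes[i], sample = sample_id,
                 replicate = seq_len(n_replicates),
                 cp = true_cp[i] + noise, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

landmarks_unique <- function(seq, landmarks) {
  all(vapply(landmarks, function(l) {
    length(gregexpr(l, seq, fixed = TRUE)[[1L]]) == 1L &&
      gregexpr(l, seq, fixed = TRUE)[[1L]][1L] != -1L
  }, logical(1L)))
}

rand_aa <- function(n, exclude = character(0L)) {
  paste(sample(setdiff(AA_STANDARD, exclude), n, replace = TRUE),
        collapse = "")
}

#' Build a synthetic database model conforming to a packaged edit script
#'
#' Constructs, for each of the six curated rice serpins, a synthetic
#' "database prediction" carrying the landmarks and segment lengths that
#' the corresponding [build_rice_scripts()] script expects, at the printed
#' pre-curation length (QKG 423, LRS 468 printed-block total, PLP 439,
#' PSG 452, PTY 510, PGY 524 aa). Applying the script yields the printed
#' curated length. Filler residues are random; generation retries until
#' every landmark is unique in the built sequence.
#'
#' @param which One of `"QKG"`, `"LRS"`, `"PLP"`, `"PSG"`, `"PTY"`,
#'   `"PGY"`.
#' @param seed Integer seed.
#' @return A [serpin_record()] for the synthetic pre-curation model.
#' @export
conforming_sequence <- function(which = c("QKG", "LRS", "PLP", "PSG",
                                          "PTY", "PGY"),
                                seed = 1L) {
  which <- match.arg(which)
  scripts <- build_rice_scripts()
  script <- scripts[[which]]
  plp_ext <- "MQVSSYLRRALRRPPFPAGDANHRRLSSAPAPKPEAPAEAMPPPP"
  with_seed(seed, {
    for (try in 1:100) {
      seq <- switch(which,
        QKG = paste0("MAAL", rand_aa(21L), "MAPP", rand_aa(394L)),
        LRS = paste0("MADD", rand_aa(129L), "FQTK",
                     "WLLL", rand_aa(64L), "TSGK",
                     "AAEV", rand_aa(244L), "VGHV",
                     "AAEVLGQ"),
        PLP = paste0(plp_ext, "MPTRPW", rand_aa(388L)),
        PSG = paste0(rand_aa(120L),
                     PSG_INTRON_START, rand_aa(22L), PSG_INTRON_END,
                     rand_aa(100L, exclude = "A"),
                     "AAAAA",
                     rand_aa(197L, exclude = "A")),
        PTY = paste0(rand_aa(117L), "M", rand_aa(392L)),
        PGY = paste0(rand_aa(126L), "M", rand_aa(397L))
      )
      needed <- switch(which,
        LRS = c("MADD", "FQTK", "WLLL", "TSGK", "VGHV"),
        PLP = "MPTRPW",
        PSG = c(PSG_INTRON_START, PSG_INTRON_END, "AAAAA"),
        character(0L)
      )
      ok <- landmarks_unique(seq, needed)
      if (ok && which == "PLP" && startsWith(seq, "MPTRPW")) ok <- FALSE
      if (ok) {
        return(serpin_record(script$locus_id, seq,
                             description = paste0("synthetic conforming ",
                                                  which, " model")))
      }
    }
    stop("failed to build a conforming sequence for ", which)
  })
}
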