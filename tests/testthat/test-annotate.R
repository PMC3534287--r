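test_that("find_hinge recovers a unique planted anchor and reports score", {
  gs <- generate_serpin(synthetic_serpin_spec(hinge_quality = 1, seed = 1))
  hit <- find_hinge(gs$record)
  expect_equal(hit$p17_index, gs$truth$p17_index)
  expect_equal(hit$hinge_score, 10L)  # full consensus profile
  expect_error(find_hinge(serpin_record("short", strrep("A", 50L))),
               "too short")
  # no Glu anywhere -> no candidate
  gs0 <- generate_serpin(synthetic_serpin_spec(hinge_quality = 0, seed = 2))
  expect_error(find_hinge(gs0$record), "no hinge candidate")
  # alternative profiles are injectable through the config
  cfg <- annotation_config(hinge_profile = list(
    list(label = "P17", offset = 0L, allowed = "E", weight = 1L)))
  expect_equal(find_hinge(gs$record, cfg)$hinge_score, 1L)
})

test_that("find_hinge picks the higher-scoring of competing Glu candidates,
           matching the exhaustive oracle", {
  for (seed in 1:25) {
    gs <- generate_serpin(synthetic_serpin_spec(
      hinge_quality = 1, decoy_glu_count = 3L, seed = seed))
    hit <- find_hinge(gs$record)
    expect_equal(hit$p17_index, oracle_hinge(gs$record$sequence))
    expect_equal(hit$p17_index, gs$truth$p17_index)
  }
  # degraded planted hinge can lose to the oracle's pick; implementation
  # must still agree with the oracle exactly
  for (seed in 1:25) {
    gs <- generate_serpin(synthetic_serpin_spec(
      hinge_quality = 0.6, decoy_glu_count = 2L, seed = seed))
    expect_equal(find_hinge(gs$record)$p17_index,
                 oracle_hinge(gs$record$sequence))
  }
})

test_that("assign_p_positions follows the canonical counting rule", {
  gs <- generate_serpin(synthetic_serpin_spec(seed = 3))
  hit <- find_hinge(gs$record)
  pm <- assign_p_positions(gs$record, hit)
  p17 <- hit$p17_index
  expect_equal(pm[["P1"]], p17 + 16L)
  expect_equal(pm[["P1'"]], p17 + 17L)
  expect_equal(pm[["P2"]], p17 + 15L)
  expect_equal(pm[["P3'"]], p17 + 19L)
  expect_true(all(diff(pm) == 1L))
  # boundary: anchor at index 0 of a 20-residue toy puts P3' at 19
  toy <- serpin_record("toy", paste0("E", strrep("A", 19L)))
  pm2 <- assign_p_positions(toy, list(p17_index = 0L))
  expect_equal(pm2[["P3'"]], 19L)
  # map exceeding the sequence end errors
  toy2 <- serpin_record("toy2", paste0("EE", strrep("A", 18L)))
  expect_error(assign_p_positions(toy2, list(p17_index = 1L)), "exceed")
})

test_that("reactive_centre_code extracts the planted P2-P1' triplet", {
  for (code in c("GKS", "LRS", "QKG")) {
    gs <- generate_serpin(synthetic_serpin_spec(planted_code = code,
                                                seed = 5))
    ann <- annotate_serpin(gs$record)
    expect_equal(ann$code, code)
  }
})

test_that("classify_inhibitory reproduces the published call pattern", {
  config <- annotation_config()
  # perfect hinge, small P1' -> inhibitory
  gs <- generate_serpin(synthetic_serpin_spec(planted_code = "LRS", seed = 1))
  expect_equal(annotate_serpin(gs$record)$class_label, "inhibitory")
  # non-small P1' with degraded distal hinge (>=2 of P12-P9 non-small)
  # -> non-inhibitory (the PLP pattern)
  gs2 <- generate_serpin(synthetic_serpin_spec(
    planted_code = "PLP", degrade_positions = c("P12", "P10"), seed = 2))
  ann2 <- annotate_serpin(gs2$record)
  expect_equal(ann2$class_label, "non_inhibitory")
  expect_true("P1prime_not_small" %in% ann2$flags)
  # non-small P1' but otherwise consensus hinge -> uncertain
  gs3 <- generate_serpin(synthetic_serpin_spec(planted_code = "PTY",
                                               seed = 3))
  ann3 <- annotate_serpin(gs3$record)
  expect_equal(ann3$class_label, "uncertain")
  # property: P1prime_not_small never coexists with an inhibitory label
  set.seed(99)
  for (seed in 1:40) {
    q <- sample(c(0.5, 0.7, 1), 1L)
    code <- paste(sample(AA20, 3L, TRUE), collapse = "")
    g <- generate_serpin(synthetic_serpin_spec(planted_code = code,
                                               hinge_quality = q,
                                               seed = seed))
    a <- tryCatch(annotate_serpin(g$record), error = function(e) NULL)
    if (!is.null(a) && "P1prime_not_small" %in% a$flags) {
      expect_false(a$class_label == "inhibitory")
    }
  }
})

test_that("scan_plant_motif finds literal and variant matches", {
  r <- serpin_record("m1", paste0("YAAGADARAF", strrep("K", 90L)))
  hits <- scan_plant_motif(r)
  expect_equal(hits$start, 0L)
  expect_equal(hits$motif_name, "plant_motif")

  r0 <- serpin_record("m0", strrep("A", 100L))
  expect_equal(nrow(scan_plant_motif(r0)), 0L)

  # one relaxed anchor (R -> K) is a conservative variant
  rv <- serpin_record("mv", paste0(strrep("K", 10L), "YAAGADAKAF",
                                   strrep("K", 10L)))
  hv <- scan_plant_motif(rv)
  expect_equal(hv$motif_name, "plant_motif_variant")
  expect_equal(hv$start, 10L)
  # two mismatched anchors is no match
  r2 <- serpin_record("m2", paste0("YAAGAAAKAF", strrep("K", 20L)))
  expect_equal(nrow(scan_plant_motif(r2)), 0L)
  # variants disabled by config
  cfg <- annotation_config(motif_max_anchor_mismatch = 0L)
  expect_equal(nrow(scan_plant_motif(rv, cfg)), 0L)
})

test_that("check_breach_core reports residues at anchored columns", {
  m <- msa(c(ref = "YAF", two = "YAL", three = "AAA", gapped = "-AF"))
  rep <- check_breach_core(m, "ref", breach_col = 1L, core_col = 3L)
  expect_equal(sum(rep$breach_present), 2L)
  expect_equal(sum(rep$core_present), 3L)  # F, L, F
  expect_true(rep$gap_flagged[rep$id == "gapped"])
  expect_false(rep$breach_present[rep$id == "gapped"])
  expect_error(check_breach_core(m, "gapped", 1L, 3L), "gap at reference")
  expect_error(check_breach_core(m, "ref", 9L, 3L), "out of range")
})
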