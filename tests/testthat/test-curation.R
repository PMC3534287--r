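test_that("edit ops transform sequences and account for residues", {
  sc <- edit_script("toy", list(edit_op("trim_n_terminal_count", n = 2L)))
  res <- apply_edit_script("AAMAPP", sc)
  expect_equal(res$sequence, "MAPP")
  expect_equal(res$report$delta, -2L)

  sc2 <- edit_script("toy", list(
    edit_op("excise", start_landmark = "WLLL", end_landmark = "TSGK")))
  res2 <- apply_edit_script("MADDWLLLKKKTSGKVVVV", sc2)
  expect_equal(res2$sequence, "MADDVVVV")

  sc3 <- edit_script("toy", list(
    edit_op("replace_c_terminal", old_suffix = "AAEVLGQ",
            new_suffix = "VNPLLAA")))
  expect_equal(apply_edit_script("MKVAAEVLGQ", sc3)$sequence, "MKVVNPLLAA")

  sc4 <- edit_script("toy", list(edit_op("remove_run", residue = "A",
                                         count = 5L)))
  expect_equal(apply_edit_script("MKVAAAAAWL", sc4)$sequence, "MKVWL")
  # run embedded in a longer run is refused
  expect_error(apply_edit_script("MKVAAAAAAWL", sc4), "longer run")

  # empty script is the identity
  sc0 <- edit_script("toy", list())
  res0 <- apply_edit_script("MAPP", sc0)
  expect_equal(res0$sequence, "MAPP")
  expect_equal(nrow(res0$report), 0L)
})

test_that("landmark errors name the failing op and are not silent", {
  sc <- edit_script("L1", list(
    edit_op("excise", start_landmark = "WWWW", end_landmark = "TSGK")))
  expect_error(apply_edit_script("MADDTSGKVVVV", sc), "op 1.*WWWW")
  sc2 <- edit_script("L2", list(
    edit_op("excise", start_landmark = "KKK", end_landmark = "VVV")))
  expect_error(apply_edit_script("MKKKPPKKKVVVW", sc2), "ambiguous")
  sc3 <- edit_script("L3", list(
    edit_op("excise", start_landmark = "VVV", end_landmark = "KKK")))
  expect_error(apply_edit_script("MKKKPPPVVVW", sc3), "after")
  # expected-length mismatch is a hard error
  sc4 <- edit_script("L4", list(edit_op("trim_n_terminal_count", n = 1L)),
                     expected_final_length = 99L)
  expect_error(apply_edit_script("MAPP", sc4), "does not match expected")
})

test_that("packaged rice scripts reproduce printed lengths on conforming input", {
  scripts <- build_rice_scripts()
  expected <- c(QKG = 398L, LRS = 396L, PLP = 394L, PSG = 417L,
                PTY = 393L, PGY = 398L)
  input_len <- c(QKG = 423L, LRS = 468L, PLP = 439L, PSG = 452L,
                 PTY = 510L, PGY = 524L)
  for (w in names(scripts)) {
    cs <- conforming_sequence(w, seed = 42L)
    expect_equal(nchar(cs$sequence), input_len[[w]], info = w)
    res <- apply_edit_script(cs, scripts[[w]])
    expect_equal(res$final_length, expected[[w]], info = w)
    # accounting conservation: output length = input + sum of deltas
    expect_equal(res$final_length,
                 nchar(cs$sequence) + sum(res$report$delta), info = w)
  }
  # QKG is a pure -25 trim and the result begins MAPP, not MAAL
  qkg <- apply_edit_script(conforming_sequence("QKG", seed = 1L),
                           scripts$QKG)
  expect_equal(sum(qkg$report$delta), -25L)
  expect_true(startsWith(qkg$sequence, "MAPP"))
  # PLP result begins at the printed landmark
  plp <- apply_edit_script(conforming_sequence("PLP", seed = 1L),
                           scripts$PLP)
  expect_true(startsWith(plp$sequence, "MPTRPW"))
  # LRS C-terminus replaced per cDNA evidence
  lrs <- apply_edit_script(conforming_sequence("LRS", seed = 1L),
                           scripts$LRS)
  expect_true(endsWith(lrs$sequence, "VNPLLAA"))
})

test_that("applying a script twice fails at landmark resolution", {
  scripts <- build_rice_scripts()
  for (w in names(scripts)) {
    once <- apply_edit_script(conforming_sequence(w, seed = 3L), scripts[[w]])
    expect_error(apply_edit_script(once$sequence, scripts[[w]]), info = w)
  }
})

test_that("edit scripts round-trip through the plain-text config", {
  scripts <- build_rice_scripts()
  f <- withr::local_tempfile(fileext = ".cfg")
  write_edit_scripts(scripts, f)
  back <- read_edit_scripts(f)
  expect_identical(names(back), names(scripts))
  for (w in names(scripts)) {
    expect_equal(back[[w]]$locus_id, scripts[[w]]$locus_id)
    expect_equal(back[[w]]$expected_final_length,
                 scripts[[w]]$expected_final_length)
    expect_equal(lapply(back[[w]]$ops, unclass),
                 lapply(scripts[[w]]$ops, unclass))
  }
  # the shipped config file matches the in-code scripts
  shipped <- read_edit_scripts(system.file("extdata",
                                           "rice_edit_scripts.cfg",
                                           package = "serpintools"))
  for (w in names(scripts)) {
    expect_equal(lapply(shipped[[w]]$ops, unclass),
                 lapply(scripts[[w]]$ops, unclass), info = w)
  }
})

test_that("validate_intron_count flags deviations from the curated models", {
  md <- data.frame(
    locus_id = c("Os03g41419", "Os01g16200", "Os03g41438"),
    declared_introns = c(4L, 0L, 1L))
  rep <- validate_intron_count(md)
  expect_true(rep$flagged[rep$locus_id == "Os03g41419"])   # 4 vs 1
  expect_false(rep$flagged[rep$locus_id == "Os01g16200"])  # intronless
  expect_false(rep$flagged[rep$locus_id == "Os03g41438"])
  expect_equal(rep$expected_introns,
               c(1L, 0L, 1L))
})
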