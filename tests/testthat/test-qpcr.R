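test_that("cp_to_abundance anchors CP 20 at 100,000 units", {
  expect_identical(cp_to_abundance(20), 100000)
  expect_equal(cp_to_abundance(21), 50000)
  expect_equal(cp_to_abundance(19), 200000)
  expect_error(cp_to_abundance(0), "positive")
  expect_error(cp_to_abundance(-3), "positive")
  # halving law and strict monotonicity
  set.seed(2)
  cp <- runif(200, 5, 40)
  expect_equal(cp_to_abundance(cp - 1), 2 * cp_to_abundance(cp))
  expect_true(all(diff(cp_to_abundance(sort(cp))) < 0))
})

test_that("detection_call applies the CP threshold", {
  expect_false(detection_call(36.5))
  expect_true(detection_call(36))
  expect_true(detection_call(20))
  expect_false(detection_call(NA))
  expect_equal(detection_call(c(20, 37, NA)), c(TRUE, FALSE, FALSE))
})

test_that("summarise_qpcr normalises to the reference within sample", {
  tb <- data.frame(gene = rep(c("g", "Actin"), each = 3L), sample = "s1",
                   cp = c(23, 23, 23, 20, 20, 20))
  res <- summarise_qpcr(tb, "Actin")
  expect_equal(res$normalised_ratio[res$gene == "g"], 0.125)
  expect_equal(res$relative_units[res$gene == "Actin"], 100000)
  expect_equal(res$log10_units[res$gene == "Actin"], 5)

  # gene CP equal to reference CP -> ratio 1
  tb2 <- data.frame(gene = rep(c("g", "Actin"), each = 3L), sample = "s1",
                    cp = 24)
  expect_equal(summarise_qpcr(tb2, "Actin")$normalised_ratio, c(1, 1))

  # ratio is shift-invariant: adding a constant to all CPs cancels
  tb3 <- tb; tb3$cp <- tb3$cp + 4.7
  expect_equal(summarise_qpcr(tb3, "Actin")$normalised_ratio,
               summarise_qpcr(tb, "Actin")$normalised_ratio)
})

test_that("summarise_qpcr excludes late replicates and handles no-signal", {
  # one replicate beyond threshold is dropped from the mean
  tb <- data.frame(gene = rep(c("g", "Actin"), each = 3L), sample = "s1",
                   cp = c(24, 24, 37, 20, 20, 20))
  res <- summarise_qpcr(tb, "Actin")
  expect_equal(res$mean_cp[res$gene == "g"], 24)
  expect_equal(res$n_replicates_used[res$gene == "g"], 2L)
  # all replicates late -> not detected, no units, no ratio
  tb$cp[tb$gene == "g"] <- c(36.5, 38, NA)
  res2 <- summarise_qpcr(tb, "Actin")
  g <- res2[res2$gene == "g", ]
  expect_false(g$detected)
  expect_true(is.na(g$relative_units))
  expect_true(is.na(g$normalised_ratio))
  # undetected reference: warning, ratios NA, raw units still present
  tb3 <- data.frame(gene = rep(c("g", "Actin"), each = 3L), sample = "s1",
                    cp = c(25, 25, 25, 37, 37, 37))
  expect_warning(res3 <- summarise_qpcr(tb3, "Actin"), "reference gene")
  expect_true(is.na(res3$normalised_ratio[res3$gene == "g"]))
  expect_false(is.na(res3$relative_units[res3$gene == "g"]))
  # reference absent entirely is an error
  expect_error(summarise_qpcr(data.frame(gene = "g", sample = "s", cp = 20),
                              "Actin"), "absent")
})

test_that("find_amplicon predicts product span and length", {
  set.seed(6)
  fwd <- paste(sample(c("A", "C", "G", "T"), 20L, TRUE), collapse = "")
  rvs <- paste(sample(c("A", "C", "G", "T"), 20L, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rvs)))
  spacer <- paste(sample(c("A", "C", "G", "T"), 10L, TRUE), collapse = "")
  template <- paste0("ACGT", fwd, spacer, rc, "TTTT")
  pr <- primer_pair("g1", fwd, rvs)
  res <- find_amplicon(template, pr)
  expect_equal(res$length, 50L)  # 20 + 10 + 20
  expect_equal(res$start, 4L)
  # template lacking the reverse site
  expect_error(find_amplicon(paste0("ACGT", fwd, spacer), pr), "no amplicon")
  # two forward sites upstream of one reverse site -> multiple products
  t2 <- paste0(fwd, "AC", fwd, spacer, rc)
  expect_error(find_amplicon(t2, pr), "multiple amplicons")
  expect_error(primer_pair("g", "ACGU", "ACGT"), "A/C/G/T")
})

test_that("find_amplicon equals the exhaustive two-site oracle", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    fwd <- paste(sample(bases, 8L, TRUE), collapse = "")
    rvs <- paste(sample(bases, 8L, TRUE), collapse = "")
    template <- paste(sample(bases, 300L, TRUE), collapse = "")
    # plant sites with varying multiplicity
    n_f <- sample(0:2, 1L); n_r <- sample(0:2, 1L)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rvs)))
    pos <- sort(sample(seq(1L, 250L, by = 30L), n_f + n_r))
    pieces <- strsplit(template, "")[[1L]]
    ins <- c(rep(fwd, n_f), rep(rc, n_r))
    if (length(ins) > 0L) {
      ins <- sample(ins)
      for (k in seq_along(pos)) {
        pieces[pos[k]:(pos[k] + 7L)] <- strsplit(ins[k], "")[[1L]]
      }
    }
    template <- paste(pieces, collapse = "")
    n_products <- oracle_amplicon_count(template, fwd, rvs)
    pr <- primer_pair("g", fwd, rvs)
    got <- tryCatch(find_amplicon(template, pr), error = function(e)
      if (grepl("no amplicon", conditionMessage(e))) 0L else Inf)
    if (n_products == 1L) {
      expect_type(got, "list")
    } else if (n_products == 0L) {
      expect_equal(got, 0L)
    } else {
      expect_equal(got, Inf)
    }
  }
})
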