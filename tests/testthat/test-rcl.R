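test_that("scan_hinge finds planted, pattern-conforming hinges", {
  # P17 E, P16 E, P15 G, P14 T, P13 A, P12-P9 AAAA, then P8..P4' arbitrary
  s <- paste0(strrep("L", 300), "EEGTAAAAA", strrep("V", 12), strrep("W", 15))
  cand <- scan_hinge(s)
  expect_equal(cand$hinge_start[1], 300)
  expect_equal(cand$score[1], 8)

  # P16 K is allowed; P12-P9 drawn from {A,G,S}
  s2 <- paste0(strrep("L", 300), "EKGTAASGS", strrep("V", 12), strrep("W", 10))
  expect_equal(scan_hinge(s2)$hinge_start[1], 300)

  # a critical-subsite violation (P15 != G) is never a candidate
  s3 <- paste0(strrep("L", 300), "EEATAAAAA", strrep("V", 12))
  expect_equal(nrow(scan_hinge(s3)), 0)

  # fewer than 21 residues after P17: not a candidate
  s4 <- paste0(strrep("L", 300), "EEGTAAAAA", strrep("V", 5))
  expect_equal(nrow(scan_hinge(s4)), 0)
})

test_that("scan_hinge agrees with per-window brute-force evaluation", {
  withr::local_seed(31)
  hits <- 0
  for (i in 1:200) {
    # enriched alphabet so hinge-like windows actually occur
    s <- rand_protein(sample(60:150, 1),
                      alphabet = c("E", "G", "T", "A", "S"))
    got <- sort(scan_hinge(s)$hinge_start)
    exp <- sort(hinge_oracle_starts(s))
    expect_equal(got, exp)
    hits <- hits + length(exp)
  }
  expect_gt(hits, 50)   # the equivalence was exercised on real matches
})

test_that("candidate ranking prefers score, then the most C-terminal site", {
  # two perfect hinges: the downstream one must win
  s <- paste0(strrep("L", 100), "EEGTAAAAA", strrep("L", 30),
              "EEGTAAAAA", strrep("V", 25))
  cand <- scan_hinge(s)
  expect_equal(cand$hinge_start[1], 139)
  # scan output is stable under N-terminal extension (positions shift only)
  s_ext <- paste0(strrep("Q", 57), s)
  cand_ext <- scan_hinge(s_ext)
  expect_equal(nchar(s_ext) - cand_ext$hinge_start,
               nchar(s) - cand$hinge_start)
  expect_equal(cand_ext$score, cand$score)
})

test_that("extract_rcl takes the 21-residue P17-P4' window with P1 at +16", {
  p <- paste0("EEGTA", strrep("A", 4), strrep("L", 7), "K", "VVVV")
  ann <- extract_rcl(p, 0)
  expect_equal(ann$rcl_seq, p)
  expect_equal(ann$p1_index, 16)
  expect_equal(ann$p1_residue, "K")
  expect_equal(nchar(ann$rcl_seq), 21)

  long <- paste0(strrep("A", 350), strrep("C", 21), "DD")
  ann2 <- extract_rcl(long, 350)
  expect_equal(ann2$hinge_start, 350)
  expect_equal(ann2$p1_index, 366)
  expect_equal(ann2$rcl_seq, strrep("C", 21))

  expect_error(extract_rcl(strrep("A", 30), 15), "truncated",
               class = "rcl_extraction_error")
})

test_that("P1 classification is the fixed chemistry table with target map", {
  expect_equal(classify_p1("K"),
               list(p1_class = "polar basic",
                    predicted_target = "Trypsin- or thrombin-like proteases"))
  expect_equal(classify_p1("Y")$p1_class, "polar uncharged")
  expect_equal(classify_p1("Y")$predicted_target,
               "Elastase- or chymotrypsin-like proteases")
  expect_equal(classify_p1("I"),
               list(p1_class = "hydrophobic", predicted_target = "Not specified"))
  expect_equal(classify_p1("D")$p1_class, "polar acidic")
  expect_error(classify_p1("X"), "non-standard")

  # the table is total and disjoint over the 20 standard residues
  classes <- vapply(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                    function(r) classify_p1(r)$p1_class, character(1))
  expect_equal(length(classes), 20)
  expect_setequal(unique(classes),
                  c("polar basic", "polar uncharged", "polar acidic",
                    "hydrophobic"))
})

test_that("p1_summary reproduces the published class shares", {
  res <- c("K", "C", "C", "K", "K", "C", "R", "I", "L", "S", "R", "R",
           "Y", "Y", "T", "R", "K")
  ps <- p1_summary(res)
  expect_equal(unname(ps$percentages["polar basic"]), 47.06)
  expect_equal(unname(ps$percentages["polar uncharged"]), 41.18)
  expect_equal(unname(ps$percentages["hydrophobic"]), 11.76)
  expect_equal(ps$distinct_residues, 8)

  one <- p1_summary("K")
  expect_equal(unname(one$percentages["polar basic"]), 100)
  expect_equal(one$distinct_residues, 1)
  expect_error(p1_summary(character(0)), "no annotations")
})

test_that("rounded class percentages drift at most 0.03 from 100", {
  withr::local_seed(13)
  for (i in 1:50) {
    res <- sample(c("K", "R", "S", "T", "C", "Y", "I", "L", "D", "E"),
                  sample(3:40, 1), replace = TRUE)
    expect_lt(abs(sum(p1_summary(res)$percentages) - 100), 0.03 + 1e-9)
  }
})

test_that("conservation report flags deviating subsites", {
  loop <- paste0("EEGTA", "AAAA", strrep("L", 7), "K", "VVVV")
  same <- rep(loop, 17)
  rep1 <- hinge_conservation_report(same)
  expect_true(all(rep1$conserved))
  expect_equal(rep1$modal_freq, rep(1, 21))

  dev <- same
  substr(dev[5], 2, 2) <- "W"   # P16 deviates outside [E/K/R]
  rep2 <- hinge_conservation_report(dev)
  expect_false(rep2$conserved[rep2$subsite == "P16"])
  expect_true(rep2$conserved[rep2$subsite == "P17"])
  # frequencies match direct column counting
  expect_equal(unname(rep2$freqs[[2]]["E"]), 16 / 17)
  expect_equal(unname(rep2$freqs[[2]]["W"]), 1 / 17)
})

test_that("logo matrix computes information-content-weighted frequencies", {
  # fully conserved column: IC = log2(20)
  loops <- rep(paste(rep("E", 21), collapse = ""), 5)
  lm <- logo_matrix(loops)
  expect_equal(unname(lm[1, "E"]), log2(20), tolerance = 1e-12)
  expect_equal(sum(lm[1, ] > 0), 1)

  # column uniform over all 20 residues: IC = 0
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  loops2 <- paste0(aa, strrep("G", 20))
  lm2 <- logo_matrix(loops2)
  expect_equal(unname(lm2[1, ]), rep(0, 20))

  expect_error(logo_matrix(c("AAA", "AAAA")), "unequal")

  # independent entropy computation on random alignments
  withr::local_seed(3)
  loops3 <- replicate(12, rand_protein(21))
  lm3 <- logo_matrix(loops3)
  mat <- do.call(rbind, strsplit(loops3, ""))
  for (j in c(1, 7, 21)) {
    p <- table(mat[, j]) / nrow(mat)
    ic <- log2(20) + sum(p * log2(p))
    for (r in names(p)) {
      expect_equal(unname(lm3[j, r]), unname(p[r] * ic), tolerance = 1e-10)
    }
  }
})
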