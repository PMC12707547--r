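mk_counts <- function(ids, lengths, ...) {
  data.frame(transcript_id = ids, length = lengths, ...,
             stringsAsFactors = FALSE)
}

test_that("TPM follows the standard definition and conserves 1e6", {
  one <- compute_tpm(mk_counts("t1", 500, s1 = 42))
  expect_equal(one$s1, 1e6)
  two <- compute_tpm(mk_counts(c("a", "b"), c(300, 300), s1 = c(10, 10)))
  expect_equal(two$s1, c(5e5, 5e5))

  withr::local_seed(4)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    tab <- mk_counts(paste0("t", 1:n), sample(200:2000, n, TRUE),
                     s1 = rpois(n, 40), s2 = rpois(n, 5))
    tab$s1[1] <- tab$s1[1] + 1   # keep at least one read
    tpm <- compute_tpm(tab)
    expect_equal(sum(tpm$s1), 1e6, tolerance = 1e-6)
    expect_equal(sum(tpm$s2), 1e6, tolerance = 1e-6)
  }
  expect_warning(compute_tpm(mk_counts("a", 100, s1 = 0)), "no reads")
  expect_error(compute_tpm(mk_counts("a", 100, s1 = -1)), "negative")
  expect_error(compute_tpm(mk_counts("a", 0, s1 = 1)), "lengths")
})

test_that("FPKM and IsoPct follow their definitions", {
  f <- compute_fpkm(mk_counts("t", 1000, s1 = 10))
  expect_equal(f$s1, 1e6)   # 1e9 * 10 / (1000 * 10)

  tpm <- compute_tpm(mk_counts(c("a", "b", "c"), c(500, 500, 800),
                               s1 = c(10, 30, 0)))
  iso <- compute_isopct(tpm)
  expect_equal(iso$s1, c(100, 100, 0))   # sole isoforms

  gm <- data.frame(transcript_id = c("a", "b", "c"),
                   gene_id = c("g1", "g1", "g2"), stringsAsFactors = FALSE)
  iso2 <- compute_isopct(tpm, gm)
  expect_equal(iso2$s1[1] + iso2$s1[2], 100)   # sums to 100 per expressed gene
  expect_equal(iso2$s1[3], 0)
  expect_equal(iso2$s1[2] / iso2$s1[1], 3)     # proportional to TPM
})

test_that("the zero-TPM rule yields the published 4/15/91 arithmetic", {
  n <- 110
  ids <- sprintf("t%03d", 1:n)
  fe <- ids[1:4]; ma <- ids[5:19]; sh <- ids[20:110]
  counts <- mk_counts(ids, rep(1000, n),
                      F1 = ifelse(ids %in% c(fe, sh), 5, 0),
                      M1 = ifelse(ids %in% c(ma, sh), 7, 0))
  part <- partition_by_sex(compute_tpm(counts),
                           data.frame(sample = c("F1", "M1"),
                                      sex = c("F", "M")))
  expect_equal(part$n_male, 106)
  expect_equal(part$n_female, 95)
  expect_equal(unname(part$percentages["female_only"]), 3.64)
  expect_equal(unname(part$percentages["male_only"]), 13.64)
  expect_setequal(part$female_only, fe)
  expect_setequal(part$male_only, ma)
  expect_setequal(part$shared, sh)
})

test_that("all-zero transcripts belong to no set; sets partition the expressed", {
  counts <- mk_counts(c("a", "b", "z"), c(500, 500, 500),
                      F1 = c(3, 0, 0), M1 = c(0, 2, 0))
  part <- partition_by_sex(compute_tpm(counts),
                           data.frame(sample = c("F1", "M1"),
                                      sex = c("female", "male")))
  expect_false("z" %in% c(part$female_only, part$male_only, part$shared))
  expect_equal(part$n_expressed, 2)
  expect_equal(length(part$female_only) + length(part$male_only) +
                 length(part$shared), part$n_expressed)
})

test_that("partition equals per-row brute force; invariant to order/rescaling", {
  withr::local_seed(8)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    ids <- paste0("t", 1:n)
    counts <- mk_counts(ids, sample(300:1500, n, TRUE),
                        F1 = rbinom(n, 1, 0.6) * rpois(n, 20),
                        F2 = rbinom(n, 1, 0.6) * rpois(n, 20),
                        M1 = rbinom(n, 1, 0.6) * rpois(n, 20),
                        M2 = rbinom(n, 1, 0.6) * rpois(n, 20))
    counts$F1[1] <- counts$F1[1] + 1; counts$M1[1] <- counts$M1[1] + 1
    sm <- data.frame(sample = c("F1", "F2", "M1", "M2"),
                     sex = c("F", "F", "M", "M"))
    part <- partition_by_sex(compute_tpm(counts), sm)
    in_f <- counts$F1 > 0 | counts$F2 > 0   # brute force on raw counts:
    in_m <- counts$M1 > 0 | counts$M2 > 0   # TPM > 0 iff count > 0
    expect_setequal(part$female_only, ids[in_f & !in_m])
    expect_setequal(part$male_only, ids[in_m & !in_f])
    expect_setequal(part$shared, ids[in_f & in_m])

    # sample order and positive per-sample rescaling change nothing
    counts2 <- counts[, c("transcript_id", "length", "M2", "F1", "M1", "F2")]
    counts2$M2 <- counts2$M2 * 3
    part2 <- partition_by_sex(compute_tpm(counts2), sm)
    expect_equal(part2$female_only, part$female_only)
    expect_equal(part2$male_only, part$male_only)
    expect_equal(part2$shared, part$shared)
  }
})

test_that("log2 matrix applies the pseudocount and preserves order", {
  tpm <- data.frame(transcript_id = c("a", "b", "c"),
                    s1 = c(0, 7, 100), stringsAsFactors = FALSE)
  m <- log2_matrix(tpm)
  expect_equal(unname(m[, "s1"]), c(0, 3, log2(101)))
  expect_true(all(diff(m[, "s1"]) > 0))   # monotone in TPM
  expect_error(log2_matrix(tpm, pseudocount = 0))
})
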