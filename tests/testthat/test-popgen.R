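# Reference rows whose genotype counts are forced by the published MAF
# and F_IS (n = 34 unless missing data imply fewer).
ref_rows <- list(
  lepr  = list(counts = c(9, 16, 9),  maf = 0.500, he = 0.508,
               fis = 0.074,  hw = 0.7387),
  igf1  = list(counts = c(32, 2, 0),  maf = 0.029, he = 0.058,
               fis = -0.015, hw = 1),
  mstn1 = list(counts = c(24, 8, 2),  maf = 0.176, he = 0.296,
               fis = 0.205,  hw = 0.249),
  actc  = list(counts = c(13, 17, 4), maf = 0.368, he = 0.471,
               fis = -0.060, hw = 1),
  akt3  = list(counts = c(26, 8, 0),  maf = 0.118, he = 0.210,
               fis = -0.119, hw = 1))

test_that("MAF, unbiased He and F_IS reproduce the reference panel rows", {
  for (nm in names(ref_rows)) {
    r <- ref_rows[[nm]]
    expect_equal(round(maf(r$counts[1], r$counts[2], r$counts[3]), 3),
                 r$maf, info = nm)
    expect_equal(round(he_unbiased(r$counts[1], r$counts[2], r$counts[3]), 3),
                 r$he, info = nm)
    expect_equal(round(fis(r$counts[1], r$counts[2], r$counts[3]), 3),
                 r$fis, info = nm)
  }
})

test_that("the exact HW test matches published p-values and a hand enumeration", {
  expect_equal(round(hw_exact(9, 16, 9), 4), 0.7387)
  expect_equal(round(hw_exact(24, 8, 2), 3), 0.249)
  expect_equal(hw_exact(32, 2, 0), 1)
  # two alleles of each kind in two diploids: configurations are h = 0
  # (probability 1/3) and h = 2 (probability 2/3); observed h = 0
  expect_equal(hw_exact(1, 0, 1), 1 / 3)
  expect_equal(hw_exact(0, 2, 0), 1)
  # monomorphic data carry no evidence against equilibrium
  expect_equal(hw_exact(10, 0, 0), 1)
})

test_that("the HW enumeration agrees exactly with a genotype-multiset oracle at n <= 8", {
  for (n in 2:8) {
    for (n_minor in 1:n) {
      hs <- seq(n_minor %% 2, n_minor, by = 2)
      for (h in hs) {
        b <- (n_minor - h) / 2
        a <- n - h - b
        if (a < b) next  # keep the first allele the major one
        expect_equal(hw_exact(a, h, b), hw_exact_bruteforce(a, h, b),
                     tolerance = 1e-9,
                     info = paste("n =", n, "counts", a, h, b))
      }
    }
  }
})

test_that("the enumeration is a proper distribution: the modal configuration has p = 1", {
  for (case in list(c(50, 100, 50), c(150, 40, 10), c(9, 16, 9),
                    c(99, 2, 99))) {
    n <- sum(case)
    m <- min(2 * case[1] + case[2], 2 * case[3] + case[2])
    hs <- seq(m %% 2, min(m, 2 * n - m), by = 2)
    ps <- vapply(hs, function(h) {
      hw_exact((2 * n - m - h) / 2, h, (m - h) / 2)
    }, double(1))
    expect_true(all(ps > 0 & ps <= 1))
    expect_equal(max(ps), 1, tolerance = 1e-9)
  }
})

test_that("F_IS is 1 without heterozygotes and negative under excess", {
  expect_equal(fis(5, 0, 5), 1)
  expect_lt(fis(1, 18, 1), 0)
  he <- he_unbiased(1, 18, 1)
  expect_lt(he, 18 / 20)  # Ho exceeds He here
  expect_error(fis(10, 0, 0), class = "qtlsnp_argument_error")
  expect_error(he_unbiased(1, 0, 0), class = "qtlsnp_argument_error")
  expect_error(maf(0, 0, 0), class = "qtlsnp_argument_error")
})

test_that("assay classification separates failed, monomorphic and polymorphic", {
  expect_identical(classify_assay(rep(NA_character_, 10)), "failed")
  expect_identical(classify_assay(c(rep("A/A", 4), rep(NA, 6))), "failed")
  expect_identical(classify_assay(rep("A/A", 34)), "monomorphic")
  expect_identical(classify_assay(c(rep("A/A", 30), rep("A/G", 4))),
                   "polymorphic")
})

test_that("the G-test matches a hand-computed table and its p-value floor", {
  # identical genotype columns, 34 individuals split 17/17: the 2x2 table
  # is diagonal with expectation 8.5, so G = 2 * 34 * ln 2
  ga <- rep(c("A/A", "A/G"), each = 17)
  res <- ld_gtest(ga, ga, m = 99, seed = 1)
  expect_equal(res$g, 68 * log(2), tolerance = 1e-9)
  expect_equal(res$p, (0 + 1) / (99 + 1))

  expect_error(ld_gtest(rep("A/A", 10), rep(c("A/A", "A/G"), 5)),
               class = "qtlsnp_argument_error")
})

test_that("missing individuals are dropped pairwise in the LD test", {
  ga <- c(NA, rep(c("A/A", "A/G"), each = 10))
  gb <- c("C/C", rep(c("C/C", "C/T"), each = 10))
  res <- ld_gtest(ga, gb, m = 19, seed = 2)
  expect_identical(res$n, 20L)
  expect_equal(res$g, 40 * log(2), tolerance = 1e-9)
})

test_that("genotype counts, genepop round trip and summary work end to end", {
  gt <- dplyr::bind_rows(
    gt_from_counts("lepr", 9, 16, 9, alleles = c("A", "G")),
    gt_from_counts("igf1", 32, 2, 0, alleles = c("G", "T")),
    gt_from_counts("mono", 34, 0, 0, alleles = c("C", "C")),
    gt_from_counts("dead", 0, 0, 0, alleles = c("A", "C"), n_missing = 34))
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(gt, path)
  back <- read_genepop(path)
  expect_identical(
    dplyr::arrange(back, locus, individual)$genotype,
    dplyr::arrange(gt, locus, individual)$genotype)

  s <- popgen_summary(gt)
  expect_identical(s$means$n_assays, 4L)
  expect_identical(s$means$n_feasible, 3L)
  expect_identical(s$means$n_polymorphic, 2L)
  expect_identical(s$n_ld_pairs, choose(2, 2) * 1)
  lepr <- dplyr::filter(s$loci, locus == "lepr")
  expect_equal(round(lepr$he, 3), 0.508)
  expect_equal(round(lepr$fis, 3), 0.074)
  expect_equal(round(lepr$hw_p, 4), 0.7387)
  expect_identical(lepr$major, "A")  # tie at 0.5/0.5 broken alphabetically

  rep_tbl <- report_locus_stats(s, withr::local_tempfile(fileext = ".tsv"))
  expect_identical(rep_tbl$he[rep_tbl$locus == "mono"], "-")
})

test_that("counts_from_stats inverts rounded statistics on forced rows", {
  expect_equal(unlist(counts_from_stats(0.5, 0.508, 0.074)),
               c(n = 34, nAA = 9, nAa = 16, naa = 9))
  expect_equal(unlist(counts_from_stats(0.176, 0.296, 0.205)),
               c(n = 34, nAA = 24, nAa = 8, naa = 2))
  # a locus with missing genotypes: n recovered below 34
  expect_equal(unlist(counts_from_stats(0.344, 0.461, 0.322))[["n"]], 32)
  # self-consistency over the full reference panel
  ref <- reference_panel_stats()
  poly <- ref[ref$status == "polymorphic", ]
  for (i in seq_len(nrow(poly))) {
    cts <- counts_from_stats(poly$maf[i], poly$he[i], poly$fis[i])
    expect_false(is.na(cts$n), info = poly$locus[i])
    expect_equal(round(he_unbiased(cts$nAA, cts$nAa, cts$naa), 3),
                 poly$he[i], info = poly$locus[i])
  }
})

test_that("bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni(0.05, 741), 0.05 / 741)
  expect_equal(round(bonferroni(0.05, 741), 5), 0.00007)
  expect_equal(bonferroni(k = 1), 0.05)
  expect_equal(bonferroni(k = 2), 0.025)
  expect_error(bonferroni(0.05, 0), class = "qtlsnp_argument_error")
})

test_that("ld_scan counts pairs, applies Bonferroni flags and is seeded", {
  pp <- tibble::tibble(locus = sprintf("l%02d", 1:6), ref = "A", alt = "G",
                       p = 0.4, f = 0)
  gt <- sim_genotype_matrix(pp, n = 34, missing_rate = 0, seed = 9)
  ld <- ld_scan(gt, m = 49, seed = 3)
  expect_equal(nrow(ld), choose(6, 2))
  expect_equal(attr(ld, "n_tests"), choose(6, 2))
  expect_equal(attr(ld, "bonferroni_threshold"), 0.05 / choose(6, 2))
  expect_true(all(ld$p >= 1 / 50 & ld$p <= 1))
  ld2 <- ld_scan(gt, m = 49, seed = 3)
  expect_identical(ld$p, ld2$p)
})
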