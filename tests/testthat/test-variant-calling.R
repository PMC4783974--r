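q30 <- function(n) strrep(rawToChar(as.raw(30 + 33)), n)

make_tally <- function(...) {
  # build a tally from named counts at q30
  counts <- c(...)
  bases <- paste(rep(names(counts), counts), collapse = "")
  tally_site(bases, q30(sum(counts)), min_base_qual = 20)
}

test_that("base-quality filtering drops low-quality observations", {
  expect_identical(tally_site(strrep("A", 12), q30(12))$filtered_depth, 12L)

  mixed <- tally_site(paste0(strrep("A", 10), strrep("G", 5)),
                      paste0(q30(10), strrep(rawToChar(as.raw(15 + 33)), 5)),
                      min_base_qual = 20)
  expect_identical(mixed$filtered_depth, 10L)
  expect_identical(unname(mixed$counts["A"]), 10L)
  expect_false("G" %in% names(mixed$counts))

  expect_identical(tally_site("", "")$filtered_depth, 0L)
})

test_that("calls obey the depth and minor-allele-count thresholds", {
  snp <- call_variant(make_tally(A = 8, G = 4))
  expect_identical(snp$variant_class, "SNP")
  expect_identical(c(snp$major, snp$minor), c("A", "G"))
  expect_identical(snp$subst_type, "A/G")

  expect_null(call_variant(make_tally(A = 10, G = 2)))   # MAC 2 < 3
  expect_null(call_variant(make_tally(A = 6, G = 3)))    # depth 9 < 10
  expect_null(call_variant(make_tally(A = 15)))          # single allele

  indel <- call_variant(make_tally(A = 8, `*` = 4))
  expect_identical(indel$variant_class, "non-SNP polymorphism")
  expect_true(is.na(indel$subst_type))

  tri <- call_variant(make_tally(A = 8, G = 5, C = 3))
  expect_true(tri$multiallelic)
  expect_match(tri$note, "C=3")
})

test_that("transitions and transversions are classified by definition", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("T", "C"), "transition")
  for (pair in list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))) {
    expect_identical(classify_substitution(pair[1], pair[2]), "transversion")
  }
  expect_error(classify_substitution("A", "A"), class = "qtlsnp_argument_error")
  expect_error(classify_substitution("A", "N"), class = "qtlsnp_argument_error")
})

fake_calls <- function(subst, class = "SNP", multi = FALSE) {
  tibble::tibble(
    scaffold = "S", pos = seq_along(subst), ref = "A",
    major = "A", minor = "G", major_count = 8L, minor_count = 4L,
    depth = 12L, variant_class = class, subst_type = subst,
    ts_tv = ifelse(subst %in% c("A/G", "C/T"), "transition", "transversion"),
    multiallelic = multi, note = NA_character_)
}

test_that("the substitution spectrum reproduces hand-computed ratios", {
  calls <- rbind(fake_calls(rep(c("A/G", "C/T"), c(30, 26))),
                 fake_calls(rep(c("A/C", "A/T", "C/G", "G/T"), 11)))
  sp <- spectrum(calls)
  expect_identical(sp$ts_count, 56L)
  expect_identical(sp$tv_count, 44L)
  expect_equal(sp$ts_tv_ratio, 56 / 44, tolerance = 1e-12)
  expect_identical(sum(tidy(sp)$count), sp$n_snps)

  all_ts <- spectrum(fake_calls(rep("A/G", 5)))
  expect_true(is.na(all_ts$ts_tv_ratio))

  mixed <- rbind(fake_calls(rep("A/G", 10)),
                 fake_calls(NA_character_, class = "non-SNP polymorphism"))
  expect_equal(spectrum(mixed)$snp_fraction, 10 / 11, tolerance = 1e-12)
})

test_that("SNPs per gene summarises only genes that carry SNPs", {
  feats <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), transcript_id = paste0(c("g1", "g2", "g3"), ".t1"),
    type = "gene", scaffold = "S", strand = "+",
    start = c(100L, 1000L, 5000L), end = c(400L, 1800L, 5900L))
  pos <- c(150L, 250L, 1100L:1103L, 5100L:5105L, 9000L)
  calls <- fake_calls(rep("A/G", length(pos)))
  calls$pos <- pos
  res <- snps_per_gene(calls, feats)
  expect_identical(sort(tidy(res)$n_snps), c(2L, 4L, 6L))
  expect_equal(res$mean, 4)
  expect_identical(c(res$min, res$max), c(2L, 6L))

  none <- snps_per_gene(fake_calls("A/G")[0, ], feats)
  expect_identical(nrow(tidy(none)), 0L)
  expect_true(is.na(none$mean))
})

test_that("raising any caller threshold never increases the number of calls", {
  cfg <- tiny_cfg(seed = 21)
  fx <- emit_fixtures(cfg, withr::local_tempdir())
  base <- nrow(call_variants(fx$pileup, 20, 10, 3))
  expect_gte(base, 1L)
  for (args in list(c(30, 10, 3), c(20, 20, 3), c(20, 10, 5))) {
    stricter <- nrow(call_variants(fx$pileup, args[1], args[2], args[3]))
    expect_lte(stricter, base)
  }
})

test_that("SNP and non-SNP classes partition all calls", {
  cfg <- tiny_cfg(seed = 22)
  g <- gen_genome(cfg)
  truth <- sim_truth(g, cfg)
  pu <- sim_pileup(g, truth, cfg)
  calls <- call_variants(pu)
  sp <- spectrum(calls)
  expect_identical(sp$n_snps + sp$n_other, nrow(calls))
  # six-type counts cover exactly the biallelic SNPs
  expect_identical(sum(tidy(sp)$count),
                   sum(calls$variant_class == "SNP" & !calls$multiallelic))
})

test_that("pileups from two libraries are combined by adding tallies", {
  one <- tibble::tibble(scaffold = "S", pos = 10L, ref = "A",
                        bases = strrep("A", 5), quals = q30(5))
  two <- tibble::tibble(scaffold = "S", pos = 10L, ref = "A",
                        bases = paste0(strrep("A", 3), strrep("G", 3)),
                        quals = q30(6))
  # each library alone is below the depth threshold
  expect_identical(nrow(call_variants(one)), 0L)
  expect_identical(nrow(call_variants(two)), 0L)
  combined <- call_variants(dplyr::bind_rows(one, two))
  expect_identical(nrow(combined), 1L)
  expect_identical(combined$depth, 11L)
  expect_identical(combined$minor_count, 3L)
})
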