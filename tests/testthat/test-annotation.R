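test_that("codon effects match hand translation on the toy gene", {
  g <- toy_gene_plus()
  # CDS is ATG GTT TAA at 3..11; offset 5 is the middle T of GTT (Val)
  nonsyn <- classify_snp_region("S", 7L, "T", "C", g$features, g$scaffolds)
  expect_identical(nonsyn$region, "Exon V-A")  # GTT=Val -> GCT=Ala
  expect_identical(c(nonsyn$aa_ref, nonsyn$aa_alt), c("V", "A"))

  syn <- classify_snp_region("S", 8L, "T", "C", g$features, g$scaffolds)
  expect_identical(syn$region, "Exon syn")     # GTT -> GTC, both Val

  utr5 <- classify_snp_region("S", 1L, "A", "G", g$features, g$scaffolds)
  expect_identical(utr5$region, "5' UTR")
  utr3 <- classify_snp_region("S", 12L, "C", "A", g$features, g$scaffolds)
  expect_identical(utr3$region, "3' UTR")

  expect_error(classify_snp_region("S", 20L, "A", "G", g$features,
                                   g$scaffolds),
               "outside", class = "qtlsnp_argument_error")
})

test_that("an intronic position between two exons classifies as intron", {
  cfg <- tiny_cfg(seed = 31, exons_per_gene = c(2, 2))
  g <- gen_genome(cfg)
  iv <- gene_region_intervals(g$features)
  intron <- dplyr::filter(iv, region == "Intron")[1, ]
  pos <- intron$start
  ref <- substr(g$scaffolds[[intron$scaffold]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  rc <- classify_snp_region(intron$scaffold, pos, ref, alt, g$features,
                            g$scaffolds)
  expect_identical(rc$region, "Intron")
})

test_that("every in-gene position receives exactly one region (partition sweep)", {
  cfg <- sim_config(seed = 33, n_scaffolds = 1, scaffold_length_bp = 6000,
                    n_genes = 2, exons_per_gene = c(2, 3),
                    utr_lengths_bp = c(30, 40))
  g <- gen_genome(cfg)
  spans <- gene_spans(g$features)
  labels <- c("5' UTR", "3' UTR", "Exon syn", "Intron")
  for (i in seq_len(nrow(spans))) {
    for (pos in seq(spans$start[i], spans$end[i])) {
      ref <- substr(g$scaffolds[[spans$scaffold[i]]], pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      rc <- classify_snp_region(spans$scaffold[i], pos, ref, alt,
                                g$features, g$scaffolds)
      expect_length(rc$region, 1L)
      expect_true(rc$region %in% labels || grepl("^Exon [A-Z*]-[A-Z*]$",
                                                 rc$region))
    }
  }
})

test_that("region and amino-acid calls are invariant under strand mirroring", {
  g <- toy_gene_plus()
  m <- mirror_gene(g)
  L <- nchar(g$scaffolds[["S"]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in 1:13) {
    ref <- substr(g$scaffolds[["S"]], pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      fwd <- classify_snp_region("S", pos, ref, alt, g$features, g$scaffolds)
      rev <- classify_snp_region("S", L - pos + 1L, comp[[ref]], comp[[alt]],
                                 m$features, m$scaffolds)
      expect_identical(rev$region, fwd$region)
    }
  }
})

test_that("on the minus strand the 5' UTR is the higher-coordinate UTR", {
  cfg <- tiny_cfg(seed = 35)
  g <- gen_genome(cfg)
  iv <- gene_region_intervals(g$features)
  minus <- dplyr::filter(iv, strand == "-",
                         region %in% c("5' UTR", "3' UTR"))
  for (gid in unique(minus$gene_id)) {
    u <- dplyr::filter(minus, gene_id == gid)
    expect_gt(u$start[u$region == "5' UTR"], u$end[u$region == "3' UTR"])
  }
  plus <- dplyr::filter(iv, strand == "+",
                        region %in% c("5' UTR", "3' UTR"))
  for (gid in unique(plus$gene_id)) {
    u <- dplyr::filter(plus, gene_id == gid)
    expect_lt(u$end[u$region == "5' UTR"], u$start[u$region == "3' UTR"])
  }
})

test_that("the seed-and-extend scan finds identical and reverse-complemented queries", {
  set.seed(101)
  refs <- c(ref1 = paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                         collapse = ""))
  self <- scan_orthologs(c(q = refs[["ref1"]]), refs, min_aligned_len = 100)
  expect_identical(nrow(self), 1L)
  expect_equal(self$identity, 1.0)
  expect_identical(self$strand, "+")
  expect_true(self$best)
  expect_identical(c(self$r_start, self$r_end), c(1L, 600L))

  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(refs[["ref1"]])))
  hit <- scan_orthologs(c(q = rc), refs, min_aligned_len = 100)
  expect_identical(hit$strand, "-")
  expect_equal(hit$identity, 1.0)

  expect_error(scan_orthologs(c(q = "ACGT"), refs, k = 11),
               class = "qtlsnp_argument_error")
})

test_that("random queries produce no high-identity long hits", {
  set.seed(202)
  refs <- c(r = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                      collapse = ""))
  for (i in 1:20) {
    q <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    hits <- scan_orthologs(c(q = q), refs, min_identity = 0.9,
                           min_aligned_len = 100)
    expect_identical(nrow(hits), 0L)
  }
})

test_that("gene placement requires a unique passing scaffold", {
  cfg <- tiny_cfg(seed = 37)
  g <- gen_genome(cfg)
  span <- gene_spans(g$features)[1, ]
  tx <- substr(g$scaffolds[[span$scaffold]], span$start, span$end)

  placed <- place_gene(c(t1 = tx), g$scaffolds, min_aligned_len = 100)
  expect_true(placed$placed)
  expect_identical(placed$scaffold, span$scaffold)
  expect_identical(c(placed$start, placed$end),
                   c(span$start, span$end))

  dup <- g$scaffolds
  dup[["Sm_2"]] <- paste0(substr(dup[["Sm_2"]], 1, 3000), tx)
  amb <- place_gene(c(t1 = tx), dup, min_aligned_len = 100)
  expect_false(amb$placed)
  expect_identical(amb$reason, "non-unique")

  set.seed(303)
  absent <- place_gene(
    c(t1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")),
    g$scaffolds, min_aligned_len = 100)
  expect_false(absent$placed)
  expect_identical(absent$reason, "no hit")
})
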