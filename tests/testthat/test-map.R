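anchors3 <- tibble::tibble(
  marker = c("m1", "m2", "m3", "m4", "m5"),
  lg = c("LG16", "LG16", "LG5", "LG7", "LG2"),
  cm = c(10, 12, 3, 8, 1),
  scaffold = c("Sm_9", "Sm_9", "Sm_3", "Sm_3", "Sm_4"),
  bp = c(1000001L, 2500000L, 40000L, 90000L, 5000L))

test_that("scaffolds inherit the LG of their anchors; conflicts stay unanchored", {
  expect_identical(anchor_scaffold("Sm_9", anchors3)$lg, "LG16")
  none <- anchor_scaffold("Sm_99", anchors3)
  expect_true(is.na(none$lg))
  expect_identical(none$reason, "no anchors")
  conf <- anchor_scaffold("Sm_3", anchors3)
  expect_true(is.na(conf$lg))
  expect_identical(conf$reason, "conflict")
})

test_that("synteny inference takes a strict majority and refuses ties", {
  chrom_to_lg <- tibble::tibble(chrom = c("chrI", "chrII", "chrIII"),
                                lg = c("LG16", "LG2", "LG9"))
  votes <- tibble::tibble(gene = c("a", "b", "c"),
                          chrom = c("chrI", "chrI", "chrI"))
  res <- infer_lg_synteny(votes, chrom_to_lg)
  expect_identical(res$lg, "LG16")
  expect_true(res$inferred)

  tie <- infer_lg_synteny(tibble::tibble(gene = c("a", "b"),
                                         chrom = c("chrII", "chrIII")),
                          chrom_to_lg)
  expect_true(is.na(tie$lg))
  expect_identical(tie$reason, "tie")

  empty <- infer_lg_synteny(tibble::tibble(gene = character(),
                                           chrom = character()),
                            chrom_to_lg)
  expect_identical(empty$reason, "no data")
})

test_that("gene-marker distances are boundary gaps, zero inside the span", {
  genes <- tibble::tibble(gene = "fgf_like", scaffold = "Sm_9",
                          start = 1034001L, end = 1040000L)
  qtls <- tibble::tibble(trait = "K", lg = "LG16", marker = "m1",
                         vpe = 25, ci_markers = NA_character_)
  cl <- colocalize(genes, qtls, anchors3)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$distance_bp, 34000)
  expect_true(cl$within_preference)
  expect_identical(cl$evidence, "direct-marker")

  inside <- colocalize(
    tibble::tibble(gene = "g", scaffold = "Sm_9", start = 900000L,
                   end = 1100000L), qtls, anchors3)
  expect_identical(inside$distance_bp, 0)

  other <- colocalize(
    tibble::tibble(gene = "g", scaffold = "Sm_4", start = 1L, end = 2000L),
    qtls, anchors3)
  expect_identical(nrow(other), 0L)
  rep <- report_colocalization(
    tibble::tibble(gene = "g", scaffold = "Sm_4", start = 1L, end = 2000L),
    other, anchors3)
  expect_identical(rep$qtl_marker, "nd")
})

test_that("QTLs without an associated marker fall back to CI reference markers", {
  genes <- tibble::tibble(gene = "g", scaffold = "Sm_9",
                          start = 2510000L, end = 2512000L)
  qtls <- tibble::tibble(trait = "BW", lg = "LG16", marker = "nd",
                         vpe = NA_real_, ci_markers = "m1, m2")
  cl <- colocalize(genes, qtls, anchors3)
  expect_identical(nrow(cl), 2L)
  expect_true(all(cl$evidence == "closest-marker"))
  expect_identical(min(cl$distance_bp), 10000)

  bad <- tibble::tibble(trait = "BW", lg = "LG16", marker = "nd",
                        vpe = NA_real_, ci_markers = NA_character_)
  expect_error(colocalize(genes, bad, anchors3),
               class = "qtlsnp_argument_error")

  ghost <- tibble::tibble(trait = "BW", lg = "LG16", marker = "ghost",
                          vpe = 5, ci_markers = NA_character_)
  expect_warning(res <- colocalize(genes, ghost, anchors3), "unresolvable")
  expect_identical(nrow(res), 0L)
})

test_that("physical-genetic conversion uses 0.5 Mb/cM and round-trips", {
  expect_equal(mb_to_cm(1.9), 3.8)
  expect_equal(mb_to_cm(0), 0)
  expect_equal(mb_to_cm(0.5), 1)
  expect_equal(cm_to_mb(4), 2)
  for (d in c(0, 0.1, 1.9, 12.5)) {
    expect_equal(cm_to_mb(mb_to_cm(d)), d)
  }
  expect_error(mb_to_cm(-1), class = "qtlsnp_argument_error")
  expect_error(cm_to_mb(1, mb_per_cm = 0), class = "qtlsnp_argument_error")
})

test_that("co-localization distances match a brute-force oracle on a fixture", {
  cfg <- tiny_cfg(seed = 41)
  fx <- emit_fixtures(cfg, withr::local_tempdir())
  genes <- dplyr::rename(gene_spans(fx$genome$features), gene = gene_id)
  cl <- colocalize(genes, fx$map$qtls, fx$map$anchors)

  # brute force over all gene x resolvable-marker pairs
  expected <- list()
  for (i in seq_len(nrow(fx$map$qtls))) {
    q <- fx$map$qtls[i, ]
    mks <- if (q$marker != "nd") q$marker else
      strsplit(q$ci_markers, ",\\s*")[[1]]
    for (mk in mks) {
      a <- fx$map$anchors[fx$map$anchors$marker == mk, ]
      if (nrow(a) == 0) next
      for (j in seq_len(nrow(genes))) {
        if (genes$scaffold[j] != a$scaffold) next
        d <- if (a$bp >= genes$start[j] && a$bp <= genes$end[j]) 0 else
          min(abs(a$bp - genes$start[j]), abs(a$bp - genes$end[j]))
        expected[[length(expected) + 1]] <-
          data.frame(gene = genes$gene[j], qtl_marker = mk, d = d)
      }
    }
  }
  expected <- do.call(rbind, expected)
  got <- dplyr::arrange(cl, gene, qtl_marker)
  want <- dplyr::arrange(tibble::as_tibble(expected), gene, qtl_marker)
  expect_identical(nrow(got), nrow(want))
  expect_equal(got$distance_bp, want$d)
  expect_equal(mean(got$distance_bp), mean(want$d))
  expect_true(all(got$distance_bp >= 0))
  expect_identical(got$distance_bp == 0,
                   want$d == 0)
})
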