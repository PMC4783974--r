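#' Per-locus genotype counts from a long genotype table
#'
#' Only biallelic loci are supported.  The major homozygote count `nAA`
#' refers to the more frequent allele (ties broken alphabetically).
#'
#' @param gt Long genotype tibble (`individual`, `locus`, `genotype` with
#'   sorted `"X/Y"` strings, `NA` missing).
#' @return Tibble per locus: `locus`, `n_typed`, `n_missing`, `major`,
#'   `minor`, `nAA`, `nAa`, `naa`, `maf`.
#' @export
genotype_counts <- function(gt) {
  gt |>
    group_by(.data$locus) |>
    summarise(counts = list(count_one_locus(.data$genotype)),
              .groups = "drop") |>
    tidyr::unnest_wider("counts")
}

count_one_locus <- function(genotype) {
  typed <- genotype[!is.na(genotype)]
  n_missing <- sum(is.na(genotype))
  if (length(typed) == 0L) {
    return(list(n_typed = 0L, n_missing = n_missing, major = NA_character_,
                minor = NA_character_, nAA = 0L, nAa = 0L, naa = 0L,
                maf = NA_real_))
  }
  al <- strsplit(typed, "/", fixed = TRUE)
  alleles <- unlist(al)
  ac <- sort(table(alleles), decreasing = TRUE)
  if (length(ac) > 2L) {
    stop_arg("locus is not biallelic: alleles ",
             paste(names(ac), collapse = ", "))
  }
  major <- names(ac)[1]
  # alphabetical tie-break for equally frequent alleles
  if (length(ac) == 2L && ac[1] == ac[2]) {
    major <- sort(names(ac))[1]
  }
  minor <- if (length(ac) == 2L) setdiff(names(ac), major) else NA_character_
  het <- vapply(al, function(a) a[1] != a[2], logical(1))
  nAa <- sum(het)
  nAA <- sum(!het & vapply(al, function(a) a[1] == major, logical(1)))
  naa <- length(typed) - nAa - nAA
  n <- length(typed)
  minor_count <- if (is.na(minor)) 0L else unname(ac[minor])
  list(n_typed = n, n_missing = n_missing, major = major, minor = minor,
       nAA = nAA, nAa = nAa, naa = naa,
       maf = minor_count / (2 * n))
}

check_counts <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0) ||
      any(c(nAA, nAa, naa) != trunc(c(nAA, nAa, naa)))) {
    stop_arg("genotype counts must be non-negative integers")
  }
}

#' Minor allele frequency from genotype counts
#'
#' @param nAA,nAa,naa Counts of major homozygotes, heterozygotes and
#'   minor homozygotes.
#' @return MAF in `[0, 0.5]`.
#' @export
#' @examples
#' maf(9, 16, 9)   # 0.5
#' maf(32, 2, 0)   # 2/68
maf <- function(nAA, nAa, naa) {
  check_counts(nAA, nAa, naa)
  n <- nAA + nAa + naa
  if (n == 0L) stop_arg("MAF undefined: no typed individuals")
  min(2 * nAA + nAa, 2 * naa + nAa) / (2 * n)
}

#' Unbiased gene diversity (expected heterozygosity)
#'
#' Nei's unbiased estimator
#' `He = n/(n-1) * (1 - sum(p_i^2) - Ho/(2n))`
#' with `n` typed individuals and observed heterozygosity `Ho`.
#'
#' @inheritParams maf
#' @return He in `[0, 1]`.
#' @export
#' @examples
#' round(he_unbiased(9, 16, 9), 3)  # 0.508
he_unbiased <- function(nAA, nAa, naa) {
  check_counts(nAA, nAa, naa)
  n <- nAA + nAa + naa
  if (n < 2L) stop_arg("He undefined: need at least 2 typed individuals")
  p <- (2 * nAA + nAa) / (2 * n)
  ho <- nAa / n
  n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n))
}

#' Fixation index F_IS
#'
#' `F_IS = 1 - Ho / He` with the unbiased He of [he_unbiased()].
#' Positive values indicate heterozygote deficit, negative values excess.
#'
#' @inheritParams maf
#' @return F_IS (at most 1; exactly 1 when `Ho = 0` and `He > 0`).
#' @export
#' @examples
#' round(fis(9, 16, 9), 3)  # 0.074
fis <- function(nAA, nAa, naa) {
  he <- he_unbiased(nAA, nAa, naa)
  if (he <= 0) stop_arg("F_IS undefined: He = 0 (monomorphic locus)")
  1 - (nAa / (nAA + nAa + naa)) / he
}

#' Exact Hardy-Weinberg test by complete enumeration
#'
#' Conditional on the observed allele counts, every heterozygote count of
#' matching parity is enumerated; the p-value of the probability-ordering
#' (two-sided) exact test is the total probability of configurations no
#' more likely than the observed one.  Computed with log-factorials; a
#' relative tolerance of 1e-12 treats equal probabilities as ties.
#'
#' @inheritParams maf
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' round(hw_exact(9, 16, 9), 4)  # 0.7387
#' hw_exact(1, 0, 1)             # 1/3
hw_exact <- function(nAA, nAa, naa) {
  check_counts(nAA, nAa, naa)
  n <- nAA + nAa + naa
  if (n < 1L) stop_arg("HW test undefined: no typed individuals")
  n_min <- min(2 * nAA + nAa, 2 * naa + nAa)
  n_maj <- 2L * n - n_min
  if (n_min == 0L) return(1)  # monomorphic: single configuration
  hs <- seq.int(n_min %% 2L, min(n_min, n_maj), by = 2L)
  logp <- vapply(hs, function(h) {
    hom_min <- (n_min - h) / 2
    hom_maj <- (n_maj - h) / 2
    lfactorial(n) + h * log(2) -
      lfactorial(hom_min) - lfactorial(h) - lfactorial(hom_maj)
  }, double(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hs)]
  if (is.na(obs)) stop_arg("inconsistent genotype counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Classify a genotyped assay
#'
#' @param genotype Genotype column of one locus (`NA` missing).
#' @param max_missing Maximum tolerated missing fraction.
#' @return `"failed"`, `"monomorphic"` or `"polymorphic"`.
#' @export
classify_assay <- function(genotype, max_missing = 0.5) {
  if (length(genotype) == 0L) return("failed")
  if (mean(is.na(genotype)) > max_missing) return("failed")
  typed <- genotype[!is.na(genotype)]
  alleles <- unique(unlist(strsplit(typed, "/", fixed = TRUE)))
  if (length(alleles) <= 1L) "monomorphic" else "polymorphic"
}

#' Bonferroni threshold
#'
#' @param alpha Family-wise error rate.
#' @param k Number of tests (>= 1).
#' @return `alpha / k`.
#' @export
#' @examples
#' bonferroni(k = 741)  # 0.0000675
bonferroni <- function(alpha = 0.05, k) {
  if (!is_count(k)) stop_arg("`k` must be a positive count")
  if (alpha <= 0 || alpha > 1) stop_arg("`alpha` must lie in (0, 1]")
  alpha / k
}

#' Genotypic linkage-disequilibrium G-test with permutation null
#'
#' Builds the genotype-by-genotype contingency table of two loci over
#' individuals typed at both, computes the log-likelihood ratio statistic
#' `G = 2 * sum(O * ln(O / E))` (zero cells skipped), and estimates the
#' p-value from `m` random permutations of one locus across individuals
#' as `(b + 1) / (m + 1)`, where `b` is the count of permuted G values at
#' least as large as the observed one.
#'
#' @param ga,gb Genotype columns of the two loci (same individuals).
#' @param m Number of permutations.
#' @param seed Integer seed for the permutation null.
#' @return One-row tibble: `g`, `p`, `m`, `n` (individuals used).
#' @export
ld_gtest <- function(ga, gb, m = 10000L, seed = 1L) {
  keep <- !is.na(ga) & !is.na(gb)
  a <- factor(ga[keep])
  b <- factor(gb[keep])
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop_arg("LD G-test undefined: fewer than 2 distinct genotypes at a locus")
  }
  ai <- as.integer(a); bi <- as.integer(b)
  ka <- nlevels(a); kb <- nlevels(b)
  n <- length(ai)
  g_stat <- function(ai, bi) {
    o <- tabulate(ai + ka * (bi - 1L), ka * kb)
    ra <- tabulate(ai, ka); rb <- tabulate(bi, kb)
    e <- as.vector(outer(ra, rb)) / n
    nz <- o > 0L
    2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  g_obs <- g_stat(ai, bi)
  set.seed(seed)
  b_ge <- 0L
  for (i in seq_len(m)) {
    if (g_stat(ai, sample(bi)) >= g_obs - 1e-9) b_ge <- b_ge + 1L
  }
  tibble(g = g_obs, p = (b_ge + 1) / (m + 1), m = as.integer(m),
         n = as.integer(n))
}

#' Pairwise LD scan over the polymorphic loci of a panel
#'
#' Runs [ld_gtest()] for every pair of polymorphic loci and flags nominal
#' and Bonferroni-corrected significance (`p <= alpha`, respectively
#' `p <= alpha / n_pairs`).
#'
#' @param gt Long genotype tibble.
#' @param m Permutations per pair.
#' @param seed Integer seed; each pair uses a distinct derived seed.
#' @param alpha Nominal significance level.
#' @param max_missing Passed to [classify_assay()].
#' @return Tibble `locus_a`, `locus_b`, `g`, `p`, `significant_nominal`,
#'   `significant_bonferroni`, with attributes `n_tests` and
#'   `bonferroni_threshold`.
#' @export
ld_scan <- function(gt, m = 10000L, seed = 1L, alpha = 0.05,
                    max_missing = 0.5) {
  cols <- gt |>
    group_by(.data$locus) |>
    summarise(status = classify_assay(.data$genotype, max_missing),
              .groups = "drop")
  poly <- cols$locus[cols$status == "polymorphic"]
  wide <- gt |>
    filter(.data$locus %in% poly) |>
    tidyr::pivot_wider(names_from = "locus", values_from = "genotype")
  pairs <- if (length(poly) >= 2L) utils::combn(poly, 2L) else
    matrix(character(0), nrow = 2L)
  k <- ncol(pairs)
  rows <- purrr::map(seq_len(k), function(i) {
    res <- ld_gtest(wide[[pairs[1L, i]]], wide[[pairs[2L, i]]],
                    m = m, seed = seed + i)
    mutate(res, locus_a = pairs[1L, i], locus_b = pairs[2L, i],
           .before = 1L)
  })
  out <- bind_rows(rows)
  if (k == 0L) {
    out <- tibble(locus_a = character(), locus_b = character(),
                  g = double(), p = double(), m = integer(), n = integer())
  }
  thr <- if (k >= 1L) bonferroni(alpha, k) else NA_real_
  out <- mutate(out, significant_nominal = .data$p <= alpha,
                significant_bonferroni = .data$p <= thr)
  attr(out, "n_tests") <- k
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Expand genotype counts into a genotype column
#'
#' Convenience constructor used in validation work: builds the explicit
#' genotype vector corresponding to per-locus genotype counts.
#'
#' @inheritParams maf
#' @param alleles Major and minor allele labels.
#' @return Character vector of length `nAA + nAa + naa`.
#' @export
#' @examples
#' table(genotypes_from_counts(9, 16, 9))
genotypes_from_counts <- function(nAA, nAa, naa, alleles = c("A", "G")) {
  check_counts(nAA, nAa, naa)
  a <- alleles[1]; b <- alleles[2]
  het <- paste(sort(c(a, b)), collapse = "/")
  c(rep(paste0(a, "/", a), nAA), rep(het, nAa), rep(paste0(b, "/", b), naa))
}

#' Summarise a validation genotype matrix
#'
#' Classifies every assay, then computes MAF, observed heterozygosity,
#' unbiased He, F_IS and the exact Hardy-Weinberg p-value for each
#' polymorphic locus, plus panel means and the number of LD pairs
#' (`choose(n_polymorphic, 2)`).
#'
#' @param gt Long genotype tibble.
#' @param max_missing Missing-fraction threshold for failed assays.
#' @return Object of class `popgen_summary`: list with `loci` (per-locus
#'   tibble), `means` (one-row tibble of panel means and SD/SE over
#'   polymorphic loci) and `n_ld_pairs`.
#' @export
#' @examples
#' gt <- tibble::tibble(individual = sprintf("i%02d", 1:34),
#'                      locus = "lepr",
#'                      genotype = genotypes_from_counts(9, 16, 9))
#' popgen_summary(gt)$loci
popgen_summary <- function(gt, max_missing = 0.5) {
  counts <- genotype_counts(gt)
  status <- gt |>
    group_by(.data$locus) |>
    summarise(status = classify_assay(.data$genotype, max_missing),
              .groups = "drop")
  loci <- left_join(counts, status, by = "locus") |>
    rowwise() |>
    mutate(
      ho = if (.data$status == "polymorphic")
        .data$nAa / .data$n_typed else NA_real_,
      he = if (.data$status == "polymorphic")
        he_unbiased(.data$nAA, .data$nAa, .data$naa) else NA_real_,
      fis = if (.data$status == "polymorphic")
        fis(.data$nAA, .data$nAa, .data$naa) else NA_real_,
      hw_p = if (.data$status == "polymorphic")
        hw_exact(.data$nAA, .data$nAa, .data$naa) else NA_real_,
      maf = if (.data$status == "polymorphic") .data$maf else NA_real_) |>
    ungroup() |>
    relocate("status", .after = "locus")
  poly <- filter(loci, .data$status == "polymorphic")
  k <- nrow(poly)
  means <- tibble(
    n_assays = nrow(loci),
    n_feasible = sum(loci$status != "failed"),
    n_polymorphic = k,
    mean_maf = mean(poly$maf), sd_maf = sd(poly$maf),
    mean_he = mean(poly$he), sd_he = sd(poly$he),
    mean_fis = mean(poly$fis), sd_fis = sd(poly$fis),
    se_fis = sd(poly$fis) / sqrt(max(k, 1)))
  structure(list(loci = loci, means = means,
                 n_ld_pairs = choose(k, 2)),
            class = "popgen_summary")
}

#' @export
print.popgen_summary <- function(x, ...) {
  m <- x$means
  cat("<popgen_summary>", m$n_assays, "assays:", m$n_feasible, "feasible,",
      m$n_polymorphic, "polymorphic;", x$n_ld_pairs, "LD pairs\n")
  if (m$n_polymorphic > 0) {
    cat("  mean MAF", round(m$mean_maf, 3), "| mean He", round(m$mean_he, 3),
        "| mean F_IS", round(m$mean_fis, 3), "\n")
  }
  invisible(x)
}

#' @export
tidy.popgen_summary <- function(x, ...) x$loci

#' @export
glance.popgen_summary <- function(x, ...) {
  mutate(x$means, n_ld_pairs = x$n_ld_pairs)
}

#' @export
autoplot.popgen_summary <- function(object, ...) {
  poly <- filter(object$loci, .data$status == "polymorphic")
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$maf, y = .data$he)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fis), size = 2) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey60",
                                    high = "red", midpoint = 0) +
    ggplot2::labs(x = "minor allele frequency", y = "unbiased He",
                  colour = expression(F[IS])) +
    ggplot2::theme_minimal()
}

#' Write a panel validation report
#'
#' One row per assayed locus in the conventional panel-table shape: SNP,
#' variant alleles, genomic position (`scaffold: pos`), gene region, MAF,
#' exact HW p-value, He and F_IS, rounded to 3 decimals (HW p to 4).
#' Failed and monomorphic assays keep `-` in the statistic columns.
#'
#' @param summary A [popgen_summary()].
#' @param path Output TSV path.
#' @param panel_info Optional tibble `locus`, `snp`, `variant`,
#'   `genomic_position`, `gene_region` merged into the report.
#' @return The report tibble, invisibly written to `path`.
#' @export
report_locus_stats <- function(summary, path = NULL, panel_info = NULL) {
  loci <- summary$loci
  fmt <- function(x, d) ifelse(is.na(x), "-", formatC(round(x, d),
                                                      format = "fg"))
  rep_tbl <- tibble(
    locus = loci$locus,
    status = loci$status,
    variant = ifelse(is.na(loci$minor), loci$major,
                     paste0(loci$major, "/", loci$minor)),
    maf = fmt(loci$maf, 3),
    p_hw = fmt(loci$hw_p, 4),
    he = fmt(loci$he, 3),
    fis = fmt(loci$fis, 3))
  if (!is.null(panel_info)) {
    rep_tbl <- left_join(panel_info, rep_tbl, by = "locus")
  }
  if (!is.null(path)) readr::write_tsv(rep_tbl, path)
  invisible(rep_tbl)
}

#' Recover genotype counts from rounded summary statistics
#'
#' Given a locus's published minor allele frequency, unbiased He and
#' F_IS (all rounded to 3 decimals) for a sample of at most `n_max`
#' diploids, searches the small discrete space of genotype configurations
#' for one that reproduces all three printed values.  Useful to rebuild
#' genotype data from reference panel tables that print statistics but
#' not raw genotypes; counts are uniquely forced in practice because the
#' three statistics over-determine the two free counts.
#'
#' @param maf,he,fis Printed statistics (3 decimals).
#' @param n_max Largest plausible number of typed individuals; smaller
#'   `n` values are tried down to `n_min` (some loci have missing
#'   genotypes).
#' @param n_min Smallest `n` tried.
#' @return One-row tibble `n`, `nAA`, `nAa`, `naa`, or all-`NA` when no
#'   configuration matches.
#' @export
#' @examples
#' counts_from_stats(0.5, 0.508, 0.074)   # 9, 16, 9
counts_from_stats <- function(maf, he, fis, n_max = 34L, n_min = 26L) {
  for (n in seq.int(n_max, n_min)) {
    m <- round(2 * n * maf)
    if (m < 1) next
    ho_target <- (1 - fis) * he
    hs <- seq.int(m %% 2L, m, by = 2L)
    hs <- hs[order(abs(hs - n * ho_target))]
    for (h in hs) {
      a <- (2L * n - m - h) / 2L
      b <- (m - h) / 2L
      if (a < 0 || b < 0) next
      he_c <- he_unbiased(a, h, b)
      if (he_c <= 0) next
      if (round(m / (2 * n), 3) == maf && round(he_c, 3) == he &&
          round(1 - (h / n) / he_c, 3) == fis) {
        return(tibble(n = n, nAA = a, nAa = h, naa = b))
      }
    }
  }
  tibble(n = NA_integer_, nAA = NA_integer_, nAa = NA_integer_,
         naa = NA_integer_)
}
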