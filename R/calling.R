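#' Tally bases at one pileup site after quality filtering
#'
#' Observations with Phred quality below `min_base_qual` are discarded;
#' the rest are counted per allele (`*` counts as an indel token).
#'
#' @param bases String of observed bases over `A/C/G/T/*`.
#' @param quals Matching Phred+33 quality string.
#' @param min_base_qual Minimum Phred base quality retained.
#' @return List with `counts` (named integer vector, decreasing) and
#'   `filtered_depth` (`sum(counts)`).
#' @export
#' @examples
#' tally_site("AAAAGGGG", "IIIIII55", min_base_qual = 20)
tally_site <- function(bases, quals, min_base_qual = 20L) {
  if (nchar(bases) != nchar(quals)) {
    stop_arg("`bases` and `quals` must have equal length")
  }
  if (nchar(bases) == 0L) {
    return(list(counts = integer(0), filtered_depth = 0L))
  }
  b <- strsplit(bases, "", fixed = TRUE)[[1]]
  q <- utf8ToInt(quals) - 33L
  if (any(q < 0L)) stop_arg("negative Phred quality in `quals`")
  keep <- q >= min_base_qual
  counts <- sort(table(b[keep]), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, filtered_depth = sum(counts))
}

#' Call a variant from an allele tally
#'
#' A call is emitted iff the filtered depth reaches `min_depth`, at least
#' two alleles were observed, and the second-most-frequent allele count
#' reaches `min_mac`.  Ties in allele frequency are broken
#' lexicographically.  The call is a SNP when both top alleles are single
#' bases; an indel token among them makes it a non-SNP polymorphism.
#' Further alleles that also reach `min_mac` are recorded in `note` and
#' flag the site as multi-allelic.
#'
#' @param tally Result of [tally_site()].
#' @param min_depth Minimum filtered depth.
#' @param min_mac Minimum minor (second) allele count.
#' @return One-row tibble (`major`, `minor`, counts, `variant_class`,
#'   `subst_type`, `ts_tv`, `multiallelic`, `note`) or `NULL` for no-call.
#' @export
call_variant <- function(tally, min_depth = 10L, min_mac = 3L) {
  counts <- tally$counts
  if (tally$filtered_depth < min_depth || length(counts) < 2L) return(NULL)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  if (counts[2L] < min_mac) return(NULL)
  major <- names(counts)[1L]
  minor <- names(counts)[2L]
  extra <- counts[-(1:2)]
  extra <- extra[extra >= min_mac]
  is_snp <- major %in% DNA_BASES && minor %in% DNA_BASES
  subst <- if (is_snp) paste(sort(c(major, minor)), collapse = "/") else NA
  tibble(
    major = major, minor = minor,
    major_count = unname(counts[1L]), minor_count = unname(counts[2L]),
    depth = tally$filtered_depth,
    variant_class = if (is_snp) "SNP" else "non-SNP polymorphism",
    subst_type = subst,
    ts_tv = if (is_snp) classify_substitution(major, minor) else NA_character_,
    multiallelic = length(extra) > 0L,
    note = if (length(extra) > 0L) {
      paste0("extra alleles: ",
             paste0(names(extra), "=", extra, collapse = ","))
    } else NA_character_)
}

#' Call variants over a whole pileup
#'
#' Applies [tally_site()] then [call_variant()] to every site.  Tallies
#' from repeated sites (the same scaffold and position seen in several
#' libraries) are added together before calling.
#'
#' @param pileup Pileup tibble (`scaffold`, `pos`, `ref`, `bases`,
#'   `quals`).
#' @param min_base_qual,min_depth,min_mac Caller thresholds.
#' @return Tibble of calls with site columns plus the [call_variant()]
#'   fields.
#' @export
call_variants <- function(pileup, min_base_qual = 20L, min_depth = 10L,
                          min_mac = 3L) {
  merged <- pileup |>
    group_by(.data$scaffold, .data$pos, .data$ref) |>
    summarise(bases = paste(.data$bases, collapse = ""),
              quals = paste(.data$quals, collapse = ""),
              .groups = "drop")
  rows <- purrr::pmap(merged, function(scaffold, pos, ref, bases, quals) {
    cl <- call_variant(tally_site(bases, quals, min_base_qual),
                       min_depth = min_depth, min_mac = min_mac)
    if (is.null(cl)) return(NULL)
    bind_cols(tibble(scaffold = scaffold, pos = pos, ref = ref), cl)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(scaffold = character(), pos = integer(), ref = character(),
                  major = character(), minor = character(),
                  major_count = integer(), minor_count = integer(),
                  depth = integer(), variant_class = character(),
                  subst_type = character(), ts_tv = character(),
                  multiallelic = logical(), note = character()))
  }
  arrange(out, .data$scaffold, .data$pos)
}

#' Classify a base substitution as transition or transversion
#'
#' A<->G and C<->T are transitions; every other base pair is a
#' transversion.
#'
#' @param a,b Two distinct bases.
#' @return `"transition"` or `"transversion"`.
#' @export
#' @examples
#' classify_substitution("A", "G")
classify_substitution <- function(a, b) {
  check_base(a, "a"); check_base(b, "b")
  if (a == b) stop_arg("`a` and `b` must differ")
  pair <- paste(sort(c(a, b)), collapse = "/")
  if (pair %in% c("A/G", "C/T")) "transition" else "transversion"
}

SUBST_TYPES <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")

#' Substitution spectrum of a call set
#'
#' Counts biallelic SNPs per substitution type (A/G, C/T, A/C, A/T, C/G,
#' G/T), the transition and transversion totals and their ratio, and the
#' SNP fraction among all polymorphisms.  Non-SNP polymorphisms and
#' multi-allelic SNPs are excluded from the six-type partition but counted
#' in the totals.
#'
#' @param calls Call tibble ([call_variants()]).
#' @return Object of class `snp_spectrum` with fields `type_counts`
#'   (tibble), `ts_count`, `tv_count`, `ts_tv_ratio` (`NA` when no
#'   transversions), `n_snps`, `n_other`, `n_multiallelic`,
#'   `snp_fraction`.
#' @export
spectrum <- function(calls) {
  snps <- filter(calls, .data$variant_class == "SNP")
  bi <- filter(snps, !.data$multiallelic)
  counts <- table(factor(bi$subst_type, levels = SUBST_TYPES))
  ts <- sum(counts[c("A/G", "C/T")])
  tv <- sum(counts[c("A/C", "A/T", "C/G", "G/T")])
  n_other <- sum(calls$variant_class != "SNP")
  structure(list(
    type_counts = tibble(subst_type = SUBST_TYPES,
                         count = as.integer(counts),
                         class = ifelse(SUBST_TYPES %in% c("A/G", "C/T"),
                                        "transition", "transversion")),
    ts_count = ts, tv_count = tv,
    ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
    n_snps = nrow(snps), n_other = n_other,
    n_multiallelic = sum(snps$multiallelic),
    snp_fraction = if (nrow(calls) > 0) nrow(snps) / nrow(calls) else NA_real_),
    class = "snp_spectrum")
}

#' @export
print.snp_spectrum <- function(x, ...) {
  cat("<snp_spectrum>", x$n_snps, "SNPs /", x$n_snps + x$n_other,
      "polymorphisms (fraction",
      ifelse(is.na(x$snp_fraction), "NA", round(x$snp_fraction, 3)),
      ")\n  ts =", x$ts_count, ", tv =", x$tv_count, ", ts/tv =",
      ifelse(is.na(x$ts_tv_ratio), "undefined", round(x$ts_tv_ratio, 3)),
      "\n")
  invisible(x)
}

#' @export
tidy.snp_spectrum <- function(x, ...) x$type_counts

#' @export
glance.snp_spectrum <- function(x, ...) {
  tibble(n_snps = x$n_snps, n_other = x$n_other,
         n_multiallelic = x$n_multiallelic, ts_count = x$ts_count,
         tv_count = x$tv_count, ts_tv_ratio = x$ts_tv_ratio,
         snp_fraction = x$snp_fraction)
}

#' @export
autoplot.snp_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$type_counts,
                  ggplot2::aes(x = .data$subst_type, y = .data$count,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution type", y = "SNPs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' SNPs per gene
#'
#' Assigns each biallelic SNP call to the genes whose span contains it and
#' summarises the per-gene counts.  Genes without any SNP are excluded, so
#' the reported minimum is at least 1.
#'
#' @param calls Call tibble.
#' @param features Gene-model feature tibble.
#' @return Object of class `snp_gene_summary`: list with `per_gene`
#'   (tibble `gene_id`, `n_snps`) and `mean`, `sd`, `min`, `max`.
#' @export
snps_per_gene <- function(calls, features) {
  spans <- gene_spans(features)
  snps <- filter(calls, .data$variant_class == "SNP")
  per_gene <- spans |>
    rowwise() |>
    mutate(n_snps = sum(snps$scaffold == .data$scaffold &
                          snps$pos >= .data$start &
                          snps$pos <= .data$end)) |>
    ungroup() |>
    filter(.data$n_snps > 0L) |>
    select("gene_id", "n_snps")
  structure(list(
    per_gene = per_gene,
    mean = if (nrow(per_gene)) mean(per_gene$n_snps) else NA_real_,
    sd = if (nrow(per_gene) > 1L) sd(per_gene$n_snps) else NA_real_,
    min = if (nrow(per_gene)) min(per_gene$n_snps) else NA_integer_,
    max = if (nrow(per_gene)) max(per_gene$n_snps) else NA_integer_),
    class = "snp_gene_summary")
}

#' @export
print.snp_gene_summary <- function(x, ...) {
  cat("<snp_gene_summary>", nrow(x$per_gene), "genes with SNPs; mean",
      round(x$mean, 2), "+/-", round(x$sd, 2), "; range", x$min, "-",
      x$max, "\n")
  invisible(x)
}

#' @export
tidy.snp_gene_summary <- function(x, ...) x$per_gene

#' @export
glance.snp_gene_summary <- function(x, ...) {
  tibble(n_genes = nrow(x$per_gene), mean = x$mean, sd = x$sd,
         min = x$min, max = x$max)
}
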