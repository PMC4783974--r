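#' Configuration for panel selection
#'
#' Codifies the manual-inspection step of assay design as reproducible
#' rules: a minimum discovery minor-allele fraction, a clean-flank
#' requirement, a strict region priority and a bonus for co-localizing
#' with a QTL marker within the preference distance.
#'
#' @param min_discovery_maf Candidates below this pooled minor-allele
#'   fraction are excluded.
#' @param min_flank_bp Flank length (clean bases either side) at which the
#'   flank adequacy term saturates.
#' @param region_priority Strict ordering of region classes, best first.
#'   `"Exon nonsyn"` stands for every `"Exon X-Y"` label.
#' @param qtl_bonus Score bonus for a within-preference co-localization.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(min_discovery_maf = 0.1,
                             min_flank_bp = 30L,
                             region_priority = c("Exon nonsyn", "5' UTR",
                                                 "3' UTR", "Exon syn",
                                                 "Intron"),
                             qtl_bonus = 5) {
  if (min_discovery_maf < 0 || min_discovery_maf > 0.5) {
    stop_arg("`min_discovery_maf` must lie in [0, 0.5]")
  }
  if (anyDuplicated(region_priority)) {
    stop_arg("`region_priority` must be a strict ordering")
  }
  structure(list(min_discovery_maf = min_discovery_maf,
                 min_flank_bp = as.integer(min_flank_bp),
                 region_priority = region_priority,
                 qtl_bonus = qtl_bonus),
            class = "selection_config")
}

region_class <- function(region) {
  ifelse(grepl("^Exon ", region) & region != "Exon syn",
         "Exon nonsyn", region)
}

#' Score candidate SNPs for panel selection
#'
#' The score is `10 * region rank + qtl bonus + flank term`: the region
#' rank follows the configured strict priority (spacing guarantees the
#' priority always dominates), the bonus applies when the gene has any
#' within-preference co-localization, and the flank term grows with flank
#' length and saturates at `min_flank_bp`.  Candidates below
#' `min_discovery_maf` score `-Inf` and are excluded.
#'
#' @param candidates Tibble with columns `gene`, `scaffold`, `pos`,
#'   `region`, `maf` (discovery minor-allele fraction), `flank` (clean
#'   bases up/downstream).
#' @param colocs [colocalize()] result (may be empty).
#' @param cfg A [selection_config()].
#' @return `candidates` with a `score` column added.
#' @export
score_snps <- function(candidates, colocs = NULL, cfg = selection_config()) {
  pr <- rev(cfg$region_priority)  # rank 1 = lowest priority
  rank <- match(region_class(candidates$region), pr)
  if (anyNA(rank)) {
    stop_arg("unknown region class: ",
             paste(unique(candidates$region[is.na(rank)]), collapse = ", "))
  }
  bonus_genes <- if (is.null(colocs) || nrow(colocs) == 0L) character(0) else
    unique(colocs$gene[colocs$within_preference])
  flank_term <- pmin(candidates$flank, cfg$min_flank_bp) / cfg$min_flank_bp
  score <- 10 * rank + cfg$qtl_bonus * (candidates$gene %in% bonus_genes) +
    flank_term
  score[candidates$maf < cfg$min_discovery_maf] <- -Inf
  mutate(candidates, score = score)
}

#' Select one assay-worthy SNP per gene
#'
#' Per gene the maximum-score candidate wins; ties are broken by larger
#' flank, then by smaller genomic coordinate.  Genes whose candidates are
#' all excluded are reported as unselectable.
#'
#' @inheritParams score_snps
#' @return Object of class `snp_panel`: list with `entries` (one row per
#'   selected gene, including a human-readable `rationale`) and
#'   `unselectable` (tibble `gene`, `reason`).
#' @export
select_panel <- function(candidates, colocs = NULL,
                         cfg = selection_config()) {
  if (nrow(candidates) == 0L) {
    return(structure(list(entries = mutate(candidates, score = double(0),
                                           rationale = character(0)),
                          unselectable = tibble(gene = character(),
                                                reason = character()),
                          config = cfg),
                     class = "snp_panel"))
  }
  scored <- score_snps(candidates, colocs, cfg)
  eligible <- filter(scored, is.finite(.data$score))
  entries <- eligible |>
    group_by(.data$gene) |>
    arrange(desc(.data$score), desc(.data$flank), .data$scaffold,
            .data$pos, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  coloc_note <- function(g) {
    if (is.null(colocs) || nrow(colocs) == 0L) return("no QTL link")
    cl <- colocs |>
      filter(.data$gene == g, .data$within_preference) |>
      arrange(.data$distance_bp)
    if (nrow(cl) == 0L) return("no QTL link")
    paste0("QTL ", cl$qtl_marker[1], " at ",
           round(cl$distance_bp[1] / 1000), " kbp")
  }
  entries <- entries |>
    rowwise() |>
    mutate(rationale = paste0("region=", .data$region, "; MAF=",
                              round(.data$maf, 3), "; flank=", .data$flank,
                              " bp; ", coloc_note(.data$gene))) |>
    ungroup() |>
    arrange(.data$gene)
  unselectable <- tibble(
    gene = setdiff(unique(candidates$gene), entries$gene),
    reason = "no candidate passed the discovery-MAF filter")
  structure(list(entries = entries, unselectable = unselectable,
                 config = cfg),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel>", nrow(x$entries), "genes selected;",
      nrow(x$unselectable), "unselectable\n")
  invisible(x)
}

#' @export
tidy.snp_panel <- function(x, ...) x$entries

#' @export
glance.snp_panel <- function(x, ...) {
  br <- panel_region_breakdown(x)
  tibble(n_selected = nrow(x$entries), n_unselectable = nrow(x$unselectable),
         utr_fraction = br$utr_fraction[1] %||% NA_real_,
         coding_fraction = br$coding_fraction[1] %||% NA_real_)
}

#' Region breakdown of a selected panel
#'
#' @param panel A [select_panel()] result (or a tibble with a `region`
#'   column).
#' @return Tibble with one row per region class (`region`, `n`,
#'   `fraction`) plus constant columns `utr_fraction` (5' + 3' UTR) and
#'   `coding_fraction` (synonymous + non-synonymous exon SNPs).
#' @export
panel_region_breakdown <- function(panel) {
  entries <- if (inherits(panel, "snp_panel")) panel$entries else panel
  if (nrow(entries) == 0L) {
    return(tibble(region = character(), n = integer(), fraction = double(),
                  utr_fraction = double(), coding_fraction = double()))
  }
  cls <- region_class(entries$region)
  tb <- count(tibble(region = cls), .data$region, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n))
  utr <- sum(tb$fraction[tb$region %in% c("5' UTR", "3' UTR")])
  coding <- sum(tb$fraction[tb$region %in% c("Exon syn", "Exon nonsyn")])
  mutate(tb, utr_fraction = utr, coding_fraction = coding)
}

#' @export
autoplot.snp_panel <- function(object, ...) {
  br <- panel_region_breakdown(object)
  ggplot2::ggplot(br, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "panel SNPs") +
    ggplot2::theme_minimal()
}
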