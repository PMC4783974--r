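#' Convert physical to genetic distance and back
#'
#' Uses a constant genome-wide rate (default 0.5 Mb per cM).
#'
#' @param mb,cm Distances in Mb / cM; must be non-negative.
#' @param mb_per_cm Rate in Mb per cM, > 0.
#' @return Numeric distance in the other unit.
#' @export
#' @examples
#' mb_to_cm(1.9)  # 3.8 cM
mb_to_cm <- function(mb, mb_per_cm = 0.5) {
  if (mb_per_cm <= 0) stop_arg("`mb_per_cm` must be > 0")
  if (any(mb < 0)) stop_arg("distances must be non-negative")
  mb / mb_per_cm
}

#' @rdname mb_to_cm
#' @export
cm_to_mb <- function(cm, mb_per_cm = 0.5) {
  if (mb_per_cm <= 0) stop_arg("`mb_per_cm` must be > 0")
  if (any(cm < 0)) stop_arg("distances must be non-negative")
  cm * mb_per_cm
}

#' Anchor a scaffold to a linkage group
#'
#' A scaffold inherits the LG of its anchor markers; markers from two or
#' more LGs are a conflict and leave the scaffold unanchored.
#'
#' @param scaffold Scaffold id.
#' @param anchors Anchor tibble (`marker`, `lg`, `cm`, `scaffold`, `bp`).
#' @return One-row tibble `scaffold`, `lg` (`NA` if unanchored),
#'   `reason` (`NA`, `"no anchors"` or `"conflict"`).
#' @export
anchor_scaffold <- function(scaffold, anchors) {
  lgs <- unique(anchors$lg[anchors$scaffold == scaffold])
  if (length(lgs) == 0L) {
    tibble(scaffold = scaffold, lg = NA_character_, reason = "no anchors")
  } else if (length(lgs) > 1L) {
    tibble(scaffold = scaffold, lg = NA_character_, reason = "conflict")
  } else {
    tibble(scaffold = scaffold, lg = lgs, reason = NA_character_)
  }
}

#' Infer a linkage group by comparative synteny
#'
#' For genes on scaffolds without anchor markers: each mapped ortholog in
#' a model species votes for the LG paired with its chromosome; a strict
#' majority wins and is flagged as inferred.  Ties or no data give no
#' assignment.
#'
#' @param ortholog_positions Tibble `gene`, `chrom` (model-species
#'   chromosome of each mapped ortholog).
#' @param chrom_to_lg Tibble `chrom`, `lg` pairing model chromosomes with
#'   linkage groups.
#' @return One-row tibble `lg` (`NA` if undecided), `inferred` (logical),
#'   `reason` (`NA`, `"no data"` or `"tie"`).
#' @export
infer_lg_synteny <- function(ortholog_positions, chrom_to_lg) {
  votes <- ortholog_positions |>
    inner_join(chrom_to_lg, by = "chrom") |>
    count(.data$lg, sort = TRUE)
  if (nrow(votes) == 0L) {
    return(tibble(lg = NA_character_, inferred = FALSE, reason = "no data"))
  }
  if (nrow(votes) > 1L && votes$n[1] == votes$n[2]) {
    return(tibble(lg = NA_character_, inferred = FALSE, reason = "tie"))
  }
  tibble(lg = votes$lg[1], inferred = TRUE, reason = NA_character_)
}

#' Co-localize placed genes with growth-QTL markers
#'
#' For every QTL whose markers resolve (via the anchor table) to the
#' scaffold of a placed gene, reports the physical gene-marker distance:
#' 0 when the marker lies inside the gene span, otherwise the gap from
#' the nearest span boundary.  QTLs without an associated marker
#' (`marker == "nd"`) are represented by their confidence-interval
#' reference markers with evidence `"closest-marker"`.  Genes on
#' unanchored scaffolds can be linked to QTLs on their synteny-inferred
#' LG (pass `inferred_lg`), with evidence `"synteny-inferred"` and no
#' physical distance.
#'
#' Distances below `max_pref` set `within_preference`; this is a ranking
#' preference, not a filter.
#'
#' @param placements Tibble of placed genes: `gene`, `scaffold`, `start`,
#'   `end`.
#' @param qtls QTL tibble (`trait`, `lg`, `marker`, `vpe`, `ci_markers`).
#' @param anchors Anchor tibble resolving markers to `scaffold`/`bp`.
#' @param max_pref Preference distance in bp (default 1 Mbp).
#' @param inferred_lg Optional tibble `scaffold`, `lg` of synteny-inferred
#'   assignments for unanchored scaffolds.
#' @return Tibble `gene`, `trait`, `qtl_marker`, `distance_bp`,
#'   `within_preference`, `evidence`.  Marker ids that cannot be resolved
#'   are reported in the `unresolved` attribute (and a warning), never an
#'   error.
#' @export
colocalize <- function(placements, qtls, anchors, max_pref = 1e6,
                       inferred_lg = NULL) {
  bad <- qtls$marker == "nd" &
    (is.na(qtls$ci_markers) | !nzchar(qtls$ci_markers))
  if (any(bad)) {
    stop_arg("QTL row with marker 'nd' must list CI reference markers")
  }
  qtl_markers <- qtls |>
    rowwise() |>
    reframe(trait = .data$trait, lg = .data$lg,
            qtl_marker = if (.data$marker != "nd") .data$marker else
              strsplit(.data$ci_markers, ",\\s*")[[1]],
            evidence = if (.data$marker != "nd") "direct-marker" else
              "closest-marker")
  resolved <- qtl_markers |>
    left_join(select(anchors, "marker", m_scaffold = "scaffold",
                     m_bp = "bp"),
              by = c(qtl_marker = "marker"))
  unresolved <- unique(resolved$qtl_marker[is.na(resolved$m_scaffold)])
  if (length(unresolved) > 0L) {
    warning("unresolvable QTL marker id(s): ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  resolved <- filter(resolved, !is.na(.data$m_scaffold))

  out <- list()
  for (i in seq_len(nrow(placements))) {
    g <- placements[i, ]
    same <- filter(resolved, .data$m_scaffold == g$scaffold)
    if (nrow(same) > 0L) {
      d <- ifelse(same$m_bp >= g$start & same$m_bp <= g$end, 0,
                  pmin(abs(same$m_bp - g$start), abs(same$m_bp - g$end)))
      out[[length(out) + 1L]] <- tibble(
        gene = g$gene, trait = same$trait, qtl_marker = same$qtl_marker,
        distance_bp = as.numeric(d),
        within_preference = d < max_pref,
        evidence = same$evidence)
    } else if (!is.null(inferred_lg)) {
      ilg <- inferred_lg$lg[match(g$scaffold, inferred_lg$scaffold)]
      if (!is.na(ilg) && length(ilg) == 1L) {
        hit <- filter(qtls, .data$lg == ilg)
        if (nrow(hit) > 0L) {
          out[[length(out) + 1L]] <- tibble(
            gene = g$gene, trait = hit$trait,
            qtl_marker = hit$marker, distance_bp = NA_real_,
            within_preference = FALSE, evidence = "synteny-inferred")
        }
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(gene = character(), trait = character(),
                  qtl_marker = character(), distance_bp = double(),
                  within_preference = logical(), evidence = character())
  }
  attr(res, "unresolved") <- unresolved
  res
}

#' Assemble a co-localization report
#'
#' One row per gene, shaped like a candidate-gene summary table: organ
#' flags, LG, closest QTL marker, distance in kbp and evidence tier.
#' Genes whose scaffold holds no QTL marker are reported with `"nd"`.
#'
#' @param placements Tibble `gene`, `scaffold`, `start`, `end`.
#' @param colocs [colocalize()] result.
#' @param anchors Anchor tibble.
#' @param genes Optional tibble `gene`, `organ`.
#' @param inferred_lg Optional tibble `scaffold`, `lg` (synteny); those
#'   LGs are marked with `*`.
#' @return Tibble `gene`, `organ`, `lg`, `qtl_marker`, `distance_kbp`,
#'   `evidence`.
#' @export
report_colocalization <- function(placements, colocs, anchors,
                                  genes = NULL, inferred_lg = NULL) {
  lg_of <- function(scf) {
    a <- anchor_scaffold(scf, anchors)
    if (!is.na(a$lg)) return(a$lg)
    if (!is.null(inferred_lg)) {
      ilg <- inferred_lg$lg[match(scf, inferred_lg$scaffold)]
      if (length(ilg) == 1L && !is.na(ilg)) return(paste0(ilg, " *"))
    }
    NA_character_
  }
  rows <- purrr::pmap(placements, function(gene, scaffold, start, end, ...) {
    cl <- colocs |>
      filter(.data$gene == !!gene) |>
      arrange(.data$distance_bp)
    if (nrow(cl) == 0L) {
      tibble(gene = gene, lg = lg_of(scaffold), qtl_marker = "nd",
             distance_kbp = NA_real_, evidence = NA_character_)
    } else {
      tibble(gene = gene, lg = lg_of(scaffold), qtl_marker = cl$qtl_marker[1],
             distance_kbp = round(cl$distance_bp[1] / 1000, 0),
             evidence = cl$evidence[1])
    }
  })
  out <- bind_rows(rows)
  if (!is.null(genes)) {
    out <- left_join(out, genes, by = "gene") |>
      relocate("organ", .after = "gene")
  }
  out
}
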