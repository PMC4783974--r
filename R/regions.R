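#' Derive region intervals (UTRs, CDS, introns) from gene features
#'
#' Introns are the gaps between consecutive exons of a transcript.  The
#' returned intervals partition each gene span: every in-gene position
#' belongs to exactly one region.
#'
#' @param features Feature tibble ([gen_genome()] / [read_gff3()]).
#' @return Tibble `gene_id`, `transcript_id`, `scaffold`, `strand`,
#'   `region` (one of `"5' UTR"`, `"3' UTR"`, `"CDS"`, `"Intron"`),
#'   `start`, `end` (1-based inclusive).
#' @export
gene_region_intervals <- function(features) {
  direct <- features |>
    filter(.data$type %in% c("five_prime_UTR", "three_prime_UTR", "CDS")) |>
    mutate(region = unname(c(five_prime_UTR = "5' UTR",
                             three_prime_UTR = "3' UTR",
                             CDS = "CDS")[.data$type])) |>
    select("gene_id", "transcript_id", "scaffold", "strand", "region",
           "start", "end")
  introns <- features |>
    filter(.data$type == "exon") |>
    group_by(.data$gene_id, .data$transcript_id, .data$scaffold,
             .data$strand) |>
    arrange(.data$start, .by_group = TRUE) |>
    reframe(int_start = head(.data$end, -1L) + 1L,
            int_end = .data$start[-1L] - 1L) |>
    rename(start = "int_start", end = "int_end") |>
    filter(.data$end >= .data$start) |>
    mutate(region = "Intron")
  bind_rows(direct, introns) |>
    arrange(.data$scaffold, .data$gene_id, .data$start)
}

# Region (interval level) at a single position within a transcript's
# intervals; NA_character_ if the position is not covered.
region_at <- function(intervals, scaffold, pos) {
  hit <- intervals$scaffold == scaffold & intervals$start <= pos &
    intervals$end >= pos
  if (!any(hit)) return(NA_character_)
  intervals$region[which(hit)[1L]]
}

# Canonical transcript per gene: the one with the longest total CDS
# (ties: first by id).
canonical_transcripts <- function(features) {
  features |>
    filter(.data$type == "CDS") |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(cds_len = sum(.data$end - .data$start + 1L),
              .groups = "drop") |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$cds_len), .data$transcript_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    pull(.data$transcript_id, name = .data$gene_id)
}

#' Classify the gene region and codon effect of a SNP
#'
#' Maps a genomic position inside a gene to one of five region classes.
#' For CDS positions the reference codon is read strand-aware from the
#' genome, the alternate allele is substituted (reverse-complemented on the
#' minus strand) and both codons are translated with the standard genetic
#' code: equal amino acids give `"Exon syn"`, different ones
#' `"Exon X-Y"` with the reference amino acid first.
#'
#' When the gene carries several transcripts the canonical one (longest
#' CDS) is used.
#'
#' @param scaffold,pos Genomic position (1-based).
#' @param ref,alt Reference and alternate alleles on the forward strand.
#' @param features Feature tibble for the gene models.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param gene_id Optionally restrict to a specific gene; by default the
#'   gene whose span contains the position is used.
#' @return One-row tibble: `gene_id`, `region`, `aa_ref`, `aa_alt`.
#'   `region` uses the vocabulary `"5' UTR"`, `"3' UTR"`, `"Exon syn"`,
#'   `"Exon X-Y"`, `"Intron"`; the amino-acid columns are `NA` except for
#'   non-synonymous calls.
#' @export
#' @examples
#' g <- gen_genome(sim_config(seed = 3, n_genes = 2))
#' iv <- gene_region_intervals(g$features)
#' p <- iv$start[iv$region == "Intron"][1]
#' s <- iv$scaffold[iv$region == "Intron"][1]
#' ref <- substr(g$scaffolds[[s]], p, p)
#' classify_snp_region(s, p, ref, setdiff(c("A", "C", "G", "T"), ref)[1],
#'                     g$features, g$scaffolds)
classify_snp_region <- function(scaffold, pos, ref, alt, features, scaffolds,
                                gene_id = NULL) {
  check_base(ref, "ref"); check_base(alt, "alt")
  if (ref == alt) stop_arg("`ref` and `alt` must differ")
  spans <- gene_spans(features)
  if (is.null(gene_id)) {
    hit <- spans$scaffold == scaffold & spans$start <= pos & spans$end >= pos
    if (!any(hit)) {
      stop_arg("position ", scaffold, ":", pos, " lies outside all gene spans")
    }
    gene_id <- spans$gene_id[which(hit)[1L]]
  }
  tx <- canonical_transcripts(features)[[gene_id]]
  gf <- filter(features, .data$transcript_id == tx)
  strand <- gf$strand[1L]
  iv <- gene_region_intervals(gf)
  region <- region_at(iv, scaffold, pos)
  if (is.na(region)) {
    stop_arg("position ", scaffold, ":", pos, " is outside gene ", gene_id)
  }
  if (region != "CDS") {
    return(tibble(gene_id = gene_id, region = region,
                  aa_ref = NA_character_, aa_alt = NA_character_))
  }

  cds <- filter(gf, .data$type == "CDS")
  cds <- cds[order(if (strand == "+") cds$start else -cds$start), ]
  seqs <- vapply(seq_len(nrow(cds)), function(i) {
    s <- substr(scaffolds[[scaffold]], cds$start[i], cds$end[i])
    if (strand == "-") revcomp(s) else s
  }, character(1))
  cds_seq <- paste(seqs, collapse = "")
  if (nchar(cds_seq) %% 3L != 0L) {
    abort(paste0("CDS of ", gene_id, " is not a multiple of 3"),
          class = "qtlsnp_model_error")
  }
  lens <- cds$end - cds$start + 1L
  before <- cumsum(c(0L, lens))[seq_len(nrow(cds))]
  ci <- which(cds$start <= pos & cds$end >= pos)
  offset <- before[ci] +
    if (strand == "+") pos - cds$start[ci] + 1L else cds$end[ci] - pos + 1L
  tx_ref <- if (strand == "+") ref else complement_base(ref)
  if (substr(cds_seq, offset, offset) != tx_ref) {
    abort(paste0("reference base mismatch at ", scaffold, ":", pos,
                 " in gene ", gene_id), class = "qtlsnp_model_error")
  }
  codon_i <- (offset - 1L) %/% 3L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  within <- offset - codon_i * 3L
  alt_codon <- codon
  substr(alt_codon, within, within) <-
    if (strand == "+") alt else complement_base(alt)
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  if (aa_ref == aa_alt) {
    tibble(gene_id = gene_id, region = "Exon syn",
           aa_ref = NA_character_, aa_alt = NA_character_)
  } else {
    tibble(gene_id = gene_id, region = paste0("Exon ", aa_ref, "-", aa_alt),
           aa_ref = aa_ref, aa_alt = aa_alt)
  }
}

#' Annotate variant calls with gene and region
#'
#' Joins calls against gene spans and classifies the region of every call
#' that falls inside a gene; calls outside all genes keep `NA`.
#'
#' @param calls Tibble of calls ([call_variants()]); needs `scaffold`,
#'   `pos`, `ref` and a `minor`/`alt` column.
#' @param features,scaffolds Gene models and genome.
#' @return `calls` with `gene_id` and `region` columns added.
#' @export
annotate_calls <- function(calls, features, scaffolds) {
  alt_col <- if ("minor" %in% names(calls)) "minor" else "alt"
  spans <- gene_spans(features)
  out <- calls
  out$gene_id <- NA_character_
  out$region <- NA_character_
  if (nrow(calls) == 0L || nrow(spans) == 0L) return(out)
  for (i in seq_len(nrow(calls))) {
    hit <- spans$scaffold == calls$scaffold[i] &
      spans$start <= calls$pos[i] & spans$end >= calls$pos[i]
    if (!any(hit)) next
    alt <- calls[[alt_col]][i]
    if (alt == calls$ref[i] && "major" %in% names(calls)) {
      alt <- calls$major[i]  # the reference allele is the minor one here
    }
    if (!alt %in% DNA_BASES || calls$ref[i] == alt) next
    rc <- classify_snp_region(calls$scaffold[i], calls$pos[i], calls$ref[i],
                              alt, features, scaffolds,
                              gene_id = spans$gene_id[which(hit)[1L]])
    out$gene_id[i] <- rc$gene_id
    out$region[i] <- rc$region
  }
  out
}
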