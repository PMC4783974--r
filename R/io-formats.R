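#' Read and write the pipeline's file formats
#'
#' All on-disk coordinates are 1-based inclusive.  The pileup dialect is a
#' TSV with columns `scaffold`, `pos`, `ref`, `bases`, `quals`, where
#' `bases` is a string over `A/C/G/T/*` (`*` marks an indel observation)
#' and `quals` the matching Phred+33 characters.
#'
#' @name qtlsnp-io
NULL

#' @rdname qtlsnp-io
#' @param scaffolds Named character vector of sequences.
#' @param path File path.
#' @export
write_fasta <- function(scaffolds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(scaffolds), path,
                              width = 70L)
  invisible(path)
}

#' @rdname qtlsnp-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname qtlsnp-io
#' @param features Feature tibble ([gen_genome()]).
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) == 0L) return(invisible(path))
  f <- features |>
    arrange(.data$scaffold,
            match(.data$gene_id, unique(.data$gene_id)),
            match(.data$type, c("gene", "mRNA", "exon", "CDS",
                                "five_prime_UTR", "three_prime_UTR")),
            .data$start)
  phase <- rep(".", nrow(f))
  for (tx in unique(f$transcript_id)) {
    idx <- which(f$transcript_id == tx & f$type == "CDS")
    if (length(idx) == 0L) next
    ord <- idx[order(if (f$strand[idx[1]] == "+") f$start[idx]
                     else -f$start[idx])]
    lens <- f$end[ord] - f$start[ord] + 1L
    phase[ord] <- as.character((3L - cumsum(c(0L, lens))[seq_along(ord)] %% 3L) %% 3L)
  }
  attr_col <- ifelse(
    f$type == "gene", paste0("ID=", f$gene_id),
    ifelse(f$type == "mRNA",
           paste0("ID=", f$transcript_id, ";Parent=", f$gene_id),
           paste0("Parent=", f$transcript_id)))
  writeLines(paste(f$scaffold, "qtlsnp", f$type, f$start, f$end, ".",
                   f$strand, phase, attr_col, sep = "\t"), con)
  invisible(path)
}

#' @rdname qtlsnp-io
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_features())
  m <- strsplit(lines, "\t", fixed = TRUE)
  tb <- tibble(
    scaffold = vapply(m, `[[`, character(1), 1L),
    type = vapply(m, `[[`, character(1), 3L),
    start = as.integer(vapply(m, `[[`, character(1), 4L)),
    end = as.integer(vapply(m, `[[`, character(1), 5L)),
    strand = vapply(m, `[[`, character(1), 7L),
    attrs = vapply(m, `[[`, character(1), 9L))
  id <- stringr::str_match(tb$attrs, "ID=([^;]+)")[, 2]
  parent <- stringr::str_match(tb$attrs, "Parent=([^;]+)")[, 2]
  tb$transcript_id <- ifelse(tb$type == "gene", paste0(id, ".t1"),
                             ifelse(tb$type == "mRNA", id, parent))
  tb$gene_id <- ifelse(tb$type == "gene", id,
                       ifelse(tb$type == "mRNA", parent,
                              sub("\\.t\\d+$", "", parent)))
  tb |>
    select("gene_id", "transcript_id", "type", "scaffold", "strand",
           "start", "end") |>
    arrange_features()
}

#' @rdname qtlsnp-io
#' @param pileup Pileup tibble ([sim_pileup()]).
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path, na = "")
  invisible(path)
}

#' @rdname qtlsnp-io
#' @export
read_pileup <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    scaffold = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), bases = readr::col_character(),
    quals = readr::col_character()), na = character(), progress = FALSE)
}

#' @rdname qtlsnp-io
#' @param anchors Map-anchor tibble: `marker`, `lg`, `cm`, `scaffold`, `bp`.
#' @export
write_anchors <- function(anchors, path) {
  readr::write_tsv(anchors, path)
  invisible(path)
}

#' @rdname qtlsnp-io
#' @export
read_anchors <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), lg = readr::col_character(),
    cm = readr::col_double(), scaffold = readr::col_character(),
    bp = readr::col_integer()), progress = FALSE)
}

#' @rdname qtlsnp-io
#' @param qtls QTL tibble: `trait`, `lg`, `marker` (`"nd"` when no
#'   associated marker), `vpe` (percent or `NA`), `ci_markers`
#'   (comma-separated reference markers).
#' @export
write_qtl <- function(qtls, path) {
  readr::write_tsv(qtls, path, na = "")
  invisible(path)
}

#' @rdname qtlsnp-io
#' @export
read_qtl <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trait = readr::col_character(), lg = readr::col_character(),
    marker = readr::col_character(), vpe = readr::col_double(),
    ci_markers = readr::col_character()), na = "", progress = FALSE)
}

#' @rdname qtlsnp-io
#' @param truth A `truth_set` ([sim_truth()]).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(variants = truth$variants,
                            pop_params = truth$pop_params),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname qtlsnp-io
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(variants = as_tibble(x$variants),
                 pop_params = as_tibble(x$pop_params)),
            class = "truth_set")
}

#' Write variant calls as a minimal VCF v4.2
#'
#' SNP rows carry `REF`/`ALT` bases and an `INFO` field with `DP` (filtered
#' depth), `AC` (minor-allele count) and `TSTV` (transition/transversion).
#' Non-SNP polymorphisms are written with the symbolic allele
#' `<NON_SNP>`.
#'
#' @param calls Call tibble ([call_variants()]).
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=qtlsnp",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Minor allele count\">",
    "##INFO=<ID=TSTV,Number=1,Type=String,Description=\"transition or transversion\">",
    "##ALT=<ID=NON_SNP,Description=\"Non-SNP polymorphism (indel allele)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) == 0L) return(invisible(path))
  alt <- ifelse(calls$variant_class == "SNP",
                ifelse(calls$minor == calls$ref, calls$major, calls$minor),
                "<NON_SNP>")
  info <- paste0("DP=", calls$depth, ";AC=", calls$minor_count,
                 ifelse(is.na(calls$ts_tv), "",
                        paste0(";TSTV=", calls$ts_tv)))
  writeLines(paste(calls$scaffold, calls$pos, ".", calls$ref, alt, ".",
                   "PASS", info, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble(scaffold = character(), pos = integer(), ref = character(),
                  alt = character(), depth = integer(),
                  minor_count = integer(), ts_tv = character()))
  }
  m <- strsplit(lines, "\t", fixed = TRUE)
  info <- vapply(m, `[[`, character(1), 8L)
  grab <- function(key) {
    v <- stringr::str_match(info, paste0(key, "=([^;]+)"))[, 2]
    v
  }
  tibble(
    scaffold = vapply(m, `[[`, character(1), 1L),
    pos = as.integer(vapply(m, `[[`, character(1), 2L)),
    ref = vapply(m, `[[`, character(1), 4L),
    alt = vapply(m, `[[`, character(1), 5L),
    depth = as.integer(grab("DP")),
    minor_count = as.integer(grab("AC")),
    ts_tv = grab("TSTV"))
}
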