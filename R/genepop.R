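#' Read and write GENEPOP genotype files
#'
#' Two-digit allele codes with the fixed nucleotide convention
#' `A = 01, C = 02, G = 03, T = 04` (so files round-trip to base-labelled
#' genotypes); `0000` marks a missing genotype.  Only the single-population
#' layout used for panel validation is supported: a title line, one locus
#' name per line, a `Pop` line, then `individual ,  g1 g2 ...` records.
#'
#' @param gt Long genotype tibble: `individual`, `locus`, `genotype`
#'   (`"X/Y"` with sorted alleles, `NA` missing).
#' @param path File path.
#' @param title Title line content.
#' @return `read_genepop()` returns the long genotype tibble;
#'   `write_genepop()` returns `path` invisibly.
#' @export
write_genepop <- function(gt, path, title = "qtlsnp panel genotypes") {
  loci <- unique(gt$locus)
  inds <- unique(gt$individual)
  code <- c(A = "01", C = "02", G = "03", T = "04")
  wide <- gt |>
    mutate(coded = ifelse(is.na(.data$genotype), "0000",
                          paste0(code[sub("/.*", "", .data$genotype)],
                                 code[sub(".*/", "", .data$genotype)]))) |>
    select("individual", "locus", "coded") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "coded",
                       values_fill = "0000")
  wide <- wide[match(inds, wide$individual), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci, "Pop"), con)
  writeLines(paste0(wide$individual, " ,  ",
                    apply(as.matrix(wide[, loci, drop = FALSE]), 1L,
                          paste, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_genepop
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  pop_at <- which(toupper(trimws(lines)) == "POP")[1]
  if (is.na(pop_at) || pop_at < 2L) {
    stop_arg("not a GENEPOP file (no Pop line): ", path)
  }
  loci <- trimws(lines[2:(pop_at - 1L)])
  # locus names may also be comma-separated on one line
  loci <- unlist(strsplit(loci, ",\\s*"))
  recs <- lines[(pop_at + 1L):length(lines)]
  recs <- recs[nzchar(trimws(recs))]
  base <- c(`01` = "A", `02` = "C", `03` = "G", `04` = "T")
  rows <- purrr::imap(recs, function(line, i) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop_arg("malformed GENEPOP record at line ", pop_at + i, ": ", line)
    }
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci)) {
      stop_arg("line ", pop_at + i, ": ", length(codes),
               " genotypes for ", length(loci), " loci")
    }
    a1 <- base[substr(codes, 1L, 2L)]
    a2 <- base[substr(codes, 3L, 4L)]
    g <- ifelse(codes == "0000", NA_character_,
                ifelse(a1 <= a2, paste0(a1, "/", a2), paste0(a2, "/", a1)))
    tibble(individual = trimws(parts[1]), locus = loci, genotype = unname(g))
  })
  bind_rows(rows)
}
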