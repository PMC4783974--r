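#' Simulate a scaffold genome with strand-aware gene models
#'
#' Generates random scaffolds named `Sm_<k>` and plants `n_genes` gene
#' models on them (round-robin over scaffolds, alternating use of both
#' strands).  Every gene has a 5' UTR, one or more CDS exons separated by
#' introns, and a 3' UTR; the CDS starts with ATG, ends with a stop codon,
#' has length divisible by 3 and contains no internal stop.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_genome`: a list with
#'   * `scaffolds`: named character vector of scaffold sequences,
#'   * `features`: tibble of gene features (`gene_id`, `transcript_id`,
#'     `type`, `scaffold`, `strand`, `start`, `end`), 1-based inclusive
#'     coordinates, types `gene`/`mRNA`/`exon`/`CDS`/`five_prime_UTR`/
#'     `three_prime_UTR`.
#' @export
#' @examples
#' g <- gen_genome(sim_config(seed = 1, n_genes = 2))
#' dplyr::count(g$features, type)
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  scaffold_names <- paste0("Sm_", seq_len(cfg$n_scaffolds))
  scaffolds <- setNames(
    vapply(scaffold_names, function(s) rand_dna(cfg$scaffold_length_bp),
           character(1)),
    scaffold_names)

  if (cfg$n_genes == 0L) {
    return(structure(list(scaffolds = scaffolds, features = empty_features()),
                     class = "sim_genome"))
  }

  gene_scaffold <- scaffold_names[(seq_len(cfg$n_genes) - 1L) %%
                                    cfg$n_scaffolds + 1L]
  feats <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    scf <- gene_scaffold[i]
    on_scf <- which(gene_scaffold == scf)
    slot <- match(i, on_scf)
    block <- cfg$scaffold_length_bp %/% length(on_scf)
    gene <- build_gene(cfg)
    margin <- 100L
    if (gene$length + 2L * margin > block) {
      stop_arg("scaffold ", scf, " too short to host ", length(on_scf),
               " genes: gene of ", gene$length, " bp does not fit a ",
               block, " bp slot")
    }
    gstart <- (slot - 1L) * block + margin +
      sample.int(block - gene$length - 2L * margin + 1L, 1L)
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("gene%02d", i)
    inserted <- if (strand == "+") gene$seq else revcomp(gene$seq)
    substr(scaffolds[[scf]], gstart, gstart + gene$length - 1L) <- inserted
    tf <- gene$features
    if (strand == "+") {
      tf$start2 <- gstart + tf$start - 1L
      tf$end2 <- gstart + tf$end - 1L
    } else {
      tf$start2 <- gstart + gene$length - tf$end
      tf$end2 <- gstart + gene$length - tf$start
    }
    feats[[i]] <- tibble(
      gene_id = gene_id,
      transcript_id = paste0(gene_id, ".t1"),
      type = tf$type,
      scaffold = scf,
      strand = strand,
      start = as.integer(tf$start2),
      end = as.integer(tf$end2))
  }
  features <- arrange_features(bind_rows(feats))
  structure(list(scaffolds = scaffolds, features = features),
            class = "sim_genome")
}

FEATURE_TYPES <- c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
                   "three_prime_UTR")

# Canonical deterministic ordering shared by the generator and the GFF3
# reader, so round trips compare identical.
arrange_features <- function(features) {
  arrange(features, .data$scaffold, .data$gene_id,
          match(.data$type, FEATURE_TYPES), .data$start)
}

empty_features <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         type = character(), scaffold = character(), strand = character(),
         start = integer(), end = integer())
}

# One gene in transcript orientation: returns the genic sequence plus a
# feature table in 1-based transcript coordinates.
build_gene <- function(cfg) {
  k <- if (cfg$exons_per_gene[1] == cfg$exons_per_gene[2]) {
    cfg$exons_per_gene[1]
  } else {
    sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
  }
  u5 <- cfg$utr_lengths_bp[1]
  u3 <- cfg$utr_lengths_bp[2]
  n_codons <- sample(50:110, 1L)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG",
                paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
  cds_len <- nchar(cds)
  # split the CDS over k exons, each part >= 3 bp
  cuts <- if (k > 1L) sort(sample(seq(3L, cds_len - 3L), k - 1L)) else integer()
  parts <- diff(c(0L, cuts, cds_len))
  while (any(parts < 3L)) {  # resample degenerate splits
    cuts <- sort(sample(seq(3L, cds_len - 3L), k - 1L))
    parts <- diff(c(0L, cuts, cds_len))
  }
  introns <- if (k > 1L) sample(80:300, k - 1L, replace = TRUE) else integer()

  pieces <- character(0)
  rows <- list()
  pos <- 0L
  add <- function(type, len) {
    rows[[length(rows) + 1L]] <<- list(type = type, start = pos + 1L,
                                       end = pos + len)
    pos <<- pos + len
  }
  cds_off <- 0L
  for (j in seq_len(k)) {
    exon_start <- pos + 1L
    if (j == 1L) {
      pieces <- c(pieces, rand_dna(u5))
      add("five_prime_UTR", u5)
    }
    pieces <- c(pieces, substr(cds, cds_off + 1L, cds_off + parts[j]))
    add("CDS", parts[j])
    cds_off <- cds_off + parts[j]
    if (j == k) {
      pieces <- c(pieces, rand_dna(u3))
      add("three_prime_UTR", u3)
    }
    rows[[length(rows) + 1L]] <- list(type = "exon", start = exon_start,
                                      end = pos)
    if (j < k) {
      pieces <- c(pieces, rand_dna(introns[j]))
      add("intron_skip", introns[j])  # dropped below; introns are implicit
    }
  }
  total <- pos
  tf <- bind_rows(lapply(rows, as_tibble)) |>
    filter(.data$type != "intron_skip")
  tf <- bind_rows(
    tibble(type = c("gene", "mRNA"), start = 1L, end = total),
    tf)
  list(seq = paste(pieces, collapse = ""), length = total, features = tf)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>", length(x$scaffolds), "scaffolds,",
      sum(x$features$type == "gene"), "genes\n")
  invisible(x)
}

#' Gene spans from a feature table
#'
#' @param features Feature tibble as produced by [gen_genome()] or
#'   [read_gff3()].
#' @return Tibble with one row per gene: `gene_id`, `scaffold`, `strand`,
#'   `start`, `end`.
#' @export
gene_spans <- function(features) {
  features |>
    filter(.data$type == "gene") |>
    select("gene_id", "scaffold", "strand", "start", "end")
}
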