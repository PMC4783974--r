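# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

tiny_cfg <- function(seed = 1L, n_genes = 4L, ...) {
  sim_config(seed = seed, n_scaffolds = 2L, scaffold_length_bp = 20000L,
             n_genes = n_genes, ...)
}

# A hand-built single-exon gene on a tiny scaffold, used for codon-effect
# oracles.  Layout (+ strand): 2 bp 5' UTR, CDS "ATG GTT TAA" at 3..11,
# 2 bp 3' UTR, then padding.
toy_gene_plus <- function() {
  scaffold <- paste0("AA", "ATGGTTTAA", "CC", rand_dna_fixed(20))
  features <- tibble::tibble(
    gene_id = "toy", transcript_id = "toy.t1",
    type = c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
             "three_prime_UTR"),
    scaffold = "S", strand = "+",
    start = c(1L, 1L, 1L, 1L, 3L, 12L),
    end = c(13L, 13L, 13L, 2L, 11L, 13L))
  list(scaffolds = c(S = scaffold), features = features)
}

# The same gene mirrored onto the reverse strand of a reverse-complemented
# scaffold: coordinate x maps to L - x + 1.
mirror_gene <- function(g) {
  scf <- names(g$scaffolds)[1]
  L <- nchar(g$scaffolds[[scf]])
  features <- g$features
  new_start <- L - features$end + 1L
  new_end <- L - features$start + 1L
  features$start <- new_start
  features$end <- new_end
  features$strand <- ifelse(features$strand == "+", "-", "+")
  seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(g$scaffolds[scf])))
  list(scaffolds = stats::setNames(seq, scf), features = features)
}

rand_dna_fixed <- function(n) {
  paste(rep(c("A", "C", "G", "T"), length.out = n), collapse = "")
}

# Long genotype tibble for one locus from explicit genotype counts.
gt_from_counts <- function(locus, nAA, nAa, naa, alleles = c("A", "G"),
                           n_missing = 0L) {
  g <- c(genotypes_from_counts(nAA, nAa, naa, alleles),
         rep(NA_character_, n_missing))
  tibble::tibble(individual = sprintf("i%03d", seq_along(g)),
                 locus = locus, genotype = g)
}

# Brute-force HW exact test by enumerating every genotype configuration
# (a, h, b) with a + h + b = n, conditioning on the observed allele count.
# Independent of the package's log-factorial path.
hw_exact_bruteforce <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  m <- min(2 * nAA + nAa, 2 * naa + nAa)  # minor allele count
  cfgs <- expand.grid(a = 0:n, h = 0:n)
  cfgs$b <- n - cfgs$a - cfgs$h
  cfgs <- cfgs[cfgs$b >= 0 & (2 * cfgs$b + cfgs$h) == m, ]
  w <- apply(cfgs, 1, function(r) {
    exp(lgamma(n + 1) - lgamma(r["a"] + 1) - lgamma(r["h"] + 1) -
          lgamma(r["b"] + 1)) * 2^r["h"]
  })
  pr <- w / sum(w)
  obs <- pr[cfgs$h == nAa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# The published per-locus statistics of the reference validation panel
# (43 genotyped growth-gene SNPs in a 34-fish wild turbot sample).
reference_panel_stats <- function() {
  readr::read_tsv(system.file("extdata", "panel_reference_stats.tsv",
                              package = "qtlsnp"),
                  col_types = "ccddd", na = "NA", progress = FALSE)
}
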