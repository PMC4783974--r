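#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator into one validated object.  The
#' defaults emulate the study design the package targets: a pooled discovery
#' sample observed as a single pileup with site-level alternate-allele
#' frequencies, and a validation population of 34 diploid individuals
#' genotyped at the selected panel loci.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   fixture files.
#' @param n_scaffolds Number of genome scaffolds (named `Sm_1`, `Sm_2`, ...).
#' @param scaffold_length_bp Length of each scaffold in bp.
#' @param n_genes Total number of genes distributed round-robin over the
#'   scaffolds.  May be 0 for a gene-free genome.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param utr_lengths_bp Pair `c(utr5, utr3)` of UTR lengths in bp.
#' @param snp_density Planted SNPs per kb of scaffold.
#' @param genic_fraction Fraction of planted variants placed inside gene
#'   spans (transcriptome-derived discovery concentrates variants in
#'   transcribed sequence).
#' @param transition_prob Probability that a planted alternate allele is
#'   the transition partner of the reference; the default emulates the
#'   transition excess typical of fish transcriptome SNP sets
#'   (ts/tv around 1.35).
#' @param pooled_allele_freq_range Range `c(lo, hi)` in (0, 1) from which the
#'   pooled alternate-allele frequency of each planted variant is drawn.
#' @param mean_depth Expected read depth per pileup site (Poisson mean).
#' @param qual_profile Named numeric vector of mixture weights over Phred
#'   quality values; names are the quality values.
#' @param pop_n Diploid individuals in the validation population.
#' @param pop_f Inbreeding coefficient used to draw validation genotypes;
#'   may be negative down to the feasibility bound (heterozygote excess).
#' @param missing_rate Fraction of validation genotypes set to missing.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 4)
#' cfg$pop_n
sim_config <- function(seed = 1L,
                       n_scaffolds = 4L,
                       scaffold_length_bp = 50000L,
                       n_genes = 12L,
                       exons_per_gene = c(2L, 4L),
                       utr_lengths_bp = c(150L, 250L),
                       snp_density = 1,
                       genic_fraction = 0.5,
                       transition_prob = 0.574,
                       pooled_allele_freq_range = c(0.1, 0.5),
                       mean_depth = 50,
                       qual_profile = c(`37` = 0.70, `30` = 0.20,
                                        `20` = 0.07, `12` = 0.03),
                       pop_n = 34L,
                       pop_f = 0,
                       missing_rate = 0.02) {
  if (!is_count(seed + 1)) stop_arg("`seed` must be a single integer")
  for (nm in c("n_scaffolds", "scaffold_length_bp", "pop_n")) {
    if (!is_count(get(nm))) stop_arg("`", nm, "` must be a positive count")
  }
  if (!(is.numeric(n_genes) && length(n_genes) == 1L && n_genes >= 0 &&
        n_genes == trunc(n_genes))) {
    stop_arg("`n_genes` must be a non-negative count")
  }
  if (length(exons_per_gene) != 2L || any(exons_per_gene < 1) ||
      exons_per_gene[1] > exons_per_gene[2]) {
    stop_arg("`exons_per_gene` must be an increasing pair of counts >= 1")
  }
  if (length(utr_lengths_bp) != 2L || any(utr_lengths_bp < 1)) {
    stop_arg("`utr_lengths_bp` must be a pair of positive lengths")
  }
  if (snp_density <= 0) stop_arg("`snp_density` must be > 0")
  if (genic_fraction < 0 || genic_fraction > 1) {
    stop_arg("`genic_fraction` must lie in [0, 1]")
  }
  if (transition_prob < 0 || transition_prob > 1) {
    stop_arg("`transition_prob` must lie in [0, 1]")
  }
  rng <- pooled_allele_freq_range
  if (length(rng) != 2L || any(rng <= 0) || any(rng >= 1) || rng[1] > rng[2]) {
    stop_arg("`pooled_allele_freq_range` must lie within (0, 1)")
  }
  if (mean_depth <= 0) stop_arg("`mean_depth` must be > 0")
  if (is.null(names(qual_profile)) ||
      any(is.na(suppressWarnings(as.integer(names(qual_profile))))) ||
      any(qual_profile < 0) || sum(qual_profile) <= 0) {
    stop_arg("`qual_profile` must be non-negative weights named by Phred values")
  }
  if (pop_f < -1 || pop_f > 1) stop_arg("`pop_f` must lie in [-1, 1]")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_arg("`missing_rate` must lie in [0, 1)")
  }
  structure(
    list(seed = as.integer(seed),
         n_scaffolds = as.integer(n_scaffolds),
         scaffold_length_bp = as.integer(scaffold_length_bp),
         n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         utr_lengths_bp = as.integer(utr_lengths_bp),
         snp_density = snp_density,
         genic_fraction = genic_fraction,
         transition_prob = transition_prob,
         pooled_allele_freq_range = rng,
         mean_depth = mean_depth,
         qual_profile = qual_profile / sum(qual_profile),
         pop_n = as.integer(pop_n),
         pop_f = pop_f,
         missing_rate = missing_rate),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_scaffolds, "scaffolds x",
      x$scaffold_length_bp, "bp |", x$n_genes, "genes |",
      "depth", x$mean_depth, "| pop n =", x$pop_n, "f =", x$pop_f, "\n")
  invisible(x)
}
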