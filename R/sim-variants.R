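#' Plant ground-truth variants on a simulated genome
#'
#' Plants biallelic SNPs at `snp_density` sites per kb of scaffold, each
#' with a pooled alternate-allele frequency drawn from the configured
#' range.  Variants falling inside genes are labelled with the containing
#' gene and its interval-level region (UTR/CDS/intron); those loci also
#' receive population parameters `(p, f)` used later to draw validation
#' genotypes.
#'
#' @param genome A [gen_genome()] result.
#' @param cfg The [sim_config()] used to build it.
#' @return An object of class `truth_set`: list with `variants` (tibble
#'   `scaffold`, `pos`, `ref`, `alt`, `alt_freq`, `gene_id`, `region`) and
#'   `pop_params` (tibble `locus`, `scaffold`, `pos`, `ref`, `alt`, `p`,
#'   `f` for the in-gene loci).
#' @export
sim_truth <- function(genome, cfg) {
  stopifnot(inherits(genome, "sim_genome"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  rng <- cfg$pooled_allele_freq_range
  spans_all <- gene_spans(genome$features)
  vars <- purrr::map(names(genome$scaffolds), function(scf) {
    len <- nchar(genome$scaffolds[[scf]])
    n <- round(cfg$snp_density * len / 1000)
    if (n == 0L) return(NULL)
    sp <- filter(spans_all, .data$scaffold == scf)
    genic_pos <- if (nrow(sp)) {
      unlist(purrr::map2(sp$start, sp$end, seq.int))
    } else integer(0)
    n_genic <- min(round(cfg$genic_fraction * n), length(genic_pos))
    pos_g <- if (n_genic > 0L) sample(genic_pos, n_genic) else integer(0)
    other <- setdiff(seq_len(len), genic_pos)
    pos_o <- sample(other, min(n - n_genic, length(other)))
    pos <- sort(unique(c(pos_g, pos_o)))
    seq <- genome$scaffolds[[scf]]
    ref <- vapply(pos, function(p) substr(seq, p, p), character(1))
    tibble(scaffold = scf, pos = pos, ref = ref,
           alt = mutate_base(ref, cfg$transition_prob),
           alt_freq = runif(length(pos), rng[1], rng[2]))
  }) |> bind_rows()

  vars$gene_id <- NA_character_
  vars$region <- NA_character_
  if (nrow(vars) > 0L && cfg$n_genes > 0L) {
    iv <- gene_region_intervals(genome$features)
    spans <- gene_spans(genome$features)
    for (i in seq_len(nrow(vars))) {
      hit <- spans$scaffold == vars$scaffold[i] &
        spans$start <= vars$pos[i] & spans$end >= vars$pos[i]
      if (!any(hit)) next
      vars$gene_id[i] <- spans$gene_id[which(hit)[1L]]
      vars$region[i] <- region_at(
        filter(iv, .data$gene_id == vars$gene_id[i]),
        vars$scaffold[i], vars$pos[i])
    }
  }
  genic <- filter(vars, !is.na(.data$gene_id))
  pop_params <- tibble(
    locus = paste0(genic$scaffold, "_", genic$pos),
    scaffold = genic$scaffold, pos = genic$pos,
    ref = genic$ref, alt = genic$alt,
    p = genic$alt_freq, f = cfg$pop_f)
  structure(list(variants = vars, pop_params = pop_params),
            class = "truth_set")
}

#' Simulate a pooled-sample pileup
#'
#' Emits one pileup site per planted variant plus `background_sites`
#' variant-free positions per scaffold.  Depth is Poisson with mean
#' `cfg$mean_depth`; each read base is the alternate allele with
#' probability equal to the site's pooled alternate frequency (0 at
#' background sites) and the reference otherwise, then flipped to a random
#' other base with the per-base error implied by its Phred quality,
#' `10^(-Q/10)`.  Qualities are drawn from `cfg$qual_profile`.
#'
#' @param genome,truth,cfg Simulated genome, [sim_truth()] result and
#'   configuration.
#' @param background_sites Variant-free sites per scaffold.
#' @param error_model `"phred"` applies the quality-derived error;
#'   `"none"` disables sequencing error entirely (qualities still drawn),
#'   giving noise-free pileups for calibration.
#' @return Tibble `scaffold`, `pos`, `ref`, `bases`, `quals` (Phred+33);
#'   zero-depth sites carry empty strings.
#' @export
sim_pileup <- function(genome, truth, cfg, background_sites = 50L,
                       error_model = c("phred", "none")) {
  stopifnot(inherits(genome, "sim_genome"), inherits(truth, "truth_set"))
  error_model <- match.arg(error_model)
  set.seed(cfg$seed + 2L)
  vars <- truth$variants
  bad <- vars[!vapply(seq_len(nrow(vars)), function(i) {
    substr(genome$scaffolds[[vars$scaffold[i]]], vars$pos[i], vars$pos[i]) ==
      vars$ref[i]
  }, logical(1)), ]
  if (nrow(bad) > 0L) {
    stop_arg("truth positions disagree with the genome (e.g. ",
             bad$scaffold[1], ":", bad$pos[1], ")")
  }

  sites <- bind_rows(
    vars |> select("scaffold", "pos", "ref", "alt", "alt_freq"),
    purrr::map(names(genome$scaffolds), function(scf) {
      len <- nchar(genome$scaffolds[[scf]])
      pos <- setdiff(sample.int(len, min(len, background_sites + 50L)),
                     vars$pos[vars$scaffold == scf])
      pos <- sort(head(pos, background_sites))
      tibble(scaffold = scf, pos = pos,
             ref = vapply(pos, function(p) {
               substr(genome$scaffolds[[scf]], p, p)
             }, character(1)),
             alt = NA_character_, alt_freq = 0)
    }) |> bind_rows())
  sites <- arrange(sites, .data$scaffold, .data$pos)

  qvals <- as.integer(names(cfg$qual_profile))
  out <- purrr::pmap(sites, function(scaffold, pos, ref, alt, alt_freq) {
    d <- rpois(1L, cfg$mean_depth)
    if (d == 0L) {
      return(tibble(scaffold = scaffold, pos = pos, ref = ref,
                    bases = "", quals = ""))
    }
    base <- ifelse(runif(d) < alt_freq, alt, ref)
    q <- qvals[sample.int(length(qvals), d, replace = TRUE,
                          prob = cfg$qual_profile)]
    if (error_model == "phred") {
      err <- runif(d) < 10^(-q / 10)
      if (any(err)) base[err] <- other_base(base[err])
    }
    tibble(scaffold = scaffold, pos = pos, ref = ref,
           bases = paste(base, collapse = ""),
           quals = intToUtf8(q + 33L))
  }) |> bind_rows()
  out
}

#' Draw diploid genotypes under Wright's inbreeding equilibrium
#'
#' Genotype probabilities are `P(AA) = p^2 + f p q`,
#' `P(Aa) = 2 p q (1 - f)` and `P(aa) = q^2 + f p q` with `q = 1 - p`.
#' `f` may be negative down to the feasibility bound
#' `f >= max(-p/q, -q/p)` (all probabilities non-negative), which models
#' heterozygote excess.
#'
#' @param p Frequency of allele `alleles[1]`, in `[0, 1]`.
#' @param f Inbreeding coefficient.
#' @param n Number of diploid individuals.
#' @param missing_rate Fraction of genotypes replaced by `NA`.
#' @param seed Optional integer seed applied before drawing.
#' @param alleles Two allele labels.
#' @return Character vector of length `n` with entries like `"A/G"`
#'   (alleles sorted within a genotype) and `NA` for missing.
#' @export
#' @examples
#' table(sim_genotypes(0.5, 0, 20, seed = 1))
sim_genotypes <- function(p, f, n, missing_rate = 0, seed = NULL,
                          alleles = c("A", "G")) {
  if (p < 0 || p > 1) stop_arg("`p` must lie in [0, 1]")
  if (!is_count(n)) stop_arg("`n` must be a positive count")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_arg("`missing_rate` must lie in [0, 1)")
  }
  q <- 1 - p
  probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  if (any(probs < -1e-12)) {
    stop_arg("invalid (p, f): genotype probabilities would be negative; ",
             "need f >= ", signif(max(-p / q, -q / p), 3))
  }
  probs <- pmax(probs, 0)
  if (!is.null(seed)) set.seed(seed)
  a <- alleles
  gts <- c(paste0(a[1], "/", a[1]),
           paste(sort(a), collapse = "/"),
           paste0(a[2], "/", a[2]))
  g <- sample(gts, n, replace = TRUE, prob = probs)
  if (missing_rate > 0) g[runif(n) < missing_rate] <- NA_character_
  g
}

#' Simulate a validation genotype matrix for a set of loci
#'
#' @param pop_params Tibble with `locus`, `ref`, `alt`, `p`, `f` (for
#'   example `truth$pop_params`); `p` is the alternate-allele frequency.
#' @param n Diploid individuals.
#' @param missing_rate Fraction of missing genotypes.
#' @param seed Integer seed.
#' @return Long genotype tibble: `individual`, `locus`, `genotype`
#'   (`"X/Y"`, alleles sorted; `NA` missing).
#' @export
sim_genotype_matrix <- function(pop_params, n = 34L, missing_rate = 0.02,
                                seed = 1L) {
  set.seed(seed)
  inds <- sprintf("ind%03d", seq_len(n))
  purrr::pmap(pop_params, function(locus, ref, alt, p, f, ...) {
    tibble(individual = inds, locus = locus,
           genotype = sim_genotypes(p, f, n, missing_rate,
                                    alleles = c(alt, ref)))
  }) |> bind_rows()
}
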