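#' Simulate genetic-map anchors and growth-QTL marker tables
#'
#' A configurable fraction of scaffolds is anchored to linkage groups
#' (one LG per scaffold), each with a few anchor markers whose cM
#' positions follow the physical positions at the configured Mb-per-cM
#' rate.  A subset of markers becomes trait-associated QTL markers
#' (traits BW/L/K); some QTL rows carry no associated marker (`"nd"`) and
#' list confidence-interval reference markers instead.
#'
#' @param genome A [gen_genome()] result.
#' @param cfg The matching [sim_config()].
#' @param anchored_fraction Fraction of scaffolds anchored to an LG.
#' @param markers_per_scaffold Anchor markers per anchored scaffold.
#' @param n_qtl Number of QTL records.
#' @param mb_per_cm Physical-to-genetic rate used for cM positions.
#' @return List with tibbles `anchors` (`marker`, `lg`, `cm`, `scaffold`,
#'   `bp`) and `qtls` (`trait`, `lg`, `marker`, `vpe`, `ci_markers`).
#' @export
sim_map <- function(genome, cfg, anchored_fraction = 0.8,
                    markers_per_scaffold = 3L, n_qtl = 4L,
                    mb_per_cm = 0.5) {
  set.seed(cfg$seed + 3L)
  scfs <- names(genome$scaffolds)
  n_anchored <- max(1L, round(anchored_fraction * length(scfs)))
  anchored <- scfs[seq_len(n_anchored)]
  anchors <- purrr::imap(anchored, function(scf, i) {
    len <- nchar(genome$scaffolds[[scf]])
    bp <- sort(sample.int(len, markers_per_scaffold))
    tibble(marker = sprintf("Sma-SYN%d%02d", i, seq_along(bp)),
           lg = paste0("LG", i),
           cm = round(bp / 1e6 / mb_per_cm, 3),
           scaffold = scf, bp = bp)
  }) |> bind_rows()

  traits <- sample(c("BW", "L", "K"), n_qtl, replace = TRUE)
  with_marker <- seq_len(n_qtl) <= max(1L, n_qtl - 1L)
  qtl_markers <- sample(anchors$marker, n_qtl)
  qtls <- tibble(
    trait = traits,
    lg = anchors$lg[match(qtl_markers, anchors$marker)],
    marker = ifelse(with_marker, qtl_markers, "nd"),
    vpe = ifelse(with_marker, round(runif(n_qtl, 4, 25), 0), NA_real_),
    ci_markers = ifelse(with_marker, NA_character_, qtl_markers))
  list(anchors = anchors, qtls = qtls)
}

#' Emit a cross-consistent fixture bundle
#'
#' Runs the whole simulator for one configuration and writes every input
#' file the pipeline consumes: genome FASTA, gene-model GFF3, pileup TSV,
#' map-anchor TSV, QTL TSV, candidate-gene list TSV, GENEPOP validation
#' genotypes and the ground-truth JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Writable output directory (created if needed).
#' @param error_model Passed to [sim_pileup()].
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `truth`, `pileup`, `map`, `genotypes`, `genes`) and a `paths` list of
#'   the files written.
#' @export
#' @examples
#' \donttest{
#' fx <- emit_fixtures(sim_config(seed = 1, n_genes = 4), tempfile())
#' names(fx$paths)
#' }
emit_fixtures <- function(cfg, dir, error_model = "phred") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_arg("cannot create fixture directory: ", dir)
  genome <- gen_genome(cfg)
  truth <- sim_truth(genome, cfg)
  pileup <- sim_pileup(genome, truth, cfg, error_model = error_model)
  map <- sim_map(genome, cfg)
  genotypes <- sim_genotype_matrix(truth$pop_params, n = cfg$pop_n,
                                   missing_rate = cfg$missing_rate,
                                   seed = cfg$seed + 4L)
  set.seed(cfg$seed + 5L)
  spans <- gene_spans(genome$features)
  genes <- tibble(gene = spans$gene_id,
                  organ = sample(c("M", "L", "M&L"), nrow(spans),
                                 replace = TRUE, prob = c(0.3, 0.2, 0.5)))
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    pileup = file.path(dir, "pileup.tsv"),
    anchors = file.path(dir, "anchors.tsv"),
    qtl = file.path(dir, "qtl.tsv"),
    genes = file.path(dir, "genes.tsv"),
    genepop = file.path(dir, "genotypes.gen"),
    truth = file.path(dir, "truth.json"))
  tryCatch({
    write_fasta(genome$scaffolds, paths$genome)
    write_gff3(genome$features, paths$gff3)
    write_pileup(pileup, paths$pileup)
    write_anchors(map$anchors, paths$anchors)
    write_qtl(map$qtls, paths$qtl)
    readr::write_tsv(genes, paths$genes)
    if (nrow(genotypes) > 0L) write_genepop(genotypes, paths$genepop)
    write_truth(truth, paths$truth)
  }, error = function(e) {
    stop_arg("failed writing fixtures under ", dir, ": ",
             conditionMessage(e))
  })
  invisible(list(genome = genome, truth = truth, pileup = pileup, map = map,
                 genotypes = genotypes, genes = genes, paths = paths))
}
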