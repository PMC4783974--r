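#' Derive candidate panel SNPs from annotated calls
#'
#' Keeps biallelic SNP calls that fall inside genes, computes the
#' discovery minor-allele fraction from the filtered tallies and the
#' clean flank: bases to the nearest other called variant on the same
#' scaffold (capped by the scaffold ends).
#'
#' @param annotated Calls annotated by [annotate_calls()].
#' @param scaffolds Named character vector of scaffold sequences.
#' @return Candidate tibble for [select_panel()]: `gene`, `scaffold`,
#'   `pos`, `ref`, `major`, `minor`, `region`, `maf`, `flank`.
#' @export
candidate_snps <- function(annotated, scaffolds) {
  ann <- annotated |>
    group_by(.data$scaffold) |>
    arrange(.data$pos, .by_group = TRUE) |>
    mutate(gap_prev = .data$pos - lag(.data$pos),
           gap_next = lead(.data$pos) - .data$pos) |>
    ungroup() |>
    mutate(
      len = nchar(scaffolds)[match(.data$scaffold, names(scaffolds))],
      flank = pmin(coalesce(.data$gap_prev - 1L, .data$pos - 1L),
                   coalesce(.data$gap_next - 1L, .data$len - .data$pos),
                   .data$pos - 1L, .data$len - .data$pos))
  ann |>
    filter(.data$variant_class == "SNP", !.data$multiallelic,
           !is.na(.data$gene_id), !is.na(.data$region)) |>
    transmute(gene = .data$gene_id, scaffold = .data$scaffold,
              pos = .data$pos, ref = .data$ref, major = .data$major,
              minor = .data$minor, region = .data$region,
              maf = .data$minor_count / .data$depth,
              flank = as.integer(.data$flank))
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()] to generate inputs, or `NULL` to read the
#'   files named in `inputs`.
#' @param inputs Named list of input paths (`genome`, `gff3`, `pileup`,
#'   `anchors`, `qtl`, `genes`, `genepop`); filled automatically when
#'   simulating.
#' @param out_dir Output directory.
#' @param min_base_qual,min_depth,min_mac Caller thresholds.
#' @param max_pref Co-localization preference distance (bp).
#' @param selection A [selection_config()].
#' @param alpha,ld_permutations,seed Validation-statistics settings; the
#'   seed drives every stochastic stage.
#' @param error_model Passed to the simulator.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = list(),
                            out_dir = tempfile("qtlsnp_run_"),
                            min_base_qual = 20L, min_depth = 10L,
                            min_mac = 3L, max_pref = 1e6,
                            selection = selection_config(),
                            alpha = 0.05, ld_permutations = 200L,
                            seed = 1L, error_model = "phred") {
  structure(list(sim = sim, inputs = inputs, out_dir = out_dir,
                 min_base_qual = min_base_qual, min_depth = min_depth,
                 min_mac = min_mac, max_pref = max_pref,
                 selection = selection, alpha = alpha,
                 ld_permutations = as.integer(ld_permutations),
                 seed = as.integer(seed), error_model = error_model),
            class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message("[qtlsnp] ", stage, ": ", ...)
}

#' Run the full SNP-mining pipeline
#'
#' Executes simulate (optional), call, annotate, co-localize, select and
#' validate, writing a VCF of calls, the substitution-spectrum TSV, the
#' panel TSV, a co-localization report, the per-locus validation report,
#' the LD report and a machine-readable JSON summary into
#' `cfg$out_dir`.  Every stage logs its input and output record counts to
#' stderr.  A failing stage aborts with the stage named.
#'
#' @param cfg A [pipeline_config()].
#' @return List of class `pipeline_result` with the in-memory stage
#'   outputs (`calls`, `spectrum`, `annotated`, `colocs`, `panel`,
#'   `popgen`, `ld`), the `summary` list and `paths` of files written.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "qtlsnp_stage_error")
    })
  }

  if (!is.null(cfg$sim)) {
    fx <- stage("simulate",
                emit_fixtures(cfg$sim, file.path(cfg$out_dir, "fixtures"),
                              error_model = cfg$error_model))
    cfg$inputs <- fx$paths
    log_stage("simulate", nrow(fx$truth$variants), " planted variants, ",
              nrow(fx$pileup), " pileup sites")
  }
  ins <- cfg$inputs
  for (nm in c("genome", "gff3", "pileup", "anchors", "qtl", "genepop")) {
    if (is.null(ins[[nm]]) || !file.exists(ins[[nm]])) {
      abort(paste0("pipeline stage 'load' failed: missing input file '",
                   nm, "': ", ins[[nm]] %||% "<unset>"),
            class = "qtlsnp_stage_error")
    }
  }
  scaffolds <- stage("load", read_fasta(ins$genome))
  features <- stage("load", read_gff3(ins$gff3))
  pileup <- stage("load", read_pileup(ins$pileup))
  anchors <- stage("load", read_anchors(ins$anchors))
  qtls <- stage("load", read_qtl(ins$qtl))
  gt <- stage("load", read_genepop(ins$genepop))
  genes <- if (!is.null(ins$genes) && file.exists(ins$genes)) {
    readr::read_tsv(ins$genes, col_types = "cc", progress = FALSE)
  } else NULL
  log_stage("load", nrow(pileup), " pileup sites, ",
            sum(features$type == "gene"), " genes, ",
            nrow(anchors), " anchors, ", nrow(qtls), " QTLs")

  calls <- stage("call", call_variants(pileup, cfg$min_base_qual,
                                       cfg$min_depth, cfg$min_mac))
  spec <- spectrum(calls)
  log_stage("call", nrow(calls), " calls (", spec$n_snps, " SNPs)")

  annotated <- stage("annotate", annotate_calls(calls, features, scaffolds))
  log_stage("annotate", sum(!is.na(annotated$gene_id)), " in-gene calls")

  placements <- gene_spans(features) |>
    transmute(gene = .data$gene_id, scaffold = .data$scaffold,
              start = .data$start, end = .data$end)
  colocs <- stage("colocalize",
                  colocalize(placements, qtls, anchors,
                             max_pref = cfg$max_pref))
  log_stage("colocalize", nrow(colocs), " gene-QTL links")

  candidates <- stage("select", candidate_snps(annotated, scaffolds))
  panel <- stage("select", select_panel(candidates, colocs, cfg$selection))
  log_stage("select", nrow(panel$entries), " panel SNPs from ",
            nrow(candidates), " candidates")

  pg <- stage("popgen", popgen_summary(gt))
  ld <- if (pg$n_ld_pairs >= 1) {
    stage("popgen", ld_scan(gt, m = cfg$ld_permutations,
                            seed = cfg$seed, alpha = cfg$alpha))
  } else NULL
  log_stage("popgen", pg$means$n_polymorphic, " polymorphic loci, ",
            pg$n_ld_pairs, " LD pairs")

  paths <- list(
    vcf = file.path(cfg$out_dir, "calls.vcf"),
    spectrum = file.path(cfg$out_dir, "spectrum.tsv"),
    panel = file.path(cfg$out_dir, "panel.tsv"),
    coloc = file.path(cfg$out_dir, "colocalization.tsv"),
    locus_stats = file.path(cfg$out_dir, "locus_stats.tsv"),
    ld = file.path(cfg$out_dir, "ld.tsv"),
    summary = file.path(cfg$out_dir, "summary.json"))
  stage("report", {
    write_vcf(calls, paths$vcf)
    readr::write_tsv(tidy(spec), paths$spectrum)
    readr::write_tsv(panel$entries, paths$panel)
    readr::write_tsv(report_colocalization(placements, colocs, anchors,
                                           genes = genes), paths$coloc)
    readr::write_tsv(report_locus_stats(pg), paths$locus_stats)
    if (!is.null(ld)) readr::write_tsv(ld, paths$ld)
  })

  summary <- list(
    n_calls = nrow(calls), n_snps = spec$n_snps,
    n_non_snp = spec$n_other,
    snp_fraction = spec$snp_fraction, ts_tv_ratio = spec$ts_tv_ratio,
    n_in_gene = sum(!is.na(annotated$gene_id)),
    n_panel = nrow(panel$entries),
    n_polymorphic = pg$means$n_polymorphic,
    mean_he = pg$means$mean_he, mean_maf = pg$means$mean_maf,
    mean_fis = pg$means$mean_fis, n_ld_pairs = pg$n_ld_pairs,
    seed = cfg$seed)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, na = "null")
  log_stage("report", "outputs written to ", cfg$out_dir)

  structure(list(calls = calls, spectrum = spec, annotated = annotated,
                 colocs = colocs, panel = panel, popgen = pg, ld = ld,
                 summary = summary, paths = paths, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>", s$n_calls, "calls |", s$n_snps, "SNPs |",
      s$n_panel, "panel SNPs |", s$n_polymorphic, "polymorphic loci\n")
  invisible(x)
}
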