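#' Pipeline run configuration
#'
#' Single place for every knob of the end-to-end run: one seed drives all
#' randomness, population sizes default to the study design (550 RILs, 2145
#' F2, 384-cultivar panel), coverage defaults to 20x parents / 3x RILs.
#'
#' @param seed master seed for the run.
#' @param n_founders founder count (11).
#' @param n_sites simulated variant sites (1000).
#' @param n_rils RIL count (550).
#' @param n_f2 F2 count (2145).
#' @param n_panel cultivar-panel size (384).
#' @param n_panel_mutant cultivars planted with the mutant allele (12).
#' @param lambda_parent,lambda_ril,lambda_f2 mean depths per class.
#' @param error per-read allele error rate.
#' @param filter_mode "permissive" or "strict".
#' @param tolerant_exclusion apply the tolerant-RIL exclusion rule (rule d).
#'   Default NULL: on for strict (full-coverage) runs, off for permissive
#'   (low-coverage) runs, where a hom-alt call at shallow depth is
#'   indistinguishable from a miscalled het carrier.
#' @param out_dir optional output directory for VCF/TSV artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_founders = 11L, n_sites = 1000L,
                       n_rils = 550L, n_f2 = 2145L, n_panel = 384L,
                       n_panel_mutant = 12L, lambda_parent = 20,
                       lambda_ril = 3, lambda_f2 = 20, error = 0.001,
                       filter_mode = "permissive", tolerant_exclusion = NULL,
                       out_dir = NULL) {
  if (n_rils < 1L) stop("n_rils must be >= 1")
  if (n_f2 < 1L) stop("n_f2 must be >= 1")
  if (n_founders < 2L) stop("need at least 2 founders")
  if (n_panel_mutant > n_panel) stop("more mutant cultivars than panel size")
  structure(as.list(environment()), class = "run_config")
}

.stage_log <- function(stage, fmt, ...)
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))

#' Run the full mapping-by-sequencing pipeline on synthetic data
#'
#' Simulates founders and the MAGIC RIL population, observes genotypes at
#' the configured coverages, applies the phenotype-concordance filter,
#' annotates the causal variant against a synthetic 5-exon gene model
#' spanning the causal position, simulates the biparental F2, tests its
#' tolerant:sensitive segregation against 3:1, and computes
#' marker-phenotype concordance at the causal site. Identical seeds give
#' identical reports.
#'
#' @param config a `run_config`.
#' @return a `pipeline_report` list: `config`, `candidates`, `causal_found`,
#'   `effect`, `segregation`, `concordance`, `n_sensitive_rils`,
#'   `ril_heterozygosity`; plus file paths when `out_dir` is set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 1L, 8L)

  .stage_log("simulate", "founders: %d founders x %d sites",
             config$n_founders, config$n_sites)
  panel <- simulate_founders(config$n_founders, config$n_sites,
                             seed = seeds[1])
  sensitive_parent <- panel$founder_names[panel$causal_founder]

  .stage_log("simulate", "MAGIC: %d RILs (5 cycles, 6 selfing generations)",
             config$n_rils)
  rils <- run_magic(panel, breeding_design(n_out = config$n_rils),
                    seed = seeds[2])
  ril_ids <- sprintf("RIL%04d", seq_along(rils))
  phen <- assign_phenotypes(rils, panel, ids = ril_ids)
  n_sens <- sum(phen$phenotype == "sensitive")
  .stage_log("simulate", "%d of %d RILs sensitive", n_sens, length(rils))

  .stage_log("observe", "parents at %gx, RILs at %gx, error %g",
             config$lambda_parent, config$lambda_ril, config$error)
  founder_pop <- lapply(seq_len(config$n_founders),
                        function(i) founder_individual(panel$map, i))
  cm <- coverage_model(c(parent = config$lambda_parent,
                         RIL = config$lambda_ril,
                         F2 = config$lambda_f2), config$error)
  gm_par <- observe_genotypes(founder_pop, panel, cm, classes = "parent",
                              ids = panel$founder_names, seed = seeds[3])
  gm_ril <- observe_genotypes(rils, panel, cm, classes = "RIL",
                              ids = ril_ids, seed = seeds[4])
  gm <- cbind_genotypes(gm_par, gm_ril)

  .stage_log("filter", "concordance filter, %s mode", config$filter_mode)
  rt <- if (is.null(config$tolerant_exclusion))
    config$filter_mode == "strict" else isTRUE(config$tolerant_exclusion)
  cands <- concordance_filter(
    gm, phen, sensitive_parent,
    filter_config(config$filter_mode, require_tolerant_exclusion = rt))
  causal <- panel$sites[panel$causal_site, ]
  causal_found <- any(cands$chrom == causal$chrom & cands$pos == causal$pos)
  .stage_log("filter", "%d candidate(s); causal site %s",
             nrow(cands), if (causal_found) "retained" else "LOST")

  # synthetic 5-exon gene model with the causal position inside exon 3
  gene <- causal_gene_model(causal$chrom, causal$pos)
  eff <- classify_variant_effect(
    variant(causal$chrom, causal$pos, causal$ref, causal$alt), gene)
  .stage_log("annotate", "causal variant: %s, exon %s", eff$category,
             eff$exon)

  .stage_log("simulate", "F2: n = %d", config$n_f2)
  tolerant_parent <- if (panel$causal_founder == 1L) 2L else 1L
  f2 <- run_f2(panel, panel$causal_founder, tolerant_parent, config$n_f2,
               seed = seeds[5])
  f2_ids <- sprintf("F2_%04d", seq_along(f2))
  f2_phen <- assign_phenotypes(f2, panel, ids = f2_ids)
  counts <- c(tolerant = sum(f2_phen$phenotype == "tolerant"),
              sensitive = sum(f2_phen$phenotype == "sensitive"))
  seg <- chi_square_segregation(counts, c(3, 1))
  .stage_log("segtest", "F2 %d:%d vs 3:1 -> X2 = %.3f (%s)",
             counts[1], counts[2], seg$statistic, seg$verdict)

  f2_true <- population_genotypes(f2, panel)
  conc <- marker_concordance(f2_true[panel$causal_site, ], f2_phen)
  .stage_log("concordance", "%d discordant of %d F2", conc$n_discordant,
             length(f2))

  report <- list(config = config,
                 sensitive_parent = sensitive_parent,
                 candidates = cands, causal_found = causal_found,
                 causal_site = causal, effect = eff, segregation = seg,
                 concordance = conc, n_sensitive_rils = n_sens,
                 ril_heterozygosity =
                   mean(population_heterozygosity(rils, panel)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_vcf(gm, p("magic.vcf"), seed = config$seed)
    write_phenotypes(phen, p("ril_phenotypes.tsv"))
    write_candidates(cands, p("candidates.tsv"), p("candidates.bed"))
    write_gff3(list(gene), p("causal_gene.gff3"))
    write_founder_table(panel, p("founder_alleles.tsv"))
    cfg_out <- config[setdiff(names(config), "out_dir")]
    jsonlite::write_json(cfg_out, p("config.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    report$files <- c(vcf = p("magic.vcf"),
                      founders = p("founder_alleles.tsv"),
                      config = p("config.json"),
                      phenotypes = p("ril_phenotypes.tsv"),
                      candidates = p("candidates.tsv"),
                      bed = p("candidates.bed"),
                      gff3 = p("causal_gene.gff3"))
    summary_lines <- c(
      sprintf("seed\t%d", config$seed),
      sprintf("candidates\t%d", nrow(cands)),
      sprintf("causal_found\t%s", causal_found),
      sprintf("causal_effect\t%s", eff$category),
      sprintf("f2_chi_square\t%.4f", seg$statistic),
      sprintf("f2_verdict\t%s", seg$verdict),
      sprintf("f2_discordant\t%d", conc$n_discordant),
      sprintf("sensitive_rils\t%d", n_sens))
    writeLines(summary_lines, p("summary.tsv"))
    report$files["summary"] <- p("summary.tsv")
  }
  structure(report, class = "pipeline_report")
}

#' Synthetic gene model around the causal position
#'
#' Builds a 5-exon plus-strand gene whose third exon contains the given
#' position (a stand-in for the real gene model, which is not distributed).
#'
#' @param chrom chromosome name.
#' @param pos genomic position to place inside exon 3.
#' @param exon_len exon length (default 300).
#' @param intron_len intron length (default 200).
#' @return a `gene_model`.
#' @export
causal_gene_model <- function(chrom, pos, exon_len = 300L,
                              intron_len = 200L) {
  # exon 3 centred on pos
  e3_start <- pos - exon_len %/% 2L
  starts <- e3_start + (-2:2) * (exon_len + intron_len)
  gene_model("CausalGene_synthetic", chrom, "+",
             cbind(starts, starts + exon_len - 1L))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  candidates: %d (causal %s)\n", nrow(x$candidates),
              if (x$causal_found) "retained" else "lost"))
  cat(sprintf("  causal effect: %s (exon %s)\n", x$effect$category,
              x$effect$exon))
  cat(sprintf("  F2 segregation: X2 = %.3f (%s)\n",
              x$segregation$statistic, x$segregation$verdict))
  cat(sprintf("  F2 discordant: %d\n", x$concordance$n_discordant))
  cat(sprintf("  sensitive RILs: %d; mean RIL heterozygosity: %.4f\n",
              x$n_sensitive_rils, x$ril_heterozygosity))
  invisible(x)
}
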