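# End-to-end pipeline: read all inputs, run the GWAS, expression and
# integrated analyses, compare the three significant sets, and write
# every artifact to disk.

#' Pipeline configuration
#'
#' Collects all input/output paths and analysis parameters. Defaults are
#' the standard settings of the method: 50 kb mapping window, tagging at
#' r-squared 0.8, MAF 0.01 / HWE 0.001 / call rate 0.25 QC, pathways of
#' 5-200 genes, 100,000 permutations, q < 0.05. The configuration
#' round-trips losslessly through YAML via [write_pipeline_config()] and
#' [read_pipeline_config()].
#'
#' @param ped,map,panel,bed,expression,groups,gmt Input file paths.
#' @param outdir Output directory.
#' @param maf_min,hwe_p_min,call_rate_min QC thresholds, see
#'   [qc_thresholds()].
#' @param hwe_in Samples used for the HWE test (`"controls"` or
#'   `"all"`).
#' @param window_bp SNP-to-gene mapping window (default 50000).
#' @param r2_threshold Tagging threshold (default 0.8).
#' @param min_genes,max_genes Pathway size filter (defaults 5, 200).
#' @param n_perm Permutation replicates (default 100000).
#' @param seed Integer seed.
#' @param tie_rule Permutation tie rule (`"strict"` or `"add_one"`).
#' @param fdr_method FDR procedure (`"bh"` or `"storey"`).
#' @param q_threshold Significance threshold (default 0.05).
#' @param ttest_variant `"student"` or `"welch"`.
#' @param collapse_rule Probe collapse rule (used only for probe-level
#'   input).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ped, map, panel, bed, expression, groups, gmt,
                            outdir,
                            maf_min = 0.01, hwe_p_min = 0.001,
                            call_rate_min = 0.25,
                            hwe_in = "controls",
                            window_bp = 50000, r2_threshold = 0.8,
                            min_genes = 5, max_genes = 200,
                            n_perm = 100000, seed = 1,
                            tie_rule = "strict", fdr_method = "bh",
                            q_threshold = 0.05,
                            ttest_variant = "student",
                            collapse_rule = "median") {
  cfg <- list(
    ped = ped, map = map, panel = panel, bed = bed,
    expression = expression, groups = groups, gmt = gmt, outdir = outdir,
    maf_min = maf_min, hwe_p_min = hwe_p_min,
    call_rate_min = call_rate_min, hwe_in = hwe_in,
    window_bp = window_bp, r2_threshold = r2_threshold,
    min_genes = min_genes, max_genes = max_genes,
    n_perm = n_perm, seed = seed, tie_rule = tie_rule,
    fdr_method = fdr_method, q_threshold = q_threshold,
    ttest_variant = ttest_variant, collapse_rule = collapse_rule
  )
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config` object.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] (or edited
#'   by hand).
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  check_file(path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

log_stage <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    pi_abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             class = "pathintegrate_error_stage")
  })
}

#' Run the full integrative pathway analysis pipeline
#'
#' Executes the three arms of the workflow: (I) genotype QC, trend tests,
#' tagSNP selection and gene-wise minimum-p scores; (II) per-gene
#' differential expression t-tests; (III) Fisher integration of the two
#' gene p-values and pathway permutation tests in all three modes (GWAS,
#' expression, integrated), followed by the mode comparison. Every stage
#' logs its counts to stderr, and all result tables plus the resolved
#' configuration are written under `config$outdir`.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a `pipeline_run` list: `gene_scores`, `results`
#'   (one `pathway_analysis` per mode), `comparison` (a
#'   `mode_comparison`), `paths` (written files).
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    pi_abort("`config` must come from `pipeline_config()`",
             class = "pathintegrate_error_config")
  }
  genotypes <- run_stage("read_genotypes",
                         read_genotypes_plink_text(config$ped, config$map))
  panel <- run_stage("read_panel", read_panel(config$panel))
  annotation <- run_stage("read_annotation", read_annotation_bed(config$bed))
  expression <- run_stage("read_expression",
                          read_expression(config$expression, config$groups))
  pathways <- run_stage("read_pathways", read_gmt(config$gmt))
  log_stage("inputs",
            samples = nrow(genotypes$samples), snps = nrow(genotypes$snps),
            genes = nrow(annotation), pathways = nrow(pathways))

  gwas <- run_stage("gwas_gene_scores", gwas_gene_scores(
    genotypes, annotation, panel,
    thresholds = qc_thresholds(config$maf_min, config$hwe_p_min,
                               config$call_rate_min),
    window_bp = config$window_bp, r2_threshold = config$r2_threshold,
    hwe_in = config$hwe_in
  ))
  qc_report <- attr(gwas, "qc_report")
  log_stage("gwas", snps_pass_qc = attr(qc_report, "n_out"),
            genes_scored = nrow(gwas))

  expr <- run_stage("expression_scores",
                    differential_expression_ttest(expression,
                                                  variant = config$ttest_variant))
  log_stage("expression", genes_scored = nrow(expr))

  gene_scores <- run_stage("integration", build_integrated_scores(gwas, expr))
  log_stage("integration", genes_both = attr(gene_scores, "n_both"))

  run_mode <- function(mode) {
    run_stage(paste0("pathway_", mode), run_pathway_analysis(
      gene_scores, pathways, mode = mode,
      n_perm = config$n_perm, seed = config$seed,
      min_genes = config$min_genes, max_genes = config$max_genes,
      tie_rule = config$tie_rule, fdr_method = config$fdr_method,
      q_threshold = config$q_threshold
    ))
  }
  results <- list(
    gwas = run_mode("gwas"),
    expression = run_mode("expression"),
    integrated = run_mode("integrated")
  )
  for (mode in names(results)) {
    log_stage(paste0("pathway_", mode),
              tested = nrow(results[[mode]]$results),
              significant = sum(results[[mode]]$results$significant))
  }
  comparison <- run_stage("compare", compare_modes(
    results$gwas, results$expression, results$integrated,
    q_threshold = config$q_threshold
  ))

  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(
    gene_scores = file.path(outdir, "gene_scores.tsv"),
    gwas = file.path(outdir, "pathway_results_gwas.tsv"),
    expression = file.path(outdir, "pathway_results_expression.tsv"),
    integrated = file.path(outdir, "pathway_results_integrated.tsv"),
    comparison = file.path(outdir, "comparison.tsv"),
    config = file.path(outdir, "config_resolved.yaml")
  )
  run_stage("write_outputs", {
    write_gene_scores(gene_scores, paths[["gene_scores"]])
    write_results(results$gwas, paths[["gwas"]])
    write_results(results$expression, paths[["expression"]])
    write_results(results$integrated, paths[["integrated"]])
    readr::write_tsv(comparison$membership, paths[["comparison"]])
    write_pipeline_config(config, paths[["config"]])
  })
  log_stage("done", outdir = outdir)
  invisible(structure(
    list(gene_scores = gene_scores, results = results,
         comparison = comparison, paths = paths, qc_report = qc_report),
    class = "pipeline_run"
  ))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$comparison)
  invisible(x)
}
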