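#' Simulation configuration for a synthetic integrative study
#'
#' Bundles every parameter of the synthetic-data generator. The generator
#' emulates the structure of a case-control GWAS (biallelic SNPs in
#' within-gene LD blocks, a planted per-allele odds ratio at causal SNPs),
#' a two-group normalized expression matrix with planted mean shifts, and a
#' pathway collection in which some pathways are enriched for the planted
#' signal genes. The defaults describe the reference study conditions used
#' throughout the package's validation: 500 cases vs 500 controls, 20 vs 20
#' expression samples, 100 pathways of which 5 are enriched at
#' `enrichment_fraction = 0.5`, per-allele odds ratio 1.5 and a standardized
#' expression shift of 1.5.
#'
#' @param n_cases,n_controls Number of affected / unaffected genotyped
#'   samples (retrospective sampling by affection status).
#' @param n_genes Number of genes in the annotation.
#' @param snps_per_gene Integer range; SNPs per gene are drawn uniformly
#'   from it.
#' @param maf_range Range in (0, 0.5] for the per-block minor allele
#'   frequency. All SNPs of a gene share one MAF (SNPs in strong LD have
#'   similar frequencies).
#' @param ld_block_rho Target pairwise allelic r-squared between SNPs of
#'   the same gene, in `[0, 1)`. Implemented by a haplotype-copying block
#'   model: each haplotype draws a founder allele per gene and each SNP
#'   copies it with probability `ld_block_rho^(1/4)`, giving pairwise
#'   allelic correlation `sqrt(ld_block_rho)`, i.e. r-squared
#'   `ld_block_rho`.
#' @param causal_gene_fraction Fraction of genes that carry one causal SNP
#'   (ignored when `genotype_odds_ratio` is 1).
#' @param genotype_odds_ratio Per-minor-allele odds ratio at causal SNPs
#'   (logistic disease model); 1 means no genetic effect.
#' @param de_gene_fraction Fraction of genes differentially expressed
#'   (ignored when `de_effect_size` is 0).
#' @param de_effect_size Standardized mean shift (in units of
#'   `expr_noise_sd`) added to case samples of DE genes.
#' @param expr_noise_sd Residual standard deviation of expression values.
#' @param de_causal_overlap Fraction of DE genes drawn from the causal
#'   genes, so that the integrated analysis sees joint signal.
#' @param n_expr_cases,n_expr_controls Expression sample sizes per group.
#' @param n_pathways Number of gene sets to emit.
#' @param pathway_size_range Range of pathway sizes, within `[5, 200]` by
#'   default (the usual size filter for pathway databases).
#' @param n_enriched_pathways Number of pathways enriched for planted
#'   signal genes.
#' @param enrichment_fraction Fraction of an enriched pathway's members
#'   drawn from the planted-signal genes (causal or DE).
#' @param missing_rate Genotype missingness rate injected into the study
#'   calls (exercises the call-rate QC path).
#' @param n_panel Number of diploid reference-panel samples (two phased
#'   haplotypes each).
#' @param base_prevalence Baseline disease prevalence of the logistic
#'   model (controls the retrospective sampling pool).
#' @param seed Integer seed; a fixed seed makes the whole output bundle
#'   reproducible byte for byte.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(n_genes = 50, n_pathways = 10, seed = 1)
#' @export
simulation_config <- function(n_cases = 500L,
                              n_controls = 500L,
                              n_genes = 800L,
                              snps_per_gene = c(2L, 6L),
                              maf_range = c(0.05, 0.5),
                              ld_block_rho = 0.8,
                              causal_gene_fraction = 0.1,
                              genotype_odds_ratio = 1.5,
                              de_gene_fraction = 0.1,
                              de_effect_size = 1.5,
                              expr_noise_sd = 1,
                              de_causal_overlap = 0.7,
                              n_expr_cases = 20L,
                              n_expr_controls = 20L,
                              n_pathways = 100L,
                              pathway_size_range = c(5L, 200L),
                              n_enriched_pathways = 5L,
                              enrichment_fraction = 0.5,
                              missing_rate = 0.01,
                              n_panel = 500L,
                              base_prevalence = 0.2,
                              seed = 1L) {
  cfg <- list(
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    n_genes = assert_count(n_genes, "n_genes"),
    snps_per_gene = assert_range(as.integer(snps_per_gene), "snps_per_gene", lo = 1),
    maf_range = assert_range(maf_range, "maf_range", lo = 0, hi = 0.5),
    ld_block_rho = ld_block_rho,
    causal_gene_fraction = assert_proportion(causal_gene_fraction, "causal_gene_fraction"),
    genotype_odds_ratio = genotype_odds_ratio,
    de_gene_fraction = assert_proportion(de_gene_fraction, "de_gene_fraction"),
    de_effect_size = de_effect_size,
    expr_noise_sd = expr_noise_sd,
    de_causal_overlap = assert_proportion(de_causal_overlap, "de_causal_overlap"),
    n_expr_cases = assert_count(n_expr_cases, "n_expr_cases", min = 2),
    n_expr_controls = assert_count(n_expr_controls, "n_expr_controls", min = 2),
    n_pathways = assert_count(n_pathways, "n_pathways"),
    pathway_size_range = assert_range(as.integer(pathway_size_range), "pathway_size_range", lo = 1),
    n_enriched_pathways = assert_count(n_enriched_pathways, "n_enriched_pathways", min = 0),
    enrichment_fraction = assert_proportion(enrichment_fraction, "enrichment_fraction"),
    missing_rate = assert_proportion(missing_rate, "missing_rate"),
    n_panel = assert_count(n_panel, "n_panel", min = 2),
    base_prevalence = assert_proportion(base_prevalence, "base_prevalence"),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (maf_range[1] <= 0) {
    pi_abort("`maf_range` must lie within (0, 0.5]", class = "pathintegrate_error_config")
  }
  if (length(ld_block_rho) != 1 || is.na(ld_block_rho) ||
      ld_block_rho < 0 || ld_block_rho >= 1) {
    pi_abort("`ld_block_rho` must lie in [0, 1)", class = "pathintegrate_error_config")
  }
  if (genotype_odds_ratio < 1) {
    pi_abort("`genotype_odds_ratio` must be >= 1", class = "pathintegrate_error_config")
  }
  if (de_effect_size < 0 || expr_noise_sd <= 0) {
    pi_abort("`de_effect_size` must be >= 0 and `expr_noise_sd` > 0",
             class = "pathintegrate_error_config")
  }
  if (cfg$n_enriched_pathways > cfg$n_pathways) {
    pi_abort("`n_enriched_pathways` cannot exceed `n_pathways`",
             class = "pathintegrate_error_config")
  }
  if (base_prevalence <= 0 || base_prevalence >= 1) {
    pi_abort("`base_prevalence` must lie in (0, 1)", class = "pathintegrate_error_config")
  }
  structure(cfg, class = "sim_config")
}

assert_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    pi_abort("`config` must be created by `simulation_config()`",
             class = "pathintegrate_error_config")
  }
  invisible(config)
}

#' Generate a synthetic gene annotation
#'
#' Lays non-overlapping gene intervals (1-based, inclusive) on one or more
#' chromosomes. Gaps between adjacent genes alternate between short
#' (< 100 kb, so the two genes' 50 kb mapping windows overlap) and long
#' (> 100 kb, so they do not), ensuring both regimes are exercised.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
generate_annotation <- function(config) {
  assert_sim_config(config)
  n_genes <- config$n_genes
  withr::with_seed(substream_seed(config$seed, "annotation"), {
    n_chrom <- min(22L, max(1L, ceiling(n_genes / 100)))
    chrom_of <- rep(seq_len(n_chrom), length.out = n_genes)
    chrom_of <- sort(chrom_of)
    lens <- sample(5000:50000, n_genes, replace = TRUE)
    start <- integer(n_genes)
    end <- integer(n_genes)
    for (c_id in unique(chrom_of)) {
      idx <- which(chrom_of == c_id)
      pos <- 100000L
      for (k in seq_along(idx)) {
        i <- idx[k]
        start[i] <- pos
        end[i] <- pos + lens[i] - 1L
        gap <- if (k %% 2 == 1) {
          sample(10000:80000, 1)     # windows of the two genes overlap
        } else {
          sample(120000:300000, 1)   # windows stay disjoint
        }
        pos <- end[i] + gap + 1L
      }
    }
    tibble(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chrom = as.character(chrom_of),
      start = start,
      end = end
    )
  })
}

# Haplotype block generator: exchangeable copying model. Each haplotype
# draws one founder allele for the gene; every SNP copies it with
# probability rho^(1/4), otherwise draws a fresh Bernoulli(maf) allele.
# Pairwise allelic correlation is sqrt(rho), i.e. r^2 = rho.
sim_gene_haplotypes <- function(n_hap, m, maf, rho) {
  gamma <- if (rho <= 0) 0 else rho^(1 / 4)
  founder <- rbinom(n_hap, 1L, maf)
  copy <- matrix(rbinom(n_hap * m, 1L, gamma), n_hap, m)
  fresh <- matrix(rbinom(n_hap * m, 1L, maf), n_hap, m)
  copy * founder + (1L - copy) * fresh
}

#' Simulate case-control genotypes, a reference panel, and ground truth
#'
#' Haplotypes are generated per gene by an exchangeable copying model with
#' within-block r-squared `ld_block_rho` (see [simulation_config()]).
#' Affection status follows a logistic model with per-minor-allele log-odds
#' `log(genotype_odds_ratio)` at one causal SNP per causal gene; cases and
#' controls are then sampled retrospectively by status, as in a
#' case-control GWAS. The reference panel is drawn from the same haplotype
#' process, independently of the case-control draw.
#'
#' @param config A [simulation_config()].
#' @param annotation Gene annotation from [generate_annotation()].
#' @return A list with elements `genotypes` (a `genotype_data` object),
#'   `panel` (a phased `ref_panel`), and `truth` (a `ground_truth` list
#'   with `causal_snp_ids` and `causal_gene_ids`).
#' @export
simulate_genotypes <- function(config, annotation) {
  assert_sim_config(config)
  withr::with_seed(substream_seed(config$seed, "genotypes"), {
    n_genes <- nrow(annotation)
    rng <- config$snps_per_gene
    m_g <- if (rng[1] == rng[2]) rep(rng[1], n_genes) else
      sample(rng[1]:rng[2], n_genes, replace = TRUE)
    maf_g <- runif(n_genes, config$maf_range[1], config$maf_range[2])

    snps <- pmap(
      list(annotation$gene_id, annotation$chrom, annotation$start,
           annotation$end, m_g),
      function(gid, chrom, start, end, m) {
        pos <- sort(sample.int(end - start + 1L, m)) + start - 1L
        tibble(
          snp_id = sprintf("%s_snp%02d", gid, seq_len(m)),
          chrom = chrom, pos = pos
        )
      }
    )
    snps <- bind_rows(snps)
    snps$allele_major <- "A"
    snps$allele_minor <- "G"
    n_snps <- nrow(snps)
    gene_first_col <- cumsum(c(1L, m_g))[seq_len(n_genes)]

    # Planted truth: one causal SNP per causal gene (none when OR = 1).
    causal_genes <- character(0)
    causal_snps <- character(0)
    if (config$genotype_odds_ratio > 1 && config$causal_gene_fraction > 0) {
      n_causal <- round(config$causal_gene_fraction * n_genes)
      if (n_causal > 0) {
        causal_idx <- sort(sample.int(n_genes, n_causal))
        causal_genes <- annotation$gene_id[causal_idx]
        causal_snps <- map_chr(causal_idx, function(i) {
          sprintf("%s_snp%02d", annotation$gene_id[i],
                  sample.int(m_g[i], 1))
        })
      }
    }
    causal_cols <- match(causal_snps, snps$snp_id)
    beta <- log(config$genotype_odds_ratio)
    # center the genetic score so the population prevalence stays near
    # base_prevalence regardless of how many causal SNPs are planted
    causal_gene_idx <- match(sub("_snp[0-9]+$", "", causal_snps),
                             annotation$gene_id)
    expected_dose <- sum(2 * maf_g[causal_gene_idx])
    alpha <- qlogis(config$base_prevalence) - beta * expected_dose

    draw_genotype_chunk <- function(n_ind) {
      g <- matrix(0L, n_ind, n_snps)
      for (i in seq_len(n_genes)) {
        h <- sim_gene_haplotypes(2L * n_ind, m_g[i], maf_g[i],
                                 config$ld_block_rho)
        cols <- gene_first_col[i]:(gene_first_col[i] + m_g[i] - 1L)
        g[, cols] <- h[seq(1, 2 * n_ind, by = 2), , drop = FALSE] +
          h[seq(2, 2 * n_ind, by = 2), , drop = FALSE]
      }
      g
    }

    # Retrospective sampling: draw population chunks, assign status from
    # the logistic model, keep until both quotas are filled.
    need_cases <- config$n_cases
    need_controls <- config$n_controls
    chunk_n <- max(500L, ceiling(1.2 * (need_cases + need_controls)))
    case_rows <- list()
    control_rows <- list()
    got_cases <- 0L
    got_controls <- 0L
    for (chunk in seq_len(60L)) {
      if (got_cases >= need_cases && got_controls >= need_controls) break
      g <- draw_genotype_chunk(chunk_n)
      eta <- alpha
      if (length(causal_cols)) {
        eta <- alpha + beta * rowSums(g[, causal_cols, drop = FALSE])
      }
      status <- rbinom(chunk_n, 1L, plogis(eta))
      if (got_cases < need_cases) {
        take <- which(status == 1L)[seq_len(min(sum(status == 1L),
                                                need_cases - got_cases))]
        if (length(take)) {
          case_rows[[length(case_rows) + 1L]] <- g[take, , drop = FALSE]
          got_cases <- got_cases + length(take)
        }
      }
      if (got_controls < need_controls) {
        take <- which(status == 0L)[seq_len(min(sum(status == 0L),
                                                need_controls - got_controls))]
        if (length(take)) {
          control_rows[[length(control_rows) + 1L]] <- g[take, , drop = FALSE]
          got_controls <- got_controls + length(take)
        }
      }
    }
    if (got_cases < need_cases || got_controls < need_controls) {
      pi_abort("could not fill case/control quotas; check `base_prevalence`",
               class = "pathintegrate_error_config")
    }
    calls <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
    if (config$missing_rate > 0) {
      miss <- runif(length(calls)) < config$missing_rate
      calls[miss] <- NA_integer_
    }
    samples <- tibble(
      sample_id = c(sprintf("CASE_%04d", seq_len(need_cases)),
                    sprintf("CTRL_%04d", seq_len(need_controls))),
      phenotype = rep(c("case", "control"), c(need_cases, need_controls))
    )
    dimnames(calls) <- list(samples$sample_id, snps$snp_id)
    genotypes <- new_genotype_data(samples, snps, calls)

    # Reference panel: same generating process, independent draw.
    hap <- matrix(0L, 2L * config$n_panel, n_snps)
    for (i in seq_len(n_genes)) {
      cols <- gene_first_col[i]:(gene_first_col[i] + m_g[i] - 1L)
      hap[, cols] <- sim_gene_haplotypes(2L * config$n_panel, m_g[i],
                                         maf_g[i], config$ld_block_rho)
    }
    colnames(hap) <- snps$snp_id
    panel <- new_ref_panel(
      snps = snps,
      haplotypes = hap,
      phased = TRUE,
      sample_ids = sprintf("PANEL_%04d", seq_len(config$n_panel))
    )

    truth <- structure(
      list(
        causal_snp_ids = causal_snps,
        causal_gene_ids = causal_genes,
        de_gene_ids = character(0),
        enriched_pathway_ids = character(0)
      ),
      class = "ground_truth"
    )
    list(genotypes = genotypes, panel = panel, truth = truth)
  })
}

#' Simulate a normalized expression matrix with planted DE genes
#'
#' Non-DE genes are a gene-specific baseline plus Gaussian noise; DE genes
#' are shifted upward in case samples by `de_effect_size * expr_noise_sd`.
#' DE genes preferentially overlap the planted causal genes
#' (`de_causal_overlap`), so the integrated analysis has joint signal.
#'
#' @param config A [simulation_config()].
#' @param annotation Gene annotation tibble.
#' @param truth Ground truth from [simulate_genotypes()] (updated and
#'   returned).
#' @return A list with elements `expression` (an `expression_data` object)
#'   and `truth` (with `de_gene_ids` filled in).
#' @export
simulate_expression <- function(config, annotation, truth) {
  assert_sim_config(config)
  withr::with_seed(substream_seed(config$seed, "expression"), {
    n_genes <- nrow(annotation)
    de_genes <- character(0)
    if (config$de_effect_size > 0 && config$de_gene_fraction > 0) {
      n_de <- round(config$de_gene_fraction * n_genes)
      if (n_de > 0) {
        n_overlap <- min(round(config$de_causal_overlap * n_de),
                         length(truth$causal_gene_ids))
        from_causal <- if (n_overlap > 0) {
          sample(truth$causal_gene_ids, n_overlap)
        } else character(0)
        others <- setdiff(annotation$gene_id, truth$causal_gene_ids)
        de_genes <- sort(c(from_causal,
                           sample(others, n_de - length(from_causal))))
      }
    }
    n1 <- config$n_expr_cases
    n2 <- config$n_expr_controls
    baseline <- rnorm(n_genes, mean = 8, sd = 1)
    values <- baseline +
      matrix(rnorm(n_genes * (n1 + n2), sd = config$expr_noise_sd),
             n_genes, n1 + n2)
    shift_rows <- match(de_genes, annotation$gene_id)
    if (length(shift_rows)) {
      values[shift_rows, seq_len(n1)] <-
        values[shift_rows, seq_len(n1)] +
        config$de_effect_size * config$expr_noise_sd
    }
    samples <- c(sprintf("ECASE_%03d", seq_len(n1)),
                 sprintf("ECTRL_%03d", seq_len(n2)))
    dimnames(values) <- list(annotation$gene_id, samples)
    groups <- tibble(
      sample_id = samples,
      group = rep(c("case", "control"), c(n1, n2))
    )
    truth$de_gene_ids <- de_genes
    list(
      expression = new_expression_data(values, groups, level = "gene"),
      truth = truth
    )
  })
}

#' Generate a pathway collection with planted enriched pathways
#'
#' Pathway sizes are drawn uniformly from `pathway_size_range`. Enriched
#' pathways draw `enrichment_fraction` of their members from the planted
#' signal genes (causal or DE); all other members, and all members of
#' background pathways, are drawn uniformly.
#'
#' @param config A [simulation_config()].
#' @param annotation Gene annotation tibble.
#' @param truth Ground truth carrying the planted gene sets.
#' @return A list with elements `pathways` (a tibble with columns
#'   `pathway_id`, `name`, and list-column `genes`) and `truth` (with
#'   `enriched_pathway_ids` filled in).
#' @export
generate_pathways <- function(config, annotation, truth) {
  assert_sim_config(config)
  if (config$pathway_size_range[2] > nrow(annotation)) {
    pi_abort("requested pathway size exceeds the number of available genes",
             class = "pathintegrate_error_config")
  }
  withr::with_seed(substream_seed(config$seed, "pathways"), {
    all_genes <- annotation$gene_id
    signal <- union(truth$causal_gene_ids, truth$de_gene_ids)
    background_pool <- setdiff(all_genes, signal)
    rng <- config$pathway_size_range
    sizes <- if (rng[1] == rng[2]) rep(rng[1], config$n_pathways) else
      sample(rng[1]:rng[2], config$n_pathways, replace = TRUE)
    ids <- sprintf("PW_%04d", seq_len(config$n_pathways))
    enriched <- if (config$n_enriched_pathways > 0) {
      sort(sample(ids, config$n_enriched_pathways))
    } else character(0)
    genes <- map2(ids, sizes, function(id, size) {
      if (id %in% enriched && length(signal) > 0) {
        n_sig <- min(round(config$enrichment_fraction * size), length(signal),
                     size)
        n_bg <- size - n_sig
        if (n_bg > length(background_pool)) {
          pi_abort("requested pathway size exceeds available background genes",
                   class = "pathintegrate_error_config")
        }
        sort(c(sample(signal, n_sig), sample(background_pool, n_bg)))
      } else {
        sort(sample(all_genes, size))
      }
    })
    pathways <- tibble(
      pathway_id = ids,
      name = sprintf("Synthetic pathway %d", seq_len(config$n_pathways)),
      genes = genes
    )
    truth$enriched_pathway_ids <- enriched
    list(pathways = pathways, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [simulate_genotypes()], [simulate_expression()] and
#' [generate_pathways()]. With a fixed seed the returned bundle is fully
#' reproducible.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `config`, `annotation`, `genotypes`,
#'   `panel`, `expression`, `pathways`, `truth`.
#' @examples
#' study <- simulate_study(simulation_config(
#'   n_cases = 50, n_controls = 50, n_genes = 40, n_pathways = 8,
#'   pathway_size_range = c(5, 10), n_enriched_pathways = 2, seed = 7
#' ))
#' @export
simulate_study <- function(config) {
  assert_sim_config(config)
  annotation <- generate_annotation(config)
  geno <- simulate_genotypes(config, annotation)
  expr <- simulate_expression(config, annotation, geno$truth)
  pw <- generate_pathways(config, annotation, expr$truth)
  list(
    config = config,
    annotation = annotation,
    genotypes = geno$genotypes,
    panel = geno$panel,
    expression = expr$expression,
    pathways = pw$pathways,
    truth = pw$truth
  )
}

#' Write a simulated study to disk as a plain-text fixture bundle
#'
#' Emits PLINK text genotypes (`.ped`/`.map`), a phased VCF reference
#' panel, a BED gene annotation, expression and group TSVs, a GMT pathway
#' file, and a ground-truth TSV. Re-reading the bundle with the package's
#' readers reproduces the in-memory objects.
#'
#' @param study A study list from [simulate_study()].
#' @param outdir Output directory (created if absent).
#' @return A tibble manifest with columns `artifact` and `path`.
#' @export
write_fixture_bundle <- function(study, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) {
      pi_abort(paste0("cannot create output directory: ", outdir),
               class = "pathintegrate_error_io")
    }
  }
  paths <- c(
    ped = file.path(outdir, "study.ped"),
    map = file.path(outdir, "study.map"),
    panel = file.path(outdir, "panel.vcf"),
    bed = file.path(outdir, "genes.bed"),
    expression = file.path(outdir, "expression.tsv"),
    groups = file.path(outdir, "groups.tsv"),
    gmt = file.path(outdir, "pathways.gmt"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_genotypes_plink(study$genotypes, paths[["ped"]], paths[["map"]])
  write_panel_vcf(study$panel, paths[["panel"]])
  write_annotation_bed(study$annotation, paths[["bed"]])
  write_expression_tsv(study$expression, paths[["expression"]], paths[["groups"]])
  write_gmt(study$pathways, paths[["gmt"]])
  write_truth_tsv(study$truth, paths[["truth"]])
  tibble(artifact = names(paths), path = unname(paths))
}

#' Write ground truth to TSV
#'
#' @param truth A `ground_truth` list.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- bind_rows(
    tibble(category = "causal_snp", id = truth$causal_snp_ids),
    tibble(category = "causal_gene", id = truth$causal_gene_ids),
    tibble(category = "de_gene", id = truth$de_gene_ids),
    tibble(category = "enriched_pathway", id = truth$enriched_pathway_ids)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read ground truth from TSV
#'
#' @param path Truth TSV written by [write_truth_tsv()].
#' @return A `ground_truth` list.
#' @export
read_truth_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  pick <- function(cat) df$id[df$category == cat]
  structure(
    list(
      causal_snp_ids = pick("causal_snp"),
      causal_gene_ids = pick("causal_gene"),
      de_gene_ids = pick("de_gene"),
      enriched_pathway_ids = pick("enriched_pathway")
    ),
    class = "ground_truth"
  )
}
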