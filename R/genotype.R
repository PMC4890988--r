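# Gene-wise association scoring from case-control genotypes: QC, the
# Cochran-Armitage trend test, window-based SNP-to-gene mapping, greedy
# tagSNP selection against a reference panel, and the minimum-p rule.

#' SNP quality-control thresholds
#'
#' SNPs failing any of the three filters are excluded: minor allele
#' frequency below `maf_min`, Hardy-Weinberg p-value below `hwe_p_min`, or
#' call rate below `call_rate_min`. The default call-rate threshold of
#' 0.25 follows the convention of excluding SNPs with a genotyping
#' percentage under 25%; users wanting stringent modern QC can set 0.95.
#'
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param hwe_p_min Minimum Hardy-Weinberg equilibrium p-value (default
#'   0.001).
#' @param call_rate_min Minimum per-SNP call rate (default 0.25).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 0.001,
                          call_rate_min = 0.25) {
  for (v in c(maf_min, hwe_p_min, call_rate_min)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      pi_abort("QC thresholds must be single values in [0, 1]",
               class = "pathintegrate_error_config")
    }
  }
  structure(
    list(maf_min = maf_min, hwe_p_min = hwe_p_min,
         call_rate_min = call_rate_min),
    class = "qc_thresholds"
  )
}

# Vectorized 1-df chi-square goodness-of-fit test for Hardy-Weinberg
# proportions. Monomorphic SNPs get p = 1.
hwe_chisq_vec <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p_hat <- ifelse(n > 0, (2 * n_aa + n_ab) / (2 * n), NA_real_)
  e_aa <- n * p_hat^2
  e_ab <- 2 * n * p_hat * (1 - p_hat)
  e_bb <- n * (1 - p_hat)^2
  mono <- is.na(p_hat) | p_hat == 0 | p_hat == 1
  stat <- ifelse(
    mono, 0,
    (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab + (n_bb - e_bb)^2 / e_bb
  )
  ifelse(mono, 1, pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exact Hardy-Weinberg test (conditional on allele counts), summing the
# probabilities of all heterozygote counts no more likely than observed.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized log-probabilities built by the standard recurrence
  lp <- numeric(length(hets))
  names(lp) <- hets
  mid <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  lp[mid] <- 0
  if (mid < length(hets)) {
    for (i in (mid + 1):length(hets)) {
      h <- hets[i - 1]
      hom_a <- (n_a - h) / 2
      hom_b <- (n_b - h) / 2
      lp[i] <- lp[i - 1] + log(4 * hom_a * hom_b) - log((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (i in (mid - 1):1) {
      h <- hets[i + 1]
      hom_a <- (n_a - h) / 2
      hom_b <- (n_b - h) / 2
      lp[i] <- lp[i + 1] + log(h * (h - 1)) - log(4 * (hom_a + 1) * (hom_b + 1))
    }
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[as.character(n_ab)] * (1 + 1e-12)]))
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against the proportions expected from
#' the estimated allele frequency. The default is the 1-df chi-square
#' goodness-of-fit test; an exact test (conditional on allele counts) is
#' available via `method = "exact"`. A monomorphic SNP returns p = 1 with
#' attribute `monomorphic = TRUE`.
#'
#' @param genotype_counts Integer vector `c(n_AA, n_Aa, n_aa)`.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return The p-value, with attribute `monomorphic`.
#' @examples
#' hwe_test(c(30, 40, 30))  # chi-square statistic 4, p ~ 0.0455
#' @export
hwe_test <- function(genotype_counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(genotype_counts) != 3 || anyNA(genotype_counts) ||
      any(genotype_counts < 0) || sum(genotype_counts) == 0) {
    pi_abort("`genotype_counts` must be 3 non-negative counts with total > 0",
             class = "pathintegrate_error_domain")
  }
  n_aa <- genotype_counts[1]; n_ab <- genotype_counts[2]; n_bb <- genotype_counts[3]
  mono <- (2 * n_aa + n_ab == 0) || (2 * n_bb + n_ab == 0)
  p <- if (mono) {
    1
  } else if (method == "chisq") {
    hwe_chisq_vec(n_aa, n_ab, n_bb)
  } else {
    hwe_exact_p(n_aa, n_ab, n_bb)
  }
  structure(p, monomorphic = mono)
}

#' Cochran-Armitage trend test for a 2 x 3 genotype table
#'
#' Tests for a linear trend in case proportion across genotype dose with
#' additive scores (0, 1, 2). The squared trend statistic is compared to a
#' chi-square distribution with 1 df (two-sided).
#'
#' @param case_counts Integer vector `c(r0, r1, r2)` of case genotype
#'   counts.
#' @param control_counts Integer vector `c(s0, s1, s2)` of control
#'   genotype counts.
#' @return A list with elements `statistic` (the chi-square trend
#'   statistic) and `p_value`.
#' @examples
#' cochran_armitage_trend(c(10, 15, 25), c(20, 15, 15))
#' @export
cochran_armitage_trend <- function(case_counts, control_counts) {
  if (length(case_counts) != 3 || length(control_counts) != 3 ||
      anyNA(case_counts) || anyNA(control_counts) ||
      any(case_counts < 0) || any(control_counts < 0) ||
      sum(case_counts) == 0 || sum(control_counts) == 0) {
    pi_abort("each group needs 3 non-negative counts with positive total",
             class = "pathintegrate_error_domain")
  }
  res <- trend_stat_vec(case_counts[1], case_counts[2], case_counts[3],
                        control_counts[1], control_counts[2], control_counts[3])
  if (is.na(res$statistic)) {
    pi_abort("trend statistic undefined: genotype dose has zero variance",
             class = "pathintegrate_error_degenerate")
  }
  list(statistic = res$statistic, p_value = res$p_value)
}

# Vectorized trend statistic over parallel count vectors; NA where the
# variance term vanishes.
trend_stat_vec <- function(r0, r1, r2, s0, s1, s2) {
  w <- c(0, 1, 2)
  R <- r0 + r1 + r2
  S <- s0 + s1 + s2
  N <- R + S
  n0 <- r0 + s0; n1 <- r1 + s1; n2 <- r2 + s2
  sum_wr <- r1 + 2 * r2
  sum_wn <- n1 + 2 * n2
  sum_w2n <- n1 + 4 * n2
  denom <- R * S * (N * sum_w2n - sum_wn^2)
  num <- N * (N * sum_wr - R * sum_wn)^2
  stat <- ifelse(denom > 0, num / denom, NA_real_)
  list(statistic = stat,
       p_value = ifelse(is.na(stat), NA_real_,
                        pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Per-SNP Cochran-Armitage trend tests for a genotype dataset
#'
#' @param dataset A `genotype_data` object.
#' @return A tibble with columns `snp_id`, `statistic`, `p_value`
#'   (`NA` where the genotype dose has zero variance).
#' @export
snp_trend_tests <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_data"))
  is_case <- dataset$samples$phenotype == "case"
  cc <- dataset$calls[is_case, , drop = FALSE]
  ct <- dataset$calls[!is_case, , drop = FALSE]
  r0 <- colSums(cc == 0L, na.rm = TRUE)
  r1 <- colSums(cc == 1L, na.rm = TRUE)
  r2 <- colSums(cc == 2L, na.rm = TRUE)
  s0 <- colSums(ct == 0L, na.rm = TRUE)
  s1 <- colSums(ct == 1L, na.rm = TRUE)
  s2 <- colSums(ct == 2L, na.rm = TRUE)
  res <- trend_stat_vec(r0, r1, r2, s0, s1, s2)
  tibble(snp_id = dataset$snps$snp_id,
         statistic = unname(res$statistic),
         p_value = unname(res$p_value))
}

#' SNP quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min`, Hardy-Weinberg
#' p-value below `hwe_p_min`, or call rate below `call_rate_min`. MAF and
#' call rate are computed over the non-missing calls of all samples; HWE
#' is tested in controls only by default (standard GWAS practice, since
#' true association distorts HWE in cases).
#'
#' @param dataset A `genotype_data` object.
#' @param thresholds A [qc_thresholds()] object.
#' @param hwe_in `"controls"` (default) or `"all"`: samples used for the
#'   HWE test.
#' @return A list with elements `dataset` (filtered `genotype_data`) and
#'   `report` (tibble: `snp_id`, `maf`, `hwe_p`, `call_rate`, `pass`,
#'   `reasons`, with attributes `n_in` and `n_out`).
#' @export
snp_qc <- function(dataset, thresholds = qc_thresholds(),
                   hwe_in = c("controls", "all")) {
  stopifnot(inherits(dataset, "genotype_data"))
  hwe_in <- match.arg(hwe_in)
  if (!inherits(thresholds, "qc_thresholds")) {
    pi_abort("`thresholds` must come from `qc_thresholds()`",
             class = "pathintegrate_error_config")
  }
  calls <- dataset$calls
  n_samples <- nrow(calls)
  non_missing <- colSums(!is.na(calls))
  call_rate <- non_missing / n_samples
  minor_count <- colSums(calls, na.rm = TRUE)
  maf <- ifelse(non_missing > 0, minor_count / (2 * non_missing), NA_real_)
  maf <- pmin(maf, 1 - maf)

  hwe_rows <- if (hwe_in == "controls") {
    dataset$samples$phenotype == "control"
  } else {
    rep(TRUE, n_samples)
  }
  hc <- calls[hwe_rows, , drop = FALSE]
  hwe_p <- hwe_chisq_vec(colSums(hc == 0L, na.rm = TRUE),
                         colSums(hc == 1L, na.rm = TRUE),
                         colSums(hc == 2L, na.rm = TRUE))

  fail_maf <- is.na(maf) | maf < thresholds$maf_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_cr <- call_rate < thresholds$call_rate_min
  pass <- !(fail_maf | fail_hwe | fail_cr)
  reasons <- pmap(list(unname(fail_maf), unname(fail_hwe), unname(fail_cr)),
                  function(a, b, c) {
    paste(c(if (a) "low_maf", if (b) "hwe_fail", if (c) "low_call_rate"),
          collapse = ",")
  })
  report <- tibble(
    snp_id = dataset$snps$snp_id,
    maf = unname(maf),
    hwe_p = unname(hwe_p),
    call_rate = unname(call_rate),
    pass = unname(pass),
    reasons = unlist(reasons)
  )
  attr(report, "n_in") <- ncol(calls)
  attr(report, "n_out") <- sum(pass)
  if (!any(pass)) {
    pi_abort("no SNP survives quality control (empty after QC)",
             class = "pathintegrate_error_empty_qc")
  }
  keep <- which(pass)
  filtered <- new_genotype_data(
    dataset$samples,
    dataset$snps[keep, , drop = FALSE],
    dataset$calls[, keep, drop = FALSE]
  )
  list(dataset = filtered, report = report)
}

#' Map SNPs to genes by a flanking window
#'
#' A SNP is assigned to a gene if it lies within the gene body or within
#' `window_bp` immediately upstream or downstream (inclusive, same
#' chromosome). A SNP may map to several genes; unmapped SNPs are listed
#' in the `unmapped` attribute.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (1-based bp).
#' @param annotation Tibble with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param window_bp Flanking window in base pairs (default 50000).
#' @return A tibble with columns `snp_id`, `gene_id`, `chrom`, `pos`, and
#'   attributes `window_bp` and `unmapped`.
#' @export
map_snps_to_genes <- function(snps, annotation, window_bp = 50000) {
  if (length(intersect(unique(snps$chrom), unique(annotation$chrom))) == 0) {
    pi_abort(
      paste0("no shared chromosome between SNPs (",
             paste(unique(snps$chrom), collapse = ","),
             ") and annotation (",
             paste(unique(annotation$chrom), collapse = ","), ")"),
      class = "pathintegrate_error_chrom"
    )
  }
  hits <- inner_join(
    select(snps, "snp_id", "chrom", "pos"),
    select(annotation, "gene_id", "chrom", "start", "end"),
    by = "chrom", relationship = "many-to-many"
  )
  hits <- filter(hits,
                 .data$pos >= .data$start - window_bp,
                 .data$pos <= .data$end + window_bp)
  out <- select(arrange(hits, .data$gene_id, .data$pos),
                "snp_id", "gene_id", "chrom", "pos")
  attr(out, "window_bp") <- window_bp
  attr(out, "unmapped") <- setdiff(snps$snp_id, out$snp_id)
  out
}

panel_matrix <- function(panel, snp_ids) {
  idx <- match(snp_ids, panel$snps$snp_id)
  list(idx = idx, mat = panel$haplotypes)
}

#' Pairwise linkage disequilibrium r-squared from a reference panel
#'
#' For a phased panel this is the haplotype-frequency r-squared
#' `D^2 / (pA pa pB pb)`, computed as the squared correlation of the two
#' 0/1 haplotype vectors (the two are algebraically identical). For an
#' unphased panel the squared composite genotype correlation is used.
#'
#' @param panel A `ref_panel` object.
#' @param snp_a,snp_b SNP ids present in the panel.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(panel, snp_a, snp_b) {
  stopifnot(inherits(panel, "ref_panel"))
  ia <- match(snp_a, panel$snps$snp_id)
  ib <- match(snp_b, panel$snps$snp_id)
  if (is.na(ia) || is.na(ib)) {
    pi_abort("both SNPs must be present in the panel",
             class = "pathintegrate_error_domain")
  }
  x <- panel$haplotypes[, ia]
  y <- panel$haplotypes[, ib]
  if (sd(x) == 0 || sd(y) == 0) {
    pi_abort("r-squared undefined: SNP monomorphic in panel",
             class = "pathintegrate_error_monomorphic")
  }
  unname(cor(x, y)^2)
}

#' Select tagSNPs for a set of SNPs by greedy r-squared cover
#'
#' Repeatedly picks the SNP covering (r-squared at or above the
#' threshold, in the panel) the largest number of still-uncovered SNPs,
#' until every SNP is covered. Ties are broken by smaller genomic
#' position, then lexicographic id. SNPs absent from the panel, or
#' monomorphic in it, become their own tags.
#'
#' @param snp_ids SNP ids of one gene (at least one).
#' @param panel A `ref_panel` object.
#' @param r2_threshold Coverage threshold in (0, 1] (default 0.8).
#' @param positions Optional named vector of genomic positions used for
#'   tie-breaking.
#' @return A `tag_set` list: `tags` (ordered tag ids), `coverage` (tibble
#'   `snp_id`, `tag_id`, `r2` for non-tag SNPs), `r2_threshold`,
#'   `snp_ids`.
#' @export
select_tag_snps <- function(snp_ids, panel, r2_threshold = 0.8,
                            positions = NULL) {
  if (length(snp_ids) == 0) {
    pi_abort("`snp_ids` must contain at least one SNP",
             class = "pathintegrate_error_domain")
  }
  if (r2_threshold <= 0 || r2_threshold > 1) {
    pi_abort("`r2_threshold` must lie in (0, 1]",
             class = "pathintegrate_error_config")
  }
  idx <- match(snp_ids, panel$snps$snp_id)
  in_panel <- !is.na(idx)
  poly <- rep(FALSE, length(snp_ids))
  if (any(in_panel)) {
    sub <- panel$haplotypes[, idx[in_panel], drop = FALSE]
    poly[in_panel] <- apply(sub, 2, sd) > 0
  }
  self_tagged <- snp_ids[!(in_panel & poly)]
  usable <- snp_ids[in_panel & poly]

  tags <- character(0)
  coverage <- tibble(snp_id = character(0), tag_id = character(0),
                     r2 = double(0))
  if (length(usable) > 0) {
    mat <- panel$haplotypes[, idx[match(usable, snp_ids)], drop = FALSE]
    r2 <- suppressWarnings(cor(mat)^2)
    dimnames(r2) <- list(usable, usable)
    covers <- r2 >= r2_threshold
    diag(covers) <- TRUE
    pos <- if (!is.null(positions)) {
      as.double(positions[usable])
    } else {
      seq_along(usable)
    }
    uncovered <- rep(TRUE, length(usable))
    while (any(uncovered)) {
      gain <- colSums(covers[uncovered, , drop = FALSE])
      best <- which(gain == max(gain))
      if (length(best) > 1) {
        best <- best[order(pos[best], usable[best])][1]
      }
      tags <- c(tags, usable[best])
      uncovered <- uncovered & !covers[, best]
    }
    non_tags <- setdiff(usable, tags)
    if (length(non_tags) > 0) {
      cover_tag <- map_chr(non_tags, function(s) {
        cand <- tags[covers[s, tags]]
        cand[which.max(r2[s, cand])]
      })
      coverage <- tibble(
        snp_id = non_tags,
        tag_id = cover_tag,
        r2 = r2[cbind(non_tags, cover_tag)]
      )
    }
  }
  structure(
    list(tags = c(tags, self_tagged), coverage = coverage,
         r2_threshold = r2_threshold, snp_ids = snp_ids),
    class = "tag_set"
  )
}

#' Gene-wise association p-values by the minimum-p rule over tagSNPs
#'
#' For each gene the gene-wise association p-value is the smallest
#' trend-test p-value among its tagSNPs. Genes with no mapped SNPs do not
#' appear in the output.
#'
#' @param assignment SNP-to-gene assignment from [map_snps_to_genes()].
#' @param snp_pvalues Tibble with columns `snp_id`, `p_value` (e.g. from
#'   [snp_trend_tests()]).
#' @param tagsets Named list of `tag_set` objects, one per gene.
#' @return A tibble with columns `gene_id`, `p_gwas`, `top_snp_id`,
#'   `n_snps`, `n_tags`.
#' @export
gene_wise_association <- function(assignment, snp_pvalues, tagsets) {
  pmap_df <- snp_pvalues$p_value
  names(pmap_df) <- snp_pvalues$snp_id
  n_snps_of <- table(assignment$gene_id)
  rows <- imap(tagsets, function(ts, gid) {
    p <- pmap_df[ts$tags]
    if (anyNA(p)) {
      pi_abort(
        paste0("tagSNP without a p-value in gene ", gid, ": ",
               paste(ts$tags[is.na(p)], collapse = ",")),
        class = "pathintegrate_error_consistency"
      )
    }
    best <- which.min(p)
    tibble(
      gene_id = gid,
      p_gwas = unname(p[best]),
      top_snp_id = ts$tags[best],
      n_snps = as.integer(n_snps_of[gid] %||% length(ts$snp_ids)),
      n_tags = length(ts$tags)
    )
  })
  arrange(bind_rows(rows), .data$gene_id)
}

#' GWAS gene scores: QC, trend tests, mapping, tagging, minimum-p
#'
#' Runs the full genotype arm: SNP QC, per-SNP Cochran-Armitage trend
#' tests, window-based SNP-to-gene mapping, per-gene greedy tagSNP
#' selection against the reference panel, and the minimum-p rule over
#' tagSNPs.
#'
#' @param genotypes A `genotype_data` object.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param panel A `ref_panel` object.
#' @param thresholds A [qc_thresholds()] object.
#' @param window_bp SNP-to-gene mapping window (default 50000).
#' @param r2_threshold Tagging r-squared threshold (default 0.8).
#' @param hwe_in Samples used for the HWE test (see [snp_qc()]).
#' @return A tibble of gene scores (see [gene_wise_association()]) with
#'   attributes `qc_report`, `snp_tests`, and `n_genes_scored`.
#' @export
gwas_gene_scores <- function(genotypes, annotation, panel,
                             thresholds = qc_thresholds(),
                             window_bp = 50000, r2_threshold = 0.8,
                             hwe_in = c("controls", "all")) {
  hwe_in <- match.arg(hwe_in)
  qc <- snp_qc(genotypes, thresholds, hwe_in = hwe_in)
  tests <- snp_trend_tests(qc$dataset)
  defined <- !is.na(tests$p_value)
  if (any(!defined)) {
    warn(sprintf("%d SNPs with undefined trend statistic dropped",
                 sum(!defined)))
  }
  snps <- qc$dataset$snps[defined, , drop = FALSE]
  tests <- tests[defined, , drop = FALSE]
  if (length(intersect(snps$snp_id, panel$snps$snp_id)) == 0) {
    pi_abort("no overlapping SNP ids between study data and panel",
             class = "pathintegrate_error_consistency"
    )
  }
  assignment <- map_snps_to_genes(snps, annotation, window_bp = window_bp)
  positions <- setNames(snps$pos, snps$snp_id)
  by_gene <- split(assignment$snp_id, assignment$gene_id)
  tagsets <- map(by_gene, function(ids) {
    select_tag_snps(ids, panel, r2_threshold = r2_threshold,
                    positions = positions)
  })
  scores <- gene_wise_association(assignment, tests, tagsets)
  attr(scores, "qc_report") <- qc$report
  attr(scores, "snp_tests") <- tests
  attr(scores, "n_genes_scored") <- nrow(scores)
  scores
}
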