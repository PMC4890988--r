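# Genotype arm: HWE, trend test, QC, mapping, LD r2, tagging, min-p.

test_that("Hardy-Weinberg test matches hand-computed chi-square values", {
  p <- hwe_test(c(25, 50, 25))
  expect_equal(as.numeric(p), 1)              # exact HWE proportions
  p <- hwe_test(c(30, 40, 30))
  # oracle: p-hat = 0.5, E = (25, 50, 25), chi-square = 1 + 2 + 1 = 4
  expect_equal(as.numeric(p), pchisq(4, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  p <- hwe_test(c(50, 0, 0))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "monomorphic"))
  expect_error(hwe_test(c(0, 0, 0)), class = "pathintegrate_error_domain")
})

test_that("exact HWE test agrees with brute-force conditional enumeration", {
  brute <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    n_a <- 2 * n_aa + n_ab
    rare <- min(n_a, 2 * n - n_a)
    hets <- seq(rare %% 2, rare, by = 2)
    pr <- vapply(hets, function(h) {
      hom_a <- (n_a - h) / 2
      hom_b <- n - h - hom_a
      exp(lgamma(n + 1) - lgamma(hom_a + 1) - lgamma(h + 1) -
            lgamma(hom_b + 1) + h * log(2) +
            lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1))
    }, numeric(1))
    sum(pr[pr <= pr[hets == n_ab] * (1 + 1e-12)])
  }
  cases <- list(c(3, 1, 1), c(10, 2, 8), c(5, 5, 5), c(1, 9, 1), c(40, 12, 3))
  for (cc in cases) {
    expect_equal(as.numeric(hwe_test(cc, method = "exact")),
                 brute(cc[1], cc[2], cc[3]), tolerance = 1e-10)
  }
})

test_that("Cochran-Armitage trend test matches its formula and a reference implementation", {
  res <- cochran_armitage_trend(c(10, 20, 10), c(10, 20, 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- cochran_armitage_trend(c(10, 15, 25), c(20, 15, 15))
  expect_equal(res$statistic, 5.797, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0160, tolerance = 1e-2)
  ref <- suppressWarnings(
    stats::prop.trend.test(c(10, 15, 25), c(30, 30, 40), score = 0:2)
  )
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)

  doubled <- cochran_armitage_trend(2 * c(10, 15, 25), 2 * c(20, 15, 15))
  expect_gt(doubled$statistic, res$statistic)
  expect_lt(doubled$p_value, res$p_value)

  expect_error(cochran_armitage_trend(c(10, 0, 0), c(20, 0, 0)),
               class = "pathintegrate_error_degenerate")
})

test_that("trend test matches direct formula evaluation on random tables", {
  withr::local_seed(71)
  for (i in 1:100) {
    repeat {
      r <- rpois(3, 15)
      s <- rpois(3, 15)
      n <- r + s
      ok <- sum(r) > 0 && sum(s) > 0 &&
        (sum(n) * sum(0:2 * 0:2 * n) - sum(0:2 * n)^2) > 0
      if (ok) break
    }
    mine <- cochran_armitage_trend(r, s)
    orc <- ca_trend_oracle(r, s)
    expect_equal(mine$statistic, orc$statistic, tolerance = 1e-12)
    expect_equal(mine$p_value, orc$p_value, tolerance = 1e-12)
  }
})

test_that("snp_qc applies the three filters exactly and reports reasons", {
  # 100 samples; each bad SNP violates exactly one filter
  n <- 100
  phen <- rep(c("case", "control"), each = 50)
  snp_maf <- c(rep(0L, 99), 1L)                                # MAF 0.005
  snp_hwe <- rep(c(0L, 2L), c(60, 40))                         # no hets
  snp_cr <- c(rep(NA_integer_, 90), rep(1L, 10))               # call rate 0.1
  # clean SNPs built so cases AND controls each sit in HWE proportions
  snp_ok1 <- c(rep(0:2, c(12, 26, 12)), rep(0:2, c(13, 24, 13)))
  snp_ok2 <- c(rep(0:2, c(18, 24, 8)), rep(0:2, c(18, 24, 8)))
  calls <- cbind(snp_maf, snp_hwe, snp_cr, snp_ok1, snp_ok2)
  colnames(calls) <- paste0("snp", 1:5)
  ds <- make_genotypes(calls, phen)
  out <- snp_qc(ds, qc_thresholds())
  expect_equal(out$dataset$snps$snp_id, c("snp4", "snp5"))
  rep_ <- out$report
  expect_equal(rep_$reasons[1], "low_maf")
  expect_match(rep_$reasons[2], "hwe_fail")
  expect_match(rep_$reasons[3], "low_call_rate")
  expect_equal(attr(rep_, "n_in"), 5)
  expect_equal(attr(rep_, "n_out"), 2)
  expect_identical(rep_$pass, rep_$reasons == "")

  # vacuous thresholds remove nothing
  all_pass <- snp_qc(ds, qc_thresholds(0, 0, 0))
  expect_equal(nrow(all_pass$dataset$snps), 5)

  # nothing surviving is an explicit error
  expect_error(snp_qc(ds, qc_thresholds(maf_min = 0.6)),
               class = "pathintegrate_error_empty_qc")
})

test_that("snp_qc agrees with a direct recomputation oracle and is idempotent", {
  withr::local_seed(19)
  n <- 120
  m <- 200
  calls <- matrix(rbinom(n * m, 2, runif(m, 0.005, 0.4)[rep(1:m, each = n)]),
                  n, m)
  calls[runif(n * m) < 0.05] <- NA_integer_
  colnames(calls) <- sprintf("s%03d", 1:m)
  ds <- make_genotypes(calls, rep(c("case", "control"), each = 60))
  th <- qc_thresholds(maf_min = 0.05, hwe_p_min = 0.01, call_rate_min = 0.9)
  out <- snp_qc(ds, th)

  # oracle: recompute the three statistics per SNP from scratch
  ctl <- calls[61:120, ]
  keep_oracle <- vapply(1:m, function(j) {
    g <- calls[, j]
    cr <- mean(!is.na(g))
    maf <- min(mean(g, na.rm = TRUE) / 2, 1 - mean(g, na.rm = TRUE) / 2)
    cnt <- table(factor(ctl[, j], levels = 0:2))
    hp <- as.numeric(hwe_test(as.integer(cnt)))
    maf >= th$maf_min && hp >= th$hwe_p_min && cr >= th$call_rate_min
  }, logical(1))
  expect_equal(out$dataset$snps$snp_id, colnames(calls)[keep_oracle])

  # idempotence: re-filtering the filtered dataset removes nothing
  again <- snp_qc(out$dataset, th)
  expect_equal(again$dataset$snps$snp_id, out$dataset$snps$snp_id)
})

test_that("SNP-to-gene mapping honors the inclusive 50 kb window on both sides", {
  ann <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "1",
                        start = c(100000L, 160000L), end = c(105000L, 165000L))
  snps <- tibble::tibble(
    snp_id = c("at_edge", "just_out", "inside", "in_overlap", "other_chr"),
    chrom = c("1", "1", "1", "1", "1"),
    pos = c(50000L, 49999L, 102000L, 130000L, 900000L)
  )
  asg <- map_snps_to_genes(snps, ann, window_bp = 50000)
  expect_true(all(c("at_edge", "inside") %in%
                    asg$snp_id[asg$gene_id == "gA"]))
  expect_false("just_out" %in% asg$snp_id)
  # overlap of the two windows: mapped to both genes
  expect_setequal(asg$gene_id[asg$snp_id == "in_overlap"], c("gA", "gB"))
  expect_true(all(c("just_out", "other_chr") %in% attr(asg, "unmapped")))

  snps_bad <- dplyr::mutate(snps, chrom = "7")
  expect_error(map_snps_to_genes(snps_bad, ann),
               class = "pathintegrate_error_chrom")
  expect_error(map_snps_to_genes(snps_bad, ann), "7")
})

test_that("panel r-squared equals the haplotype-frequency formula", {
  # independence: equal haplotype counts
  panel <- make_panel(haps_from_counts(25, 25, 25, 25))
  expect_equal(pairwise_r2(panel, "snp01", "snp02"), 0)
  expect_equal(pairwise_r2(panel, "snp01", "snp01"), 1)
  # AB=40, Ab=10, aB=10, ab=40: D = 0.15, r2 = 0.0225 / 0.0625 = 0.36
  panel <- make_panel(haps_from_counts(40, 10, 10, 40))
  expect_equal(pairwise_r2(panel, "snp01", "snp02"), 0.36, tolerance = 1e-12)

  mono <- make_panel(cbind(rep(1, 50), rbinom(50, 1, 0.5)))
  expect_error(pairwise_r2(mono, "snp01", "snp02"),
               class = "pathintegrate_error_monomorphic")
})

test_that("greedy tag selection picks covering hubs and self-tags panel orphans", {
  one <- select_tag_snps("only", make_panel(cbind(rbinom(100, 1, 0.4)), "only"))
  expect_equal(one$tags, "only")

  # b and c are copies of a with disjoint 4% XOR flips: exactly,
  # r2(a,b) = r2(a,c) = 0.92^2 = 0.8464 and r2(b,c) = 0.84^2 = 0.7056,
  # so a covers both but b does not cover c
  n <- 4000
  i <- seq_len(n)
  a <- i %% 2L
  b <- ifelse(i %% 25L == 0L, 1L - a, a)
  c_ <- ifelse(i %% 25L == 1L, 1L - a, a)
  hap <- cbind(a = a, b = b, c = c_)
  panel <- make_panel(hap, c("a", "b", "c"))
  r2_ab <- pairwise_r2(panel, "a", "b")
  r2_bc <- pairwise_r2(panel, "b", "c")
  expect_gt(r2_ab, 0.8)
  expect_lt(r2_bc, 0.8)
  ts <- select_tag_snps(c("a", "b", "c"), panel,
                        positions = c(a = 1, b = 2, c = 3))
  expect_equal(ts$tags, "a")
  expect_setequal(ts$coverage$snp_id, c("b", "c"))
  expect_true(all(ts$coverage$r2 >= 0.8))

  # full redundancy: identical columns collapse to a single tag
  same <- matrix(rep(rbinom(200, 1, 0.3), 4), ncol = 4)
  ts <- select_tag_snps(paste0("s", 1:4), make_panel(same, paste0("s", 1:4)))
  expect_length(ts$tags, 1)

  # SNP absent from the panel, and monomorphic-in-panel SNP: own tags
  hap2 <- cbind(x = rbinom(200, 1, 0.4), y = rep(0L, 200))
  ts <- select_tag_snps(c("x", "y", "ghost"), make_panel(hap2, c("x", "y")))
  expect_setequal(ts$tags, c("x", "y", "ghost"))

  expect_error(select_tag_snps(character(0), panel),
               class = "pathintegrate_error_domain")
})

test_that("greedy cover is valid and near-optimal on random instances", {
  withr::local_seed(33)
  for (i in 1:40) {
    m <- sample(2:8, 1)
    n <- 600
    base <- rbinom(n, 1, runif(1, 0.2, 0.5))
    hap <- sapply(seq_len(m), function(j) {
      rate <- runif(1, 0, 0.6)
      ifelse(runif(n) < rate, rbinom(n, 1, 0.4), base)
    })
    ids <- sprintf("s%02d", seq_len(m))
    panel <- make_panel(hap, ids)
    keep <- apply(hap, 2, sd) > 0
    if (!all(keep)) next
    ts <- select_tag_snps(ids, panel, positions = setNames(seq_len(m), ids))
    r2 <- cor(hap)^2
    covers <- r2 >= 0.8
    diag(covers) <- TRUE
    # validity: every non-tag SNP covered by some tag at r2 >= 0.8 (exact)
    for (s_id in setdiff(ids, ts$tags)) {
      expect_true(any(covers[match(s_id, ids), match(ts$tags, ids)]))
    }
    # near-optimality: greedy size <= exhaustive minimum + 1
    expect_lte(length(ts$tags), min_cover_size(covers) + 1)
  }
})

test_that("gene-wise score is the exact minimum over tagSNP p-values", {
  pvals <- tibble::tibble(snp_id = c("t1", "t2", "t3"),
                          p_value = c(0.5, 0.01, 0.2))
  asg <- tibble::tibble(snp_id = c("t1", "t2", "t3"),
                        gene_id = "g1", chrom = "1", pos = 1:3)
  ts <- structure(list(tags = c("t1", "t2", "t3"),
                       coverage = tibble::tibble(),
                       r2_threshold = 0.8, snp_ids = c("t1", "t2", "t3")),
                  class = "tag_set")
  out <- gene_wise_association(asg, pvals, list(g1 = ts))
  expect_equal(out$p_gwas, 0.01)
  expect_equal(out$top_snp_id, "t2")
  expect_equal(out$n_tags, 3)

  # singleton
  ts1 <- structure(list(tags = "t1", coverage = tibble::tibble(),
                        r2_threshold = 0.8, snp_ids = "t1"),
                   class = "tag_set")
  out <- gene_wise_association(asg[1, ], pvals[1, ], list(g1 = ts1))
  expect_equal(out$p_gwas, 0.5)

  # missing tag p-value is a consistency error
  expect_error(
    gene_wise_association(asg, pvals[1:2, ], list(g1 = ts)),
    class = "pathintegrate_error_consistency"
  )
})

test_that("full GWAS arm scores match brute-force minima and dominate tag p-values", {
  st <- simulate_study(tiny_config(seed = 21))
  scores <- suppressWarnings(
    gwas_gene_scores(st$genotypes, st$annotation, st$panel)
  )
  qc <- snp_qc(st$genotypes)
  tests <- snp_trend_tests(qc$dataset)
  defined <- tests[!is.na(tests$p_value), ]
  pmap_ <- setNames(defined$p_value, defined$snp_id)
  snps <- qc$dataset$snps[qc$dataset$snps$snp_id %in% defined$snp_id, ]
  asg <- map_snps_to_genes(snps, st$annotation)
  positions <- setNames(snps$pos, snps$snp_id)
  withr::local_seed(3)
  for (g in sample(scores$gene_id, 10)) {
    ids <- asg$snp_id[asg$gene_id == g]
    ts <- select_tag_snps(ids, st$panel, positions = positions)
    # min-p dominance: the gene p equals the brute-force minimum over tags
    expect_equal(scores$p_gwas[scores$gene_id == g],
                 min(pmap_[ts$tags]))
  }
})

test_that("trend-test p-values are uniform under the global null", {
  cfg <- null_config(
    seed = 13, n_cases = 300, n_controls = 300, n_genes = 1250,
    snps_per_gene = c(4, 4), ld_block_rho = 0, maf_range = c(0.1, 0.5),
    missing_rate = 0, n_panel = 10
  )
  g <- simulate_genotypes(cfg, generate_annotation(cfg))
  p <- snp_trend_tests(g$genotypes)$p_value
  p <- p[!is.na(p)]
  expect_gte(length(p), 4900)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # empirical type-I error at alpha = 0.05 within the 99% binomial band
  n <- length(p)
  hits <- sum(p < 0.05)
  expect_gte(hits, qbinom(0.005, n, 0.05))
  expect_lte(hits, qbinom(0.995, n, 0.05))
})
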