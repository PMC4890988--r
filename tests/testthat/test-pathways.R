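# Pathway inference: size filter, Fisher scores, permutation null, FDR,
# the three-mode comparison.

test_that("size filter keeps the inclusive 5-200 range and matches a recount", {
  coll <- tibble::tibble(
    pathway_id = paste0("p", 1:4),
    name = paste0("p", 1:4),
    genes = list(paste0("g", 1:4), paste0("g", 1:5),
                 paste0("g", 1:200), paste0("g", 1:201))
  )
  out <- filter_pathways_by_size(coll)
  expect_equal(out$pathway_id, c("p2", "p3"))
  expect_equal(filter_pathways_by_size(coll, 1, Inf), coll)

  withr::local_seed(14)
  rand <- tibble::tibble(
    pathway_id = paste0("r", 1:50), name = paste0("r", 1:50),
    genes = lapply(sample(1:30, 50, TRUE), function(k) paste0("g", 1:k))
  )
  out <- filter_pathways_by_size(rand, 5, 20)
  expect_equal(out$pathway_id,
               rand$pathway_id[lengths(rand$genes) >= 5 &
                                 lengths(rand$genes) <= 20])
})

test_that("pathway score is the Fisher sum over scored members", {
  expect_equal(pathway_association_score(rep(1, 5)), 0)
  expect_equal(pathway_association_score(c(0.01, 0.1)),
               -2 * (log(0.01) + log(0.1)), tolerance = 1e-12)
  expect_equal(pathway_association_score(c(0.01, 0.1)), 13.8155,
               tolerance = 1e-3)
  expect_equal(pathway_association_score(c(0.01, 0.1, 1)),
               pathway_association_score(c(0.01, 0.1)))
  expect_error(pathway_association_score(numeric(0)),
               class = "pathintegrate_error_domain")
})

test_that("permutation p-value matches exhaustive enumeration on a small universe", {
  ps <- c(a = 0.01, b = 0.1, c = 0.5, d = 0.9)
  s_true <- pathway_association_score(ps[c("a", "b")])
  # oracle: all C(4,2) = 6 subsets
  w <- -2 * log(ps)
  orc <- exhaustive_perm(w, 2, s_true)
  expect_equal(orc$p_gt, 0)       # no subset strictly exceeds
  expect_equal(orc$p_ge, 1 / 6)   # only the pathway itself ties

  out <- permutation_pvalue(s_true, 2, ps, n_perm = 3000, seed = 99)
  expect_equal(out$p_permutation, 0)
  out_c <- permutation_pvalue(s_true, 2, ps, n_perm = 3000, seed = 99,
                              tie_rule = "add_one")
  # non-strict exceedance fraction converges to 1/6
  expect_equal(out_c$n_exceed / out_c$n_perm, 1 / 6,
               tolerance = 3 * sqrt((1 / 6) * (5 / 6) / 3000))

  # degenerate resampling: pathway = entire universe, strict rule gives 0
  s_all <- pathway_association_score(ps)
  out <- permutation_pvalue(s_all, 4, ps, n_perm = 500, seed = 1)
  expect_equal(out$p_permutation, 0)

  # determinism under a fixed seed
  a <- permutation_pvalue(10, 3, ps, n_perm = 1000, seed = 7)
  b <- permutation_pvalue(10, 3, ps, n_perm = 1000, seed = 7)
  expect_identical(a, b)

  expect_error(permutation_pvalue(10, 5, ps, n_perm = 10, seed = 1),
               class = "pathintegrate_error_domain")
  expect_error(permutation_pvalue(10, 2, ps, n_perm = 0, seed = 1),
               class = "pathintegrate_error_config")
})

test_that("BH q-values match the worked vector and the reference step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 6)), rep(1, 6))
  expect_equal(adjust_fdr(numeric(0)), numeric(0))

  withr::local_seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-15)
  }

  # order preservation: q sorted by p is non-decreasing, and equal p
  # values share the same q
  p <- round(runif(100), 2)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(tapply(q, p, function(v) diff(range(v))) == 0))
})

test_that("Storey q-values are valid, monotone, and no larger than BH", {
  withr::local_seed(43)
  p <- c(runif(400), runif(100)^4)
  q_bh <- adjust_fdr(p)
  q_st <- adjust_fdr(p, method = "storey")
  expect_true(all(q_st >= 0 & q_st <= 1))
  expect_true(all(diff(q_st[order(p)]) >= -1e-12))
  expect_true(all(q_st <= q_bh + 1e-12))
})

test_that("run_pathway_analysis wires scores, permutation and FDR together", {
  st <- simulate_study(tiny_config(seed = 10))
  gw <- suppressWarnings(gwas_gene_scores(st$genotypes, st$annotation, st$panel))
  ex <- differential_expression_ttest(st$expression)
  gs <- build_integrated_scores(gw, ex)

  pa <- run_pathway_analysis(gs, st$pathways, mode = "integrated",
                             n_perm = 300, seed = 2)
  res <- tidy(pa)
  expect_true(all(res$s_true >= 0))
  expect_true(all(res$p_perm >= 0 & res$p_perm <= 1))
  expect_true(all(res$q >= res$p_perm & res$q <= 1))
  expect_identical(res$significant, res$q < 0.05)
  expect_false(is.unsorted(res$p_perm))
  # s_true recomputable from the gene table (oracle)
  for (i in 1:3) {
    genes <- st$pathways$genes[[match(res$pathway_id[i], st$pathways$pathway_id)]]
    p_members <- gs$p_combined[gs$gene_id %in% genes & !is.na(gs$p_combined)]
    expect_equal(res$s_true[i], pathway_association_score(p_members),
                 tolerance = 1e-9)
  }
  g <- glance(pa)
  expect_equal(g$n_pathways, nrow(res))
  expect_equal(g$mode, "integrated")

  # determinism and invariance to pathway evaluation order
  pa2 <- run_pathway_analysis(gs, st$pathways, mode = "integrated",
                              n_perm = 300, seed = 2)
  expect_identical(tidy(pa), tidy(pa2))
  shuffled <- st$pathways[rev(seq_len(nrow(st$pathways))), ]
  pa3 <- run_pathway_analysis(gs, shuffled, mode = "integrated",
                              n_perm = 300, seed = 2)
  expect_identical(tidy(pa), tidy(pa3))

  # error contracts
  expect_error(run_pathway_analysis(gs, st$pathways, mode = "integrated",
                                    n_perm = 0, seed = 1),
               class = "pathintegrate_error_config")
  expect_error(run_pathway_analysis(dplyr::select(gs, -"p_combined"), st$pathways,
                                    mode = "integrated", n_perm = 10),
               "p_combined")
  off <- dplyr::mutate(gs, gene_id = paste0("zz_", gene_id))
  expect_error(
    suppressWarnings(run_pathway_analysis(off, st$pathways,
                                          mode = "integrated", n_perm = 10)),
    class = "pathintegrate_error_empty"
  )
})

test_that("mode comparison performs exact set algebra", {
  ids <- sprintf("p%02d", 1:12)
  qs <- setNames(rep(0.5, 12), ids)
  mk <- function(sig_ids, mode) {
    q <- ifelse(ids %in% sig_ids, 0.01, 0.5)
    fake_analysis(ids, q, mode)
  }
  # identical inputs: integrated-only set empty
  same <- compare_modes(mk(ids[1:4], "gwas"), mk(ids[1:4], "expression"),
                        mk(ids[1:4], "integrated"))
  expect_length(same$integrated_only, 0)
  expect_equal(sort(same$all_three), ids[1:4])

  # disjoint significant sets: all intersections empty
  disj <- compare_modes(mk(ids[1:2], "gwas"), mk(ids[3:4], "expression"),
                        mk(ids[5:6], "integrated"))
  expect_length(disj$all_three, 0)
  expect_true(all(lengths(disj$pairwise) == 0))
  expect_equal(sort(disj$integrated_only), ids[5:6])

  # random sets against brute-force set operations
  withr::local_seed(51)
  for (i in 1:10) {
    sg <- sample(ids, sample(0:8, 1))
    se <- sample(ids, sample(0:8, 1))
    si <- sample(ids, sample(0:8, 1))
    cmp <- compare_modes(mk(sg, "gwas"), mk(se, "expression"),
                         mk(si, "integrated"))
    expect_setequal(cmp$all_three, intersect(intersect(sg, se), si))
    expect_setequal(cmp$integrated_only, setdiff(si, union(sg, se)))
    expect_setequal(cmp$pairwise$gwas_expression, intersect(sg, se))
    gl <- glance(cmp)
    expect_equal(gl$n_shared_all, length(intersect(intersect(sg, se), si)))
    # inclusion-exclusion consistency on the membership table
    m <- tidy(cmp)
    expect_equal(sum(m$sig_integrated), length(si))
    expect_equal(sum(m$category == "integrated_only"),
                 length(setdiff(si, union(sg, se))))
  }

  expect_error(
    compare_modes(mk(ids[1:2], "gwas"), mk(ids[1:2], "expression"),
                  fake_analysis(sprintf("x%02d", 1:12), rep(0.5, 12))),
    class = "pathintegrate_error_consistency"
  )
})

test_that("with joint planted signal, integration dominates on average and FDR holds", {
  # fixture in which every planted gene carries both genotype and
  # expression signal (full DE/causal overlap)
  tp <- matrix(NA_real_, 3, 20,
               dimnames = list(c("gwas", "expression", "integrated"), NULL))
  fdp <- numeric(20)
  for (s in 1:20) {
    st <- simulate_study(simulation_config(seed = s, de_causal_overlap = 1))
    gw <- suppressWarnings(
      gwas_gene_scores(st$genotypes, st$annotation, st$panel)
    )
    ex <- differential_expression_ttest(st$expression)
    gs <- build_integrated_scores(gw, ex)
    for (m in rownames(tp)) {
      pa <- run_pathway_analysis(gs, st$pathways, mode = m,
                                 n_perm = 1000, seed = s)
      sig <- tidy(pa)$pathway_id[tidy(pa)$significant]
      tp[m, s] <- sum(st$truth$enriched_pathway_ids %in% sig)
      if (m == "integrated") {
        fdp[s] <- if (length(sig) > 0) {
          sum(!sig %in% st$truth$enriched_pathway_ids) / length(sig)
        } else 0
      }
    }
  }
  # power ordering, averaged over the 20 replicates
  expect_gte(mean(tp["integrated", ]), mean(tp["gwas", ]))
  expect_gte(mean(tp["integrated", ]), mean(tp["expression", ]))
  # empirical false discovery proportion at q < 0.05 stays controlled
  expect_lte(mean(fdp), 0.10)
})
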