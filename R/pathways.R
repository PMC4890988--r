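# Pathway-level inference: Fisher pathway scores, a gene-resampling
# permutation null, FDR adjustment, significance calls, and the
# comparison of the three analysis modes.

# Relative tolerance used when comparing permuted scores to the observed
# score: sums of the same weights in a different order can differ by
# floating-point noise, which must not count as an exceedance.
SCORE_TOL <- 1e-9

#' Filter a pathway collection by size
#'
#' Keeps pathways whose full membership count lies in
#' `[min_genes, max_genes]` (inclusive). Size is measured on the full
#' member list, not on the subset that happens to have gene scores.
#'
#' @param collection Tibble with columns `pathway_id`, `name`, and
#'   list-column `genes`.
#' @param min_genes,max_genes Inclusive size bounds (defaults 5 and 200,
#'   the usual guard against overly narrow or broad functional
#'   categories).
#' @return The filtered collection tibble.
#' @export
filter_pathways_by_size <- function(collection, min_genes = 5,
                                    max_genes = 200) {
  sizes <- lengths(collection$genes)
  collection[sizes >= min_genes & sizes <= max_genes, , drop = FALSE]
}

#' Fisher pathway association score
#'
#' `S = -2 * sum(log(p))` over the member genes that carry a gene
#' association p-value.
#'
#' @param member_gene_ps P-values of the scored member genes (at least
#'   one).
#' @return The pathway score `S` (non-negative).
#' @examples
#' pathway_association_score(c(0.01, 0.1))  # ~ 13.8155
#' @export
pathway_association_score <- function(member_gene_ps) {
  if (length(member_gene_ps) == 0) {
    pi_abort("at least one scored member gene is required",
             class = "pathintegrate_error_domain")
  }
  p <- clamp_pvalues(member_gene_ps)
  -2 * sum(log(p))
}

# Permutation core over a precomputed weight vector w = -2 log p.
perm_exceed_counts <- function(w, k, n_perm, s_true) {
  n <- length(w)
  s_random <- vapply(seq_len(n_perm),
                     function(i) sum(w[sample.int(n, k)]),
                     numeric(1))
  tol <- SCORE_TOL * max(1, abs(s_true))
  list(
    n_gt = sum(s_random - s_true > tol),
    n_ge = sum(s_random - s_true > -tol),
    null_mean = mean(s_random),
    null_sd = sd(s_random)
  )
}

#' Permutation p-value for one pathway score
#'
#' Each replicate samples `n_scored` genes without replacement from the
#' universe of scored genes, recomputes the Fisher pathway score, and the
#' p-value is the fraction of replicates whose score exceeds the observed
#' one. The default tie rule is the strict count
#' `#(S_random > S_true) / n_perm`; the `"add_one"` rule
#' `(#(S_random >= S_true) + 1) / (n_perm + 1)` is offered because strict
#' zero p-values are statistically improper.
#'
#' @param s_true Observed pathway score.
#' @param n_scored Number of genes that entered the observed score.
#' @param universe_gene_ps Named vector of gene p-values over the
#'   non-redundant union of scored genes across all analyzed pathways.
#' @param n_perm Number of permutation replicates (default 100000).
#' @param seed Integer seed for this pathway's RNG substream.
#' @param tie_rule `"strict"` (default) or `"add_one"`.
#' @return A list: `p_permutation`, `n_exceed`, `n_perm`, `null_mean`,
#'   `null_sd`, `tie_rule`.
#' @export
permutation_pvalue <- function(s_true, n_scored, universe_gene_ps,
                               n_perm = 100000, seed = 1,
                               tie_rule = c("strict", "add_one")) {
  tie_rule <- match.arg(tie_rule)
  if (n_perm < 1) {
    pi_abort("`n_perm` must be at least 1", class = "pathintegrate_error_config")
  }
  if (n_scored > length(universe_gene_ps)) {
    pi_abort("`n_scored` exceeds the size of the gene universe",
             class = "pathintegrate_error_domain")
  }
  w <- -2 * log(clamp_pvalues(universe_gene_ps))
  cnt <- withr::with_seed(seed, perm_exceed_counts(w, n_scored, n_perm, s_true))
  p <- if (tie_rule == "strict") {
    cnt$n_gt / n_perm
  } else {
    (cnt$n_ge + 1) / (n_perm + 1)
  }
  list(
    p_permutation = p,
    n_exceed = if (tie_rule == "strict") cnt$n_gt else cnt$n_ge,
    n_perm = n_perm,
    null_mean = cnt$null_mean,
    null_sd = cnt$null_sd,
    tie_rule = tie_rule
  )
}

#' Adjust p-values for multiple testing
#'
#' The default is the Benjamini-Hochberg step-up procedure with
#' monotonicity enforcement; Storey's q-value (with a smoother-based
#' estimate of the null proportion pi0) is offered via
#' `method = "storey"`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` (default) or `"storey"`.
#' @return Vector of q-values in `[0, 1]`, in the input order.
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_fdr <- function(p_values, method = c("bh", "storey")) {
  method <- match.arg(method)
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    pi_abort("p-values must lie in [0, 1]", class = "pathintegrate_error_domain")
  }
  o <- order(p_values)
  ps <- p_values[o]
  pi0 <- 1
  if (method == "storey") {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p_values > l) / (1 - l), 0)
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- min(1, max(predict(fit, x = 0.95)$y, 1 / m))
  }
  q_sorted <- pmin(1, pi0 * ((m / seq_len(m)) * ps))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Run a pathway association analysis in one mode
#'
#' Applies the size filter, computes each pathway's Fisher score from its
#' scored member genes, assesses it against a gene-resampling permutation
#' null, adjusts for multiple testing, and flags significant pathways at
#' `q < q_threshold`. Each pathway draws its permutations from an RNG
#' substream derived deterministically from `(seed, pathway_id)`, so
#' results do not depend on pathway evaluation order.
#'
#' @param gene_scores Tibble of gene scores: for `mode = "gwas"` it must
#'   carry `p_gwas`, for `"expression"` `p_expr`, for `"integrated"`
#'   `p_combined` (genes with `NA` in the relevant column are unscored).
#' @param pathways Pathway collection tibble (`pathway_id`, `name`,
#'   list-column `genes`).
#' @param mode `"gwas"`, `"expression"`, or `"integrated"`.
#' @param n_perm Permutation replicates per pathway (default 100000).
#' @param seed Integer base seed.
#' @param min_genes,max_genes Pathway size filter (defaults 5 and 200).
#' @param tie_rule Permutation tie rule, see [permutation_pvalue()].
#' @param fdr_method FDR procedure, see [adjust_fdr()].
#' @param q_threshold Significance threshold on the q-value (default
#'   0.05).
#' @return A `pathway_analysis` object; `tidy()` returns the per-pathway
#'   results tibble (`pathway_id`, `name`, `n_members`, `n_scored`,
#'   `s_true`, `p_perm`, `q`, `significant`), sorted by
#'   (`p_perm`, `q`, `pathway_id`).
#' @export
run_pathway_analysis <- function(gene_scores, pathways,
                                 mode = c("gwas", "expression", "integrated"),
                                 n_perm = 100000, seed = 1,
                                 min_genes = 5, max_genes = 200,
                                 tie_rule = c("strict", "add_one"),
                                 fdr_method = c("bh", "storey"),
                                 q_threshold = 0.05) {
  mode <- match.arg(mode)
  tie_rule <- match.arg(tie_rule)
  fdr_method <- match.arg(fdr_method)
  if (n_perm < 1) {
    pi_abort("`n_perm` must be at least 1", class = "pathintegrate_error_config")
  }
  p_col <- switch(mode, gwas = "p_gwas", expression = "p_expr",
                  integrated = "p_combined")
  if (!p_col %in% names(gene_scores)) {
    pi_abort(sprintf("`gene_scores` lacks the `%s` column required for mode '%s'",
                     p_col, mode),
             class = "pathintegrate_error_domain")
  }
  scored <- gene_scores[!is.na(gene_scores[[p_col]]), ]
  gene_p <- setNames(scored[[p_col]], scored$gene_id)

  filtered <- filter_pathways_by_size(pathways, min_genes, max_genes)
  members <- map(filtered$genes, function(g) intersect(g, names(gene_p)))
  n_scored <- lengths(members)
  skipped <- filtered$pathway_id[n_scored == 0]
  if (length(skipped) > 0) {
    warn(sprintf("%d pathways without scored member genes skipped: %s",
                 length(skipped), paste(head(skipped, 5), collapse = ",")))
  }
  keep <- n_scored > 0
  if (!any(keep)) {
    pi_abort("no pathway has any scored member gene",
             class = "pathintegrate_error_empty")
  }
  filtered <- filtered[keep, , drop = FALSE]
  members <- members[keep]
  n_scored <- n_scored[keep]

  # canonical order: the permutation draws must not depend on the order
  # in which pathways were listed
  universe <- sort(unique(unlist(members)))
  w <- -2 * log(clamp_pvalues(gene_p[universe]))
  names(w) <- universe

  s_true <- map_dbl(members, function(g) sum(w[g]))
  perm <- pmap(
    list(filtered$pathway_id, s_true, n_scored),
    function(pid, s, k) {
      cnt <- withr::with_seed(
        substream_seed(seed, pid),
        perm_exceed_counts(w, k, n_perm, s)
      )
      if (tie_rule == "strict") cnt$n_gt / n_perm else
        (cnt$n_ge + 1) / (n_perm + 1)
    }
  )
  p_perm <- unlist(perm)
  q <- adjust_fdr(p_perm, method = fdr_method)
  results <- tibble(
    pathway_id = filtered$pathway_id,
    name = filtered$name,
    n_members = lengths(filtered$genes),
    n_scored = as.integer(n_scored),
    s_true = unname(s_true),
    p_perm = p_perm,
    q = q,
    significant = q < q_threshold
  )
  results <- arrange(results, .data$p_perm, .data$q, .data$pathway_id)
  structure(
    list(
      results = results, mode = mode, n_perm = n_perm, seed = seed,
      tie_rule = tie_rule, fdr_method = fdr_method,
      q_threshold = q_threshold, universe_size = length(universe),
      skipped = skipped
    ),
    class = "pathway_analysis"
  )
}

#' @export
print.pathway_analysis <- function(x, ...) {
  cat(sprintf(
    "<pathway_analysis> mode=%s: %d pathways, %d significant (q < %g), universe %d genes, %d permutations\n",
    x$mode, nrow(x$results), sum(x$results$significant), x$q_threshold,
    x$universe_size, x$n_perm
  ))
  print(head(x$results, 10))
  invisible(x)
}

#' Compare the significant pathway sets of the three analysis modes
#'
#' Computes the significant sets of the GWAS-only, expression-only, and
#' integrated analyses, all their intersections, and the
#' integrated-only ("novel") set: pathways the integration flags that
#' neither single-source analysis does.
#'
#' @param results_gwas,results_expr,results_integrated
#'   `pathway_analysis` objects over the same pathway collection.
#' @param q_threshold Significance threshold (default 0.05).
#' @return A `mode_comparison` object; `tidy()` gives the per-pathway
#'   membership table, `glance()` the set counts.
#' @export
compare_modes <- function(results_gwas, results_expr, results_integrated,
                          q_threshold = 0.05) {
  objs <- list(gwas = results_gwas, expression = results_expr,
               integrated = results_integrated)
  ids <- map(objs, function(o) sort(o$results$pathway_id))
  if (!identical(ids[[1]], ids[[2]]) || !identical(ids[[1]], ids[[3]])) {
    pi_abort("the three result sets cover different pathway universes",
             class = "pathintegrate_error_consistency")
  }
  sig <- map(objs, function(o) {
    o$results$pathway_id[o$results$q < q_threshold]
  })
  all_three <- Reduce(intersect, sig)
  integrated_only <- setdiff(sig$integrated, union(sig$gwas, sig$expression))
  membership <- tibble(
    pathway_id = ids[[1]],
    sig_gwas = ids[[1]] %in% sig$gwas,
    sig_expression = ids[[1]] %in% sig$expression,
    sig_integrated = ids[[1]] %in% sig$integrated
  )
  membership$category <- case_when(
    membership$sig_gwas & membership$sig_expression & membership$sig_integrated ~ "all_three",
    membership$sig_integrated & !membership$sig_gwas & !membership$sig_expression ~ "integrated_only",
    membership$sig_integrated ~ "integrated_and_one",
    membership$sig_gwas & membership$sig_expression ~ "gwas_and_expression",
    membership$sig_gwas ~ "gwas_only",
    membership$sig_expression ~ "expression_only",
    TRUE ~ "none"
  )
  structure(
    list(
      significant = sig,
      pairwise = list(
        gwas_expression = intersect(sig$gwas, sig$expression),
        gwas_integrated = intersect(sig$gwas, sig$integrated),
        expression_integrated = intersect(sig$expression, sig$integrated)
      ),
      all_three = all_three,
      integrated_only = integrated_only,
      membership = membership,
      q_threshold = q_threshold
    ),
    class = "mode_comparison"
  )
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf(
    "<mode_comparison> significant at q < %g: gwas %d, expression %d, integrated %d; shared by all %d; integrated-only %d\n",
    x$q_threshold, length(x$significant$gwas),
    length(x$significant$expression), length(x$significant$integrated),
    length(x$all_three), length(x$integrated_only)
  ))
  invisible(x)
}
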