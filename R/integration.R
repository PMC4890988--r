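# Fisher's combined probability test: the bridge from the two
# single-source gene p-values to one integrated gene association p-value.

#' Combine p-values by Fisher's method
#'
#' Computes the Fisher score `g = -2 * sum(log(p_j))` over `k` p-values
#' and the combined p-value as the upper tail of a chi-square distribution
#' with `2k` degrees of freedom at `g` (natural logarithm, which is what
#' makes the chi-square tail exact). Inputs are clamped to
#' `[1e-300, 1]` before the log so degenerate upstream values keep the
#' score finite and the ordering intact.
#'
#' @param p_values Numeric vector of `k >= 1` p-values in `[0, 1]`.
#' @return A list with elements `score` (`g`), `p_value` (combined), and
#'   `k`.
#' @examples
#' fisher_combine_pvalues(c(0.05, 0.05))  # g ~ 11.98, p ~ 0.0175
#' @export
fisher_combine_pvalues <- function(p_values) {
  if (length(p_values) == 0) {
    pi_abort("at least one p-value is required",
             class = "pathintegrate_error_domain")
  }
  p <- clamp_pvalues(p_values)
  g <- -2 * sum(log(p))
  list(
    score = g,
    p_value = pchisq(g, df = 2 * length(p), lower.tail = FALSE),
    k = length(p)
  )
}

# Vectorized k = 2 combination used for the gene table.
fisher_combine_k2_vec <- function(p1, p2) {
  g <- -2 * (log(pmax(p1, P_FLOOR)) + log(pmax(p2, P_FLOOR)))
  list(score = g, p_value = pchisq(g, df = 4, lower.tail = FALSE))
}

#' Build the integrated gene score table
#'
#' Joins the GWAS gene scores and the expression gene scores by gene id.
#' Genes present in both sources get a Fisher score and combined p-value
#' (k = 2); genes with a single evidence source are retained with an
#' `evidence` flag but carry no combined value (and are excluded from
#' integrated pathway scoring). Errors if the two gene universes are
#' disjoint.
#'
#' @param gwas Tibble with columns `gene_id`, `p_gwas` (from
#'   [gwas_gene_scores()]).
#' @param expr Tibble with columns `gene_id`, `p_expr` (from
#'   [differential_expression_ttest()]).
#' @return A tibble with columns `gene_id`, `p_gwas`, `p_expr`,
#'   `evidence` (`"both"`, `"gwas_only"`, `"expr_only"`), `score`,
#'   `p_combined`; attribute `n_both` holds the intersection size.
#' @export
build_integrated_scores <- function(gwas, expr) {
  if (!"p_gwas" %in% names(gwas) || !"p_expr" %in% names(expr)) {
    pi_abort("inputs must carry `p_gwas` and `p_expr` columns",
             class = "pathintegrate_error_domain")
  }
  n_both <- length(intersect(gwas$gene_id, expr$gene_id))
  if (n_both == 0) {
    pi_abort("no gene has both a GWAS and an expression p-value",
             class = "pathintegrate_error_empty_intersection")
  }
  tab <- full_join(
    select(gwas, "gene_id", "p_gwas"),
    select(expr, "gene_id", "p_expr"),
    by = "gene_id"
  )
  tab <- mutate(
    tab,
    evidence = case_when(
      !is.na(.data$p_gwas) & !is.na(.data$p_expr) ~ "both",
      !is.na(.data$p_gwas) ~ "gwas_only",
      TRUE ~ "expr_only"
    )
  )
  comb <- fisher_combine_k2_vec(tab$p_gwas, tab$p_expr)
  tab <- mutate(
    tab,
    score = ifelse(.data$evidence == "both", comb$score, NA_real_),
    p_combined = ifelse(.data$evidence == "both", comb$p_value, NA_real_)
  )
  tab <- arrange(tab, .data$gene_id)
  attr(tab, "n_both") <- n_both
  tab
}
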