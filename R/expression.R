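# Differential-expression gene scores from a normalized matrix with
# binary group labels. Normalization itself (e.g. RMA of raw array files)
# is upstream of this package; the matrix is consumed as-is.

#' Collapse probe-level expression to gene level
#'
#' Summarizes all probes mapped to a gene into one row per sample. The
#' default rule is the per-sample median across the gene's probes;
#' `"mean"` and `"max_mean_probe"` (keep the probe with the largest
#' overall mean) are offered. Probes without a gene mapping are dropped.
#'
#' @param dataset A probe-level `expression_data` object.
#' @param map Tibble with columns `probe_id`, `gene_id`.
#' @param rule Collapse rule: `"median"` (default), `"mean"`, or
#'   `"max_mean_probe"`.
#' @return A gene-level `expression_data` object.
#' @export
collapse_probes_to_genes <- function(dataset, map,
                                     rule = c("median", "mean",
                                              "max_mean_probe")) {
  stopifnot(inherits(dataset, "expression_data"))
  rule <- match.arg(rule)
  if (dataset$level == "gene") {
    warn("dataset is already gene-level; returning it unchanged")
    return(dataset)
  }
  if (nrow(map) == 0 || !all(c("probe_id", "gene_id") %in% names(map))) {
    pi_abort("`map` must be a non-empty tibble with probe_id and gene_id",
             class = "pathintegrate_error_domain")
  }
  map <- filter(map, .data$probe_id %in% rownames(dataset$values))
  if (nrow(map) == 0) {
    pi_abort("no probe of `map` is present in the dataset",
             class = "pathintegrate_error_domain")
  }
  by_gene <- split(map$probe_id, map$gene_id)
  rows <- map(by_gene, function(probes) {
    sub <- dataset$values[probes, , drop = FALSE]
    switch(rule,
      median = apply(sub, 2, median),
      mean = colMeans(sub),
      max_mean_probe = sub[which.max(rowMeans(sub)), ]
    )
  })
  values <- do.call(rbind, rows)
  rownames(values) <- names(by_gene)
  colnames(values) <- colnames(dataset$values)
  new_expression_data(values, dataset$groups, level = "gene")
}

#' Per-gene two-sample t-tests for differential expression
#'
#' Computes a two-sided two-sample t-test per gene between case and
#' control samples. The default is the Student (pooled-variance) test;
#' Welch's unequal-variance test is available via `variant = "welch"`.
#' Degenerate genes (zero variance in both groups) get p = 1 when the
#' group means are equal, or the smallest positive double when they
#' differ, and are flagged.
#'
#' @param dataset A gene-level `expression_data` object with at least two
#'   samples per group.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A tibble with columns `gene_id`, `p_expr`, `statistic`
#'   (case minus control), `mean_case`, `mean_control`, `degenerate`.
#' @examples
#' vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(vals) <- paste0("s", 1:6)
#' ds <- new_expression_data(
#'   vals,
#'   tibble::tibble(sample_id = paste0("s", 1:6),
#'                  group = rep(c("case", "control"), each = 3))
#' )
#' differential_expression_ttest(ds)
#' @export
differential_expression_ttest <- function(dataset,
                                          variant = c("student", "welch")) {
  stopifnot(inherits(dataset, "expression_data"))
  variant <- match.arg(variant)
  if (dataset$level != "gene") {
    pi_abort("dataset must be gene-level; collapse probes first",
             class = "pathintegrate_error_domain")
  }
  is_case <- dataset$groups$group == "case"
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) {
    pi_abort("at least two samples per group are required",
             class = "pathintegrate_error_domain")
  }
  x <- dataset$values[, is_case, drop = FALSE]
  y <- dataset$values[, !is_case, drop = FALSE]
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- se == 0
  stat <- ifelse(degenerate, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                 (m1 - m2) / se)
  p <- ifelse(
    degenerate,
    ifelse(m1 == m2, 1, .Machine$double.xmin),
    2 * pt(-abs((m1 - m2) / ifelse(se == 0, 1, se)), df = df)
  )
  tibble(
    gene_id = rownames(dataset$values),
    p_expr = unname(p),
    statistic = unname(stat),
    mean_case = unname(m1),
    mean_control = unname(m2),
    degenerate = unname(degenerate)
  )
}
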