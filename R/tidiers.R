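# broom-style accessors for the fitted result objects.

#' Tidy a pathway analysis
#'
#' @param x A `pathway_analysis` object.
#' @param ... Unused.
#' @return The per-pathway results tibble.
#' @method tidy pathway_analysis
#' @export
tidy.pathway_analysis <- function(x, ...) {
  x$results
}

#' One-row summary of a pathway analysis
#'
#' @param x A `pathway_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: mode, counts, universe size, permutation
#'   settings.
#' @method glance pathway_analysis
#' @export
glance.pathway_analysis <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_pathways = nrow(x$results),
    n_significant = sum(x$results$significant),
    universe_size = x$universe_size,
    n_perm = x$n_perm,
    tie_rule = x$tie_rule,
    fdr_method = x$fdr_method,
    q_threshold = x$q_threshold
  )
}

#' Tidy a mode comparison
#'
#' @param x A `mode_comparison` object.
#' @param ... Unused.
#' @return Per-pathway membership tibble with significance flags per mode
#'   and a set-algebra `category`.
#' @method tidy mode_comparison
#' @export
tidy.mode_comparison <- function(x, ...) {
  x$membership
}

#' One-row summary of a mode comparison
#'
#' @param x A `mode_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble of set sizes, including the pathways shared
#'   by all three modes and those found only by the integrated analysis.
#' @method glance mode_comparison
#' @export
glance.mode_comparison <- function(x, ...) {
  tibble(
    n_sig_gwas = length(x$significant$gwas),
    n_sig_expression = length(x$significant$expression),
    n_sig_integrated = length(x$significant$integrated),
    n_gwas_and_expression = length(x$pairwise$gwas_expression),
    n_shared_all = length(x$all_three),
    n_integrated_only = length(x$integrated_only),
    q_threshold = x$q_threshold
  )
}
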