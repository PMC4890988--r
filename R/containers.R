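# Lightweight S3 containers for the non-tabular inputs. Result tables are
# plain tibbles throughout.

#' Construct a case-control genotype dataset
#'
#' @param samples Tibble with columns `sample_id` and `phenotype`
#'   (`"case"`/`"control"`).
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`,
#'   `allele_major`, `allele_minor`.
#' @param calls Integer matrix, samples x SNPs, counting minor-allele
#'   copies (0/1/2), `NA` for missing.
#' @return A `genotype_data` object.
#' @export
new_genotype_data <- function(samples, snps, calls) {
  if (!all(c("sample_id", "phenotype") %in% names(samples))) {
    pi_abort("`samples` needs columns sample_id, phenotype")
  }
  if (!all(samples$phenotype %in% c("case", "control"))) {
    pi_abort("phenotype must be 'case' or 'control'")
  }
  if (anyDuplicated(snps$snp_id)) {
    pi_abort("SNP ids must be unique")
  }
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(snps)) {
    pi_abort("`calls` dimensions must match samples x snps")
  }
  ok <- calls %in% c(0L, 1L, 2L, NA_integer_)
  if (!all(ok)) {
    pi_abort("genotype calls must be 0, 1, 2 or NA")
  }
  structure(
    list(samples = as_tibble(samples), snps = as_tibble(snps), calls = calls),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf(
    "<genotype_data> %d samples (%d cases, %d controls) x %d SNPs\n",
    nrow(x$samples), sum(x$samples$phenotype == "case"),
    sum(x$samples$phenotype == "control"), nrow(x$snps)
  ))
  invisible(x)
}

#' Construct a reference LD panel
#'
#' @param snps Tibble of SNP metadata (`snp_id`, `chrom`, `pos`, alleles).
#' @param haplotypes For a phased panel, a 0/1 matrix of haplotypes x SNPs
#'   (two rows per sample); for an unphased panel, a 0/1/2 genotype matrix
#'   of samples x SNPs.
#' @param phased Logical flag.
#' @param sample_ids Panel sample identifiers.
#' @return A `ref_panel` object.
#' @export
new_ref_panel <- function(snps, haplotypes, phased, sample_ids) {
  if (ncol(haplotypes) != nrow(snps)) {
    pi_abort("panel matrix columns must match SNP metadata rows")
  }
  structure(
    list(snps = as_tibble(snps), haplotypes = haplotypes,
         phased = isTRUE(phased), sample_ids = sample_ids),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %s, %d samples x %d SNPs\n",
              if (x$phased) "phased haplotypes" else "unphased genotypes",
              length(x$sample_ids), nrow(x$snps)))
  invisible(x)
}

#' Construct an expression dataset
#'
#' @param values Numeric matrix of features x samples (normalized
#'   intensities).
#' @param groups Tibble with columns `sample_id` and `group`
#'   (`"case"`/`"control"`), one row per matrix column.
#' @param level `"gene"` or `"probe"`.
#' @return An `expression_data` object.
#' @export
new_expression_data <- function(values, groups, level = c("gene", "probe")) {
  level <- match.arg(level)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    pi_abort("`groups` needs columns sample_id, group")
  }
  if (anyNA(groups$group) || !all(groups$group %in% c("case", "control"))) {
    pi_abort("groups must be 'case' or 'control' with no missing labels")
  }
  if (ncol(values) != nrow(groups)) {
    pi_abort("one group label per expression column is required")
  }
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), groups$sample_id)) {
    pi_abort("expression column names must match `groups$sample_id` in order")
  }
  structure(
    list(values = values, groups = as_tibble(groups), level = level),
    class = "expression_data"
  )
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("<expression_data> %d %ss x %d samples (%d cases, %d controls)\n",
              nrow(x$values), x$level, ncol(x$values),
              sum(x$groups$group == "case"),
              sum(x$groups$group == "control")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d causal SNPs, %d causal genes, %d DE genes, %d enriched pathways\n",
    length(x$causal_snp_ids), length(x$causal_gene_ids),
    length(x$de_gene_ids), length(x$enriched_pathway_ids)
  ))
  invisible(x)
}
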