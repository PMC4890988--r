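# Shared fixture builders. Everything is generated in code at test time.

# Small planted-signal study used by unit tests; strong effects so that
# recovery checks are robust at this reduced scale.
tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_cases = 80, n_controls = 80, n_genes = 40,
    snps_per_gene = c(2, 4), maf_range = c(0.1, 0.4),
    causal_gene_fraction = 0.15, genotype_odds_ratio = 2.5,
    de_gene_fraction = 0.15, de_effect_size = 2.5,
    n_pathways = 10, pathway_size_range = c(5, 12),
    n_enriched_pathways = 2, n_panel = 150, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Global-null configuration: no genetic effect, no differential expression.
null_config <- function(seed = 1, ...) {
  tiny_config(seed = seed, genotype_odds_ratio = 1, de_effect_size = 0, ...)
}

# Hand-constructed genotype dataset from an explicit call matrix.
make_genotypes <- function(calls, phenotype, chrom = "1") {
  n <- nrow(calls)
  m <- ncol(calls)
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    phenotype = phenotype
  )
  snps <- tibble::tibble(
    snp_id = colnames(calls) %||% sprintf("snp%02d", seq_len(m)),
    chrom = chrom,
    pos = seq(1000L, by = 1000L, length.out = m),
    allele_major = "A",
    allele_minor = "G"
  )
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  new_genotype_data(samples, snps, calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phased panel built from an explicit haplotype matrix (haplotypes x SNPs).
make_panel <- function(hap, snp_ids = NULL, pos = NULL) {
  m <- ncol(hap)
  snp_ids <- snp_ids %||% sprintf("snp%02d", seq_len(m))
  snps <- tibble::tibble(
    snp_id = snp_ids, chrom = "1",
    pos = pos %||% seq(1000L, by = 1000L, length.out = m),
    allele_major = "A", allele_minor = "G"
  )
  colnames(hap) <- snp_ids
  new_ref_panel(snps, hap, phased = TRUE,
                sample_ids = sprintf("P%03d", seq_len(nrow(hap) / 2)))
}

# Haplotype pair columns with exact 2x2 haplotype counts (AB, Ab, aB, ab),
# giving an exactly known r^2.
haps_from_counts <- function(n_ab, n_aB, n_Ab, n_AB) {
  # columns: first = SNP A allele, second = SNP B allele
  rbind(
    matrix(rep(c(1, 1), n_AB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), n_Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), n_aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), n_ab), ncol = 2, byrow = TRUE)
  )
}

# Independent oracle for the Cochran-Armitage trend statistic: direct
# evaluation of the textbook formula with scores (0, 1, 2).
ca_trend_oracle <- function(r, s) {
  w <- 0:2
  R <- sum(r); S <- sum(s); N <- R + S
  n <- r + s
  num <- N * (N * sum(w * r) - R * sum(w * n))^2
  den <- R * S * (N * sum(w^2 * n) - sum(w * n)^2)
  stat <- num / den
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exhaustive minimum covering-set size for greedy-vs-optimal tag checks.
min_cover_size <- function(covers) {
  m <- nrow(covers)
  for (k in seq_len(m)) {
    sets <- utils::combn(m, k, simplify = FALSE)
    for (s in sets) {
      if (all(colSums(covers[s, , drop = FALSE] > 0) > 0)) return(k)
    }
  }
  m
}

# Exhaustive permutation oracle: exact strict / non-strict exceedance
# fractions over all subsets of size k.
exhaustive_perm <- function(w, k, s_true) {
  subs <- utils::combn(length(w), k, simplify = FALSE)
  s_rand <- vapply(subs, function(i) sum(w[i]), numeric(1))
  tol <- 1e-9 * max(1, abs(s_true))
  list(
    p_gt = mean(s_rand - s_true > tol),
    p_ge = mean(s_rand - s_true > -tol),
    n = length(subs)
  )
}

# Build a bare-bones pathway_analysis object for set-algebra tests.
fake_analysis <- function(ids, q, mode = "gwas") {
  structure(
    list(
      results = tibble::tibble(
        pathway_id = ids, name = ids, n_members = 10L, n_scored = 10L,
        s_true = 1, p_perm = q, q = q, significant = q < 0.05
      ),
      mode = mode, n_perm = 100, seed = 1, tie_rule = "strict",
      fdr_method = "bh", q_threshold = 0.05,
      universe_size = 10L, skipped = character(0)
    ),
    class = "pathway_analysis"
  )
}
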