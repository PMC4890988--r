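# Readers and writers for the standard interchange formats: PLINK text
# .ped/.map genotypes, a phased VCF (or haplotype TSV) reference panel,
# BED gene annotation, GMT pathway sets, and TSV tables. BED input is
# 0-based half-open and converted to the internal 1-based inclusive
# convention on read.

check_file <- function(path) {
  if (!file.exists(path)) {
    pi_abort(paste0("file not found: ", path), class = "pathintegrate_error_io")
  }
  invisible(path)
}

#' Read case-control genotypes from PLINK text files
#'
#' Parses a `.ped`/`.map` pair. The minor allele of each SNP is
#' determined from the data (ties broken toward the lexicographically
#' later allele); `0 0` is honored as the missing genotype; phenotype
#' column 6 is mapped 1 = control, 2 = case.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A `genotype_data` object.
#' @export
read_genotypes_plink_text <- function(ped_path, map_path) {
  check_file(ped_path); check_file(map_path)
  map_lines <- strsplit(trimws(readr::read_lines(map_path)), "\\s+")
  bad <- which(lengths(map_lines) != 4)
  if (length(bad) > 0) {
    pi_abort(sprintf("malformed .map line %d: expected 4 fields", bad[1]),
             class = "pathintegrate_error_parse")
  }
  map_mat <- do.call(rbind, map_lines)
  snps <- tibble(
    snp_id = map_mat[, 2],
    chrom = map_mat[, 1],
    pos = as.integer(map_mat[, 4])
  )
  n_snps <- nrow(snps)

  ped_lines <- strsplit(trimws(readr::read_lines(ped_path)), "\\s+")
  want <- 6L + 2L * n_snps
  bad <- which(lengths(ped_lines) != want)
  if (length(bad) > 0) {
    pi_abort(
      sprintf(".ped line %d has %d fields; expected %d (ped/map mismatch or ragged row)",
              bad[1], lengths(ped_lines)[bad[1]], want),
      class = "pathintegrate_error_parse"
    )
  }
  ped <- do.call(rbind, ped_lines)
  pheno_raw <- ped[, 6]
  bad <- which(!pheno_raw %in% c("1", "2"))
  if (length(bad) > 0) {
    pi_abort(
      sprintf("unknown phenotype code '%s' on .ped line %d (expected 1 or 2)",
              pheno_raw[bad[1]], bad[1]),
      class = "pathintegrate_error_parse"
    )
  }
  samples <- tibble(
    sample_id = ped[, 2],
    phenotype = ifelse(pheno_raw == "2", "case", "control")
  )
  a1 <- ped[, 6 + 2 * seq_len(n_snps) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(n_snps), drop = FALSE]

  calls <- matrix(NA_integer_, nrow(ped), n_snps)
  allele_major <- character(n_snps)
  allele_minor <- character(n_snps)
  for (j in seq_len(n_snps)) {
    al <- c(a1[, j], a2[, j])
    observed <- al[al != "0"]
    alleles <- sort(unique(observed))
    if (length(alleles) > 2) {
      pi_abort(sprintf("SNP %s has more than two alleles", snps$snp_id[j]),
               class = "pathintegrate_error_parse")
    }
    if (length(alleles) == 0) {
      allele_major[j] <- "0"; allele_minor[j] <- "0"
      next
    }
    if (length(alleles) == 1) {
      # monomorphic: the observed allele is the major one, no minor copies
      allele_major[j] <- alleles; allele_minor[j] <- alleles
      g <- rep(0L, nrow(ped))
      g[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
      calls[, j] <- g
      next
    }
    counts <- table(factor(observed, levels = alleles))
    # ties go to the lexicographically later allele, matching the writer
    minor <- if (counts[1] < counts[2]) alleles[1] else alleles[2]
    allele_minor[j] <- minor
    allele_major[j] <- setdiff(alleles, minor)
    g <- (a1[, j] == minor) + (a2[, j] == minor)
    g[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  snps$allele_major <- allele_major
  snps$allele_minor <- allele_minor
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  new_genotype_data(samples, snps, calls)
}

#' Write genotypes as PLINK text files
#'
#' @param dataset A `genotype_data` object.
#' @param ped_path,map_path Output paths.
#' @return The ped path, invisibly.
#' @export
write_genotypes_plink <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "genotype_data"))
  snps <- dataset$snps
  readr::write_lines(
    paste(snps$chrom, snps$snp_id, 0, snps$pos, sep = "\t"),
    map_path
  )
  n <- nrow(dataset$samples)
  pheno <- ifelse(dataset$samples$phenotype == "case", 2L, 1L)
  geno_txt <- matrix("", n, nrow(snps))
  for (j in seq_len(nrow(snps))) {
    g <- dataset$calls[, j]
    maj <- snps$allele_major[j]
    mnr <- snps$allele_minor[j]
    txt <- c(paste(maj, maj), paste(maj, mnr), paste(mnr, mnr))[g + 1L]
    txt[is.na(g)] <- "0 0"
    geno_txt[, j] <- txt
  }
  lines <- paste(
    dataset$samples$sample_id, dataset$samples$sample_id, 0, 0, 0, pheno,
    apply(geno_txt, 1, paste, collapse = " ")
  )
  readr::write_lines(lines, ped_path)
  invisible(ped_path)
}

#' Read a reference LD panel
#'
#' Dispatches on the file extension: `.vcf` is parsed with the `vcfR`
#' package (phased `0|1` genotypes become two haplotypes per sample;
#' multi-allelic records are skipped with a warning); anything else is
#' read as the package's haplotype TSV dialect (see
#' [write_panel_tsv()]).
#'
#' @param path Panel file.
#' @return A `ref_panel` object.
#' @export
read_panel <- function(path) {
  check_file(path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_panel_vcf(path)
  } else {
    read_panel_tsv(path)
  }
}

read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("%d multi-allelic VCF records skipped", sum(multi)))
  }
  keep <- which(!multi)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ok <- grepl("^[01]([|/])[01]$", gt)
  if (!all(ok)) {
    idx <- which(!ok)[1]
    rec <- ((idx - 1) %% nrow(gt)) + 1
    smp <- ((idx - 1) %/% nrow(gt)) + 1
    pi_abort(
      sprintf("malformed GT '%s' at VCF record %d (ID %s), sample %s",
              gt[rec, smp], rec, fix$ID[rec], colnames(gt)[smp]),
      class = "pathintegrate_error_parse"
    )
  }
  phased <- all(grepl("|", gt, fixed = TRUE))
  snps <- tibble(
    snp_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    allele_major = fix$REF,
    allele_minor = fix$ALT
  )
  h1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
  h2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
  if (phased) {
    hap <- matrix(0L, 2L * ncol(gt), nrow(gt))
    hap[seq(1, nrow(hap), by = 2), ] <- t(h1)
    hap[seq(2, nrow(hap), by = 2), ] <- t(h2)
    colnames(hap) <- snps$snp_id
    new_ref_panel(snps, hap, phased = TRUE, sample_ids = colnames(gt))
  } else {
    geno <- t(h1 + h2)
    colnames(geno) <- snps$snp_id
    new_ref_panel(snps, geno, phased = FALSE, sample_ids = colnames(gt))
  }
}

#' Write a phased panel as VCF
#'
#' @param panel A phased `ref_panel`.
#' @param path Output `.vcf` path.
#' @return The path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "ref_panel"), panel$phased)
  n <- length(panel$sample_ids)
  h1 <- panel$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
  h2 <- panel$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
  gt_rows <- vapply(seq_len(nrow(panel$snps)), function(j) {
    paste(paste0(h1[, j], "|", h2[, j]), collapse = "\t")
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pathintegrate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  )
  body <- paste(
    panel$snps$chrom, panel$snps$pos, panel$snps$snp_id,
    panel$snps$allele_major, panel$snps$allele_minor,
    ".", "PASS", ".", "GT", gt_rows,
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a phased panel as a haplotype TSV
#'
#' Columns: `snp_id`, `chrom`, `pos`, `allele_major`, `allele_minor`,
#' then two 0/1 haplotype columns per panel sample
#' (`<sample>_h1`, `<sample>_h2`).
#'
#' @param panel A phased `ref_panel`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "ref_panel"), panel$phased)
  hap_t <- t(panel$haplotypes)
  colnames(hap_t) <- paste0(rep(panel$sample_ids, each = 2),
                            c("_h1", "_h2"))
  df <- bind_cols(panel$snps, as_tibble(hap_t))
  readr::write_tsv(df, path)
  invisible(path)
}

read_panel_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = "c", chrom = "c", pos = "i",
    allele_major = "c", allele_minor = "c", .default = "i"
  ))
  meta_cols <- c("snp_id", "chrom", "pos", "allele_major", "allele_minor")
  if (!all(meta_cols %in% names(df))) {
    pi_abort("panel TSV must carry snp_id, chrom, pos, allele_major, allele_minor",
             class = "pathintegrate_error_parse")
  }
  hap_cols <- setdiff(names(df), meta_cols)
  if (length(hap_cols) == 0 || length(hap_cols) %% 2 != 0) {
    pi_abort("panel TSV needs an even number of haplotype columns",
             class = "pathintegrate_error_parse")
  }
  hap <- t(as.matrix(df[, hap_cols]))
  colnames(hap) <- df$snp_id
  storage.mode(hap) <- "integer"
  samples <- unique(sub("_h[12]$", "", hap_cols))
  new_ref_panel(
    df[, meta_cols], hap, phased = TRUE, sample_ids = samples
  )
}

#' Read a gene annotation from BED
#'
#' BED is 0-based half-open; intervals are converted to the internal
#' 1-based inclusive convention (via `rtracklayer`).
#'
#' @param path BED file with gene ids in the name column.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation_bed <- function(path) {
  check_file(path)
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Write a gene annotation as BED (0-based half-open)
#'
#' @param annotation Tibble with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  readr::write_lines(
    paste(annotation$chrom, annotation$start - 1L, annotation$end,
          annotation$gene_id, sep = "\t"),
    path
  )
  invisible(path)
}

#' Read a pathway collection from GMT
#'
#' Membership is parsed with `fgsea::gmtPathways()`; the description
#' column (second field) becomes the pathway name.
#'
#' @param path GMT file (tab-separated: id, description, member genes).
#' @return A tibble with columns `pathway_id`, `name`, list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  check_file(path)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    pi_abort(paste0("duplicate pathway ids in GMT: ",
                    names(sets)[duplicated(names(sets))][1]),
             class = "pathintegrate_error_parse")
  }
  if (any(lengths(sets) == 0)) {
    pi_abort(paste0("pathway with empty member list in GMT: ",
                    names(sets)[lengths(sets) == 0][1]),
             class = "pathintegrate_error_parse")
  }
  fields <- strsplit(readr::read_lines(path), "\t")
  names_of <- setNames(vapply(fields, function(f) f[2], ""),
                       vapply(fields, function(f) f[1], ""))
  tibble(
    pathway_id = names(sets),
    name = unname(names_of[names(sets)]),
    genes = unname(sets)
  )
}

#' Write a pathway collection as GMT
#'
#' @param pathways Tibble with columns `pathway_id`, `name`, list-column
#'   `genes`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- pmap(
    list(pathways$pathway_id, pathways$name, pathways$genes),
    function(id, name, genes) paste(c(id, name, genes), collapse = "\t")
  )
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Read an expression matrix and group labels
#'
#' @param path TSV with a `gene_id` (or first) identifier column and one
#'   column per sample.
#' @param groups_path TSV with columns `sample_id` and `group`
#'   (`case`/`control`). Every matrix sample must be labelled and every
#'   labelled sample must exist in the matrix.
#' @param level `"gene"` (default) or `"probe"`.
#' @return An `expression_data` object.
#' @export
read_expression <- function(path, groups_path, level = c("gene", "probe")) {
  check_file(path); check_file(groups_path)
  level <- match.arg(level)
  df <- readr::read_tsv(path, col_types = readr::cols())
  id_col <- names(df)[1]
  values <- as.matrix(df[, -1])
  rownames(values) <- df[[id_col]]
  groups <- readr::read_tsv(groups_path, col_types = readr::cols(.default = "c"))
  if (!all(c("sample_id", "group") %in% names(groups))) {
    pi_abort("groups file needs columns sample_id, group",
             class = "pathintegrate_error_parse")
  }
  unknown <- setdiff(groups$sample_id, colnames(values))
  if (length(unknown) > 0) {
    pi_abort(paste0("unknown samples in groups file: ",
                    paste(head(unknown, 5), collapse = ",")),
             class = "pathintegrate_error_parse")
  }
  unlabeled <- setdiff(colnames(values), groups$sample_id)
  if (length(unlabeled) > 0) {
    pi_abort(paste0("expression samples without group label: ",
                    paste(head(unlabeled, 5), collapse = ",")),
             class = "pathintegrate_error_parse")
  }
  groups <- groups[match(colnames(values), groups$sample_id), ]
  new_expression_data(values, groups, level = level)
}

#' Write an expression dataset and its group labels as TSV
#'
#' @param dataset An `expression_data` object.
#' @param path Output TSV for the matrix.
#' @param groups_path Output TSV for the group labels.
#' @return The matrix path, invisibly.
#' @export
write_expression_tsv <- function(dataset, path, groups_path) {
  df <- bind_cols(
    tibble(gene_id = rownames(dataset$values)),
    as_tibble(dataset$values)
  )
  readr::write_tsv(df, path)
  readr::write_tsv(dataset$groups, groups_path)
  invisible(path)
}

#' Write pathway analysis results as TSV
#'
#' Columns: `pathway_id`, `name`, `n_members`, `n_scored`, `S_true`,
#' `p_perm`, `q`, `significant`.
#'
#' @param results A `pathway_analysis` object (or its tidy tibble).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  tab <- if (inherits(results, "pathway_analysis")) results$results else results
  out <- rename(tab, S_true = "s_true")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a gene score table as TSV
#'
#' @param table Gene score tibble (e.g. from
#'   [build_integrated_scores()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_scores <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
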