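#' Case/control genotype container
#'
#' Holds a sample-by-SNP dosage matrix (0/1/2 effect-allele copies), the
#' binary phenotype, and the SNP annotation (gene assignment and position).
#'
#' @param dosages Integer/numeric matrix, samples in rows, SNPs in columns
#'   (column names = SNP ids), values in \{0, 1, 2\} with no missingness.
#' @param phenotype Vector of 0 (control) / 1 (case), one per sample.
#' @param snp_info Tibble with columns `snp_id`, `gene` and optionally
#'   `chrom`, `pos`, covering every dosage column.
#' @return Object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, phenotype, snp_info) {
  if (anyNA(dosages) || !all(dosages %in% 0:2))
    stopf("dosages must be complete and in {0, 1, 2}")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(dosages))
    stopf("phenotype length must match sample count")
  if (!all(phenotype %in% 0:1) || length(unique(phenotype)) < 2L)
    stopf("phenotype must contain both cases (1) and controls (0)")
  if (!all(colnames(dosages) %in% snp_info$snp_id))
    stopf("every SNP needs an annotation row")
  structure(list(dosages = dosages, phenotype = phenotype,
                 snp_info = as_tibble(snp_info)),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d samples (%d cases / %d controls) x %d SNPs in %d genes\n",
              nrow(x$dosages), sum(x$phenotype == 1), sum(x$phenotype == 0),
              ncol(x$dosages), length(unique(x$snp_info$gene))))
  invisible(x)
}

#' @export
tidy.genotype_data <- function(x, ...) {
  tibble(sample = rep(rownames(x$dosages) %||%
                        as.character(seq_len(nrow(x$dosages))),
                      ncol(x$dosages)),
         snp_id = rep(colnames(x$dosages), each = nrow(x$dosages)),
         dosage = as.integer(x$dosages),
         phenotype = rep(x$phenotype, ncol(x$dosages)))
}

# Cochran-Armitage trend chi-square (scores 0/1/2) for all columns of X at
# once, via the identity T = N * cor(y, x)^2. Monomorphic columns get 0.
trend_stats <- function(X, y) {
  n <- length(y)
  vx <- matrixStats_colVars(X)
  sy <- sd(y)
  r <- suppressWarnings(as.numeric(cor(y, X)))
  stat <- n * r^2
  stat[vx < 1e-12 | sy < 1e-12] <- 0
  stat
}

matrixStats_colVars <- function(X) {
  mu <- colMeans(X)
  (colSums(X^2) - nrow(X) * mu^2) / (nrow(X) - 1)
}

#' Single-SNP trend association test
#'
#' Cochran-Armitage trend test (1 df, additive scores 0/1/2) of case/control
#' status against genotype dosage, with its asymptotic chi-square p-value.
#' A monomorphic SNP cannot carry association and is returned flagged with
#' statistic 0 and p = 1.
#'
#' @param g A [genotype_data()].
#' @param snp SNP id.
#' @return Tibble `snp_id`, `statistic`, `p`, `monomorphic`.
#' @export
snp_stat <- function(g, snp) {
  if (!snp %in% colnames(g$dosages)) stopf("SNP '%s' not present", snp)
  x <- g$dosages[, snp]
  mono <- stats::var(x) < 1e-12
  stat <- if (mono) 0 else trend_stats(matrix(x, ncol = 1), g$phenotype)
  tibble(snp_id = snp, statistic = as.numeric(stat),
         p = if (mono) 1 else pchisq(stat, df = 1, lower.tail = FALSE),
         monomorphic = mono)
}

#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors.
#'
#' @param g A [genotype_data()].
#' @param snp_i,snp_j SNP ids (both must be polymorphic).
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(g, snp_i, snp_j) {
  xi <- g$dosages[, snp_i]
  xj <- g$dosages[, snp_j]
  if (stats::var(xi) < 1e-12 || stats::var(xj) < 1e-12)
    stopf("cannot compute LD r^2 with a monomorphic SNP")
  cor(xi, xj)^2
}

# greedy informative-marker selection on precomputed inputs:
# order SNPs by ascending p (ties: lexicographic id); accept a SNP iff its
# p < p_include and its r^2 with every already-accepted SNP is < r2_max
select_greedy <- function(snp_ids, p, r2, r2_max, p_include) {
  ord <- order(p, snp_ids)
  acc <- integer(0)
  for (i in ord) {
    if (p[i] >= p_include) next
    if (length(acc) && any(r2[i, acc] >= r2_max)) next
    acc <- c(acc, i)
  }
  snp_ids[acc]
}

#' Select informative markers within a SNP set
#'
#' LD filtering in the PLINK set-test style: SNPs are visited in order of
#' ascending single-SNP p-value and accepted only if nominally associated
#' (`p < p_include`) and not in linkage disequilibrium (`r^2 < r2_max`) with
#' any SNP already accepted. No cap is placed on the number accepted; the
#' retained SNPs are pairwise below the r-squared bound.
#'
#' @param g A [genotype_data()].
#' @param set_snps Character vector of SNP ids in the set.
#' @param stats Optional tibble (`snp_id`, `statistic`, `p`) of
#'   precomputed trend statistics; computed if missing.
#' @param r2_max LD exclusion bound (default 0.50).
#' @param p_include Single-SNP inclusion threshold (default 0.05; set to 1
#'   to include every marker).
#' @return Character vector of selected SNP ids (possibly empty).
#' @export
select_informative <- function(g, set_snps, stats = NULL, r2_max = 0.50,
                               p_include = 0.05) {
  if (length(set_snps) == 0L) stopf("SNP set is empty")
  X <- g$dosages[, set_snps, drop = FALSE]
  if (is.null(stats)) {
    st <- trend_stats(X, g$phenotype)
    p <- pchisq(st, df = 1, lower.tail = FALSE)
    p[st == 0] <- 1
  } else {
    p <- stats$p[match(set_snps, stats$snp_id)]
  }
  r2 <- suppressWarnings(cor(X)^2)
  r2[!is.finite(r2)] <- 1   # monomorphic SNPs never add information
  select_greedy(set_snps, p, r2, r2_max, p_include)
}

#' Permutation set-based association test
#'
#' Tests whether a gene set is associated with case/control status. The set
#' is expanded to every genotyped SNP annotated to a member gene; the
#' observed statistic is the mean Cochran-Armitage trend chi-square over the
#' informative markers selected by [select_informative()] (0 if none pass).
#' Phenotype labels are then permuted `n_perm` times and, in each
#' permutation, the per-SNP statistics are recomputed and the marker
#' selection is re-run before averaging, so the empirical p-value
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)` is valid for the whole
#' selection-plus-averaging procedure. It is never exactly 0.
#'
#' @param g A [genotype_data()].
#' @param set A [build_set()] `gene_set`, or a character vector of gene
#'   symbols.
#' @param n_perm Number of phenotype permutations (default 10000).
#' @param seed Integer seed.
#' @param r2_max,p_include Marker-selection parameters (see
#'   [select_informative()]).
#' @param set_id Label for the result (defaults to the set's index/level).
#' @return Object of class `set_test_result` with the observed statistic,
#'   empirical p, selected SNPs and permutation statistics.
#' @export
set_test <- function(g, set, n_perm = 10000, seed = 1L, r2_max = 0.50,
                     p_include = 0.05, set_id = NULL) {
  genes <- if (inherits(set, "gene_set")) set$members$gene else
    as.character(set)
  if (is.null(set_id))
    set_id <- if (inherits(set, "gene_set"))
      paste(set$index, set$level, sep = "/") else "set"
  snps <- g$snp_info$snp_id[g$snp_info$gene %in% genes]
  snps <- intersect(snps, colnames(g$dosages))
  if (length(snps) == 0L)
    stopf("set '%s' expands to no genotyped SNPs", set_id)
  X <- g$dosages[, snps, drop = FALSE]
  r2 <- suppressWarnings(cor(X)^2)
  r2[!is.finite(r2)] <- 1
  stat_of <- function(y) {
    st <- trend_stats(X, y)
    p <- pchisq(st, df = 1, lower.tail = FALSE)
    p[st == 0] <- 1
    sel <- select_greedy(snps, p, r2, r2_max, p_include)
    if (length(sel) == 0L) list(stat = 0, sel = character(0))
    else list(stat = mean(st[match(sel, snps)]), sel = sel)
  }
  obs <- stat_of(g$phenotype)
  perm_stats <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm))
      perm_stats[b] <- stat_of(sample(g$phenotype))$stat
  })
  p_emp <- (1 + sum(perm_stats >= obs$stat)) / (n_perm + 1)
  structure(
    list(set_id = set_id, statistic = obs$stat, p = p_emp,
         selected_snps = obs$sel, n_perm = n_perm, seed = seed,
         perm_stats = perm_stats, n_snps = length(snps)),
    class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf(
    "<set_test_result> %s: mean trend stat %.3f over %d selected SNPs (of %d); empirical p = %.4g (%d perms)\n",
    x$set_id, x$statistic, length(x$selected_snps), x$n_snps, x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.set_test_result <- function(x, ...) {
  tibble(set_id = x$set_id, statistic = x$statistic, p = x$p,
         n_selected = length(x$selected_snps), n_snps = x$n_snps,
         n_perm = x$n_perm)
}

#' @export
glance.set_test_result <- function(x, ...) tidy(x)

#' @export
autoplot.set_test_result <- function(object, ...) {
  ggplot2::ggplot(tibble(stat = object$perm_stats),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick") +
    ggplot2::labs(x = "permuted set statistic", y = "count",
                  title = sprintf("%s: p = %.4g", object$set_id, object$p))
}

#' Set-based association over index genes and inclusion levels
#'
#' Convenience wrapper running [set_test()] at the `top10`, `top24` and
#' `top25` inclusion levels for each index gene, producing one row per
#' index with the empirical p-values at each level and the mean member
#' correlation of its top-25 set.
#'
#' @param g A [genotype_data()].
#' @param expr Gene-level expression tibble for [correlation_rank()].
#' @param index_genes Character vector of index gene symbols.
#' @param assignment Optional tibble (`gene`, `cluster`) used to report each
#'   index's cluster.
#' @param n_perm,seed,r2_max,p_include Passed to [set_test()].
#' @return Tibble `cluster`, `index`, `p_top10`, `p_top24`, `p_top25`,
#'   `mean_r`.
#' @export
set_assoc_table <- function(g, expr, index_genes, assignment = NULL,
                            n_perm = 10000, seed = 1L, r2_max = 0.50,
                            p_include = 0.05) {
  rows <- lapply(seq_along(index_genes), function(i) {
    idx <- index_genes[i]
    ranked <- correlation_rank(expr, idx)
    ps <- vapply(c("top10", "top24", "top25"), function(lv) {
      s <- build_set(ranked, lv, idx)
      set_test(g, s, n_perm = n_perm, seed = derive_seed(seed, i),
               r2_max = r2_max, p_include = p_include)$p
    }, numeric(1))
    cl <- if (!is.null(assignment))
      assignment$cluster[match(idx, assignment$gene)] else NA_character_
    tibble(cluster = cl, index = idx, p_top10 = ps[["top10"]],
           p_top24 = ps[["top24"]], p_top25 = ps[["top25"]],
           mean_r = build_set(ranked, "top25", idx)$mean_r)
  })
  bind_rows(rows)
}
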