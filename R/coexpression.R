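#' Rank genes by expression-profile correlation to an index gene
#'
#' Computes the Pearson correlation between the index gene's regional
#' profile and every other retained gene, across the pooled regions of all
#' brains present in `expr` (each brain's profiles are z-scored before
#' concatenation, so donors contribute on a common scale). Genes are
#' returned in descending correlation order with lexicographic tie-breaks.
#'
#' @param expr Gene-level expression tibble (`brain`, `gene`, `region_id`,
#'   `value`); probe-collapsed.
#' @param index Index gene symbol (must be present).
#' @param exclude Optional predicate `function(gene) TRUE/FALSE` or a
#'   character vector of gene symbols to drop (e.g. unnamed transcripts).
#' @return Tibble `rank`, `gene`, `r` over all non-index retained genes.
#' @export
correlation_rank <- function(expr, index, exclude = NULL) {
  if (!index %in% expr$gene) stopf("index gene '%s' not in matrix", index)
  drop <- if (is.null(exclude)) character(0)
  else if (is.function(exclude)) {
    g <- unique(expr$gene)
    g[vapply(g, exclude, logical(1))]
  } else as.character(exclude)
  drop <- setdiff(drop, index)
  expr <- filter(expr, !(.data$gene %in% drop))
  zs <- zscore_genes(expr)
  mats <- lapply(split(zs, zs$brain), expr_to_matrix)
  m <- do.call(cbind, mats)             # genes x pooled regions
  r <- as.numeric(cor(m[index, ], t(m[setdiff(rownames(m), index), ,
                                      drop = FALSE])))
  genes <- setdiff(rownames(m), index)
  ord <- order(-r, genes)
  tibble(rank = seq_along(ord), gene = genes[ord], r = r[ord])
}

#' Assemble a correlation-defined gene set
#'
#' Builds a set from a correlation ranking at one of three inclusion
#' levels: `top10` and `top25` take the index gene plus the 9 or 24 most
#' correlated genes; `top24` takes the 24 most correlated genes with the
#' index gene deliberately removed, which is the ablation used to check that
#' a set's association does not ride solely on its index.
#'
#' @param ranked Output of [correlation_rank()].
#' @param level `"top10"`, `"top25"` or `"top24"`.
#' @param index Index gene symbol.
#' @return Object of class `gene_set`: list with `index`, `level`,
#'   `members` (tibble `gene`, `r`, index first where included) and
#'   `mean_r` (mean correlation of the non-index members with the index).
#' @export
build_set <- function(ranked, level = c("top10", "top25", "top24"), index) {
  level <- match.arg(level)
  n_other <- c(top10 = 9L, top25 = 24L, top24 = 24L)[[level]]
  if (nrow(ranked) < n_other)
    stopf("ranking has %d genes; need %d for %s", nrow(ranked), n_other,
          level)
  others <- ranked[seq_len(n_other), ]
  members <- if (level == "top24") {
    tibble(gene = others$gene, r = others$r)
  } else {
    bind_rows(tibble(gene = index, r = 1), tibble(gene = others$gene,
                                                  r = others$r))
  }
  if (anyDuplicated(members$gene)) stopf("duplicate genes in set")
  structure(
    list(index = index, level = level, members = members,
         mean_r = mean(others$r)),
    class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s of index %s: %d genes, mean member r = %.2f\n",
              x$level, x$index, nrow(x$members), x$mean_r))
  invisible(x)
}

#' @export
tidy.gene_set <- function(x, ...) {
  mutate(x$members, index = x$index, level = x$level)
}

#' @export
glance.gene_set <- function(x, ...) {
  tibble(index = x$index, level = x$level, n_genes = nrow(x$members),
         mean_r = x$mean_r)
}

#' Overlap between two gene sets
#'
#' @param a,b `gene_set` objects.
#' @return List with `count` and `shared` (character vector of shared gene
#'   symbols, sorted).
#' @export
set_overlap <- function(a, b) {
  shared <- sort(intersect(a$members$gene, b$members$gene))
  list(count = length(shared), shared = shared)
}
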