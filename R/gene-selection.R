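#' Assign SNPs to single candidate genes
#'
#' Candidate-gene filter over an association SNP list: a SNP is assigned to
#' a gene only if that gene is the *single* gene whose window-extended
#' interval `[start - window, end + window]` (boundary inclusive) contains
#' the SNP position on the same chromosome. SNPs near no gene are excluded
#' as intergenic; SNPs near two or more genes are excluded as ambiguous.
#' Interval overlap is computed with `IRanges`.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (1-based bp) and
#'   optionally `p`.
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end`
#'   (1-based, inclusive; `start <= end`).
#' @param window_bp Window in bp added to each side of every gene interval
#'   (default 100000).
#' @return Tibble `snp_id`, `chrom`, `pos`, `gene` (`NA` unless assigned),
#'   `status` in `assigned` / `excluded_intergenic` / `excluded_multiple`.
#' @export
assign_single_gene <- function(snps, genes, window_bp = 100000) {
  if (any(genes$start > genes$end)) stopf("malformed gene interval(s)")
  if (any(snps$pos < 1)) stopf("SNP positions must be >= 1")
  out <- mutate(snps, gene = NA_character_,
                status = "excluded_intergenic")
  for (chr in unique(snps$chrom)) {
    si <- which(snps$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0L) next
    q <- IRanges::IRanges(start = snps$pos[si], width = 1L)
    s <- IRanges::IRanges(
      start = pmax(1, genes$start[gi] - window_bp),
      end = genes$end[gi] + window_bp)
    hits <- IRanges::findOverlaps(q, s)
    nh <- IRanges::countOverlaps(q, s)
    one <- which(nh == 1L)
    multi <- which(nh >= 2L)
    first_hit <- S4Vectors::subjectHits(hits)[
      match(one, S4Vectors::queryHits(hits))]
    out$gene[si[one]] <- genes$gene[gi][first_hit]
    out$status[si[one]] <- "assigned"
    out$status[si[multi]] <- "excluded_multiple"
  }
  select(out, "snp_id", "chrom", "pos", "gene", "status")
}

#' Collapse an assignment to its candidate gene list
#'
#' Several SNPs often map to the same gene; the candidate list is the set of
#' distinct assigned genes, sorted.
#'
#' @param assignment Output of [assign_single_gene()].
#' @return Character vector of unique assigned gene symbols.
#' @export
candidate_genes <- function(assignment) {
  sort(unique(assignment$gene[assignment$status == "assigned"]))
}
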