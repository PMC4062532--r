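# Readers and writers for the pipeline's plain-text interchange formats:
# expression TSV + region side table, GingerALE-style foci text, PLINK-style
# .ped/.map genotypes, NIfTI voxel maps and Newick dendrograms.

#' Write / read regional expression tables
#'
#' The expression matrix travels as a wide TSV per brain (rows = probes,
#' columns = region ids, plus `probe` and `gene` columns) and a shared
#' region side table (`region_id`, `structure_name`, `x`, `y`, `z`,
#' `hemisphere`).
#'
#' @param expr Long expression tibble (`brain`, `probe`, `gene`,
#'   `region_id`, `value`); gene-level tibbles without a `probe` column are
#'   accepted (probe = gene).
#' @param regions Region side table.
#' @param dir Output directory (created if missing).
#' @return `write_expression_tsv`: invisible vector of written paths;
#'   `read_expression_tsv`: list with `expression` and `regions` tibbles.
#' @export
write_expression_tsv <- function(expr, regions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!"probe" %in% names(expr)) expr$probe <- expr$gene
  paths <- character(0)
  for (b in unique(expr$brain)) {
    wide <- expr |>
      filter(.data$brain == b) |>
      select("probe", "gene", "region_id", "value") |>
      tidyr::pivot_wider(names_from = "region_id", values_from = "value") |>
      arrange(.data$probe)
    f <- file.path(dir, paste0("expression_", b, ".tsv"))
    readr::write_tsv(wide, f)
    paths <- c(paths, f)
  }
  f <- file.path(dir, "regions.tsv")
  readr::write_tsv(regions, f)
  invisible(c(paths, f))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(dir) {
  files <- list.files(dir, pattern = "^expression_.*\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0L) stopf("no expression TSVs under %s", dir)
  expr <- bind_rows(lapply(files, function(f) {
    b <- sub("^expression_(.*)\\.tsv$", "\\1", basename(f))
    readr::read_tsv(f, show_col_types = FALSE) |>
      tidyr::pivot_longer(cols = -c("probe", "gene"),
                          names_to = "region_id", values_to = "value") |>
      mutate(brain = b)
  })) |>
    select("brain", "probe", "gene", "region_id", "value")
  regions <- readr::read_tsv(file.path(dir, "regions.tsv"),
                             show_col_types = FALSE)
  list(expression = expr, regions = regions)
}

#' Write / read GingerALE-style foci text
#'
#' One text file per contrast direction: each study is a header line
#' `// <study_id>: n=<subjects>` followed by whitespace-separated `x y z`
#' rows, studies separated by blank lines.
#'
#' @param studies Foci tibble (`study_id`, `n_subjects`, `x`, `y`, `z`);
#'   rows should share one contrast direction per file.
#' @param path Output file.
#' @param space,direction Metadata attached to the rows on reading.
#' @return `read_foci`: a foci tibble.
#' @export
write_foci <- function(studies, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sid in unique(studies$study_id)) {
    s <- filter(studies, .data$study_id == sid)
    writeLines(sprintf("// %s: n=%d", sid, s$n_subjects[1]), con)
    writeLines(sprintf("%.3f\t%.3f\t%.3f", s$x, s$y, s$z), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_foci
#' @export
read_foci <- function(path, space = "Talairach", direction = NA_character_) {
  lines <- readLines(path)
  out <- list()
  sid <- NULL
  nsub <- NA_integer_
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "//")) {
      m <- regmatches(ln, regexec("^//\\s*(.+?):\\s*n=(\\d+)", ln))[[1]]
      if (length(m) != 3L) stopf("malformed study header: '%s'", ln)
      sid <- m[2]
      nsub <- as.integer(m[3])
      if (nsub <= 6)
        warn(sprintf("study '%s' has <= 6 subjects", sid))
      next
    }
    if (is.null(sid)) stopf("focus row before any study header")
    xyz <- as.numeric(strsplit(ln, "\\s+")[[1]])
    if (length(xyz) != 3L || anyNA(xyz)) stopf("malformed focus row: '%s'", ln)
    out[[length(out) + 1L]] <- tibble(study_id = sid, n_subjects = nsub,
                                      space = space, direction = direction,
                                      x = xyz[1], y = xyz[2], z = xyz[3])
  }
  bind_rows(out)
}

#' Write / read PLINK-style text genotypes
#'
#' `.ped` rows carry family/individual ids, a phenotype code (2 = case,
#' 1 = control) and two alleles per SNP (`A` = reference, `B` = effect);
#' `.map` lists chromosome, SNP id and bp position. A two-column
#' `snp_to_gene` TSV carries the gene annotation.
#'
#' @param g A [genotype_data()].
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`,
#'   `<prefix>.snp2gene.tsv`).
#' @return `read_ped_map`: a `genotype_data`.
#' @export
write_ped_map <- function(g, prefix) {
  snp_ids <- colnames(g$dosages)
  info <- g$snp_info[match(snp_ids, g$snp_info$snp_id), ]
  readr::write_tsv(
    tibble(chrom = info$chrom %||% 1L, snp_id = snp_ids, cm = 0,
           pos = info$pos %||% seq_along(snp_ids)),
    paste0(prefix, ".map"), col_names = FALSE)
  alle <- matrix("A", nrow(g$dosages), 2 * ncol(g$dosages))
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    alle[, 2 * j - 1] <- ifelse(d >= 1, "B", "A")
    alle[, 2 * j] <- ifelse(d == 2, "B", "A")
  }
  ids <- rownames(g$dosages) %||% sprintf("S%05d", seq_len(nrow(g$dosages)))
  ped <- cbind(ids, ids, "0", "0", "0", as.character(g$phenotype + 1L), alle)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  readr::write_tsv(tibble(snp_id = snp_ids, gene = info$gene),
                   paste0(prefix, ".snp2gene.tsv"))
  invisible(prefix)
}

#' @rdname write_ped_map
#' @export
read_ped_map <- function(prefix) {
  map <- readr::read_tsv(paste0(prefix, ".map"),
                         col_names = c("chrom", "snp_id", "cm", "pos"),
                         show_col_types = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           colClasses = "character")
  s2g <- readr::read_tsv(paste0(prefix, ".snp2gene.tsv"),
                         show_col_types = FALSE)
  alle <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- ncol(alle) / 2
  dos <- (alle[, 2 * seq_len(m) - 1, drop = FALSE] == "B") +
    (alle[, 2 * seq_len(m), drop = FALSE] == "B")
  storage.mode(dos) <- "integer"
  colnames(dos) <- map$snp_id
  rownames(dos) <- ped[, 2]
  genotype_data(dos, as.integer(ped[, 6]) - 1L,
                left_join(map, s2g, by = "snp_id"))
}

#' Write / read a voxel map as NIfTI
#'
#' Stores the array with an affine placing voxel `(1, 1, 1)` at the map's
#' origin and isotropic spacing; the mask travels as a companion file when
#' requested. Use a `.nii` extension for uncompressed (byte-reproducible)
#' output.
#'
#' @param vm A `voxel_map`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `read_voxel_map`: a `voxel_map` (all-`TRUE` mask).
#' @export
write_voxel_map <- function(vm, path) {
  aff <- diag(c(rep(vm$spacing, 3), 1))
  aff[1:3, 4] <- vm$origin
  img <- RNifti::asNifti(vm$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_map
#' @export
read_voxel_map <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  voxel_map(array(as.numeric(img), dim(img)[1:3]),
            origin = aff[1:3, 4], spacing = aff[1, 1])
}

#' Export a gene dendrogram as Newick text
#'
#' @param dend A [cluster_genes()] result.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend$tree), file = path)
  invisible(path)
}
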