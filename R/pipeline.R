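#' Default end-to-end pipeline configuration
#'
#' Nested parameter list covering every stage (simulation, clustering,
#' ALE meta-analysis, distance-null overlap, gene sets, set association),
#' with one global seed from which every stochastic stage derives its own
#' sub-seed deterministically. The defaults describe a scaled synthetic run
#' that exercises the whole pipeline in minutes.
#'
#' @param seed Global integer seed.
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      n_regions = 300, n_genes = 40, cluster_sizes = c(7, 7, 4),
      within_cluster_corr_target = 0.6, n_brains = 2,
      n_studies = 18, noise_foci_per_study = 3, foci_jitter_sd = 5,
      true_locus = c(-24, -30, -12),
      n_cases = 300, n_controls = 300, n_snps_per_gene = 6,
      ld_block_corr = 0.8, effect_snp_ids = character(0),
      effect_odds_ratio = 1.3
    ),
    mask = list(voxel_size_mm = 4, semi_axes_mm = c(68, 86, 59)),
    cluster = list(cut_height = 0.7, min_cluster_size = 2, fwhm_mm = 12,
                   z_threshold = 1, min_separation_mm = 12),
    ale = list(n_perm = 100, q = 0.05, min_volume_mm3 = 224,
               pooling = "all_foci"),
    overlap = list(n_pairs = 50000, alphas = c(0.05, 0.01, 0.005)),
    sets = list(index_genes = c("G01", "G10"), levels = c("top10", "top24",
                                                          "top25")),
    assoc = list(n_perm = 200, r2_max = 0.50, p_include = 0.05)
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys at any level are rejected so typos fail fast; values given
#' in the file override the defaults.
#'
#' @param path YAML file.
#' @param seed Fallback global seed if the file sets none.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  base <- unclass(default_config(seed))
  merged <- merge_config(base, user, path = "config")
  validate_config(structure(merged, class = "pipeline_config"))
}

merge_config <- function(base, user, path) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stopf("unknown %s key(s): %s", path, paste(unknown, collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]], paste0(path, "$", k))
    else user[[k]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(config) {
  s <- config$simulate
  if (any(c(s$n_regions, s$n_genes, s$n_brains, s$n_studies, s$n_cases,
            s$n_controls, s$n_snps_per_gene) < 1))
    stopf("simulate: all counts must be positive")
  if (length(s$cluster_sizes) < 1 || any(s$cluster_sizes < 1))
    stopf("simulate$cluster_sizes must be positive")
  if (sum(s$cluster_sizes) > s$n_genes)
    stopf("simulate$cluster_sizes exceed n_genes")
  if (s$effect_odds_ratio <= 0) stopf("simulate$effect_odds_ratio must be > 0")
  if (config$ale$n_perm < 1) stopf("ale$n_perm must be >= 1")
  if (config$assoc$n_perm < 1) stopf("assoc$n_perm must be >= 1")
  if (config$overlap$n_pairs < 1) stopf("overlap$n_pairs must be >= 1")
  invisible(config)
}

#' Run the full pipeline on synthetic data
#'
#' Chains simulate, cluster, map, ALE meta-analysis, overlap and set-based
#' association with stage-specific sub-seeds derived from the global seed,
#' writes every artefact under `outdir` (TSV tables, Newick dendrograms,
#' uncompressed NIfTI maps) and returns a manifest recording parameters,
#' seeds and the MD5 of every output so a repeated run can be verified
#' byte-for-byte.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param outdir Output directory.
#' @return The manifest (also written to `outdir/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- config$simulate
  scfg <- sim_config(
    n_regions = s$n_regions, n_genes = s$n_genes,
    cluster_sizes = s$cluster_sizes,
    within_cluster_corr_target = s$within_cluster_corr_target,
    n_brains = s$n_brains, n_studies = s$n_studies,
    noise_foci_per_study = s$noise_foci_per_study,
    foci_jitter_sd = s$foci_jitter_sd,
    true_loci = matrix(s$true_locus, nrow = 1),
    n_cases = s$n_cases, n_controls = s$n_controls,
    n_snps_per_gene = s$n_snps_per_gene, ld_block_corr = s$ld_block_corr,
    effect_snp_ids = s$effect_snp_ids,
    effect_odds_ratio = s$effect_odds_ratio,
    seed = derive_seed(config$seed, 1L))
  mask <- gen_brain_mask(config$mask$voxel_size_mm, config$mask$semi_axes_mm)

  # stage 1: simulate
  sim <- gen_expression(scfg)
  foci <- gen_foci_studies(scfg, mask)
  geno <- gen_genotypes(scfg)
  write_expression_tsv(sim$expression, sim$regions, outdir)
  for (dir_lab in unique(foci$direction))
    write_foci(filter(foci, .data$direction == dir_lab),
               file.path(outdir, paste0("foci_", gsub("[^A-Za-z]", "",
                                                      dir_lab), ".txt")))
  write_ped_map(geno$genotypes, file.path(outdir, "genotypes"))

  # stage 2: cluster + consensus + maps + peaks
  zs <- zscore_genes(collapse_probes(sim$expression))
  brains <- unique(zs$brain)
  dends <- lapply(brains, function(b)
    cluster_genes(filter(zs, .data$brain == b),
                  cut_height = config$cluster$cut_height))
  names(dends) <- brains
  cons <- consensus_clusters(dends[[1]]$labels, dends[[2]]$labels,
                             min_cluster_size = config$cluster$min_cluster_size)
  readr::write_tsv(tidy(cons), file.path(outdir, "clusters.tsv"))
  for (b in brains)
    write_dendrogram_newick(dends[[b]],
                            file.path(outdir, paste0("dendrogram_", b, ".nwk")))
  peak_rows <- list()
  for (cl in sort(unique(stats::na.omit(cons$cluster)))) {
    zmap <- cluster_zmap(zs, cons, cl, sim$regions, grid = mask,
                         fwhm_mm = config$cluster$fwhm_mm)
    write_voxel_map(zmap, file.path(outdir, paste0("zmap_", cl, ".nii")))
    pk <- extract_extrema(zmap, z_threshold = config$cluster$z_threshold,
                          min_separation_mm = config$cluster$min_separation_mm)
    if (nrow(pk)) peak_rows[[cl]] <- mutate(pk, cluster = cl)
  }
  peaks <- bind_rows(peak_rows)
  readr::write_tsv(peaks, file.path(outdir, "expression_peaks.tsv"))

  # stage 3: ALE per direction
  cluster_rows <- list()
  for (dir_lab in unique(foci$direction)) {
    res <- ale_meta(filter(foci, .data$direction == dir_lab), mask,
                    n_perm = config$ale$n_perm, q = config$ale$q,
                    min_volume_mm3 = config$ale$min_volume_mm3,
                    pooling = config$ale$pooling,
                    seed = derive_seed(config$seed, 3L))
    write_voxel_map(res$ale, file.path(outdir, paste0(
      "ale_", gsub("[^A-Za-z]", "", dir_lab), ".nii")))
    if (nrow(res$clusters))
      cluster_rows[[dir_lab]] <- mutate(res$clusters, direction = dir_lab)
  }
  mri_clusters <- bind_rows(cluster_rows)
  readr::write_tsv(mri_clusters, file.path(outdir, "ale_clusters.tsv"))

  # stage 4: distance null + overlap
  dnull <- sample_null(mask, n_pairs = config$overlap$n_pairs,
                       seed = derive_seed(config$seed, 4L))
  cps <- alpha_cutpoints(dnull, config$overlap$alphas)
  ov <- if (nrow(peaks) && nrow(mri_clusters))
    overlap_table(peaks,
                  mutate(mri_clusters,
                         label = sprintf("%s_%d", .data$direction,
                                         dplyr::row_number())), cps)
  else tibble(mri_label = character(0), cluster = character(0),
              distance_mm = numeric(0), level = numeric(0))
  readr::write_tsv(ov, file.path(outdir, "overlap.tsv"))

  # stage 5 + 6: gene sets and set-based association
  assoc <- set_assoc_table(
    geno$genotypes, zs, config$sets$index_genes, assignment = cons,
    n_perm = config$assoc$n_perm, seed = derive_seed(config$seed, 6L),
    r2_max = config$assoc$r2_max, p_include = config$assoc$p_include)
  readr::write_tsv(assoc, file.path(outdir, "set_association.tsv"))

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    config = unclass(config),
    stage_seeds = list(simulate = derive_seed(config$seed, 1L),
                       ale = derive_seed(config$seed, 3L),
                       overlap = derive_seed(config$seed, 4L),
                       assoc = derive_seed(config$seed, 6L)),
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outdir, f)))),
    cutpoints_mm = as.list(cps))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
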