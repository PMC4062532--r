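#' Simulation configuration for synthetic pipeline inputs
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' Defaults reproduce the study conditions the pipeline is designed around:
#' ~900 sampled brain regions in two donor brains, 60 candidate genes of
#' which 22 carry planted expression clusters of sizes 9/9/4, 18 imaging
#' studies with a convergent locus plus uniform noise foci, and a
#' case/control genotype panel (2200 cases, 1436 controls) with LD-blocked
#' SNPs and optional planted risk alleles.
#'
#' @param n_regions Number of sampled brain regions per donor (left/right
#'   mirrored pairs; one midline region if odd).
#' @param n_genes Number of genes.
#' @param cluster_sizes Integer vector of planted expression-cluster sizes;
#'   `sum(cluster_sizes) <= n_genes`. Remaining genes are pure noise.
#' @param within_cluster_corr_target Target mean pairwise Pearson correlation
#'   between genes of the same planted cluster, in (0, 1]. A target of 1
#'   switches gene- and donor-level noise off entirely.
#' @param n_brains Number of donor brains.
#' @param region_coord_bounds Named list with elements `x`, `y`, `z`, each a
#'   length-2 mm range; right-hemisphere regions are sampled in this box
#'   (intersected with the default ellipsoid) and mirrored through x = 0.
#' @param field_bandwidth_mm Bandwidth of the Gaussian kernel that smooths
#'   the latent white-noise fields into spatially contiguous expression
#'   territories.
#' @param donor_noise_frac Donor-level noise variance as a fraction of
#'   gene-level noise variance.
#' @param n_probes_per_gene Microarray probes simulated per gene (probe
#'   values are the gene profile plus probe noise when > 1).
#' @param probe_noise_sd Probe-level noise SD (log-intensity units).
#' @param n_studies Number of imaging studies.
#' @param subjects_per_study Length-2 integer range; subject counts are drawn
#'   uniformly from it.
#' @param true_loci Matrix (rows = loci) of 3D mm coordinates at which the
#'   studies' foci converge; may have zero rows.
#' @param noise_foci_per_study Number of additional foci per study drawn
#'   uniformly over the brain mask.
#' @param foci_jitter_sd Isotropic Gaussian jitter SD (mm) applied to each
#'   study's report of a true locus.
#' @param prop_con_gt_bd Probability that a study's contrast direction is
#'   `CON>BD` (the rest are `BD>CON`).
#' @param n_cases,n_controls Case/control sample sizes.
#' @param n_snps_per_gene SNPs simulated per gene (one LD block per gene).
#' @param ld_block_corr Autoregressive correlation of the latent haplotype
#'   liabilities within an LD block, in [0, 1).
#' @param maf_range Length-2 range of minor-allele frequencies (uniform).
#' @param effect_snp_ids Character vector of SNP ids (format `<gene>_s<j>`)
#'   carrying a phenotype effect; empty for a null simulation.
#' @param effect_odds_ratio Per-effect-allele odds ratio (> 0) applied to
#'   every SNP in `effect_snp_ids`.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 896,
                       n_genes = 60,
                       cluster_sizes = c(9, 9, 4),
                       within_cluster_corr_target = 0.6,
                       n_brains = 2,
                       region_coord_bounds = list(x = c(4, 66), y = c(-84, 84),
                                                  z = c(-57, 57)),
                       field_bandwidth_mm = 20,
                       donor_noise_frac = 0.25,
                       n_probes_per_gene = 1,
                       probe_noise_sd = 0.2,
                       n_studies = 18,
                       subjects_per_study = c(12, 100),
                       true_loci = matrix(c(-24, -30, -12), nrow = 1),
                       noise_foci_per_study = 3,
                       foci_jitter_sd = 5,
                       prop_con_gt_bd = 0.8,
                       n_cases = 2200,
                       n_controls = 1436,
                       n_snps_per_gene = 8,
                       ld_block_corr = 0.8,
                       maf_range = c(0.1, 0.5),
                       effect_snp_ids = character(0),
                       effect_odds_ratio = 1.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_regions = n_regions, n_genes = n_genes, n_brains = n_brains,
              n_studies = n_studies, n_cases = n_cases, n_controls = n_controls,
              n_snps_per_gene = n_snps_per_gene,
              n_probes_per_gene = n_probes_per_gene)
  if (any(counts < 1)) stopf("all counts must be positive")
  if (length(cluster_sizes) >= 1 && any(cluster_sizes < 1))
    stopf("`cluster_sizes` must be positive")
  if (sum(cluster_sizes) > n_genes)
    stopf("sum(cluster_sizes) = %d exceeds n_genes = %d",
          sum(cluster_sizes), n_genes)
  assert_scalar_num(within_cluster_corr_target, "within_cluster_corr_target",
                    lower = 1e-6, upper = 1)
  assert_scalar_num(ld_block_corr, "ld_block_corr", lower = 0, upper = 1 - 1e-9)
  if (effect_odds_ratio <= 0) stopf("`effect_odds_ratio` must be > 0")
  if (noise_foci_per_study < 0) stopf("`noise_foci_per_study` must be >= 0")
  if (!is.matrix(true_loci)) true_loci <- matrix(true_loci, ncol = 3)
  cfg$true_loci <- true_loci
  structure(cfg, class = "sim_config")
}

gene_names <- function(n) sprintf("G%02d", seq_len(n))

#' Simulate regional gene-expression matrices with planted clusters
#'
#' Generates per-donor gene-by-region expression with the statistical
#' structure the clustering pipeline assumes: each planted cluster shares a
#' spatially smooth latent profile (Gaussian-kernel smoothed white noise over
#' the region coordinates), to which gene-level noise (shared across donors)
#' and donor-level noise are added; unclustered genes are independent noise.
#' Mixing weights are chosen so the realised mean within-cluster pairwise
#' correlation tracks `within_cluster_corr_target`.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `expression`: tibble with columns `brain`, `probe`, `gene`,
#'     `region_id`, `value` (log-intensity-like units);
#'   * `regions`: tibble with columns `region_id`, `structure_name`, `x`,
#'     `y`, `z`, `hemisphere`;
#'   * `truth`: tibble with columns `gene`, `cluster` (`NA` for noise genes).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 11L), {
    regions <- sample_regions(config)
    n_r <- nrow(regions)
    coords <- as.matrix(regions[, c("x", "y", "z")])

    k <- length(config$cluster_sizes)
    rho <- config$within_cluster_corr_target
    noise_var <- 1 - rho
    gene_var <- noise_var / (1 + config$donor_noise_frac)
    donor_var <- noise_var - gene_var

    # latent cluster fields: kernel-smoothed white noise, orthogonalised
    # over the sampled regions (distinct clusters must not share signal:
    # cross-cluster correlation stays near zero by construction), then
    # standardised
    latent <- NULL
    if (k > 0) {
      d2 <- as.matrix(stats::dist(coords))^2
      kern <- exp(-d2 / (2 * config$field_bandwidth_mm^2))
      latent <- vapply(seq_len(k), function(i) {
        f <- as.numeric(kern %*% rnorm(n_r))
        f - mean(f)
      }, numeric(n_r))
      for (i in seq_len(k)) {
        if (i > 1) {
          prev <- latent[, seq_len(i - 1), drop = FALSE]
          coef <- crossprod(prev, latent[, i]) / colSums(prev^2)
          latent[, i] <- latent[, i] - as.numeric(prev %*% coef)
        }
        latent[, i] <- latent[, i] / sd(latent[, i])
      }
    }

    genes <- gene_names(config$n_genes)
    truth <- rep(NA_character_, config$n_genes)
    if (k > 0)
      truth[seq_len(sum(config$cluster_sizes))] <-
        rep(sprintf("C%d", seq_len(k)), config$cluster_sizes)

    std <- function(v) (v - mean(v)) / sd(v)
    gene_noise <- vapply(seq_len(config$n_genes),
                         function(i) std(rnorm(n_r)), numeric(n_r))
    baseline <- runif(config$n_genes, 5, 9)

    rows <- vector("list", config$n_brains)
    for (b in seq_len(config$n_brains)) {
      donor_noise <- vapply(seq_len(config$n_genes),
                            function(i) std(rnorm(n_r)), numeric(n_r))
      prof <- matrix(0, n_r, config$n_genes)
      for (i in seq_len(config$n_genes)) {
        p <- if (!is.na(truth[i])) {
          cl <- match(truth[i], sprintf("C%d", seq_len(k)))
          sqrt(rho) * latent[, cl] + sqrt(gene_var) * gene_noise[, i] +
            sqrt(donor_var) * donor_noise[, i]
        } else {
          gene_noise[, i]
        }
        prof[, i] <- baseline[i] + 1.5 * p
      }
      per_probe <- lapply(seq_len(config$n_probes_per_gene), function(j) {
        v <- prof
        if (config$n_probes_per_gene > 1)
          v <- v + matrix(rnorm(length(prof), sd = config$probe_noise_sd),
                          nrow(prof))
        tibble(
          brain = sprintf("donor%d", b),
          probe = rep(sprintf("%s_p%d", genes, j), each = n_r),
          gene = rep(genes, each = n_r),
          region_id = rep(regions$region_id, config$n_genes),
          value = as.numeric(v)
        )
      })
      rows[[b]] <- bind_rows(per_probe)
    }
    list(
      expression = bind_rows(rows),
      regions = regions,
      truth = tibble(gene = genes, cluster = truth)
    )
  })
}

# right-hemisphere regions uniform in the coordinate box intersected with the
# default ellipsoid, then mirrored through x = 0; midline region if n is odd
sample_regions <- function(config) {
  b <- config$region_coord_bounds
  nh <- config$n_regions %/% 2L
  n_mid <- config$n_regions - 2L * nh
  semi <- c(68, 86, 59)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < nh) {
    m <- cbind(runif(2 * nh, b$x[1], b$x[2]), runif(2 * nh, b$y[1], b$y[2]),
               runif(2 * nh, b$z[1], b$z[2]))
    ok <- rowSums(sweep(m, 2, semi, `/`)^2) <= 1
    pts <- rbind(pts, m[ok, , drop = FALSE])
  }
  pts <- pts[seq_len(nh), , drop = FALSE]
  right <- tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                  hemisphere = "right")
  left <- tibble(x = -pts[, 1], y = pts[, 2], z = pts[, 3],
                 hemisphere = "left")
  mid <- if (n_mid > 0)
    tibble(x = 0, y = runif(n_mid, b$y[1], b$y[2]),
           z = runif(n_mid, b$z[1], b$z[2]), hemisphere = "midline")
  else NULL
  out <- bind_rows(right, left, mid)
  out <- mutate(out,
                region_id = sprintf("R%04d", seq_len(nrow(out))),
                structure_name = sprintf("synthetic_region_%04d",
                                         seq_len(nrow(out))))
  select(out, "region_id", "structure_name", "x", "y", "z", "hemisphere")
}

#' Simulate per-study foci tables
#'
#' Each study reports one jittered focus per planted locus plus a number of
#' noise foci uniform over the brain mask, together with a subject count and
#' a contrast direction, mimicking the coordinate tables of a voxel-based
#' morphometry literature.
#'
#' @param config A [sim_config()].
#' @param mask A `voxel_map` brain mask; defaults to the Talairach-like
#'   ellipsoid of [gen_brain_mask()].
#' @return Tibble with columns `study_id`, `n_subjects`, `space`,
#'   `direction`, `x`, `y`, `z` (one row per focus, Talairach mm).
#' @export
gen_foci_studies <- function(config, mask = gen_brain_mask()) {
  stopifnot(inherits(config, "sim_config"))
  mask_idx <- which(mask$mask)
  if (length(mask_idx) == 0L) stopf("brain mask is empty")
  loci <- config$true_loci
  if (nrow(loci) > 0) {
    inside <- mask$mask[coords_to_index(mask, loci)]
    if (!all(inside)) stopf("true_loci must lie inside the brain mask")
  }
  with_seed(derive_seed(config$seed, 23L), {
    out <- vector("list", config$n_studies)
    for (s in seq_len(config$n_studies)) {
      n_sub <- sample(seq(config$subjects_per_study[1],
                          config$subjects_per_study[2]), 1L)
      dir <- if (runif(1) < config$prop_con_gt_bd) "CON>BD" else "BD>CON"
      f_true <- if (nrow(loci) > 0)
        loci + matrix(rnorm(3 * nrow(loci), sd = config$foci_jitter_sd),
                      ncol = 3)
      else matrix(numeric(0), 0, 3)
      f_noise <- if (config$noise_foci_per_study > 0)
        voxel_coords(mask, sample(mask_idx, config$noise_foci_per_study,
                                  replace = TRUE))
      else matrix(numeric(0), 0, 3)
      f <- rbind(f_true, f_noise)
      out[[s]] <- tibble(study_id = sprintf("study%02d", s),
                         n_subjects = n_sub, space = "Talairach",
                         direction = dir,
                         x = f[, 1], y = f[, 2], z = f[, 3])
    }
    bind_rows(out)
  })
}

#' Simulate LD-blocked case/control genotypes
#'
#' One LD block per gene: latent haplotype liabilities follow an AR(1)
#' process with correlation `ld_block_corr` across the block's SNPs and are
#' thresholded at the SNP's allele frequency; dosage is the sum of two
#' haplotypes. Case/control status follows a logistic model with
#' `log(effect_odds_ratio)` per effect-allele copy at the planted effect
#' SNPs and zero elsewhere; cases and controls are accumulated until the
#' configured quotas are met, so the returned sample sizes are exact.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of gene labels to simulate blocks for;
#'   defaults to all `n_genes` gene labels.
#' @return A list with elements `genotypes` (a `genotype_data` object, see
#'   [genotype_data()]) and `effect_snps` (the planted effect SNP ids).
#' @export
gen_genotypes <- function(config, genes = gene_names(config$n_genes)) {
  stopifnot(inherits(config, "sim_config"))
  m_per <- config$n_snps_per_gene
  snp_ids <- as.character(t(outer(genes, seq_len(m_per),
                                  function(g, j) sprintf("%s_s%d", g, j))))
  if (!all(config$effect_snp_ids %in% snp_ids))
    stopf("effect_snp_ids must be among the simulated SNPs")
  m <- length(snp_ids)
  eff_idx <- match(config$effect_snp_ids, snp_ids)
  log_or <- log(config$effect_odds_ratio)

  with_seed(derive_seed(config$seed, 37L), {
    # one allele frequency per LD block: equal thresholds keep the dosage
    # r^2 of tightly linked SNPs close to the latent correlation
    maf <- rep(runif(length(genes), config$maf_range[1],
                     config$maf_range[2]), each = m_per)
    thr <- qnorm(maf)
    n_target <- c(cases = config$n_cases, controls = config$n_controls)
    # intercept roughly centres the case fraction at the design ratio
    beta0 <- stats::qlogis(n_target[1] / sum(n_target)) -
      log_or * sum(2 * maf[eff_idx])

    sim_batch <- function(n) {
      hap <- function() {
        z <- matrix(0, n, m)
        rho <- config$ld_block_corr
        for (g in seq_along(genes)) {
          j0 <- (g - 1L) * m_per
          z[, j0 + 1L] <- rnorm(n)
          if (m_per > 1) for (j in 2:m_per)
            z[, j0 + j] <- rho * z[, j0 + j - 1L] +
              sqrt(1 - rho^2) * rnorm(n)
        }
        sweep(z, 2, thr, `<`) + 0L
      }
      hap() + hap()
    }

    cases <- controls <- NULL
    need <- function() is.null(cases) || nrow(cases) < n_target[1] ||
      is.null(controls) || nrow(controls) < n_target[2]
    while (need()) {
      batch <- sim_batch(max(1000L, sum(n_target) %/% 2L))
      eta <- beta0 + if (length(eff_idx))
        as.numeric(batch[, eff_idx, drop = FALSE] %*% rep(log_or,
                                                          length(eff_idx)))
      else 0
      is_case <- runif(nrow(batch)) < stats::plogis(eta)
      cases <- rbind(cases, batch[is_case, , drop = FALSE])
      controls <- rbind(controls, batch[!is_case, , drop = FALSE])
    }
    dos <- rbind(cases[seq_len(n_target[1]), , drop = FALSE],
                 controls[seq_len(n_target[2]), , drop = FALSE])
    colnames(dos) <- snp_ids
    rownames(dos) <- sprintf("S%05d", seq_len(nrow(dos)))
    g <- genotype_data(
      dosages = dos,
      phenotype = rep(c(1L, 0L), n_target),
      snp_info = tibble(snp_id = snp_ids,
                        gene = rep(genes, each = m_per),
                        chrom = rep(seq_along(genes), each = m_per),
                        pos = rep(seq_len(m_per) * 5000L, length(genes)))
    )
    list(genotypes = g, effect_snps = config$effect_snp_ids)
  })
}
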