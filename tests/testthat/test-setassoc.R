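test_that("trend statistic matches hand arithmetic and prop.trend.test", {
  # perfect separation: 20 cases all dosage 2, 20 controls all dosage 0
  g <- small_genotypes(cbind(s1 = rep(c(2L, 0L), each = 20)),
                       rep(c(1L, 0L), each = 20))
  out <- snp_stat(g, "s1")
  expect_equal(out$statistic, 40)            # N * cor(y, x)^2 with r = 1
  expect_false(out$monomorphic)
  set.seed(9)
  for (case in 1:20) {
    n <- 60
    x <- sample(0:2, n, replace = TRUE)
    y <- rbinom(n, 1, 0.4 + 0.1 * x / 2)
    if (var(x) == 0 || var(y) == 0) next
    g <- small_genotypes(cbind(s1 = as.integer(x)), y)
    ours <- snp_stat(g, "s1")
    tab <- table(factor(x, 0:2), factor(y, 0:1))
    ref <- suppressWarnings(
      prop.trend.test(tab[, "1"], rowSums(tab), score = 0:2))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("trend statistic is invariant under label swap with recoding", {
  set.seed(2)
  x <- sample(0:2, 50, replace = TRUE)
  y <- rbinom(50, 1, 0.5)
  a <- snp_stat(small_genotypes(cbind(s1 = as.integer(x)), y), "s1")
  b <- snp_stat(small_genotypes(cbind(s1 = as.integer(2L - x)), 1L - y), "s1")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("monomorphic SNPs are flagged with a null statistic", {
  g <- small_genotypes(cbind(s1 = rep(1L, 30)), rep(c(1L, 0L), 15))
  out <- snp_stat(g, "s1")
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  expect_true(out$monomorphic)
  expect_error(snp_stat(g, "nope"), "not present")
})

test_that("LD r-squared is the squared dosage correlation", {
  d <- cbind(s1 = c(0L, 0L, 2L, 2L), s2 = c(0L, 0L, 2L, 2L),
             s3 = c(0L, 2L, 0L, 2L), s4 = rep(1L, 4))
  g <- small_genotypes(d, c(1L, 0L, 1L, 0L))
  expect_equal(ld_r2(g, "s1", "s2"), 1)
  expect_equal(ld_r2(g, "s1", "s3"), 0)
  expect_error(ld_r2(g, "s1", "s4"), "monomorphic")
})

test_that("under a null phenotype per-SNP rejections stay near alpha", {
  cfg <- sim_config(n_genes = 100, cluster_sizes = c(2), n_snps_per_gene = 5,
                    n_cases = 250, n_controls = 250, ld_block_corr = 0,
                    seed = 77L)
  g <- gen_genotypes(cfg)$genotypes
  st <- neurexmap:::trend_stats(g$dosages, g$phenotype)
  p <- pchisq(st, 1, lower.tail = FALSE)
  rate <- mean(p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 0.005)
})

test_that("informative-marker selection follows the greedy definition", {
  # perfectly correlated SNPs: only the most significant survives
  d <- cbind(s1 = c(0L, 0L, 1L, 2L, 2L, 1L), s2 = c(0L, 0L, 1L, 2L, 2L, 1L),
             s3 = c(0L, 0L, 1L, 2L, 2L, 1L))
  g <- small_genotypes(d, c(0L, 0L, 0L, 1L, 1L, 1L))
  sel <- select_informative(g, c("s1", "s2", "s3"), p_include = 1)
  expect_equal(length(sel), 1)
  expect_equal(sel, "s1")   # equal p: lexicographic tie-break
  # independent significant SNPs are all kept
  set.seed(33)
  n <- 200
  y <- rep(c(1L, 0L), each = n / 2)
  dos <- sapply(1:4, function(j)
    as.integer(pmin(2, rbinom(n, 2, 0.3 + 0.25 * y))))
  colnames(dos) <- paste0("t", 1:4)
  g2 <- small_genotypes(dos, y)
  r2 <- cor(dos)^2
  if (max(r2[upper.tri(r2)]) < 0.5) {
    sel2 <- select_informative(g2, paste0("t", 1:4))
    expect_setequal(sel2, paste0("t", 1:4))
  }
})

test_that("greedy selection matches the exhaustive replay oracle", {
  set.seed(51)
  for (case in 1:50) {
    m <- sample(3:12, 1)
    n <- 80
    dos <- matrix(as.integer(rbinom(n * m, 2, runif(1, 0.2, 0.5))), n)
    colnames(dos) <- sprintf("s%02d", sample(m))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    g <- small_genotypes(dos, y)
    st <- neurexmap:::trend_stats(dos, y)
    p <- pchisq(st, 1, lower.tail = FALSE); p[st == 0] <- 1
    r2 <- suppressWarnings(cor(dos)^2); r2[!is.finite(r2)] <- 1
    r2_max <- sample(c(0.2, 0.5, 0.8), 1)
    p_inc <- sample(c(0.05, 0.5, 1), 1)
    sel <- select_informative(g, colnames(dos), r2_max = r2_max,
                              p_include = p_inc)
    expect_identical(sel, oracle_select(colnames(dos), p, r2, r2_max, p_inc))
    # invariant: retained SNPs are pairwise below the r^2 bound
    if (length(sel) > 1) {
      rs <- r2[sel, sel]
      expect_lt(max(rs[upper.tri(rs)]), r2_max)
    }
  }
})

test_that("set test p-values are valid, reproducible and order-invariant", {
  cfg <- sim_config(n_genes = 4, cluster_sizes = c(2), n_snps_per_gene = 4,
                    n_cases = 80, n_controls = 80, seed = 3L)
  g <- gen_genotypes(cfg)$genotypes
  r1 <- set_test(g, c("G01", "G02"), n_perm = 99, seed = 5L)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  r2 <- set_test(g, c("G01", "G02"), n_perm = 99, seed = 5L)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$perm_stats, r2$perm_stats)
  r3 <- set_test(g, c("G02", "G01"), n_perm = 99, seed = 5L)
  expect_equal(r1$statistic, r3$statistic)
  expect_equal(r1$p, r3$p)
  expect_error(set_test(g, c("NOPE"), n_perm = 9), "no genotyped SNPs")
})

test_that("power rises with sample size at a fixed odds ratio", {
  p_at_n <- function(n, s) {
    cfg <- sim_config(n_genes = 5, cluster_sizes = c(2), n_snps_per_gene = 4,
                      n_cases = n, n_controls = n,
                      effect_snp_ids = sprintf("G01_s%d", 1:2),
                      effect_odds_ratio = 1.5, seed = s)
    g <- gen_genotypes(cfg)$genotypes
    set_test(g, sprintf("G%02d", 1:5), n_perm = 99, seed = 100 + s)$p
  }
  small <- vapply(1:8, function(s) p_at_n(60, s), numeric(1))
  large <- vapply(1:8, function(s) p_at_n(500, s), numeric(1))
  expect_lt(median(large), median(small))
})
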