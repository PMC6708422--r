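test_that("r2 matches hand-counted haplotype examples", {
  x <- c(rep(1, 50), rep(0, 50))
  expect_equal(r2(x, x), 1)
  # counts (AB, Ab, aB, ab) = (40, 10, 10, 40): D = 0.15, r2 = 0.36
  a <- c(rep(1, 40), rep(1, 10), rep(0, 10), rep(0, 40))
  b <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(r2(a, b), 0.36)
  # independent loci (25, 25, 25, 25)
  a <- rep(c(1, 1, 0, 0), 25)
  b <- rep(c(1, 0, 1, 0), 25)
  expect_equal(r2(a, b), 0)
  # monomorphic input is missing, not an error
  expect_true(is.na(r2(rep(1, 10), rbinom(10, 1, 0.5))))
  expect_error(r2(1, c(1, 0)), "equal length")
})

test_that("r2 agrees with the contingency-count oracle on all 4-haplotype pairs", {
  grid <- expand.grid(replicate(4, 0:1, simplify = FALSE))
  for (i in seq_len(16)) {
    for (j in seq_len(16)) {
      x <- as.numeric(grid[i, ]); y <- as.numeric(grid[j, ])
      ours <- r2(x, y)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) {
        expect_true(is.na(ours))
      } else {
        expect_equal(ours, suppressWarnings(stats::cor(x, y))^2,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(50)
  for (k in 1:20) {
    x <- rbinom(30, 1, 0.5); y <- rbinom(30, 1, 0.5)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(r2(x, y), r2(y, x))
    expect_equal(r2(x, y), r2(1 - x, y))
    expect_equal(r2(x, y), r2(x, 1 - y))
  }
})

test_that("r2 drops missing entries pairwise", {
  a <- c(1, 1, 0, 0, NA, 1)
  b <- c(1, NA, 0, 1, 0, 1)
  keep <- !is.na(a) & !is.na(b)
  expect_equal(r2(a, b), suppressWarnings(stats::cor(a[keep], b[keep]))^2)
})

test_that("the decay curve enumerates small sets exactly", {
  m <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 0), c(0, 0, 1))
  hs <- toy_hs(m, cm = c(0.2, 1.4, 2.6))
  cur <- ld_decay_curve(hs, bin_width = 1, max_cm = 5)
  expect_equal(sum(cur$n_pairs), 3L)  # exactly the three pairs
  expect_equal(cur$n_pairs[1:3], c(0L, 2L, 1L))  # distances 1.2, 1.2, 2.4
  expect_true(all(cur$mean_r2 >= 0, na.rm = TRUE))
})

test_that("selfing raises short-range LD relative to random mating", {
  lvl <- function(s_out, seed) {
    set.seed(seed)
    cur <- simulate_ld_decay(s_out, sim_params(N = 100, mu = 5e-4, lambda_xo = 1,
                                               s_out = 0.5, n_chrom = 4,
                                               n_loci = 250),
                             generations = 120, max_pairs = 15000)
    mean(cur$mean_r2[1:3], na.rm = TRUE)
  }
  selfing <- sapply(1:5, function(k) lvl(0.03, 60 + k))
  outcrossing <- sapply(1:5, function(k) lvl(1.0, 80 + k))
  expect_gt(stats::median(selfing), stats::median(outcrossing))
})

test_that("background LD percentile is deterministic and near the null level", {
  set.seed(52)
  # independent loci on two chromosomes: r2 between n haplotypes ~ 1/n scale
  n <- 200
  mat <- matrix(rbinom(2 * n * 60, 1, 0.5), nrow = 2 * n)
  loci <- rbind(toy_loci(30, "1A"), toy_loci(30, "2B"))
  loci$locus <- paste0(loci$chrom, "_", seq_len(60))
  hs <- haplotype_set(mat, paste0("i", 1:n), loci)
  set.seed(7); q1 <- background_ld_percentile(hs, 0.99, n_pairs = 20000)
  set.seed(7); q2 <- background_ld_percentile(hs, 0.99, n_pairs = 20000)
  expect_identical(q1, q2)
  # chi-square null: r2 ~ chisq_1 / n_hap, so P99 is about 6.6 / n_hap
  expect_lt(q1, 3 * 6.63 / (2 * n))
  expect_gt(q1, 6.63 / (3 * 2 * n))
  expect_error(background_ld_percentile(toy_hs(matrix(0L, 2, 3))), "two chromosomes")
})

test_that("the inter-region verdict follows the strict-majority rule", {
  cfg <- ld_config()
  # 6 x 5 SNP matrix, flat r2 pattern (no outliers): 4/6 and 3/5 above 0.161
  m <- matrix(0.1, 6, 5)
  m[1:4, ] <- 0.3   # rows 1-4 have median 0.3
  m[, 1:3] <- m[, 1:3] + 0.05  # columns 1-3 medians pushed above the cut
  res <- interregion_verdict(m, cfg, threshold = 0.161)
  expect_true(res$eligible)
  frac_x <- mean(apply(m, 1, median) > 0.161)
  frac_y <- mean(apply(m, 2, median) > 0.161)
  expect_equal(res$frac_x, frac_x)
  expect_equal(res$frac_y, frac_y)
  expect_equal(res$in_ld, frac_x > 0.5 && frac_y > 0.5)

  # strict majority: exactly half is not enough
  m2 <- rbind(matrix(0.3, 3, 4), matrix(0.05, 3, 4))
  res2 <- interregion_verdict(m2, cfg, threshold = 0.161)
  expect_equal(res2$frac_x, 0.5)
  expect_false(res2$in_ld)

  # all-1 and all-0 corner cases
  expect_true(interregion_verdict(matrix(1, 5, 5), cfg)$in_ld)
  expect_equal(interregion_verdict(matrix(1, 5, 5), cfg)$max_r2, 1)
  expect_false(interregion_verdict(matrix(0, 5, 5), cfg)$in_ld)
})

test_that("outlier SNPs are excluded before the verdict", {
  cfg <- ld_config()
  m <- matrix(0.05, 8, 8)
  m[1, ] <- 0.95  # one SNP wildly off the general pattern
  res <- interregion_verdict(m, cfg, threshold = 0.161)
  expect_false(1 %in% res$retained_x)
  expect_false(res$in_ld)
  expect_lt(res$max_r2, 0.95)  # the outlier row cannot set the report
})

test_that("interregion_ld is invariant to SNP order and honours min_snps", {
  hs <- sim_toy_hs(seed = 53, n_ind = 40, n_loci = 60, n_chrom = 2,
                   mu = 2e-3, s_out = 0.3, generations = 30)
  f <- colMeans(hs$alleles)
  poly <- which(f > 0.1 & f < 0.9)
  rx <- poly[poly <= 60][1:6]
  ry <- poly[poly > 60][1:6]
  a <- interregion_ld(rx, ry, hs)
  b <- interregion_ld(sample(rx), sample(ry), hs)
  expect_equal(a$in_ld, b$in_ld)
  expect_equal(a$max_r2, b$max_r2)
  expect_false(interregion_ld(rx[1:3], ry, hs)$eligible)
})

test_that("ld_cluster reports components and per-component mean r2", {
  # three regions on different chromosomes in perfect pairwise LD, one
  # independent region: expect one 3-clique plus a singleton
  n <- 30
  set.seed(54)
  base <- rbinom(2 * n, 1, 0.5)
  indep <- matrix(rbinom(2 * n * 6, 1, 0.5), ncol = 6)
  mat <- cbind(matrix(base, 2 * n, 18), indep)
  loci <- do.call(rbind, lapply(c("1A", "2B", "3D", "5A"), function(ch) toy_loci(6, ch)))
  loci$locus <- paste0(loci$chrom, "_", seq_len(24))
  hs <- haplotype_set(mat, paste0("i", 1:n), loci)
  sweeps <- sweep_table(chr = c("1A", "2B", "3D", "5A"),
                        pos_start = rep(1, 4), pos_end = rep(6, 4),
                        pops = rep(list("Post70"), 4),
                        methods = rep(list("FST"), 4))
  cl <- ld_cluster(sweeps, hs, threshold = 0.161)
  sizes <- table(cl$membership$component)
  expect_setequal(as.integer(sizes), c(3L, 1L))
  expect_equal(nrow(cl$edges), 3L)  # the clique's three edges
  expect_equal(cl$mean_r2, 1)

  # no in-LD pairs -> all singletons
  hs2 <- hs; hs2$alleles <- matrix(rbinom(2 * n * 24, 1, 0.5), ncol = 24)
  cl2 <- ld_cluster(sweeps, hs2, threshold = 0.5)
  expect_equal(length(unique(cl2$membership$component)), 4L)
})
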