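test_that("monomorphic initialization has zero heterozygosity", {
  p <- sim_params(N = 20, mu = 0, lambda_xo = 1, s_out = 0.5,
                  n_chrom = 1, n_loci = 30)
  pop <- initialize_population(p, "monomorphic")
  expect_equal(observed_heterozygosity(pop), 0)
})

test_that("stationary initialization is Hardy-Weinberg under random mating", {
  set.seed(101)
  p <- sim_params(N = 800, mu = 3e-4, lambda_xo = 1, s_out = 1,
                  n_chrom = 1, n_loci = 1500)
  pop <- initialize_population(p, "stationary")
  f <- allele_freqs(pop)[[1]]
  poly <- f > 0.05 & f < 0.95
  m <- pop$haps[[1]]
  odd <- m[poly, seq(1, 2 * p$N, 2)]
  even <- m[poly, seq(2, 2 * p$N, 2)]
  obs <- rowMeans(odd != even)
  expd <- 2 * f[poly] * (1 - f[poly])
  # per-locus binomial error, pooled
  expect_lt(abs(mean(obs) - mean(expd)), 3 * sqrt(mean(expd) / (sum(poly) * p$N)))
})

test_that("initialization and stepping are deterministic under a seed", {
  p <- sim_params(N = 30, mu = 1e-3, lambda_xo = 1, s_out = 0.3,
                  n_chrom = 2, n_loci = 40)
  set.seed(7); a <- run_generations(initialize_population(p, "stationary"), p, 5)
  set.seed(7); b <- run_generations(initialize_population(p, "stationary"), p, 5)
  expect_identical(a$haps, b$haps)
})

test_that("a homozygous selfer is a reproductive fixed point under mu = 0", {
  p <- sim_params(N = 1, mu = 0, lambda_xo = 2, s_out = 0,
                  n_chrom = 1, n_loci = 25)
  pop <- initialize_population(p, "monomorphic")
  pop$haps[[1]][1:10, ] <- 1L  # homozygous non-trivial pattern
  off <- step_generation(pop, p, n_off = 1)
  expect_identical(off$haps, pop$haps)
})

test_that("no novel alleles arise when mu = 0", {
  set.seed(8)
  p <- sim_params(N = 40, mu = 0, lambda_xo = 1, s_out = 0.2,
                  n_chrom = 1, n_loci = 60)
  pop <- initialize_population(p, "monomorphic")
  pop$haps[[1]][1:5, 1:20] <- 1L
  had <- rowSums(pop$haps[[1]]) > 0
  pop2 <- run_generations(pop, p, 15)
  expect_true(all(pop2$haps[[1]][!had, ] == 0))
})

test_that("selfing halves heterozygosity each generation", {
  set.seed(9)
  p <- sim_params(N = 2000, mu = 0, lambda_xo = 1, s_out = 0,
                  n_chrom = 1, n_loci = 2)
  pop <- initialize_population(p, "monomorphic")
  pop$haps[[1]][, seq(1, 2 * p$N, 2)] <- 1L  # all individuals heterozygous
  h <- numeric(5)
  for (g in 1:5) {
    pop <- step_generation(pop, p)
    h[g] <- observed_heterozygosity(pop)
  }
  for (g in 1:5) {
    se <- sqrt(0.5^g * (1 - 0.5^g) / p$N)
    expect_lt(abs(h[g] - 0.5^g), 4 * se)
  }
})

test_that("found_taxon reaches the target size within the growth phase", {
  set.seed(10)
  p <- sim_params(N = 500, mu = 0, lambda_xo = 1, s_out = 0.3,
                  n_chrom = 1, n_loci = 10)
  src <- initialize_population(p, "monomorphic")
  tx <- found_taxon(src, p, growth_generations = 100)
  expect_equal(pop_size(tx), 500L)
  expect_true(all(tx$haps[[1]] == 0))  # monomorphic founder stays monomorphic
  expect_error(found_taxon(src, p, growth_generations = 0), "growth_generations")
})

test_that("taxon founding induces drift at polymorphic loci", {
  set.seed(11)
  p <- sim_params(N = 60, mu = 5e-4, lambda_xo = 1, s_out = 0.5,
                  n_chrom = 1, n_loci = 300)
  src <- initialize_population(p, "stationary")
  freqs <- replicate(8, {
    tx <- found_taxon(src, p, growth_generations = 10)
    mean(allele_freqs(tx)[[1]])
  })
  expect_gt(stats::var(freqs), 0)
})

test_that("polyploidization doubles a gamete and unions the subgenomes", {
  set.seed(12)
  p <- sim_params(N = 30, mu = 0, lambda_xo = 1, s_out = 0.5,
                  n_chrom = 2, n_loci = 40)
  A <- initialize_population(p, "stationary", subgenomes = "A", label = "A")
  B <- initialize_population(p, "stationary", subgenomes = "B", label = "B")
  # founder only: grow for one generation at size 1 to inspect the amphiploid
  AB <- polyploidize(A, B, p, growth_generations = 1)
  expect_setequal(AB$subgenomes, c("A", "B"))
  expect_setequal(names(AB$haps), c("1A", "2A", "1B", "2B"))

  # fixed differences become homoeologous, never within-subgenome
  A$haps <- lapply(A$haps, function(m) { m[] <- 1L; m })
  B$haps <- lapply(B$haps, function(m) { m[] <- 0L; m })
  AB <- polyploidize(A, B, p, growth_generations = 15)
  expect_equal(observed_heterozygosity(AB), 0)  # within-subgenome homozygous
  expect_true(all(AB$haps[["1A"]] == 1L))
  expect_true(all(AB$haps[["1B"]] == 0L))
  expect_error(polyploidize(A, A, p), "disjoint")
})

test_that("the amphiploid founder is fully homozygous", {
  set.seed(13)
  p <- sim_params(N = 30, mu = 0, lambda_xo = 1, s_out = 1,
                  n_chrom = 1, n_loci = 50)
  A <- initialize_population(p, "stationary", subgenomes = "A")
  B <- initialize_population(p, "stationary", subgenomes = "B")
  p1 <- p; p1$N <- 1L
  AB <- polyploidize(A, B, p1, growth_generations = 1)
  expect_equal(observed_heterozygosity(AB), 0)
})

test_that("split_population partitions exactly and reproducibly", {
  set.seed(14)
  p <- sim_params(N = 482, mu = 0, lambda_xo = 1, s_out = 0.5,
                  n_chrom = 1, n_loci = 20)
  pop <- initialize_population(p, "monomorphic")
  set.seed(99); s1 <- split_population(pop, 259, 223)
  set.seed(99); s2 <- split_population(pop, 259, 223)
  expect_equal(pop_size(s1[[1]]), 259L)
  expect_equal(pop_size(s1[[2]]), 223L)
  expect_identical(s1[[1]]$haps, s2[[1]]$haps)
  expect_error(split_population(pop, 300, 200), "exceeds")

  # monomorphic split: Fst estimate is NA (no polymorphic loci) -> treated 0
  expect_true(is.na(fst_genomewide(s1[[1]], s1[[2]])))
})

test_that("a fresh split of a polymorphic population has near-zero Fst", {
  set.seed(15)
  p <- sim_params(N = 200, mu = 5e-4, lambda_xo = 1, s_out = 1,
                  n_chrom = 1, n_loci = 800)
  pop <- initialize_population(p, "stationary")
  s <- split_population(pop, 100, 100)
  expect_lt(fst_genomewide(s[[1]], s[[2]]), 0.02)
})

test_that("neutral allele frequencies are a martingale", {
  set.seed(16)
  p <- sim_params(N = 30, mu = 0, lambda_xo = 1, s_out = 0.5,
                  n_chrom = 1, n_loci = 1)
  pop0 <- initialize_population(p, "monomorphic")
  pop0$haps[[1]][1, 1:18] <- 1L  # p0 = 0.3
  p0 <- mean(pop0$haps[[1]][1, ])
  final <- replicate(250, mean(run_generations(pop0, p, 10)$haps[[1]][1, ]))
  se <- stats::sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - p0), 3 * se)
})

test_that("neutral fixation probability approximates the initial frequency", {
  set.seed(17)
  p <- sim_params(N = 50, mu = 0, lambda_xo = 1, s_out = 0.5,
                  n_chrom = 1, n_loci = 1)
  pop0 <- initialize_population(p, "monomorphic")
  pop0$haps[[1]][1, 1:20] <- 1L  # p0 = 0.2
  outcomes <- replicate(500, {
    pop <- pop0
    for (g in 1:1500) {
      pop <- step_generation(pop, p)
      f <- mean(pop$haps[[1]][1, ])
      if (f == 0 || f == 1) break
    }
    f
  })
  fixed <- outcomes[outcomes %in% c(0, 1)]
  expect_gt(length(fixed), 450)  # nearly all absorbed
  phat <- mean(fixed == 1)
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / length(fixed)))
})

test_that("alleles never cross between subgenomes (disomic inheritance)", {
  set.seed(18)
  p <- sim_params(N = 25, mu = 0, lambda_xo = 2, s_out = 0.5,
                  n_chrom = 1, n_loci = 30)
  A <- initialize_population(p, "monomorphic", subgenomes = "A")
  B <- initialize_population(p, "monomorphic", subgenomes = "B")
  B$haps[[1]][] <- 1L  # tag the B subgenome
  AB <- polyploidize(A, B, p, growth_generations = 10)
  AB <- run_generations(AB, p, 20)
  expect_true(all(AB$haps[["1A"]] == 0L))
  expect_true(all(AB$haps[["1B"]] == 1L))
})

test_that("observed heterozygosity counts only polymorphic loci", {
  p <- sim_params(N = 10, mu = 0, lambda_xo = 1, s_out = 1,
                  n_chrom = 1, n_loci = 3)
  pop <- initialize_population(p, "monomorphic")
  # one polymorphic locus with exactly one heterozygote among 10 individuals
  pop$haps[[1]][2, 1] <- 1L
  expect_equal(observed_heterozygosity(pop), 0.1)
})

test_that("population checkpoints round-trip through disk", {
  set.seed(19)
  p <- sim_params(N = 8, mu = 1e-3, lambda_xo = 1, s_out = 0.3,
                  n_chrom = 2, n_loci = 30)
  pop <- run_generations(initialize_population(p, "stationary",
                                               subgenomes = c("A", "B")),
                         p, 4)
  path <- withr::local_tempfile()
  write_population(pop, path)
  back <- read_population(path)
  expect_identical(back$haps, pop$haps)
  expect_equal(back$generation, pop$generation)
  expect_equal(back$subgenomes, pop$subgenomes)
  expect_equal(back$label, pop$label)
})
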