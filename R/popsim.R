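#' Simulation parameters
#'
#' @param N population size (individuals).
#' @param mu per-locus, per-generation symmetric flip mutation rate.
#' @param lambda_xo mean crossovers per chromosome per meiosis (Poisson, no
#'   interference). A chromosome with `lambda_xo = 1` is 100 cM long; locus
#'   `i` of `n_loci` maps to `100 * i / n_loci` cM and 1 cM corresponds to
#'   1 Mb of physical sequence.
#' @param s_out outcrossing probability per offspring; with probability
#'   `1 - s_out` an offspring is produced by selfing one uniformly chosen
#'   parent.
#' @param n_chrom chromosomes per subgenome.
#' @param n_loci loci per chromosome, evenly spaced.
#' @param seed optional integer convenience seed recorded with the parameters.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(N = 500, mu = 1e-5, lambda_xo = 1, s_out = 0.033,
                       n_chrom = 7, n_loci = 1e5, seed = NULL) {
  stopifnot(N >= 1, mu >= 0, mu <= 1, lambda_xo >= 0,
            s_out >= 0, s_out <= 1, n_chrom >= 1, n_loci >= 1)
  structure(list(N = as.integer(N), mu = mu, lambda_xo = lambda_xo,
                 s_out = s_out, n_chrom = as.integer(n_chrom),
                 n_loci = as.integer(n_loci), seed = seed),
            class = "sim_params")
}

#' Equilibrium inbreeding coefficient under partial selfing
#'
#' At a selfing rate `1 - s_out`, the inbreeding coefficient converges to
#' `F = (1 - s_out) / (1 + s_out)` and the effective population size is
#' reduced to `N / (1 + F)`.
#' @param s_out outcrossing probability.
#' @return the equilibrium inbreeding coefficient.
#' @export
selfing_f_eq <- function(s_out) (1 - s_out) / (1 + s_out)

#' @rdname selfing_f_eq
#' @param N census population size.
#' @export
effective_size <- function(N, s_out) N / (1 + selfing_f_eq(s_out))

.chrom_names <- function(subgenomes, n_chrom) {
  as.vector(vapply(subgenomes,
                   function(g) paste0(seq_len(n_chrom), g),
                   character(n_chrom)))
}

.new_population <- function(haps, subgenomes, n_loci, label, generation = 0L) {
  structure(list(label = label, subgenomes = subgenomes,
                 n_chrom = length(haps) %/% length(subgenomes),
                 n_loci = n_loci, haps = haps,
                 generation = as.integer(generation)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population '%s': %d individuals, subgenomes {%s}, %d x %d loci, generation %d\n",
              x$label, pop_size(x), paste(x$subgenomes, collapse = ","),
              length(x$haps), x$n_loci, x$generation))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `population`.
#' @return integer.
#' @export
pop_size <- function(pop) ncol(pop$haps[[1]]) %/% 2L

#' Initialize a population
#'
#' `"monomorphic"` starts all alleles at 0. `"stationary"` draws per-locus
#' allele frequencies from the symmetric mutation-drift stationary
#' distribution, Beta(theta, theta) with `theta = 4 * Ne * mu` and
#' `Ne = N / (1 + F)` under the selfing equilibrium inbreeding `F`, then
#' samples genotypes at that equilibrium inbreeding (replacing a long
#' burn-in).
#'
#' @param params a `sim_params`.
#' @param init `"monomorphic"` or `"stationary"`.
#' @param subgenomes character vector of subgenome labels (default a single
#'   ancestral genome `"P"`).
#' @param label population label.
#' @return a `population`.
#' @export
initialize_population <- function(params, init = c("monomorphic", "stationary"),
                                  subgenomes = "P", label = "ancestor") {
  init <- match.arg(init)
  N <- params$N
  L <- params$n_loci
  nm <- .chrom_names(subgenomes, params$n_chrom)
  f_eq <- selfing_f_eq(params$s_out)
  theta <- 4 * effective_size(N, params$s_out) * params$mu
  haps <- lapply(nm, function(ch) {
    if (init == "monomorphic") {
      matrix(0L, nrow = L, ncol = 2L * N)
    } else {
      # theta = 0 is the mutation-free limit of Beta(theta, theta):
      # every locus fixed for 0 or 1 with equal probability
      p <- if (theta > 0) stats::rbeta(L, theta, theta) else
        sample(c(0, 1), L, replace = TRUE)
      ibd <- matrix(stats::runif(L * N) < f_eq, nrow = L)
      a1 <- matrix(stats::rbinom(L * N, 1L, p), nrow = L)
      a2 <- matrix(stats::rbinom(L * N, 1L, p), nrow = L)
      a2[ibd] <- a1[ibd]
      m <- matrix(0L, nrow = L, ncol = 2L * N)
      m[, seq(1L, 2L * N, 2L)] <- a1
      m[, seq(2L, 2L * N, 2L)] <- a2
      m
    }
  })
  names(haps) <- nm
  .new_population(haps, subgenomes, L, label)
}

# Parent choice for one brood: selfing with probability 1 - s_out, otherwise
# a cross of two distinct uniform parents. A single-parent population can
# only self.
.choose_parents <- function(n_parents, n_off, s_out) {
  p1 <- sample.int(n_parents, n_off, replace = TRUE)
  p2 <- p1
  if (n_parents > 1L && s_out > 0) {
    outx <- stats::runif(n_off) < s_out
    k <- sum(outx)
    if (k) {
      d <- sample.int(n_parents - 1L, k, replace = TRUE)
      p2[outx] <- ifelse(d >= p1[outx], d + 1L, d)
    }
  }
  list(p1 = p1, p2 = p2)
}

#' Advance a population by one generation
#'
#' Produces `n_off` offspring. Each offspring is a self of one uniformly
#' chosen parent with probability `1 - s_out`, otherwise the cross of two
#' distinct uniform parents. Each transmitted chromosome is an independent
#' recombinant with Poisson(`lambda_xo`) crossovers, and each transmitted
#' allele flips with probability `mu`. Inheritance is disomic: alleles never
#' move between subgenome chromosomes.
#'
#' @param pop a `population`.
#' @param params a `sim_params`.
#' @param n_off number of offspring (default `params$N`).
#' @return the next-generation `population`.
#' @export
step_generation <- function(pop, params, n_off = params$N) {
  n <- pop_size(pop)
  if (n == 0L) stop("cannot reproduce an empty population")
  par <- .choose_parents(n, n_off, params$s_out)
  haps <- cpp_make_offspring(pop$haps, par$p1 - 1L, par$p2 - 1L,
                             params$lambda_xo, params$mu)
  .new_population(haps, pop$subgenomes, pop$n_loci, pop$label,
                  pop$generation + 1L)
}

# Reproduction with a migrant pool: a fraction m of offspring take their
# second parent from the other population (forced outcross).
.step_with_migration <- function(pop, pool, params, m, n_off = pop_size(pop)) {
  n <- pop_size(pop)
  n_pool <- pop_size(pool)
  par <- .choose_parents(n, n_off, params$s_out)
  if (m > 0 && n_pool > 0L) {
    mig <- stats::runif(n_off) < m
    if (any(mig)) par$p2[mig] <- n + sample.int(n_pool, sum(mig), replace = TRUE)
  }
  mats <- mapply(function(a, b) cbind(a, b), pop$haps, pool$haps,
                 SIMPLIFY = FALSE)
  haps <- cpp_make_offspring(mats, par$p1 - 1L, par$p2 - 1L,
                             params$lambda_xo, params$mu)
  .new_population(haps, pop$subgenomes, pop$n_loci, pop$label,
                  pop$generation + 1L)
}

#' Run several generations at constant size
#' @param pop a `population`.
#' @param params a `sim_params`.
#' @param generations number of generations.
#' @return a `population`.
#' @export
run_generations <- function(pop, params, generations) {
  for (i in seq_len(generations)) pop <- step_generation(pop, params)
  pop
}

.grow_from_founder <- function(pop, params, growth_generations) {
  if (growth_generations < 1L) stop("growth_generations must be >= 1")
  for (t in seq_len(growth_generations)) {
    n_t <- min(params$N, 2L^min(t, 30L))
    pop <- step_generation(pop, params, n_off = n_t)
  }
  pop
}

#' Found a new taxon from a single individual
#'
#' A new population is seeded from one uniformly chosen individual of the
#' source and grown by geometric doubling, reaching the target size `params$N`
#' at or before `growth_generations` generations and held there afterwards.
#'
#' @param src source `population`.
#' @param params a `sim_params`.
#' @param growth_generations generations of the founding phase (default 100).
#' @param label label for the new taxon.
#' @param subgenome optional new subgenome label replacing the source's
#'   (single-subgenome sources only).
#' @return a `population`.
#' @export
found_taxon <- function(src, params, growth_generations = 100L,
                        label = src$label, subgenome = NULL) {
  idx <- sample.int(pop_size(src), 1L)
  haps <- lapply(src$haps, function(m) m[, c(2L * idx - 1L, 2L * idx), drop = FALSE])
  names(haps) <- names(src$haps)
  subgenomes <- src$subgenomes
  if (!is.null(subgenome)) {
    if (length(subgenomes) != 1L) stop("subgenome relabel requires a single-subgenome source")
    subgenomes <- subgenome
    names(haps) <- .chrom_names(subgenomes, src$n_chrom)
  }
  pop <- .new_population(haps, subgenomes, src$n_loci, label, src$generation)
  .grow_from_founder(pop, params, growth_generations)
}

#' Merge two genomes into an amphiploid population
#'
#' One gamete is sampled (through a normal meiosis) from a uniformly chosen
#' individual of each parent population; the amphiploid founder carries both
#' gametes chromosome-doubled, so it is fully homozygous within every
#' subgenome. The founder population then grows as in [found_taxon()].
#' Subgenomes are inherited disomically ever after; fixed differences between
#' the parents become homoeologous differences, never within-subgenome
#' polymorphism.
#'
#' @param popA,popB parent `population`s with equal chromosome structure and
#'   disjoint subgenome label sets.
#' @param params a `sim_params` (the target size of the new population).
#' @param growth_generations founding-phase length.
#' @param label label for the new population.
#' @return a `population` carrying the union of the parents' subgenomes.
#' @export
polyploidize <- function(popA, popB, params, growth_generations = 100L,
                         label = paste0(popA$label, popB$label)) {
  if (popA$n_chrom != popB$n_chrom || popA$n_loci != popB$n_loci) {
    stop("incompatible chromosome structure")
  }
  if (length(intersect(popA$subgenomes, popB$subgenomes))) {
    stop("subgenome label sets must be disjoint")
  }
  gam <- function(pop) {
    idx <- sample.int(pop_size(pop), 1L)
    g <- cpp_make_offspring(pop$haps, idx - 1L, idx - 1L,
                            params$lambda_xo, params$mu)
    lapply(g, function(m) m[, 1L, drop = FALSE])
  }
  gA <- gam(popA)
  gB <- gam(popB)
  haps <- c(lapply(gA, function(g) cbind(g, g)),
            lapply(gB, function(g) cbind(g, g)))
  names(haps) <- c(names(popA$haps), names(popB$haps))
  pop <- .new_population(haps, c(popA$subgenomes, popB$subgenomes),
                         popA$n_loci, label,
                         max(popA$generation, popB$generation))
  .grow_from_founder(pop, params, growth_generations)
}

#' Randomly split a population into two disjoint cohorts
#'
#' @param pop a `population`.
#' @param n1,n2 cohort sizes; `n1 + n2` must not exceed the population size.
#' @param labels labels for the two cohorts.
#' @return a list of two `population`s.
#' @export
split_population <- function(pop, n1, n2, labels = c("Pre70", "Post70")) {
  n <- pop_size(pop)
  if (n1 + n2 > n) stop("n1 + n2 exceeds the population size")
  idx <- sample.int(n, n1 + n2)
  take <- function(ids, label) {
    cols <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    haps <- lapply(pop$haps, function(m) m[, cols, drop = FALSE])
    names(haps) <- names(pop$haps)
    .new_population(haps, pop$subgenomes, pop$n_loci, label, pop$generation)
  }
  list(take(idx[seq_len(n1)], labels[1]), take(idx[n1 + seq_len(n2)], labels[2]))
}

#' Per-locus allele frequencies
#' @param pop a `population`.
#' @return a list of numeric vectors, one per chromosome.
#' @export
allele_freqs <- function(pop) lapply(pop$haps, rowMeans)

#' Observed heterozygosity
#'
#' The fraction of (individual, locus) genotype calls that are heterozygous,
#' averaged over the loci polymorphic in the population; 0 when no locus is
#' polymorphic.
#'
#' @param pop a `population`.
#' @return a fraction in `[0, 1]`.
#' @export
observed_heterozygosity <- function(pop) {
  n <- pop_size(pop)
  rates <- numeric(0)
  for (m in pop$haps) {
    f <- rowMeans(m)
    poly <- f > 0 & f < 1
    if (!any(poly)) next
    odd <- m[poly, seq(1L, 2L * n, 2L), drop = FALSE]
    even <- m[poly, seq(2L, 2L * n, 2L), drop = FALSE]
    rates <- c(rates, rowMeans(odd != even))
  }
  if (!length(rates)) return(0)
  mean(rates)
}

#' Genome-wide Fst between two populations
#'
#' A drift-consistent ratio-of-sums estimator: across loci polymorphic in the
#' pooled pair, the among-population sample variance of allele frequency
#' (with the K/(K-1) small-K correction) is summed and divided by the summed
#' pooled heterozygosity `p(1-p)`. For two isolated populations of effective
#' size Ne this tracks `1 - exp(-t / (2 Ne))`. The per-locus scan statistic
#' used by [fst_scan()] is intentionally different (it follows the published
#' moment form); see the methods vignette.
#'
#' @param freq_x,freq_y per-chromosome allele-frequency lists (or
#'   `population` objects).
#' @return the genome-wide Fst estimate (`NA` when no locus is polymorphic).
#' @export
fst_genomewide <- function(freq_x, freq_y) {
  if (inherits(freq_x, "population")) freq_x <- allele_freqs(freq_x)
  if (inherits(freq_y, "population")) freq_y <- allele_freqs(freq_y)
  p1 <- unlist(freq_x, use.names = FALSE)
  p2 <- unlist(freq_y, use.names = FALSE)
  pbar <- (p1 + p2) / 2
  keep <- pbar > 0 & pbar < 1
  if (!any(keep)) return(NA_real_)
  num <- sum((p1[keep] - p2[keep])^2 / 2)
  den <- sum(pbar[keep] * (1 - pbar[keep]))
  num / den
}

#' Checkpoint a population to disk
#'
#' The haplotypes are written in the hapmatrix format (with its map TSV)
#' and a JSON sidecar records the population metadata (label, subgenomes,
#' chromosome structure, generation counter), so a long simulation can be
#' resumed or inspected with the dataio tools.
#'
#' @param pop a `population`.
#' @param path base path; `<path>` (hapmatrix), `<path>.map` and
#'   `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  hs <- as_haplotype_set(pop)
  write_haplotypes(hs, path, "hapmatrix")
  meta <- list(label = pop$label, subgenomes = pop$subgenomes,
               n_chrom = pop$n_chrom, n_loci = pop$n_loci,
               generation = pop$generation)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hs <- read_haplotypes(path, "hapmatrix")
  chroms <- unique(as.character(hs$loci$chrom))
  haps <- lapply(chroms, function(ch) {
    cols <- which(hs$loci$chrom == ch)
    m <- t(hs$alleles[, cols, drop = FALSE])
    dimnames(m) <- NULL
    m
  })
  names(haps) <- chroms
  .new_population(haps, meta$subgenomes, as.integer(meta$n_loci),
                  meta$label, meta$generation)
}

#' Convert populations to a haplotype set
#'
#' Loci are embedded on the simulator's uniform map: locus `i` of `L` on a
#' 100 cM chromosome sits at `100 * i / L` cM and `1e6 * cM` bp. Individuals
#' of all supplied populations are concatenated; `names(pops)` (or the
#' population labels) become the cohort labels returned in the `cohorts`
#' attribute.
#'
#' @param pops a `population` or list of `population`s sharing structure.
#' @return a `haplotype_set` with a `cohorts` attribute (factor over
#'   individuals).
#' @export
as_haplotype_set <- function(pops) {
  if (inherits(pops, "population")) pops <- list(pops)
  labels <- names(pops)
  if (is.null(labels)) labels <- vapply(pops, function(p) p$label, "")
  ref <- pops[[1]]
  L <- ref$n_loci
  chroms <- names(ref$haps)
  loci <- do.call(rbind, lapply(chroms, function(ch) {
    cm <- 100 * seq_len(L) / L
    data.frame(locus = paste0(ch, "_", seq_len(L)), chrom = ch, cM = cm,
               bp = cm * 1e6, stringsAsFactors = FALSE)
  }))
  n_ind <- vapply(pops, pop_size, 1L)
  total <- sum(n_ind)
  alleles <- matrix(NA_integer_, nrow = 2L * total, ncol = nrow(loci))
  row0 <- 0L
  for (p in pops) {
    rows <- row0 + seq_len(2L * pop_size(p))
    col0 <- 0L
    for (ch in chroms) {
      alleles[rows, col0 + seq_len(L)] <- t(p$haps[[ch]])
      col0 <- col0 + L
    }
    row0 <- row0 + 2L * pop_size(p)
  }
  ids <- unlist(mapply(function(lb, n) sprintf("%s_%03d", lb, seq_len(n)),
                       labels, n_ind, SIMPLIFY = FALSE), use.names = FALSE)
  hs <- haplotype_set(alleles, ids, loci,
                      ploidy_note = length(ref$subgenomes))
  attr(hs, "cohorts") <- factor(rep(labels, n_ind), levels = unique(labels))
  hs
}
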