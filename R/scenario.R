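#' Demography profiles for the Australian wheat scenario
#'
#' The `"full"` profile mirrors the published simulation scheme literally:
#' a common ancestor of 500 individuals with seven chromosomes of 100,000
#' loci, mutation rate 1e-5, Poisson(1) crossovers, outcrossing 0.033; the A
#' genome founded at generation 6,000, B at 6,200, D at 11,000; the AB
#' tetraploid at 12,000 and the 482-individual hexaploid at 18,000; run to
#' 25,000 generations, then split into cohorts of 259 (Pre70) and 223
#' (Post70) that differentiate under restricted gene flow until the
#' genome-wide Fst reaches 0.13; finally a 9,858-locus SNP panel is
#' ascertained in 19 Post70 individuals. It is cluster-scale.
#'
#' The `"desk"` profile is the package's down-scaled study condition for
#' laptop-speed testing: 200 individuals, one chromosome per subgenome with
#' 2,000 loci, mutation rate 5e-4 (chosen to preserve the full profile's
#' per-centimorgan mutation density, 1e-2 per cM per meiosis, under the
#' 50-fold thinner locus grid), stationary initialization replacing the
#' burn-in, a compressed event schedule, cohorts of 108/92, and a 1,500-locus
#' ascertained panel (about 5 panel SNPs per cM, matching the density of the
#' real chip panel). The methods vignette discusses the scaling.
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... named overrides of any config field.
#' @return a list of class `wheat_scenario_config`.
#' @export
wheat_scenario_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "desk") {
    list(params = sim_params(N = 200, mu = 5e-4, lambda_xo = 1,
                             s_out = 0.033, n_chrom = 1, n_loci = 2000),
         init = "stationary",
         gen_A = 60, gen_B = 70, gen_D = 90, gen_AB = 130, gen_hex = 170,
         gen_end = 390, growth_generations = 20,
         N_hex = 200, n_pre = 108, n_post = 92,
         target_fst = 0.13, m = 1e-4, max_gen_fst = 2000,
         panel_size = 19, tetraploid_panel = 0, n_snps = 1500)
  } else {
    list(params = sim_params(N = 500, mu = 1e-5, lambda_xo = 1,
                             s_out = 0.033, n_chrom = 7, n_loci = 1e5),
         init = "stationary",
         gen_A = 6000, gen_B = 6200, gen_D = 11000, gen_AB = 12000,
         gen_hex = 18000, gen_end = 25000, growth_generations = 100,
         N_hex = 482, n_pre = 259, n_post = 223,
         target_fst = 0.13, m = 1e-4, max_gen_fst = 5000,
         panel_size = 19, tetraploid_panel = 0, n_snps = 9858)
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$profile <- profile
  stopifnot(cfg$gen_A < cfg$gen_B, cfg$gen_B < cfg$gen_D,
            cfg$gen_AB > cfg$gen_B, cfg$gen_hex > cfg$gen_D,
            cfg$gen_hex > cfg$gen_AB, cfg$gen_end >= cfg$gen_hex,
            cfg$target_fst > 0, cfg$target_fst < 1)
  class(cfg) <- "wheat_scenario_config"
  cfg
}

#' Read a scenario profile from YAML
#'
#' The YAML file names a base `profile` and any overriding fields.
#' @param path YAML file path.
#' @return a `wheat_scenario_config`.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- if (is.null(y$profile)) "desk" else y$profile
  y$profile <- NULL
  pr <- y$params
  y$params <- NULL
  cfg <- do.call(wheat_scenario_config, c(list(profile = profile), y))
  if (!is.null(pr)) cfg$params[names(pr)] <- pr
  cfg
}

#' Differentiate two populations until a target Fst is reached
#'
#' Each generation both populations reproduce independently, except that a
#' fraction `m` of offspring draw one parent from the other population.
#' Differentiation is tracked after every generation and the process stops
#' at the first generation at which it reaches `target_fst`.
#'
#' The tracked quantity is the population-drift coefficient measured from
#' the split: with `pi` the pooled allele frequencies at entry, it is the
#' genome-wide ratio `sum mean_j (p_j - pi)^2 / sum pi (1 - pi)` over the
#' loci polymorphic at the split. Its expectation is
#' `1 - exp(-t / (2 Ne))` for isolated populations of effective size `Ne`
#' (the pooled-pair estimator [fst_genomewide()] saturates below that,
#' because pooled heterozygosity itself shrinks as the demes drift).
#'
#' @param pop_x,pop_y `population`s (typically a fresh random split).
#' @param params a `sim_params` (mutation, recombination and selfing rates).
#' @param target_fst stopping level, in `[0, 1)`.
#' @param m per-offspring migrant-parent probability.
#' @param max_gen abort (with the trajectory attached to the error condition)
#'   if the target is not reached in this many generations.
#' @return a list with `generations`, `fst`, `trajectory`, and the two final
#'   `population`s (`pop_x`, `pop_y`).
#' @export
drift_until_fst <- function(pop_x, pop_y, params, target_fst, m = 1e-4,
                            max_gen = 2000L) {
  stopifnot(target_fst >= 0, target_fst < 1, m >= 0, m < 1)
  n_x <- pop_size(pop_x)
  n_y <- pop_size(pop_y)
  p_x <- unlist(allele_freqs(pop_x), use.names = FALSE)
  p_y <- unlist(allele_freqs(pop_y), use.names = FALSE)
  pi0 <- (n_x * p_x + n_y * p_y) / (n_x + n_y)
  keep <- pi0 > 0 & pi0 < 1
  den <- sum(pi0[keep] * (1 - pi0[keep]))
  track <- function(px, py) {
    if (!any(keep) || den == 0) return(NA_real_)
    sum(((px[keep] - pi0[keep])^2 + (py[keep] - pi0[keep])^2) / 2) / den
  }
  fst <- track(p_x, p_y)
  traj <- c(fst)
  if (target_fst <= 0 || isTRUE(fst >= target_fst)) {
    return(list(generations = 0L, fst = fst, trajectory = traj,
                pop_x = pop_x, pop_y = pop_y))
  }
  for (g in seq_len(max_gen)) {
    new_x <- .step_with_migration(pop_x, pop_y, params, m)
    new_y <- .step_with_migration(pop_y, pop_x, params, m)
    pop_x <- new_x
    pop_y <- new_y
    fst <- track(unlist(allele_freqs(pop_x), use.names = FALSE),
                 unlist(allele_freqs(pop_y), use.names = FALSE))
    traj <- c(traj, fst)
    if (isTRUE(fst >= target_fst)) {
      return(list(generations = g, fst = fst, trajectory = traj,
                  pop_x = pop_x, pop_y = pop_y))
    }
  }
  stop(errorCondition(
    sprintf("Fst target %.3g not reached within %d generations (last %.3g)",
            target_fst, max_gen, fst),
    trajectory = traj, class = "fst_target_error"))
}

#' Run the Australian wheat demography end to end
#'
#' Executes the scenario of [wheat_scenario_config()]: stationary (or
#' monomorphic) ancestor, founding of the A, B and D genomes, the AB
#' tetraploid, the hexaploid population, the random cohort split and the
#' Fst-tracked differentiation. Every taxon starts from a single individual
#' and grows geometrically.
#'
#' @param cfg a `wheat_scenario_config`.
#' @return a list of class `sim_dataset` with elements `haplotypes` (a
#'   `haplotype_set` of both cohorts, cohort labels in the `cohorts`
#'   attribute and `$cohorts`), `populations` (the two cohort `population`s),
#'   `tetraploid` (the retained AB population), `fst_generations`,
#'   `fst` and `config`.
#' @export
run_wheat_scenario <- function(cfg) {
  p <- cfg$params
  gg <- cfg$growth_generations
  anc <- initialize_population(p, cfg$init, subgenomes = "P")
  anc <- run_generations(anc, p, cfg$gen_A)
  A <- found_taxon(anc, p, gg, label = "A", subgenome = "A")
  anc <- run_generations(anc, p, cfg$gen_B - cfg$gen_A)
  B <- found_taxon(anc, p, gg, label = "B", subgenome = "B")
  anc <- run_generations(anc, p, cfg$gen_D - cfg$gen_B)
  D <- found_taxon(anc, p, gg, label = "D", subgenome = "D")
  A <- run_generations(A, p, cfg$gen_AB - cfg$gen_A - gg)
  B <- run_generations(B, p, cfg$gen_AB - cfg$gen_B - gg)
  AB <- polyploidize(A, B, p, gg, label = "AB")
  AB <- run_generations(AB, p, cfg$gen_hex - cfg$gen_AB - gg)
  D <- run_generations(D, p, cfg$gen_hex - cfg$gen_D - gg)
  p_hex <- p
  p_hex$N <- as.integer(cfg$N_hex)
  HEX <- polyploidize(AB, D, p_hex, gg, label = "hexaploid")
  HEX <- run_generations(HEX, p_hex, cfg$gen_end - cfg$gen_hex - gg)
  cohorts <- split_population(HEX, cfg$n_pre, cfg$n_post,
                              labels = c("Pre70", "Post70"))
  dr <- drift_until_fst(cohorts[[1]], cohorts[[2]], p, cfg$target_fst,
                        m = cfg$m, max_gen = cfg$max_gen_fst)
  pops <- list(Pre70 = dr$pop_x, Post70 = dr$pop_y)
  hs <- as_haplotype_set(pops)
  structure(list(haplotypes = hs, cohorts = attr(hs, "cohorts"),
                 populations = pops, tetraploid = AB,
                 fst_generations = dr$generations, fst = dr$fst,
                 config = cfg),
            class = "sim_dataset")
}

#' Ascertainment specification
#'
#' @param panel_size number of discovery-panel individuals drawn from the
#'   Post70 cohort (19 in the published design).
#' @param n_snps number of panel-polymorphic loci to retain (9,858 in the
#'   full profile).
#' @param tetraploid_panel optional number of tetraploid accessions added to
#'   the discovery panel (18 mimics the published chip-design panel; 0 by
#'   default; including durum-like accessions was found not to change the
#'   thresholds materially in the original study design).
#' @return a list of class `ascertainment_spec`.
#' @export
ascertainment_spec <- function(panel_size = 19L, n_snps, tetraploid_panel = 0L) {
  stopifnot(panel_size >= 1, n_snps >= 1, tetraploid_panel >= 0)
  structure(list(panel_size = as.integer(panel_size),
                 n_snps = as.integer(n_snps),
                 tetraploid_panel = as.integer(tetraploid_panel)),
            class = "ascertainment_spec")
}

#' Emulate SNP-array ascertainment bias
#'
#' Draws a small discovery panel uniformly from the Post70 cohort (optionally
#' plus tetraploid accessions), keeps only loci polymorphic within that
#' panel, samples exactly `spec$n_snps` of them uniformly without
#' replacement, and restricts the genotypes of *all* individuals to the
#' retained loci. This shifts the folded site-frequency spectrum toward
#' common alleles, as chip genotyping does.
#'
#' @param dataset a `sim_dataset` from [run_wheat_scenario()].
#' @param spec an `ascertainment_spec`.
#' @return the dataset with `haplotypes` reduced to the retained loci (the
#'   panel individual IDs are recorded in `$panel`).
#' @export
ascertain_snp_panel <- function(dataset, spec) {
  hs <- dataset$haplotypes
  cohorts <- dataset$cohorts
  post_ids <- hs$individuals[cohorts == "Post70"]
  if (length(post_ids) < spec$panel_size) stop("Post70 cohort smaller than the panel")
  panel <- sample(post_ids, spec$panel_size)
  rows_of <- function(ids) {
    k <- match(ids, hs$individuals)
    as.vector(rbind(2L * k - 1L, 2L * k))
  }
  pa <- hs$alleles[rows_of(panel), , drop = FALSE]
  if (spec$tetraploid_panel > 0L) {
    tet <- dataset$tetraploid
    if (is.null(tet)) stop("no tetraploid population retained in this dataset")
    n_tet <- pop_size(tet)
    ids <- sample.int(n_tet, min(spec$tetraploid_panel, n_tet))
    tet_hs <- as_haplotype_set(list(tetraploid = tet))
    ta <- matrix(NA_integer_, nrow = 2L * length(ids), ncol = ncol(hs$alleles))
    shared <- match(tet_hs$loci$locus, hs$loci$locus)
    ok <- !is.na(shared)
    rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    ta[, shared[ok]] <- tet_hs$alleles[rows, ok, drop = FALSE]
    pa <- rbind(pa, ta)
  }
  f <- colMeans(pa, na.rm = TRUE)
  poly <- which(!is.na(f) & f > 0 & f < 1)
  if (length(poly) < spec$n_snps) {
    stop(sprintf("only %d loci polymorphic in the panel; %d requested",
                 length(poly), spec$n_snps))
  }
  keep <- sort(sample(poly, spec$n_snps))
  dataset$haplotypes <- subset_haplotypes(hs, loci = keep)
  attr(dataset$haplotypes, "cohorts") <- cohorts
  dataset$panel <- panel
  dataset
}

#' Subsample a state-like cohort and differentiate it from the rest
#'
#' Draws `n_pre_state` individuals from the Pre70 cohort and `n_post_state`
#' from the Post70 cohort to form a "state" population, the remaining
#' individuals forming the "rest", then applies [drift_until_fst()] to the
#' pair at the state-specific target.
#'
#' @param dataset a `sim_dataset` with `$populations`.
#' @param n_pre_state,n_post_state cohort draws.
#' @param target_fst_state state-vs-rest Fst stopping level.
#' @param m migrant fraction during differentiation.
#' @param max_gen abort limit.
#' @return a list with `haplotypes` (labelled `state` / `rest`),
#'   `generations` and `fst`.
#' @export
subsample_state <- function(dataset, n_pre_state, n_post_state,
                            target_fst_state, m = 1e-4, max_gen = 2000L) {
  pre <- dataset$populations$Pre70
  post <- dataset$populations$Post70
  if (n_pre_state > pop_size(pre) || n_post_state > pop_size(post)) {
    stop("requested state cohort exceeds the available individuals")
  }
  s_pre <- split_population(pre, n_pre_state, pop_size(pre) - n_pre_state,
                            labels = c("state", "rest"))
  s_post <- split_population(post, n_post_state, pop_size(post) - n_post_state,
                             labels = c("state", "rest"))
  join <- function(a, b, label) {
    haps <- mapply(cbind, a$haps, b$haps, SIMPLIFY = FALSE)
    names(haps) <- names(a$haps)
    .new_population(haps, a$subgenomes, a$n_loci, label, a$generation)
  }
  state <- join(s_pre[[1]], s_post[[1]], "state")
  rest <- join(s_pre[[2]], s_post[[2]], "rest")
  dr <- drift_until_fst(state, rest, dataset$config$params, target_fst_state,
                        m = m, max_gen = max_gen)
  hs <- as_haplotype_set(list(state = dr$pop_x, rest = dr$pop_y))
  list(haplotypes = hs, generations = dr$generations, fst = dr$fst)
}

#' Parameters of the LD-decay calibration simulations
#'
#' A single partially selfing population at stationary diversity, used to map
#' an outcrossing rate to an LD-decay curve. The default is deliberately
#' larger than the scan desk profile (300 individuals, eight chromosomes of
#' 300 loci): the pedigree, which all chromosomes share, dominates the
#' replicate-to-replicate variance of mean r-squared, and a larger
#' population both steadies the curve and steepens its response to the
#' outcrossing rate.
#' @param N,n_chrom,n_loci,mu population size, chromosomes, loci per
#'   chromosome, mutation rate.
#' @return a `sim_params`.
#' @export
calibration_params <- function(N = 300, n_chrom = 8, n_loci = 300,
                               mu = 2.5e-4) {
  # s_out is a placeholder here; simulate_ld_decay() overwrites it
  sim_params(N = N, mu = mu, lambda_xo = 1, s_out = 0.033,
             n_chrom = n_chrom, n_loci = n_loci)
}

#' Simulate an LD-decay curve at a given outcrossing rate
#'
#' @param s_out outcrossing rate.
#' @param params a `sim_params` (the `s_out` field is overwritten).
#' @param generations generations run after stationary initialization.
#' @param maf_floor loci below this minor-allele frequency are dropped
#'   before the curve is computed, mimicking the common-allele content of a
#'   genotyping array (the LD target this curve is compared against comes
#'   from chip SNPs).
#' @param bin_width,max_cm,max_pairs passed to [ld_decay_curve()].
#' @return a decay-curve data frame (`bin_mid_cM`, `mean_r2`, `n_pairs`).
#' @export
simulate_ld_decay <- function(s_out, params = calibration_params(),
                              generations = 250, maf_floor = 0.05,
                              bin_width = 1, max_cm = 50,
                              max_pairs = 20000) {
  params$s_out <- s_out
  pop <- initialize_population(params, "stationary", subgenomes = "A",
                               label = "calib")
  pop <- run_generations(pop, params, generations)
  hs <- as_haplotype_set(pop)
  f <- colMeans(hs$alleles)
  keep <- which(pmin(f, 1 - f) >= maf_floor)
  if (length(keep) < 2) stop("fewer than two common loci in the calibration run")
  ld_decay_curve(subset_haplotypes(hs, loci = keep), bin_width = bin_width,
                 max_cm = max_cm, max_pairs = max_pairs)
}

#' Fit the outcrossing rate against a target LD-decay curve
#'
#' Two-pass grid search reproducing the published calibration protocol: a
#' coarse pass over `coarse_grid` (0.01..0.10 by 0.01), then a fine pass at
#' `fine_step` (0.001) over the coarse bracketing interval (the argmin and
#' its better-scoring neighbour). The objective is the mean squared
#' difference between the binned simulated and target r-squared curves over
#' 0-`max_cm` cM, averaging `replicates` simulations per grid point.
#'
#' @param target_curve a decay-curve data frame as from [ld_decay_curve()].
#' @param coarse_grid,fine_step search grid controls.
#' @param replicates,fine_replicates simulations per coarse / fine point.
#' @param params,generations,max_cm,bin_width,max_pairs simulation controls
#'   (see [simulate_ld_decay()]).
#' @return a list of class `calibration_result`: `rate` (the fitted
#'   outcrossing rate), `objective` (data frame of every evaluated point) and
#'   `curves` (mean simulated curve at the fitted rate).
#' @export
fit_outcrossing_rate <- function(target_curve,
                                 coarse_grid = seq(0.01, 0.10, by = 0.01),
                                 fine_step = 0.001,
                                 replicates = 4, fine_replicates = 14,
                                 params = calibration_params(),
                                 generations = 250, max_cm = 50,
                                 bin_width = 1, max_pairs = 40000) {
  tb <- target_curve[!is.na(target_curve$mean_r2) &
                       target_curve$bin_mid_cM <= max_cm, ]
  if (!nrow(tb)) stop("degenerate target curve: no usable bins")
  sim_curve <- function(rate, reps) {
    cs <- lapply(seq_len(reps), function(i)
      simulate_ld_decay(rate, params, generations, bin_width = bin_width,
                        max_cm = max_cm, max_pairs = max_pairs))
    mids <- cs[[1]]$bin_mid_cM
    mean_r2 <- rowMeans(do.call(cbind, lapply(cs, `[[`, "mean_r2")), na.rm = TRUE)
    data.frame(bin_mid_cM = mids, mean_r2 = mean_r2)
  }
  objective <- function(sim) {
    m <- merge(tb, sim, by = "bin_mid_cM", suffixes = c("_t", "_s"))
    m <- m[!is.na(m$mean_r2_s), ]
    if (!nrow(m)) return(NA_real_)
    mean((m$mean_r2_s - m$mean_r2_t)^2)
  }
  rows <- list()
  best_curve <- NULL
  evaluate <- function(rate, reps, pass) {
    sim <- sim_curve(rate, reps)
    obj <- objective(sim)
    rows[[length(rows) + 1L]] <<- data.frame(rate = rate, objective = obj,
                                             pass = pass, replicates = reps)
    list(obj = obj, sim = sim)
  }
  coarse_obj <- vapply(coarse_grid,
                       function(r) evaluate(r, replicates, "coarse")$obj,
                       numeric(1))
  i_best <- which.min(coarse_obj)
  nb <- c(i_best - 1L, i_best + 1L)
  nb <- nb[nb >= 1L & nb <= length(coarse_grid)]
  i_nb <- nb[which.min(coarse_obj[nb])]
  lo <- min(coarse_grid[c(i_best, i_nb)])
  hi <- max(coarse_grid[c(i_best, i_nb)])
  fine_grid <- seq(lo, hi, by = fine_step)
  fine <- lapply(fine_grid, function(r) evaluate(r, fine_replicates, "fine"))
  fine_obj <- vapply(fine, `[[`, numeric(1), "obj")
  k <- which.min(fine_obj)
  structure(list(rate = fine_grid[k],
                 objective = do.call(rbind, rows),
                 curves = fine[[k]]$sim,
                 target = tb),
            class = "calibration_result")
}
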