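# Small builders used across the test files.

toy_loci <- function(n, chrom = "1A", cm = NULL) {
  if (is.null(cm)) cm <- seq_len(n)
  data.frame(locus = paste0(chrom, "_", seq_len(n)), chrom = chrom,
             cM = cm, bp = cm * 1e6, stringsAsFactors = FALSE)
}

# A haplotype_set from an explicit haplotype-by-locus matrix (rows =
# haplotypes, two consecutive rows per individual).
toy_hs <- function(mat, chrom = "1A", cm = NULL) {
  mat <- as.matrix(mat)
  n_ind <- nrow(mat) / 2
  haplotype_set(mat, paste0("ind", seq_len(n_ind)),
                toy_loci(ncol(mat), chrom, cm))
}

# A small simulated population converted to a haplotype_set.
sim_toy_hs <- function(seed = 1, n_ind = 10, n_loci = 50, n_chrom = 2,
                       mu = 2e-3, s_out = 0.5, generations = 20) {
  set.seed(seed)
  p <- sim_params(N = n_ind, mu = mu, lambda_xo = 1, s_out = s_out,
                  n_chrom = n_chrom, n_loci = n_loci)
  pop <- initialize_population(p, "stationary", subgenomes = "A")
  pop <- run_generations(pop, p, generations)
  as_haplotype_set(pop)
}

# Brute-force EHH by pair enumeration: probability that two random carrier
# haplotypes are identical on the closed interval from the core out to each
# site in one direction.
oracle_ehh <- function(mat, core, allele, step) {
  rows <- which(mat[, core] == allele)
  n <- length(rows)
  if (n < 2) return(NULL)
  np <- choose(n, 2)
  L <- ncol(mat)
  sites <- if (step > 0) core:L else core:1
  sapply(sites, function(s) {
    rng <- min(core, s):max(core, s)
    cnt <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (all(mat[rows[a], rng] == mat[rows[b], rng])) cnt <- cnt + 1
    }
    cnt / np
  })
}

# Brute-force iHH with the package's truncation contract: trapezoid over cM,
# stop after the first segment whose right end falls below the cutoff, NA if
# the chromosome edge is reached first.
oracle_ihh_side <- function(ehh_curve, pos, cutoff) {
  if (length(ehh_curve) == 1) return(NA_real_)
  total <- 0
  for (t in 2:length(ehh_curve)) {
    total <- total + (ehh_curve[t] + ehh_curve[t - 1]) / 2 *
      abs(pos[t] - pos[t - 1])
    if (ehh_curve[t] < cutoff) return(total)
  }
  NA_real_
}

oracle_ihs_raw <- function(mat, core, pos, cutoff = 0.05) {
  f1 <- mean(mat[, core])
  major <- if (f1 >= 0.5) 1 else 0
  ihh_for <- function(allele) {
    rows <- which(mat[, core] == allele)
    if (length(rows) < 2) return(NA_real_)
    er <- oracle_ehh(mat, core, allele, +1)
    el <- oracle_ehh(mat, core, allele, -1)
    r <- oracle_ihh_side(er, pos[core:ncol(mat)], cutoff)
    l <- oracle_ihh_side(el, pos[core:1], cutoff)
    if (is.na(r) || is.na(l)) NA_real_ else r + l
  }
  maj <- ihh_for(major)
  mnr <- ihh_for(1 - major)
  if (is.na(maj) || is.na(mnr) || maj <= 0 || mnr <= 0) return(NA_real_)
  log(maj / mnr)
}

# Brute-force nSL by explicit maximal-interval expansion per pair.
oracle_sl_mean <- function(mat, core, allele) {
  rows <- which(mat[, core] == allele)
  n <- length(rows)
  if (n < 2) return(NA_real_)
  L <- ncol(mat)
  tot <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    l <- core
    while (l > 1 && mat[rows[a], l - 1] == mat[rows[b], l - 1]) l <- l - 1
    r <- core
    while (r < L && mat[rows[a], r + 1] == mat[rows[b], r + 1]) r <- r + 1
    tot <- tot + (r - l + 1)
  }
  tot / choose(n, 2)
}

oracle_nsl_raw <- function(mat, core) {
  f1 <- mean(mat[, core])
  major <- if (f1 >= 0.5) 1 else 0
  maj <- oracle_sl_mean(mat, core, major)
  mnr <- oracle_sl_mean(mat, core, 1 - major)
  if (is.na(maj) || is.na(mnr) || maj <= 0 || mnr <= 0) return(NA_real_)
  log(maj / mnr)
}
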