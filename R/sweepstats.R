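#' Scan configuration
#'
#' Parameterization of the four selection scans. Defaults follow the
#' published analysis: Fst averaged in sliding windows of 15 SNPs with a
#' one-SNP step; XPCLR on a 1 Mb grid with a 1 cM window, at most 50 SNPs
#' per window and LD pruning at r-squared > 0.95; iHS/nSL with a minor-allele
#' frequency floor of 0.05, EHH truncation at 0.05, a 2 cM maximum gap and
#' standardization in frequency bins of width 0.025.
#'
#' @param fst_window,fst_step Fst sliding-window size and step (SNPs).
#' @param xpclr_grid_bp,xpclr_window_cm,xpclr_max_snps,xpclr_prune_r2 XPCLR
#'   evaluation grid spacing (bp), window size (cM), SNP cap and pruning
#'   threshold.
#' @param xpclr_s_grid selection-intensity grid maximized over.
#' @param xpclr_ne effective size entering the escape-probability map from
#'   genetic distance to hitchhiking strength.
#' @param xpclr_nodes Gauss-Legendre node count for the frequency integral.
#' @param maf_floor minimum minor-allele frequency for iHS/nSL cores.
#' @param ehh_cutoff EHH truncation level for the iHS integral.
#' @param max_gap_cm iHS scores spanning a larger inter-SNP gap are missing.
#' @param std_bin_width allele-frequency bin width for standardization.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(fst_window = 15L, fst_step = 1L,
                        xpclr_grid_bp = 1e6, xpclr_window_cm = 1,
                        xpclr_max_snps = 50L, xpclr_prune_r2 = 0.95,
                        xpclr_s_grid = 10^seq(-5, -1, length.out = 20),
                        xpclr_ne = 500, xpclr_nodes = 40L,
                        maf_floor = 0.05, ehh_cutoff = 0.05,
                        max_gap_cm = 2, std_bin_width = 0.025) {
  stopifnot(fst_window >= 1, fst_step >= 1, xpclr_prune_r2 > 0,
            xpclr_prune_r2 <= 1, ehh_cutoff > 0, ehh_cutoff <= 1)
  structure(as.list(environment()), class = "scan_config")
}

.new_score_track <- function(df, statistic, snp_idx = NULL) {
  if (!is.null(snp_idx)) df$snp_idx <- I(snp_idx)
  class(df) <- c("score_track", "data.frame")
  attr(df, "statistic") <- statistic
  df
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track [%s]: %d evaluation points on %d chromosome(s)\n",
              attr(x, "statistic"), nrow(x), length(unique(x$chrom))))
  invisible(x)
}

.pop_rows <- function(hs, labels, level) {
  k <- which(labels == level)
  as.vector(rbind(2L * k - 1L, 2L * k))
}

#' Per-locus population-differentiation statistic
#'
#' The population-drift moment form: with K population allele frequencies
#' `p_j` and their unweighted mean `p`, the per-locus value is
#' `mean((p_j - p)^2) / (p (1 - p))`. Loci with pooled frequency 0 or 1 are
#' missing.
#'
#' @param freq_matrix K x L matrix of population allele frequencies.
#' @return numeric vector of per-locus values.
#' @export
fst_per_locus <- function(freq_matrix) {
  pbar <- colMeans(freq_matrix)
  num <- colMeans(sweep(freq_matrix, 2, pbar)^2)
  out <- num / (pbar * (1 - pbar))
  out[pbar <= 0 | pbar >= 1] <- NA_real_
  out
}

#' Sliding-window Fst scan
#'
#' Computes the per-locus drift moment statistic between the supplied
#' populations and averages it in sliding windows (15 SNPs, step 1 by
#' default), reporting each window at its center SNP.
#'
#' @param hs a `haplotype_set`.
#' @param pop_labels factor/character over individuals giving the population
#'   of each (at least two levels present).
#' @param cfg a `scan_config`.
#' @return a `score_track` with columns `chrom`, `pos_cM`, `pos_bp`, `raw`,
#'   `standardized` (`NA` for Fst), `n_snps` (non-missing per-locus values in
#'   the window) and a `snp_idx` list column of contributing locus indices.
#' @export
fst_scan <- function(hs, pop_labels, cfg = scan_config()) {
  pop_labels <- as.factor(pop_labels)
  lev <- levels(droplevels(pop_labels))
  if (length(lev) < 2) stop("need at least two populations")
  if (any(!table(pop_labels[pop_labels %in% lev]))) stop("population with zero samples")
  P <- do.call(rbind, lapply(lev, function(l) {
    colMeans(hs$alleles[.pop_rows(hs, pop_labels, l), , drop = FALSE],
             na.rm = TRUE)
  }))
  f <- fst_per_locus(P)
  w <- cfg$fst_window
  out <- list()
  idx <- list()
  chrom <- as.character(hs$loci$chrom)
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    if (length(cols) < w) next
    starts <- seq(1L, length(cols) - w + 1L, by = cfg$fst_step)
    for (s in starts) {
      win <- cols[s:(s + w - 1L)]
      vals <- f[win]
      center <- win[ceiling((w + 1L) / 2L)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos_cM = hs$loci$cM[center], pos_bp = hs$loci$bp[center],
        raw = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
        standardized = NA_real_, n_snps = sum(!is.na(vals)),
        stringsAsFactors = FALSE)
      idx[[length(idx) + 1L]] <- win
    }
  }
  .new_score_track(do.call(rbind, out), "FST", idx)
}

# Raw haplotype-homozygosity pair counts around a core (both directions,
# including the core site).
.hh_for_core <- function(mat, core, rows) {
  cpp_hh_counts(mat, core - 1L, rows - 1L)
}

#' Extended haplotype homozygosity curve
#'
#' For the carriers of one core allele, `EHH(x)` is the probability that two
#' randomly chosen carrier haplotypes are identical at every site from the
#' core out to `x`: `sum_h C(n_h, 2) / C(n, 2)` over the haplotype groups at
#' that extension. `EHH(0) = 1` and the curve is non-increasing.
#'
#' @param haps haplotype matrix for one chromosome (rows = haplotypes,
#'   columns = sites).
#' @param core core site index.
#' @param allele core allele (0 or 1) whose carriers are followed.
#' @param direction `"right"`, `"left"` or `"both"`.
#' @param positions optional site positions (cM) used for the `distance`
#'   column; defaults to site indices.
#' @return a data frame with `site`, `distance` and `ehh` (`NULL` when fewer
#'   than two carriers exist).
#' @export
ehh <- function(haps, core, allele = 1L, direction = c("both", "right", "left"),
                positions = NULL) {
  direction <- match.arg(direction)
  rows <- which(haps[, core] == allele)
  if (length(rows) < 2L) return(NULL)
  if (is.null(positions)) positions <- seq_len(ncol(haps))
  npair <- choose(length(rows), 2)
  hh <- .hh_for_core(haps, core, rows)
  mk <- function(counts, step) {
    # once every carrier pair differs the count stays 0: pad to the edge
    full <- if (step > 0) ncol(haps) - core + 1L else core
    counts <- c(counts, rep(0, full - length(counts)))
    sites <- core + step * (seq_along(counts) - 1L)
    data.frame(site = sites, distance = abs(positions[sites] - positions[core]),
               ehh = counts / npair)
  }
  right <- mk(hh$right, +1L)
  left <- mk(hh$left, -1L)
  switch(direction, right = right, left = left,
         both = rbind(left[rev(seq_len(nrow(left))[-1]), ], right))
}

# Shared driver for iHS and nSL: one C++ pass per chromosome computes the
# EHH integrals and the pair-identity sums for both allele classes of every
# eligible core, and both statistics are assembled from it.
.haplo_scan_both <- function(hs, cfg) {
  chrom <- as.character(hs$loci$chrom)
  dfs_ihs <- list()
  dfs_nsl <- list()
  idx_out <- list()
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    mat <- hs$alleles[, cols, drop = FALSE]
    pos <- hs$loci$cM[cols]
    ks <- cpp_haplo_scan(mat, pos, cfg$maf_floor, cfg$ehh_cutoff,
                         cfg$max_gap_cm)
    maf <- pmin(ks$freq1, 1 - ks$freq1)
    eligible <- which(!is.na(maf) & maf >= cfg$maf_floor)
    if (!length(eligible)) next
    major1 <- ks$freq1[eligible] >= 0.5
    pick <- function(v0, v1, take1) ifelse(take1, v1[eligible], v0[eligible])
    ratio <- function(s_maj, s_min) {
      ifelse(!is.na(s_maj) & !is.na(s_min) & s_maj > 0 & s_min > 0,
             log(s_maj / s_min), NA_real_)
    }
    base <- data.frame(
      chrom = ch, pos_cM = pos[eligible], pos_bp = hs$loci$bp[cols[eligible]],
      raw = NA_real_, standardized = NA_real_, n_snps = ks$n[eligible],
      freq_der = maf[eligible], stringsAsFactors = FALSE)
    ihs_df <- base
    ihs_df$raw <- ratio(pick(ks$ihh0, ks$ihh1, major1),
                        pick(ks$ihh0, ks$ihh1, !major1))
    nsl_df <- base
    nsl_df$raw <- ratio(pick(ks$sl0, ks$sl1, major1),
                        pick(ks$sl0, ks$sl1, !major1))
    dfs_ihs[[length(dfs_ihs) + 1L]] <- ihs_df
    dfs_nsl[[length(dfs_nsl) + 1L]] <- nsl_df
    idx_out <- c(idx_out, as.list(cols[eligible]))
  }
  finish <- function(dfs, statistic) {
    if (!length(dfs)) {
      df <- data.frame(chrom = character(), pos_cM = numeric(),
                       pos_bp = numeric(), raw = numeric(),
                       standardized = numeric(), n_snps = integer(),
                       freq_der = numeric())
      return(.new_score_track(df, statistic))
    }
    df <- do.call(rbind, dfs)
    df$standardized <- standardize_by_frequency(df$raw, df$freq_der,
                                                cfg$std_bin_width)
    .new_score_track(df, statistic, idx_out)
  }
  list(ihs = finish(dfs_ihs, "IHS"), nsl = finish(dfs_nsl, "NSL"))
}

#' Standardize scores within allele-frequency bins
#'
#' Scores are centered and scaled to unit variance within bins of the
#' (minor/derived) allele frequency. Bins with fewer than `min_bin`
#' non-missing scores are merged with their lower neighbour so the bin
#' moments are estimable.
#'
#' @param raw raw scores (`NA` allowed).
#' @param freq frequencies in `(0, 0.5]` matching `raw`.
#' @param bin_width frequency bin width.
#' @param min_bin minimum scores per bin before merging.
#' @return standardized scores.
#' @export
standardize_by_frequency <- function(raw, freq, bin_width = 0.025,
                                     min_bin = 10L) {
  breaks <- seq(0, 0.5 + bin_width, by = bin_width)
  bin <- findInterval(freq, breaks, rightmost.closed = TRUE)
  ok <- !is.na(raw)
  # merge sparse bins downward (first bin merges upward)
  repeat {
    tab <- table(bin[ok])
    small <- names(tab)[tab < min_bin]
    if (!length(small) || length(tab) <= 1L) break
    b <- as.integer(small[1])
    lower <- unique(bin[ok])
    lower <- lower[lower != b]
    tgt <- if (any(lower < b)) max(lower[lower < b]) else min(lower[lower > b])
    bin[bin == b] <- tgt
  }
  out <- rep(NA_real_, length(raw))
  for (b in unique(bin[ok])) {
    sel <- ok & bin == b
    mu <- mean(raw[sel])
    sdv <- stats::sd(raw[sel])
    if (is.na(sdv) || sdv == 0) next
    out[sel] <- (raw[sel] - mu) / sdv
  }
  out
}

#' Integrated haplotype score scan
#'
#' For each core SNP above the frequency floor, EHH is integrated (trapezoid
#' rule over cM) away from the core in both directions until it falls below
#' the truncation cutoff, separately for the carriers of the two alleles.
#' The raw score is `ln(iHH_major / iHH_minor)` -- ancestral states are
#' unknown on chip data, so alleles are polarized by the major allele in the
#' combined sample -- and scores are standardized to mean 0, variance 1
#' within minor-allele-frequency bins. Cores whose EHH is still above the
#' cutoff at the chromosome edge, or whose integration would span a gap
#' larger than `max_gap_cm`, are missing.
#'
#' @param hs a `haplotype_set` (phased or inbred haplotypes with a cM map).
#' @param cfg a `scan_config`.
#' @return a `score_track` (columns as in [fst_scan()], plus `freq_der`).
#' @export
ihs_scan <- function(hs, cfg = scan_config()) {
  if (any(is.na(hs$loci$cM))) stop("unmapped loci: cM positions required")
  .haplo_scan_both(hs, cfg)$ihs
}

#' Number-of-segregating-sites-by-length scan
#'
#' For a pair of carrier haplotypes, SL is the number of consecutive
#' segregating sites in the maximal interval containing the core on which
#' the pair is identical. The raw score is `ln(SL_major / SL_minor)` with
#' SL averaged over carrier pairs; standardization as in [ihs_scan()]. No
#' genetic map is required.
#'
#' @param hs a `haplotype_set`.
#' @param cfg a `scan_config`.
#' @return a `score_track`.
#' @export
nsl_scan <- function(hs, cfg = scan_config()) {
  .haplo_scan_both(hs, cfg)$nsl
}

# Composite likelihood of the objective-population allele counts under the
# hitchhiking mixture (escape probability c per SNP) with Brownian drift
# variance omega; c = 1 reproduces the neutral model, so the likelihood
# ratio is non-negative by construction. Each Gaussian component is
# integrated against the binomial with Gauss-Legendre nodes mapped onto the
# component's own +/- 8 sigma support, so narrow drift densities are
# resolved; probability mass outside (0, 1) is lumped at the boundaries.
.xpclr_cll <- function(k, n, p1, cc, omega, gl) {
  sig <- cc * sqrt(omega * p1 * (1 - p1))
  m0 <- cc * p1
  m1 <- cc * p1 + (1 - cc)
  comp <- function(k_i, n_i, m, s) {
    if (s < 1e-9) {
      return(stats::dbinom(k_i, n_i, min(max(m, 0), 1)))
    }
    lo <- max(0, m - 8 * s)
    hi <- min(1, m + 8 * s)
    interior <- if (hi > lo) {
      u <- lo + (hi - lo) * gl$x
      (hi - lo) * sum(gl$w * stats::dbinom(k_i, n_i, u) *
                        stats::dnorm(u, m, s))
    } else 0
    interior +
      stats::pnorm(0, m, s) * (k_i == 0) +
      stats::pnorm(1, m, s, lower.tail = FALSE) * (k_i == n_i)
  }
  ll <- numeric(length(k))
  for (i in seq_along(k)) {
    L <- (1 - p1[i]) * comp(k[i], n[i], m0[i], sig[i]) +
      p1[i] * comp(k[i], n[i], m1[i], sig[i])
    ll[i] <- log(max(L, 1e-300))
  }
  sum(ll)
}

#' Cross-population composite likelihood ratio scan
#'
#' Scores evaluation points on a regular physical grid (1 Mb) using the SNPs
#' within a 1 cM window: the composite likelihood of the objective
#' population's allele counts given the reference population's frequencies
#' under a Brownian-drift-plus-hitchhiking model, maximized over a fixed
#' selection-intensity grid, against the pure-drift model. The drift
#' variance is estimated genome-wide from the two populations. Within each
#' window one random SNP of every pair with r-squared above the pruning
#' threshold is kept and windows are capped at `xpclr_max_snps` SNPs by
#' uniform thinning (both seeded by the R RNG).
#'
#' @param obj_hs objective-population `haplotype_set`.
#' @param ref_hs reference-population `haplotype_set` (same loci).
#' @param cfg a `scan_config`.
#' @return a `score_track`; `raw` holds the likelihood-ratio score
#'   (non-negative; 0 when the sweep model cannot beat neutrality), windows
#'   with no usable SNP are missing.
#' @export
xpclr_scan <- function(obj_hs, ref_hs, cfg = scan_config()) {
  if (!identical(as.character(obj_hs$loci$locus),
                 as.character(ref_hs$loci$locus))) {
    stop("objective and reference must share loci")
  }
  if (any(is.na(obj_hs$loci$bp))) stop("missing bp positions")
  loci <- obj_hs$loci
  p_ref <- colMeans(ref_hs$alleles, na.rm = TRUE)
  k_obj <- colSums(obj_hs$alleles == 1L, na.rm = TRUE)
  n_obj <- colSums(!is.na(obj_hs$alleles))
  p_obj <- ifelse(n_obj > 0, k_obj / n_obj, NA)
  usable <- !is.na(p_ref) & p_ref > 0 & p_ref < 1 & n_obj > 0
  if (!any(usable)) stop("no loci polymorphic in the reference population")
  omega <- max(mean(((p_obj - p_ref)^2 / (p_ref * (1 - p_ref)))[usable]),
               1e-6)
  gl <- pracma::gaussLegendre(cfg$xpclr_nodes, 0, 1)
  all_haps <- rbind(obj_hs$alleles, ref_hs$alleles)
  chrom <- as.character(loci$chrom)
  out <- list()
  idx_out <- list()
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    grid <- seq(min(loci$bp[cols]), max(loci$bp[cols]), by = cfg$xpclr_grid_bp)
    g_cm <- stats::approx(loci$bp[cols], loci$cM[cols], xout = grid,
                          rule = 2)$y
    for (gi in seq_along(grid)) {
      win <- cols[abs(loci$cM[cols] - g_cm[gi]) <= cfg$xpclr_window_cm / 2 &
                    usable[cols]]
      score <- NA_real_
      if (length(win)) {
        win <- .prune_window(win, all_haps, cfg)
        r_m <- abs(loci$cM[win] - g_cm[gi]) / 100
        neutral <- .xpclr_cll(k_obj[win], n_obj[win], p_ref[win],
                              rep(1, length(win)), omega, gl)
        best <- neutral
        for (s in cfg$xpclr_s_grid) {
          cc <- 1 - exp(-(r_m / s) * log(2 * cfg$xpclr_ne))
          cc <- pmin(pmax(cc, 1e-12), 1)
          cll <- .xpclr_cll(k_obj[win], n_obj[win], p_ref[win], cc, omega, gl)
          if (cll > best) best <- cll
        }
        score <- 2 * (best - neutral)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos_cM = g_cm[gi], pos_bp = grid[gi], raw = score,
        standardized = NA_real_, n_snps = length(win),
        stringsAsFactors = FALSE)
      idx_out[[length(idx_out) + 1L]] <- win
    }
  }
  .new_score_track(do.call(rbind, out), "XPCLR", idx_out)
}

# LD pruning (keep one random SNP of each pair above the threshold) followed
# by uniform thinning to the window cap.
.prune_window <- function(win, haps, cfg) {
  if (length(win) >= 2L) {
    R2 <- cpp_r2_cross(haps[, win, drop = FALSE], haps[, win, drop = FALSE])
    keep <- rep(TRUE, length(win))
    for (a in seq_len(length(win) - 1L)) {
      if (!keep[a]) next
      for (b in (a + 1L):length(win)) {
        if (!keep[b]) next
        if (!is.na(R2[a, b]) && R2[a, b] > cfg$xpclr_prune_r2) {
          if (stats::runif(1) < 0.5) keep[a] <- FALSE else keep[b] <- FALSE
          if (!keep[a]) break
        }
      }
    }
    win <- win[keep]
  }
  if (length(win) > cfg$xpclr_max_snps) {
    win <- sort(sample(win, cfg$xpclr_max_snps))
  }
  win
}

#' Write a score track as TSV
#' @param track a `score_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  df <- track[, c("chrom", "pos_cM", "pos_bp", "raw", "standardized", "n_snps")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
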