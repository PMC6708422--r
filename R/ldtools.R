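#' Linkage-disequilibrium configuration
#'
#' @param background_percentile percentile of inter-chromosomal r-squared
#'   defining "background LD" (0.99).
#' @param background_threshold default background cut used when no empirical
#'   panel is supplied; 0.161 is the published 99th percentile for the
#'   Australian wheat panel.
#' @param min_snps regions with fewer SNPs are ineligible for the
#'   inter-region analysis (5).
#' @param majority fraction of a region's retained SNPs that must exceed the
#'   background cut (strict majority, > 1/2).
#' @param outlier_mad SNPs whose inter-region LD exceeds the region median by
#'   more than this many median absolute deviations are excluded as not
#'   following the general pattern.
#' @param decay_bin_cm decay-curve bin width in cM.
#' @return a list of class `ld_config`.
#' @export
ld_config <- function(background_percentile = 0.99,
                      background_threshold = 0.161,
                      min_snps = 5L, majority = 0.5, outlier_mad = 3,
                      decay_bin_cm = 1) {
  stopifnot(background_percentile > 0, background_percentile < 1,
            background_threshold >= 0, background_threshold <= 1,
            min_snps >= 1, majority > 0, majority < 1)
  structure(as.list(environment()), class = "ld_config")
}

#' Hill-Robertson r-squared between two loci
#'
#' `r2 = D^2 / (pA qA pB qB)` with `D = f_AB - pA pB` computed from
#' haplotype counts; entries missing at either locus are dropped pairwise.
#' Returns `NA` ("missing") when either locus is monomorphic after
#' filtering.
#'
#' @param x,y 0/1/`NA` haplotype allele vectors of equal length (>= 2).
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) return(NA_real_)
  pa <- mean(x); pb <- mean(y)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  D <- mean(x * y) - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' r-squared matrix between two sets of loci
#'
#' @param hs a `haplotype_set`.
#' @param loci_x,loci_y locus (column) indices.
#' @return a `length(loci_x)` x `length(loci_y)` matrix.
#' @export
r2_matrix <- function(hs, loci_x, loci_y = loci_x) {
  cpp_r2_cross(hs$alleles[, loci_x, drop = FALSE],
               hs$alleles[, loci_y, drop = FALSE])
}

#' LD-decay curve
#'
#' Mean r-squared of intra-chromosomal locus pairs binned by genetic
#' distance. All pairs are enumerated when their number does not exceed
#' `max_pairs`; otherwise a uniform random sample of pairs is used
#' (deterministic under a fixed seed).
#'
#' @param hs a `haplotype_set` with mapped loci.
#' @param bin_width bin width in cM.
#' @param max_cm maximum pair distance considered.
#' @param max_pairs enumeration/sampling switch.
#' @return data frame with `bin_mid_cM`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_curve <- function(hs, bin_width = 1, max_cm = 50, max_pairs = 50000) {
  chrom <- as.character(hs$loci$chrom)
  cm <- hs$loci$cM
  ii <- integer(0); jj <- integer(0)
  total_pairs <- sum(vapply(unique(chrom),
                            function(ch) choose(sum(chrom == ch), 2),
                            numeric(1)))
  if (total_pairs == 0) stop("no mapped intra-chromosomal pairs")
  if (total_pairs <= max_pairs) {
    for (ch in unique(chrom)) {
      cols <- which(chrom == ch)
      if (length(cols) < 2) next
      pr <- utils::combn(cols, 2)
      ii <- c(ii, pr[1, ]); jj <- c(jj, pr[2, ])
    }
  } else {
    # sample pairs proportionally to per-chromosome pair counts
    for (ch in unique(chrom)) {
      cols <- which(chrom == ch)
      if (length(cols) < 2) next
      n_ch <- ceiling(max_pairs * choose(length(cols), 2) / total_pairs)
      a <- sample(cols, n_ch, replace = TRUE)
      b <- sample(cols, n_ch, replace = TRUE)
      keep <- a != b
      ii <- c(ii, pmin(a[keep], b[keep])); jj <- c(jj, pmax(a[keep], b[keep]))
    }
  }
  d <- abs(cm[ii] - cm[jj])
  keep <- d <= max_cm
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  vals <- cpp_r2_pairs(hs$alleles, ii - 1L, jj - 1L)
  breaks <- seq(0, max_cm, by = bin_width)
  if (max(breaks) < max_cm) breaks <- c(breaks, max_cm)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  ok <- !is.na(vals)
  mean_r2 <- rep(NA_real_, length(mids))
  n_pairs <- integer(length(mids))
  for (b in seq_along(mids)) {
    sel <- ok & bin == b
    n_pairs[b] <- sum(sel)
    if (n_pairs[b]) mean_r2[b] <- mean(vals[sel])
  }
  data.frame(bin_mid_cM = mids, mean_r2 = mean_r2, n_pairs = n_pairs)
}

#' Background-LD percentile
#'
#' Empirical quantile (linear interpolation, the same rule as
#' [derive_threshold()]) of r-squared over a random sample of
#' inter-chromosomal SNP pairs.
#'
#' @param hs a `haplotype_set` with at least two chromosomes.
#' @param q percentile (0.99).
#' @param n_pairs pair sample size.
#' @return the background r-squared percentile.
#' @export
background_ld_percentile <- function(hs, q = 0.99, n_pairs = 50000) {
  chrom <- as.character(hs$loci$chrom)
  if (length(unique(chrom)) < 2) stop("need at least two chromosomes")
  L <- ncol(hs$alleles)
  a <- sample.int(L, n_pairs, replace = TRUE)
  b <- sample.int(L, n_pairs, replace = TRUE)
  keep <- chrom[a] != chrom[b]
  vals <- cpp_r2_pairs(hs$alleles, a[keep] - 1L, b[keep] - 1L)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no polymorphic inter-chromosomal pairs")
  unname(stats::quantile(vals, q, type = 7))
}

#' Inter-region LD verdict from a precomputed r-squared matrix
#'
#' Implements the decision rule on an explicit SNP-by-SNP matrix: each SNP's
#' inter-region LD is its median r-squared against the other region's SNPs;
#' SNPs exceeding the region median by more than `outlier_mad` raw median
#' absolute deviations are excluded as not following the general pattern;
#' the pair is "in LD" iff a strict majority of the retained SNPs on *both*
#' sides exceeds the background threshold. The reported value is the highest
#' r-squared among retained SNP pairs.
#'
#' @param r2_xy matrix of r-squared values (rows = region X SNPs, columns =
#'   region Y SNPs).
#' @param cfg an `ld_config`.
#' @param threshold background-LD cut (defaults to `cfg$background_threshold`).
#' @return a list of class `region_ld_result`: `eligible`, `in_ld`,
#'   `frac_x`, `frac_y`, `max_r2`, `retained_x`, `retained_y`.
#' @export
interregion_verdict <- function(r2_xy, cfg = ld_config(),
                                threshold = cfg$background_threshold) {
  med_x <- apply(r2_xy, 1, stats::median, na.rm = TRUE)
  med_y <- apply(r2_xy, 2, stats::median, na.rm = TRUE)
  retain <- function(v) {
    m <- stats::median(v, na.rm = TRUE)
    s <- stats::mad(v, constant = 1, na.rm = TRUE)
    which(!is.na(v) & v <= m + cfg$outlier_mad * s)
  }
  kx <- retain(med_x)
  ky <- retain(med_y)
  if (!length(kx) || !length(ky)) {
    return(structure(list(eligible = FALSE, in_ld = FALSE, frac_x = NA,
                          frac_y = NA, max_r2 = NA_real_,
                          retained_x = integer(0), retained_y = integer(0)),
                     class = "region_ld_result"))
  }
  frac_x <- mean(med_x[kx] > threshold)
  frac_y <- mean(med_y[ky] > threshold)
  in_ld <- frac_x > cfg$majority && frac_y > cfg$majority
  max_r2 <- suppressWarnings(max(r2_xy[kx, ky, drop = FALSE], na.rm = TRUE))
  if (!is.finite(max_r2)) max_r2 <- NA_real_
  structure(list(eligible = TRUE, in_ld = in_ld, frac_x = frac_x,
                 frac_y = frac_y, max_r2 = max_r2, retained_x = kx,
                 retained_y = ky),
            class = "region_ld_result")
}

#' Inter-region LD analysis for two SNP sets
#'
#' @param region_x,region_y locus (column) indices of the two regions.
#' @param hs a `haplotype_set`.
#' @param cfg an `ld_config`.
#' @param threshold background-LD cut.
#' @return a `region_ld_result`; regions with fewer than `cfg$min_snps` SNPs
#'   give an ineligible verdict.
#' @export
interregion_ld <- function(region_x, region_y, hs, cfg = ld_config(),
                           threshold = cfg$background_threshold) {
  if (length(region_x) < cfg$min_snps || length(region_y) < cfg$min_snps) {
    return(structure(list(eligible = FALSE, in_ld = FALSE, frac_x = NA,
                          frac_y = NA, max_r2 = NA_real_,
                          retained_x = integer(0), retained_y = integer(0)),
                     class = "region_ld_result"))
  }
  interregion_verdict(r2_matrix(hs, region_x, region_y), cfg, threshold)
}

#' Locus indices covered by sweep-table regions
#' @param sweeps a `sweep_table`.
#' @param hs a `haplotype_set`.
#' @return a list of integer vectors, one per region.
#' @export
region_snp_sets <- function(sweeps, hs) {
  chrom <- as.character(hs$loci$chrom)
  cm <- hs$loci$cM
  lapply(seq_len(nrow(sweeps)), function(i) {
    which(chrom == sweeps$chr[i] & cm >= sweeps$pos_start[i] &
            cm <= sweeps$pos_end[i])
  })
}

#' Cluster unlinked sweep regions by inter-region LD
#'
#' Builds a graph whose vertices are the regions (restricted to those with
#' at least `cfg$min_snps` SNPs) and whose edges connect region pairs on
#' different chromosomes whose inter-region LD verdict is positive;
#' connected components are reported with the mean of the reported pairwise
#' r-squared values.
#'
#' @param sweeps a `sweep_table`.
#' @param hs a `haplotype_set`.
#' @param cfg an `ld_config`.
#' @param threshold background-LD cut.
#' @return a list with `membership` (data frame region/component), `edges`
#'   (data frame of in-LD pairs with their representative r-squared),
#'   `mean_r2` (mean over in-LD pairs) and `component_mean_r2`.
#' @export
ld_cluster <- function(sweeps, hs, cfg = ld_config(),
                       threshold = cfg$background_threshold) {
  sets <- region_snp_sets(sweeps, hs)
  n <- nrow(sweeps)
  edges <- data.frame(i = integer(0), j = integer(0), r2 = numeric(0))
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sweeps$chr[i] == sweeps$chr[j]) next
        res <- interregion_ld(sets[[i]], sets[[j]], hs, cfg, threshold)
        if (res$eligible && res$in_ld) {
          edges <- rbind(edges, data.frame(i = i, j = j, r2 = res$max_r2))
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  comp <- igraph::components(g)$membership
  comp_r2 <- vapply(sort(unique(comp)), function(k) {
    sel <- edges$i %in% which(comp == k) & edges$j %in% which(comp == k)
    if (any(sel)) mean(edges$r2[sel]) else NA_real_
  }, numeric(1))
  list(membership = data.frame(region = sweeps$region, component = comp,
                               stringsAsFactors = FALSE),
       edges = transform(edges,
                         region_i = sweeps$region[i],
                         region_j = sweeps$region[j]),
       mean_r2 = if (nrow(edges)) mean(edges$r2) else NA_real_,
       component_mean_r2 = comp_r2)
}
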