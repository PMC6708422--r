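#' Null distribution of a scan statistic
#'
#' Pools the relevant score values (|standardized| for the two-sided iHS and
#' nSL, raw otherwise) from neutral-replicate score tracks.
#'
#' @param statistic one of `"FST"`, `"IHS"`, `"NSL"`, `"XPCLR"`.
#' @param values numeric values (non-finite values are dropped).
#' @param replicate optional replicate provenance vector.
#' @return a list of class `null_distribution`.
#' @export
null_distribution <- function(statistic, values, replicate = NULL) {
  statistic <- match.arg(statistic, SWEEP_METHODS)
  keep <- is.finite(values)
  if (!is.null(replicate)) replicate <- replicate[keep]
  values <- values[keep]
  if (!length(values)) stop("empty null distribution")
  structure(list(statistic = statistic, values = values,
                 replicate = replicate),
            class = "null_distribution")
}

#' Extract the thresholded score values from a track
#'
#' iHS and nSL are two-sided and compared on |standardized|; Fst and XPCLR
#' are one-sided on the raw (windowed) value.
#' @param track a `score_track`.
#' @return numeric vector aligned with the track rows.
#' @export
track_values <- function(track) {
  stat <- attr(track, "statistic")
  if (stat %in% c("IHS", "NSL")) abs(track$standardized) else track$raw
}

#' Pool neutral tracks into a null distribution
#' @param tracks list of `score_track`s of one statistic.
#' @return a `null_distribution`.
#' @export
null_from_tracks <- function(tracks) {
  stat <- unique(vapply(tracks, attr, "", "statistic"))
  if (length(stat) != 1) stop("tracks mix statistics")
  vals <- unlist(lapply(tracks, track_values), use.names = FALSE)
  rep_id <- rep(seq_along(tracks),
                vapply(tracks, nrow, 1L))[is.finite(unlist(lapply(tracks, track_values)))]
  null_distribution(stat, vals, rep_id)
}

#' Derive a significance threshold from a neutral null
#'
#' Empirical quantile with linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param null a `null_distribution`.
#' @param percentile e.g. 0.99 (XPCLR, iHS, nSL) or 0.999 (Fst, whose null
#'   has higher variance).
#' @return a list of class `sweep_threshold` with `statistic`, `percentile`
#'   and `value`.
#' @export
derive_threshold <- function(null, percentile) {
  stopifnot(percentile > 0, percentile < 1)
  n_rec <- ceiling(1 / (1 - percentile))
  if (length(null$values) < n_rec) {
    warning(sprintf("only %d null values for the %.4g percentile (>= %d recommended)",
                    length(null$values), percentile, n_rec))
  }
  v <- null$values
  if (null$statistic %in% c("IHS", "NSL")) v <- abs(v)
  structure(list(statistic = null$statistic, percentile = percentile,
                 value = unname(stats::quantile(v, percentile, type = 7,
                                                na.rm = TRUE))),
            class = "sweep_threshold")
}

#' Select the evaluation points exceeding a threshold
#'
#' Strictly greater than the threshold value; order preserved; missing
#' scores never significant.
#'
#' @param track a `score_track`.
#' @param thr a `sweep_threshold` of the same statistic.
#' @return the significant subset of `track` (still a `score_track`).
#' @export
call_significant_windows <- function(track, thr) {
  if (!identical(attr(track, "statistic"), thr$statistic)) {
    stop(sprintf("statistic mismatch: track is %s, threshold is %s",
                 attr(track, "statistic"), thr$statistic))
  }
  v <- track_values(track)
  keep <- which(!is.na(v) & v > thr$value)
  out <- track[keep, , drop = FALSE]
  class(out) <- class(track)
  attr(out, "statistic") <- attr(track, "statistic")
  out
}

#' Merge adjacent significant points into sweep regions
#'
#' Consecutive significant points on one chromosome are merged into a single
#' signature when their contributing SNPs are in strong LD: the mean
#' r-squared between the two points' SNP sets must exceed the background-LD
#' cut (by default the 99th background percentile, the same rule as the
#' inter-region analysis). Singleton points become zero-length regions.
#'
#' @param points a significant `score_track` (from
#'   [call_significant_windows()]) carrying `snp_idx`.
#' @param hs the `haplotype_set` the scan was computed on.
#' @param ld_threshold the "strong LD" cut (numeric), e.g.
#'   [background_ld_percentile()] output or the published constant 0.161.
#' @param population population label recorded in the output rows.
#' @return a `sweep_table`.
#' @export
merge_regions <- function(points, hs, ld_threshold = 0.161,
                          population = "Post70") {
  stat <- attr(points, "statistic")
  if (!nrow(points)) {
    return(sweep_table(chr = character(0), pos_start = numeric(0),
                       pos_end = numeric(0), pops = list(), methods = list()))
  }
  o <- order(points$chrom, points$pos_cM)
  points <- points[o, , drop = FALSE]
  n <- nrow(points)
  new_region <- rep(TRUE, n)
  for (i in seq_len(n - 1L)) {
    same <- points$chrom[i + 1L] == points$chrom[i]
    if (!same) next
    a <- points$snp_idx[[i]]
    b <- points$snp_idx[[i + 1L]]
    if (!length(a) || !length(b)) next
    r2m <- cpp_r2_cross(hs$alleles[, a, drop = FALSE],
                        hs$alleles[, b, drop = FALSE])
    m <- mean(r2m, na.rm = TRUE)
    if (!is.na(m) && m > ld_threshold) new_region[i + 1L] <- FALSE
  }
  grp <- cumsum(new_region)
  chr <- tapply(points$chrom, grp, `[`, 1)
  start <- tapply(points$pos_cM, grp, min)
  end <- tapply(points$pos_cM, grp, max)
  sweep_table(chr = as.character(chr), pos_start = as.numeric(start),
              pos_end = as.numeric(end),
              pops = rep(list(population), length(chr)),
              methods = rep(list(stat), length(chr)))
}

#' Combine per-method, per-population sweep tables
#'
#' Intervals on the same chromosome that overlap (closed intervals, any cM
#' overlap, transitively) are unioned into a single row whose method and
#' population sets are the unions and whose interval is the union span.
#' The operation is idempotent and order-independent.
#'
#' @param tables a list of `sweep_table`s (or a single one).
#' @return a `sweep_table`.
#' @export
combine_scans <- function(tables) {
  if (inherits(tables, "sweep_table")) tables <- list(tables)
  tables <- Filter(nrow, tables)
  if (!length(tables)) {
    return(sweep_table(chr = character(0), pos_start = numeric(0),
                       pos_end = numeric(0), pops = list(), methods = list()))
  }
  all <- do.call(rbind, lapply(tables, function(t) {
    data.frame(chr = t$chr, pos_start = t$pos_start, pos_end = t$pos_end,
               stringsAsFactors = FALSE)
  }))
  pops <- do.call(c, lapply(tables, `[[`, "pops"))
  methods <- do.call(c, lapply(tables, `[[`, "methods"))
  o <- order(all$chr, all$pos_start, all$pos_end)
  all <- all[o, , drop = FALSE]
  pops <- pops[o]
  methods <- methods[o]
  out_chr <- character(0); out_s <- numeric(0); out_e <- numeric(0)
  out_p <- list(); out_m <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    out_chr <<- c(out_chr, cur$chr); out_s <<- c(out_s, cur$s)
    out_e <<- c(out_e, cur$e)
    out_p[[length(out_p) + 1L]] <<- intersect(SWEEP_POPS, unique(cur$p))
    out_m[[length(out_m) + 1L]] <<- intersect(SWEEP_METHODS, unique(cur$m))
  }
  for (i in seq_len(nrow(all))) {
    if (!is.null(cur) && all$chr[i] == cur$chr && all$pos_start[i] <= cur$e) {
      cur$e <- max(cur$e, all$pos_end[i])
      cur$p <- c(cur$p, pops[[i]])
      cur$m <- c(cur$m, methods[[i]])
    } else {
      flush()
      cur <- list(chr = all$chr[i], s = all$pos_start[i], e = all$pos_end[i],
                  p = pops[[i]], m = methods[[i]])
    }
  }
  flush()
  sweep_table(chr = out_chr, pos_start = out_s, pos_end = out_e,
              pops = out_p, methods = out_m)
}

#' Write thresholds as JSON
#' @param thresholds list of `sweep_threshold`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  x <- lapply(thresholds, function(t) {
    list(statistic = t$statistic, percentile = t$percentile, value = t$value)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
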