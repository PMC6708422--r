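#' Summarize a sweep-region table
#'
#' Recomputes the headline counts of the published analysis from a
#' `sweep_table`: regions per detecting method and per population,
#' method-exclusive counts, pairwise method overlaps, interval lengths and
#' the number of regions found in more than one population.
#'
#' @param t a `sweep_table`.
#' @return a list of class `sweep_summary`.
#' @export
summarize_sweep_table <- function(t) {
  n <- nrow(t)
  has_m <- function(m) vapply(t$methods, function(x) m %in% x, TRUE)
  has_p <- function(p) vapply(t$pops, function(x) p %in% x, TRUE)
  method_counts <- vapply(SWEEP_METHODS, function(m) sum(has_m(m)), 1L)
  pop_counts <- vapply(SWEEP_POPS, function(p) sum(has_p(p)), 1L)
  exclusive <- vapply(SWEEP_METHODS, function(m) {
    sum(vapply(t$methods, function(x) identical(x, m), TRUE))
  }, 1L)
  overlap <- matrix(0L, 4, 4, dimnames = list(SWEEP_METHODS, SWEEP_METHODS))
  for (a in SWEEP_METHODS) {
    for (b in SWEEP_METHODS) {
      overlap[a, b] <- sum(has_m(a) & has_m(b))
    }
  }
  fst_only_post70 <- sum(vapply(t$methods, function(x) identical(x, "FST"), TRUE) &
                           has_p("Post70"))
  lengths <- t$pos_end - t$pos_start
  structure(list(
    n_regions = n,
    method_counts = method_counts,
    pop_counts = pop_counts,
    method_exclusive_counts = exclusive,
    method_overlap = overlap,
    fst_only_post70 = fst_only_post70,
    multi_population_count = sum(vapply(t$pops, length, 1L) >= 2L),
    lengths = stats::setNames(lengths, t$region),
    max_length = if (n) max(lengths) else 0,
    mean_length = if (n) mean(lengths) else 0
  ), class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("sweep_summary:", x$n_regions, "regions\n")
  cat("  per method: ",
      paste(names(x$method_counts), x$method_counts, sep = "=",
            collapse = ", "), "\n")
  cat("  per population: ",
      paste(names(x$pop_counts), x$pop_counts, sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("  max length %.1f cM, mean length %.2f cM\n",
              x$max_length, x$mean_length))
  invisible(x)
}

#' Mean off-diagonal r-squared of an LD matrix
#'
#' Arithmetic mean of all non-missing off-diagonal cells (asymmetric cells
#' each count once, matching the printed table's convention).
#'
#' @param m an `ld_matrix_fixture` or square numeric matrix.
#' @return a list with `mean` (unrounded) and `rounded` (two decimals).
#' @export
mean_offdiag <- function(m) {
  if (inherits(m, "ld_matrix_fixture")) m <- m$r2
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  off <- m[row(m) != col(m)]
  if (all(is.na(off))) stop("all off-diagonal cells are missing")
  mu <- mean(off, na.rm = TRUE)
  list(mean = mu, rounded = round(mu, 2))
}

#' Expected heterozygosity after g generations of selfing
#'
#' A cultivar released after `g` generations of self-pollination (counting
#' the heterozygous founder as generation 1) retains a fraction
#' `1 / 2^(g - 1)` of heterozygosity at a polymorphic locus: 3.125% at g = 6,
#' 0.78% at g = 8.
#'
#' @param g number of selfed generations (integer >= 1).
#' @return the expected heterozygous fraction.
#' @export
selfing_het <- function(g) {
  if (any(g < 1) || any(g != round(g))) stop("g must be an integer >= 1")
  1 / 2^(g - 1)
}

#' Pipeline configuration
#'
#' @param profile scenario profile (see [wheat_scenario_config()]).
#' @param n_null_replicates neutral replicates pooled into the null
#'   distributions.
#' @param seed integer seed controlling every random draw.
#' @param scan a `scan_config`.
#' @param ld an `ld_config`.
#' @param percentiles named percentiles per statistic; the published choice
#'   is the 99th percentile for XPCLR/iHS/nSL and the 99.9th for Fst.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @param scenario_overrides named list forwarded to
#'   [wheat_scenario_config()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = "desk", n_null_replicates = 10L,
                            seed = 1L, scan = scan_config(), ld = ld_config(),
                            percentiles = c(FST = 0.999, IHS = 0.99,
                                            NSL = 0.99, XPCLR = 0.99),
                            out_dir = NULL, scenario_overrides = list()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Scan one simulated dataset with all four statistics
#'
#' Fst and XPCLR contrast the Pre70 (reference) and Post70 (objective)
#' cohorts. The single-population haplotype statistics iHS and nSL are by
#' default applied to the whole population (both cohorts pooled, as the
#' published analysis also did); at desk scale the pooled sample leaves many
#' more cores with a truncating EHH curve than a single small cohort does.
#'
#' @param dataset an (ascertained) `sim_dataset`.
#' @param scan a `scan_config`.
#' @param haplo_population `"all"` or a cohort label: the sample scanned by
#'   iHS/nSL.
#' @return a named list of four `score_track`s.
#' @export
scan_dataset <- function(dataset, scan = scan_config(),
                         haplo_population = "all") {
  hs <- dataset$haplotypes
  cohorts <- dataset$cohorts
  post <- subset_haplotypes(hs, individuals = which(cohorts == "Post70"))
  pre <- subset_haplotypes(hs, individuals = which(cohorts == "Pre70"))
  target <- if (identical(haplo_population, "all")) hs else
    subset_haplotypes(hs, individuals = which(cohorts == haplo_population))
  haplo <- .haplo_scan_both(target, scan)
  list(FST = fst_scan(hs, cohorts, scan),
       IHS = haplo$ihs,
       NSL = haplo$nsl,
       XPCLR = xpclr_scan(post, pre, scan))
}

.simulate_ascertained <- function(scen_cfg) {
  ds <- run_wheat_scenario(scen_cfg)
  spec <- ascertainment_spec(panel_size = scen_cfg$panel_size,
                             n_snps = scen_cfg$n_snps,
                             tetraploid_panel = scen_cfg$tetraploid_panel)
  ascertain_snp_panel(ds, spec)
}

#' Run the full null-calibrated scan pipeline
#'
#' Simulates `n_null_replicates` neutral datasets plus one target dataset
#' under the configured demography, ascertains the SNP panel in each, scans
#' all four statistics, derives thresholds from the pooled neutral scores,
#' calls and merges significant windows on the target dataset, combines the
#' per-method tables and runs the inter-region LD clustering.
#'
#' @param cfg a `pipeline_config`.
#' @return a list of class `pipeline_result` with `sweeps` (combined
#'   `sweep_table`), `thresholds`, `tracks`, `null_sizes`,
#'   `significant_fraction` (per statistic, on the target dataset),
#'   `background_ld`, `cluster`, `summary`, `dataset` and `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  set.seed(cfg$seed)
  scen <- do.call(wheat_scenario_config,
                  c(list(profile = cfg$profile), cfg$scenario_overrides))
  null_tracks <- list(FST = list(), IHS = list(), NSL = list(), XPCLR = list())
  for (r in seq_len(cfg$n_null_replicates)) {
    ds <- .simulate_ascertained(scen)
    tr <- scan_dataset(ds, cfg$scan)
    for (m in SWEEP_METHODS) null_tracks[[m]][[r]] <- tr[[m]]
  }
  target <- .simulate_ascertained(scen)
  target_tracks <- scan_dataset(target, cfg$scan)
  thresholds <- list()
  sig_frac <- c()
  per_method_tables <- list()
  bg <- background_ld_percentile(target$haplotypes,
                                 q = cfg$ld$background_percentile)
  skipped <- character(0)
  for (m in SWEEP_METHODS) {
    nd <- tryCatch(null_from_tracks(null_tracks[[m]]), error = function(e) NULL)
    if (is.null(nd)) {
      # no evaluable score anywhere in the neutral replicates (e.g. iHS when
      # every EHH curve runs off the chromosome): record and move on
      skipped <- c(skipped, m)
      sig_frac[m] <- NA_real_
      next
    }
    thr <- derive_threshold(nd, cfg$percentiles[[m]])
    thresholds[[m]] <- thr
    sig <- call_significant_windows(target_tracks[[m]], thr)
    v <- track_values(target_tracks[[m]])
    sig_frac[m] <- nrow(sig) / sum(is.finite(v))
    per_method_tables[[m]] <- merge_regions(sig, target$haplotypes,
                                            ld_threshold = bg,
                                            population = "Post70")
  }
  sweeps <- combine_scans(per_method_tables)
  cluster <- ld_cluster(sweeps, target$haplotypes, cfg$ld, threshold = bg)
  summary <- summarize_sweep_table(sweeps)
  result <- structure(list(sweeps = sweeps, thresholds = thresholds,
                           tracks = target_tracks,
                           null_sizes = vapply(null_tracks, function(x)
                             sum(vapply(x, nrow, 1L)), 1L),
                           significant_fraction = sig_frac,
                           skipped = skipped,
                           background_ld = bg, cluster = cluster,
                           summary = summary, dataset = target,
                           config = cfg),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sweep_table(sweeps, file.path(cfg$out_dir, "sweep_regions.tsv"))
    write_thresholds(thresholds, file.path(cfg$out_dir, "thresholds.json"))
    for (m in SWEEP_METHODS) {
      write_score_track(target_tracks[[m]],
                        file.path(cfg$out_dir, sprintf("track_%s.tsv", m)))
    }
    run_info <- list(
      seed = cfg$seed, profile = cfg$profile,
      n_null_replicates = cfg$n_null_replicates,
      migration = scen$m, n_snps = scen$n_snps,
      percentiles = as.list(cfg$percentiles),
      background_ld = bg,
      skipped = skipped,
      null_sizes = as.list(result$null_sizes),
      significant_fraction = as.list(sig_frac),
      n_regions = nrow(sweeps))
    jsonlite::write_json(run_info, file.path(cfg$out_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
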