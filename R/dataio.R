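#' Phased haplotype container
#'
#' A `haplotype_set` stores biallelic haplotypes for a set of inbred or phased
#' individuals together with locus metadata. The allele matrix has two rows
#' per individual (rows `2i - 1` and `2i` are the two haplotypes of individual
#' `i` on every chromosome; inheritance is disomic within each subgenome, so
#' two rows suffice even for an allopolyploid) and one column per locus.
#' Allele values are 0, 1 or `NA`.
#'
#' @param alleles integer matrix of 0/1/`NA`, `2 * length(individuals)` rows,
#'   one column per locus.
#' @param individuals character vector of sample IDs.
#' @param loci data frame with columns `locus`, `chrom`, `cM`, `bp`. Loci must
#'   be sorted by (chromosome, genetic position); genetic positions must be
#'   non-decreasing and physical positions strictly increasing within a
#'   chromosome. Chromosome labels carry the subgenome (e.g. `"1A"`, `"3D"`).
#' @param ploidy_note number of homoeologous subgenomes carried (1-3). If
#'   `NULL`, inferred from the trailing letters of the chromosome labels.
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(alleles, individuals, loci, ploidy_note = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(individuals)) {
    stop("alleles must have exactly two haplotype rows per individual")
  }
  if (ncol(alleles) != nrow(loci)) {
    stop("alleles must have one column per locus")
  }
  bad <- !(alleles %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("allele values must be 0, 1 or NA")
  loci <- as.data.frame(loci)
  need <- c("locus", "chrom", "cM", "bp")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns locus, chrom, cM, bp")
  }
  .check_loci_sorted(loci)
  if (is.null(ploidy_note)) {
    sub <- unique(gsub("^[0-9]+", "", as.character(loci$chrom)))
    ploidy_note <- max(1L, length(sub[nzchar(sub)]))
  }
  rownames(alleles) <- paste0(rep(individuals, each = 2L),
                              rep(c("_h1", "_h2"), length(individuals)))
  colnames(alleles) <- loci$locus
  structure(list(alleles = alleles,
                 individuals = as.character(individuals),
                 loci = loci,
                 ploidy_note = as.integer(ploidy_note)),
            class = "haplotype_set")
}

.check_loci_sorted <- function(loci) {
  chrom <- as.character(loci$chrom)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cm <- loci$cM[idx]
    bp <- loci$bp[idx]
    off <- which(diff(cm) < 0)
    if (length(off)) {
      stop(sprintf("loci unsorted: genetic position decreases at index %d (chromosome %s)",
                   idx[off[1] + 1L], ch))
    }
    off <- which(diff(bp) <= 0)
    if (length(off)) {
      stop(sprintf("loci unsorted: physical position not strictly increasing at index %d (chromosome %s)",
                   idx[off[1] + 1L], ch))
    }
  }
  # chromosome blocks must be contiguous
  r <- rle(chrom)
  if (any(duplicated(r$values))) {
    stop("loci unsorted: chromosome blocks are not contiguous")
  }
  invisible(TRUE)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d individuals, %d loci on %d chromosome(s), %d subgenome(s)\n",
              length(x$individuals), nrow(x$loci),
              length(unique(x$loci$chrom)), x$ploidy_note))
  invisible(x)
}

#' Number of haplotype rows in a haplotype set
#' @param hs a `haplotype_set`.
#' @return integer.
#' @export
n_haplotypes <- function(hs) nrow(hs$alleles)

#' Subset a haplotype set
#'
#' @param hs a `haplotype_set`.
#' @param individuals character vector or indices of individuals to keep.
#' @param loci logical/integer index of loci to keep (order preserved).
#' @return a `haplotype_set`.
#' @export
subset_haplotypes <- function(hs, individuals = NULL, loci = NULL) {
  ind <- hs$individuals
  if (!is.null(individuals)) {
    keep <- if (is.character(individuals)) match(individuals, ind) else individuals
    if (anyNA(keep)) stop("unknown individual(s)")
    rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
    hs$alleles <- hs$alleles[rows, , drop = FALSE]
    hs$individuals <- ind[keep]
  }
  if (!is.null(loci)) {
    hs$alleles <- hs$alleles[, loci, drop = FALSE]
    hs$loci <- hs$loci[loci, , drop = FALSE]
    rownames(hs$loci) <- NULL
  }
  haplotype_set(hs$alleles, hs$individuals, hs$loci, hs$ploidy_note)
}

#' Read haplotypes from disk
#'
#' Two formats are supported. `"hapmatrix"` is a TSV with one row per
#' haplotype (column `haplotype` holding `<sample>_h1` / `<sample>_h2` IDs)
#' and one 0/1/NA column per locus, accompanied by a map TSV
#' (`<path>.map` by default) with columns `locus`, `chrom`, `cM`, `bp`.
#' `"vcf"` reads biallelic SNPs; phased and unphased calls are treated
#' identically (the order of the two haplotype rows is unspecified because
#' downstream statistics operate on haplotype multisets); a heterozygous call
#' becomes one 0 row and one 1 row. Genetic positions are taken from the
#' `CM` INFO field when present, otherwise `cM = bp / 1e6`.
#'
#' @param path file path.
#' @param format `"hapmatrix"` or `"vcf"`.
#' @param map_path map TSV path for the hapmatrix format; defaults to
#'   `paste0(path, ".map")`.
#' @return a `haplotype_set`.
#' @export
read_haplotypes <- function(path, format = c("hapmatrix", "vcf"),
                            map_path = paste0(path, ".map")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "hapmatrix") {
    .read_hapmatrix(path, map_path)
  } else {
    .read_vcf(path)
  }
}

.read_hapmatrix <- function(path, map_path) {
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  map <- utils::read.delim(map_path, check.names = FALSE)
  if (!"haplotype" %in% names(tab)) stop("hapmatrix must have a 'haplotype' column")
  hap_ids <- tab$haplotype
  alleles <- as.matrix(tab[, setdiff(names(tab), "haplotype"), drop = FALSE])
  storage.mode(alleles) <- "integer"
  if (!identical(colnames(alleles), as.character(map$locus))) {
    stop("hapmatrix locus columns do not match the map file")
  }
  individuals <- unique(sub("_h[12]$", "", hap_ids))
  haplotype_set(alleles, individuals, map)
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop(sprintf("multiallelic record not supported: %s:%s (%s)",
                 fix[multi, "CHROM"][1], fix[multi, "POS"][1],
                 fix[multi, "ID"][1]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  info <- vcfR::getINFO(v)
  cm <- suppressWarnings(as.numeric(sub(".*CM=([0-9.eE+-]+).*", "\\1", info)))
  bp <- as.numeric(fix[, "POS"])
  if (all(is.na(cm))) cm <- bp / 1e6
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  loci <- data.frame(locus = ids, chrom = fix[, "CHROM"], cM = cm, bp = bp,
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$cM, loci$bp)
  loci <- loci[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  n_loci <- nrow(loci)
  alleles <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_loci)
  split_gt <- function(g) {
    a <- strsplit(g, "[/|]")
    a
  }
  for (j in seq_along(samples)) {
    parts <- split_gt(gt[, j])
    a1 <- vapply(parts, function(p) p[1], character(1))
    a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], character(1))
    alleles[2L * j - 1L, ] <- suppressWarnings(as.integer(a1))
    alleles[2L * j, ] <- suppressWarnings(as.integer(a2))
  }
  haplotype_set(alleles, samples, loci)
}

#' Write haplotypes to disk
#'
#' Lossless for allele values 0/1/`NA` in both formats. The hapmatrix format
#' also writes the companion map TSV; the VCF format stores the genetic
#' position in the `CM` INFO field and encodes the two haplotype rows of each
#' individual as a phased genotype.
#'
#' @param hs a `haplotype_set`.
#' @param path output path.
#' @param format `"hapmatrix"` or `"vcf"`.
#' @param map_path map TSV path for the hapmatrix format.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(hs, path, format = c("hapmatrix", "vcf"),
                             map_path = paste0(path, ".map")) {
  format <- match.arg(format)
  if (format == "hapmatrix") {
    ids <- rownames(hs$alleles)
    if (is.null(ids)) ids <- character(nrow(hs$alleles))
    tab <- data.frame(haplotype = ids,
                      hs$alleles, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hs$loci, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in centimorgans\">",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", hs$individuals), collapse = "\t")),
               con)
    n_ind <- length(hs$individuals)
    a <- hs$alleles
    for (l in seq_len(nrow(hs$loci))) {
      g1 <- a[seq(1L, 2L * n_ind, by = 2L), l]
      g2 <- a[seq(2L, 2L * n_ind, by = 2L), l]
      gt <- paste(ifelse(is.na(g1), ".", g1), ifelse(is.na(g2), ".", g2),
                  sep = "|")
      row <- c(as.character(hs$loci$chrom[l]),
               format(hs$loci$bp[l], scientific = FALSE),
               as.character(hs$loci$locus[l]), "A", "T", ".", "PASS",
               sprintf("CM=%.6g", hs$loci$cM[l]), "GT", gt)
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}
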