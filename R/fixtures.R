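#' Canonical method and population vocabularies
#'
#' The four scan statistics and the seven population contrasts used for the
#' Australian wheat germplasm: the post-Green-Revolution cohort (`Post70`),
#' the whole 482-cultivar population (`All`) and the five states.
#' @name vocab
#' @keywords internal
NULL

SWEEP_METHODS <- c("FST", "IHS", "NSL", "XPCLR")
SWEEP_POPS <- c("Post70", "All", "NSW", "QLD", "SA", "VIC", "WA")

.normalize_methods <- function(x) {
  toks <- trimws(strsplit(x, ",")[[1]])
  out <- character(0)
  for (t in toks) {
    out <- c(out, switch(tolower(gsub("[*_ ]", "", t)),
                         "fst" = "FST",
                         "ihs" = "IHS",
                         "his" = "IHS",  # printed typo for iHS in one row
                         "nsl" = "NSL",
                         "xpclr" = "XPCLR",
                         "all" = SWEEP_METHODS,
                         stop("unknown method token: ", t)))
  }
  intersect(SWEEP_METHODS, out)  # canonical order, unique
}

.normalize_pops <- function(x) {
  x <- trimws(x)
  if (x == "All comparisons") return(SWEEP_POPS)
  toks <- trimws(strsplit(x, ",")[[1]])
  bad <- setdiff(toks, SWEEP_POPS)
  if (length(bad)) stop("unknown population token: ", paste(bad, collapse = ", "))
  intersect(SWEEP_POPS, toks)
}

#' Construct a sweep-region table
#'
#' Intervals are closed `[start, end]` in centimorgans; a single-SNP region
#' has `start == end` and length zero. `pops` and `methods` are list columns
#' of canonical tokens (see [SWEEP_POPS] and [SWEEP_METHODS]).
#'
#' @param region region IDs (`"<chr>-<start>:<end>"` if `NULL`).
#' @param chr chromosome labels.
#' @param pos_start,pos_end interval bounds in cM.
#' @param pops list of character vectors over the population vocabulary.
#' @param methods list of character vectors over the method vocabulary.
#' @param annotations optional free-text column.
#' @return a data frame of class `sweep_table`.
#' @export
sweep_table <- function(region = NULL, chr, pos_start, pos_end, pops, methods,
                        annotations = NULL) {
  stopifnot(all(pos_start <= pos_end))
  if (any(!vapply(methods, length, 1L))) stop("methods must be non-empty")
  if (any(!vapply(pops, length, 1L))) stop("populations must be non-empty")
  if (is.null(region)) {
    region <- sprintf("%s-%s:%s", chr, format(pos_start, trim = TRUE),
                      format(pos_end, trim = TRUE))
  }
  if (is.null(annotations)) annotations <- rep("", length(chr))
  out <- data.frame(region = region, chr = as.character(chr),
                    pos_start = pos_start, pos_end = pos_end,
                    stringsAsFactors = FALSE)
  out$pops <- pops
  out$methods <- methods
  out$annotations <- annotations
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Load the packaged table of published sweep regions
#'
#' Returns the 86 genomic regions flagged as affected by artificial selection
#' in the Australian wheat germplasm, transcribed from the published table:
#' chromosome, closed cM interval, the populations in which each region was
#' detected and the detecting statistics. The printed shorthand is expanded:
#' `"All comparisons"` denotes every population contrast, the Analysis value
#' `"All"` denotes all four statistics, and the printed `"his"` is normalized
#' to `IHS`.
#'
#' @return a `sweep_table` with 86 rows.
#' @export
load_sweep_table_fixture <- function() {
  path <- system.file("extdata", "sweep_regions_table1.tsv",
                      package = "polysweep", mustWork = TRUE)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sweep_table(region = raw$Region, chr = raw$Chr,
              pos_start = raw$PosStart, pos_end = raw$PosEnd,
              pops = lapply(raw$Pops, .normalize_pops),
              methods = lapply(raw$Analysis, .normalize_methods))
}

#' Load the packaged inter-region r-squared matrix
#'
#' The published 17 x 17 matrix of r-squared values between 13 unlinked sweep
#' regions and 4 characterized genes, transcribed as printed: asymmetric cells
#' are preserved and missing entries (printed as dashes) are `NA`. The
#' diagonal is 1.
#'
#' @return a list with elements `labels` (17 labels) and `r2` (17 x 17 numeric
#'   matrix with dimnames), of class `ld_matrix_fixture`.
#' @export
load_ld_matrix_fixture <- function() {
  path <- system.file("extdata", "interregion_r2_table3.tsv",
                      package = "polysweep", mustWork = TRUE)
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(raw)
  structure(list(labels = rownames(m), r2 = m), class = "ld_matrix_fixture")
}

#' Write and read sweep tables as TSV
#'
#' Serialization uses comma-joined `Pops` and `Methods` columns.
#' @param t a `sweep_table`.
#' @param path file path.
#' @return `path` (write) or a `sweep_table` (read).
#' @export
write_sweep_table <- function(t, path) {
  out <- data.frame(Region = t$region, Chr = t$chr, PosStart = t$pos_start,
                    PosEnd = t$pos_end,
                    Pops = vapply(t$pops, paste, "", collapse = ","),
                    Methods = vapply(t$methods, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_table
#' @export
read_sweep_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sweep_table(region = raw$Region, chr = raw$Chr, pos_start = raw$PosStart,
              pos_end = raw$PosEnd,
              pops = lapply(strsplit(raw$Pops, ","), trimws),
              methods = lapply(strsplit(raw$Methods, ","), trimws))
}
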