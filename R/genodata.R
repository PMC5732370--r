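#' Construct a genotype table
#'
#' Container for allele dosage data: one row per analysis unit
#' (diploid individual or population), one column per biallelic locus.
#' Individual-level tables hold counts of the counted allele (0, 1 or 2);
#' population-level tables hold allele frequencies in \[0, 1\].
#'
#' @param dosages numeric matrix, units x loci.
#' @param unit_ids character vector of unit identifiers; defaults to the
#'   matrix rownames.
#' @param locus_ids character vector of locus identifiers; defaults to the
#'   matrix colnames.
#' @param type `"dosage"` for diploid 0/1/2 counts, `"frequency"` for
#'   per-population allele frequencies.
#'
#' @return An object of class `genotype_table` with elements `dosages`,
#'   `unit_ids`, `locus_ids`, `type` and a logical `monomorphic` flag per
#'   locus.
#' @export
genotype_table <- function(dosages, unit_ids = rownames(dosages),
                           locus_ids = colnames(dosages),
                           type = c("dosage", "frequency")) {
  type <- match.arg(type)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_len(n))
  if (is.null(locus_ids)) locus_ids <- paste0("locus_", seq_len(m))
  unit_ids <- as.character(unit_ids)
  locus_ids <- as.character(locus_ids)
  if (length(unit_ids) != n || anyNA(unit_ids) || any(unit_ids == ""))
    stop_validation("unit_ids must be complete and match the number of rows")
  if (anyDuplicated(unit_ids))
    stop_validation("duplicated unit_ids")
  if (length(locus_ids) != m)
    stop_validation("locus_ids must match the number of columns")
  if (anyNA(dosages))
    stop_validation("missing dosage values; impute or remove them first")
  if (type == "dosage" && !all(dosages %in% c(0, 1, 2)))
    stop_validation("diploid dosages must be 0, 1 or 2")
  if (type == "frequency" && (any(dosages < 0) || any(dosages > 1)))
    stop_validation("population frequencies must lie in [0, 1]")
  mono <- apply(dosages, 2, function(x) length(unique(x)) < 2L)
  dimnames(dosages) <- list(unit_ids, locus_ids)
  structure(
    list(dosages = dosages, unit_ids = unit_ids, locus_ids = locus_ids,
         type = type, monomorphic = mono),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d units x %d loci (%s scale), %d monomorphic\n",
              nrow(x$dosages), ncol(x$dosages), x$type, sum(x$monomorphic)))
  invisible(x)
}

#' Read genotype data from file
#'
#' Reads either a dosage CSV (header `unit,locus1,...,locusM`, cells 0/1/2)
#' or a VCF 4.x with diploid GT fields. Non-biallelic VCF sites are skipped
#' with a warning. Missing cells are an error unless `impute_mean = TRUE`,
#' in which case they are filled with the column mean (which keeps the
#' column centred after centring).
#'
#' @param path path to the input file.
#' @param format `"dosage"` (CSV) or `"vcf"`.
#' @param impute_mean fill missing dosages with the locus mean.
#'
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf"),
                           impute_mean = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_validation("cannot read genotype file: ", path)
  d <- switch(format,
              dosage = read_dosage_csv(path),
              vcf = read_vcf_dosages(path))
  d <- impute_or_fail(d, impute_mean)
  tab <- genotype_table(d)
  if (all(tab$monomorphic))
    stop_validation("all loci are monomorphic; nothing to analyse")
  tab
}

read_dosage_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop_validation("dosage CSV needs a unit column plus at least one locus")
  units <- as.character(raw[[1L]])
  loci <- colnames(raw)[-1L]
  d <- matrix(NA_real_, nrow(raw), length(loci),
              dimnames = list(units, loci))
  for (j in seq_along(loci)) {
    col <- raw[[j + 1L]]
    if (is.character(col)) {
      col_trim <- trimws(col)
      num <- suppressWarnings(as.numeric(col_trim))
      bad <- which(is.na(num) & !(col_trim %in% c("NA", "", "NaN")))
      if (length(bad))
        stop(sprintf("non-numeric dosage '%s' at row '%s', locus '%s'",
                     col[bad[1L]], units[bad[1L]], loci[j]))
      col <- num
    }
    d[, j] <- as.numeric(col)
  }
  d
}

read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    warning(sprintf("skipping %d non-biallelic site(s) in %s",
                    sum(!bi), basename(path)))
    v <- v[bi, ]
  }
  if (nrow(v@fix) == 0L)
    stop_validation("no biallelic sites in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles per genotype string; tolerate '/' or '|' phasing
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  d <- apply(gt, c(1, 2), count_alt)
  ids <- v@fix[, "ID"]
  rn <- ifelse(is.na(ids) | ids == ".",
               paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = "_"), ids)
  rownames(d) <- rn
  t(d)  # units x loci
}

impute_or_fail <- function(d, impute_mean) {
  if (!anyNA(d)) return(d)
  if (!impute_mean) {
    idx <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing dosage at row '%s', locus '%s' (use impute_mean)",
                 rownames(d)[idx[1L]], colnames(d)[idx[2L]]))
  }
  for (j in which(colSums(is.na(d)) > 0L)) {
    mu <- mean(d[, j], na.rm = TRUE)
    d[is.na(d[, j]), j] <- mu
  }
  d
}

#' Centred allele-frequency matrix
#'
#' Converts dosages to allele frequencies (dosage/2 for diploid tables,
#' frequencies used as-is for population tables), removes monomorphic
#' columns and centres every column to mean zero. This matrix is the `X`
#' of the sPCA eigenproblem.
#'
#' @param g a [genotype_table()], a plain numeric matrix already on the
#'   frequency scale, or a `centred_freq` object (returned unchanged up to
#'   re-centring, which is a no-op).
#' @param scale also divide each column by its standard deviation
#'   (default off: the analysis centres only).
#'
#' @return An object of class `centred_freq`: list with the n x p matrix
#'   `X` (column means zero), `unit_ids` and `column_ids`.
#' @export
centre_frequencies <- function(g, scale = FALSE) UseMethod("centre_frequencies")

#' @export
centre_frequencies.genotype_table <- function(g, scale = FALSE) {
  f <- if (g$type == "dosage") g$dosages / 2 else g$dosages
  centre_frequencies.matrix(f, scale = scale)
}

#' @export
centre_frequencies.centred_freq <- function(g, scale = FALSE) {
  centre_frequencies.matrix(g$X, scale = scale)
}

#' @export
centre_frequencies.matrix <- function(g, scale = FALSE) {
  n <- nrow(g)
  if (n < 3L)
    stop_validation("need at least 3 units for the analysis")
  keep <- apply(g, 2, function(x) stats::var(x) > 0)
  if (!any(keep))
    stop_validation("all loci are monomorphic after filtering")
  X <- scale(g[, keep, drop = FALSE], center = TRUE, scale = scale)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  structure(
    list(X = X,
         unit_ids = rownames(X) %||% paste0("unit_", seq_len(n)),
         column_ids = colnames(X) %||% paste0("col_", seq_len(ncol(X)))),
    class = "centred_freq")
}

#' @export
print.centred_freq <- function(x, ...) {
  cat(sprintf("centred_freq: %d units x %d polymorphic columns\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Aggregate individual genotypes to population allele frequencies
#'
#' Each population's entry is the mean allele frequency of its members
#' (haploid convention: values in \[0, 1\]; downstream centring then uses
#' the frequency directly).
#'
#' @param g a [genotype_table()] of diploid individuals.
#' @param assignment named character vector or factor mapping every unit id
#'   to a population label.
#'
#' @return A population-level [genotype_table()] with `type = "frequency"`.
#' @export
population_frequencies <- function(g, assignment) {
  stopifnot(inherits(g, "genotype_table"))
  assignment <- stats::setNames(as.character(assignment),
                                names(assignment) %||% g$unit_ids)
  missing <- setdiff(g$unit_ids, names(assignment))
  if (length(missing))
    stop_validation("units without population assignment: ",
                    paste(utils::head(missing, 5L), collapse = ", "))
  pops <- assignment[g$unit_ids]
  freq <- if (g$type == "dosage") g$dosages / 2 else g$dosages
  agg <- rowsum(freq, group = pops, reorder = TRUE) /
    as.vector(table(pops)[sort(unique(pops))])
  genotype_table(agg, unit_ids = rownames(agg), locus_ids = g$locus_ids,
                 type = "frequency")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# validation errors carry their own condition class so the CLI can map
# them to exit status 2
stop_validation <- function(...) {
  msg <- paste0(...)
  stop(structure(class = c("spcatest_validation", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
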