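# shared fixtures and independent oracle implementations

# all permutations of 1..n (n small), as a list of integer vectors
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# naive double-loop Moran's I (row-standardised convention)
moran_naive <- function(z, L) {
  z <- z - mean(z)
  n <- length(z)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + (L[i, j] + L[j, i]) / 2 * z[i] * z[j]
    }
  }
  num / sum(z^2)
}

# random centred data plus a KNN network
make_test_data <- function(n = 15, p = 8, k = 3, seed = 1) {
  set.seed(seed)
  X <- centre_frequencies(matrix(runif(n * p), n, p))
  W <- knn_graph(matrix(runif(2 * n), n, 2), k = k)
  list(X = X, W = W)
}

write_dosage_fixture <- function(path, dosages, units = NULL) {
  units <- units %||% paste0("ind", seq_len(nrow(dosages)))
  df <- data.frame(unit = units, dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# minimal VCF: five biallelic SNPs and one triallelic site, three samples
write_vcf_fixture <- function(path) {
  gt <- c("0/0\t0/1\t1/1",
          "0/1\t0/1\t0/0",
          "1/1\t0/0\t0/1",
          "0/0\t0/0\t0/1",
          "0/1\t1/1\t1/1",
          "0/1\t0/2\t1/2")  # triallelic, must be skipped
  alt <- c("T", "G", "C", "A", "T", "G,C")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    vapply(seq_along(gt), function(i)
      paste("1", 100 * i, paste0("snp", i), "A", alt[i], ".", "PASS", ".",
            "GT", gt[i], sep = "\t"), character(1)))
  writeLines(lines, path)
  path
}

# all-pairs F_ST estimator (1 - mean within-deme diversity over mean
# diversity across every pair of gene copies), matching the Slatkin
# (T_bar - T_w)/T_bar formulation of the island-model closed form
fst_allpairs <- function(g) {
  demes <- attr(g, "deme")
  dos <- g$dosages
  pw_all <- pw_w <- 0
  n_w <- 0
  dm2 <- rep(demes, each = 2)
  nc <- 2 * nrow(dos)
  for (loc in seq_len(ncol(dos))) {
    # expand diploid dosages to gene copies (0/1 alleles)
    a <- as.vector(rbind(pmin(dos[, loc], 1), pmax(dos[, loc] - 1, 0)))
    c1 <- sum(a)
    pw_all <- pw_all + c1 * (nc - c1)
    for (d in unique(dm2)) {
      ad <- a[dm2 == d]
      pw_w <- pw_w + sum(ad) * (length(ad) - sum(ad))
    }
  }
  n_all <- choose(nc, 2) * ncol(dos)
  n_w <- sum(vapply(unique(dm2), function(d) choose(sum(dm2 == d), 2),
                    numeric(1))) * ncol(dos)
  1 - (pw_w / n_w) / (pw_all / n_all)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
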