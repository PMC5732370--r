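#' Spatial principal component analysis
#'
#' Eigen-analysis of the symmetric matrix
#' \deqn{H = \frac{1}{2n} X^T (L^T + L) X,}
#' where X is the n x p matrix of centred allele frequencies and L the
#' n x n spatial weight matrix. Each eigenvector v gives a principal
#' component with score z = Xv; its eigenvalue factorises into the score
#' variance times the Moran's I of the score (exactly so for
#' row-standardised L), so positive eigenvalues carry global (positively
#' autocorrelated) structure and negative eigenvalues local (negatively
#' autocorrelated) structure.
#'
#' Eigenvalues with `|lambda| <= tol * max(|lambda|)` are discarded as
#' rank-deficiency zeros (centring alone removes one dimension). The sign
#' of each eigenvector is fixed so its largest-magnitude loading is
#' positive, making permutation runs and reruns comparable.
#'
#' @param X a `centred_freq` object from [centre_frequencies()], or a
#'   numeric matrix with column means zero (checked to 1e-8).
#' @param W a [spatial_weights] object, or a raw square matrix used
#'   directly as L.
#' @param tol relative threshold for discarding null eigenvalues.
#'
#' @return An object of class `spca_result` with fields `lambda_pos`
#'   (decreasing), `lambda_neg` (negative values, decreasing `|lambda|`),
#'   `V_pos`, `V_neg` (unit-norm loadings, one column per axis),
#'   `scores_pos`, `scores_neg` (z = Xv), `var_moran` (per-axis data frame
#'   with columns axis, sign, lambda, variance, moran), `n`, `p`, `rank`.
#' @export
#' @examples
#' set.seed(1)
#' X <- centre_frequencies(matrix(runif(60), 12, 5))
#' W <- knn_graph(matrix(runif(24), 12, 2), k = 3)
#' res <- spca(X, W)
#' res$var_moran
spca <- function(X, W, tol = 1e-9) {
  Xm <- if (inherits(X, "centred_freq")) X$X else as.matrix(X)
  if (max(abs(colMeans(Xm))) > 1e-8)
    stop_validation("X is not column-centred (use centre_frequencies)")
  L <- weights_matrix(W)
  n <- nrow(Xm)
  if (nrow(L) != n)
    stop_validation("dimension mismatch: X has ", n, " rows, L is ",
                    nrow(L), " x ", ncol(L))
  M2 <- t(L) + L
  H <- crossprod(Xm, M2 %*% Xm) / (2 * n)
  eg <- eigen(H, symmetric = TRUE)
  lam <- eg$values
  thr <- tol * max(abs(lam))
  keep <- abs(lam) > thr
  lam <- lam[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(Xm)
  pos <- lam > 0
  # eigen() returns decreasing values: positives already decreasing,
  # negatives must be reversed to get decreasing |lambda|
  ord_neg <- rev(which(!pos))
  V_pos <- V[, which(pos), drop = FALSE]
  V_neg <- V[, ord_neg, drop = FALSE]
  lambda_pos <- lam[pos]
  lambda_neg <- lam[ord_neg]
  scores_pos <- Xm %*% V_pos
  scores_neg <- Xm %*% V_neg
  style <- weights_style(W)
  axis_stats <- function(Z, lambda) {
    if (!length(lambda))
      return(data.frame(lambda = numeric(), variance = numeric(),
                        moran = numeric()))
    v <- colSums(Z^2) / n
    mi <- apply(Z, 2, moran_quadform, M2 = M2, style = style, L = L, n = n)
    data.frame(lambda = lambda, variance = v, moran = mi)
  }
  vm <- rbind(
    cbind(sign = rep("+", length(lambda_pos)),
          axis_stats(scores_pos, lambda_pos)),
    cbind(sign = rep("-", length(lambda_neg)),
          axis_stats(scores_neg, lambda_neg)))
  vm <- cbind(axis = seq_len(nrow(vm)), vm)
  rownames(vm) <- NULL
  structure(
    list(lambda_pos = lambda_pos, lambda_neg = lambda_neg,
         V_pos = V_pos, V_neg = V_neg,
         scores_pos = scores_pos, scores_neg = scores_neg,
         var_moran = vm, n = n, p = ncol(Xm), rank = length(lam),
         tol = tol),
    class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat(sprintf(
    "spca_result: n=%d units, p=%d columns, rank %d (%d positive, %d negative eigenvalues)\n",
    x$n, x$p, x$rank, length(x$lambda_pos), length(x$lambda_neg)))
  if (length(x$lambda_pos))
    cat("  leading lambda+:",
        paste(signif(utils::head(x$lambda_pos, 4L), 4), collapse = ", "), "\n")
  if (length(x$lambda_neg))
    cat("  leading lambda-:",
        paste(signif(utils::head(x$lambda_neg, 4L), 4), collapse = ", "), "\n")
  invisible(x)
}

# shared quadratic-form kernel; z assumed centred
moran_quadform <- function(z, M2, style, L, n) {
  num <- drop(crossprod(z, M2 %*% z)) / 2
  den <- sum(z^2)
  if (style == "binary") (n / sum(L)) * num / den else num / den
}

#' Moran's I spatial autocorrelation of a vector
#'
#' For row-standardised weights returns
#' \eqn{z^T ((L + L^T)/2) z / z^T z} with z centred internally; for binary
#' weights the classical \eqn{(n/S_0)} normalisation with \eqn{S_0} the
#' total weight. Positive values indicate smooth spatial variation,
#' negative values alternation between neighbours.
#'
#' @param z numeric vector, one value per unit (not all equal).
#' @param W a [spatial_weights] object or square weight matrix.
#' @return Scalar Moran's I.
#' @export
moran_index <- function(z, W) {
  L <- weights_matrix(W)
  if (length(z) != nrow(L))
    stop_validation("z length does not match the weight matrix")
  z <- z - mean(z)
  if (all(abs(z) < .Machine$double.eps * 100))
    stop_validation("Moran's I is undefined for a constant vector")
  moran_quadform(z, M2 = t(L) + L, style = weights_style(W), L = L,
                 n = length(z))
}

#' Write sPCA tables to TSV files
#'
#' Writes `<prefix>_eigenvalues.tsv` (axis, sign, lambda, variance,
#' moran), `<prefix>_scores.tsv` and `<prefix>_loadings.tsv`.
#'
#' @param res an `spca_result`.
#' @param prefix output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_spca_tables <- function(res, prefix) {
  stopifnot(inherits(res, "spca_result"))
  paths <- paste0(prefix, c("_eigenvalues.tsv", "_scores.tsv",
                            "_loadings.tsv"))
  utils::write.table(res$var_moran, paths[1L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- cbind(res$scores_pos, res$scores_neg)
  ld <- cbind(res$V_pos, res$V_neg)
  ax <- res$var_moran$axis
  colnames(sc) <- colnames(ld) <- paste0("axis", ax, res$var_moran$sign)
  utils::write.table(data.frame(unit = rownames(sc) %||% seq_len(nrow(sc)),
                                sc, check.names = FALSE),
                     paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(column = rownames(ld) %||% seq_len(nrow(ld)),
                                ld, check.names = FALSE),
                     paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
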