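#' Define a simulation scenario
#'
#' One scenario fully seeds one replicate of the benchmarking design:
#' migration model, migration rate, sample layout, number of loci and
#' spatial-pattern type. Defaults mirror the benchmark conditions: 4
#' demes of 25 diploid individuals for island (IS) and stepping-stone
#' (SS) migration, a 100-individual lattice population for isolation by
#' distance (IBD), 200 unlinked biallelic SNPs and migration rates in
#' \{0.005, 0.01, 0.1\}.
#'
#' `migration_rate` is the total per-gene-copy emigration probability per
#' generation, split equally over the receiving demes (IS: all other
#' demes; SS: chain neighbours at rate m/2 per adjacent edge; IBD:
#' lattice neighbours at rate m/4 per edge).
#'
#' @param model `"IS"`, `"SS"` or `"IBD"`.
#' @param migration_rate per-generation emigration probability, in (0, 1).
#' @param n_demes number of demes (IS/SS; ignored for IBD).
#' @param per_deme diploid individuals sampled per deme (IS/SS).
#' @param n_loci number of unlinked biallelic SNPs.
#' @param N diploid effective size of each deme. Default (`NULL`) is
#'   model-specific: 4000 for IS/SS, chosen so the island-model
#'   differentiation `F_ST = 1/(1 + 4Nm(d/(d-1))^2)` spans the benchmark
#'   regimes across the three study rates (strong structure at m = 0.005,
#'   moderate at 0.01, effectively panmictic at 0.1); 100 for the IBD
#'   lattice, where neighbourhood differentiation stays strong at every
#'   study rate.
#' @param pattern spatial pattern of the coordinates: `"random"` (no
#'   structure), `"global"` (spatially segregated patches / gradient /
#'   lattice), `"local"` (genetic-distance quartile neighbour graph).
#' @param lattice_side side of the IBD deme lattice (1 diploid sampled
#'   per deme, `lattice_side^2` individuals in total).
#' @param grid_scale side length of the coordinate square.
#' @param ss_ring connect the SS chain into a ring.
#' @param seed integer seed for the replicate.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(model = c("SS", "IS", "IBD"),
                         migration_rate = 0.005,
                         n_demes = 4L, per_deme = 25L, n_loci = 200L,
                         N = NULL, pattern = c("random", "global", "local"),
                         lattice_side = 10L, grid_scale = 1,
                         ss_ring = FALSE, seed = NULL) {
  model <- match.arg(model)
  pattern <- match.arg(pattern)
  N <- N %||% if (model == "IBD") 100 else 4000
  if (migration_rate <= 0 || migration_rate >= 1)
    stop_validation("migration_rate must be in (0, 1)")
  if (n_loci < 1L || n_demes < 2L || per_deme < 1L || N < 1)
    stop_validation("invalid scenario dimensions")
  structure(
    list(model = model, migration_rate = migration_rate,
         n_demes = as.integer(n_demes), per_deme = as.integer(per_deme),
         n_loci = as.integer(n_loci), N = N, pattern = pattern,
         lattice_side = as.integer(lattice_side),
         grid_scale = grid_scale, ss_ring = ss_ring, seed = seed),
    class = "sim_scenario")
}

# backward migration rate matrix between demes, total emigration = m
# (chain endpoints / lattice borders have fewer edges, hence less)
migration_matrix <- function(s) {
  m <- s$migration_rate
  if (s$model == "IS") {
    d <- s$n_demes
    M <- matrix(m / (d - 1), d, d)
    diag(M) <- 0
    return(M)
  }
  if (s$model == "SS") {
    d <- s$n_demes
    M <- matrix(0, d, d)
    for (i in seq_len(d - 1L)) M[i, i + 1L] <- M[i + 1L, i] <- m / 2
    if (s$ss_ring) M[1L, d] <- M[d, 1L] <- m / 2
    return(M)
  }
  # IBD: von Neumann neighbours on a lattice_side^2 lattice
  side <- s$lattice_side
  d <- side * side
  M <- matrix(0, d, d)
  idx <- function(r, c) (r - 1L) * side + c
  for (r in seq_len(side)) for (c in seq_len(side)) {
    if (r < side) M[idx(r, c), idx(r + 1L, c)] <- M[idx(r + 1L, c), idx(r, c)] <- m / 4
    if (c < side) M[idx(r, c), idx(r, c + 1L)] <- M[idx(r, c + 1L), idx(r, c)] <- m / 4
  }
  M
}

# deme index (1-based) of each sampled diploid individual
sample_demes <- function(s) {
  if (s$model == "IBD") seq_len(s$lattice_side^2)
  else rep(seq_len(s$n_demes), each = s$per_deme)
}

#' Simulate unlinked biallelic SNP genotypes
#'
#' Per locus, an independent structured-coalescent genealogy of the
#' sampled gene copies is simulated under the scenario's migration model,
#' and one mutation is placed uniformly at random on the branches
#' (infinite sites, conditioned segregating), yielding a biallelic SNP.
#' Diploid dosages pair consecutive gene copies within individuals.
#'
#' @param s a [sim_scenario()].
#' @return A [genotype_table()] of 0/1/2 dosages with the deme assignment
#'   in attribute `"deme"`.
#' @export
simulate_snps <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  if (!is.null(s$seed)) set.seed(s$seed)
  demes <- sample_demes(s)
  n <- length(demes)
  copy_deme <- rep(demes, each = 2L) - 1L
  al <- coalescent_snps(as.integer(copy_deme), migration_matrix(s),
                        twoN = 2 * s$N, n_loci = s$n_loci)
  dos <- al[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    al[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  g <- genotype_table(dos,
                      unit_ids = sprintf("ind_%03d", seq_len(n)),
                      locus_ids = sprintf("L%03d", seq_len(s$n_loci)))
  attr(g, "deme") <- demes
  g
}

#' Spatial pattern generators
#'
#' `random_coordinates` draws n points uniformly on a square (no spatial
#' structure). `patched_coordinates` partitions the square into one
#' contiguous block per deme and places each deme's individuals uniformly
#' within its own block (spatially segregated patches); with
#' `gradient = TRUE` the blocks are laid out along the x axis, giving a
#' one-dimensional gradient. `lattice_coordinates` places the IBD sample
#' at its deme's lattice position plus a small uniform jitter.
#'
#' @param n number of points.
#' @param grid_scale side length of the square.
#' @param seed optional seed.
#' @return An n x 2 coordinate matrix with unit rownames.
#' @export
random_coordinates <- function(n, grid_scale = 1, seed = NULL) {
  if (n < 3L) stop_validation("need n >= 3 coordinates")
  if (!is.null(seed)) set.seed(seed)
  xy <- matrix(stats::runif(2L * n, 0, grid_scale), n, 2L,
               dimnames = list(sprintf("ind_%03d", seq_len(n)), c("x", "y")))
  xy
}

#' @rdname random_coordinates
#' @param n_demes,per_deme deme layout.
#' @param gradient lay blocks along one axis instead of a block grid.
#' @export
patched_coordinates <- function(n_demes, per_deme, grid_scale = 1,
                                gradient = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- as.integer(n_demes)
  if (gradient) {
    bx <- seq_len(D); by <- rep(1L, D); nbx <- D; nby <- 1L
  } else {
    nbx <- ceiling(sqrt(D)); nby <- ceiling(D / nbx)
    bx <- ((seq_len(D) - 1L) %% nbx) + 1L
    by <- ((seq_len(D) - 1L) %/% nbx) + 1L
  }
  xs <- grid_scale / nbx; ys <- grid_scale / nby
  xy <- do.call(rbind, lapply(seq_len(D), function(d) {
    cbind(stats::runif(per_deme, (bx[d] - 1) * xs, bx[d] * xs),
          stats::runif(per_deme, (by[d] - 1) * ys, by[d] * ys))
  }))
  dimnames(xy) <- list(sprintf("ind_%03d", seq_len(D * per_deme)),
                       c("x", "y"))
  xy
}

#' @rdname random_coordinates
#' @param lattice_side side of the deme lattice.
#' @export
lattice_coordinates <- function(lattice_side, grid_scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  side <- as.integer(lattice_side)
  step <- grid_scale / side
  rc <- expand.grid(c = seq_len(side), r = seq_len(side))
  xy <- cbind((rc$c - 0.5) * step, (rc$r - 0.5) * step) +
    matrix(stats::runif(2L * side^2, -step / 4, step / 4), side^2, 2L)
  dimnames(xy) <- list(sprintf("ind_%03d", seq_len(side^2)), c("x", "y"))
  xy
}

#' Local-pattern neighbour graph from genotypes
#'
#' Emulates a worst-case local structure: the most genetically distinct
#' units (pairs in the upper quartile of pairwise Euclidean genetic
#' distances on centred frequencies) are declared neighbours, all others
#' non-neighbours. Units left without any neighbour are dropped with a
#' warning. A one-dimensional layout (first genetic principal component,
#' second coordinate zero) is returned for reporting.
#'
#' @param g a [genotype_table()] or `centred_freq` with at least 8 units.
#' @return List of class `local_pattern`: `weights` (row-standardised
#'   [spatial_weights]), `coords` (retained units x 2), `retained`
#'   (logical per original unit).
#' @export
local_pattern_graph <- function(g) {
  Xc <- centre_frequencies(g)
  X <- Xc$X
  n <- nrow(X)
  if (n < 8L) stop_validation("local pattern graph needs at least 8 units")
  D <- as.matrix(stats::dist(X))
  q <- stats::quantile(D[upper.tri(D)], 0.75)
  A <- 1 * (D >= q)
  diag(A) <- 0
  retained <- rowSums(A) > 0
  if (!all(retained)) {
    warning(sprintf("dropping %d unit(s) isolated in the quartile graph",
                    sum(!retained)))
    A <- A[retained, retained, drop = FALSE]
  }
  W <- new_spatial_weights(row_standardise(A), "row_standardised",
                           list(method = "genetic_quartile", q = unname(q)))
  sv <- svd(X, nu = 1L, nv = 0L)
  pc1 <- sv$u[, 1L] * sv$d[1L]
  coords <- cbind(x = pc1[retained], y = 0)
  rownames(coords) <- rownames(X)[retained]
  structure(list(weights = W, coords = coords, retained = retained),
            class = "local_pattern")
}

#' Simulate a complete benchmark dataset
#'
#' Runs the genotype simulator, then builds the coordinates and the
#' connection network implied by the scenario's spatial pattern:
#' `"random"` draws coordinates independently of the genotypes (true
#' negative), `"global"` spatially segregates the demes (patches for IS,
#' a gradient for SS, the lattice itself for IBD), `"local"` applies a
#' genetic-distance quartile graph built from an *independent* replicate
#' simulated under the stepping-stone model at m = 0.005 (the benchmark's
#' source of local-pattern graphs); building the graph from a different
#' dataset than the one analysed keeps the local test non-circular.
#' Random and global patterns use a k-nearest-neighbour network with
#' `k = max(1, round(sqrt(n)))` unless `k` is given.
#'
#' @param s a [sim_scenario()].
#' @param k neighbours for the KNN network (default `round(sqrt(n))`).
#' @return List of class `sim_dataset`: `genotypes`, `coords`, `weights`,
#'   `truth` (pattern label), `scenario`.
#' @export
simulate_dataset <- function(s, k = NULL) {
  stopifnot(inherits(s, "sim_scenario"))
  if (!is.null(s$seed)) set.seed(s$seed)
  g <- simulate_snps(sim_scenario_no_seed(s))
  n <- nrow(g$dosages)
  if (s$pattern == "local") {
    src <- sim_scenario(model = "SS", migration_rate = 0.005,
                        n_demes = s$n_demes, per_deme = s$per_deme,
                        n_loci = s$n_loci, N = s$N,
                        lattice_side = s$lattice_side)
    if (s$model == "IBD")  # keep the unit count aligned with the focal sample
      src$per_deme <- as.integer(ceiling(s$lattice_side^2 / src$n_demes))
    g_src <- simulate_snps(src)  # continues the replicate RNG stream
    if (nrow(g_src$dosages) != n)
      g_src <- subset_genotypes(g_src, seq_len(n))
    lp <- local_pattern_graph(g_src)
    g <- subset_genotypes(g, lp$retained)
    coords <- lp$coords
    W <- lp$weights
  } else {
    coords <- switch(
      s$pattern,
      random = random_coordinates(n, s$grid_scale),
      global = if (s$model == "IBD")
        lattice_coordinates(s$lattice_side, s$grid_scale)
      else patched_coordinates(s$n_demes, s$per_deme, s$grid_scale,
                               gradient = (s$model == "SS")))
    k <- k %||% max(1L, round(sqrt(nrow(coords))))
    W <- knn_graph(coords, k = k)
  }
  structure(
    list(genotypes = g, coords = coords, weights = W,
         truth = list(structure = s$pattern != "random", type = s$pattern),
         scenario = s),
    class = "sim_dataset")
}

# scenario copy whose seed is NULL (the caller controls the RNG stream)
sim_scenario_no_seed <- function(s) { s$seed <- NULL; s }

subset_genotypes <- function(g, keep) {
  out <- genotype_table(g$dosages[keep, , drop = FALSE], type = g$type)
  dm <- attr(g, "deme")
  if (!is.null(dm)) attr(out, "deme") <- dm[keep]
  out
}

# deterministic per-replicate seed: stable under extending n_reps
child_seed <- function(seed, cell, rep) {
  as.integer((as.double(seed) * 48271 + cell * 100003 + rep * 7919) %%
               2147483629)
}

#' Type-I error and power study
#'
#' For every cell of the scenario grid (model x rate x pattern x loci),
#' simulates `n_reps` independent datasets, runs [spca_randtest()] on
#' each, and tabulates the proportion of replicates with `p <= alpha`
#' separately for the global (f+) and local (f-) statistics. Under
#' `pattern = "random"` this proportion estimates the type-I error;
#' under global/local patterns it estimates power.
#'
#' @param models,rates,patterns,n_loci vectors defining the grid.
#' @param n_reps replicates per cell (>= 20).
#' @param B permutations per test (>= 99).
#' @param alphas significance thresholds tabulated.
#' @param k KNN neighbours (default `round(sqrt(n))`).
#' @param seed master seed; replicate seeds are derived deterministically
#'   from it, so extending `n_reps` reuses the same leading replicates.
#' @return Long-format data frame with columns model, rate, pattern,
#'   loci, alpha, side, proportion_significant, n_reps, B, seed. The
#'   per-rank frequency of cascade-significant eigenvalues (at
#'   `alphas[1]`) is attached as attribute `"rank_hist"`, and the raw
#'   per-replicate p-values as attribute `"replicates"`.
#' @export
power_study <- function(models = "SS", rates = 0.005, patterns = "random",
                        n_reps = 100L, B = 199L, alphas = c(0.05, 0.01),
                        n_loci = 200L, k = NULL, seed = 1L) {
  if (n_reps < 20L) stop_validation("n_reps must be >= 20")
  if (B < 99L) stop_validation("B must be >= 99")
  grid <- expand.grid(model = models, rate = rates, pattern = patterns,
                      loci = n_loci, stringsAsFactors = FALSE)
  reps <- list()
  hist_pos <- integer(0)
  hist_neg <- integer(0)
  for (cell in seq_len(nrow(grid))) {
    gr <- grid[cell, ]
    for (rp in seq_len(n_reps)) {
      cs <- child_seed(seed, cell, rp)
      s <- sim_scenario(model = gr$model, migration_rate = gr$rate,
                        n_loci = gr$loci, pattern = gr$pattern, seed = cs)
      ds <- simulate_dataset(s, k = k)
      rt <- spca_randtest(centre_frequencies(ds$genotypes), ds$weights,
                          B = B, alpha = alphas[1L], seed = cs + 1L)
      reps[[length(reps) + 1L]] <- data.frame(
        cell = cell, model = gr$model, rate = gr$rate,
        pattern = gr$pattern, loci = gr$loci, rep = rp,
        p_global = rt$p_global, p_local = rt$p_local,
        n_sig_pos = rt$n_sig_pos, n_sig_neg = rt$n_sig_neg)
      if (rt$n_sig_pos > 0L)
        hist_pos <- c(hist_pos, seq_len(rt$n_sig_pos))
      if (rt$n_sig_neg > 0L)
        hist_neg <- c(hist_neg, seq_len(rt$n_sig_neg))
    }
  }
  repdf <- do.call(rbind, reps)
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    sub <- repdf[repdf$cell == cell, ]
    gr <- grid[cell, ]
    for (a in alphas) for (side in c("global", "local")) {
      p <- if (side == "global") sub$p_global else sub$p_local
      rows[[length(rows) + 1L]] <- data.frame(
        model = gr$model, rate = gr$rate, pattern = gr$pattern,
        loci = gr$loci, alpha = a, side = side,
        proportion_significant = mean(p <= a),
        n_reps = n_reps, B = B, seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rank_hist") <- list(
    positive = if (length(hist_pos)) table(hist_pos) else table(integer()),
    negative = if (length(hist_neg)) table(hist_neg) else table(integer()))
  attr(out, "replicates") <- repdf
  out
}
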