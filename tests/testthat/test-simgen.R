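test_that("scenario defaults mirror the benchmark design and validate inputs", {
  s <- sim_scenario("SS")
  expect_equal(s$n_demes, 4L)
  expect_equal(s$per_deme, 25L)
  expect_equal(s$n_loci, 200L)
  expect_error(sim_scenario("SS", migration_rate = 0), "migration_rate")
  expect_error(sim_scenario("SS", migration_rate = 1.2), "migration_rate")

  # migration matrices: symmetric, zero diagonal, expected topology
  Mis <- spcatest:::migration_matrix(sim_scenario("IS", 0.06))
  expect_equal(Mis, t(Mis))
  expect_equal(unname(Mis[1, 2]), 0.02)  # m/(d-1)
  Mss <- spcatest:::migration_matrix(sim_scenario("SS", 0.06))
  expect_equal(unname(Mss[1, 2]), 0.03)  # m/2 per chain edge
  expect_equal(unname(Mss[1, 3]), 0)
  Mibd <- spcatest:::migration_matrix(sim_scenario("IBD", 0.08, lattice_side = 3))
  expect_equal(sum(Mibd[5, ] > 0), 4L)  # centre deme has 4 neighbours
})

test_that("SNP simulation is seeded, diploid and always polymorphic", {
  s <- sim_scenario("SS", 0.01, n_loci = 30, per_deme = 5, N = 100, seed = 9)
  g1 <- simulate_snps(s)
  g2 <- simulate_snps(s)
  expect_identical(g1$dosages, g2$dosages)
  expect_equal(dim(g1$dosages), c(20L, 30L))
  expect_true(all(g1$dosages %in% 0:2))
  # conditioned-segregating: every locus polymorphic at the copy level
  copies_var <- apply(g1$dosages, 2, function(x) length(unique(x)) > 1)
  expect_true(all(copies_var))
})

test_that("high migration approaches the panmictic limit", {
  set.seed(14)
  s <- sim_scenario("IS", 0.9, n_loci = 200, N = 100)
  f <- replicate(20, fst_allpairs(simulate_snps(s)))
  expect_lt(abs(mean(f)), 0.02)
})

test_that("island-model differentiation matches the closed form", {
  set.seed(15)
  N <- 100; m <- 0.005; d <- 4
  s <- sim_scenario("IS", m, n_loci = 200, N = N)
  f <- replicate(20, fst_allpairs(simulate_snps(s)))
  expected <- 1 / (1 + 4 * (d / (d - 1))^2 * N * m)
  expect_lt(abs(mean(f) - expected), 3 * sd(f) / sqrt(length(f)))
})

test_that("differentiation decreases with deme size (sensitivity to N)", {
  set.seed(16)
  f_small <- replicate(8, fst_allpairs(simulate_snps(
    sim_scenario("IS", 0.005, n_loci = 100, N = 100))))
  f_large <- replicate(8, fst_allpairs(simulate_snps(
    sim_scenario("IS", 0.005, n_loci = 100, N = 1000))))
  expect_gt(mean(f_small), mean(f_large))
})

test_that("coordinate generators respect their geometry", {
  xy <- random_coordinates(100, grid_scale = 3, seed = 1)
  expect_true(all(xy >= 0 & xy <= 3))
  expect_false(identical(random_coordinates(10, seed = 1),
                         random_coordinates(10, seed = 2)))
  expect_identical(random_coordinates(10, seed = 1),
                   random_coordinates(10, seed = 1))

  # 4 demes x 25: each deme confined to its own quadrant
  p <- patched_coordinates(4, 25, seed = 3)
  deme <- rep(1:4, each = 25)
  quad <- paste(p[, 1] > 0.5, p[, 2] > 0.5)
  expect_equal(length(unique(tapply(quad, deme, unique))), 4L)
  # deme centroids separate farther than any within-deme spread
  cent <- apply(p, 2, tapply, deme, mean)
  cd <- min(dist(cent))
  spread <- max(tapply(seq_len(100), deme, function(i)
    max(dist(p[i, , drop = FALSE]))))
  expect_gt(cd, 0.2 * spread)

  gp <- patched_coordinates(4, 25, gradient = TRUE, seed = 4)
  cx <- tapply(gp[, 1], deme, mean)
  expect_true(all(diff(cx) > 0))

  lc <- lattice_coordinates(10, seed = 5)
  expect_equal(nrow(lc), 100L)
})

test_that("the quartile graph wires distant units and induces negative Moran", {
  # two well-separated genetic clusters: all edges run between clusters
  set.seed(21)
  freq <- c(rep(0.05, 10), rep(0.95, 10))  # divergent allele frequencies
  base <- cbind(
    t(vapply(freq, function(f) rbinom(30, 2, f), numeric(30))),
    matrix(rbinom(20 * 10, 2, 0.5), 20, 10))
  g <- genotype_table(base)
  suppressWarnings(lp <- local_pattern_graph(g))
  A <- lp$weights$L > 0
  cl <- rep(1:2, each = 10)[lp$retained]
  between <- outer(cl, cl, "!=")
  expect_false(any(A & !between))  # no within-cluster edges

  # about a quarter of all unordered pairs become edges (no distance ties;
  # dropped units are isolated, so they carry no edges)
  set.seed(22)
  suppressWarnings(lpr <- local_pattern_graph(matrix(runif(30 * 40), 30, 40)))
  expect_lt(abs(sum(lpr$weights$L > 0) / 2 / choose(30, 2) - 0.25), 0.02)

  # Moran's I of the first genetic PC on this graph is negative
  ss <- simulate_snps(sim_scenario("SS", 0.005, n_loci = 100, per_deme = 10,
                                   N = 100, seed = 23))
  suppressWarnings(lps <- local_pattern_graph(ss))
  X <- centre_frequencies(ss)$X[lps$retained, , drop = FALSE]
  pc1 <- svd(X, nu = 1)$u[, 1]
  expect_lt(moran_index(pc1, lps$weights), 0)
})

test_that("simulated datasets align genotypes, coordinates and weights", {
  for (pat in c("random", "global", "local")) {
    s <- sim_scenario("SS", 0.01, n_loci = 40, per_deme = 8, N = 100,
                      pattern = pat, seed = 30)
    suppressWarnings(ds <- simulate_dataset(s))
    expect_equal(nrow(ds$genotypes$dosages), nrow(ds$coords))
    expect_equal(nrow(ds$weights$L), nrow(ds$coords))
    expect_equal(ds$truth$structure, pat != "random")
  }
  s <- sim_scenario("IBD", 0.01, n_loci = 30, lattice_side = 5,
                    N = 50, pattern = "global", seed = 31)
  ds <- simulate_dataset(s)
  expect_equal(nrow(ds$genotypes$dosages), 25L)
})

test_that("power study tabulates cells and keeps a stable seed stream", {
  res <- suppressWarnings(
    power_study(models = "SS", rates = 0.01, patterns = "random",
                n_reps = 20, B = 99, n_loci = 20, seed = 5))
  expect_equal(nrow(res), 4L)  # 1 cell x 2 alphas x 2 sides
  expect_true(all(res$proportion_significant >= 0 &
                  res$proportion_significant <= 1))
  reps20 <- attr(res, "replicates")

  res40 <- suppressWarnings(
    power_study(models = "SS", rates = 0.01, patterns = "random",
                n_reps = 40, B = 99, n_loci = 20, seed = 5))
  reps40 <- attr(res40, "replicates")
  expect_equal(reps40$p_global[1:20], reps20$p_global)
  expect_error(power_study(n_reps = 5), "n_reps")
})

test_that("null p-values from the study pipeline are uniform", {
  res <- suppressWarnings(
    power_study(models = "SS", rates = 0.01, patterns = "random",
                n_reps = 120, B = 99, n_loci = 40, seed = 77))
  reps <- attr(res, "replicates")
  ks <- suppressWarnings(stats::ks.test(reps$p_global, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("more loci never cost power at a fixed scenario", {
  pow <- function(loci) {
    res <- suppressWarnings(
      power_study(models = "SS", rates = 0.01, patterns = "global",
                  n_reps = 25, B = 99, alphas = 0.05, n_loci = loci,
                  seed = 41))
    res$proportion_significant[res$side == "global"]
  }
  p200 <- pow(200)
  p40 <- pow(40)
  expect_gte(p200, p40)
  expect_gt(p200, 0.5)
})
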