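test_that("windowed pi equals brute-force pairwise differences", {
  # worked example: 2 diploids (4 haplotypes), one site with 2 alt
  # carriers, 10-kb window
  gm <- toy_gm(matrix(c(1L, 1L), 1, 2), pos = 5L)
  out <- windowed_pi(gm, window = 10000)
  expect_equal(out$pi, (2 * 2 * 2 / (4 * 3)) / 10000)
  expect_equal(out$pi, oracle_pi(gm$gt, 10000))

  # 1 diploid treated as 2 haplotypes: 1 het of 10 sites, window 10
  gm2 <- toy_gm(matrix(c(1L, rep(0L, 9)), 10, 1), pos = 1:10)
  expect_equal(windowed_pi(gm2, window = 10)$pi, 0.1)

  # monomorphic window is 0
  gm3 <- toy_gm(matrix(2L, 5, 3), pos = 1:5)
  expect_equal(windowed_pi(gm3, window = 10)$pi, 0)

  # exhaustive random fixtures vs the oracle, incl. missing data
  set.seed(33)
  for (rep in 1:8) {
    n_sites <- sample(5:50, 1)
    n_strains <- sample(2:4, 1)
    gt <- matrix(sample(c(0:2, NA), n_sites * n_strains, replace = TRUE),
                 n_sites, n_strains)
    gmx <- toy_gm(gt, pos = sample(1:900, n_sites))
    expect_equal(windowed_pi(gmx, window = 1000)$pi,
                 oracle_pi(gt, 1000), tolerance = 1e-12)
  }
})

test_that("Tajima constants match independent values for n in 4..20", {
  # independent oracle: literal transcription of the 1989 definitions,
  # written against harmonic-number identities rather than loops
  harm <- function(n, p) sum((1 / seq_len(n - 1))^p)
  for (n in 4:20) {
    cc <- tajima_constants(n)
    a1 <- harm(n, 1); a2 <- harm(n, 2)
    expect_equal(cc$a1, a1)
    expect_equal(cc$a2, a2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    expect_equal(cc$e1, (b1 - 1 / a1) / a1)
    expect_equal(cc$e2, (b2 - (n + 2) / (a1 * n) + a2 / a1^2) / (a1^2 + a2))
  }
})

test_that("Tajima's D matches the hand-derived singleton value at n = 4", {
  # 2 diploids, one singleton in the window
  gm <- toy_gm(matrix(c(1L, 0L), 1, 2), pos = 3L)
  d <- windowed_tajimas_d(gm, window = 10000)
  expect_equal(d$n_haplotypes, 4)
  expect_equal(d$tajima_d, -0.612, tolerance = 1e-3)

  # no segregating sites: undefined, not zero
  gm0 <- toy_gm(matrix(0L, 3, 2), pos = 1:3)
  expect_true(all(is.na(windowed_tajimas_d(gm0, window = 100)$tajima_d)))

  # a doubleton-only spectrum at n = 4 pushes D positive
  gm2 <- toy_gm(matrix(c(1L, 1L), 1, 2), pos = 3L)
  expect_gt(windowed_tajimas_d(gm2, window = 100)$tajima_d, 0)
})

test_that("strain heterozygosity is het calls over called variants", {
  gt <- cbind(a = c(1L, 1L, 1L, rep(0L, 7L)),
              b = rep(c(0L, 2L), 5),
              c = rep(NA_integer_, 10))
  h <- strain_heterozygosity(toy_gm(gt))
  expect_equal(unname(h["a"]), 0.3)
  expect_equal(unname(h["b"]), 0.0)
  expect_true(is.na(h["c"]))

  # heterozygous introgressions push the ratio up relative to homozygous
  cfg <- tiny_config(het_fraction = 1)
  sim_het <- simulate_dataset(cfg)
  cfg_hom <- tiny_config(het_fraction = 0)
  sim_hom <- simulate_dataset(cfg_hom)
  carriers <- function(sim) unique(sim$truth$strain[sim$truth$state != "absent"])
  h_het <- mean(strain_heterozygosity(sim_het$focal_gm)[carriers(sim_het)])
  h_hom <- mean(strain_heterozygosity(sim_hom$focal_gm)[carriers(sim_hom)])
  expect_gt(h_het, h_hom)
})

test_that("IBS matrix matches hand-counted allele sharing", {
  gt <- cbind(a = c(0L, 1L, 2L, 0L),
              b = c(0L, 1L, 2L, 0L),
              c = c(2L, 1L, 0L, NA))
  ibs <- ibs_matrix(toy_gm(gt))
  expect_equal(ibs["a", "b"], 1.0)
  # a vs c over co-called sites 1..3: 0, 1, 0
  expect_equal(ibs["a", "c"], 1 / 3)
  expect_true(all(diag(ibs) == 1))
  expect_equal(ibs, t(ibs))

  # opposite homozygotes everywhere
  gt2 <- cbind(a = rep(0L, 4), b = rep(2L, 4))
  expect_equal(ibs_matrix(toy_gm(gt2))["a", "b"], 0.0)

  # pair with no co-called sites is NA
  gt3 <- cbind(a = c(0L, NA), b = c(NA, 0L), c = c(0L, 0L))
  expect_true(is.na(ibs_matrix(toy_gm(gt3))["a", "b"]))
})

test_that("weighted Fst matches the component formulas and end points", {
  # two populations fixed for alternative alleles
  gt <- cbind(p1a = 0L, p1b = 0L, p1c = 0L, p2a = 2L, p2b = 2L, p2c = 2L)
  gt <- matrix(rep(gt, 5), 5, 6, byrow = TRUE,
               dimnames = list(NULL, colnames(gt)))
  pops <- stats::setNames(rep(c("P1", "P2"), each = 3), colnames(gt))
  expect_equal(weighted_fst(toy_gm(gt), pops)$fst, 1.0)

  # single site, p1 = 0.5 (10 diploids: 5 hom alt, 5 hom ref),
  # p2 = 0 (10 diploids): independent transcription of the a/b/c formulas
  gt1 <- matrix(c(rep(2L, 5), rep(0L, 5), rep(0L, 10)), 1, 20)
  colnames(gt1) <- paste0("s", 1:20)
  pops1 <- stats::setNames(rep(c("P1", "P2"), each = 10), colnames(gt1))
  got <- weighted_fst(toy_gm(gt1), pops1)
  r <- 2; ni <- c(10, 10); pi_ <- c(0.5, 0); hi <- c(0, 0)
  nbar <- 10; nc <- (20 - 200 / 20) / 1
  pbar <- sum(ni * pi_) / 20
  s2 <- sum(ni * (pi_ - pbar)^2) / nbar
  hbar <- 0
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - hbar * 19 / 40)
  expect_equal(got$fst, a / (a + b + hbar / 2))

  # identical allele frequencies under panmixia: near zero
  set.seed(12)
  p <- stats::runif(600, 0.1, 0.9)
  gtp <- matrix(stats::rbinom(600 * 20, 2, p), 600, 20)
  colnames(gtp) <- paste0("s", 1:20)
  popsp <- stats::setNames(rep(c("P1", "P2"), each = 10), colnames(gtp))
  expect_lt(abs(weighted_fst(toy_gm(gtp, pos = 1:600), popsp)$fst), 0.05)

  # monomorphic input: NA
  gtm <- matrix(0L, 4, 6, dimnames = list(NULL, names(pops)))
  expect_true(is.na(weighted_fst(toy_gm(gtm), pops)$fst))
})

test_that("the Spearman Mantel test attains its floor and its direction", {
  set.seed(5)
  x <- matrix(stats::runif(100), 10)
  d1 <- as.matrix(stats::dist(x))
  # monotone transform: perfect rank concordance
  d2 <- sqrt(d1)
  m <- mantel_spearman(d1, d2, n_perm = 9999, seed = 2)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1e-4)  # 1 / (9999 + 1)

  # reversed ranks: r = -1 and a one-sided p near 1
  d3 <- max(d1) - d1; diag(d3) <- 0
  m2 <- mantel_spearman(d1, d3, n_perm = 999, seed = 2)
  expect_equal(m2$r, -1)
  expect_gt(m2$p, 0.9)

  expect_error(mantel_spearman(d1, matrix(1, 10, 10) - diag(10) * 0, 99, 1),
               "constant")
})

test_that("Mantel r and p agree with the independent vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  x <- matrix(stats::runif(48), 12)
  g <- matrix(stats::runif(24), 12)
  d1 <- as.matrix(stats::dist(x))
  d2 <- as.matrix(stats::dist(g + 0.5 * x[, 1:2]))
  ours <- mantel_spearman(d1, d2, n_perm = 9999, seed = 7)
  ref <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       method = "spearman", permutations = 9999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.02)
})

test_that("classical MDS reproduces realizable geometry", {
  # 3 collinear points: the 1-D embedding reproduces pairwise distances
  d <- as.matrix(stats::dist(c(0, 3, 7)))
  emb <- mds_embedding(d, n_components = 1)
  expect_equal(as.matrix(stats::dist(emb)), d, ignore_attr = TRUE,
               tolerance = 1e-9)

  # two tight clusters separate on component 1
  set.seed(4)
  pts <- rbind(matrix(stats::rnorm(20, 0, 0.1), 10),
               matrix(stats::rnorm(20, 5, 0.1), 10))
  dd <- as.matrix(stats::dist(pts))
  emb2 <- mds_embedding(dd, 2)
  gap <- abs(mean(emb2[1:10, 1]) - mean(emb2[11:20, 1]))
  spread <- max(stats::sd(emb2[1:10, 1]), stats::sd(emb2[11:20, 1]))
  expect_gt(gap, 10 * spread)

  # all-zero distances embed at the origin
  expect_true(all(mds_embedding(matrix(0, 4, 4), 2) == 0))
  expect_error(mds_embedding(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("haversine distances match closed-form references", {
  co <- tibble::tibble(strain = c("a", "b", "c", "d"),
                       lon = c(0, 180, 0, 1), lat = c(0, 0, 0, 0))
  d <- geographic_distance(co)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-3)        # antipodal
  expect_equal(d["c", "d"], 2 * pi * 6371 / 360, tolerance = 1e-3)  # 1 deg
  expect_error(geographic_distance(
    tibble::tibble(strain = "x", lon = 0, lat = 91)), "lat")
})
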