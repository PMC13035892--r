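window_index <- function(pos, window) (pos - 1L) %/% window

#' Windowed nucleotide diversity (pi)
#'
#' Per non-overlapping window (fixed width, anchored at position 0 of each
#' chromosome), pi is the site-frequency form of the average pairwise
#' difference: for each site, `2 j (k - j) / (k (k - 1))` where `k` is the
#' number of called haplotypes (2 per diploid) and `j` the alternate-allele
#' count, summed over sites and divided by the window width. Missing
#' genotypes are excluded per site.
#'
#' @param gm A [genotype_matrix()].
#' @param window Window width in bp.
#' @return Tibble with `chrom`, `start` (0-based), `end`, `n_sites`, `S`
#'   (segregating sites), `pi` per window.
#' @export
windowed_pi <- function(gm, window = 10000) {
  per_site <- site_freqs(gm)
  agg <- window_table(gm, per_site, window)
  agg$pi <- agg$pi_sum / window
  agg[, c("chrom", "start", "end", "n_sites", "S", "pi")]
}

site_freqs <- function(gm) {
  called <- rowSums(!is.na(gm$gt))
  k <- 2 * called
  j <- rowSums(gm$gt, na.rm = TRUE)
  contrib <- ifelse(k >= 2, 2 * j * (k - j) / (k * pmax(k - 1, 1)), 0)
  tibble::tibble(chrom = gm$sites$chrom, pos = gm$sites$pos,
                 k = k, j = j, pi_site = contrib,
                 segregating = j > 0 & j < k)
}

window_table <- function(gm, per_site, window) {
  w <- window_index(per_site$pos, window)
  key <- paste(per_site$chrom, w)
  parts <- split(seq_len(nrow(per_site)), key)
  out <- lapply(parts, function(ii) {
    x <- per_site[ii, ]
    tibble::tibble(chrom = x$chrom[1],
                   start = window_index(x$pos[1], window) * window,
                   n_sites = nrow(x), S = sum(x$segregating),
                   pi_sum = sum(x$pi_site),
                   mean_k = mean(x$k[x$segregating]))
  })
  out <- do.call(rbind, out)
  out$end <- out$start + window
  out[order(out$chrom, out$start),
      c("chrom", "start", "end", "n_sites", "S", "pi_sum", "mean_k")]
}

#' Tajima's D constants for a sample of n haplotypes
#'
#' The standard normalization constants (a1, a2, b1, b2, c1, c2, e1, e2)
#' of the D statistic.
#'
#' @param n Number of haplotypes (>= 2).
#' @return Named list of constants.
#' @export
tajima_constants <- function(n) {
  abort_if(n < 2, "tajima_constants: need n >= 2")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Windowed Tajima's D
#'
#' Per window, `D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S - 1))` where
#' `pi_hat` is the summed average pairwise difference over the window's
#' sites and `S` the number of segregating sites; `D` is undefined (`NA`)
#' when `S = 0`. The haplotype count `n` per window is the rounded mean
#' number of called haplotypes over segregating sites.
#'
#' @param gm A [genotype_matrix()].
#' @param window Window width in bp.
#' @return Tibble with window coordinates, `S`, `n_haplotypes`,
#'   `tajima_d`.
#' @export
windowed_tajimas_d <- function(gm, window = 10000) {
  per_site <- site_freqs(gm)
  agg <- window_table(gm, per_site, window)
  d <- rep(NA_real_, nrow(agg))
  for (i in seq_len(nrow(agg))) {
    S <- agg$S[i]
    if (S == 0) next
    n <- round(agg$mean_k[i])
    if (n < 2) next
    cc <- tajima_constants(n)
    denom <- sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
    if (denom == 0) next
    d[i] <- (agg$pi_sum[i] - S / cc$a1) / denom
  }
  tibble::tibble(chrom = agg$chrom, start = agg$start, end = agg$end,
                 S = agg$S, n_haplotypes = round(agg$mean_k),
                 tajima_d = d)
}

#' Per-strain heterozygosity ratio
#'
#' Number of heterozygous variant calls divided by the number of called
#' variants, per strain; `NA` when a strain has no called variants.
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector.
#' @export
strain_heterozygosity <- function(gm) {
  called <- colSums(!is.na(gm$gt))
  het <- colSums(gm$gt == 1L, na.rm = TRUE)
  ifelse(called > 0, het / called, NA_real_)
}

#' Pairwise identity-by-state matrix
#'
#' Per strain pair, the mean over co-called sites of the shared-allele
#' fraction `1 - |dosage_a - dosage_b| / 2`; diagonal 1. The complementary
#' allele-sharing distance is `1 - IBS`.
#'
#' @param gm A [genotype_matrix()].
#' @return Symmetric matrix; entries are `NA` for pairs with no co-called
#'   sites.
#' @export
ibs_matrix <- function(gm) {
  abort_if(length(gm$strains) < 2, "ibs_matrix: need >= 2 strains")
  G <- gm$gt
  I0 <- (!is.na(G) & G == 0L) * 1
  I1 <- (!is.na(G) & G == 1L) * 1
  I2 <- (!is.na(G) & G == 2L) * 1
  A <- (!is.na(G)) * 1
  N <- crossprod(A)
  S <- crossprod(I0, I1) + crossprod(I1, I0) +
    crossprod(I1, I2) + crossprod(I2, I1) +
    2 * (crossprod(I0, I2) + crossprod(I2, I0))
  ibs <- 1 - (S / 2) / N
  ibs[N == 0] <- NA_real_
  diag(ibs) <- 1
  dimnames(ibs) <- list(gm$strains, gm$strains)
  ibs
}

#' Weighted Weir-Cockerham Fst
#'
#' The ratio-of-sums ("weighted") estimator: per biallelic site the
#' variance components a (between populations), b (between individuals
#' within populations) and c (within individuals) are computed from
#' population sample sizes, allele frequencies and observed
#' heterozygosities, then Fst = sum(a) / sum(a + b + c) over sites with
#' defined components. Slightly negative estimates are reported as-is.
#'
#' @param gm A [genotype_matrix()].
#' @param pops Named character vector or factor mapping strains to
#'   populations (>= 2 populations, >= 2 strains each).
#' @return A list with `fst`, component sums `a`, `b`, `c`, and
#'   `n_sites` used; `fst` is `NA` for monomorphic input.
#' @export
weighted_fst <- function(gm, pops) {
  pops <- pops[gm$strains]
  abort_if(any(is.na(pops)), "weighted_fst: every strain needs a population")
  pop_levels <- unique(pops)
  r <- length(pop_levels)
  abort_if(r < 2, "weighted_fst: need >= 2 populations")
  cols <- lapply(pop_levels, function(p) which(pops == p))
  abort_if(any(lengths(cols) < 2),
           "weighted_fst: need >= 2 strains per population")
  G <- gm$gt
  n_i <- sapply(cols, function(ii) rowSums(!is.na(G[, ii, drop = FALSE])))
  p_i <- sapply(cols, function(ii)
    rowSums(G[, ii, drop = FALSE], na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(cols, function(ii)
    rowSums(G[, ii, drop = FALSE] == 1L, na.rm = TRUE)) / n_i
  if (!is.matrix(n_i)) {
    n_i <- matrix(n_i, 1); p_i <- matrix(p_i, 1); h_i <- matrix(h_i, 1)
  }
  ok <- rowSums(n_i >= 1) == r & rowSums(n_i) > r  # need nbar > 1
  a_s <- b_s <- c_s <- 0
  used <- 0L
  for (s in which(ok)) {
    ni <- n_i[s, ]; pi_ <- p_i[s, ]; hi <- h_i[s, ]
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    a_s <- a_s + a; b_s <- b_s + b; c_s <- c_s + cc
    used <- used + 1L
  }
  denom <- a_s + b_s + c_s
  list(fst = if (used == 0 || denom == 0) NA_real_ else a_s / denom,
       a = a_s, b = b_s, c = c_s, n_sites = used)
}

#' One-sided Spearman Mantel test
#'
#' Spearman correlation between the lower-triangle entries of two distance
#' matrices; the null distribution is generated by simultaneously
#' permuting rows and columns of the second matrix, and the one-sided
#' p-value is `(count(r_perm >= r_obs) + 1) / (n_perm + 1)`, so its floor
#' is `1 / (n_perm + 1)`.
#'
#' @param d1,d2 Symmetric distance matrices over the same strains, in the
#'   same order.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_spearman <- function(d1, d2, n_perm = 9999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  abort_if(!all(dim(d1) == dim(d2)), "mantel_spearman: dimension mismatch")
  abort_if(max(abs(d1 - t(d1))) > 1e-8 || max(abs(d2 - t(d2))) > 1e-8,
           "mantel_spearman: matrices must be symmetric")
  v1 <- lower_tri_vec(d1); v2 <- lower_tri_vec(d2)
  abort_if(stats::sd(v1) == 0 || stats::sd(v2) == 0,
           "mantel_spearman: constant distance matrix; r undefined")
  r1 <- rank(v1)
  # permuting rows+columns leaves the off-diagonal multiset unchanged, so
  # ranks can be assigned once and subset per permutation
  R2 <- matrix(0, nrow(d2), ncol(d2))
  R2[lower.tri(R2)] <- rank(v2)
  R2 <- R2 + t(R2)
  r_obs <- stats::cor(r1, R2[lower.tri(R2)])
  n <- nrow(d2)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(r1, lower_tri_vec(R2[p, p])) >= r_obs
    }, logical(1)))
  })
  list(r = r_obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       seed = seed)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centering plus eigendecomposition (via `stats::cmdscale`),
#' components ordered by eigenvalue. Sign convention: within each
#' component, the loading of largest magnitude is made positive.
#'
#' @param d Symmetric distance matrix.
#' @param n_components Number of components.
#' @return Numeric matrix (strains x components).
#' @export
mds_embedding <- function(d, n_components = 2) {
  d <- as.matrix(d)
  abort_if(max(abs(d - t(d))) > 1e-8, "mds_embedding: matrix must be symmetric")
  if (all(d == 0)) {
    return(matrix(0, nrow(d), n_components,
                  dimnames = list(rownames(d), NULL)))
  }
  pts <- stats::cmdscale(d, k = n_components)
  if (ncol(pts) < n_components)
    pts <- cbind(pts, matrix(0, nrow(pts), n_components - ncol(pts)))
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  pts
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances in kilometres.
#'
#' @param coords Tibble with `strain`, `lon`, `lat` (degrees).
#' @return Symmetric matrix (km) with strains as dimnames.
#' @export
geographic_distance <- function(coords) {
  abort_if(any(abs(coords$lat) > 90), "geographic_distance: |lat| > 90")
  abort_if(any(abs(coords$lon) > 360), "geographic_distance: bad longitude")
  # mean Earth radius, the conventional haversine convention
  m <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(m) <- list(coords$strain, coords$strain)
  m
}
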