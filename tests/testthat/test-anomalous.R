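test_that("Patterson cross-peak combinatorics", {
  expect_equal(count_patterson_cross_peaks(17), 272L)
  expect_equal(count_patterson_cross_peaks(2), 2L)
  expect_equal(count_patterson_cross_peaks(1), 0L)
  expect_equal(count_patterson_cross_peaks(0), 0L)
  expect_error(count_patterson_cross_peaks(-1), ">= 0")
})

test_that("Bijvoet deltas vanish without f'' and track the ground truth", {
  gt0 <- toy_gt(n_sites = 3, f_double_prime = 0, d_min = 3)
  st0 <- simulate_images(gt0, 80, scale_sigma = 0, p_min = 1,
                         noise_gain = 0, seed = 2)
  d0 <- bijvoet_deltas(merge_unscaled(st0))
  expect_equal(max(abs(d0$dF)), 0, tolerance = 1e-9)
  expect_equal(attr(d0, "ratio_pct"), 0, tolerance = 1e-9)

  gt <- toy_gt(n_sites = 3, f_double_prime = 1.5, d_min = 3)
  st <- simulate_images(gt, 150, mean_obs = 80, scale_sigma = 0,
                        p_min = 1, noise_gain = 0, seed = 2)
  de <- bijvoet_deltas(merge_unscaled(st), phases = gt$refl)
  key <- paste(de$h, de$k, de$l)
  gkey <- paste(gt$refl$h, gt$refl$k, gt$refl$l)
  tru <- gt$refl[match(key, gkey), ]
  expect_equal(de$dF, sqrt(tru$I_plus) - sqrt(tru$I_minus),
               tolerance = 1e-8)
})

delta_fixture <- function(n = 12, sg = p1(), cell = unit_cell(15, 17, 19),
                          seed = 1, phases = TRUE) {
  set.seed(seed)
  de <- data.frame(h = sample(-3:3, n, TRUE), k = sample(-3:3, n, TRUE),
                   l = sample(1:3, n, TRUE), dF = rnorm(n), weight = 1)
  de <- de[rowSums(abs(de[, 1:3])) > 0, ]
  de$phi <- if (phases) runif(nrow(de), -pi, pi) else NA_real_
  structure(de, cell = cell, sg = sg,
            class = c("sfx_deltas", "data.frame"))
}

test_that("one-reflection Patterson is the bare cosine", {
  de <- structure(data.frame(h = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                             k = 0, l = 0, dF = 1, weight = 1),
                  cell = unit_cell(10, 10, 10), sg = p1(),
                  class = c("sfx_deltas", "data.frame"))
  p <- patterson_map(de, dims = c(8, 4, 4))
  ux <- (0:7) / 8
  # ten identical copies of (1,0,0) deduplicate to one: P(u) = 2 cos(2 pi ux)
  expect_equal(p$values[, 1, 1], 2 * cos(2 * pi * ux), tolerance = 1e-12)
  expect_true(all(abs(sweep(p$values, 1, p$values[, 1, 1])) < 1e-12))
})

test_that("two-site Patterson peaks at the inter-site vector", {
  cell <- unit_cell(12, 12, 12)
  sites <- data.frame(x = c(0.1, 0.35), y = c(0.2, 0.5),
                      z = c(0.15, 0.65))
  gt <- build_ground_truth(cell, p1(), sites = sites, f_double_prime = 3,
                           protein_scale = 60, d_min = 2, seed = 4)
  st <- simulate_images(gt, 100, mean_obs = 150, scale_sigma = 0,
                        p_min = 1, noise_gain = 0, seed = 4)
  de <- bijvoet_deltas(merge_unscaled(st))
  p <- patterson_map(de, dims = c(24, 24, 24))
  pk <- map_peaks(p)
  pk <- pk[-1, ]   # drop origin
  target <- (as.numeric(sites[1, ]) - as.numeric(sites[2, ])) %% 1
  d1 <- frac_dist(matrix(as.numeric(pk[1, 1:3]), 1), matrix(target, 1),
                  cell)
  d2 <- frac_dist(matrix(as.numeric(pk[2, 1:3]), 1), matrix(-target, 1) %% 1,
                  cell)
  expect_lt(min(d1, d2), 12 / 24 * sqrt(3) + 1e-9)  # within a grid step
})

test_that("maps agree with an independent per-point cosine oracle", {
  de <- delta_fixture()
  p <- patterson_map(de, dims = c(9, 8, 7))
  f <- difference_fourier(de, dims = c(9, 8, 7))
  set.seed(2)
  pts_idx <- cbind(sample(9, 5), sample(8, 5), sample(7, 5))
  for (i in 1:5) {
    u <- (pts_idx[i, ] - 1) / c(9, 8, 7)
    H <- as.matrix(de[, c("h", "k", "l")])
    # oracle for P1: Friedel-completed cosine sum, duplicates removed
    key <- paste(H[, 1], H[, 2], H[, 3])
    keep <- !duplicated(key)
    Hk <- H[keep, , drop = FALSE]; dFk <- de$dF[keep]
    phk <- de$phi[keep]
    keym <- paste(-Hk[, 1], -Hk[, 2], -Hk[, 3])
    both <- rbind(Hk, -Hk[!keym %in% key[keep], , drop = FALSE])
    cboth <- c(dFk^2, (dFk^2)[!keym %in% key[keep]])
    o_p <- sum(cboth * cos(2 * pi * drop(both %*% u)))
    expect_equal(p$values[pts_idx[i, 1], pts_idx[i, 2], pts_idx[i, 3]],
                 o_p, tolerance = 1e-10)
    # difference Fourier is normalized; apply the same transform to the
    # oracle using the oracle's own full-grid moments
    vals_raw <- sum(dFk * cos(2 * pi * drop(Hk %*% u) - (phk - pi / 2)))
    grid <- as.matrix(expand.grid(x = (0:8) / 9, y = (0:7) / 8,
                                  z = (0:6) / 7))
    all_raw <- colSums(dFk * cos(2 * pi * (Hk %*% t(grid)) -
                                   (phk - pi / 2)))
    o_norm <- (vals_raw - mean(all_raw)) / sd(all_raw)
    expect_equal(f$values[pts_idx[i, 1], pts_idx[i, 2], pts_idx[i, 3]],
                 o_norm, tolerance = 1e-10)
  }
})

test_that("Patterson maps are centrosymmetric", {
  for (sg in list(p1(), p41212())) {
    de <- delta_fixture(sg = sg, cell = toy_cell(), seed = 6)
    p <- patterson_map(de, dims = c(10, 10, 12))
    rev_idx <- function(n) c(1, n:2)
    asym <- max(abs(p$values - p$values[rev_idx(10), rev_idx(10),
                                        rev_idx(12)]))
    expect_lt(asym, 1e-8 * max(p$values))
    expect_equal(which.max(p$values), 1L)  # origin is the maximum
  }
})

test_that("ground-truth sites are strong maxima of the difference Fourier", {
  gt <- toy_gt(n_sites = 3, f_double_prime = 2, d_min = 2.2,
               protein_scale = 150, seed = 7)
  st <- simulate_images(gt, 200, mean_obs = 80, scale_sigma = 0, p_min = 1,
                        noise_gain = 0, seed = 8)
  de <- bijvoet_deltas(merge_unscaled(st), phases = gt$refl)
  f <- difference_fourier(de, dims = c(32, 32, 48))
  heights <- sapply(seq_len(nrow(gt$sites)), function(i)
    s_ano(f, gt$sites[i, , drop = FALSE]))
  expect_true(all(heights > 5))
  # flipping all phases by 180 degrees negates the map
  de2 <- de
  de2$phi <- de$phi + pi
  attributes(de2) <- attributes(de)
  de2$phi <- de$phi + pi
  f2 <- difference_fourier(de2, dims = c(32, 32, 48))
  expect_equal(f2$values, -f$values, tolerance = 1e-9)
})

test_that("S_ano separates true sites from decoys", {
  gt <- toy_gt(n_sites = 3, f_double_prime = 2, d_min = 2.2,
               protein_scale = 150, seed = 7)
  st <- simulate_images(gt, 200, mean_obs = 80, scale_sigma = 0, p_min = 1,
                        noise_gain = 0, seed = 8)
  de <- bijvoet_deltas(merge_unscaled(st), phases = gt$refl)
  f <- difference_fourier(de, dims = c(24, 24, 36))
  s_true <- s_ano(f, gt$sites)
  set.seed(3)
  s_dec <- replicate(200, s_ano(f, matrix(runif(9), 3)))
  expect_gt(s_true, quantile(s_dec, 0.975))
  expect_lt(abs(mean(s_dec)), 3 / sqrt(3) + 1)  # null is near zero
})

test_that("map correlation behaves at its extremes", {
  de <- delta_fixture(seed = 9)
  f <- difference_fourier(de, dims = c(8, 8, 8))
  expect_equal(map_correlation(f, f), 1)
  neg <- f; neg$values <- -f$values
  expect_equal(map_correlation(f, neg), -1)
  small <- difference_fourier(de, dims = c(6, 6, 6))
  expect_error(map_correlation(f, small), "dimension")
})
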