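toy_obs <- function(I, image_id = seq_along(I), h = 3, k = 1, l = 2) {
  data.frame(image_id = image_id, h = h, k = k, l = l, I = I, sigma = 1)
}

test_that("unscaled merging reproduces hand-computed means and sigmas", {
  cell <- toy_cell(); sg <- p41212()
  m1 <- merge_unscaled(toy_obs(7), cell, sg)
  expect_equal(m1$I, 7)
  expect_equal(m1$mult, 1)
  expect_equal(m1$sigma, 1)   # single observation keeps its own sigma
  m3 <- merge_unscaled(toy_obs(c(10, 12, 14)), cell, sg)
  expect_equal(m3$I, 12)
  expect_equal(m3$sigma, 2 / sqrt(3))
  expect_equal(m3$mult, 3)
})

test_that("merging is order-invariant and half-sets partition the data", {
  gt <- toy_gt()
  st <- simulate_images(gt, 50, seed = 4)
  m <- merge_unscaled(st)
  perm <- st
  idx <- sample(nrow(perm$obs))
  perm$obs <- perm$obs[idx, ]
  mp <- merge_unscaled(perm)
  expect_equal(as.data.frame(m), as.data.frame(mp))
  expect_equal(m$n1 + m$n2, m$mult)
  expect_equal(sum(m$mult), nrow(st$obs))
})

test_that("image scales match hand arithmetic and flag bad images", {
  cell <- toy_cell(); sg <- p41212()
  ref <- merge_unscaled(data.frame(image_id = 1, h = c(3, 4), k = c(1, 1),
                                   l = c(2, 3), I = c(10, 20), sigma = 1),
                        cell, sg, anomalous = FALSE)
  obs <- data.frame(image_id = 5, h = c(3, 4), k = c(1, 1), l = c(2, 3),
                    I = c(4, 8), sigma = 1)
  sc <- image_scale(obs, ref, min_common = 2)
  expect_equal(sc$s, 30 / 12)
  expect_equal(sc$cc, 1.0)
  # proportional data: I_obs = 2 * I_ref -> s = 0.5
  obs2 <- obs; obs2$I <- c(20, 40)
  expect_equal(image_scale(obs2, ref, min_common = 2)$s, 0.5)
  # negative intensity sum is unusable
  obs3 <- obs; obs3$I <- c(-5, -2)
  expect_false(image_scale(obs3, ref, min_common = 2)$usable)
  expect_false(image_scale(obs, ref, min_common = 10)$usable)
})

test_that("two-pass scaling recovers per-image scales on clean data", {
  gt <- toy_gt(n_sites = 0, d_min = 3)
  st <- simulate_images(gt, 300, mean_obs = 40, scale_sigma = 0.5,
                        p_min = 1, noise_gain = 0, seed = 6)
  sm <- two_pass_merge(st, n_iter = 2)
  expect_gt(cor(sm$scales$s, 1 / st$images$s_true), 0.999)
  # residual scale spread after scaling is far below the input spread
  resid <- sm$scales$s * st$images$s_true
  expect_lt(sd(log(resid)), 0.01 * sd(log(st$images$s_true)))
})

test_that("degenerate data make the scaled merge equal the unscaled merge", {
  # no anomalous signal: the Friedel-merged pass-1 reference is then an
  # exact per-reflection mean and all derived scales are exactly 1
  gt <- toy_gt(n_sites = 0, d_min = 3)
  st <- simulate_images(gt, 30, scale_sigma = 0, p_min = 1, noise_gain = 0,
                        seed = 3)
  sm <- two_pass_merge(st)
  expect_true(all(abs(sm$scales$s - 1) < 1e-12))
  mm <- merge_unscaled(st)
  expect_equal(sm$merged$I, mm$I, tolerance = 1e-12)
  expect_identical(sm$merged$mult, mm$mult)
  expect_identical(sm$merged[, c("h", "k", "l", "sign")],
                   mm[, c("h", "k", "l", "sign")])
  # noise-free duplicates: both sigma estimates are (numerically) zero
  expect_lt(max(abs(sm$merged$sigma - mm$sigma)), 1e-8)
})

test_that("outlier rejection removes an injected spike and conserves counts", {
  gt <- toy_gt(n_sites = 0, d_min = 3)
  # enough multiplicity that one spike cannot drag its merged mean far
  st <- simulate_images(gt, 200, mean_obs = 80, scale_sigma = 0, p_min = 1,
                        noise_gain = 1, seed = 5)
  m <- merge_unscaled(st)
  clean <- reject_outliers(st$obs, m, z_max = 6)
  expect_equal(clean$n_rejected, 0)
  spiked <- st$obs
  spiked$I[17] <- spiked$I[17] + 100 * spiked$sigma[17]
  mspk <- merge_unscaled(spiked, st$cell, st$sg)
  rej <- reject_outliers(spiked, mspk, z_max = 6)
  expect_equal(rej$n_rejected, 1)
  expect_false(17 %in% as.integer(rownames(rej$obs)))
  m2 <- merge_unscaled(rej$obs, st$cell, st$sg)
  expect_equal(sum(m2$mult), sum(mspk$mult) - rej$n_rejected)
  # monotone in z_max
  counts <- vapply(c(2, 4, 6, 10), function(z)
    reject_outliers(spiked, mspk, z_max = z)$n_rejected, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("image selection thresholds behave and deplete noisy images first", {
  gt <- toy_gt(n_sites = 0, d_min = 3)
  st <- simulate_images(gt, 200, mean_obs = 40, scale_sigma = 0.3,
                        p_min = 0.5, noise_gain = 1, seed = 7)
  noisy <- st$images$image_id %% 10 == 0   # 10% corrupted population
  set.seed(1)
  corr <- rlnorm(nrow(st$obs), 0, 1)       # strong multiplicative scatter
  st$obs$I <- ifelse(noisy[st$obs$image_id], st$obs$I * corr, st$obs$I)
  sm <- two_pass_merge(st)
  expect_equal(sort(select_images(sm$scales, -1)), st$images$image_id)
  expect_length(select_images(sm$scales, 1.5), 0)
  fracs <- vapply(c(0.2, 0.5, 0.8), function(cc) {
    sel <- select_images(sm$scales, cc)
    length(sel) / nrow(st$images)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  sel <- select_images(sm$scales, 0.8)
  expect_lt(mean(noisy[sel]), mean(noisy))
})

test_that("merged Bijvoet signs track the true anomalous differences", {
  gt <- toy_gt(n_sites = 4, f_double_prime = 2, d_min = 2.8,
               protein_scale = 100)
  st <- simulate_images(gt, 800, mean_obs = 60, scale_sigma = 0.3,
                        p_min = 0.5, noise_gain = 0.3, seed = 12)
  sm <- two_pass_merge(st)
  bp <- sfxsad:::bijvoet_pairs(sm$merged)
  key <- paste(bp$h, bp$k, bp$l)
  gkey <- paste(gt$refl$h, gt$refl$k, gt$refl$l)
  tru <- gt$refl[match(key, gkey), ]
  dtru <- tru$I_plus - tru$I_minus
  strong <- abs(dtru) > stats::quantile(abs(dtru), 0.5)
  agree <- sign(bp$I_plus - bp$I_minus)[strong] == sign(dtru)[strong]
  expect_gt(mean(agree), 0.95)
})
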