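test_that("self-alignment is the identity and allowed shifts are recovered", {
  cell <- toy_cell(); sg <- p41212()
  sol <- random_sites(8, seed = 1)
  sol$occ <- seq(1, 0.3, length.out = 8)
  al <- align_solution(sol, sol, sg, cell)
  expect_equal(al$matched_fraction, 1)
  expect_false(al$transform$hand)
  expect_equal(unname(al$transform$shift), c(0, 0, 0))
  expect_equal(al$mean_dist, 0)
  # an allowed origin shift is undone exactly
  sh <- allowed_origin_shifts(sg)[3, ]
  shifted <- sol
  shifted[, 1:3] <- sweep(as.matrix(sol[, 1:3]), 2, sh, "+") %% 1
  al2 <- align_solution(shifted, sol, sg, cell)
  expect_equal(al2$matched_fraction, 1)
  expect_lt(al2$mean_dist, 1e-9)
  # hand-inverted solutions are recovered with the hand flag set
  inv <- sol
  inv[, 1:3] <- (-as.matrix(sol[, 1:3])) %% 1
  al3 <- align_solution(inv, sol, sg, cell)
  expect_equal(al3$matched_fraction, 1)
  expect_true(al3$transform$hand)
})

test_that("unrelated random site sets rarely match", {
  cell <- tetragonal_cell(58.6, 151.3); sg <- p41212()
  hits <- vapply(1:100, function(i) {
    a <- random_sites(17, seed = i)
    b <- random_sites(17, seed = 1000 + i)
    align_solution(a, b, sg, cell, tol = 1.5)$matched_fraction
  }, numeric(1))
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("consensus keeps exactly the recurrent sites", {
  cell <- tetragonal_cell(58.6, 151.3); sg <- p41212()
  truth <- random_sites(17, seed = 4)
  sols <- simulate_substructure_solutions(truth, sg, cell,
                                          n_solutions = 5, n_decoys = 14,
                                          seed = 11)
  cons <- consensus_filter(sols, sg, cell, min_count = 5, tol = 1.5)
  expect_equal(nrow(cons$sites), 17)
  expect_true(all(cons$sites$votes == 5))
  # truth sites present in 4/5 solutions plus per-solution decoys,
  # min_count = 3: exactly the truth sites survive
  sols4 <- sols
  sols4[[5]] <- sols4[[5]][18:31, ]   # drop the strong sites from one
  cons4 <- consensus_filter(sols4, sg, cell, min_count = 3, tol = 1.5)
  expect_equal(nrow(cons4$sites), 17)
  expect_true(all(cons4$sites$votes >= 4))
})

test_that("identical solutions vote unanimously; min_count=1 keeps the union", {
  # a roomy cell keeps unrelated random sites from colliding within tol
  cell <- tetragonal_cell(58.6, 151.3); sg <- p41212()
  sol <- random_sites(6, seed = 2); sol$occ <- 0.8
  sols <- list(sol, sol, sol)
  cons <- consensus_filter(sols, sg, cell, min_count = 3, tol = 1.0)
  expect_equal(nrow(cons$sites), 6)
  expect_true(all(cons$sites$votes == 3))
  # second solution shares one site (so alignment anchors) plus 3 of its own
  other <- rbind(sol[1, c("x", "y", "z")] + 1e-3, random_sites(3, seed = 30))
  other$occ <- 0.5
  cons1 <- consensus_filter(list(sol, other), sg, cell, min_count = 1,
                            tol = 1.0)
  expect_equal(nrow(cons1$sites), 9)
})

test_that("consensus votes are equivariant under global transforms", {
  cell <- tetragonal_cell(58.6, 151.3); sg <- p41212()
  truth <- random_sites(10, seed = 8)
  sols <- simulate_substructure_solutions(truth, sg, cell, n_solutions = 4,
                                          n_decoys = 5, scramble = FALSE,
                                          seed = 3)
  base <- consensus_filter(sols, sg, cell, min_count = 4, tol = 1.5)
  # apply one global allowed shift + hand flip to every solution
  sh <- allowed_origin_shifts(sg)[2, ]
  sols2 <- lapply(sols, function(s) {
    s[, 1:3] <- sweep((-as.matrix(s[, 1:3])) %% 1, 2, sh, "+") %% 1
    s
  })
  moved <- consensus_filter(sols2, sg, cell, min_count = 4, tol = 1.5)
  expect_equal(sort(moved$sites$votes), sort(base$sites$votes))
  expect_equal(nrow(moved$sites), nrow(base$sites))
})

test_that("consensus is invariant to the order of non-reference solutions", {
  cell <- tetragonal_cell(58.6, 151.3); sg <- p41212()
  truth <- random_sites(12, seed = 5)
  sols <- simulate_substructure_solutions(truth, sg, cell, n_solutions = 4,
                                          n_decoys = 6, seed = 7)
  a <- consensus_filter(sols, sg, cell, min_count = 4, tol = 1.5)
  b <- consensus_filter(sols[c(1, 4, 2, 3)], sg, cell, min_count = 4,
                        tol = 1.5)
  expect_equal(nrow(a$sites), nrow(b$sites))
  expect_equal(sort(round(a$sites$occ, 6)), sort(round(b$sites$occ, 6)))
})

test_that("occupancy cutoff finds the largest relative gap", {
  r <- occupancy_cutoff(c(1.0, 0.95, 0.9, 0.88, 0.30, 0.25), min_keep = 2)
  expect_equal(r$cut, 4)
  expect_false(r$no_cut)
  flat <- occupancy_cutoff(rep(0.7, 6))
  expect_true(flat$no_cut)
  expect_equal(flat$cut, 6)
  expect_error(occupancy_cutoff(c(1, 0.5)), "at least 3")
})

test_that("disulfide superatoms expand into centred half-occupancy pairs", {
  cell <- toy_cell()
  site <- data.frame(x = 0.4, y = 0.5, z = 0.6, occ = 1.0)
  pair <- expand_disulfide(site, cell, separation = 2.05)
  expect_equal(nrow(pair), 2)
  expect_equal(pair$occ, c(0.5, 0.5))
  d <- frac_dist(as.matrix(pair[1, 1:3]), as.matrix(pair[2, 1:3]), cell)
  expect_equal(unname(d), 2.05, tolerance = 1e-9)
  expect_equal(mean(pair$x), site$x)
  expect_equal(pair$y, rep(site$y, 2))
})

test_that("res-style site lists round-trip with their JSON sidecar", {
  sites <- random_sites(5, seed = 6)
  sites$occ <- round(runif(5, 0.3, 1), 4)
  sites$disulfide <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  sites$votes <- c(5L, 4L, 3L, 5L, 3L)
  path <- tempfile(fileext = ".res")
  write_res_sites(sites, path)
  back <- read_res_sites(path)
  expect_equal(back$x, sites$x, tolerance = 1e-6)
  expect_equal(back$occ, sites$occ, tolerance = 1e-4)
  expect_equal(back$disulfide, sites$disulfide)
  expect_equal(back$votes, sites$votes)
})
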