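# Synthetic still-diffraction data with a recoverable ground truth.
#
# The simulator emulates the fluctuation structure of serial still data:
# per-image multiplicative scales, partiality, counting noise, detector-
# distance drift between runs (which rescales apparent cells) and per-tile
# spot-position offsets.  Scattering physics is deliberately simplified:
# scattering factors are resolution-independent, so all downstream
# intensity-statistical procedures have exact oracles.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Enumerate unique reflections to a resolution limit
#'
#' Generates the full sphere of Miller indices inside the resolution
#' range, removes systematic absences, and reduces to one row per unique
#' reflection (Friedel mates share a row; `centric` marks reflections with
#' no Bijvoet difference).
#'
#' @param cell A `unit_cell`.
#' @param sg A `space_group`.
#' @param d_min High-resolution limit in Angstrom.
#' @param d_max Low-resolution limit in Angstrom (default 1000).
#' @return Data frame with columns h, k, l (unique representative),
#'   centric, d.
#' @export
reflection_table <- function(cell, sg, d_min, d_max = 1000) {
  if (d_min <= 0) stop("d_min must be > 0")
  hmax <- ceiling(cell$a / d_min); kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  H <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  H <- H[rowSums(abs(H)) > 0, , drop = FALSE]
  d <- d_spacing(H, cell)
  H <- H[d >= d_min & d <= d_max, , drop = FALSE]
  H <- H[!is_absent(H, sg), , drop = FALSE]
  m <- map_to_asu(H, sg, anomalous = TRUE)
  key <- paste(m$hkl[, 1], m$hkl[, 2], m$hkl[, 3])
  first <- !duplicated(key)
  out <- data.frame(h = m$hkl[first, 1], k = m$hkl[first, 2],
                    l = m$hkl[first, 3], centric = m$centric[first])
  out$d <- d_spacing(as.matrix(out[, 1:3]), cell)
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
}

#' Build a ground-truth structure-factor set with an anomalous substructure
#'
#' Protein background amplitudes are drawn once per unique reflection from
#' Wilson statistics (complex Gaussian for acentrics; phase-restricted real
#' Gaussian for centrics).  Anomalous scatterers contribute
#' sum over sites and symmetry operators of
#' (f0 + f' + i f'') * occ * exp(2 pi i (R x + t) . h), so Bijvoet
#' differences arise only from f''.  Model phases (computed with f'' = 0)
#' are stored for difference-Fourier work.
#'
#' @param cell,sg Crystal form.
#' @param n_sites Number of anomalous scatterers drawn at random fractional
#'   positions (ignored when `sites` is given).
#' @param sites Optional data frame with columns x, y, z and optionally
#'   occ, f0, fp, fpp overriding the scalar defaults.
#' @param f0,f_prime,f_double_prime Normal and anomalous scattering-factor
#'   components in electrons (defaults emulate sulfur near 6 keV).
#' @param occupancy Default site occupancy in (0, 1].
#' @param protein_scale RMS protein structure amplitude (electrons).  The
#'   default, with 17 sulfur-like sites in a thaumatin-like tetragonal
#'   cell, puts the Bijvoet ratio <|dF|>/<F> in the 1-2 percent regime
#'   typical of native-sulfur phasing.
#' @param d_min,d_max Resolution range in Angstrom.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `sfx_ground_truth`: list with `cell`, `sg`,
#'   `sites`, `refl` (data frame: h, k, l, centric, d, I_plus, I_minus,
#'   phi), `params`, `seed`.  For centrics `I_plus == I_minus`.
#' @export
build_ground_truth <- function(cell, sg, n_sites = 0, sites = NULL,
                               f0 = 16, f_prime = 0.3, f_double_prime = 0.7,
                               occupancy = 1, protein_scale = 650,
                               d_min, d_max = 1000, seed = 1) {
  if (d_min <= 0) stop("d_min must be > 0")
  refl <- reflection_table(cell, sg, d_min, d_max)
  with_seed(seed, {
    if (is.null(sites)) {
      sites <- data.frame(x = stats::runif(n_sites), y = stats::runif(n_sites),
                          z = stats::runif(n_sites))
    }
    sites <- as.data.frame(sites)
    if (is.null(sites$occ)) sites$occ <- rep(occupancy, nrow(sites))
    if (is.null(sites$f0)) sites$f0 <- rep(f0, nrow(sites))
    if (is.null(sites$fp)) sites$fp <- rep(f_prime, nrow(sites))
    if (is.null(sites$fpp)) sites$fpp <- rep(f_double_prime, nrow(sites))
    if (nrow(sites) && (any(sites$fpp < 0) || any(sites$occ <= 0) ||
                        any(sites$occ > 1)))
      stop("site f'' must be >= 0 and occupancy in (0, 1]")

    H <- as.matrix(refl[, c("h", "k", "l")])
    n <- nrow(H)
    # protein background
    sigma <- protein_scale
    Fp <- complex(real = stats::rnorm(n, 0, sigma / sqrt(2)),
                  imaginary = stats::rnorm(n, 0, sigma / sqrt(2)))
    if (any(refl$centric)) {
      idx <- which(refl$centric)
      phi0 <- centric_phase(H[idx, , drop = FALSE], sg)
      phi0[is.na(phi0)] <- 0 # P1 has no centrics; guard anyway
      Fp[idx] <- stats::rnorm(length(idx), 0, sigma) * exp(1i * phi0)
    }
    # substructure contribution over the symmetry-expanded site set
    S_plus <- S_minus <- S_normal <- complex(real = numeric(n))
    if (nrow(sites)) {
      P <- expand_sites(as.matrix(sites[, c("x", "y", "z")]), sg)
      occ <- rep(sites$occ, times = length(sg$ops))
      fn <- rep(sites$f0 + sites$fp, times = length(sg$ops))
      fa <- rep(sites$fpp, times = length(sg$ops))
      theta <- 2 * pi * (H %*% t(P))   # n_refl x n_positions
      E <- exp(1i * theta)
      S_plus <- drop(E %*% (occ * (fn + 1i * fa)))
      S_minus <- drop(Conj(E) %*% (occ * (fn + 1i * fa)))
      S_normal <- drop(E %*% (occ * fn))
    }
    F_plus <- Fp + S_plus
    F_minus <- Conj(Fp) + S_minus
    refl$I_plus <- Mod(F_plus)^2
    refl$I_minus <- Mod(F_minus)^2
    if (any(refl$centric)) { # no Bijvoet split for centrics by symmetry
      refl$I_minus[refl$centric] <- refl$I_plus[refl$centric]
    }
    refl$phi <- Arg(Fp + S_normal)   # model phase, f'' excluded
    structure(list(cell = cell, sg = sg, sites = sites, refl = refl,
                   params = list(protein_scale = protein_scale,
                                 d_min = d_min, d_max = d_max),
                   seed = seed),
              class = "sfx_ground_truth")
  })
}

#' @export
print.sfx_ground_truth <- function(x, ...) {
  cat(sprintf("sfx ground truth: %d unique reflections (%d centric), %d sites, d >= %.2f A\n",
              nrow(x$refl), sum(x$refl$centric), nrow(x$sites),
              x$params$d_min))
  invisible(x)
}

#' Bijvoet ratio of a ground truth
#'
#' Mean absolute Bijvoet amplitude difference over mean amplitude, in
#' percent, over acentric reflections.
#'
#' @param gt An `sfx_ground_truth`.
#' @return Percent value.
#' @export
bijvoet_ratio <- function(gt) {
  r <- gt$refl[!gt$refl$centric, ]
  Fp <- sqrt(r$I_plus); Fm <- sqrt(r$I_minus)
  100 * mean(abs(Fp - Fm)) / mean((Fp + Fm) / 2)
}

#' Simulate still images
#'
#' Each image observes a random subset of reflections (a proxy for a
#' random orientation), with observed intensity
#' `I = s_true * p * I_truth + noise`: `s_true` log-normal with log-sd
#' `scale_sigma`, partiality `p` uniform on (`p_min`, 1) per spot, and
#' noise Normal(0, `noise_gain * sqrt(max(I, 1))`).  Negative observed
#' intensities are kept.  Apparent cell lengths are the true lengths
#' times assumed/true detector distance for the image's run, with optional
#' per-axis multiplicative indexing jitter.
#'
#' @param gt An `sfx_ground_truth`.
#' @param n_images Number of images (>= 1).
#' @param mean_obs Mean number of observations per image.
#' @param scale_sigma Log-sd of the per-image scale.
#' @param p_min Lower bound of the partiality multiplier (1 = no
#'   partiality).
#' @param noise_gain Counting-noise gain (0 = noise free).
#' @param distance_schedule Data frame with columns `run`, `true_mm`,
#'   `assumed_mm` (one row per run; images are split across runs in
#'   order).  Default: a single run with both distances 100 mm.
#' @param cell_jitter Relative per-axis sd of apparent-cell indexing
#'   jitter.
#' @param scramble_indices Emit each observation under a random
#'   symmetry-equivalent Miller index (exercises ASU mapping downstream).
#' @param seed Integer seed.
#' @return Object of class `sfx_still_set`: list with `images` (data
#'   frame: image_id, run, s_true, a, b, c, assumed_mm, true_mm), `obs`
#'   (data frame: image_id, h, k, l, I, sigma), `cell`, `sg`.
#' @export
simulate_images <- function(gt, n_images, mean_obs = 60, scale_sigma = 0.3,
                            p_min = 0.3, noise_gain = 1,
                            distance_schedule = NULL, cell_jitter = 5e-4,
                            scramble_indices = TRUE, seed = 1) {
  if (n_images < 1) stop("n_images must be >= 1")
  if (nrow(gt$refl) == 0) stop("empty ground truth")
  if (is.null(distance_schedule))
    distance_schedule <- data.frame(run = 1L, true_mm = 100, assumed_mm = 100)
  with_seed(seed, {
    # observable catalog: one entry per Bijvoet mate (acentrics twice)
    r <- gt$refl
    ac <- !r$centric
    cat_h <- rbind(as.matrix(r[, c("h", "k", "l")]),
                   -as.matrix(r[ac, c("h", "k", "l")]))
    cat_I <- c(r$I_plus, r$I_minus[ac])
    ncat <- nrow(cat_h)

    run_of <- distance_schedule$run[
      ceiling(seq_len(n_images) / n_images * nrow(distance_schedule))]
    sched <- distance_schedule[match(run_of, distance_schedule$run), ]
    s_true <- stats::rlnorm(n_images, 0, scale_sigma)
    ratio <- sched$assumed_mm / sched$true_mm
    jit <- matrix(1 + stats::rnorm(3 * n_images, 0, cell_jitter), ncol = 3)
    images <- data.frame(image_id = seq_len(n_images), run = run_of,
                         s_true = s_true,
                         a = gt$cell$a * ratio * jit[, 1],
                         b = gt$cell$b * ratio * jit[, 2],
                         c = gt$cell$c * ratio * jit[, 3],
                         assumed_mm = sched$assumed_mm,
                         true_mm = sched$true_mm)

    nobs <- pmin(pmax(stats::rpois(n_images, mean_obs), 3L), ncat)
    idx <- unlist(lapply(nobs, function(k) sample.int(ncat, k)))
    img <- rep(seq_len(n_images), times = nobs)
    I_true <- cat_I[idx]
    p <- stats::runif(length(idx), p_min, 1)
    I0 <- s_true[img] * p * I_true
    sd0 <- noise_gain * sqrt(pmax(I0, 1))
    I_obs <- I0 + stats::rnorm(length(idx), 0, sd0)
    sigma <- pmax(sd0, 1e-6)

    Hobs <- cat_h[idx, , drop = FALSE]
    if (scramble_indices && length(gt$sg$ops) > 1) {
      opi <- sample.int(length(gt$sg$ops), length(idx), replace = TRUE)
      for (j in seq_along(gt$sg$ops)) {
        sel <- opi == j
        if (any(sel))
          Hobs[sel, ] <- Hobs[sel, , drop = FALSE] %*% gt$sg$ops[[j]]$R
      }
    }
    obs <- data.frame(image_id = img, h = Hobs[, 1], k = Hobs[, 2],
                      l = Hobs[, 3], I = I_obs, sigma = sigma)
    structure(list(images = images, obs = obs, cell = gt$cell, sg = gt$sg),
              class = "sfx_still_set")
  })
}

#' @export
print.sfx_still_set <- function(x, ...) {
  cat(sprintf("sfx still set: %d images, %d observations, %d runs\n",
              nrow(x$images), nrow(x$obs), length(unique(x$images$run))))
  invisible(x)
}

#' Simulate per-tile spot displacements
#'
#' Predicted spot positions are drawn uniformly on each tile; observed
#' positions are the predictions rotated about the tile centre, translated
#' by the tile's offset, plus isotropic Gaussian noise.
#'
#' @param tile_layout Data frame: tile, x0, y0 (tile centres, px), half
#'   widths `hw` (default 96 px).
#' @param offsets Data frame: tile, dx, dy (px), dtheta (degrees).
#' @param n_spots Spots per tile.
#' @param noise_px Positional noise sd in px.
#' @param seed Integer seed.
#' @return List with `predicted`, `observed` (data frames: tile, x, y) and
#'   `truth` (the offsets).
#' @export
simulate_tile_spots <- function(tile_layout, offsets, n_spots = 50,
                                noise_px = 0, seed = 1) {
  stopifnot(all(is.finite(as.matrix(offsets[, c("dx", "dy", "dtheta")]))))
  if (is.null(tile_layout$hw)) tile_layout$hw <- 96
  with_seed(seed, {
    pred <- obs <- NULL
    for (i in seq_len(nrow(tile_layout))) {
      tl <- tile_layout[i, ]
      off <- offsets[offsets$tile == tl$tile, ]
      p <- cbind(stats::runif(n_spots, tl$x0 - tl$hw, tl$x0 + tl$hw),
                 stats::runif(n_spots, tl$y0 - tl$hw, tl$y0 + tl$hw))
      th <- off$dtheta * pi / 180
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      o <- sweep(sweep(p, 2, c(tl$x0, tl$y0)) %*% t(Rm), 2,
                 c(tl$x0 + off$dx, tl$y0 + off$dy), "+")
      o <- o + matrix(stats::rnorm(2 * n_spots, 0, noise_px), ncol = 2)
      pred <- rbind(pred, data.frame(tile = tl$tile, x = p[, 1], y = p[, 2]))
      obs <- rbind(obs, data.frame(tile = tl$tile, x = o[, 1], y = o[, 2]))
    }
    list(predicted = pred, observed = obs, truth = offsets)
  })
}

#' Simulate ranked substructure-solver solutions
#'
#' Emulates the shape of dual-space solver output for consensus testing: a
#' set of ranked site lists that share `n_common` true sites (strong
#' occupancies) plus per-solution decoys (weak occupancies), each solution
#' scrambled by a random allowed origin shift, optional hand flip, and
#' random per-site symmetry images.
#'
#' @param true_sites Data frame with columns x, y, z (the common sites).
#' @param sg,cell Crystal form.
#' @param n_solutions Number of solutions.
#' @param n_decoys Decoy sites per solution.
#' @param occ_strong,occ_weak Length-2 ranges for strong/weak occupancies.
#' @param scramble Apply random shift/hand/symmetry transforms.
#' @param seed Integer seed.
#' @return List of data frames (x, y, z, occ, disulfide), occupancies
#'   sorted non-increasing; solver metadata (cc_all, cc_weak) attached as
#'   attributes.
#' @export
simulate_substructure_solutions <- function(true_sites, sg, cell,
                                            n_solutions = 5, n_decoys = 14,
                                            occ_strong = c(0.7, 1),
                                            occ_weak = c(0.05, 0.35),
                                            scramble = TRUE, seed = 1) {
  with_seed(seed, {
    shifts <- allowed_origin_shifts(sg)
    lapply(seq_len(n_solutions), function(i) {
      xyz <- as.matrix(true_sites[, c("x", "y", "z")])
      occ_t <- stats::runif(nrow(xyz), occ_strong[1], occ_strong[2])
      dec <- matrix(stats::runif(3 * n_decoys), ncol = 3)
      occ_d <- stats::runif(n_decoys, occ_weak[1], occ_weak[2])
      all_xyz <- rbind(xyz, dec)
      if (scramble) {
        grp <- sg
        if (stats::runif(1) < 0.5) {
          # wrong hand: sites invert and the set now obeys the
          # enantiomorph group, so per-site images must come from it
          all_xyz <- (-all_xyz) %% 1
          grp <- expand_ops(sg$enantiomorph)
        }
        sh <- shifts[sample.int(nrow(shifts), 1), ]
        all_xyz <- sweep(all_xyz, 2, sh, "+") %% 1
        opi <- sample.int(length(grp$ops), nrow(all_xyz), replace = TRUE)
        for (j in seq_len(nrow(all_xyz))) {
          op <- grp$ops[[opi[j]]]
          all_xyz[j, ] <- (op$R %*% all_xyz[j, ] + op$t / 12) %% 1
        }
      }
      sol <- data.frame(x = all_xyz[, 1], y = all_xyz[, 2], z = all_xyz[, 3],
                        occ = c(occ_t, occ_d),
                        disulfide = FALSE)
      sol <- sol[order(-sol$occ), ]
      rownames(sol) <- NULL
      attr(sol, "cc_all") <- NA_real_
      attr(sol, "cc_weak") <- NA_real_
      sol
    })
  })
}
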