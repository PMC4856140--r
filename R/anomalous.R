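# Anomalous-signal analysis: Bijvoet differences, anomalous difference
# Patterson and Fourier maps by direct summation, S_ano and CC_map.

#' Bijvoet amplitude differences from an anomalous merge
#'
#' Converts intensities to amplitudes by square-root truncation
#' (`F = sqrt(max(I, 0))`), forms `dF = F+ - F-` for acentric reflections
#' with both mates observed, and attaches model phases when available.
#' The summary `<|dF|>/<F>` (percent) is the usual measure of the
#' anomalous signal; native-sulfur signals sit around 1-2 percent.
#'
#' @param merged An anomalous `sfx_merged`.
#' @param phases Optional data frame (h, k, l, phi, radians) of model
#'   phases on the same unique representatives (e.g. from
#'   `sfx_ground_truth$refl`).
#' @return Data frame of class `sfx_deltas`: h, k, l, d, dF, F_mean, phi,
#'   weight; attribute `ratio_pct`.
#' @export
bijvoet_deltas <- function(merged, phases = NULL) {
  bp <- bijvoet_pairs(merged)
  if (nrow(bp) == 0) stop("no complete Bijvoet pairs")
  Fp <- sqrt(pmax(bp$I_plus, 0)); Fm <- sqrt(pmax(bp$I_minus, 0))
  out <- data.frame(h = bp$h, k = bp$k, l = bp$l, d = bp$d,
                    dF = Fp - Fm, F_mean = (Fp + Fm) / 2,
                    phi = NA_real_, weight = 1)
  if (!is.null(phases)) {
    key <- encode_hkl(as.matrix(out[, c("h", "k", "l")]))
    pk <- encode_hkl(as.matrix(phases[, c("h", "k", "l")]))
    out$phi <- phases$phi[match(key, pk)]
  }
  ratio <- 100 * mean(abs(out$dF)) / mean(out$F_mean)
  structure(out, ratio_pct = ratio, cell = attr(merged, "cell"),
            sg = attr(merged, "sg"),
            class = c("sfx_deltas", "data.frame"))
}

#' Expected cross-peak count in an anomalous difference Patterson map
#'
#' For n substructure sites in the asymmetric unit there are `n (n - 1)`
#' ordered non-null inter-site difference vectors, hence that many unique
#' cross-peaks to disentangle (272 for a 17-site sulfur substructure).
#'
#' @param n_sites Number of sites (>= 0).
#' @return Integer peak count.
#' @export
count_patterson_cross_peaks <- function(n_sites) {
  if (n_sites < 0) stop("n_sites must be >= 0")
  as.integer(n_sites) * (as.integer(n_sites) - 1L)
}

# Direct cosine summation of sum_i coef_i * cos(2*pi*H_i.x - phase_i) on a
# fractional grid, chunked to bound memory.
direct_sum_grid <- function(H, coef, phase, dims, chunk = 8192) {
  grid <- as.matrix(expand.grid(x = (seq_len(dims[1]) - 1) / dims[1],
                                y = (seq_len(dims[2]) - 1) / dims[2],
                                z = (seq_len(dims[3]) - 1) / dims[3]))
  vals <- numeric(nrow(grid))
  for (start in seq(1, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(grid))
    A <- 2 * pi * (H %*% t(grid[idx, , drop = FALSE])) - phase
    vals[idx] <- colSums(coef * cos(A))
  }
  array(vals, dim = dims)
}

# Expand unique reflections over the rotation group.  Structure-factor
# phases follow phi(hR) = phi(h) - 2*pi*h.t; intensity-like coefficients
# (Patterson) are translation-invariant and keep phase 0
# (`transform_phase = FALSE`).  Duplicated images (special reflections)
# are kept once.
expand_for_map <- function(H, coef, phase, sg, friedel = FALSE,
                           transform_phase = TRUE) {
  Hs <- NULL; cs <- NULL; ps <- NULL
  for (op in sg$ops) {
    Hi <- H %*% op$R
    pi_ <- if (transform_phase)
      phase - 2 * pi * drop(H %*% op$t) / 12 else phase
    Hs <- rbind(Hs, Hi); cs <- c(cs, coef); ps <- c(ps, pi_)
  }
  if (friedel) {
    Hs <- rbind(Hs, -Hs); cs <- c(cs, cs); ps <- c(ps, -ps)
  }
  key <- paste(Hs[, 1], Hs[, 2], Hs[, 3])
  keep <- !duplicated(key)
  list(H = Hs[keep, , drop = FALSE], coef = cs[keep], phase = ps[keep])
}

new_map <- function(values, cell, dims, kind) {
  structure(list(cell = cell, dims = dims, values = values, kind = kind),
            class = "sfx_map")
}

#' @export
print.sfx_map <- function(x, ...) {
  cat(sprintf("%s map on %dx%dx%d grid; range [%.3g, %.3g]\n", x$kind,
              x$dims[1], x$dims[2], x$dims[3], min(x$values),
              max(x$values)))
  invisible(x)
}

#' Anomalous difference Patterson map
#'
#' `P(u) = sum w dF^2 cos(2 pi h.u)` accumulated by direct summation over
#' the symmetry-expanded reflection set (desk-scale reflection counts make
#' direct summation exact and dependency-free).  The origin peak is the
#' maximum and the map is centrosymmetric.
#'
#' @param deltas An `sfx_deltas` (needs >= 10 reflections).
#' @param dims Grid dimensions c(nx, ny, nz).
#' @return An `sfx_map` of kind "patterson".
#' @export
patterson_map <- function(deltas, dims = c(24, 24, 24)) {
  if (nrow(deltas) < 10) stop("need at least 10 reflections")
  sg <- attr(deltas, "sg")
  H <- as.matrix(deltas[, c("h", "k", "l")])
  ex <- expand_for_map(H, deltas$weight * deltas$dF^2,
                       rep(0, nrow(H)), sg, friedel = TRUE,
                       transform_phase = FALSE)
  vals <- direct_sum_grid(ex$H, ex$coef, ex$phase, dims)
  new_map(vals, attr(deltas, "cell"), dims, "patterson")
}

#' Anomalous difference Fourier map
#'
#' `rho(x) = sum w dF cos(2 pi h.x - (phi_calc - pi/2))` by direct
#' summation over the symmetry-expanded set (signed Bijvoet difference
#' `dF = F+ - F-`), normalized to zero mean and unit RMS so values read
#' in sigma units.  The `-90 degree` phase offset places anomalous
#' scatterers at positive peaks.
#'
#' @param deltas An `sfx_deltas` with phases.
#' @param dims Grid dimensions.
#' @return An `sfx_map` of kind "difference_fourier".
#' @export
difference_fourier <- function(deltas, dims = c(24, 24, 24)) {
  if (any(is.na(deltas$phi))) stop("model phases required")
  sg <- attr(deltas, "sg")
  H <- as.matrix(deltas[, c("h", "k", "l")])
  ex <- expand_for_map(H, deltas$weight * deltas$dF,
                       deltas$phi - pi / 2, sg, friedel = FALSE)
  vals <- direct_sum_grid(ex$H, ex$coef, ex$phase, dims)
  s <- stats::sd(as.vector(vals))
  if (s > 0) vals <- (vals - mean(vals)) / s   # flat (null-signal) maps stay 0
  new_map(vals, attr(deltas, "cell"), dims, "difference_fourier")
}

# Periodic trilinear interpolation of a fractional-grid map.
map_interpolate <- function(map, xyz) {
  xyz <- as_hkl_matrix(xyz) %% 1
  dims <- map$dims
  out <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    g <- xyz[i, ] * dims
    i0 <- floor(g); f <- g - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      idx <- (c(i0[1] + dx, i0[2] + dy, i0[3] + dz) %% dims) + 1
      acc <- acc + w * map$values[idx[1], idx[2], idx[3]]
    }
    out[i] <- acc
  }
  out
}

#' Average anomalous peak height at substructure sites
#'
#' Mean trilinearly interpolated map value (sigma units for a normalized
#' difference Fourier) over the given fractional sites, reduced mod 1.
#'
#' @param map An `sfx_map`.
#' @param sites Matrix or data frame of fractional coordinates (x, y, z).
#' @return S_ano value.
#' @export
s_ano <- function(map, sites) {
  if (is.data.frame(sites)) sites <- as.matrix(sites[, c("x", "y", "z")])
  mean(map_interpolate(map, sites))
}

#' Correlation between two maps
#'
#' Pearson correlation over grid values; the grids must agree.
#'
#' @param map1,map2 `sfx_map` objects on identical grids.
#' @return Value in [-1, 1].
#' @export
map_correlation <- function(map1, map2) {
  if (!all(map1$dims == map2$dims)) stop("grid dimension mismatch")
  stats::cor(as.vector(map1$values), as.vector(map2$values))
}

#' Grid peaks of a map
#'
#' Local maxima (26-neighbourhood, periodic) above a height threshold.
#'
#' @param map An `sfx_map`.
#' @param min_height Minimum peak height.
#' @return Data frame x, y, z (fractional), height, sorted by height.
#' @export
map_peaks <- function(map, min_height = -Inf) {
  v <- map$values; d <- map$dims
  sh <- function(arr, s) {
    idx <- lapply(1:3, function(a) ((seq_len(d[a]) - 1 + s[a]) %% d[a]) + 1)
    arr[idx[[1]], idx[[2]], idx[[3]]]
  }
  ismax <- v >= min_height
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx | dy | dz) ismax <- ismax & (v >= sh(v, c(dx, dy, dz)))
  }
  w <- which(ismax, arr.ind = TRUE)
  out <- data.frame(x = (w[, 1] - 1) / d[1], y = (w[, 2] - 1) / d[2],
                    z = (w[, 3] - 1) / d[3], height = v[w])
  out[order(-out$height), ]
}

#' Write a map as a plain-text grid dump
#'
#' Header lines carry the cell and grid dims; values follow in Fortran
#' (x fastest) order, one per line.
#'
#' @param map An `sfx_map`.
#' @param path Output file.
#' @export
write_map_text <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  cl <- map$cell
  writeLines(c(sprintf("# kind %s", map$kind),
               sprintf("# cell %.4f %.4f %.4f %.2f %.2f %.2f",
                       cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
               sprintf("# dims %d %d %d", map$dims[1], map$dims[2],
                       map$dims[3]),
               format(as.vector(map$values), digits = 8)), con)
  invisible(path)
}
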