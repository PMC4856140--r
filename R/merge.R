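# Monte Carlo merging of still intensities with two-pass per-image scaling.

# Collapse an observation table to per-key sums via rowsum(); keys are
# integer-encoded (hkl, class) identifiers.
encode_hkl <- function(H, sign = NULL, base = 1024) {
  key <- ((H[, 1] + base / 2) * base + (H[, 2] + base / 2)) * base +
    (H[, 3] + base / 2)
  if (!is.null(sign)) key <- key * 4 + match(sign, c("0", "+", "-"))
  key
}

#' Merge still observations without scaling
#'
#' Monte Carlo merging: the merged intensity of a unique reflection is the
#' unweighted mean of its observations (per Bijvoet class when
#' `anomalous`), its sigma the standard error of that mean (the single
#' observation's own sigma at multiplicity 1).  Images are split into two
#' half-sets by parity of their position in a seeded shuffle, and per-half
#' means are carried for half-dataset statistics.
#'
#' @param obs Observation data frame (image_id, h, k, l, I, sigma) or an
#'   `sfx_still_set`.
#' @param cell,sg Crystal form (taken from the still set when given).
#' @param anomalous Keep Bijvoet mates separate (centrics always form a
#'   single class).
#' @param half_seed Seed of the half-set shuffle.
#' @return Data frame of class `sfx_merged`: h, k, l (unique
#'   representative), sign ("+", "-", "0"), d, I, sigma, mult, I1, n1,
#'   I2, n2; attributes `cell`, `sg`, `anomalous`.
#' @export
merge_unscaled <- function(obs, cell = NULL, sg = NULL, anomalous = TRUE,
                           half_seed = 1) {
  if (inherits(obs, "sfx_still_set")) {
    cell <- obs$cell; sg <- obs$sg; obs <- obs$obs
  }
  if (is.null(obs) || nrow(obs) == 0) stop("empty observation table")
  H <- as.matrix(obs[, c("h", "k", "l")])
  m <- map_to_asu(H, sg, anomalous = anomalous)
  sgn <- if (anomalous) m$sign else rep("0", nrow(H))
  key <- encode_hkl(m$hkl, sgn)

  ids <- sort(unique(obs$image_id))
  half <- with_seed(half_seed, sample(ids))
  half <- stats::setNames(seq_along(half) %% 2 + 1L, half)[as.character(obs$image_id)]

  f <- factor(key)
  n <- as.vector(rowsum(rep(1, nrow(obs)), f))
  s1 <- as.vector(rowsum(obs$I, f))
  ssig <- as.vector(rowsum(obs$sigma, f))
  Imean <- s1 / n
  # centered two-pass variance (avoids catastrophic cancellation)
  resid <- obs$I - Imean[as.integer(f)]
  s2c <- as.vector(rowsum(resid^2, f))
  sdv <- sqrt(s2c / pmax(n - 1, 1))
  sig <- ifelse(n >= 2, sdv / sqrt(n), ssig)

  h1 <- half == 1
  n1 <- as.vector(rowsum(as.numeric(h1), f))
  sA <- as.vector(rowsum(ifelse(h1, obs$I, 0), f))
  n2 <- n - n1
  sB <- s1 - sA

  first <- !duplicated(key)
  ord <- match(levels(f), as.character(key[first]))
  uh <- m$hkl[first, , drop = FALSE][ord, , drop = FALSE]
  out <- data.frame(h = uh[, 1], k = uh[, 2], l = uh[, 3],
                    sign = sgn[first][ord],
                    d = d_spacing(uh, cell),
                    I = Imean, sigma = sig, mult = n,
                    I1 = ifelse(n1 > 0, sA / pmax(n1, 1), NA_real_), n1 = n1,
                    I2 = ifelse(n2 > 0, sB / pmax(n2, 1), NA_real_), n2 = n2)
  out <- out[order(-out$d, out$h, out$k, out$l, out$sign), ]
  rownames(out) <- NULL
  structure(out, cell = cell, sg = sg, anomalous = anomalous,
            class = c("sfx_merged", "data.frame"))
}

#' Per-image scale factors against a reference merge
#'
#' For every image, the scale is the sum-ratio s = sum(I_ref) / sum(I_obs)
#' over the reflections the image shares with the reference (Friedel mates
#' merged, so scales are not biased by the anomalous signal), together
#' with the Pearson correlation between the image's intensities and the
#' reference.  Images with non-positive intensity sums or too few common
#' reflections are flagged unusable.
#'
#' @param obs Observation data frame or `sfx_still_set`.
#' @param reference An `sfx_merged` produced with `anomalous = FALSE`.
#' @param min_common Minimum number of common reflections (default 10).
#' @param form `"sum_ratio"` (default) or `"ratio_mean"` (mean of
#'   per-reflection ratios I_ref/I_obs).
#' @return Data frame of class `scale_records`: image_id, s, n_used, cc,
#'   usable.
#' @export
image_scale <- function(obs, reference, min_common = 10,
                        form = c("sum_ratio", "ratio_mean")) {
  form <- match.arg(form)
  if (inherits(obs, "sfx_still_set")) obs <- obs$obs
  sg <- attr(reference, "sg")
  m <- map_to_asu(as.matrix(obs[, c("h", "k", "l")]), sg, anomalous = FALSE)
  key <- encode_hkl(m$hkl)
  rkey <- encode_hkl(as.matrix(reference[, c("h", "k", "l")]))
  Iref <- reference$I[match(key, rkey)]
  okc <- !is.na(Iref)

  f <- factor(obs$image_id[okc])
  x <- obs$I[okc]; y <- Iref[okc]
  n <- as.vector(rowsum(rep(1, length(x)), f))
  sx <- as.vector(rowsum(x, f)); sy <- as.vector(rowsum(y, f))
  sxx <- as.vector(rowsum(x^2, f)); syy <- as.vector(rowsum(y^2, f))
  sxy <- as.vector(rowsum(x * y, f))
  cc <- (n * sxy - sx * sy) /
    sqrt(pmax(n * sxx - sx^2, 0) * pmax(n * syy - sy^2, 0))
  s <- if (form == "sum_ratio") sy / sx else
    as.vector(rowsum(y / x, f)) / n
  ids <- as.integer(levels(f))
  usable <- is.finite(s) & s > 0 & sx > 0 & n >= min_common
  all_ids <- sort(unique(obs$image_id))
  idx <- match(all_ids, ids)
  out <- data.frame(image_id = all_ids,
                    s = s[idx], n_used = ifelse(is.na(idx), 0L, n[idx]),
                    cc = cc[idx],
                    usable = !is.na(idx) & usable[idx])
  class(out) <- c("scale_records", class(out))
  out
}

#' Two-pass scaled Monte Carlo merge
#'
#' Pass 1 merges all observations unscaled (Friedel mates together) to
#' form a reference; per-image scales are derived against it, renormalized
#' to geometric mean 1, applied to the observations, and the scaled
#' observations are re-merged (Bijvoet mates separate when `anomalous`).
#' Additional iterations re-derive the scales against the updated
#' reference.
#'
#' @param still An `sfx_still_set`, or an observation data frame (then
#'   `cell` and `sg` are required).
#' @param n_iter Number of scale-derivation passes (default 1).
#' @param anomalous Keep Bijvoet classes separate in the final merge.
#' @inheritParams image_scale
#' @inheritParams merge_unscaled
#' @return List of class `sfx_scaled_merge`: `merged` (`sfx_merged`),
#'   `scales` (`scale_records`), `obs_scaled`, `n_dropped` (observations
#'   from unusable images).
#' @export
two_pass_merge <- function(still, cell = NULL, sg = NULL, n_iter = 1,
                           min_common = 10, form = "sum_ratio",
                           anomalous = TRUE, half_seed = 1) {
  if (inherits(still, "sfx_still_set")) {
    cell <- still$cell; sg <- still$sg; obs <- still$obs
  } else obs <- still
  if (length(unique(obs$image_id)) < 2) stop("need at least 2 images")
  reference <- merge_unscaled(obs, cell, sg, anomalous = FALSE,
                              half_seed = half_seed)
  cur <- obs
  scales <- NULL
  for (it in seq_len(n_iter)) {
    scales <- image_scale(obs, reference, min_common = min_common,
                          form = form)
    if (!any(scales$usable)) stop("all images flagged unusable")
    su <- scales$s
    su[scales$usable] <- su[scales$usable] /
      exp(mean(log(su[scales$usable])))
    scales$s <- su
    smap <- su[match(obs$image_id, scales$image_id)]
    keep <- scales$usable[match(obs$image_id, scales$image_id)]
    cur <- obs[keep, ]
    sc <- smap[keep]
    cur$I <- cur$I * sc
    cur$sigma <- cur$sigma * sc
    if (it < n_iter)
      reference <- merge_unscaled(cur, cell, sg, anomalous = FALSE,
                                  half_seed = half_seed)
  }
  merged <- merge_unscaled(cur, cell, sg, anomalous = anomalous,
                           half_seed = half_seed)
  structure(list(merged = merged, scales = scales, obs_scaled = cur,
                 n_dropped = nrow(obs) - nrow(cur)),
            class = "sfx_scaled_merge")
}

#' @export
print.sfx_scaled_merge <- function(x, ...) {
  cat(sprintf("scaled merge: %d unique rows, %d/%d images usable, %d obs dropped\n",
              nrow(x$merged), sum(x$scales$usable), nrow(x$scales),
              x$n_dropped))
  invisible(x)
}

#' Reject outlier observations against the merged means
#'
#' Drops observations deviating from their merged mean by more than
#' `z_max` effective sigmas (a documented z-score stand-in for a
#' Wilson-plot-based rejection).  Still observations scatter about the
#' Monte Carlo mean far beyond their counting sigma because of
#' partiality and residual scale spread, so the effective sigma combines
#' the observation's own sigma with a robust fractional spread estimated
#' from the data: `sqrt(sigma^2 + (kappa * I_merged)^2)` with `kappa` the
#' MAD of the relative residuals.  A gross spike is still caught, while
#' the bounded partiality scatter of clean data is not.
#'
#' @param obs Scaled observation data frame (image_id, h, k, l, I, sigma).
#' @param merged `sfx_merged` the observations were merged into.
#' @param z_max Rejection threshold in effective sigma units (default 4).
#' @return List with `obs` (filtered), `n_rejected`, `kappa`.
#' @export
reject_outliers <- function(obs, merged, z_max = 4) {
  sg <- attr(merged, "sg")
  anomalous <- attr(merged, "anomalous")
  m <- map_to_asu(as.matrix(obs[, c("h", "k", "l")]), sg,
                  anomalous = anomalous)
  sgn <- if (anomalous) m$sign else rep("0", nrow(obs))
  key <- encode_hkl(m$hkl, sgn)
  mkey <- encode_hkl(as.matrix(merged[, c("h", "k", "l")]), merged$sign)
  Im <- merged$I[match(key, mkey)]
  resid <- obs$I - Im
  denom <- pmax(abs(Im), 1e-6)
  kappa <- stats::mad(resid / denom, center = 0, na.rm = TRUE)
  z <- abs(resid) / sqrt(obs$sigma^2 + (kappa * denom)^2)
  drop <- !is.na(Im) & z > z_max
  list(obs = obs[!drop, ], n_rejected = sum(drop), kappa = kappa)
}

#' Select images by correlation to the merged reference
#'
#' @param scales A `scale_records` table.
#' @param cc_min Minimum Pearson correlation between an image's
#'   intensities and the merged reference.
#' @return Integer vector of selected image ids, in input order.
#' @export
select_images <- function(scales, cc_min) {
  scales$image_id[!is.na(scales$cc) & scales$cc >= cc_min]
}
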