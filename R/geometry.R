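# Geometry diagnostics and refinement from unit-cell and spot statistics.

#' Fit a Gaussian mixture to unit-cell lengths
#'
#' Fits 1..`max_components` one-dimensional Gaussian mixtures by EM and
#' selects the component count by BIC (via \pkg{mclust}, whose
#' deterministic hierarchical initialization makes the fit reproducible).
#' Multimodal cell-length histograms are the fingerprint of detector-
#' distance drift between portions of a serial data set; after per-run
#' distance refinement the pooled distribution should select one
#' component.
#'
#' @param values Numeric vector of cell lengths (Angstrom); at least 50.
#' @param max_components Maximum number of components (default 3).
#' @return Object of class `cell_mixture`: list with `n_components`,
#'   `weight`, `mean`, `sd` (per component) and `bic` (per candidate k).
#' @export
fit_cell_mixture <- function(values, max_components = 3) {
  values <- values[is.finite(values)]
  if (length(values) < 50)
    stop("need at least 50 values for a stable mixture fit")
  if (stats::sd(values) < 1e-8) {
    return(structure(list(n_components = 1L, weight = 1,
                          mean = mean(values), sd = 1e-6,
                          bic = stats::setNames(NA_real_, "1"),
                          degenerate = TRUE),
                     class = "cell_mixture"))
  }
  fit <- local({
    mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
    mclust::Mclust(values, G = 1:max_components, verbose = FALSE)
  })
  p <- fit$parameters
  sds <- sqrt(if (length(p$variance$sigmasq) == 1)
    rep(p$variance$sigmasq, fit$G) else p$variance$sigmasq)
  structure(list(n_components = fit$G, weight = as.numeric(p$pro),
                 mean = as.numeric(p$mean), sd = sds,
                 bic = apply(fit$BIC, 1, max, na.rm = TRUE),
                 degenerate = FALSE),
            class = "cell_mixture")
}

#' @export
print.cell_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d component(s)\n", x$n_components))
  for (i in seq_len(x$n_components))
    cat(sprintf("  w=%.3f mean=%.4f sd=%.4f\n", x$weight[i], x$mean[i],
                x$sd[i]))
  invisible(x)
}

#' Detect run boundaries where a cell-axis population flips
#'
#' For each run, computes the fraction of images whose chosen axis exceeds
#' `threshold`, and reports boundaries between consecutive runs where the
#' majority class flips.  This is the tabulation used to localize a
#' detector-distance change between runs.
#'
#' @param images Data frame with columns `run` and the axis column, or an
#'   `sfx_still_set`.
#' @param axis One of "a", "b", "c".
#' @param threshold Axis length threshold in Angstrom.
#' @return Data frame with columns `run_before`, `run_after` (empty when
#'   no flip or a single run).
#' @export
detect_run_changepoint <- function(images, axis = "b", threshold) {
  if (inherits(images, "sfx_still_set")) images <- images$images
  axis <- match.arg(axis, c("a", "b", "c"))
  runs <- sort(unique(images$run))
  if (length(runs) < 2)
    return(data.frame(run_before = integer(), run_after = integer()))
  frac <- vapply(runs, function(r)
    mean(images[[axis]][images$run == r] > threshold), numeric(1))
  maj <- frac > 0.5
  flip <- which(maj[-1] != maj[-length(maj)])
  data.frame(run_before = runs[flip], run_after = runs[flip + 1])
}

distance_objective <- function(images, D, ref_len) {
  L <- as.matrix(images[, c("a", "b", "c")]) * (D / images$assumed_mm)
  sqrt(mean((sweep(sweep(L, 2, ref_len), 2, ref_len, "/"))^2))
}

#' Refine the sample-to-detector distance of a run group
#'
#' Scans candidate distances D on a coarse grid (default 100 um steps)
#' and then a fine grid (default 20 um) around the coarse minimum.  A
#' candidate D rescales every apparent cell length by D/assumed; the
#' objective is the pooled standardized deviation of the rescaled lengths
#' from a reference cell (all three axes, each standardized by its
#' reference length so the long axis does not dominate).  Under the
#' proportional distance-to-cell surrogate a common rescaling leaves the
#' spread of a single run group unchanged, so the reference anchor is what
#' makes the distance identifiable; by default it is the per-axis median
#' of the input cells (returning the initial distance when there is no
#' drift), and a known target cell should be supplied to recover drift.
#'
#' @param images Data frame (columns a, b, c, assumed_mm) or
#'   `sfx_still_set`; all images must share one run group's assumed
#'   distance interpretation.
#' @param initial Initial distance in mm.
#' @param coarse_step,fine_step Scan steps in mm (defaults 0.100 and
#'   0.020).
#' @param span Half-width of the coarse scan in mm.
#' @param reference_cell Optional `unit_cell` anchoring the objective.
#' @return List with `distance` (refined, mm), `objective`,
#'   `objective_initial`, `scan` (data frame D, objective) and `images`
#'   (input with rescaled cells and `assumed_mm = distance`).
#' @export
refine_distance <- function(images, initial, coarse_step = 0.100,
                            fine_step = 0.020, span = 1,
                            reference_cell = NULL) {
  still <- NULL
  if (inherits(images, "sfx_still_set")) { still <- images; images <- images$images }
  if (span < coarse_step) stop("span must be >= coarse_step")
  ref_len <- if (is.null(reference_cell)) {
    apply(as.matrix(images[, c("a", "b", "c")]) *
            (initial / images$assumed_mm), 2, stats::median)
  } else c(reference_cell$a, reference_cell$b, reference_cell$c)

  scan1 <- seq(initial - span, initial + span, by = coarse_step)
  obj1 <- vapply(scan1, distance_objective, numeric(1),
                 images = images, ref_len = ref_len)
  if (any(!is.finite(obj1))) stop("non-finite distance objective")
  Dc <- scan1[which.min(obj1)]
  scan2 <- seq(Dc - coarse_step, Dc + coarse_step, by = fine_step)
  obj2 <- vapply(scan2, distance_objective, numeric(1),
                 images = images, ref_len = ref_len)
  # prefer the candidate closest to the initial distance on ties/flats
  best <- which(obj2 <= min(obj2) + 1e-15)
  D <- scan2[best[which.min(abs(scan2[best] - initial))]]

  fac <- D / images$assumed_mm
  images$a <- images$a * fac; images$b <- images$b * fac
  images$c <- images$c * fac
  images$assumed_mm <- D
  if (!is.null(still)) { still$images <- images; images <- still }
  list(distance = D, objective = min(obj2),
       objective_initial = distance_objective(
         if (inherits(images, "sfx_still_set")) images$images else images,
         initial, ref_len),
       scan = data.frame(D = c(scan1, scan2), objective = c(obj1, obj2)),
       images = images)
}

#' Refine detector distance per run group
#'
#' Splits images into run groups, refines each group's distance against a
#' common reference cell, and reports a per-group table mirroring a
#' refined-distance report (group, initial and refined distance,
#' objective before/after).
#'
#' @param still An `sfx_still_set` or image data frame.
#' @param groups Optional factor/vector assigning images to groups
#'   (default: the run id).
#' @param reference_cell Optional `unit_cell`; default per-axis median
#'   over all images at their current assumed distances.
#' @inheritParams refine_distance
#' @return List with `table` (one row per group) and `images` (updated).
#' @export
refine_run_distances <- function(still, groups = NULL, coarse_step = 0.100,
                                 fine_step = 0.020, span = 1,
                                 reference_cell = NULL) {
  images <- if (inherits(still, "sfx_still_set")) still$images else still
  if (is.null(groups)) groups <- images$run
  if (is.null(reference_cell)) {
    med <- apply(as.matrix(images[, c("a", "b", "c")]), 2, stats::median)
    reference_cell <- unit_cell(med[1], med[2], med[3])
  }
  tab <- NULL
  for (g in unique(groups)) {
    sel <- groups == g
    ini <- images$assumed_mm[sel][1]
    res <- refine_distance(images[sel, ], initial = ini,
                           coarse_step = coarse_step, fine_step = fine_step,
                           span = span, reference_cell = reference_cell)
    images[sel, ] <- res$images
    tab <- rbind(tab, data.frame(group = g, D_initial = ini,
                                 D_refined = res$distance,
                                 objective_initial = res$objective_initial,
                                 objective = res$objective))
  }
  if (inherits(still, "sfx_still_set")) still$images <- images else still <- images
  list(table = tab, images = still)
}

#' Refine tile metrology by rigid 2D registration
#'
#' Per tile, finds the rotation (about the tile centre) and translation
#' minimizing the sum of squared distances between predicted and observed
#' spot positions, in closed form (centroid subtraction, 2x2
#' cross-covariance, rotation from its polar decomposition).  The
#' least-squares optimum can never exceed the identity's residual, so the
#' RMS residual never increases.
#'
#' @param predicted,observed Data frames with columns tile, x, y.
#' @param tile_layout Optional data frame (tile, x0, y0) giving rotation
#'   centres; default: the centroid of each tile's predicted spots.
#' @return Data frame of class `tile_offsets`: tile, dx, dy (px), dtheta
#'   (deg), rms_before, rms_after, n.  Tiles with fewer than 3 pairs are
#'   skipped with a warning.
#' @export
refine_tiles <- function(predicted, observed, tile_layout = NULL) {
  out <- NULL
  for (tl in unique(predicted$tile)) {
    P <- as.matrix(predicted[predicted$tile == tl, c("x", "y")])
    O <- as.matrix(observed[observed$tile == tl, c("x", "y")])
    if (nrow(P) < 3 || nrow(O) != nrow(P)) {
      warning(sprintf("tile %s skipped: fewer than 3 spot pairs", tl))
      next
    }
    ctr <- if (!is.null(tile_layout) && tl %in% tile_layout$tile) {
      as.numeric(tile_layout[tile_layout$tile == tl, c("x0", "y0")])
    } else colMeans(P)
    Pc <- sweep(P, 2, ctr); Oc <- sweep(O, 2, ctr)
    # rotation from the polar decomposition of the cross-covariance
    H <- crossprod(Pc - rep(colMeans(Pc), each = nrow(Pc)),
                   Oc - rep(colMeans(Oc), each = nrow(Oc)))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rm <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
    th <- atan2(Rm[2, 1], Rm[1, 1])
    t_xy <- colMeans(Oc) - colMeans(Pc %*% t(Rm))
    fit <- Pc %*% t(Rm) + rep(t_xy, each = nrow(Pc))
    out <- rbind(out, data.frame(
      tile = tl, dx = t_xy[1], dy = t_xy[2], dtheta = th * 180 / pi,
      rms_before = sqrt(mean(rowSums((Pc - Oc)^2))),
      rms_after = sqrt(mean(rowSums((fit - Oc)^2))), n = nrow(P)))
  }
  if (is.null(out))
    out <- data.frame(tile = integer(), dx = numeric(), dy = numeric(),
                      dtheta = numeric(), rms_before = numeric(),
                      rms_after = numeric(), n = integer())
  class(out) <- c("tile_offsets", class(out))
  out
}
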