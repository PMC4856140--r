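# Consensus filtering of substructure solutions under origin/hand
# ambiguity: solutions from a dual-space solver are only defined up to an
# allowed origin shift, hand inversion (with enantiomorph switch) and
# per-site symmetry images, so recurrent sites can only be voted on after
# bringing all solutions to a common frame.

# Symmetry-aware distance matrix between two fractional site sets:
# d[i, j] = min over ops and lattice images of |op(a_i) - b_j|.
sym_dist_matrix <- function(A, B, sg, cell) {
  A <- as_hkl_matrix(A); B <- as_hkl_matrix(B)
  nA <- nrow(A); nB <- nrow(B)
  Aex <- expand_sites(A, sg)                # (nA * nops) x 3
  M <- cell_orth_matrix(cell)
  D2 <- matrix(Inf, nA, nB)
  for (j in seq_len(nB)) {
    d <- Aex - rep(B[j, ], each = nrow(Aex))
    d <- d - round(d)
    r2 <- rowSums((d %*% t(M))^2)
    D2[, j] <- apply(matrix(r2, nrow = nA), 1, min)
  }
  sqrt(D2)
}

#' Align a substructure solution to a reference
#'
#' Exhaustively searches allowed origin shifts and hand inversion (with
#' the enantiomorph switch) for the transform that matches the most
#' reference sites within `tol` Angstrom; site matching uses each site's
#' full symmetry-expanded image set, which also absorbs any global
#' symmetry operator.  Ties break on the smaller mean matched distance,
#' then enumeration order.
#'
#' @param sol,reference Data frames with columns x, y, z (and optionally
#'   occ, disulfide).
#' @param sg,cell Crystal form of the reference.
#' @param tol Matching tolerance in Angstrom.
#' @return List with `sites` (transformed solution), `transform`
#'   (list(hand, shift)), `matched_fraction`, `mean_dist`.
#' @export
align_solution <- function(sol, reference, sg, cell, tol = 1.5) {
  if (nrow(sol) == 0 || nrow(reference) == 0) stop("empty site list")
  if (tol <= 0) stop("tol must be > 0")
  shifts <- allowed_origin_shifts(sg)
  ref_xyz <- as.matrix(reference[, c("x", "y", "z")])
  best <- NULL
  for (hand in c(FALSE, TRUE)) {
    xyz <- as.matrix(sol[, c("x", "y", "z")])
    if (hand) xyz <- (-xyz) %% 1
    for (i in seq_len(nrow(shifts))) {
      cand <- sweep(xyz, 2, shifts[i, ], "+") %% 1
      D <- sym_dist_matrix(cand, ref_xyz, sg, cell)
      nearest <- apply(D, 2, min)          # per reference site
      score <- sum(nearest <= tol)
      md <- if (score > 0) mean(nearest[nearest <= tol]) else Inf
      if (is.null(best) || score > best$score ||
          (score == best$score && md < best$md - 1e-12)) {
        best <- list(score = score, md = md, hand = hand,
                     shift = shifts[i, ], cand = cand)
      }
    }
  }
  out <- sol
  out[, c("x", "y", "z")] <- best$cand
  list(sites = out,
       transform = list(hand = best$hand, shift = best$shift),
       matched_fraction = best$score / nrow(reference),
       mean_dist = best$md)
}

#' Consensus filtering of top substructure solutions
#'
#' Aligns every solution to the first (the top-ranked reference), pools
#' all sites, clusters them by single linkage at `tol` (symmetry-aware
#' distances), and keeps clusters supported by at least `min_count`
#' distinct solutions.  A cluster's position is the occupancy-weighted
#' mean of its members (mapped to the symmetry image nearest the cluster
#' anchor); it is flagged disulfide if any contributing solution marked
#' it so.
#'
#' @param solutions List of site data frames (x, y, z, occ, optionally
#'   disulfide), top-ranked first.
#' @param sg,cell Crystal form.
#' @param min_count Minimum number of supporting solutions.
#' @param tol Clustering/matching tolerance in Angstrom.
#' @return Object of class `sfx_consensus`: list with `sites` (x, y, z,
#'   occ, votes, disulfide), `transforms`, `excluded`, `tol`,
#'   `min_count`.
#' @export
consensus_filter <- function(solutions, sg, cell, min_count = 3,
                             tol = 1.5) {
  k <- length(solutions)
  if (k < 1 || min_count < 1 || min_count > k)
    stop("need k >= min_count >= 1 solutions")
  ref <- solutions[[1]]
  if (is.null(ref$disulfide)) ref$disulfide <- FALSE
  # The reference's own hand is not observable from its site list alone:
  # its coordinates may be consistent with either enantiomorph
  # interpretation.  Try both (as-is, and inverted into the declared
  # group) and keep whichever lets the other solutions match better.
  try_ref <- function(flip) {
    refc <- ref
    if (flip)
      refc[, c("x", "y", "z")] <- (-as.matrix(refc[, c("x", "y", "z")])) %% 1
    als <- lapply(seq_len(k)[-1], function(i)
      align_solution(solutions[[i]], refc, sg, cell, tol = tol))
    list(refc = refc, als = als,
         total = sum(vapply(als, `[[`, numeric(1), "matched_fraction")))
  }
  cand <- try_ref(FALSE)
  if (k > 1) {
    alt <- try_ref(TRUE)
    if (alt$total > cand$total) cand <- alt
  }
  aligned <- list(cand$refc)
  transforms <- list(list(hand = FALSE, shift = c(0, 0, 0)))
  excluded <- integer()
  for (j in seq_along(cand$als)) {
    al <- cand$als[[j]]
    if (al$matched_fraction == 0) {
      warning(sprintf("solution %d excluded: alignment failed", j + 1))
      excluded <- c(excluded, j + 1)
      next
    }
    s <- al$sites
    if (is.null(s$disulfide)) s$disulfide <- FALSE
    aligned <- c(aligned, list(s))
    transforms <- c(transforms, list(al$transform))
  }
  pool <- do.call(rbind, lapply(seq_along(aligned), function(i)
    cbind(aligned[[i]][, c("x", "y", "z", "occ", "disulfide")],
          solution = i)))
  X <- as.matrix(pool[, c("x", "y", "z")])
  D <- sym_dist_matrix(X, X, sg, cell)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "single"),
                      h = tol)
  sites <- NULL
  for (g in unique(cl)) {
    mem <- pool[cl == g, , drop = FALSE]
    votes <- length(unique(mem$solution))
    if (votes < min_count) next
    anchor <- as.numeric(mem[which.max(mem$occ), c("x", "y", "z")])
    # map each member onto the symmetry/lattice image nearest the anchor
    mapped <- t(apply(as.matrix(mem[, c("x", "y", "z")]), 1, function(p) {
      im <- expand_sites(matrix(p, 1), sg)
      d <- im - rep(anchor, each = nrow(im))
      sh <- round(d)
      j <- which.min(rowSums(((d - sh) %*% t(cell_orth_matrix(cell)))^2))
      im[j, ] - sh[j, ]
    }))
    w <- mem$occ / sum(mem$occ)
    pos <- colSums(mapped * w) %% 1
    sites <- rbind(sites, data.frame(
      x = pos[1], y = pos[2], z = pos[3],
      occ = mean(mem$occ), votes = votes,
      disulfide = any(mem$disulfide)))
  }
  if (!is.null(sites)) {
    sites <- sites[order(-sites$votes, -sites$occ), ]
    rownames(sites) <- NULL
  }
  structure(list(sites = sites, transforms = transforms,
                 excluded = excluded, tol = tol, min_count = min_count),
            class = "sfx_consensus")
}

#' @export
print.sfx_consensus <- function(x, ...) {
  n <- if (is.null(x$sites)) 0 else nrow(x$sites)
  cat(sprintf("consensus substructure: %d site(s) with >= %d votes (tol %.2f A)\n",
              n, x$min_count, x$tol))
  invisible(x)
}

#' Occupancy-gap cutoff in a ranked site list
#'
#' Returns the rank r maximizing the relative occupancy gap
#' `(occ_r - occ_{r+1}) / occ_r` over ranks in `[min_keep, n - 1]`; a
#' ranked solver solution typically shows a sharp occupancy drop after
#' the last correct site.  Flat occupancy lists return n with
#' `no_cut = TRUE`.
#'
#' @param occ Numeric vector of occupancies in rank order
#'   (non-increasing), or a site data frame with an `occ` column.
#' @param min_keep Smallest admissible cut rank (default 3).
#' @return List with `cut` (rank; sites 1..cut are kept), `gap` (the
#'   relative gap) and `no_cut`.
#' @export
occupancy_cutoff <- function(occ, min_keep = 3) {
  if (is.data.frame(occ)) occ <- occ$occ
  n <- length(occ)
  if (n < 3) stop("need at least 3 sites")
  r <- min_keep:(n - 1)
  gaps <- (occ[r] - occ[r + 1]) / occ[r]
  if (max(gaps) <= 1e-12)
    return(list(cut = n, gap = 0, no_cut = TRUE))
  best <- r[which.max(gaps)]
  list(cut = best, gap = max(gaps), no_cut = FALSE)
}

#' Expand a disulfide superatom into two half-occupancy sites
#'
#' At resolutions worse than ~2 Angstrom the two sulfurs of a disulfide
#' merge into one broad superatom; for downstream use the superatom is
#' split into two sites `separation` apart.  Superatoms carry no
#' orientation, so the split axis is a documented convention (cell a by
#' default).
#'
#' @param site One-row data frame (x, y, z, occ).
#' @param cell A `unit_cell`.
#' @param separation Sulfur-sulfur distance in Angstrom (default 2.05).
#' @param axis Cell axis along which to split ("a", "b" or "c").
#' @return Two-row data frame, coordinates reduced mod 1, each with half
#'   the occupancy.
#' @export
expand_disulfide <- function(site, cell, separation = 2.05, axis = "a") {
  axis <- match.arg(axis, c("a", "b", "c"))
  ax <- match(axis, c("a", "b", "c"))
  half <- (separation / 2) / cell[[axis]]
  out <- site[c(1, 1), , drop = FALSE]
  out[[c("x", "y", "z")[ax]]] <- (site[[c("x", "y", "z")[ax]]] +
                                    c(-half, half)) %% 1
  out$occ <- site$occ / 2
  rownames(out) <- NULL
  out
}

#' Read/write .res-style site lists
#'
#' One site per line: element label, fractional x y z, occupancy.  A JSON
#' sidecar (same path + ".json") carries disulfide flags and vote counts
#' when present.
#'
#' @param sites Data frame (x, y, z, occ, optionally label, disulfide,
#'   votes).
#' @param path Output file.
#' @return `write_res_sites`: the path, invisibly.  `read_res_sites`: a
#'   site data frame.
#' @export
write_res_sites <- function(sites, path) {
  lab <- if (!is.null(sites$label)) sites$label
  else sprintf("S%d", seq_len(nrow(sites)))
  lines <- sprintf("%-4s %9.6f %9.6f %9.6f %7.4f", lab, sites$x, sites$y,
                   sites$z, sites$occ)
  writeLines(lines, path)
  extra <- sites[, intersect(c("disulfide", "votes"), names(sites)),
                 drop = FALSE]
  if (ncol(extra))
    jsonlite::write_json(extra, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_res_sites
#' @export
read_res_sites <- function(path) {
  tok <- utils::read.table(path, col.names = c("label", "x", "y", "z",
                                               "occ"))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    extra <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(extra)) tok[[nm]] <- extra[[nm]]
  }
  tok
}
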