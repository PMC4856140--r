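#' Space-group machinery
#'
#' Minimal space-group support for the crystal systems this package
#' targets: P1 and the enantiomorph pair P41212 / P43212 (the tetragonal
#' group of thaumatin-like crystals).  Operators are stored as integer 3x3
#' rotation matrices and translation vectors in units of 1/12, so that
#' composition and closure are exact in integer arithmetic.
#'
#' @param symbol Hermann-Mauguin symbol; spaces, underscores and
#'   parentheses are ignored, so "P41212", "P 41 21 2" and "P4(1)2(1)2"
#'   are equivalent.
#' @return An object of class `space_group`: a list with `symbol`, `ops`
#'   (list of `list(R, t)` with `t` in twelfths) and `enantiomorph` (the
#'   partner symbol; the group's own symbol when self-enantiomorphic).
#' @examples
#' length(expand_ops("P41212")$ops)  # 8
#' @export
expand_ops <- function(symbol) {
  sym <- normalize_sg_symbol(symbol)
  gens <- sg_generators(sym)
  ops <- close_ops(gens)
  n_expected <- c(P1 = 1L, P41212 = 8L, P43212 = 8L)[[sym]]
  stopifnot(length(ops) == n_expected)
  enant <- switch(sym, P1 = "P1", P41212 = "P43212", P43212 = "P41212")
  structure(list(symbol = sym, ops = ops, enantiomorph = enant),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s: %d operators (enantiomorph partner %s)\n",
              x$symbol, length(x$ops), x$enantiomorph))
  invisible(x)
}

normalize_sg_symbol <- function(symbol) {
  sym <- toupper(gsub("[ _()]", "", symbol))
  supported <- c("P1", "P41212", "P43212")
  if (!sym %in% supported)
    stop(sprintf("unsupported space group '%s'; supported: %s",
                 symbol, paste(supported, collapse = ", ")))
  sym
}

sg_generators <- function(sym) {
  ident <- list(R = diag(3), t = c(0, 0, 0))
  fourfold <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), nrow = 3) # (-y, x, z)
  twofold <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), nrow = 3)  # (y, x, -z)
  gens <- switch(sym,
    P1 = list(),
    P41212 = list(list(R = fourfold, t = c(6, 6, 3)),   # 41 screw at 0,1/2
                  list(R = twofold, t = c(0, 0, 0))),
    P43212 = list(list(R = fourfold, t = c(6, 6, 9)),
                  list(R = twofold, t = c(0, 0, 0))))
  c(list(ident), gens)
}

op_key <- function(op) paste(c(op$R, op$t), collapse = ",")

compose_ops <- function(o1, o2) {
  # (R1, t1) after (R2, t2): x -> R1 (R2 x + t2/12) + t1/12
  list(R = o1$R %*% o2$R, t = (o1$R %*% o2$t + o1$t) %% 12)
}

close_ops <- function(gens) {
  ops <- list()
  seen <- character()
  queue <- gens
  while (length(queue)) {
    op <- queue[[1]]; queue <- queue[-1]
    op$t <- as.numeric(op$t) %% 12
    k <- op_key(op)
    if (k %in% seen) next
    seen <- c(seen, k)
    ops <- c(ops, list(op))
    for (o2 in ops) {
      queue <- c(queue, list(compose_ops(op, o2)), list(compose_ops(o2, op)))
    }
    if (length(ops) > 192) stop("operator closure did not terminate")
  }
  ops
}

# --- reciprocal-space mapping -----------------------------------------------

# All rotation images of row-vector indices: returns list of n x 3 matrices,
# one per operator (h' = h R).
hkl_images <- function(hkl, sg) {
  hkl <- as_hkl_matrix(hkl)
  lapply(sg$ops, function(op) hkl %*% op$R)
}

lex_score <- function(H, base) (H[, 1] * base + H[, 2]) * base + H[, 3]

#' Map reflections to the asymmetric unit
#'
#' Maps Miller indices to a unique representative under the space group's
#' Laue symmetry.  The representative is the lexicographically greatest
#' index among all rotation images of hkl and of its Friedel mate, so
#' Bijvoet mates of an acentric reflection share one representative and
#' are distinguished by `sign`: `"+"` when the input is rotation-equivalent
#' to the representative, `"-"` when its Friedel mate is, and `"0"` for
#' centric reflections (Friedel mate reachable by a rotation).
#'
#' @param hkl Matrix (n x 3) or length-3 vector of Miller indices.
#' @param sg A `space_group`.
#' @param anomalous Logical; when `FALSE` the Bijvoet sign is still
#'   reported but callers should merge both signs together.
#' @return A list with `hkl` (n x 3 matrix of unique representatives),
#'   `sign` (character: "+", "-", "0") and `centric` (logical).
#' @export
map_to_asu <- function(hkl, sg, anomalous = TRUE) {
  H <- as_hkl_matrix(hkl)
  if (any(rowSums(abs(H)) == 0)) stop("hkl (0,0,0) is not a reflection")
  base <- 2 * max(abs(H)) + 3
  bestP <- rep(-Inf, nrow(H)); bestM <- bestP
  bestPH <- H; bestMH <- -H
  for (op in sg$ops) {
    Hi <- H %*% op$R
    s <- lex_score(Hi, base)
    upd <- s > bestP
    bestP[upd] <- s[upd]; bestPH[upd, ] <- Hi[upd, , drop = FALSE]
    s <- lex_score(-Hi, base)
    upd <- s > bestM
    bestM[upd] <- s[upd]; bestMH[upd, ] <- -Hi[upd, , drop = FALSE]
  }
  centric <- bestP == bestM
  plus <- bestP >= bestM
  uni <- bestMH
  uni[plus, ] <- bestPH[plus, , drop = FALSE]
  dimnames(uni) <- NULL
  sign <- ifelse(centric, "0", ifelse(plus, "+", "-"))
  list(hkl = uni, sign = sign, centric = centric)
}

#' Centricity of reflections
#'
#' A reflection is centric when its Friedel mate is reachable by a
#' rotation of the space group; centric reflections carry no Bijvoet
#' difference.
#'
#' @inheritParams map_to_asu
#' @return Logical vector.
#' @export
is_centric <- function(hkl, sg) map_to_asu(hkl, sg)$centric

# Systematic absence: some operator fixes h (h R == h) with a translation
# whose phase 2*pi*h.t is not a multiple of 2*pi.
is_absent <- function(hkl, sg) {
  H <- as_hkl_matrix(hkl)
  out <- rep(FALSE, nrow(H))
  for (op in sg$ops) {
    Hi <- H %*% op$R
    fixed <- rowSums(abs(Hi - H)) == 0
    ph <- (H %*% op$t) %% 12
    out <- out | (fixed & ph != 0)
  }
  out
}

# Phase restriction for a centric reflection: phases are restricted to
# -psi/2 (mod pi) where psi = 2*pi*h.t for an operator sending h to -h.
centric_phase <- function(hkl, sg) {
  H <- as_hkl_matrix(hkl)
  psi <- rep(NA_real_, nrow(H))
  for (op in sg$ops) {
    Hi <- H %*% op$R
    hit <- rowSums(abs(Hi + H)) == 0 & is.na(psi)
    if (any(hit)) psi[hit] <- 2 * pi * ((H[hit, , drop = FALSE] %*% op$t) / 12)
  }
  -psi / 2
}

#' Allowed origin shifts
#'
#' Translations under which the space group's operator set is invariant:
#' conjugating every operator by the shift reproduces the set.  Heavy-atom
#' substructure solutions are only defined up to such shifts (and hand
#' inversion), so they must be searched when comparing solutions.  The
#' shifts are found by brute force over a candidate grid rather than table
#' lookup, which makes the result self-verifying.
#'
#' @param sg A `space_group`.
#' @param denom Candidate grid spacing denominator (default 4: the grid
#'   \{0, 1/4, 1/2, 3/4\}^3, sufficient for the supported groups).
#' @return Matrix (n x 3) of fractional shift vectors, including (0,0,0).
#' @export
allowed_origin_shifts <- function(sg, denom = 4L) {
  grid <- as.matrix(expand.grid(x = 0:(denom - 1), y = 0:(denom - 1),
                                z = 0:(denom - 1))) / denom
  keep <- rep(TRUE, nrow(grid))
  for (op in sg$ops) {
    # (R, v) conjugated by t becomes (R, v + (I - R) t); same set iff
    # (I - R) t is a lattice vector for every R (rotations are unique here).
    d <- grid %*% t(diag(3) - op$R)
    keep <- keep & rowSums(abs(d - round(d))) < 1e-9
  }
  out <- grid[keep, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Invert the hand of a substructure
#'
#' Negates all fractional coordinates (reducing to [0, 1)) and switches to
#' the enantiomorphic space group, self for P1.  Applying twice restores
#' the input.
#'
#' @param sites Matrix (n x 3) or data frame with columns x, y, z.
#' @param sg A `space_group`.
#' @return List with `sites` (same shape as input) and `sg`.
#' @export
invert_hand <- function(sites, sg) {
  if (is.data.frame(sites)) {
    sites[, c("x", "y", "z")] <- (-as.matrix(sites[, c("x", "y", "z")])) %% 1
    flipped <- sites
  } else {
    flipped <- (-as_hkl_matrix(sites)) %% 1
  }
  list(sites = flipped, sg = expand_ops(sg$enantiomorph))
}

# All symmetry images of fractional sites: returns (n_sites * n_ops) x 3
# matrix, ordered sites-within-op, reduced to [0, 1).
expand_sites <- function(xyz, sg) {
  xyz <- as_hkl_matrix(xyz)
  out <- do.call(rbind, lapply(sg$ops, function(op)
    (xyz %*% t(op$R) + rep(op$t / 12, each = nrow(xyz))) %% 1))
  out
}
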