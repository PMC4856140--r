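#' Unit cell
#'
#' Construct a unit cell from lengths (Angstrom) and angles (degrees).
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`: a named list with elements
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' unit_cell(58.6, 58.6, 151.3)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("cell lengths must be finite and > 0")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' Tetragonal unit cell
#'
#' Convenience constructor enforcing the tetragonal constraints a == b and
#' all angles 90 degrees.
#'
#' @param a Length of the a (= b) axis in Angstrom.
#' @param c Length of the c axis in Angstrom.
#' @return A `unit_cell`.
#' @export
tetragonal_cell <- function(a, c) unit_cell(a, a, c, 90, 90, 90)

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f A  alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# Orthogonalization matrix (columns are the cell basis vectors in a
# Cartesian frame, standard PDB convention).
cell_orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3)
}

#' Resolution (d-spacing) of reflections
#'
#' @param hkl Integer matrix (n x 3) or length-3 vector of Miller indices.
#' @param cell A `unit_cell`.
#' @return Numeric vector of d-spacings in Angstrom.
#' @export
d_spacing <- function(hkl, cell) {
  hkl <- as_hkl_matrix(hkl)
  M <- cell_orth_matrix(cell)
  Gstar <- solve(crossprod(M))        # reciprocal metric tensor
  q <- rowSums((hkl %*% Gstar) * hkl) # |h*|^2
  1 / sqrt(q)
}

as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  storage.mode(hkl) <- "double"
  hkl
}

# Minimum-image Cartesian distance between fractional coordinates.
# Per-axis minimum imaging is exact for orthogonal cells, which covers the
# tetragonal systems this package targets.
frac_dist <- function(x, y, cell) {
  d <- as_hkl_matrix(x) - as_hkl_matrix(y)
  d <- d - round(d)
  M <- cell_orth_matrix(cell)
  sqrt(rowSums((d %*% t(M))^2))
}
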