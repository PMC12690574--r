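# Package-wide physical conventions: coordinates in Angstrom, energies in
# kcal/mol, charges in elementary units (AMBER-style electrostatics).

#' Coulomb constant used package-wide
#'
#' Electrostatic conversion factor in kcal*Angstrom/(mol*e^2), the AMBER
#' convention.
#' @export
COULOMB_CONST <- 332.0637

# van der Waals / intrinsic GB radii by element (Angstrom), mbondi-style
.element_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.50, S = 1.80, P = 1.85,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 1.20, K = 1.50,
  MG = 1.18, ZN = 1.10, FE = 1.30
)

# HCT pairwise-descreening scaling factors by element
.hct_scale <- c(
  H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96, P = 0.86,
  F = 0.88, CL = 0.80, BR = 0.80, I = 0.80
)
.hct_scale_default <- 0.80

element_radius <- function(element) {
  el <- toupper(element)
  r <- .element_radii[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop("no atomic radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

hct_scale_factor <- function(element) {
  s <- .hct_scale[toupper(element)]
  s[is.na(s)] <- .hct_scale_default
  unname(s)
}

# Minimum distance between each row of `a` (n x 3) and any row of `b` (m x 3)
cross_min_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

# Full pairwise distance matrix between two coordinate sets
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite")
  invisible(x)
}
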