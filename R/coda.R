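#' @importFrom rlang .data
NULL

# Coerce input to an r x 3 numeric matrix (one composition per row).
.as_comp_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, seq_len(3)])
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  if (ncol(x) != 3L) stop("compositions here have exactly 3 parts", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Closure of a 3-part composition
#'
#' Divides each nonnegative part by the row total so the parts sum to one,
#' placing the vector on the simplex S^3 — the common carrier of both the
#' IBS proportions `(p0, p1, p2)` and the Cotterman coefficients
#' `(k0, k1, k2)`.
#'
#' @param x a length-3 vector, or a matrix/data frame with one composition
#'   per row (3 columns).
#' @return A matrix of closed compositions (same number of rows as `x`).
#' @export
closure <- function(x) {
  x <- .as_comp_matrix(x)
  if (any(x < 0)) stop("parts must be nonnegative", call. = FALSE)
  tot <- rowSums(x)
  if (any(tot <= 0)) stop("cannot close an all-zero composition", call. = FALSE)
  x / tot
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts with the small value `delta = 0.5 / m`, half the
#' smallest nonzero proportion observable from `m` loci, and rescales the
#' nonzero parts by `1 - z * delta` (`z` = number of zeros) so the result is
#' still closed. Needed before log-ratio transforms, whose coordinates
#' diverge to infinity when a part is exactly zero.
#'
#' @param x composition(s), as in [closure()].
#' @param m number of informative loci behind the composition (`m >= 1`);
#'   may be a vector with one value per row.
#' @return A matrix of closed, strictly positive compositions.
#' @export
replace_zeros <- function(x, m) {
  x <- closure(x)
  if (any(m < 1)) stop("`m` must be >= 1", call. = FALSE)
  delta <- 0.5 / m
  z <- rowSums(x == 0)
  out <- x * (1 - z * delta)
  out[x == 0] <- (delta + numeric(nrow(x)))[which(x == 0, arr.ind = TRUE)[, 1]]
  out
}

# Part permutation (A, B, C) per ilr basis: coordinates are
#   zb1 = ln(B/A)/sqrt(2),  zb2 = ln(A*B/C^2)/sqrt(6)
.ilr_parts <- function(basis) {
  switch(basis,
    z0 = c(A = 2L, B = 3L, C = 1L),  # (ln(p2/p1)/sqrt2, ln(p1 p2 / p0^2)/sqrt6)
    z1 = c(A = 1L, B = 3L, C = 2L),  # (ln(p2/p0)/sqrt2, ln(p0 p2 / p1^2)/sqrt6)
    z2 = c(A = 1L, B = 2L, C = 3L),  # (ln(p1/p0)/sqrt2, ln(p0 p1 / p2^2)/sqrt6)
    stop("basis must be one of 'z0', 'z1', 'z2'", call. = FALSE)
  )
}

#' Isometric log-ratio coordinates of a 3-part composition
#'
#' Maps compositions to the plane with one of the three commonly used ilr
#' bases. For basis `z1`, the coordinates of `(c0, c1, c2)` are
#' `z11 = ln(c2/c0)/sqrt(2)` and `z12 = ln(c0*c2/c1^2)/sqrt(6)`; bases `z0`
#' and `z2` permute the parts analogously. Euclidean distances between ilr
#' images equal Aitchison distances and are identical in all three bases.
#'
#' Compositions with zero parts have no finite image: the coordinates tend
#' to infinity. Rather than returning raw infinities, such rows are flagged
#' `finite = FALSE` and annotated with the unit direction in which the image
#' escapes (used to draw arrows at the frame edge). Apply [replace_zeros()]
#' first if a finite surrogate is wanted.
#'
#' @param x composition(s), as in [closure()]; will be closed.
#' @param basis `"z0"`, `"z1"` or `"z2"`.
#' @return A tibble with columns `zb1`, `zb2`, `finite`, `dir1`, `dir2` (the
#'   direction is `NA` for finite rows).
#' @export
ilr <- function(x, basis = "z1") {
  p <- .ilr_parts(basis)
  x <- closure(x)
  A <- x[, p["A"]]; B <- x[, p["B"]]; C <- x[, p["C"]]
  z1 <- log(B / A) / sqrt(2)
  z2 <- log(A * B / C^2) / sqrt(6)
  finite <- is.finite(z1) & is.finite(z2)
  d1 <- d2 <- rep(NA_real_, nrow(x))
  if (any(!finite)) {
    # direction of divergence: substitute eps for the zero parts; the
    # coordinates grow linearly in -log(eps) with these coefficients
    eA <- as.numeric(A == 0); eB <- as.numeric(B == 0); eC <- as.numeric(C == 0)
    v1 <- (eA - eB) / sqrt(2)
    v2 <- (2 * eC - eA - eB) / sqrt(6)
    nrm <- sqrt(v1^2 + v2^2)
    bad <- !finite
    d1[bad] <- (v1 / nrm)[bad]
    d2[bad] <- (v2 / nrm)[bad]
    z1[bad] <- NA_real_
    z2[bad] <- NA_real_
  }
  tibble::tibble(zb1 = z1, zb2 = z2, finite = finite, dir1 = d1, dir2 = d2)
}

#' Inverse ilr transform
#'
#' Recovers the unique closed composition whose ilr image (in the given
#' basis) is `z`; `ilr(ilr_inverse(z)) == z` to 1e-10.
#'
#' @param z a length-2 vector or a 2-column matrix/data frame of finite ilr
#'   coordinates.
#' @param basis `"z0"`, `"z1"` or `"z2"`.
#' @return A matrix of closed compositions.
#' @export
ilr_inverse <- function(z, basis = "z1") {
  if (is.data.frame(z)) z <- as.matrix(z[, 1:2])
  if (is.null(dim(z))) z <- matrix(as.numeric(z), nrow = 1)
  if (ncol(z) != 2L) stop("ilr coordinates have 2 components", call. = FALSE)
  if (!all(is.finite(z))) stop("finite coordinates required", call. = FALSE)
  p <- .ilr_parts(basis)
  # invert: ln B - ln A = sqrt2 z1 ; ln A + ln B - 2 ln C = sqrt6 z2; fix ln C = 0
  lnA <- (sqrt(6) * z[, 2] - sqrt(2) * z[, 1]) / 2
  lnB <- (sqrt(6) * z[, 2] + sqrt(2) * z[, 1]) / 2
  out <- matrix(0, nrow(z), 3)
  out[, p["A"]] <- exp(lnA - pmax(lnA, lnB, 0))
  out[, p["B"]] <- exp(lnB - pmax(lnA, lnB, 0))
  out[, p["C"]] <- exp(-pmax(lnA, lnB, 0))
  closure(out)
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance between ilr images; invariant (to 1e-10) to which
#' of the three bases computes it.
#'
#' @param a,b strictly positive 3-part compositions (apply [replace_zeros()]
#'   first if needed).
#' @param basis basis used for the computation (the result does not depend
#'   on it).
#' @return A nonnegative number (vector when `a`/`b` have multiple rows).
#' @export
aitchison_distance <- function(a, b, basis = "z1") {
  a <- closure(a); b <- closure(b)
  if (any(a == 0) || any(b == 0)) {
    stop("zero parts: apply replace_zeros() before taking Aitchison distances",
         call. = FALSE)
  }
  za <- ilr(a, basis); zb <- ilr(b, basis)
  sqrt((za$zb1 - zb$zb1)^2 + (za$zb2 - zb$zb2)^2)
}

#' Cartesian coordinates for a ternary diagram
#'
#' Barycentric-to-Cartesian map with vertex convention: part 1 (`c0`) at the
#' bottom-left origin, part 2 (`c1`) at (1, 0), part 3 (`c2`) at the apex
#' `(1/2, sqrt(3)/2)`.
#'
#' @param x closed composition(s), as in [closure()].
#' @return A tibble with columns `x`, `y`.
#' @export
ternary_xy <- function(x) {
  x <- closure(x)
  cx <- x[, 2] + 0.5 * x[, 3]
  cy <- sqrt(3) / 2 * x[, 3]
  tibble::tibble(x = cx, y = cy)
}

#' Boundary of the non-inbred feasible region
#'
#' Under absence of inbreeding the Cotterman coefficients obey Thompson's
#' inequality `k1^2 >= 4 k0 k2`, which carves an arrowhead out of the
#' ternary diagram. Its curved lower boundary `k1^2 = 4 k0 k2` is exactly
#' the Hardy-Weinberg parabola `k = (s^2, 2 s (1 - s), (1 - s)^2)`, swept
#' here uniformly in `s` from `(0, 0, 1)` to `(1, 0, 0)`; `k1` peaks at 1/2
#' in the middle point `(1/4, 1/2, 1/4)` (the full-sib reference).
#'
#' @param resolution number of points on the curve (`>= 2`).
#' @return A tibble with columns `k0`, `k1`, `k2`; each row satisfies the
#'   boundary equality to 1e-10.
#' @export
feasible_boundary <- function(resolution = 201) {
  if (resolution < 2) stop("`resolution` must be >= 2", call. = FALSE)
  s <- seq(0, 1, length.out = resolution)
  tibble::tibble(k0 = s^2, k1 = 2 * s * (1 - s), k2 = (1 - s)^2)
}

#' Ceiling of the second ilr coordinate on the feasible boundary
#'
#' Along the whole curve `k1^2 = 4 k0 k2` the second `z1` coordinate is the
#' constant `ln(1/4)/sqrt(6) = -(2/sqrt(6)) ln 2 ~ -0.566`: the horizontal
#' upper limit of the feasible region in the `z1` ilr plot.
#'
#' @return A number.
#' @export
ilr_feasible_ceiling <- function() log(1 / 4) / sqrt(6)
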