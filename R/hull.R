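#' Convex hull of a 2D point set (Andrew monotone chain)
#'
#' Computes the unique convex polygon whose vertices are input points and
#' that contains all input points, in `O(n log n)` by Andrew's monotone
#' chain: sort lexicographically, build lower and upper chains dropping
#' non-left turns. Vertices are returned counter-clockwise starting from
#' the lexicographically smallest point. Degenerate inputs (all points
#' collinear, or fewer than three distinct points) give a flagged segment
#' or single point.
#'
#' @param x,y point coordinates; alternatively `x` may be a 2-column
#'   matrix/data frame.
#' @return An object of class `convex_hull`: list with `vertices` (tibble
#'   `x`, `y`, counter-clockwise), `degenerate` (logical) and `n_points`.
#' @export
convex_hull <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- if (is.data.frame(x)) as.matrix(x[, 1:2]) else x
    x <- m[, 1]; y <- m[, 2]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) stop("no finite points to hull", call. = FALSE)
  pts <- unique(cbind(x, y)[order(x, y), , drop = FALSE])
  n <- nrow(pts)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(ord) {
    h <- integer(0)
    for (i in ord) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  if (n <= 2L) {
    v <- tibble::tibble(x = pts[, 1], y = pts[, 2])
    return(structure(list(vertices = v, degenerate = TRUE, n_points = length(x)),
                     class = "convex_hull"))
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  idx <- c(lower[-length(lower)], upper[-length(upper)])
  degen <- length(idx) < 3L
  if (degen) idx <- unique(c(lower, upper))
  v <- tibble::tibble(x = pts[idx, 1], y = pts[idx, 2])
  structure(list(vertices = v, degenerate = degen, n_points = length(x)),
            class = "convex_hull")
}

#' @export
print.convex_hull <- function(x, ...) {
  cat(sprintf("<convex_hull> %d vertices from %d points%s\n",
              nrow(x$vertices), x$n_points,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Do all points lie inside (or on) a convex hull?
#'
#' @param hull a `convex_hull`.
#' @param x,y points to test (or `x` a 2-column matrix).
#' @param tol tolerance on the half-plane tests.
#' @return Logical vector.
#' @export
in_hull <- function(hull, x, y = NULL, tol = 1e-9) {
  if (is.null(y)) {
    m <- if (is.data.frame(x)) as.matrix(x[, 1:2]) else x
    x <- m[, 1]; y <- m[, 2]
  }
  v <- as.matrix(hull$vertices)
  n <- nrow(v)
  if (n < 3L) {
    # segment/point: distance to the segment must be ~0
    if (n == 1L) return(abs(x - v[1, 1]) < tol & abs(y - v[1, 2]) < tol)
    d <- v[2, ] - v[1, ]
    t <- pmin(pmax(((x - v[1, 1]) * d[1] + (y - v[1, 2]) * d[2]) / sum(d^2), 0), 1)
    return(sqrt((x - v[1, 1] - t * d[1])^2 + (y - v[1, 2] - t * d[2])^2) < tol)
  }
  inside <- rep(TRUE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    inside <- inside &
      ((v[j, 1] - v[i, 1]) * (y - v[i, 2]) - (v[j, 2] - v[i, 2]) * (x - v[i, 1]) >= -tol)
  }
  inside
}

#' Do two convex hulls intersect?
#'
#' Separating-axis test for convex polygons (edge normals of both hulls as
#' candidate axes). Degenerate hulls (segments, points) are handled as
#' their (possibly flat) vertex sets.
#'
#' @param h1,h2 `convex_hull` objects.
#' @param tol numeric slack on the axis projections.
#' @return `TRUE` if the hulls overlap or touch, `FALSE` if a separating
#'   axis exists.
#' @export
hulls_intersect <- function(h1, h2, tol = 1e-12) {
  a <- as.matrix(h1$vertices); b <- as.matrix(h2$vertices)
  axes <- function(v) {
    n <- nrow(v)
    if (n < 2L) return(matrix(numeric(0), 0, 2))
    e <- v[c(seq_len(n)[-1], 1L), , drop = FALSE] - v
    cbind(-e[, 2], e[, 1])
  }
  ax <- rbind(axes(a), axes(b))
  if (nrow(ax) == 0L) {  # two single points
    return(all(abs(a[1, ] - b[1, ]) < tol))
  }
  for (i in seq_len(nrow(ax))) {
    pa <- a %*% ax[i, ]; pb <- b %*% ax[i, ]
    if (max(pa) < min(pb) - tol || max(pb) < min(pa) - tol) return(FALSE)
  }
  TRUE
}

#' Map pair statistics into a plot coordinate system
#'
#' The shared transform layer behind hulls and plots: turns a tibble of
#' per-pair statistics (from [ibs_pairs()], [ibd_pairs()] or
#' [simulate_pairs()]) into 2D coordinates for one of the graphic families.
#'
#' @param stats tibble with the needed columns (`mean`/`sd`, `p0..p2`
#'   and/or `k0..k2`, `n_informative`).
#' @param space one of `"msd"`, `"p_scatter"`, `"k_scatter"`,
#'   `"ternary_p"`, `"ternary_k"`, `"ilr_p"`, `"ilr_k"`.
#' @param i,j part indices (0, 1 or 2) for the scatter spaces.
#' @param basis ilr basis for the ilr spaces.
#' @param replace apply [replace_zeros()] (with each pair's
#'   `n_informative`) before ilr; if `FALSE`, zero-part rows come back
#'   non-finite.
#' @return A tibble with columns `x`, `y` (plus `finite` for ilr spaces).
#' @export
pair_coords <- function(stats, space, i = 0, j = 1, basis = "z1", replace = TRUE) {
  space <- match.arg(space, c("msd", "p_scatter", "k_scatter",
                              "ternary_p", "ternary_k", "ilr_p", "ilr_k"))
  part_cols <- function(prefix) paste0(prefix, 0:2)
  comp <- function(prefix) as.matrix(stats[, part_cols(prefix)])
  if (space == "msd") {
    return(tibble::tibble(x = stats$mean, y = stats$sd))
  }
  if (space %in% c("p_scatter", "k_scatter")) {
    stopifnot(i %in% 0:2, j %in% 0:2, i != j)
    prefix <- if (space == "p_scatter") "p" else "k"
    return(tibble::tibble(x = stats[[paste0(prefix, i)]],
                          y = stats[[paste0(prefix, j)]]))
  }
  prefix <- if (grepl("_p$", space)) "p" else "k"
  cm <- comp(prefix)
  if (grepl("^ternary", space)) return(ternary_xy(cm))
  if (replace) cm <- replace_zeros(cm, stats$n_informative)
  z <- ilr(cm, basis)
  tibble::tibble(x = z$zb1, y = z$zb2, finite = z$finite,
                 dir1 = z$dir1, dir2 = z$dir2)
}

#' Convex-hull uncertainty zone for a set of simulated pairs
#'
#' Maps each simulated pair's statistics into the requested coordinate
#' system and hulls them; the hull approximates the zone occupied by that
#' relationship in the corresponding graphic. Non-finite coordinates (only
#' possible in ilr spaces with `replace = FALSE`) are dropped and counted.
#'
#' @param sim a `sim_pairs` object (with statistics computed) or a bare
#'   stats tibble.
#' @inheritParams pair_coords
#' @return A `convex_hull` with extra fields `space`, `relationship` and
#'   `n_dropped`.
#' @export
hulls_for <- function(sim, space, i = 0, j = 1, basis = "z1", replace = TRUE) {
  stats <- if (inherits(sim, "sim_pairs")) sim$stats else sim
  if (is.null(stats)) stop("no statistics on this pair set", call. = FALSE)
  xy <- pair_coords(stats, space, i = i, j = j, basis = basis, replace = replace)
  finite <- is.finite(xy$x) & is.finite(xy$y)
  h <- convex_hull(xy$x[finite], xy$y[finite])
  h$space <- space
  h$relationship <- if (inherits(sim, "sim_pairs")) sim$relationship else
    unique(stats$relationship)[1]
  h$n_dropped <- sum(!finite)
  h
}
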