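#' Colour palette for relationship labels
#'
#' Fixed colours for comparability across all graphics: PO red, FS blue,
#' second-degree (HS/AV/GG) violet, FC gold, UN green, MZ dark green.
#'
#' @return Named character vector of colours.
#' @export
relationship_palette <- function() {
  c(MZ = "darkgreen", PO = "red", FS = "blue", HS = "violet", AV = "violet",
    GG = "violet", FC = "gold3", UN = "green3", unknown = "grey30")
}

.hull_layer <- function(hulls) {
  if (is.null(hulls)) return(NULL)
  if (inherits(hulls, "convex_hull")) hulls <- list(hulls)
  df <- purrr::map_dfr(hulls, function(h) {
    dplyr::mutate(h$vertices, relationship = h$relationship %||% "unknown")
  })
  ggplot2::geom_polygon(
    data = df,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$relationship,
                 group = .data$relationship),
    fill = NA, linewidth = 0.4, show.legend = FALSE)
}

.rel_aes <- function(stats) {
  if ("relationship" %in% names(stats)) {
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$relationship)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y)
  }
}

.rel_scale <- function() {
  ggplot2::scale_colour_manual(values = relationship_palette(), name = NULL)
}

#' Mean/sd umbrella plot of IBS counts
#'
#' Scatter of pair means against standard deviations of the IBS counts,
#' optionally over the exact attainable domain (grey umbrella), with the
#' parent-offspring boundary curve in red and the monozygotic-twin point
#' (2, 0) in green.
#'
#' @param stats tibble with `mean` and `sd` columns (e.g. [ibs_pairs()]);
#'   a `relationship` column, if present, colours the points.
#' @param domain optional [msd_domain()] tibble drawn as grey backdrop.
#' @param po_curve draw the parent-offspring boundary ([po_boundary()],
#'   using the domain's marker count or `m`).
#' @param m marker count for the boundary when `domain` is absent.
#' @param hulls optional `convex_hull` or list of them (msd space).
#' @return A ggplot object.
#' @export
plot_msd <- function(stats, domain = NULL, po_curve = TRUE, m = NULL,
                     hulls = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(domain)) {
    p <- p + ggplot2::geom_point(
      data = domain, ggplot2::aes(x = .data$mean, y = .data$sd),
      colour = "grey75", size = 0.3)
    if (is.null(m)) m <- attr(domain, "m")
  }
  if (po_curve && !is.null(m)) {
    p <- p + ggplot2::geom_path(
      data = po_boundary(m), ggplot2::aes(x = .data$mean, y = .data$sd),
      colour = "red")
  }
  df <- dplyr::rename(stats, x = "mean", y = "sd")
  p <- p + .hull_layer(hulls) +
    ggplot2::geom_point(data = df, .rel_aes(df)) +
    ggplot2::annotate("point", x = 2, y = 0, colour = "darkgreen", size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 2), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean IBS count", y = "sd of IBS counts") +
    ggplot2::theme_minimal()
  if ("relationship" %in% names(df)) p <- p + .rel_scale()
  p
}

#' Two-part scatterplot of IBS proportions or Cotterman estimates
#'
#' Plots component `i` against component `j` of `(p0, p1, p2)` or
#' `(k0, k1, k2)`. In k-space with `i = 0, j = 1` the feasible region of
#' the non-inbred constraint is outlined: the curve `k1^2 = 4 k0 k2` and
#' the hypotenuse `k0 + k1 = 1`. Distances in these plots depend on which
#' components are chosen — the compositional plots do not.
#'
#' @param stats tibble with `p0..p2` or `k0..k2` columns.
#' @param space `"p"` or `"k"`.
#' @param i,j component indices in 0..2, `i != j` (x and y axis).
#' @param hulls optional hull(s) computed in the same space.
#' @param references overlay the theoretical reference points
#'   ([cotterman_reference()]; k-space only).
#' @return A ggplot object.
#' @export
plot_pair_scatter <- function(stats, space = c("k", "p"), i = 0, j = 1,
                              hulls = NULL, references = (space[1] == "k")) {
  space <- match.arg(space)
  xy <- pair_coords(stats, paste0(space, "_scatter"), i = i, j = j)
  df <- dplyr::bind_cols(stats, xy)
  p <- ggplot2::ggplot()
  if (space == "k" && i == 0 && j == 1) {
    fb <- feasible_boundary(301)
    p <- p +
      ggplot2::geom_path(data = fb, ggplot2::aes(x = .data$k0, y = .data$k1),
                         colour = "grey50") +
      ggplot2::annotate("segment", x = 0, y = 1, xend = 1, yend = 0,
                        colour = "grey50")
  }
  p <- p + .hull_layer(hulls) + ggplot2::geom_point(data = df, .rel_aes(df))
  if (references && space == "k") {
    refs <- dplyr::distinct(cotterman_reference(), .data$k0, .data$k1, .data$k2,
                            .keep_all = TRUE)
    rxy <- tibble::tibble(x = refs[[paste0("k", i)]], y = refs[[paste0("k", j)]],
                          relationship = refs$relationship)
    p <- p + ggplot2::geom_point(data = rxy,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 3, size = 2.5, colour = "black") +
      ggplot2::geom_text(data = rxy,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$relationship),
                         vjust = -0.8, size = 3)
  }
  p + ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste0(space, i), y = paste0(space, j)) +
    ggplot2::theme_minimal() +
    (if ("relationship" %in% names(stats)) .rel_scale())
}

.ternary_frame <- function(labels) {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  xy <- ternary_xy(v)
  list(
    ggplot2::geom_polygon(data = xy, ggplot2::aes(x = .data$x, y = .data$y),
                          fill = NA, colour = "black"),
    ggplot2::annotate("text", x = xy$x + c(-0.03, 0.03, 0),
                      y = xy$y + c(-0.03, -0.03, 0.04), label = labels, size = 3.5),
    ggplot2::coord_fixed(),
    ggplot2::theme_void()
  )
}

#' Ternary diagram of IBS proportions or Cotterman estimates
#'
#' Displays all three parts of each composition at once; vertex convention:
#' part 0 bottom-left, part 1 bottom-right, part 2 top. In k-mode the
#' arrowhead boundary of the non-inbred feasible region
#' ([feasible_boundary()]) and the theoretical reference points are drawn.
#'
#' @param stats tibble with `p0..p2` or `k0..k2` columns.
#' @param mode `"p"` or `"k"`.
#' @param hulls optional hull(s) computed in the same ternary space.
#' @param references overlay reference points (k-mode only).
#' @return A ggplot object.
#' @export
plot_ternary <- function(stats, mode = c("p", "k"), hulls = NULL,
                         references = (mode[1] == "k")) {
  mode <- match.arg(mode)
  xy <- pair_coords(stats, paste0("ternary_", mode))
  df <- dplyr::bind_cols(stats, xy)
  p <- ggplot2::ggplot() + .ternary_frame(paste0(mode, 0:2))
  if (mode == "k") {
    p <- p + ggplot2::geom_path(data = ternary_xy(feasible_boundary(301)),
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "grey50")
  }
  p <- p + .hull_layer(hulls) + ggplot2::geom_point(data = df, .rel_aes(df))
  if (references && mode == "k") {
    refs <- dplyr::distinct(cotterman_reference(), .data$k0, .data$k1, .data$k2,
                            .keep_all = TRUE)
    rxy <- dplyr::bind_cols(ternary_xy(as.matrix(refs[, c("k0", "k1", "k2")])),
                            relationship = refs$relationship)
    p <- p + ggplot2::geom_point(data = rxy,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 3, size = 2.5, colour = "black")
  }
  if ("relationship" %in% names(stats)) p <- p + .rel_scale()
  p
}

#' ilr scatterplot with infinity arrows
#'
#' Plots the two ilr coordinates of each composition. Compositions with
#' zero parts have no finite image; unless zeros were replaced, such pairs
#' are drawn as arrows at the frame edge pointing in the direction their
#' image escapes. The horizontal grey line marks the feasible-region
#' ceiling of the second coordinate, `ln(1/4)/sqrt(6)`, constant along the
#' non-inbred boundary curve (k-mode).
#'
#' @param stats tibble with `p0..p2` or `k0..k2` and `n_informative`.
#' @param mode `"p"` or `"k"`.
#' @param basis ilr basis (`"z0"`, `"z1"`, `"z2"`).
#' @param replace replace zeros first ([replace_zeros()]); with `FALSE`,
#'   infinite points become edge arrows.
#' @param hulls optional hull(s) in the same ilr space.
#' @param ceiling draw the feasible-region ceiling line (k-mode default).
#' @return A ggplot object.
#' @export
plot_ilr <- function(stats, mode = c("p", "k"), basis = "z1", replace = TRUE,
                     hulls = NULL, ceiling = (mode[1] == "k")) {
  mode <- match.arg(mode)
  xy <- pair_coords(stats, paste0("ilr_", mode), basis = basis, replace = replace)
  df <- dplyr::bind_cols(stats, xy)
  fin <- dplyr::filter(df, .data$finite)
  inf <- dplyr::filter(df, !.data$finite)
  p <- ggplot2::ggplot()
  if (ceiling) {
    p <- p + ggplot2::geom_hline(yintercept = ilr_feasible_ceiling(),
                                 colour = "grey50")
  }
  p <- p + .hull_layer(hulls)
  if (nrow(fin)) p <- p + ggplot2::geom_point(data = fin, .rel_aes(fin))
  if (nrow(inf)) {
    # anchor arrows at the frame edge along their escape direction
    r <- max(abs(c(fin$x, fin$y, 1)), na.rm = TRUE) * 1.1
    inf <- dplyr::mutate(inf,
                         x0 = 0.85 * r * .data$dir1, y0 = 0.85 * r * .data$dir2,
                         x1 = r * .data$dir1, y1 = r * .data$dir2)
    seg_aes <- if ("relationship" %in% names(inf)) {
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   colour = .data$relationship)
    } else {
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1)
    }
    p <- p + ggplot2::geom_segment(
      data = inf, seg_aes, arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
  }
  p + ggplot2::labs(x = paste0(sub("z", "z", basis), "1 coordinate"),
                    y = paste0(basis, "2 coordinate")) +
    ggplot2::theme_minimal() +
    (if ("relationship" %in% names(stats)) .rel_scale())
}
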