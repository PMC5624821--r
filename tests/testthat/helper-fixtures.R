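# Fixtures are built in code at test time.

# small genotype matrix from a character matrix of "a/b" strings
geno_from_strings <- function(g, ids = NULL, markers = NULL) {
  n <- nrow(g); m <- ncol(g)
  al <- array(NA_character_, dim = c(n, m, 2L))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!is.na(g[i, j])) {
      parts <- strsplit(g[i, j], "/", fixed = TRUE)[[1]]
      al[i, j, ] <- parts
    }
  }
  genotype_matrix(al,
                  ids %||% paste0("I", seq_len(n)),
                  markers %||% paste0("M", seq_len(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a tiny PED/MAP pair; returns the two paths
write_ped_fixture <- function(ped_lines, marker_ids,
                              dir = tempfile("pedfx")) {
  dir.create(dir, showWarnings = FALSE)
  ped <- file.path(dir, "x.ped")
  map <- file.path(dir, "x.map")
  writeLines(ped_lines, ped)
  writeLines(sprintf("1 %s 0 %d", marker_ids, seq_along(marker_ids)), map)
  list(ped = ped, map = map)
}

# exhaustive (mean, sd) points over all 3^m IBS arrays — brute-force oracle;
# returns the distinct points sorted by (mean, sd). Distinct points are at
# least 1/(2m) apart, so sorted comparison at tolerance 1e-9 is exact.
sorted_msd <- function(mean, sd) {
  pts <- unique(cbind(mean, sd))
  unname(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
}

brute_msd_points <- function(m) {
  arrays <- as.matrix(expand.grid(rep(list(0:2), m)))
  mean <- rowMeans(arrays)
  sd <- sqrt(pmax(rowMeans(arrays^2) - mean^2, 0))
  sorted_msd(mean, sd)
}

# O(n^3) convex-hull oracle: a point is a hull vertex iff it is not strictly
# inside the hull; build by testing, for every ordered pair, whether all
# remaining points lie on one side
brute_hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- pts[j, ] - pts[i, ]
    s <- (pts[, 1] - pts[i, 1]) * d[2] - (pts[, 2] - pts[i, 2]) * d[1]
    if (all(s <= 1e-12)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  pts[on_hull, , drop = FALSE]
}

random_composition <- function(n) {
  x <- matrix(stats::rexp(3 * n), ncol = 3)
  x / rowSums(x)
}
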