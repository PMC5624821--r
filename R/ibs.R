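#' IBS allele sharing count for one pair of genotypes
#'
#' Two diploid genotypes can share 0, 1 or 2 alleles identical by state
#' (IBS). The count is the size of a maximum matching between the two
#' unordered allele pairs: 2 when the genotypes are equal as multisets, 1
#' when they share at least one allele, 0 otherwise. Symmetric in its
#' arguments; allele order within a genotype is irrelevant.
#'
#' @param g1,g2 length-2 vectors of allele labels. `NA` alleles mark a
#'   missing genotype.
#' @return Integer 0, 1 or 2, or `NA_integer_` when either genotype is
#'   missing (an uninformative locus — callers mask it).
#' @examples
#' ibs_count(c("A1", "A1"), c("A2", "A2")) # 0
#' ibs_count(c("A1", "A2"), c("A1", "A3")) # 1
#' ibs_count(c("A1", "A2"), c("A2", "A1")) # 2
#' @export
ibs_count <- function(g1, g2) {
  if (anyNA(g1) || anyNA(g2)) return(NA_integer_)
  as.integer(max((g1[1] == g2[1]) + (g1[2] == g2[2]),
                 (g1[1] == g2[2]) + (g1[2] == g2[1])))
}

# vectorised IBS counts for individuals i, j across all markers (NA where
# either genotype is missing)
.ibs_counts_vec <- function(a, b, c, d) {
  pmax((a == c) + (b == d), (a == d) + (b == c))
}

#' IBS counts for one pair of individuals across all markers
#'
#' @param G a [genotype_matrix()].
#' @param i,j individual indices or ids; `i != j`.
#' @return An object of class `ibs_counts`: list with `pair` (the two ids),
#'   `counts` (integer vector over markers, `NA` = locus missing in either
#'   individual) and `n_informative`.
#' @export
ibs_pair_counts <- function(G, i, j) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.character(i)) i <- match(i, G$individual_ids)
  if (is.character(j)) j <- match(j, G$individual_ids)
  if (anyNA(c(i, j))) stop("unknown individual id", call. = FALSE)
  if (i == j) stop("need two distinct individuals", call. = FALSE)
  counts <- .ibs_counts_vec(G$alleles[i, , 1L], G$alleles[i, , 2L],
                            G$alleles[j, , 1L], G$alleles[j, , 2L])
  counts <- as.integer(counts)
  counts[G$missing[i, ] | G$missing[j, ]] <- NA_integer_
  n_inf <- sum(!is.na(counts))
  if (n_inf == 0L) {
    warning("pair (", G$individual_ids[i], ", ", G$individual_ids[j],
            ") has no informative loci", call. = FALSE)
  }
  structure(list(pair = c(G$individual_ids[i], G$individual_ids[j]),
                 counts = counts, n_informative = n_inf),
            class = "ibs_counts")
}

#' Summarise an IBS count vector
#'
#' Computes the mean and standard deviation of the IBS counts and the
#' proportions of markers sharing 0, 1 and 2 IBS alleles, over informative
#' loci only (pairwise deletion). The standard deviation uses the population
#' divisor `n`, which is what makes the maximum attainable variance equal to
#' one (reached by half 0s, half 2s).
#'
#' @param counts an `ibs_counts` object or a bare integer vector of 0/1/2
#'   counts (`NA` = uninformative).
#' @return A one-row tibble: `n_informative`, `mean`, `sd`, `p0`, `p1`, `p2`
#'   (plus `id1`, `id2` when the input carries pair ids).
#' @export
ibs_summary <- function(counts) {
  pair <- NULL
  if (inherits(counts, "ibs_counts")) {
    pair <- counts$pair
    counts <- counts$counts
  }
  x <- counts[!is.na(counts)]
  n <- length(x)
  if (n == 0L) stop("no informative loci", call. = FALSE)
  if (!all(x %in% 0:2)) stop("IBS counts must be 0, 1 or 2", call. = FALSE)
  p0 <- sum(x == 0L) / n
  p1 <- sum(x == 1L) / n
  p2 <- sum(x == 2L) / n
  m <- p1 + 2 * p2
  s <- sqrt(max(p1 + 4 * p2 - m^2, 0))
  out <- tibble::tibble(n_informative = n, mean = m, sd = s,
                        p0 = p0, p1 = p1, p2 = p2)
  if (!is.null(pair)) out <- dplyr::bind_cols(tibble::tibble(id1 = pair[1], id2 = pair[2]), out)
  out
}

#' IBS summaries for all pairs of individuals
#'
#' Moves from `n` individuals to the `choose(n, 2)` unordered pairs,
#' enumerated in row-major upper-triangle order (1-2, 1-3, ..., 2-3, ...) so
#' output files are reproducible.
#'
#' @param G a [genotype_matrix()].
#' @param min_informative pairs with fewer informative loci are kept but
#'   flagged in the `informative_ok` column.
#' @return A tibble with one row per pair: `id1`, `id2`, `n_informative`,
#'   `mean`, `sd`, `p0`, `p1`, `p2`, `informative_ok`.
#' @export
ibs_pairs <- function(G, min_informative = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- n_individuals(G)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  rows <- purrr::map2(idx[, "row"], idx[, "col"], function(i, j) {
    ibs_summary(suppressWarnings(ibs_pair_counts(G, i, j)))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, informative_ok = .data$n_informative >= min_informative)
}

#' Multiset coefficient
#'
#' Number of multisets of cardinality `m` drawn from a basic set of `k`
#' outcomes, `C(k + m - 1, m)`. With `k = 3` (IBS counts 0/1/2) it bounds
#' the number of distinct (mean, sd) points attainable with `m` markers:
#' e.g. 5151 for 100 markers.
#'
#' @param k size of the basic set (`k >= 1`).
#' @param m multiset cardinality (`m >= 0`).
#' @return The exact count as a double (exact for all supported sizes).
#' @export
multiset_coefficient <- function(k, m) {
  if (k < 1 || m < 0 || k != round(k) || m != round(m)) {
    stop("need integers k >= 1, m >= 0", call. = FALSE)
  }
  round(choose(k + m - 1, m))
}

#' Attainable domain of the IBS mean/sd plot
#'
#' Enumerates every composition `(n0, n1, n2)` of `m` markers into loci
#' sharing 0, 1 and 2 IBS alleles, and maps each to its
#' (mean, population sd) point. The point cloud has the shape of an
#' umbrella; no empirical pair can fall outside it. Distinct compositions
#' mapping to the same point are collapsed with their multiplicity retained,
#' so the number of enumerated compositions equals
#' `multiset_coefficient(3, m)` while the number of distinct points may be
#' smaller.
#'
#' @param m number of markers, `1 <= m <= 2000` (enumeration is `O(m^2)`).
#' @return A tibble of distinct points (`mean`, `sd`, `multiplicity`) with
#'   attributes `m` and `n_compositions`.
#' @export
msd_domain <- function(m) {
  if (m < 1 || m > 2000 || m != round(m)) {
    stop("`m` must be an integer in [1, 2000]", call. = FALSE)
  }
  n2 <- sequence(seq_len(m + 1L)) - 1L          # 0..n for n = 0..m
  tot <- rep(0:m, times = seq_len(m + 1L))      # n1 + n2 total
  n1 <- tot - n2
  n0 <- m - tot
  mean <- (n1 + 2 * n2) / m
  sd <- sqrt(pmax((n1 + 4 * n2) / m - mean^2, 0))
  pts <- tibble::tibble(mean = mean, sd = sd) |>
    dplyr::count(.data$mean, .data$sd, name = "multiplicity")
  stopifnot(sum(pts$multiplicity) == multiset_coefficient(3, m))
  attr(pts, "m") <- m
  attr(pts, "n_compositions") <- multiset_coefficient(3, m)
  class(pts) <- c("msd_domain", class(pts))
  pts
}

#' Parent-offspring boundary of the mean/sd domain
#'
#' The right-hand edge of the umbrella: compositions `(0, m - j, j)` for
#' `j = 0..m`. These are the IBS arrays with mean at least 1 and the
#' smallest standard deviation possible at that mean — where
#' parent-offspring pairs live, since a child inherits at least one IBS
#' allele from its parent at every locus. `j = 0` gives (1, 0) (all ones);
#' `j = m` gives (2, 0), the monozygotic-twin point.
#'
#' @param m number of markers.
#' @return A tibble with columns `n2` (the `j` index), `mean`, `sd`.
#' @export
po_boundary <- function(m) {
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer", call. = FALSE)
  j <- 0:m
  mean <- 1 + j / m
  sd <- sqrt(pmax((m - j + 4 * j) / m - mean^2, 0))
  tibble::tibble(n2 = j, mean = mean, sd = sd)
}
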