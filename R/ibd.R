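#' Cotterman coefficients of the standard relationships
#'
#' Theoretical probabilities that a non-inbred pair shares 0, 1 or 2 alleles
#' identical by descent, used as fixed reference points in the IBD graphics
#' and by [classify_relationship()].
#'
#' @return A tibble with columns `relationship` (MZ, PO, FS, HS, AV, GG, FC,
#'   UN), `degree` (`Inf` for UN), `k0`, `k1`, `k2`.
#' @export
cotterman_reference <- function() {
  tibble::tribble(
    ~relationship, ~degree,  ~k0,  ~k1,  ~k2,
    "MZ",          0,        0,    0,    1,
    "PO",          1,        0,    1,    0,
    "FS",          1,        1/4,  1/2,  1/4,
    "HS",          2,        1/2,  1/2,  0,
    "AV",          2,        1/2,  1/2,  0,
    "GG",          2,        1/2,  1/2,  0,
    "FC",          3,        3/4,  1/4,  0,
    "UN",          Inf,      1,    0,    0
  )
}

# Vectorised per-locus conditional probabilities of an observed (unordered)
# genotype pair given 0/1/2 shared IBD alleles, for the non-inbred model.
# a,b and c,d: allele labels of the two genotypes; pa..pd their population
# frequencies. Returns an m x 3 matrix.
.class_probs_vec <- function(a, b, c, d, pa, pb, pc, pd) {
  hom1 <- a == b
  hom2 <- c == d
  s_ac <- a == c; s_ad <- a == d; s_bc <- b == c; s_bd <- b == d
  eqset <- (s_ac & s_bd) | (s_ad & s_bc)
  share <- s_ac | s_ad | s_bc | s_bd

  hw1 <- ifelse(hom1, pa * pa, 2 * pa * pb)
  hw2 <- ifelse(hom2, pc * pc, 2 * pc * pd)
  P0 <- hw1 * hw2
  P2 <- ifelse(eqset, hw1, 0)

  P1 <- numeric(length(a))
  # both homozygous for the same allele: p^3
  i <- hom1 & hom2 & s_ac
  P1[i] <- (pa^3)[i]
  # one homozygote, the heterozygote carries its allele: p_i^2 p_j
  i <- hom1 & !hom2 & share
  P1[i] <- (pa^2 * ifelse(s_ac, pd, pc))[i]
  i <- !hom1 & hom2 & share
  P1[i] <- (pc^2 * ifelse(s_ac | s_bc, ifelse(s_ac, pb, pa), NA_real_))[i]
  # two identical heterozygotes: p_i p_j (p_i + p_j)
  i <- !hom1 & !hom2 & eqset
  P1[i] <- (pa * pb * (pa + pb))[i]
  # two heterozygotes sharing exactly one allele: p_i p_j p_l
  i <- !hom1 & !hom2 & share & !eqset
  sh_is_a <- s_ac | s_ad
  p_i <- ifelse(sh_is_a, pa, pb)
  p_j <- ifelse(sh_is_a, pb, pa)
  p_l <- ifelse(ifelse(sh_is_a, s_ac, s_bc), pd, pc)
  P1[i] <- (p_i * p_j * p_l)[i]

  cbind(P0 = P0, P1 = P1, P2 = P2)
}

#' Conditional genotype-pair probabilities given IBD state
#'
#' Probability of observing an unordered pair of single-locus genotypes
#' given that the pair shares 0, 1 or 2 alleles identical by descent, under
#' Hardy-Weinberg proportions and no inbreeding. These are the per-locus
#' ingredients of the Cotterman likelihood: e.g. for genotypes
#' `(AiAi, AiAj)` the triple is `(2 pi^3 pj, pi^2 pj, 0)`.
#'
#' @param g1,g2 length-2 allele vectors (one locus each).
#' @param freqs named numeric vector of allele frequencies at the locus.
#' @return A named numeric vector `(P0, P1, P2)`.
#' @export
class_probs <- function(g1, g2, freqs) {
  al <- as.character(c(g1, g2))
  p <- freqs[al]
  if (anyNA(al) || anyNA(p)) {
    stop("missing genotype or allele absent from the frequency map", call. = FALSE)
  }
  drop(.class_probs_vec(al[1], al[2], al[3], al[4], p[1], p[2], p[3], p[4]))
}

#' Per-locus class probabilities for one pair of individuals
#'
#' Applies [class_probs()] marker-wise. Loci missing in either individual,
#' or where an observed allele is absent from the frequency map (possible
#' when frequencies were estimated excluding the pair), are flagged with
#' `NA` rows and skipped by the likelihood.
#'
#' @param G a [genotype_matrix()].
#' @param i,j individual indices or ids.
#' @param freqs an `allele_freqs` object aligned with `G`'s markers.
#' @return An `m x 3` matrix with columns `P0`, `P1`, `P2`; attribute
#'   `n_skipped` counts non-missing loci dropped for absent alleles.
#' @export
pair_class_probs <- function(G, i, j, freqs) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(freqs, "allele_freqs"))
  if (is.character(i)) i <- match(i, G$individual_ids)
  if (is.character(j)) j <- match(j, G$individual_ids)
  m <- n_markers(G)
  if (length(freqs$freqs) != m) stop("frequency table does not match marker count", call. = FALSE)
  a <- G$alleles[i, , 1L]; b <- G$alleles[i, , 2L]
  c_ <- G$alleles[j, , 1L]; d <- G$alleles[j, , 2L]
  # flat lookup table keyed by "<marker index>\r<allele>"
  nall <- lengths(freqs$freqs)
  key <- paste(rep.int(seq_len(m), nall), unlist(lapply(freqs$freqs, names)), sep = "\r")
  fv <- stats::setNames(unlist(freqs$freqs, use.names = FALSE), key)
  lk <- function(al) unname(fv[paste(seq_len(m), al, sep = "\r")])
  pa <- lk(a); pb <- lk(b); pc <- lk(c_); pd <- lk(d)
  miss <- G$missing[i, ] | G$missing[j, ]
  no_freq <- !miss & (is.na(pa) | is.na(pb) | is.na(pc) | is.na(pd))
  ok <- !miss & !no_freq
  P <- matrix(NA_real_, m, 3, dimnames = list(G$marker_ids, c("P0", "P1", "P2")))
  if (any(ok)) {
    P[ok, ] <- .class_probs_vec(a[ok], b[ok], c_[ok], d[ok],
                                pa[ok], pb[ok], pc[ok], pd[ok])
  }
  attr(P, "n_skipped") <- sum(no_freq)
  P
}

#' Log-likelihood of Cotterman coefficients for one pair
#'
#' The likelihood of a relationship is the probability of the observed
#' genotype pair given its Cotterman coefficients, multiplied across loci:
#' `sum over loci of log(k0 P0 + k1 P1 + k2 P2)`. Flagged (`NA`) loci are
#' skipped. At `k = (1, 0, 0)` it reduces to the sum of the log
#' Hardy-Weinberg probabilities of the two genotypes taken independently.
#'
#' @param P an `m x 3` class-probability matrix from [pair_class_probs()].
#' @param k length-3 Cotterman vector on the simplex.
#' @return The log-likelihood; `-Inf` when some locus has zero mixture
#'   probability under `k`.
#' @export
pair_loglik <- function(P, k) {
  if (abs(sum(k) - 1) > 1e-8 || any(k < -1e-12)) {
    stop("`k` must lie on the simplex", call. = FALSE)
  }
  P <- P[stats::complete.cases(P), , drop = FALSE]
  mix <- as.vector(P %*% pmax(k, 0))
  if (any(mix <= 0)) return(-Inf)
  sum(log(mix))
}

# One EM run from a given start; P must have no NA rows.
.em_run <- function(P, k0, tol, max_iter) {
  k <- k0
  ll <- pair_loglik(P, k)
  trace <- ll
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    num <- sweep(P, 2, k, `*`)
    mix <- rowSums(num)
    k_new <- colMeans(num / mix)
    ll_new <- sum(log(as.vector(P %*% k_new)))
    trace <- c(trace, ll_new)
    gain <- ll_new - ll
    k <- k_new
    ll <- ll_new
    if (gain < tol) { converged <- TRUE; break }
  }
  list(k = unname(k), loglik = ll, n_iter = iter, converged = converged, trace = trace)
}

#' Maximum-likelihood estimation of Cotterman coefficients
#'
#' Fits the per-locus three-component mixture by EM: responsibilities
#' `r_ml = k_m P_ml / sum_m' k_m' P_m'l`, update `k_m = mean_l r_ml`. The
#' update keeps the estimate on the simplex by construction and the
#' log-likelihood is non-decreasing at every iteration (the recorded trace
#' is asserted in the tests). Default start is the barycenter
#' `(1/3, 1/3, 1/3)`; `corner_starts = TRUE` adds three near-vertex starts
#' `(0.98, 0.01, 0.01)` and permutations, keeping the best final
#' log-likelihood — useful because boundary optima can slow EM down.
#'
#' @param P class-probability matrix from [pair_class_probs()].
#' @param tol stop when the log-likelihood gain drops below this (default
#'   1e-7).
#' @param max_iter iteration cap per start (default 2000).
#' @param corner_starts also start from the three near-vertex points.
#' @param min_informative error if fewer informative loci than this.
#' @return An object of class `cotterman_fit`: list with `k_hat`, `loglik`,
#'   `n_iter`, `converged`, `trace`, `n_informative`, `n_skipped`,
#'   `constrained` (FALSE here; see [apply_thompson_constraint()]) and the
#'   `P` matrix used.
#' @export
estimate_k <- function(P, tol = 1e-7, max_iter = 2000L, corner_starts = FALSE,
                       min_informative = 1L) {
  n_skipped <- attr(P, "n_skipped") %||% 0L
  Pc <- P[stats::complete.cases(P), , drop = FALSE]
  n_inf <- nrow(Pc)
  if (n_inf < min_informative) {
    stop("only ", n_inf, " informative loci (< min_informative = ",
         min_informative, ")", call. = FALSE)
  }
  starts <- list(c(1, 1, 1) / 3)
  if (corner_starts) {
    starts <- c(starts, list(c(0.98, 0.01, 0.01), c(0.01, 0.98, 0.01),
                             c(0.01, 0.01, 0.98)))
  }
  runs <- lapply(starts, function(s) .em_run(Pc, s, tol, max_iter))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  if (!best$converged) {
    warning("EM did not converge within ", max_iter,
            " iterations; best iterate returned", call. = FALSE)
  }
  structure(
    list(k_hat = best$k, loglik = best$loglik, n_iter = best$n_iter,
         converged = best$converged, trace = best$trace,
         n_informative = n_inf, n_skipped = n_skipped,
         constrained = FALSE, P = P),
    class = "cotterman_fit"
  )
}

#' @export
print.cotterman_fit <- function(x, ...) {
  cat(sprintf("<cotterman_fit> k = (%.4f, %.4f, %.4f)  logL = %.3f  (%d loci, %d iter%s%s)\n",
              x$k_hat[1], x$k_hat[2], x$k_hat[3], x$loglik,
              x$n_informative, x$n_iter,
              if (x$converged) "" else ", not converged",
              if (x$constrained) ", constrained" else ""))
  invisible(x)
}

#' Tidy a Cotterman fit
#'
#' @param x a `cotterman_fit`.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per coefficient (`term`,
#'   `estimate`); `glance()`: a one-row tibble of fit summaries.
#' @export
tidy.cotterman_fit <- function(x, ...) {
  tibble::tibble(term = c("k0", "k1", "k2"), estimate = x$k_hat)
}

#' @rdname tidy.cotterman_fit
#' @export
glance.cotterman_fit <- function(x, ...) {
  tibble::tibble(k0 = x$k_hat[1], k1 = x$k_hat[2], k2 = x$k_hat[3],
                 loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, constrained = x$constrained,
                 n_informative = x$n_informative, n_skipped = x$n_skipped)
}

#' Generic tidiers
#'
#' Broom-style generics re-exported so `tidy()`/`glance()` work without
#' attaching another package.
#' @param x an object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Maximum likelihood in ilr coordinates (cross-check mode)
#'
#' Quasi-Newton maximisation of the same per-pair likelihood after
#' reparameterising `k` by its ilr coordinates, which removes the simplex
#' constraint. Estimates agree with the simplex EM route whenever the
#' optimum is interior; for boundary optima (PO, UN, MZ) the ilr image
#' diverges and the result depends on tolerance and starting point, which
#' is why EM is the primary optimiser and this route is a cross-check.
#'
#' @inheritParams estimate_k
#' @param basis ilr basis used for the parameterisation.
#' @param start length-2 starting coordinates (default the barycenter,
#'   `c(0, 0)`).
#' @return A `cotterman_fit` (trace holds the optimiser's final value only).
#' @export
estimate_k_ilr <- function(P, basis = "z1", start = c(0, 0),
                           min_informative = 1L) {
  Pc <- P[stats::complete.cases(P), , drop = FALSE]
  if (nrow(Pc) < min_informative) {
    stop("only ", nrow(Pc), " informative loci (< min_informative = ",
         min_informative, ")", call. = FALSE)
  }
  negll <- function(z) {
    k <- drop(ilr_inverse(z, basis))
    -sum(log(pmax(as.vector(Pc %*% k), 1e-300)))
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(
    list(k_hat = drop(ilr_inverse(opt$par, basis)), loglik = -opt$value,
         n_iter = opt$counts[["function"]], converged = opt$convergence == 0,
         trace = -opt$value, n_informative = nrow(Pc),
         n_skipped = attr(P, "n_skipped") %||% 0L,
         constrained = FALSE, P = P),
    class = "cotterman_fit"
  )
}

#' Project an estimate onto the non-inbred feasible region
#'
#' Thompson's inequality `k1^2 >= 4 k0 k2` holds for any non-inbred pair.
#' If the unconstrained maximum-likelihood estimate already satisfies it,
#' the fit is returned unchanged (flagged `constrained`). Otherwise the
#' likelihood is re-maximised on the boundary curve `k1^2 = 4 k0 k2`,
#' parameterised as `k = (s^2, 2 s (1 - s), (1 - s)^2)` with `s` in [0, 1]
#' (a dense grid refined by golden-section search), since the constrained
#' optimum of a continuous likelihood over the closed feasible set lies on
#' that curve when the unconstrained optimum is infeasible.
#'
#' @param fit a `cotterman_fit`.
#' @param tol feasibility slack (default 1e-10).
#' @return A `cotterman_fit` whose `k_hat` satisfies the inequality.
#' @export
apply_thompson_constraint <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "cotterman_fit"))
  k <- fit$k_hat
  if (k[2]^2 >= 4 * k[1] * k[3] - tol) {
    fit$constrained <- TRUE
    return(fit)
  }
  Pc <- fit$P[stats::complete.cases(fit$P), , drop = FALSE]
  f <- function(s) sum(log(pmax(as.vector(Pc %*% c(s^2, 2 * s * (1 - s), (1 - s)^2)),
                                1e-300)))
  grid <- seq(0, 1, length.out = 513)
  vals <- vapply(grid, f, numeric(1))
  s0 <- grid[which.max(vals)]
  opt <- stats::optimize(f, interval = c(max(0, s0 - 0.01), min(1, s0 + 0.01)),
                         maximum = TRUE, tol = 1e-10)
  s <- opt$maximum
  fit$k_hat <- c(s^2, 2 * s * (1 - s), (1 - s)^2)
  fit$loglik <- opt$objective
  fit$constrained <- TRUE
  fit
}

#' Classify an estimate by its nearest reference relationship
#'
#' Compares an estimated Cotterman vector with the theoretical reference
#' points of the standard relationships and reports the nearest one, under
#' plain Euclidean distance on the simplex (default) or Aitchison distance
#' after zero replacement. Ties are broken toward the lower-degree (closer)
#' relationship, the cheaper error to review in quality-control use.
#'
#' @param k length-3 Cotterman vector (will be closed).
#' @param method `"euclidean"` or `"aitchison"`.
#' @param m informative-locus count behind `k`, used for zero replacement
#'   when `method = "aitchison"`.
#' @return A one-row tibble: `relationship`, `degree`, `distance`.
#' @export
classify_relationship <- function(k, method = c("euclidean", "aitchison"), m = 1000) {
  method <- match.arg(method)
  k <- closure(k)
  refs <- dplyr::distinct(cotterman_reference(), .data$k0, .data$k1, .data$k2,
                          .keep_all = TRUE)
  refs <- dplyr::arrange(refs, .data$degree)
  rk <- as.matrix(refs[, c("k0", "k1", "k2")])
  if (method == "euclidean") {
    d <- sqrt(rowSums(sweep(rk, 2, drop(k))^2))
  } else {
    kz <- replace_zeros(k, m)
    rz <- replace_zeros(rk, m)
    d <- vapply(seq_len(nrow(rz)),
                function(r) aitchison_distance(kz, rz[r, , drop = FALSE]),
                numeric(1))
  }
  best <- which.min(d)  # refs sorted by degree, so ties resolve downward
  tibble::tibble(relationship = refs$relationship[best],
                 degree = refs$degree[best], distance = d[best])
}

#' IBD estimates for all pairs of individuals
#'
#' Runs the EM estimator for every unordered pair, in the same
#' upper-triangle order as [ibs_pairs()].
#'
#' @param G a [genotype_matrix()].
#' @param freqs optional `allele_freqs`; default: counting estimates from
#'   the full sample (including each focal pair).
#' @param loo_pair estimate frequencies excluding each focal pair
#'   (leave-one-pair-out); slower, slightly less biased.
#' @param constrain apply [apply_thompson_constraint()] to each fit.
#' @param min_informative minimum informative loci per pair (default 50).
#' @param classify_method distance used for the `relationship` column.
#' @inheritParams estimate_k
#' @return A tibble with one row per pair: ids, locus counts, `k0`, `k1`,
#'   `k2`, `loglik`, `n_iter`, `converged`, `relationship`, `ref_distance`.
#' @export
ibd_pairs <- function(G, freqs = NULL, loo_pair = FALSE, constrain = FALSE,
                      min_informative = 50L, tol = 1e-7, max_iter = 2000L,
                      corner_starts = FALSE,
                      classify_method = "euclidean") {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- n_individuals(G)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  if (is.null(freqs) && !loo_pair) freqs <- estimate_allele_freqs(G)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  n_warn <- 0L
  rows <- purrr::map2(idx[, "row"], idx[, "col"], function(i, j) {
    fq <- if (loo_pair) estimate_allele_freqs(G, exclude = c(i, j)) else freqs
    P <- pair_class_probs(G, i, j, fq)
    fit <- withCallingHandlers(
      estimate_k(P, tol = tol, max_iter = max_iter,
                 corner_starts = corner_starts,
                 min_informative = min_informative),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
    if (constrain) fit <- apply_thompson_constraint(fit)
    cls <- classify_relationship(fit$k_hat, method = classify_method,
                                 m = fit$n_informative)
    dplyr::bind_cols(
      tibble::tibble(id1 = G$individual_ids[i], id2 = G$individual_ids[j]),
      glance(fit),
      tibble::tibble(relationship = cls$relationship, ref_distance = cls$distance)
    )
  })
  if (n_warn > 0L) {
    warning(n_warn, " pair(s) hit the EM iteration cap; best iterates returned",
            call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
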