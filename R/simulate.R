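#' Simulate unrelated founders under Hardy-Weinberg equilibrium
#'
#' Draws `n` individuals whose two alleles per marker are independent draws
#' from the marker's allele-frequency distribution.
#'
#' @param n number of individuals.
#' @param freqs an `allele_freqs` object (see [allele_freqs()],
#'   [equifrequent_freqs()]).
#' @param ids optional individual ids; default `S1..Sn`.
#' @return A [genotype_matrix()].
#' @export
simulate_founders <- function(n, freqs, ids = NULL) {
  stopifnot(inherits(freqs, "allele_freqs"))
  m <- length(freqs$freqs)
  al <- array(NA_character_, dim = c(n, m, 2L))
  for (j in seq_len(m)) {
    f <- freqs$freqs[[j]]
    al[, j, ] <- sample(names(f), 2L * n, replace = TRUE, prob = f)
  }
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  genotype_matrix(al, ids, freqs$marker_ids)
}

#' Mendelian gene dropping: simulate a child of two parents
#'
#' At each marker one allele is sampled uniformly from each parent,
#' independently across markers. Where either parent's genotype is missing
#' the child is missing too. By construction the child shares at least one
#' IBS allele with each parent at every observed locus.
#'
#' @param parentA,parentB `m x 2` matrices of allele labels (rows =
#'   markers), e.g. `individual_genotypes(G, i)`.
#' @return An `m x 2` matrix of child allele labels.
#' @export
simulate_child <- function(parentA, parentB) {
  m <- nrow(parentA)
  stopifnot(nrow(parentB) == m, ncol(parentA) == 2L, ncol(parentB) == 2L)
  pickA <- sample.int(2L, m, replace = TRUE)
  pickB <- sample.int(2L, m, replace = TRUE)
  child <- cbind(parentA[cbind(seq_len(m), pickA)],
                 parentB[cbind(seq_len(m), pickB)])
  miss <- is.na(parentA[, 1L]) | is.na(parentB[, 1L])
  child[miss, ] <- NA_character_
  child
}

#' Extract one individual's genotypes as an m x 2 matrix
#'
#' @param G a [genotype_matrix()].
#' @param i individual index or id.
#' @return An `m x 2` character matrix (rows = markers).
#' @export
individual_genotypes <- function(G, i) {
  if (is.character(i)) i <- match(i, G$individual_ids)
  g <- cbind(G$alleles[i, , 1L], G$alleles[i, , 2L])
  rownames(g) <- G$marker_ids
  g
}

# Pedigree templates: how to drop genes to obtain one pair of the requested
# relationship from a pool of founder genotype matrices (m x 2 each).
.drop_pair <- function(relationship, founders) {
  ch <- simulate_child
  switch(relationship,
    MZ = list(founders[[1]], founders[[1]]),
    UN = list(founders[[1]], founders[[2]]),
    PO = list(founders[[1]], ch(founders[[1]], founders[[2]])),
    FS = list(ch(founders[[1]], founders[[2]]), ch(founders[[1]], founders[[2]])),
    HS = list(ch(founders[[1]], founders[[2]]), ch(founders[[1]], founders[[3]])),
    AV = {
      c1 <- ch(founders[[1]], founders[[2]])
      c2 <- ch(founders[[1]], founders[[2]])
      list(c1, ch(c2, founders[[3]]))          # uncle/aunt vs nephew/niece
    },
    GG = {
      c1 <- ch(founders[[1]], founders[[2]])
      list(founders[[1]], ch(c1, founders[[3]]))  # grandparent vs grandchild
    },
    FC = {
      s1 <- ch(founders[[1]], founders[[2]])
      s2 <- ch(founders[[1]], founders[[2]])
      list(ch(s1, founders[[3]]), ch(s2, founders[[4]]))
    },
    stop("unknown relationship: ", relationship, call. = FALSE)
  )
}

.n_founders_needed <- c(MZ = 1L, UN = 2L, PO = 2L, FS = 2L, HS = 3L,
                        AV = 3L, GG = 3L, FC = 4L)

#' Simulate artificial relative pairs by gene dropping
#'
#' Generates `n_pairs` labelled pairs of the requested relationship. In
#' `"frequency"` mode (the self-contained default) founders are drawn from
#' Hardy-Weinberg equilibrium at the supplied allele frequencies; in
#' `"resample"` mode founders are sampled without replacement, per pair,
#' from a supplied genotype matrix of unrelated individuals — the
#' conditional-on-the-sample scheme used to build uncertainty zones around
#' observed data.
#'
#' @param relationship one of `"MZ"`, `"PO"`, `"FS"`, `"HS"`, `"AV"`,
#'   `"GG"`, `"FC"`, `"UN"`.
#' @param n_pairs number of pairs to generate.
#' @param freqs an `allele_freqs` object: the founder source in frequency
#'   mode, and the frequencies used for EM estimation in both modes.
#' @param founders optional [genotype_matrix()] of unrelated individuals;
#'   supplying it switches to resample mode.
#' @param seed optional integer; when given, the RNG is seeded locally so
#'   the same call reproduces the same pairs bit for bit.
#' @param stats compute per-pair IBS summaries (and, if `estimate`, EM
#'   Cotterman estimates) into `$stats`.
#' @param estimate run [estimate_k()] per pair.
#' @param ... passed to [estimate_k()] (e.g. `tol`, `corner_starts`).
#' @return An object of class `sim_pairs`: list with `relationship`,
#'   `pairs` (list of two-element lists of `m x 2` genotype matrices),
#'   `founder_mode`, `seed` and `stats` (tibble: `pair_id`,
#'   `n_informative`, `mean`, `sd`, `p0`, `p1`, `p2` and, with `estimate`,
#'   `k0`, `k1`, `k2`, `loglik`, `converged`).
#' @export
simulate_pairs <- function(relationship, n_pairs, freqs, founders = NULL,
                           seed = NULL, stats = TRUE, estimate = TRUE, ...) {
  relationship <- match.arg(relationship, names(.n_founders_needed))
  stopifnot(inherits(freqs, "allele_freqs"))
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  nf <- .n_founders_needed[[relationship]]
  mode <- if (is.null(founders)) "frequency" else "resample"
  if (mode == "resample" && n_individuals(founders) < nf) {
    stop("resample mode needs at least ", nf, " founder individuals for ",
         relationship, call. = FALSE)
  }
  pairs <- vector("list", n_pairs)
  for (r in seq_len(n_pairs)) {
    fg <- if (mode == "frequency") {
      Gf <- simulate_founders(nf, freqs)
      lapply(seq_len(nf), function(i) individual_genotypes(Gf, i))
    } else {
      pick <- sample.int(n_individuals(founders), nf, replace = FALSE)
      lapply(pick, function(i) individual_genotypes(founders, i))
    }
    pairs[[r]] <- .drop_pair(relationship, fg)
  }
  out <- structure(list(relationship = relationship, pairs = pairs,
                        founder_mode = mode, seed = seed, stats = NULL),
                   class = "sim_pairs")
  if (stats) out$stats <- pair_statistics_sim(out, freqs, estimate = estimate, ...)
  out
}

#' @export
print.sim_pairs <- function(x, ...) {
  cat(sprintf("<sim_pairs> %d %s pairs (%s mode%s)\n",
              length(x$pairs), x$relationship, x$founder_mode,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}

#' IBS/IBD statistics of simulated pairs
#'
#' @param sim a `sim_pairs` object.
#' @param freqs `allele_freqs` used for the EM likelihood.
#' @param estimate run the EM estimator per pair.
#' @param ... passed to [estimate_k()].
#' @return A tibble, one row per pair.
#' @export
pair_statistics_sim <- function(sim, freqs, estimate = TRUE, ...) {
  stopifnot(inherits(sim, "sim_pairs"))
  rows <- purrr::imap(sim$pairs, function(pr, r) {
    g1 <- pr[[1]]; g2 <- pr[[2]]
    G2 <- genotype_matrix(
      array(c(rbind(g1[, 1], g2[, 1]), rbind(g1[, 2], g2[, 2])),
            dim = c(2L, nrow(g1), 2L)),
      c("A", "B"), freqs$marker_ids)
    s <- ibs_summary(suppressWarnings(ibs_pair_counts(G2, 1L, 2L)))[, -(1:2)]
    row <- dplyr::bind_cols(tibble::tibble(pair_id = r), s)
    if (estimate) {
      P <- pair_class_probs(G2, 1L, 2L, freqs)
      fit <- suppressWarnings(estimate_k(P, ...))
      row <- dplyr::bind_cols(row, tibble::tibble(
        k0 = fit$k_hat[1], k1 = fit$k_hat[2], k2 = fit$k_hat[3],
        loglik = fit$loglik, converged = fit$converged))
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, relationship = sim$relationship, .before = 1)
}

#' Pick a subset of mutually unrelated individuals
#'
#' Greedy filter for choosing gene-dropping founders from an observed
#' sample: while any pair has estimated `k1 + k2` above `threshold`, drop
#' the individual involved in most such pairs.
#'
#' @param G a [genotype_matrix()].
#' @param ibd optional precomputed [ibd_pairs()] tibble for `G`.
#' @param threshold maximum tolerated `k1 + k2` (default 0.2).
#' @param ... passed to [ibd_pairs()].
#' @return Character vector of retained individual ids.
#' @export
select_unrelated <- function(G, ibd = NULL, threshold = 0.2, ...) {
  if (is.null(ibd)) ibd <- ibd_pairs(G, ...)
  keep <- G$individual_ids
  repeat {
    rel <- dplyr::filter(ibd, .data$id1 %in% keep, .data$id2 %in% keep,
                         .data$k1 + .data$k2 > threshold)
    if (nrow(rel) == 0L) break
    worst <- names(sort(table(c(rel$id1, rel$id2)), decreasing = TRUE))[1]
    keep <- setdiff(keep, worst)
  }
  keep
}
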