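test_that("class probabilities match the non-inbred conditional table", {
  f <- c("1" = 0.5, "2" = 0.5)
  expect_equal(unname(class_probs(c(1, 1), c(1, 1), f)),
               c(0.5^4, 0.5^3, 0.5^2))
  f2 <- c("1" = 0.6, "2" = 0.3, "3" = 0.1)
  pi <- 0.6; pj <- 0.3; pl <- 0.1
  expect_equal(unname(class_probs(c(1, 1), c(1, 2), f2)),
               c(2 * pi^3 * pj, pi^2 * pj, 0))
  expect_equal(unname(class_probs(c(1, 2), c(1, 1), f2)),
               c(2 * pi^3 * pj, pi^2 * pj, 0))           # symmetric
  expect_equal(unname(class_probs(c(1, 1), c(2, 2), f2)),
               c(pi^2 * pj^2, 0, 0))
  expect_equal(unname(class_probs(c(1, 1), c(2, 3), f2)),
               c(2 * pi^2 * pj * pl, 0, 0))
  expect_equal(unname(class_probs(c(1, 2), c(1, 2), f2)),
               c(4 * pi^2 * pj^2, pi * pj * (pi + pj), 2 * pi * pj))
  expect_equal(unname(class_probs(c(1, 2), c(1, 3), f2)),
               c(4 * pi^2 * pj * pl, pi * pj * pl, 0))
  expect_equal(unname(class_probs(c(2, 1), c(3, 1), f2)),
               c(4 * pi^2 * pj * pl, pi * pj * pl, 0))   # shared allele in slot 2
  f4 <- c("1" = 0.4, "2" = 0.3, "3" = 0.2, "4" = 0.1)
  expect_equal(unname(class_probs(c(1, 2), c(3, 4), f4)),
               c(4 * 0.4 * 0.3 * 0.2 * 0.1, 0, 0))
  expect_error(class_probs(c(1, 9), c(1, 1), f2), "absent")
})

test_that("class probabilities are complete: each column sums to one", {
  for (f in list(c("1" = 0.5, "2" = 0.5),
                 c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                 c("1" = 0.4, "2" = 0.3, "3" = 0.2, "4" = 0.1))) {
    alleles <- names(f)
    gts <- t(utils::combn(c(alleles, alleles), 2))
    gts <- unique(t(apply(gts, 1, sort)))
    tot <- c(0, 0, 0)
    for (i in seq_len(nrow(gts))) for (j in seq_len(nrow(gts))) {
      tot <- tot + class_probs(gts[i, ], gts[j, ], f)
    }
    expect_equal(unname(tot), c(1, 1, 1), tolerance = 1e-12)
  }
})

test_that("pair log-likelihood factorizes at k = (1,0,0) and flags zero mixtures", {
  set.seed(37)
  fr <- equifrequent_freqs(4, 30)
  G <- simulate_founders(2, fr)
  P <- pair_class_probs(G, 1, 2, fr)
  hwe <- function(i) {
    sum(vapply(1:30, function(j) {
      g <- G$alleles[i, j, ]
      f <- fr$freqs[[j]][g]
      log(if (g[1] == g[2]) f[1]^2 else 2 * f[1] * f[2])
    }, numeric(1)))
  }
  expect_equal(pair_loglik(P, c(1, 0, 0)), hwe(1) + hwe(2), tolerance = 1e-10)
  # k = (0,0,1) is impossible unless all genotype pairs are identical
  if (any(P[, "P2"] == 0)) expect_identical(pair_loglik(P, c(0, 0, 1)), -Inf)
  expect_error(pair_loglik(P, c(0.5, 0.2, 0.2)), "simplex")
})

test_that("likelihood is higher at the truth than at distant k on average", {
  set.seed(41)
  fr <- equifrequent_freqs(10, 300)
  diff <- replicate(10, {
    sim <- simulate_pairs("FS", 1, fr, stats = FALSE)
    st <- pair_statistics_sim(sim, fr, estimate = FALSE)
    g <- sim$pairs[[1]]
    G2 <- genotype_matrix(array(c(rbind(g[[1]][, 1], g[[2]][, 1]),
                                  rbind(g[[1]][, 2], g[[2]][, 2])),
                                dim = c(2, 300, 2)), c("A", "B"), fr$marker_ids)
    P <- pair_class_probs(G2, 1, 2, fr)
    pair_loglik(P, c(1 / 4, 1 / 2, 1 / 4)) - pair_loglik(P, c(0.9, 0.05, 0.05))
  })
  expect_gt(mean(diff), 0)
})

test_that("EM is monotone, stays on the simplex and matches a grid search", {
  set.seed(43)
  fr <- equifrequent_freqs(8, 200)
  grid_k <- local({
    k0 <- seq(0, 1, by = 0.005)
    g <- expand.grid(k0 = k0, k1 = k0)
    g <- g[g$k0 + g$k1 <= 1 + 1e-12, ]
    as.matrix(cbind(g, k2 = pmax(1 - g$k0 - g$k1, 0)))
  })
  for (rel in c("FS", "HS", "UN")) {
    sim <- simulate_pairs(rel, 1, fr, stats = FALSE)
    g <- sim$pairs[[1]]
    G2 <- genotype_matrix(array(c(rbind(g[[1]][, 1], g[[2]][, 1]),
                                  rbind(g[[1]][, 2], g[[2]][, 2])),
                                dim = c(2, 200, 2)), c("A", "B"), fr$marker_ids)
    P <- pair_class_probs(G2, 1, 2, fr)
    fit <- suppressWarnings(estimate_k(P, tol = 1e-9, max_iter = 20000))
    expect_true(all(diff(fit$trace) >= -1e-9))     # EM monotonicity
    expect_equal(sum(fit$k_hat), 1, tolerance = 1e-10)
    expect_true(all(fit$k_hat >= 0))
    Pc <- P[stats::complete.cases(P), ]
    gl <- colSums(log(Pc %*% t(grid_k) + 1e-300))
    expect_gte(fit$loglik, max(gl) - 1e-3)         # grid cannot beat EM by more
    best <- grid_k[which.max(gl), ]                # than one step's curvature
    expect_lt(max(abs(fit$k_hat - best)), 0.02)    # argmax within grid spacing
  }
})

test_that("EM recovers simulated truths and glance/tidy expose the fit", {
  set.seed(47)
  fr <- equifrequent_freqs(10, 600)
  sim <- simulate_pairs("PO", 3, fr)
  expect_true(all(sim$stats$k1 > 0.9))
  sim_un <- simulate_pairs("UN", 3, fr)
  expect_true(all(sim_un$stats$k0 > 0.9))
  # tidy/glance on one refit
  g <- sim$pairs[[1]]
  G2 <- genotype_matrix(array(c(rbind(g[[1]][, 1], g[[2]][, 1]),
                                rbind(g[[1]][, 2], g[[2]][, 2])),
                              dim = c(2, 600, 2)), c("A", "B"), fr$marker_ids)
  fit <- estimate_k(pair_class_probs(G2, 1, 2, fr), corner_starts = TRUE)
  td <- tidy(fit)
  expect_equal(td$term, c("k0", "k1", "k2"))
  expect_equal(sum(td$estimate), 1, tolerance = 1e-10)
  gl <- glance(fit)
  expect_true(all(c("loglik", "converged", "n_informative") %in% names(gl)))
  expect_error(estimate_k(pair_class_probs(G2, 1, 2, fr), min_informative = 1000),
               "informative loci")
})

test_that("ilr-parameterised optimisation agrees with EM at interior optima", {
  set.seed(109)
  fr <- equifrequent_freqs(10, 400)
  for (r in 1:5) {
    sim <- simulate_pairs("FS", 1, fr, stats = FALSE)
    pr <- sim$pairs[[1]]
    G2 <- genotype_matrix(array(c(rbind(pr[[1]][, 1], pr[[2]][, 1]),
                                  rbind(pr[[1]][, 2], pr[[2]][, 2])),
                                dim = c(2, 400, 2)), c("A", "B"), fr$marker_ids)
    P <- pair_class_probs(G2, 1, 2, fr)
    em <- suppressWarnings(estimate_k(P, tol = 1e-10, max_iter = 20000))
    qi <- estimate_k_ilr(P)
    expect_equal(qi$loglik, em$loglik, tolerance = 1e-6)
    expect_equal(qi$k_hat, em$k_hat, tolerance = 1e-3)
  }
})

test_that("Thompson constraint projects onto the boundary only when violated", {
  set.seed(53)
  fr <- equifrequent_freqs(10, 400)
  sim <- simulate_pairs("FS", 5, fr, stats = FALSE)
  n_changed <- 0L
  for (pr in sim$pairs) {
    G2 <- genotype_matrix(array(c(rbind(pr[[1]][, 1], pr[[2]][, 1]),
                                  rbind(pr[[1]][, 2], pr[[2]][, 2])),
                                dim = c(2, 400, 2)), c("A", "B"), fr$marker_ids)
    fit <- estimate_k(pair_class_probs(G2, 1, 2, fr))
    con <- apply_thompson_constraint(fit)
    k <- con$k_hat
    expect_gte(k[2]^2, 4 * k[1] * k[3] - 1e-10)
    expect_true(con$constrained)
    if (fit$k_hat[2]^2 >= 4 * fit$k_hat[1] * fit$k_hat[3] - 1e-10) {
      expect_identical(con$k_hat, fit$k_hat)       # feasible input unchanged
    } else {
      n_changed <- n_changed + 1L
      expect_lte(con$loglik, fit$loglik + 1e-9)    # projection cannot gain
    }
  }
  # the published FS estimate satisfies the inequality as is
  k_fs <- c(0.214, 0.617, 0.169)
  expect_gt(k_fs[2]^2, 4 * k_fs[1] * k_fs[3])
})

test_that("classification picks the nearest reference, ties toward low degree", {
  expect_equal(classify_relationship(c(0, 1, 0))$relationship, "PO")
  expect_equal(classify_relationship(c(1, 0, 0))$relationship, "UN")
  expect_equal(classify_relationship(c(0.3, 0.5, 0.2))$relationship, "FS")
  # brute-force distance check against all references
  refs <- dplyr::distinct(cotterman_reference(), k0, k1, k2, .keep_all = TRUE)
  set.seed(59)
  for (r in 1:20) {
    k <- drop(closure(stats::rexp(3)))
    d <- sqrt(colSums((t(as.matrix(refs[, c("k0", "k1", "k2")])) - k)^2))
    expect_equal(classify_relationship(k)$distance, min(d), tolerance = 1e-12)
  }
  # aitchison mode runs and agrees on a clear-cut case
  expect_equal(classify_relationship(c(0.26, 0.49, 0.25), "aitchison",
                                     m = 300)$relationship, "FS")
  # midpoint of PO (deg 1) and HS (deg 2) ties toward PO
  mid <- (c(0, 1, 0) + c(0.5, 0.5, 0)) / 2
  expect_equal(classify_relationship(mid)$relationship, "PO")
})

test_that("ibd_pairs estimates every pair and labels relationships", {
  set.seed(61)
  fr <- equifrequent_freqs(8, 120)
  G <- simulate_founders(10, fr, ids = letters[1:10])
  out <- ibd_pairs(G, freqs = fr, min_informative = 50)
  expect_equal(nrow(out), 45L)
  expect_equal(out$id1[1:9], rep("a", 9))
  expect_true(all(abs(out$k0 + out$k1 + out$k2 - 1) < 1e-10))
  expect_true(all(out$relationship %in% cotterman_reference()$relationship))
  # unrelated founders should mostly classify as UN with estimated freqs
  out2 <- ibd_pairs(G, min_informative = 50)   # full-sample frequencies
  expect_true(all(c("loglik", "ref_distance") %in% names(out2)))
  # leave-one-pair-out mode runs and may skip loci with absent alleles
  out3 <- ibd_pairs(G, loo_pair = TRUE, min_informative = 10)
  expect_true(all(out3$n_skipped >= 0))
})
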