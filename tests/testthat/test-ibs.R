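test_that("IBS counts equal the maximum matching between allele pairs", {
  expect_identical(ibs_count(c("A1", "A1"), c("A2", "A2")), 0L)
  expect_identical(ibs_count(c("A1", "A2"), c("A3", "A3")), 0L)
  expect_identical(ibs_count(c("A1", "A1"), c("A1", "A2")), 1L)
  expect_identical(ibs_count(c("A1", "A2"), c("A1", "A3")), 1L)
  expect_identical(ibs_count(c("A1", "A2"), c("A2", "A2")), 1L)
  expect_identical(ibs_count(c("A1", "A2"), c("A1", "A2")), 2L)
  expect_identical(ibs_count(c("A1", "A2"), c("A2", "A1")), 2L)
  expect_true(is.na(ibs_count(c(NA, NA), c("A1", "A1"))))
})

test_that("IBS count agrees with a brute-force matching oracle and is symmetric", {
  # oracle: best of the two possible slot pairings, enumerated explicitly
  oracle <- function(g1, g2) {
    best <- 0L
    for (perm in list(c(1, 2), c(2, 1))) {
      best <- max(best, sum(g1 == g2[perm]))
    }
    best
  }
  set.seed(3)
  for (r in 1:200) {
    g1 <- sample(1:4, 2, replace = TRUE)
    g2 <- sample(1:4, 2, replace = TRUE)
    expect_identical(ibs_count(g1, g2), as.integer(oracle(g1, g2)))
    expect_identical(ibs_count(g1, g2), ibs_count(g2, g1))
    expect_identical(ibs_count(g1, g2), ibs_count(rev(g1), g2))
  }
})

test_that("pair counts mask loci missing in either individual", {
  G <- geno_from_strings(rbind(
    c("1/2", "3/3", "1/1", NA,    "2/2"),
    c("1/2", "3/4", NA,    "1/2", "1/1")))
  v <- ibs_pair_counts(G, 1, 2)
  expect_equal(v$counts, c(2L, 1L, NA, NA, 0L))
  expect_equal(v$n_informative, 3L)
  # identical individuals share 2 everywhere
  G2 <- geno_from_strings(rbind(c("1/2", "3/3"), c("2/1", "3/3")))
  expect_equal(ibs_pair_counts(G2, 1, 2)$counts, c(2L, 2L))
  # per-locus recomputation oracle on a random pair
  set.seed(5)
  fr <- equifrequent_freqs(4, 10)
  Gr <- simulate_founders(2, fr)
  v2 <- ibs_pair_counts(Gr, 1, 2)
  manual <- vapply(1:10, function(j) {
    ibs_count(Gr$alleles[1, j, ], Gr$alleles[2, j, ])
  }, integer(1))
  expect_identical(v2$counts, manual)
})

test_that("summaries satisfy the simplex and moment identities", {
  # one hundred ones: mean 1, sd 0
  s <- ibs_summary(rep(1L, 100))
  expect_equal(c(s$mean, s$sd), c(1, 0))
  # fifty 0s and fifty 2s: the maximum-variance array, mean 1, sd 1
  s <- ibs_summary(rep(c(0L, 2L), 50))
  expect_equal(c(s$mean, s$sd), c(1, 1))
  # random arrays: p sums to one, mean = p1 + 2 p2, sd^2 = p1 + 4 p2 - mean^2
  set.seed(9)
  for (r in 1:25) {
    x <- sample(0:2, 37, replace = TRUE)
    s <- ibs_summary(x)
    expect_equal(s$p0 + s$p1 + s$p2, 1, tolerance = 1e-12)
    expect_equal(s$mean, s$p1 + 2 * s$p2, tolerance = 1e-12)
    expect_equal(s$sd^2, s$p1 + 4 * s$p2 - s$mean^2, tolerance = 1e-12)
    expect_equal(s$mean, mean(x))
    expect_equal(s$sd, sqrt(mean((x - mean(x))^2)))
  }
  expect_error(ibs_summary(rep(NA_integer_, 3)), "no informative")
})

test_that("summaries are invariant to marker order", {
  set.seed(13)
  x <- sample(c(0:2, NA), 60, replace = TRUE)
  s1 <- ibs_summary(x)
  s2 <- ibs_summary(sample(x))
  expect_equal(s1, s2)
})

test_that("all_pairs enumerates the upper triangle deterministically", {
  set.seed(17)
  G <- simulate_founders(5, equifrequent_freqs(5, 8))
  p <- ibs_pairs(G)
  expect_equal(nrow(p), 10L)
  expect_equal(p$id1[1:4], rep("S1", 4))
  expect_identical(p, ibs_pairs(G))
  G2 <- simulate_founders(2, equifrequent_freqs(5, 8))
  expect_equal(nrow(ibs_pairs(G2)), 1L)
})

test_that("multiset coefficient is exact and matches enumeration", {
  expect_equal(multiset_coefficient(3, 100), 5151)
  expect_equal(multiset_coefficient(3, 1), 3)
  # 9 ordered arrays of length 2 collapse to 6 multisets
  arr <- expand.grid(0:2, 0:2)
  expect_equal(multiset_coefficient(3, 2),
               nrow(unique(t(apply(arr, 1, sort)))))
  expect_error(multiset_coefficient(0, 5), "k >= 1")
  expect_error(multiset_coefficient(3, -1), "m >= 0")
})

test_that("msd domain enumerates all compositions; brute force agrees for small m", {
  d1 <- msd_domain(1)
  expect_equal(sorted_msd(d1$mean, d1$sd),
               cbind(c(0, 1, 2), c(0, 0, 0)))
  for (m in c(3, 4, 6)) {
    d <- msd_domain(m)
    expect_equal(sum(d$multiplicity), multiset_coefficient(3, m))
    expect_equal(sorted_msd(d$mean, d$sd), brute_msd_points(m),
                 tolerance = 1e-9)
  }
  expect_error(msd_domain(0), "\\[1, 2000\\]")
  expect_error(msd_domain(5000), "\\[1, 2000\\]")
})

test_that("domain extremes: mean in [0,2], sd in [0,1], max attained as expected", {
  d <- msd_domain(100)
  expect_true(all(d$mean >= 0 & d$mean <= 2))
  expect_true(all(d$sd >= 0 & d$sd <= 1))
  expect_equal(max(d$sd), 1)
  top <- d[which.max(d$sd), ]
  expect_equal(top$mean, 1)  # the fifty/fifty composition
  # odd m never attains sd = 1
  expect_lt(max(msd_domain(101)$sd), 1)
})

test_that("PO boundary is the minimal-sd edge for means >= 1", {
  m <- 50
  b <- po_boundary(m)
  expect_equal(nrow(b), m + 1L)
  expect_equal(unlist(b[1, c("mean", "sd")], use.names = FALSE), c(1, 0))
  expect_equal(unlist(b[m + 1, c("mean", "sd")], use.names = FALSE), c(2, 0))
  d <- msd_domain(m)
  for (r in seq_len(nrow(b))) {
    same_mean <- d$sd[abs(d$mean - b$mean[r]) < 1e-12]
    expect_equal(min(same_mean), b$sd[r], tolerance = 1e-9)
  }
})

test_that("every simulated pair falls inside the attainable domain", {
  set.seed(19)
  m <- 30
  d <- msd_domain(m)
  key <- paste(round(d$mean, 9), round(d$sd, 9))
  fr <- equifrequent_freqs(3, m)
  for (rel in c("PO", "FS", "UN")) {
    st <- simulate_pairs(rel, 10, fr, estimate = FALSE)$stats
    expect_true(all(paste(round(st$mean, 9), round(st$sd, 9)) %in% key))
  }
})
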