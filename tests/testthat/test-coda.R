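test_that("closure scales to the simplex and is idempotent", {
  expect_equal(drop(closure(c(1, 1, 2))), c(0.25, 0.25, 0.5))
  expect_equal(drop(closure(c(0.2, 0.3, 0.5))), c(0.2, 0.3, 0.5))
  expect_equal(closure(closure(c(3, 4, 5))), closure(c(3, 4, 5)))
  expect_error(closure(c(0, 0, 0)), "all-zero")
  expect_error(closure(c(-1, 1, 1)), "nonnegative")
  m <- closure(matrix(runif(30), ncol = 3))
  expect_equal(rowSums(m), rep(1, 10))
})

test_that("multiplicative zero replacement uses delta = 0.5/m", {
  out <- drop(replace_zeros(c(0, 0.65, 0.35), 100))
  expect_equal(out, c(0.005, 0.64675, 0.34825))
  expect_equal(sum(out), 1)
  # no zeros -> unchanged
  expect_equal(drop(replace_zeros(c(0.2, 0.3, 0.5), 100)), c(0.2, 0.3, 0.5))
  # two zeros, per-row m
  out2 <- replace_zeros(rbind(c(0, 1, 0), c(0, 0.5, 0.5)), c(10, 20))
  expect_equal(out2[1, ], c(0.05, 0.9, 0.05))
  expect_equal(out2[2, ], c(0.025, 0.4875, 0.4875))
  expect_true(all(out2 > 0))
})

test_that("ilr evaluates the three bases as defined", {
  z <- ilr(c(1, 1, 1) / 3, "z0")
  expect_equal(c(z$zb1, z$zb2), c(0, 0))
  for (b in c("z0", "z1", "z2")) {
    expect_equal(unlist(ilr(c(1, 1, 1) / 3, b)[, 1:2], use.names = FALSE), c(0, 0))
  }
  z1 <- ilr(c(0.25, 0.5, 0.25), "z1")
  expect_equal(z1$zb1, 0)
  expect_equal(z1$zb2, log(1 / 4) / sqrt(6), tolerance = 1e-12)
  # direct evaluation on a published full-sib composition
  p <- c(0.073, 0.532, 0.395)
  expect_equal(ilr(p, "z1")$zb1, log(0.395 / 0.073) / sqrt(2), tolerance = 1e-12)
  expect_equal(ilr(p, "z1")$zb1, 1.194, tolerance = 1e-3)
  # hand-evaluated second coordinates
  expect_equal(ilr(p, "z0")$zb1, log(0.395 / 0.532) / sqrt(2))
  expect_equal(ilr(p, "z2")$zb2, log(0.073 * 0.532 / 0.395^2) / sqrt(6))
})

test_that("zero parts give infinity flags with the right escape direction", {
  z <- ilr(c(0, 0.7, 0.3), "z1")   # c0 = 0: z11 -> +Inf, z12 -> -Inf
  expect_false(z$finite)
  expect_true(is.na(z$zb1))
  expect_equal(z$dir1 / abs(z$dir2), (1 / sqrt(2)) / (1 / sqrt(6)), tolerance = 1e-12)
  expect_gt(z$dir1, 0)
  expect_lt(z$dir2, 0)
  expect_equal(z$dir1^2 + z$dir2^2, 1)
  # c2 = 0 in z1: z11 -> -Inf
  z2 <- ilr(c(0.5, 0.5, 0), "z1")
  expect_lt(z2$dir1, 0)
  # empirical check: the epsilon-path direction converges to the flag
  dir_at <- function(eps) {
    ze <- ilr(c(eps, 0.7, 0.3), "z1")
    c(ze$zb1, ze$zb2) / sqrt(ze$zb1^2 + ze$zb2^2)
  }
  err <- function(eps) sqrt(sum((dir_at(eps) - c(z$dir1, z$dir2))^2))
  expect_lt(err(1e-40), err(1e-10))   # monotone approach
  expect_lt(err(1e-200), 0.005)
})

test_that("ilr_inverse is the exact inverse in every basis", {
  set.seed(23)
  comps <- random_composition(1000)
  for (b in c("z0", "z1", "z2")) {
    z <- ilr(comps, b)
    back <- ilr_inverse(cbind(z$zb1, z$zb2), b)
    expect_equal(back, comps, tolerance = 1e-10)
    z2 <- ilr(back, b)
    expect_equal(cbind(z2$zb1, z2$zb2), cbind(z$zb1, z$zb2), tolerance = 1e-10)
  }
  expect_equal(drop(ilr_inverse(c(0, 0), "z1")), rep(1 / 3, 3))
  # basis consistency: invert in z0, transform in z1 == direct z1
  z0 <- ilr(comps, "z0")
  via <- ilr(ilr_inverse(cbind(z0$zb1, z0$zb2), "z0"), "z1")
  direct <- ilr(comps, "z1")
  expect_equal(cbind(via$zb1, via$zb2), cbind(direct$zb1, direct$zb2),
               tolerance = 1e-10)
})

test_that("the three bases are isometries of the same geometry", {
  set.seed(29)
  a <- random_composition(200)
  b <- random_composition(200)
  d0 <- aitchison_distance(a, b, "z0")
  d1 <- aitchison_distance(a, b, "z1")
  d2 <- aitchison_distance(a, b, "z2")
  expect_equal(d0, d1, tolerance = 1e-10)
  expect_equal(d1, d2, tolerance = 1e-10)
  # metric axioms on random triples
  expect_equal(aitchison_distance(a, a), rep(0, 200))
  expect_equal(d1, aitchison_distance(b, a))
  cc <- random_composition(200)
  expect_true(all(aitchison_distance(a, cc) <=
                  d1 + aitchison_distance(b, cc) + 1e-12))
  expect_error(aitchison_distance(c(0, .5, .5), c(.2, .4, .4)), "zero parts")
})

test_that("ilr is scale invariant and its first coordinate reads ordering", {
  set.seed(31)
  raw <- matrix(rexp(300), ncol = 3)
  z1 <- ilr(closure(raw), "z1")
  z2 <- ilr(closure(raw * 7.3), "z1")
  expect_equal(z1, z2, tolerance = 1e-12)
  # z11 > 0 iff part 3 exceeds part 1
  cmp <- closure(raw)
  expect_equal(z1$zb1 > 0, cmp[, 3] > cmp[, 1])
})

test_that("ternary coordinates hit the vertex convention", {
  expect_equal(unlist(ternary_xy(c(1, 0, 0))), c(x = 0, y = 0))
  expect_equal(unlist(ternary_xy(c(0, 1, 0))), c(x = 1, y = 0))
  expect_equal(unlist(ternary_xy(c(0, 0, 1))), c(x = 0.5, y = sqrt(3) / 2))
  expect_equal(unlist(ternary_xy(c(1, 1, 1) / 3)),
               c(x = 0.5, y = sqrt(3) / 6))
})

test_that("feasible boundary satisfies k1^2 = 4 k0 k2 along the curve", {
  fb <- feasible_boundary(101)
  expect_equal(nrow(fb), 101L)
  expect_true(all(abs(fb$k1^2 - 4 * fb$k0 * fb$k2) < 1e-10))
  expect_equal(rowSums(as.matrix(fb)), rep(1, 101))
  # endpoints and apex
  expect_equal(unlist(fb[1, ], use.names = FALSE), c(0, 0, 1))
  expect_equal(unlist(fb[101, ], use.names = FALSE), c(1, 0, 0))
  expect_equal(max(fb$k1), 0.5)
  mid <- fb[which.max(fb$k1), ]
  expect_equal(unlist(mid, use.names = FALSE), c(1 / 4, 1 / 2, 1 / 4))
  expect_error(feasible_boundary(1), ">= 2")
  # the z12 coordinate is constant along the curve (the ilr ceiling)
  inner <- fb[fb$k0 > 0 & fb$k2 > 0, ]
  z <- ilr(as.matrix(inner), "z1")
  expect_equal(z$zb2, rep(ilr_feasible_ceiling(), nrow(inner)), tolerance = 1e-10)
})
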