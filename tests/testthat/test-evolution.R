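test_that("dirichlet-multinomial matches the closed-form beta-binomial at n = 2", {
  # with two categories and unit concentrations the category-1 count is
  # beta-binomial(2; 1, 1): uniform over {0, 1, 2}
  set.seed(42)
  draws <- rdirmnom(30000, 2, c(1, 1))[, 1]
  obs <- table(factor(draws, levels = 0:2))
  p <- stats::chisq.test(obs, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 1e-3)
})

test_that("dirichlet-multinomial mean is reward-proportional", {
  set.seed(43)
  draws <- rdirmnom(20000, 100, c(3, 1))
  expect_true(all(rowSums(draws) == 100))
  m <- mean(draws[, 1])
  se <- stats::sd(draws[, 1]) / sqrt(nrow(draws))
  expect_lt(abs(m - 75), 3 * se)
})

test_that("dirichlet-multinomial counts are overdispersed relative to the multinomial", {
  set.seed(44)
  alpha <- c(2, 3)
  dm <- rdirmnom(20000, 20, alpha)[, 1]
  mn <- stats::rbinom(20000, 20, alpha[1] / sum(alpha))
  expect_gt(stats::var(dm), stats::var(mn))
})

test_that("degenerate sizes and single categories are handled", {
  expect_identical(rdirmnom(3, 0, c(1, 2))[, 1], rep(0L, 3))
  expect_identical(as.vector(rdirmnom(2, 7, 5)), rep(7L, 2))
  set.seed(1)
  d <- rdirmnom(50, 10, c(0, 4, 0))
  expect_true(all(d[, c(1, 3)] == 0L))  # zero concentration, no counts
  expect_true(all(rowSums(d) == 10))
  expect_error(rdirmnom(1, 5, c(0, 0)), "any")
})

test_that("replication preserves class totals per location and is mean-faithful", {
  st <- make_state(S = c(10, 0, 5, 0), R = c(7, 7, 0, 1),
                   E = c(30, 20, 0, 0, 0, 0, 0, 0))
  rew <- list(S = c(1, 1, 1, 1), R = c(5, 1, 0, 2),
              E = c(8, 2, 0, 0, 0, 0, 0, 0))
  set.seed(9)
  e1 <- replicate(4000, replicate_population(st, rew)$E[1, 1])
  expect_equal(mean(e1), replication_mean(c(8, 2), 50)[1],
               tolerance = 3 * stats::sd(e1) / sqrt(length(e1)) / 40)
  one <- replicate_population(st, rew)
  expect_identical(sum(one$S), 15L)
  expect_identical(sum(one$R), 15L)
  expect_identical(sum(one$E), 50L)
})

test_that("a class with a single present type is unchanged by replication", {
  st <- make_state(S = c(12, 0, 0, 0), R = c(0, 0, 9, 0), E = rep(0L, 8))
  set.seed(10)
  out <- replicate_population(st, list(S = c(3, 0, 0, 0), R = c(0, 0, 1, 0),
                                       E = rep(0, 8)))
  expect_identical(out$S, st$S)
  expect_identical(out$R, st$R)
})

test_that("zero-reward classes fall back to uniform replication without crashing", {
  st <- make_state(E = c(5, 0, 0, 0, 0, 0, 0, 0))
  set.seed(11)
  out <- replicate_population(st, list(S = rep(0, 4), R = rep(0, 4),
                                       E = rep(0, 8)))
  expect_identical(sum(out$E), 5L)
  expect_identical(attr(out, "uniform_fallbacks"), 1L)
})

test_that("mutation is binomial thinning with uniform reallocation", {
  st <- make_state(S = c(10000, 0, 0, 0), R = c(0, 10000, 0, 0), E = rep(0L, 8))
  expect_identical(mutate_population(st, 0)$S, st$S)
  set.seed(13)
  all_mut <- mutate_population(st, 1)
  expect_identical(sum(all_mut$S), 10000L)
  expect_true(all(abs(all_mut$S[1, ] - 2500) < 4 * sqrt(10000 * 0.25 * 0.75)))
  some <- mutate_population(st, 0.01)
  # ~100 expected mutants; 3/4 of them land on a type other than the origin
  leaked <- sum(some$S[1, 2:4])
  expect_lt(abs(leaked - 75), 3 * sqrt(10000 * 0.01 * 0.99) + 10)
  expect_identical(sum(some$S), 10000L)
})

test_that("dispersion is a no-op on a single location and mixes on a torus", {
  st1 <- make_state(S = c(8, 1, 0, 0), R = c(4, 4, 0, 0), E = rep(0L, 8))
  expect_identical(disperse_population(st1, 1), st1)

  # 3x3 torus, everyone at the center, gamma = 1: ~1/4 at each of the 4
  # von Neumann neighbors
  S <- matrix(0L, 9, 4); S[5, 1] <- 20000L
  st <- make_state(S = S, R = matrix(0L, 9, 4), E = matrix(0L, 9, 8),
                   dims = c(3L, 3L))
  set.seed(14)
  out <- disperse_population(st, 1)
  expect_identical(sum(out$S), 20000L)
  expect_identical(out$S[5, 1], 0L)
  nbrs <- c(4, 6, 2, 8)  # column-major grid: up, down, left, right of center
  expect_true(all(out$S[nbrs, 1] > 0L))
  expect_true(all(abs(out$S[nbrs, 1] - 5000) < 4 * sqrt(20000 * 0.25 * 0.75)))
})

test_that("dispersion conserves agents under a reflecting boundary", {
  S <- matrix(0L, 4, 4); S[1, ] <- c(50L, 50L, 0L, 0L)
  st <- make_state(S = S, R = matrix(0L, 4, 4), E = matrix(0L, 4, 8),
                   dims = c(2L, 2L))
  set.seed(15)
  out <- disperse_population(st, 0.5, boundary = "reflect")
  expect_identical(sum(out$S), 100L)
  expect_true(all(out$S >= 0L))
})
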