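test_that("initial population has no endo-pairs and a near-even class split", {
  set.seed(5)
  cfg <- sim_config(total_agents = 10000L, generations = 1L)
  st <- init_population(cfg)
  expect_identical(sum(st$E), 0L)
  expect_identical(sum(st$S) + sum(st$R), 10000L)
  # binomial(N, 1/2): 4 sd tolerance around the even split
  expect_lt(abs(sum(st$S) - 5000), 4 * sqrt(10000 / 4))
})

test_that("initialization is reproducible under a fixed seed", {
  cfg <- sim_config(total_agents = 4L, generations = 1L)
  set.seed(99); a <- init_population(cfg)
  set.seed(99); b <- init_population(cfg)
  expect_identical(a, b)
  expect_error(sim_config(total_agents = 0), "total_agents")
})

test_that("encounters equal the smaller population and surplus sits out", {
  set.seed(2)
  st <- make_state(S = c(3, 0, 0, 0), R = c(2, 3, 0, 0))
  tal <- pair_encounters(st)
  expect_identical(sum(tal$extracellular), 3L)
  expect_identical(unname(tal$unpaired), c(0L, 2L))
  empty <- pair_encounters(make_state(R = c(4, 0, 0, 0)))
  expect_identical(sum(empty$extracellular), 0L)
  expect_identical(unname(empty$unpaired["R"]), 4L)
})

test_that("every endo-pair contributes exactly one intracellular encounter", {
  set.seed(3)
  st <- make_state(S = c(5, 0, 0, 0), R = c(5, 0, 0, 0),
                   E = c(2, 0, 0, 1, 0, 0, 0, 4))
  tal <- pair_encounters(st)
  expect_identical(tal$intracellular, st$E[1, ])
  expect_identical(sum(tal$intracellular), sum(st$E))
})

test_that("count-level pairing matches agent-level uniform matching", {
  s <- c(3, 1, 2, 0)
  r <- c(2, 2, 0, 0)
  reps <- 4000
  set.seed(31)
  ours <- replicate(reps, pair_encounters(make_state(S = s, R = r))$extracellular[1, 1])
  set.seed(62)
  oracle <- replicate(reps, match_agents_oracle(s, r)[1, 1])
  lv <- 0:3
  tab <- rbind(table(factor(ours, levels = lv)),
               table(factor(oracle, levels = lv)))
  keep <- colSums(tab) > 10
  p <- suppressWarnings(stats::chisq.test(tab[, keep]))$p.value
  expect_gt(p, 1e-3)
})

test_that("game play routes rewards and outcomes correctly", {
  tab <- default_payoff_table()
  # one honest/M1 sender meets an (A1 on M1, A2 on M2) receiver: outcome O1
  ex <- matrix(0L, 4, 4); ex[1, 2] <- 1L
  tal <- structure(list(extracellular = ex, intracellular = rep(0L, 8),
                        unpaired = c(S = 0L, R = 0L), location = 1L),
                   class = "encounter_tally")
  played <- play_generation(tal, tab)
  expect_equal(played$rewards$S, c(4, 0, 0, 0))
  expect_equal(played$rewards$R, c(0, 4, 0, 0))
  expect_equal(played$outcomes$extracellular, c(1, rep(0, 7)))

  # ten deceptive/M1 senders meet trusting (A1, A1) receivers: all O8
  ex2 <- matrix(0L, 4, 4); ex2[3, 1] <- 10L
  tal$extracellular <- ex2
  played2 <- play_generation(tal, tab)
  expect_equal(played2$outcomes$extracellular[8], 10)
  expect_equal(played2$rewards$R, rep(0, 4))     # U_R(O8) = 0
  expect_equal(played2$rewards$S[3], 50)         # 10 * U_S(O8)

  # one endo of type O1 earns the inclusive utility 8
  tal$extracellular <- matrix(0L, 4, 4)
  tal$intracellular <- c(1L, rep(0L, 7))
  played3 <- play_generation(tal, tab)
  expect_equal(played3$rewards$E, c(8, rep(0, 7)))
  expect_equal(played3$outcomes$intracellular, c(1, rep(0, 7)))
})

test_that("cellularization fuses encounters into endo types at the stated rate", {
  st <- make_state(S = c(3, 0, 2, 0), R = c(5, 0, 0, 0))
  set.seed(8)
  tal <- pair_encounters(st)
  expect_identical(cellularize(st, tal, 0), st)        # alpha = 0 no-op
  fused <- cellularize(st, tal, 1)                      # every encounter fuses
  expect_identical(sum(fused$E), 5L)
  expect_identical(sum(fused$S), 0L)
  expect_identical(sum(fused$R), 0L)
  # (HONEST,M1) x (A1,A1) -> O1; (DECEPTIVE,M1) x (A1,A1) -> O8
  expect_identical(unname(fused$E[1, c(1, 8)]), c(3L, 2L))
  expect_equal(total_population(fused), total_population(st))
})

test_that("decellularization reconstructs the sender exactly and the receiver up to the unseen message", {
  st <- make_state(E = c(0, 0, 0, 0, 0, 0, 0, 6))   # six O8 endo-pairs
  expect_identical(decellularize(st, 0), st)
  set.seed(12)
  out <- decellularize(st, 1)
  expect_identical(sum(out$E), 0L)
  expect_identical(unname(out$S[1, ]), c(0L, 0L, 6L, 0L))  # all (DECEPTIVE, M1)
  # receiver must answer M1 with A1: only types (A1,A1) and (A1,A2) possible
  expect_identical(sum(out$R[1, 1:2]), 6L)
  expect_identical(sum(out$R[1, 3:4]), 0L)
  expect_equal(total_population(out), total_population(st))
})

test_that("fission then fusion reproduces the original endo type", {
  for (o in 1:8) {
    st <- make_state(E = as.integer(1:8 == o))
    set.seed(40 + o)
    split <- decellularize(st, 1)
    tal <- pair_encounters(split)
    refused <- cellularize(split, tal, 1)
    expect_identical(unname(refused$E[1, ]), as.integer(1:8 == o))
  }
})

test_that("population total is conserved through all transitions", {
  set.seed(77)
  st <- make_state(S = c(9, 4, 7, 1), R = c(3, 8, 2, 5),
                   E = c(4, 1, 0, 2, 0, 3, 1, 5))
  n0 <- total_population(st)
  for (i in 1:20) {
    tal <- pair_encounters(st)
    st <- cellularize(st, tal, 0.3)
    st <- decellularize(st, 0.4)
    expect_equal(total_population(st), n0)
    expect_true(all(st$S >= 0) && all(st$R >= 0) && all(st$E >= 0))
  }
})
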