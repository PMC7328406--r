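test_that("proposals are uniform over the Moore neighbourhood with periodic
           wrap", {
  set.seed(1)
  moves <- t(replicate(90000, propose_move(c(3, 3), 5, 5)))
  key <- paste(moves[, 1], moves[, 2])
  freq <- table(key) / nrow(moves)
  expect_length(freq, 9)
  expect_true(all(abs(freq - 1 / 9) < 0.005))
  # wrap: all proposals from a corner stay on the lattice
  set.seed(2)
  corner <- t(replicate(200, propose_move(c(1, 1), 5, 5)))
  expect_true(all(corner >= 1 & corner <= 5))
  expect_setequal(unique(corner[, 1]), c(1, 2, 5))
})

test_that("acceptance ratios match the worked examples and the squared
           objective", {
  p <- grid_distribution(matrix(c(0.2, 0.1, 0.35, 0.35), 2, 2))
  m <- memory_model(2, 2)
  # 0.2 vs 0.1 cell under uniform memory: (0.2/0.1)^2 = 4
  expect_identical(acceptance_ratio(p, m, c(2, 1), c(1, 1), "trail"), 4)
  expect_identical(acceptance_ratio(p, m, c(2, 1), c(2, 1), "trail"), 1)
  expect_identical(acceptance_ratio(p, m, c(2, 1), c(2, 1), "plain_mh"), 1)
  p2 <- grid_distribution(matrix(c(0.2, 0.1, 0.35, 0.35), 2, 2))
  m2 <- memory_model(2, 2, counts = matrix(c(2, 1, 1, 1), 2, 2))
  # P 0.2 -> 0.1 with M(curr)=2, M(prop)=1: 0.5 * (0.1/1)/(0.2/2) = 0.5
  expect_equal(acceptance_ratio(p2, m2, c(1, 1), c(2, 1), "trail"), 0.5)
})

test_that("the acceptance ratio is exactly invariant under global rescaling
           of the memory", {
  p <- sparse_gamma_target(3, 3, 0.5, seed = 3)
  base <- matrix(c(1, 4, 2, 7, 1, 3, 2, 9, 5), 3, 3)
  m1 <- memory_model(3, 3, counts = base)
  m2 <- memory_model(3, 3, alpha = 10, counts = base * 10)
  for (i in 1:3) for (j in 1:3) {
    expect_identical(acceptance_ratio(p, m1, c(2, 2), c(i, j), "trail"),
                     acceptance_ratio(p, m2, c(2, 2), c(i, j), "trail"))
  }
})

test_that("zero-mass target cells never attract and never trap the walker", {
  p <- grid_distribution(matrix(c(0, 0.6, 0, 0.4), 2, 2),
                         normalize = FALSE)
  m <- memory_model(2, 2)
  expect_identical(acceptance_ratio(p, m, c(2, 1), c(1, 1), "trail"), 0)
  expect_identical(acceptance_ratio(p, m, c(2, 1), c(1, 1), "plain_mh"), 0)
  expect_identical(acceptance_ratio(p, m, c(1, 1), c(2, 1), "trail"), Inf)
  expect_identical(acceptance_ratio(p, m, c(1, 1), c(1, 2), "trail"), 1)
})

test_that("single-step transition probabilities match the brute-force oracle
           on a 3x3 grid for both variants", {
  p <- sparse_gamma_target(3, 3, 0.5, seed = 11)
  m <- memory_model(3, 3, counts = matrix(c(1, 5, 2, 3, 1, 8, 4, 1, 6),
                                          3, 3))
  for (variant in c("plain_mh", "trail")) {
    impl <- transition_matrix(p, m, variant)
    oracle <- oracle_transition_matrix(unclass(p), m$counts, variant)
    expect_equal(impl, oracle, tolerance = 1e-12)
    expect_equal(rowSums(impl), rep(1, 9), tolerance = 1e-12)
  }
})

test_that("a single step deposits exactly one marker at the post-decision
           cell", {
  p <- grid_distribution(matrix(0.25, 2, 2), normalize = FALSE)
  m <- memory_model(2, 2, alpha = 1)
  set.seed(5)
  out <- mh_step(p, m, c(1, 1), "trail")
  expect_equal(sum(out$m$counts), 5)  # 4 cells of prior + 1 deposit
  expect_equal(out$m$counts[out$state[1], out$state[2]], 2)
  expect_equal(sort(as.numeric(out$m$counts)), c(1, 1, 1, 2))
})

test_that("decay shrinks only the deposit excess, and at extreme decay the
           trail kernel reduces to Metropolis-Hastings on P^2", {
  p <- grid_distribution(matrix(0.25, 2, 2), normalize = FALSE)
  m <- memory_model(2, 2, alpha = 1, decay_lambda = 0.5,
                    counts = matrix(c(3, 1, 1, 1), 2, 2))
  set.seed(7)
  out <- mh_step(p, m, c(1, 1), "plain_mh")
  # prior mass is untouched; the excess of 2 decays by e^-0.5; one deposit
  expect_equal(sum(out$m$counts), 4 + 2 * exp(-0.5) + 1, tolerance = 1e-12)
  at_start <- all(out$state == c(1, 1))
  expect_equal(out$m$counts[1, 1],
               1 + 2 * exp(-0.5) + as.numeric(at_start), tolerance = 1e-12)
  # lambda -> Inf collapses M to the prior: trail == M-H targeting P^2
  p3 <- sparse_gamma_target(3, 3, 0.7, seed = 2)
  prior <- memory_model(3, 3, alpha = 1)
  p_sq <- grid_distribution(unclass(p3)^2)
  expect_equal(transition_matrix(p3, prior, "trail"),
               oracle_transition_matrix(unclass(p_sq),
                                        prior$counts, "plain_mh"),
               tolerance = 1e-12)
})

test_that("with frozen uniform memory the trail chain's empirical visit
           frequencies converge to P^2 renormalized", {
  p <- grid_distribution(matrix(c(0.5, 0.3, 0.2), 1, 3), normalize = FALSE)
  m <- memory_model(1, 3)
  # stationary distribution predicted by the analytic transition oracle
  tm <- oracle_transition_matrix(unclass(p), m$counts, "trail")
  ev <- eigen(t(tm))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expect_equal(stat, c(0.25, 0.09, 0.04) / 0.38, tolerance = 1e-9)
  set.seed(9)
  state <- c(1, 1)
  visits <- numeric(3)
  for (i in 1:40000) {
    out <- mh_step(p, m, state, "trail")   # m never updated: frozen memory
    state <- out$state
    visits[state[2]] <- visits[state[2]] + 1
  }
  expect_equal(visits / sum(visits), stat, tolerance = 0.02)
})

test_that("run_chain honours its contract: length, determinism, cleaning
           resets, and empty runs", {
  p <- sparse_gamma_target(5, 5, 0.5, seed = 4)
  cfg <- chain_config("trail", 500, seed = 21, cleaning_times = c(100, 300))
  tr1 <- run_chain(p, cfg)
  tr2 <- run_chain(p, cfg)
  expect_identical(tr1$states, tr2$states)
  expect_equal(nrow(tr1$states), 500)
  expect_false(identical(
    tr1$states, run_chain(p, chain_config("trail", 500, seed = 22))$states))
  # reset contract: memory equals the pure prior right after a cleaning time
  tr3 <- run_chain(p, chain_config("trail", 100, seed = 21,
                                   cleaning_times = 100))
  expect_identical(tr3$final_memory$counts, matrix(1, 5, 5))
  # empty cleaning set is identical to the no-cleaning condition
  expect_identical(run_chain(p, chain_config("trail", 400, seed = 3))$states,
                   run_chain(p, chain_config("trail", 400, seed = 3,
                                             cleaning_times = integer()))$states)
  tr0 <- run_chain(p, chain_config("trail", 0, seed = 1))
  expect_equal(nrow(tr0$states), 0)
  expect_identical(tr0$final_memory$counts, matrix(1, 5, 5))
  expect_equal(nrow(tr0$ce_curve), 0)
  expect_error(chain_config("trail", 10, cleaning_times = 11), "1..n_steps")
})

test_that("visit distributions normalize counts with optional smoothing", {
  expect_equal(unclass(visit_distribution(fake_trace(matrix(0, 2, 2)),
                                          smoothing_alpha = 1))[, ],
               matrix(0.25, 2, 2))
  expect_equal(as.numeric(visit_distribution(fake_trace(matrix(c(3, 1), 1, 2)))),
               c(0.75, 0.25))
  expect_equal(as.numeric(visit_distribution(
    fake_trace(matrix(c(1, 1, 2), 1, 3)), smoothing_alpha = 1)),
    c(2, 2, 3) / 7)
  expect_error(visit_distribution(fake_trace(matrix(0, 2, 2))), "no visits")
})

test_that("plain and trail chains both home in on a small target's
           distribution", {
  p <- sparse_gamma_target(3, 3, 1, seed = 6)
  tr <- run_chain(p, chain_config("plain_mh", 50000, seed = 8,
                                  ce_snapshot_interval = 50000))
  expect_lt(kl_divergence(p, visit_distribution(tr, 1)), 0.02)
  trt <- run_chain(p, chain_config("trail", 50000, seed = 8,
                                   ce_snapshot_interval = 50000))
  expect_lt(kl_divergence(p, visit_distribution(trt, 1)), 0.02)
  expect_equal(tail(tr$ce_curve$ce_nats, 1),
               cross_entropy(p, visit_distribution(tr, 1)),
               tolerance = 1e-12)
})
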