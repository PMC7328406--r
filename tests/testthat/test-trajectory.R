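test_that("trajectory validation catches bad spacing, bounds and columns", {
  good <- straight_trajectory()
  expect_s3_class(as_trajectories(good), "trajectories")
  bad_dt <- good
  bad_dt$t_s[3] <- bad_dt$t_s[3] + 0.05
  expect_error(as_trajectories(bad_dt), "0.1 s")
  bad_x <- good
  bad_x$x_mm[5] <- 1000
  expect_error(as_trajectories(bad_x), "arena")
  expect_error(as_trajectories(good[, -6]), "missing trajectory columns")
})

test_that("trajectory CSVs round-trip through the reader without validation
           errors", {
  trajs <- fan_cohort(n_colonies = 2, orders = 1:3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(trajs, path)
  back <- read_trajectory_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(trajs),
               tolerance = 1e-12)
})

test_that("pooled duration adds (n-1) * dt per walker", {
  trajs <- fan_cohort(n_colonies = 2, orders = 1:3, duration_s = 45)
  expect_equal(total_duration_s(trajs), 6 * 45)
})

test_that("cumulative curves hit the entropy floor in the identity case and
           stay constant for identical walkers", {
  sp <- coarse_spec()
  trajs <- fan_cohort(n_colonies = 3, orders = 1:4, duration_s = 8)
  tgt <- build_target(trajs, sp)
  cur <- cumulative_ce_curves(trajs, tgt, sp)
  expect_s3_class(cur, "ce_curve_set")
  # the pooled order-4 densities of all colonies together rebuilt the target,
  # so each colony curve ends near (above) the floor and the identity holds
  # when a single colony is the whole cohort:
  solo <- trajs[trajs$colony == "col1", ]
  tgt1 <- build_target(solo, sp)
  cur1 <- cumulative_ce_curves(solo, tgt1, sp)
  expect_equal(cur1$by_colony$ce_nats[4], entropy(tgt1), tolerance = 1e-3)
  expect_true(all(cur$by_colony$ce_nats >= cur$target_entropy))
  # six copies of one walker: flat curve
  rows <- lapply(1:6, function(k) {
    tr <- straight_trajectory(ant_id = paste0("a", k), order = k,
                              heading = 0.7, duration_s = 8)
    tr
  })
  same <- as_trajectories(do.call(rbind, rows))
  tgt2 <- build_target(same, sp)
  cur2 <- cumulative_ce_curves(same, tgt2, sp)
  expect_equal(diff(range(cur2$by_colony$ce_nats)), 0, tolerance = 1e-6)
  # summary means are plain arithmetic means over colonies
  sub <- cur$by_colony[cur$by_colony$order == 2, ]
  expect_equal(cur$summary$mean_ce[cur$summary$order == 2],
               mean(sub$ce_nats))
  expect_equal(cur$summary$n_colonies[1], 3)
})

test_that("a colony missing an order is reported by name", {
  trajs <- fan_cohort(n_colonies = 2, orders = 1:3)
  gap <- trajs[!(trajs$colony == "col2" & trajs$order == 2), ]
  tgt <- build_target(gap, coarse_spec())
  expect_error(cumulative_ce_curves(gap, tgt, coarse_spec()),
               "col2 is missing order\\(s\\) 2")
})

test_that("paired samples align colony and order across treatments", {
  sp <- coarse_spec()
  nc <- fan_cohort(3, 1:3, treatment = "NC")
  c_ <- fan_cohort(3, 1:3, treatment = "C")
  both <- as_trajectories(rbind(nc, c_))
  tgt <- build_target(both, sp)
  cur <- cumulative_ce_curves(both, tgt, sp)
  pr <- paired_treatment_samples(cur, orders = 2:3)
  expect_length(pr$values_a, 6)
  expect_equal(pr$labels$order, rep(2:3, 3))
})

test_that("markov ants concatenate admissible 1 s segments reproducibly", {
  pool <- fan_cohort(n_colonies = 2, orders = 1:6, duration_s = 10)
  mk1 <- markov_ant_resample(pool, duration_s = 30, seed = 5)
  mk2 <- markov_ant_resample(pool, duration_s = 30, seed = 5)
  expect_equal(nrow(mk1), 30 / 0.1 + 1)
  expect_identical(mk1$x_mm, mk2$x_mm)
  expect_true(all(abs(mk1$x_mm) <= 450 & abs(mk1$y_mm) <= 450))
  # zero-displacement pool pins the walker to its start
  still <- data.frame(ant_id = "s", colony = "c", treatment = "NC",
                      order = 1, t_s = seq(0, 5, 0.1), x_mm = 10, y_mm = -3)
  mk3 <- markov_ant_resample(as_trajectories(still), duration_s = 10,
                             seed = 1, start = c(10, -3))
  expect_true(all(mk3$x_mm == 10 & mk3$y_mm == -3))
  # a pool that only marches outward eventually strands the walker
  march <- data.frame(ant_id = "m", colony = "c", treatment = "NC",
                      order = 1, t_s = seq(0, 5, 0.1),
                      x_mm = seq(0, by = 8, length.out = 51), y_mm = 0)
  expect_error(markov_ant_resample(as_trajectories(march), duration_s = 20,
                                   seed = 1, max_retries = 20),
               "no admissible segment")
  expect_error(markov_ant_resample(pool[0, ]), "empty")
})

test_that("markov colonies carry colony and order labels", {
  pool <- fan_cohort(n_colonies = 1, orders = 1:2, duration_s = 10)
  mk <- simulate_markov_colonies(pool, n_colonies = 2, ants_per_colony = 3,
                                 duration_s = 5, seed = 2)
  expect_equal(length(unique(mk$colony)), 2)
  expect_equal(sort(unique(mk$order)), 1:3)
  expect_equal(nrow(mk), 2 * 3 * 51)
})

test_that("exit sides are assigned by the first interpolated boundary
           crossing", {
  w <- 100
  marching <- data.frame(ant_id = "a", colony = "c", treatment = "NC",
                         order = 1, t_s = seq(0, 2, 0.1),
                         x_mm = seq(0, 200, 10), y_mm = 0)
  res <- exit_sides(as_trajectories(marching), w)
  expect_equal(res$counts[["right"]], 1)
  # big diagonal jump: crossing x = w happens before y = w
  jump <- data.frame(ant_id = "b", colony = "c", treatment = "NC",
                     order = 1, t_s = c(0, 0.1),
                     x_mm = c(0, 2 * w), y_mm = c(0, w / 2))
  expect_equal(exit_sides(jump, w)$counts[["right"]], 1)
  steep <- data.frame(ant_id = "d", colony = "c", treatment = "NC",
                      order = 1, t_s = c(0, 0.1),
                      x_mm = c(0, w / 2), y_mm = c(0, -2 * w))
  expect_equal(exit_sides(steep, w)$counts[["bottom"]], 1)
  confined <- data.frame(ant_id = "e", colony = "c", treatment = "NC",
                         order = 1, t_s = seq(0, 1, 0.1),
                         x_mm = rep(c(10, -10), length.out = 11), y_mm = 0)
  res2 <- exit_sides(confined, w)
  expect_equal(sum(res2$counts), 0)
  expect_equal(res2$n_non_exiting, 1)
  expect_true(is.na(res2$by_ant$side))
})
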