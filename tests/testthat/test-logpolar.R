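test_that("lattice geometry follows the step sizes, padded range doubling
           the truncated one", {
  sp <- coarse_spec()
  expect_equal(sp$n_theta_trunc, 2 * floor(pi / 0.1) + 1)
  expect_equal(sp$n_theta_pad, 2 * sp$n_theta_trunc - 1)
  expect_equal(sp$n_lnr, round((6.5 - 4.3) / 0.025) + 1)
  expect_equal(range(sp$theta_nodes_trunc), c(-3.1, 3.1))
  expect_equal(sp$lnr_nodes[1], 4.3)
  expect_equal(tail(sp$lnr_nodes, 1), 6.5)
})

test_that("log-polar transform matches closed forms, drops out-of-range and
           zero-radius points, and round-trips radii", {
  pts <- data.frame(x_mm = c(100, 0, 50, 0, -300),
                    y_mm = c(0, -100, 0, 0, 0))
  lp <- cartesian_to_logpolar(pts)
  # (100, 0) -> (0, ln 100); (0, -100) -> (-pi/2, ln 100); r = 50 and r = 0
  # dropped; (-300, 0) -> (pi, ln 300)
  expect_equal(attr(lp, "n_dropped"), 2)
  expect_equal(lp$theta, c(0, -pi / 2, pi))
  expect_equal(lp$lnr, c(log(100), log(100), log(300)))
  set.seed(3)
  r <- runif(200, 80, 600)
  th <- runif(200, -pi, pi)
  lp2 <- cartesian_to_logpolar(data.frame(x_mm = r * cos(th),
                                          y_mm = r * sin(th)))
  expect_equal(exp(lp2$lnr), r[log(r) > 4.3 & log(r) < 6.5],
               tolerance = 1e-9)
})

test_that("periodic padding doubles the points with the stated +-2pi
           shifts", {
  pts <- data.frame(theta = c(-pi / 2, pi / 2, 0), lnr = c(5, 5.5, 6))
  out <- periodic_pad(pts)
  expect_equal(nrow(out), 6)
  expect_equal(out$theta[4:6], c(-pi / 2 + 2 * pi, pi / 2 - 2 * pi,
                                 0 + 2 * pi))
  expect_equal(out$lnr[4:6], pts$lnr)
})

test_that("the blur conserves mass, fixes uniform fields, and build_density
           normalizes with the mode at a lone point", {
  set.seed(8)
  a <- matrix(rpois(40 * 30, 3), 40, 30)
  expect_equal(sum(gaussian_blur(a, 4)), sum(a), tolerance = 1e-9)
  expect_equal(gaussian_blur(matrix(2, 15, 15), 5), matrix(2, 15, 15),
               tolerance = 1e-12)
  sp <- coarse_spec()
  one <- periodic_pad(data.frame(theta = 1.4, lnr = 5.3))
  d <- build_density(one, sp)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  peak <- which(unclass(d) == max(d), arr.ind = TRUE)
  expect_equal(sp$theta_nodes_trunc[peak[1]], 1.4, tolerance = 0.051)
  expect_equal(sp$lnr_nodes[peak[2]], 5.3, tolerance = 0.0126)
  # duplicating every point leaves the normalized density unchanged
  expect_equal(unclass(build_density(rbind(one, one), sp))[, ],
               unclass(d)[, ], tolerance = 1e-12)
  expect_error(build_density(one[0, ], sp), "zero points")
})

test_that("the mask filter keeps the boundary and everything outward", {
  pts <- data.frame(ant_id = "a", colony = "c", treatment = "NC", order = 1,
                    t_s = c(0, 0.1, 0.2),
                    x_mm = c(0, 400, 75), y_mm = c(0, 400, 0))
  out <- remove_mask_region(pts)
  expect_equal(out$x_mm, c(400, 75))
})

test_that("build_target produces the full-resolution lattice and composes
           the pipeline deterministically", {
  trajs <- fan_cohort(n_colonies = 1, orders = 1:3, duration_s = 6)
  tgt <- build_target(trajs)   # default spec: 629 x 881 truncated lattice
  expect_equal(dim(tgt), c(629, 881))
  expect_equal(sum(tgt), 1, tolerance = 1e-9)
  expect_identical(unclass(build_target(trajs))[, ], unclass(tgt)[, ])
  # pooling a cohort with itself changes nothing after normalization
  doubled <- as_trajectories(rbind(
    trajs, transform(trajs, ant_id = paste0(ant_id, "-copy"))))
  sp <- coarse_spec()
  expect_equal(unclass(build_target(doubled, sp))[, ],
               unclass(build_target(trajs, sp))[, ], tolerance = 1e-12)
})

test_that("a planted quadrant bias shows up in the target's angular mass", {
  set.seed(11)
  n <- 4000
  th <- c(runif(n * 0.75, pi / 2, pi), runif(n * 0.25, -pi / 2, 0))
  r <- runif(length(th), 100, 440)
  trajs <- data.frame(ant_id = "a", colony = "c", treatment = "NC",
                      order = 1, t_s = seq(0, by = 0.1,
                                           length.out = length(th)),
                      x_mm = r * cos(th), y_mm = r * sin(th))
  sp <- coarse_spec()
  tgt <- build_target(as_trajectories(trajs), sp)
  band <- function(lo, hi) sum(tgt[sp$theta_nodes_trunc > lo &
                                     sp$theta_nodes_trunc < hi, ])
  expect_gt(band(pi / 2, pi), band(-pi / 2, 0))
})
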