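# Closed-loop BMI: workspace geometry, encoder, exact viscous dynamics,
# trajectory generation with decoder stubs, and the metric suite.

test_that("workspace geometry: quadrant forces point at the target", {
  ws <- bmi_workspace()
  expect_equal(ws$side, 36)
  expect_equal(dim(ws$start_positions), c(8L, 2L))
  for (d in 1:4) {
    u <- ws$forces[d, ] / sqrt(sum(ws$forces[d, ]^2))
    v <- -ws$centroids[d, ] / sqrt(sum(ws$centroids[d, ]^2))
    expect_equal(u, v, tolerance = 1e-12)
    expect_equal(sqrt(sum(ws$forces[d, ]^2)), ws$f_mag, tolerance = 1e-12)
  }
})

test_that("the encoder partitions the plane with the stated boundary rule", {
  ws <- bmi_workspace()
  expect_equal(encode_position(c(9, 9), ws), 1L)
  expect_equal(encode_position(c(-9, 9), ws), 2L)
  expect_equal(encode_position(c(-9, -9), ws), 3L)
  expect_equal(encode_position(c(9, -9), ws), 4L)
  expect_equal(encode_position(c(0, 5), ws), 1L)    # boundary: x >= 0
  expect_equal(encode_position(c(0, 0), ws), 1L)    # origin -> region 1
  expect_error(encode_position(c(30, 0), ws), "outside")

  set.seed(17)
  pts <- matrix(runif(20000, -18, 18), ncol = 2)
  regions <- apply(pts, 1, encode_position, workspace = ws)
  expect_true(all(regions %in% 1:4))
  expect_true(all(abs(tabulate(regions, 4L) / 10000 - 0.25) < 0.02))
})

test_that("viscous dynamics match the exponential closed form", {
  m <- 0.02; b <- 0.4; dt <- 0.5
  # free decay from unit velocity
  s <- step_dynamics(list(position = c(0, 0), velocity = c(1, 0)),
                     c(0, 0), dt, m, b)
  expect_equal(s$velocity[1], exp(-b * dt / m), tolerance = 1e-12)
  # terminal velocity under constant force (100 cm/m conversion)
  s2 <- list(position = c(0, 0), velocity = c(0, 0))
  for (i in 1:40) s2 <- step_dynamics(s2, c(0.008, 0), dt, m, b)
  expect_equal(s2$velocity[1], 100 * 0.008 / b, tolerance = 1e-9)

  # one exact step vs high-resolution sub-stepping: < 1e-6 cm
  s_one <- step_dynamics(list(position = c(1, 2), velocity = c(3, -1)),
                         c(0.004, -0.002), dt, m, b)
  s_sub <- list(position = c(1, 2), velocity = c(3, -1))
  for (i in 1:100000)
    s_sub <- step_dynamics(s_sub, c(0.004, -0.002), dt / 100000, m, b)
  expect_lt(max(abs(s_one$position - s_sub$position)), 1e-6)

  # speed decreases monotonically whenever the force is zero
  st <- list(position = c(0, 0), velocity = c(2, 1))
  sp <- sqrt(sum(st$velocity^2))
  for (i in 1:10) {
    st <- step_dynamics(st, c(0, 0), 0.05, m, b)
    expect_lt(sqrt(sum(st$velocity^2)), sp)
    sp <- sqrt(sum(st$velocity^2))
  }
  expect_error(step_dynamics(st, c(NA, 0), dt, m, b), "non-finite")
})

test_that("an ideal decoder converges from every start position", {
  ws <- bmi_workspace(r_target = 2)
  for (s in seq_len(nrow(ws$start_positions))) {
    tr <- run_trajectory(ws$start_positions[s, ], ws, ideal_stub)
    expect_true(tr$converged)
    expect_lte(tr$n_steps, 100L)
    expect_lte(sqrt(sum(tr$positions[nrow(tr$positions), ]^2)), 2)
  }
  # calibration invariant: also for the smaller radii
  for (r in c(0.5, 1)) {
    ws_r <- bmi_workspace(r_target = r)
    tr <- run_trajectory(ws_r$start_positions[1, ], ws_r, ideal_stub)
    expect_true(tr$converged)
  }
})

test_that("an antipodal decoder never converges and stops at 100 steps", {
  ws <- bmi_workspace(r_target = 2)
  tr <- run_trajectory(c(14, 0), ws, antipodal_stub)
  expect_false(tr$converged)
  expect_equal(tr$n_steps, 100L)
})

test_that("closed-loop trajectories are reproducible from the seed", {
  p <- tiny_params(seed = 3, n_units = 3L)
  ses <- generate_session(p)
  sch <- make_default_schedule(0.75, p$post_span, p$artifact_blank)
  dec <- sd_decoder(assemble_dataset(ses, sch, "SI", "SUA"), k = 8,
                    p_thr = 0.8)
  ws <- bmi_workspace(r_target = 2)
  o1 <- neural_oracle(p, seed = 77, scales = ses$meta$scales)
  o2 <- neural_oracle(p, seed = 77, scales = ses$meta$scales)
  t1 <- run_trajectory(c(10, 10), ws, dec, sch, o1, max_steps = 15)
  t2 <- run_trajectory(c(10, 10), ws, dec, sch, o2, max_steps = 15)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$p_tilde, t2$p_tilde)
  expect_true(all(abs(rowSums(t1$p_tilde) - 1) < 1e-9))
})

test_that("the session protocol aggregates the declared metrics", {
  ws <- bmi_workspace(r_target = 2)
  prot <- run_session_protocol(ws, ideal_stub, reps_per_start = 2, seed = 1)
  expect_length(prot$trajectories, 16L)
  m <- prot$metrics
  expect_equal(m$convergence_rate, 100)
  expect_true(m$mean_steps > 5 && m$mean_steps < 100)
  expect_length(m$closest_distance_mm, 16L)
  expect_length(m$wtv_by_start, 8L)
  expect_length(m$mean_trajectories, 8L)
  expect_equal(dim(m$displacement_cov[[1]]), c(2L, 2L))
})

test_that("ideal-decoder convergence speeds up as the target grows", {
  steps_for <- function(r) {
    ws <- bmi_workspace(r_target = r)
    prot <- run_session_protocol(ws, ideal_stub, reps_per_start = 1, seed = 1)
    prot$metrics$mean_steps
  }
  s05 <- steps_for(0.5); s1 <- steps_for(1); s2 <- steps_for(2)
  expect_lt(s2, s1)
  expect_lt(s1, s05)
})

test_that("convergence rate is the percentage of converging trajectories", {
  mk <- function(conv) {
    structure(list(positions = rbind(c(5, 0), c(4, 0), c(3, 0)),
                   forces = rbind(c(0, 0), c(0, 0)),
                   p_tilde = matrix(0.25, 2, 4), stimuli = c(1L, 1L),
                   converged = conv, n_steps = 2L, start = c(5, 0),
                   start_index = 1L), class = "bmi_trajectory")
  }
  trajs <- c(replicate(7, mk(TRUE), simplify = FALSE),
             replicate(3, mk(FALSE), simplify = FALSE))
  m <- trajectory_metrics(trajs, bmi_workspace(r_target = 1))
  expect_equal(m$convergence_rate, 70)
})

test_that("closest-point distance is a minimum in mm, rotation-invariant", {
  pos <- cbind(seq(10, 2, length.out = 9), 0)
  tr <- list(positions = pos)
  expect_equal(closest_point_distance(tr), 20)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(closest_point_distance(list(positions = pos %*% rot)), 20,
               tolerance = 1e-9)
  # passing through the origin -> 0
  expect_equal(closest_point_distance(list(positions = rbind(c(1, 1), c(0, 0)))), 0)
})

test_that("directed force projects onto the position-to-target direction", {
  expect_equal(directed_force(c(1, 0), c(-5, 0)), 1)       # straight at it
  expect_equal(directed_force(c(0, 1), c(-5, 0)), 0)       # orthogonal
  expect_equal(directed_force(c(-3, 0), c(5, 0)), 3)       # toward target
  expect_equal(directed_force(c(3, 0), c(5, 0)), -3)       # away
  expect_true(is.na(directed_force(c(1, 0), c(0, 0))))
})

test_that("within-trajectory variance follows the root-sum-of-squares form", {
  mk_traj <- function(disp) {
    list(positions = apply(rbind(c(0, 0), disp), 2, cumsum))
  }
  # identical displacements everywhere -> zero
  t1 <- mk_traj(rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(within_trajectory_variance(list(t1, t1)), 0)

  # constructed variances C_x = 3, C_y = 4 -> wtv = 5
  set.seed(3)
  dx <- rnorm(4000); dx <- (dx - mean(dx)) / sd(dx) * sqrt(3)
  dy <- rnorm(4000); dy <- (dy - mean(dy)) / sd(dy) * sqrt(4)
  tA <- mk_traj(cbind(dx[1:2000], dy[1:2000]))
  tB <- mk_traj(cbind(dx[2001:4000], dy[2001:4000]))
  wtv <- within_trajectory_variance(list(tA, tB))
  expect_equal(wtv, 5, tolerance = 0.05)

  # invariant under a constant drift added to every displacement
  tA2 <- mk_traj(cbind(dx[1:2000] + 10, dy[1:2000] - 3))
  tB2 <- mk_traj(cbind(dx[2001:4000] + 10, dy[2001:4000] - 3))
  expect_equal(within_trajectory_variance(list(tA2, tB2)), wtv,
               tolerance = 1e-6)

  expect_error(within_trajectory_variance(list(t1)), "at least 2")
})

test_that("trajectories serialize to the documented CSV schema", {
  ws <- bmi_workspace(r_target = 2)
  prot <- run_session_protocol(ws, ideal_stub, reps_per_start = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(prot$trajectories, path)
  df <- read.csv(path)
  expect_named(df, c("trajectory_id", "step", "x_cm", "y_cm", "vx", "vy",
                     "Fx", "Fy", "stimulus", "converged"))
  expect_equal(sort(unique(df$trajectory_id)), 1:8)
})
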