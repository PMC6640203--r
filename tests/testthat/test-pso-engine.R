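make_particle <- function(position, velocity, pbest = position) {
  list(id = 1L, position = position, velocity = velocity,
       pbest_position = pbest, pbest_energy = 0, stream = NULL)
}

test_that("inertia weight descends linearly over the schedule", {
  cfg <- swarm_config(max_iter = 100)
  expect_equal(inertia_at(0, cfg), 0.8)
  expect_equal(inertia_at(100, cfg), 0.4)
  expect_equal(inertia_at(50, cfg), 0.6)
  const <- swarm_config(w_min = 0.6, w_max = 0.6)
  expect_equal(inertia_at(0, const), 0.6)
  expect_equal(inertia_at(417, const), 0.6)
})

test_that("velocity update reproduces the hand-computed example", {
  # scalar case: w = 0.4, v = 1, x = 0, pbest = 1, gbest = 2,
  # d1 = d2 = 2, eps1 = eps2 = 0.5  ->  v' = 0.4 + 1 + 2 = 3.4
  cfg <- swarm_config()
  p <- make_particle(0, 1, pbest = 1)
  v_new <- update_velocity(p, gbest = 2, w = 0.4, cfg,
                           eps1 = 0.5, eps2 = 0.5)
  expect_equal(v_new, 3.4)
  # and the position update: x' = 0 + 3.4 ... plus the stated 1 + 3.4 case
  expect_equal(update_position(1, v_new, swarm_config(velocity_clamp = NULL)),
               4.4)
})

test_that("velocity update limits: identity and vanishing attraction", {
  cfg0 <- swarm_config(d1 = 0, d2 = 0)
  p <- make_particle(c(1, 2, 3), c(0.3, -0.2, 0.1), pbest = c(0, 0, 0))
  expect_equal(update_velocity(p, c(9, 9, 9), w = 1, cfg0,
                               eps1 = runif(3), eps2 = runif(3)),
               p$velocity)
  cfg <- swarm_config()
  x <- c(0.5, -1, 2)
  p2 <- make_particle(x, c(1, 1, 1), pbest = x)
  expect_equal(update_velocity(p2, x, w = 0.7, cfg,
                               eps1 = runif(3), eps2 = runif(3)),
               0.7 * c(1, 1, 1))
  expect_error(update_velocity(p2, c(0, 0), w = 0.7, cfg), "shape")
})

test_that("position update applies the velocity clamp", {
  cfg <- swarm_config(velocity_clamp = 2.0)
  expect_equal(update_position(0, 10, cfg), 2.0)
  expect_equal(update_position(c(1, 1), c(-10, 0.5), cfg), c(-1, 1.5))
  expect_equal(update_position(c(1, 2), c(0, 0), cfg), c(1, 2))
  expect_error(update_position(c(1, 2), 1, cfg), "shape")
})

test_that("with w = 1 and no attraction, motion is straight-line inertial", {
  cfg <- swarm_config(w_min = 1, w_max = 1, d1 = 0, d2 = 0,
                      velocity_clamp = NULL)
  x0 <- c(0.2, -0.4, 1)
  v0 <- c(0.05, 0.1, -0.2)
  p <- make_particle(x0, v0, pbest = c(9, 9, 9))
  x <- x0
  for (t in 1:7) {
    v <- update_velocity(p, c(-9, 9, 0), w = 1, cfg,
                         eps1 = runif(3), eps2 = runif(3))
    x <- update_position(x, v, cfg)
    p$position <- x
    p$velocity <- v
    expect_equal(x, x0 + t * v0, tolerance = 1e-14)
  }
})

test_that("best-tracking replaces on strict improvement, keeps ties", {
  cfg <- swarm_config(n_pop = 3, seed = 5)
  s <- init_swarm(cfg, n_atoms = 2)
  e <- function(vals) lapply(vals, function(x)
    psocluster:::energy_result("ok", x))
  s <- update_bests(s, e(list(5, 3, 7)))
  expect_equal(s$gbest_energy, 3)
  expect_identical(s$gbest_position, s$particles[[2]]$pbest_position)
  # equal energy keeps the incumbent pbest position
  old_pbest <- s$particles[[2]]$pbest_position
  s$particles[[2]]$position <- s$particles[[2]]$position + 1
  s <- update_bests(s, e(list(6, 3, 8)))
  expect_identical(s$particles[[2]]$pbest_position, old_pbest)
  # improvement installs the new position and gbest follows the min
  s$particles[[1]]$position <- s$particles[[1]]$position + 2
  s <- update_bests(s, e(list(1, 4, 9)))
  expect_equal(s$gbest_energy, 1)
  expect_identical(s$gbest_position, s$particles[[1]]$position)
  pbests <- vapply(s$particles, `[[`, numeric(1), "pbest_energy")
  expect_equal(s$gbest_energy, min(pbests))
  expect_error(update_bests(s, e(list(1, 2))), "per particle")
})

test_that("stall rule fires only on a full unchanged window", {
  cfg <- swarm_config(stall_threshold = 30, energy_tol = 1e-6)
  expect_true(has_converged(rep(-5, 31), cfg))
  expect_false(has_converged(rep(-5, 30), cfg))
  expect_false(has_converged(c(rep(-5, 30), -5 - 1e-5), cfg))
  expect_true(has_converged(c(-1, rep(-5, 31)), cfg))
  expect_true(has_converged(-5 + cumsum(rep(1e-9, 31)), cfg))
})

test_that("runs are deterministic under a fixed seed", {
  b <- lj_backend()
  # 15 particles: the population size of the published computational setup
  cfg <- swarm_config(seed = 21, n_pop = 15, max_iter = 60,
                      stall_threshold = 59)
  r1 <- run_pso(cfg, b, n_atoms = 3)
  r2 <- run_pso(cfg, b, n_atoms = 3)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$best_energy, r2$best_energy)
})

test_that("gbest trajectory is non-increasing across random configurations", {
  for (seed in 1:25) {
    n_atoms <- 2 + seed %% 4
    cfg <- swarm_config(seed = seed,
                        n_pop = 4 + seed %% 5,
                        max_iter = 30,
                        stall_threshold = 29)
    r <- run_pso(cfg, lj_backend(), n_atoms = n_atoms)
    expect_true(all(diff(r$trajectory) <= 0))
    expect_equal(r$best_energy, r$trajectory[length(r$trajectory)])
  }
})

test_that("the swarm drives a 2-D sphere objective to its known minimum", {
  sphere <- function_backend(function(v) sum(v * v), name = "sphere")
  cfg <- swarm_config(seed = 8, max_iter = 500, stall_threshold = 499)
  r <- run_pso(cfg, sphere, dim = 2)
  expect_lte(r$best_energy, 1e-6)
  expect_lte(r$iterations_used, 500)
})

test_that("an all-penalty first iteration warns but the run continues", {
  always_fail <- function_backend(function(v) stop("SCF blew up"))
  cfg <- swarm_config(seed = 2, max_iter = 40)
  r <- run_pso(cfg, always_fail, n_atoms = 2)
  expect_gt(length(r$warnings), 0)
  expect_match(r$warnings[1], "penalty")
  # constant penalty energies satisfy the stall rule immediately
  expect_true(r$converged)
  expect_equal(r$best_energy, 1e6)
})

test_that("restart_search with one restart degenerates to run_pso", {
  b <- lj_backend()
  cfg <- swarm_config(seed = 13, max_iter = 50, stall_threshold = 49,
                      n_restarts = 1)
  r1 <- restart_search(cfg, b, n_atoms = 3)
  r2 <- run_pso(cfg, b, n_atoms = 3)
  expect_identical(r1$best_energy, r2$best_energy)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$restarts_used, 1L)
})

test_that("self-consistency stops the restart loop early on a unimodal landscape", {
  sphere <- function_backend(function(v) sum(v * v), name = "sphere")
  cfg <- swarm_config(seed = 4, max_iter = 400, stall_threshold = 60,
                      n_restarts = 6)
  r <- restart_search(cfg, sphere, dim = 2)
  expect_lt(r$restarts_used, 6L)
  expect_gte(r$restarts_used, 2L)
  consec <- abs(diff(r$restart_energies))
  expect_lte(consec[length(consec)], cfg$energy_tol)
  expect_true(all(diff(r$trajectory) <= 1e-12))
  expect_equal(r$best_energy, min(r$restart_energies))
})

test_that("a start geometry seeds the swarm and fixes the element labels", {
  b <- lj_backend()
  start <- unflatten_geometry(triangle_positions(1.3), c("Ar", "Ar", "Ar"))
  cfg <- swarm_config(seed = 2, max_iter = 150)
  r <- run_pso(cfg, b, start = start)
  expect_identical(r$best_geometry$elements, c("Ar", "Ar", "Ar"))
  # seeded near the triangle funnel, the run relaxes into it
  expect_lt(r$best_energy, -2.9)
})

test_that("restart trajectories and bests stay coherent on clusters", {
  b <- lj_backend()
  cfg <- swarm_config(seed = 6, max_iter = 120, n_restarts = 3)
  r <- restart_search(cfg, b, n_atoms = 3)
  expect_true(all(diff(r$trajectory) <= 0))
  expect_equal(r$best_energy, min(r$restart_energies))
  expect_equal(r$best_energy, r$trajectory[length(r$trajectory)])
  expect_s3_class(r$best_geometry, "cluster_geometry")
  expect_identical(r$best_geometry$elements, rep("C", 3))
})
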