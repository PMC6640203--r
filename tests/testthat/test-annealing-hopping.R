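test_that("Metropolis rule: downhill always, uphill by Boltzmann, Inf never", {
  expect_true(sa_accept(-1, 1e-9))
  expect_true(sa_accept(0, 0.5))
  expect_false(sa_accept(Inf, 100))
  expect_error(sa_accept(1, 0), "T must be")
  # T -> 0 greedy limit: uphill moves are never accepted
  withr::with_seed(1, {
    ups <- replicate(10000, sa_accept(0.1, 1e-12))
    expect_false(any(ups))
  })
  # a penalty jump from a finite state is effectively never accepted
  withr::with_seed(2, {
    expect_false(any(replicate(2000, sa_accept(1e6 - (-3), 5))))
  })
})

test_that("config constructors validate their invariants", {
  expect_error(sa_config(T0 = 0), "T0")
  expect_error(sa_config(alpha = 1), "alpha")
  expect_error(sa_config(step_size = 0), "step_size")
  expect_error(bh_config(accept_T = 0), "accept_T")
  expect_error(bh_config(minimizer_tol = 0), "minimizer_tol")
})

test_that("simulated annealing is deterministic and its best trace monotone", {
  b <- lj_backend()
  cfg <- sa_config(T0 = 0.5, alpha = 0.95, steps_per_T = 100,
                   step_size = 0.05, max_steps = 4000, seed = 17)
  start <- random_positions(3, 42, lo = -1, hi = 1)
  r1 <- run_sa(cfg, b, start)
  r2 <- run_sa(cfg, b, start)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$best_position, r2$best_position)
  expect_true(all(diff(r1$trajectory) <= 0))
  expect_equal(r1$best_energy, r1$trajectory[length(r1$trajectory)])
  expect_equal(r1$best_energy,
               psocluster:::eval_fast(b, r1$best_position))
})

test_that("a slow anneal finds the dimer and triangle minima", {
  b <- lj_backend()
  for (seed in 1:3) {
    cfg <- sa_config(T0 = 0.3, alpha = 0.97, steps_per_T = 300,
                     step_size = 0.01, max_steps = 30000, seed = seed)
    start <- random_positions(2, 300 + seed, lo = -1, hi = 1)
    r <- run_sa(cfg, b, start)
    expect_equal(r$best_energy, -1.0, tolerance = 1e-3)
  }
  cfg <- sa_config(T0 = 0.5, alpha = 0.97, steps_per_T = 400,
                   step_size = 0.01, max_steps = 60000, seed = 1)
  r3 <- run_sa(cfg, b, random_positions(3, 77, lo = -1.2, hi = 1.2))
  expect_equal(r3$best_energy, -3.0, tolerance = 1e-2)
})

test_that("local minimization solves the dimer and meets its gradient bound", {
  b <- lj_backend()
  m <- local_minimize(c(0, 0, 0, 1.3, 0, 0), b, tol = 1e-6)
  expect_equal(m$energy, -1.0, tolerance = 1e-8)
  expect_equal(min_pair_distance(m$position), 2^(1 / 6), tolerance = 1e-6)
  expect_lte(m$grad_norm, 1e-6)
  expect_true(m$converged)

  mm <- local_minimize(c(0, 0, 0, 1.7, 0, 0), morse_backend(De = 2, re = 1.3),
                       tol = 1e-6)
  expect_equal(mm$energy, -2.0, tolerance = 1e-8)
  expect_equal(min_pair_distance(mm$position), 1.3, tolerance = 1e-6)

  # energy never increases relative to the start
  for (seed in 1:5) {
    v <- random_positions(4, seed)
    m <- local_minimize(v, b)
    expect_lte(m$energy, psocluster:::eval_fast(b, v))
  }
})

test_that("single-point-only backends are rejected with a capability error", {
  mb <- mock_engine_backend()
  expect_error(local_minimize(random_positions(3, 1), mb), "capability")
  expect_error(run_bh(bh_config(), mb, random_positions(3, 1)),
               "capability")
})

test_that("random 4-atom minimizations land on the oracle minimum set", {
  # the multi-start oracle enumerates a single connected minimum for the
  # 4-atom cluster: the regular tetrahedron at -6
  b <- lj_backend()
  ref <- lj_reference_energies(4)
  connected <- 0L
  for (seed in 1:100) {
    v <- random_positions(4, seed, lo = -1.5, hi = 1.5)
    m <- local_minimize(v, b)
    if (!m$converged) next
    dmax <- max(sorted_pair_distances(m$position))
    if (dmax < 4) {
      connected <- connected + 1L
      expect_equal(m$energy, ref, tolerance = 1e-6)
    }
  }
  expect_gte(connected, 80L)
})

test_that("basin hopping with zero perturbation stays trapped in one basin", {
  b <- lj_backend()
  cfg <- bh_config(perturb_delta = 0, max_hops = 12, seed = 3)
  r <- run_bh(cfg, b, random_positions(4, 9, lo = -1, hi = 1))
  expect_equal(max(r$hop_energies) - min(r$hop_energies), 0,
               tolerance = 1e-9)
})

test_that("basin hopping is deterministic and finds the 5-atom minimum", {
  b <- lj_backend()
  cfg <- bh_config(max_hops = 60, seed = 11)
  start <- random_positions(5, 500, lo = -1.5, hi = 1.5)
  r1 <- run_bh(cfg, b, start)
  r2 <- run_bh(cfg, b, start)
  expect_identical(r1$hop_energies, r2$hop_energies)
  expect_identical(r1$best_energy, r2$best_energy)
  expect_true(all(diff(r1$trajectory) <= 0))
  expect_equal(r1$best_energy, min(lj_reference_energies(5)),
               tolerance = 1e-6)
})
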