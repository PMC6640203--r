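test_that("Lennard-Jones energy matches the analytic pair values", {
  r_min <- 2^(1 / 6)
  expect_equal(lj_energy(c(0, 0, 0, r_min, 0, 0)), -1.0, tolerance = 1e-12)
  expect_equal(lj_energy(c(0, 0, 0, 1, 0, 0)), 0.0, tolerance = 1e-12)
  expect_equal(lj_energy(triangle_positions(r_min)), -3.0, tolerance = 1e-12)
  # scaled parameters: dimer at 2^(1/6) sigma is -epsilon
  expect_equal(lj_energy(c(0, 0, 0, 2.5 * r_min, 0, 0),
                         epsilon = 0.7, sigma = 2.5),
               -0.7, tolerance = 1e-12)
  expect_error(lj_energy(c(0, 0, 0, 0, 0, 0)), "overlap")
})

test_that("Morse energy matches its well depth and dissociation limit", {
  expect_equal(morse_energy(c(0, 0, 0, 1, 0, 0)), -1.0, tolerance = 1e-12)
  expect_equal(morse_energy(c(0, 0, 0, 2.3, 0, 0), De = 2, a = 1.5, re = 2.3),
               -2.0, tolerance = 1e-12)
  expect_equal(morse_energy(c(0, 0, 0, 60, 0, 0)), 0.0, tolerance = 1e-10)
  expect_equal(morse_energy(triangle_positions(1)), -3.0, tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  h <- 1e-6
  fd_grad <- function(f, v) {
    vapply(seq_along(v), function(j) {
      up <- v; up[j] <- up[j] + h
      dn <- v; dn[j] <- dn[j] - h
      (f(up) - f(dn)) / (2 * h)
    }, numeric(1))
  }
  for (seed in 1:5) {
    v <- random_positions(4, seed)
    expect_equal(lj_gradient(v), fd_grad(lj_energy, v), tolerance = 1e-5)
    expect_equal(morse_gradient(v, De = 1.3, a = 1.1, re = 1.2),
                 fd_grad(function(x) morse_energy(x, 1.3, 1.1, 1.2), v),
                 tolerance = 1e-5)
  }
  # stationary at the pair minimum
  expect_equal(lj_gradient(c(0, 0, 0, 2^(1 / 6), 0, 0)), numeric(6),
               tolerance = 1e-12)
})

test_that("per-atom forces sum to zero (translation invariance)", {
  for (seed in 1:8) {
    n <- 3 + seed %% 4
    v <- random_positions(n, seed)
    for (g in list(lj_gradient(v), morse_gradient(v))) {
      m <- matrix(g, ncol = 3, byrow = TRUE)
      expect_lt(max(abs(colSums(m))), 1e-10)
    }
  }
})

test_that("pair potentials are invariant under rigid motions", {
  for (seed in 1:8) {
    v <- random_positions(5, seed)
    moved <- apply_rigid(v, random_rotation(seed + 100),
                         c(1.5, -2.2, 0.4))
    expect_equal(lj_energy(moved), lj_energy(v), tolerance = 1e-9)
    expect_equal(morse_energy(moved), morse_energy(v), tolerance = 1e-9)
  }
})

test_that("render_deck substitutes placeholders byte-stably", {
  tmpl <- engine_template("{CHARGE} {MULT}\n{COORDS}")
  g <- cluster_geometry("C", matrix(0, 1, 3))
  expect_identical(render_deck(tmpl, g),
                   "0 1\nC 0.000000 0.000000 0.000000")
  g2 <- cluster_geometry(c("C", "O"),
                         rbind(c(0.1234567, 0, -1), c(2, 3, 4)))
  expect_identical(render_deck(tmpl, g2), render_deck(tmpl, g2))
  expect_match(render_deck(tmpl, g2), "C 0\\.123457 0\\.000000 -1\\.000000")
  expect_error(engine_template("{CHARGE} {MULT}"), "COORDS")
  expect_error(engine_template("{COORDS} {WAT}"), "unknown placeholder")
})

test_that("parse_energy takes the last match and encodes failure in status", {
  ok <- parse_energy("E_TOTAL = -1.234500")
  expect_identical(ok$status, "ok")
  expect_equal(ok$energy, -1.2345)

  two <- parse_energy(c("E_TOTAL = -1.0", "noise", "E_TOTAL = -2.0"))
  expect_equal(two$energy, -2.0)

  bad <- parse_energy("")
  expect_identical(bad$status, "engine_failed")
  expect_equal(bad$energy, 1e6)
})

test_that("evaluate_energy dispatches, rejects overlaps, absorbs errors", {
  b <- lj_backend()
  v <- random_positions(4, 1)
  res <- evaluate_energy(b, v)
  expect_identical(res$status, "ok")
  expect_equal(res$energy, lj_energy(v))

  tight <- lj_backend(overlap_threshold = 0.5)
  res2 <- evaluate_energy(tight, c(0, 0, 0, 0.1, 0, 0))
  expect_identical(res2$status, "overlap_rejected")
  expect_equal(res2$energy, 1e6)

  boom <- function_backend(function(v) stop("engine exploded"))
  res3 <- evaluate_energy(boom, v)
  expect_identical(res3$status, "engine_failed")
  expect_equal(res3$energy, 1e6)
  expect_match(res3$diagnostics, "exploded")
})

test_that("mock engine round trip agrees with direct evaluation", {
  # the deck carries 6 decimals, so the comparison is made in the
  # physically relevant near-equilibrium regime; on a steep repulsive wall
  # the same rounding is amplified by the r^-12 gradient
  mb <- mock_engine_backend()
  shapes <- list(c(0, 0, 0, 2^(1 / 6), 0, 0),
                 triangle_positions(2^(1 / 6)),
                 tetrahedron_positions(2^(1 / 6)))
  k <- 0
  for (v0 in shapes) {
    for (seed in 1:2) {
      k <- k + 1
      v <- v0 + withr::with_seed(k, rnorm(length(v0), 0, 0.002))
      res <- evaluate_energy(mb, v)
      expect_identical(res$status, "ok")
      expect_equal(res$energy, lj_energy(v), tolerance = 1e-6)
    }
  }
})

test_that("external backend runs a command, parses its log, survives failure", {
  engine <- write_python_lj_engine(withr::local_tempfile(fileext = ".py"))
  tmpl <- lj_engine_template(engine)
  b <- external_backend(tmpl, rep("C", 3),
                        scratch_root = withr::local_tempdir())
  v <- triangle_positions(2^(1 / 6))
  res <- evaluate_energy(b, v)
  expect_identical(res$status, "ok")
  expect_equal(res$energy, -3.0, tolerance = 1e-5)

  # engine prints no energy -> engine_failed, scratch kept for diagnostics
  v_bad <- v
  v_bad[1] <- 600
  res2 <- evaluate_energy(b, v_bad)
  expect_identical(res2$status, "engine_failed")
  expect_equal(res2$energy, 1e6)
})
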