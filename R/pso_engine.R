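# Modified particle swarm optimizer for cluster geometry search.
#
# Velocity update, per component j of particle i:
#   v'_j = w v_j + d1 eps1_j (pbest_j - x_j) + d2 eps2_j (gbest_j - x_j)
# followed by componentwise clamping and x' = x + v'.  eps1/eps2 are drawn
# fresh per component from the particle's own substream.  The run stops
# when the global best energy has been unchanged (within energy_tol) for
# stall_threshold successive iterations, or at max_iter.

#' Inertia weight at an iteration
#'
#' Linear descent from `w_max` at iteration 0 to `w_min` at `max_iter`,
#' shifting the swarm from exploration to exploitation.  With
#' `w_min == w_max` the weight is constant.
#'
#' @param iteration Iteration index, `0 <= iteration <= max_iter`.
#' @param config A [swarm_config()].
#' @return The inertia weight.
#' @export
inertia_at <- function(iteration, config) {
  if (config$w_max == config$w_min) return(config$w_max)
  frac <- min(1, max(0, iteration / config$max_iter))
  config$w_max - (config$w_max - config$w_min) * frac
}

#' Velocity update
#'
#' Computes the new (unclamped) velocity of one particle.  When `eps1` /
#' `eps2` are not supplied they are drawn uniform in (0, 1) per component
#' from the ambient RNG; [run_pso()] always supplies draws taken from the
#' particle's own substream before dispatch.
#'
#' @param particle A particle (as stored in a [init_swarm()] swarm).
#' @param gbest Global-best position vector.
#' @param w Inertia weight.
#' @param config A [swarm_config()] (supplies `d1`, `d2`).
#' @param eps1,eps2 Optional per-component uniforms in (0, 1).
#' @return Numeric velocity vector (not yet clamped).
#' @export
update_velocity <- function(particle, gbest, w, config,
                            eps1 = NULL, eps2 = NULL) {
  d <- length(particle$position)
  if (length(particle$velocity) != d || length(particle$pbest_position) != d ||
      length(gbest) != d)
    stop("shape error: position, velocity, pbest and gbest lengths differ")
  if (is.null(eps1)) eps1 <- stats::runif(d)
  if (is.null(eps2)) eps2 <- stats::runif(d)
  if (length(eps1) != d || length(eps2) != d)
    stop("shape error: eps draws must match the position length")
  w * particle$velocity +
    config$d1 * eps1 * (particle$pbest_position - particle$position) +
    config$d2 * eps2 * (gbest - particle$position)
}

clamp_velocity <- function(velocity, config) {
  cl <- config$velocity_clamp
  if (is.null(cl)) return(velocity)
  pmin(pmax(velocity, -cl), cl)
}

#' Position update
#'
#' `x' = x + v'` after componentwise velocity clamping.  No positional
#' walls are enforced: the initialization box constrains generation only,
#' and clusters are free to relax outside it.
#'
#' @param position,velocity Equal-length numeric vectors.
#' @param config A [swarm_config()] (supplies `velocity_clamp`).
#' @return The new position vector.
#' @export
update_position <- function(position, velocity, config) {
  if (length(position) != length(velocity))
    stop("shape error: position and velocity lengths differ")
  position + clamp_velocity(velocity, config)
}

#' Update personal and global bests
#'
#' A particle's personal best is replaced only on a strict improvement
#' (`new energy < pbest_energy`); the global best is the argmin over
#' personal bests, ties keeping the incumbent.
#'
#' @param swarm A swarm.
#' @param energies List of `energy_result`, one per particle, in particle
#'   order.
#' @return The updated swarm.
#' @export
update_bests <- function(swarm, energies) {
  if (length(energies) != length(swarm$particles))
    stop("one energy result per particle is required")
  for (i in seq_along(swarm$particles)) {
    e <- energies[[i]]$energy
    if (e < swarm$particles[[i]]$pbest_energy) {
      swarm$particles[[i]]$pbest_energy <- e
      swarm$particles[[i]]$pbest_position <- swarm$particles[[i]]$position
    }
  }
  pbests <- vapply(swarm$particles, function(p) p$pbest_energy, numeric(1))
  best_i <- which.min(pbests)
  if (length(best_i) && pbests[best_i] < swarm$gbest_energy) {
    swarm$gbest_energy <- pbests[best_i]
    swarm$gbest_position <- swarm$particles[[best_i]]$pbest_position
  }
  swarm
}

#' Stall-based convergence test
#'
#' `TRUE` once the last `stall_threshold + 1` global-best energies all lie
#' within `energy_tol` of one another — the "energy unchanged for 30
#' successive iterations" termination rule.
#'
#' @param trajectory Numeric vector of per-iteration global-best energies.
#' @param config A [swarm_config()].
#' @export
has_converged <- function(trajectory, config) {
  k <- config$stall_threshold + 1L
  n <- length(trajectory)
  if (n < k) return(FALSE)
  window <- trajectory[(n - k + 1L):n]
  (max(window) - min(window)) <= config$energy_tol
}

# Core loop over a prepared swarm.  Returns the swarm plus trajectory and
# bookkeeping; used by run_pso and restart_search.
#
# The stall test is applied to the sequence of per-iteration best evaluated
# energies (the energy the swarm "finds" each iteration), not to the
# running global best: the running best is constant over long stretches of
# healthy exploration, whereas the iteration best only stabilizes once the
# swarm has genuinely collapsed.  On a constant-energy backend the two
# sequences coincide, so the 30-identical-iterations termination rule is
# unchanged there.
run_swarm <- function(swarm, backend, exec_config, trace_con = NULL) {
  config <- swarm$config
  trajectory <- numeric(0)
  iter_best <- numeric(0)
  evaluations <- 0L
  warnings <- character(0)
  stall <- 0L
  converged <- FALSE
  repeat {
    energies <- evaluate_swarm(swarm, backend, exec_config)
    evaluations <- evaluations + length(energies)
    if (swarm$iteration == 0L &&
        all(vapply(energies, function(e) e$status, character(1)) != "ok")) {
      warnings <- c(warnings,
                    "all first-iteration evaluations failed or overlapped; run continues on penalty energies")
    }
    swarm <- update_bests(swarm, energies)
    trajectory <- c(trajectory, swarm$gbest_energy)
    iter_best <- c(iter_best,
                   min(vapply(energies, function(e) e$energy, numeric(1))))
    nt <- length(trajectory)
    stall <- if (nt > 1L &&
                 abs(iter_best[nt] - iter_best[nt - 1L]) <= config$energy_tol)
      stall + 1L else 0L
    if (!is.null(trace_con)) {
      cat(sprintf("%d\t%d\t%.10g\t%d\t%d\n", swarm$restart, nt,
                  swarm$gbest_energy, evaluations, stall),
          file = trace_con, append = TRUE)
    }
    if (has_converged(iter_best, config)) {
      converged <- TRUE
      break
    }
    if (nt >= config$max_iter) break
    w <- inertia_at(swarm$iteration, config)
    for (i in seq_along(swarm$particles)) {
      p <- swarm$particles[[i]]
      d <- swarm$dim
      drawn <- stream_eval(p$stream, function()
        list(e1 = stats::runif(d), e2 = stats::runif(d)))
      v <- update_velocity(p, swarm$gbest_position, w, config,
                           eps1 = drawn$value$e1, eps2 = drawn$value$e2)
      v <- clamp_velocity(v, config)
      p$velocity <- v
      p$position <- p$position + v
      p$stream <- drawn$state
      swarm$particles[[i]] <- p
    }
    swarm$iteration <- swarm$iteration + 1L
  }
  list(swarm = swarm, trajectory = trajectory, converged = converged,
       evaluations = evaluations, warnings = warnings)
}

make_run_result <- function(method, swarm, trajectory, converged,
                            evaluations, restarts_used = 1L,
                            restart_energies = NULL, warnings = character(0)) {
  geom <- if (!is.null(swarm$elements))
    unflatten_geometry(swarm$gbest_position, swarm$elements) else NULL
  structure(list(method = method,
                 best_geometry = geom,
                 best_position = swarm$gbest_position,
                 best_energy = swarm$gbest_energy,
                 trajectory = trajectory,
                 iterations_used = length(trajectory),
                 converged = converged,
                 evaluations = evaluations,
                 restarts_used = restarts_used,
                 restart_energies = restart_energies,
                 warnings = warnings),
            class = "gm_search_result")
}

#' @export
print.gm_search_result <- function(x, ...) {
  cat(sprintf("<%s search> best energy %.8g after %d iterations (%s)\n",
              x$method, x$best_energy, x$iterations_used,
              if (x$converged) "converged" else "iteration cap"))
  if (!is.null(x$restart_energies) && length(x$restart_energies) > 1L)
    cat("restart best energies:",
        paste(format(x$restart_energies, digits = 8), collapse = ", "), "\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Run one particle swarm search
#'
#' The full loop: evaluate all particles (barrier-synchronized, see
#' [evaluate_swarm()]), update personal/global bests, record the global
#' best, test the stall rule, then update velocities and positions.  The
#' global-best trajectory is non-increasing by construction and the whole
#' run is a deterministic function of `config$seed` for any worker count.
#'
#' @param config A [swarm_config()].
#' @param backend An `energy_backend`.
#' @param n_atoms Number of atoms (ignored if `start` is given).
#' @param start Optional [cluster_geometry()] to seed the swarm: half the
#'   particles start at the geometry plus Gaussian noise
#'   (`restart_noise_sigma`), half from fresh uniform draws.
#' @param elements Optional element symbols (default carbon).
#' @param dim Search dimension for non-atomic objective backends.
#' @param exec_config An [executor_config()].
#' @param trace_file Optional path; a tab-separated trajectory log
#'   (`restart  iteration  gbest_energy  evaluations  stall`) is appended
#'   per iteration.
#' @return A `gm_search_result` with fields `best_geometry`, `best_energy`,
#'   `trajectory`, `iterations_used`, `converged`, `evaluations`.
#' @examples
#' cfg <- swarm_config(seed = 42, max_iter = 200)
#' res <- run_pso(cfg, lj_backend(), n_atoms = 3)
#' res$best_energy  # close to -3, the equilateral-triangle minimum
#' @export
run_pso <- function(config, backend, n_atoms = NULL, start = NULL,
                    elements = NULL, dim = NULL,
                    exec_config = executor_config(), trace_file = NULL) {
  stopifnot(inherits(config, "swarm_config"),
            inherits(backend, "energy_backend"))
  if (!is.null(start)) {
    stopifnot(inherits(start, "cluster_geometry"))
    elements <- start$elements
    n_atoms <- length(elements)
  }
  swarm <- init_swarm(config, n_atoms = n_atoms, elements = elements,
                      dim = dim)
  if (!is.null(start))
    swarm <- local({s <- swarm; s$restart <- 1L; reseed_restart0(s, flatten_geometry(start))})
  trace_con <- init_trace(trace_file)
  out <- run_swarm(swarm, backend, exec_config, trace_con)
  make_run_result("pso", out$swarm, out$trajectory, out$converged,
                  out$evaluations, warnings = out$warnings)
}

# Seed a swarm around a start geometry without advancing the restart index.
reseed_restart0 <- function(swarm, best_position) {
  s <- reseed_swarm(swarm, best_position)
  s$restart <- swarm$restart
  s
}

init_trace <- function(trace_file) {
  if (is.null(trace_file)) return(NULL)
  cat("restart\titeration\tgbest_energy\tevaluations\tstall\n",
      file = trace_file)
  trace_file
}

#' Restart-to-self-consistency search
#'
#' Runs up to `n_restarts` swarm searches.  After each inner run, a new
#' swarm is seeded from the incumbent best geometry (half the particles
#' perturbed by zero-mean Gaussian noise with sd `restart_noise_sigma`,
#' half fresh uniform draws) and the search repeats.  The loop stops early
#' once two consecutive restarts' best energies agree within `energy_tol`
#' — the self-consistency criterion — and the overall best is returned.
#'
#' @inheritParams run_pso
#' @return A `gm_search_result`; `restart_energies` holds each restart's
#'   best energy and `trajectory` the concatenated per-iteration record.
#' @export
restart_search <- function(config, backend, n_atoms = NULL, elements = NULL,
                           dim = NULL, exec_config = executor_config(),
                           trace_file = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  swarm <- init_swarm(config, n_atoms = n_atoms, elements = elements,
                      dim = dim)
  trace_con <- init_trace(trace_file)
  best_energy <- Inf
  best_position <- NULL
  best_swarm <- NULL
  restart_energies <- numeric(0)
  full_traj <- numeric(0)
  evaluations <- 0L
  warnings <- character(0)
  converged <- FALSE
  for (r in seq_len(config$n_restarts)) {
    out <- run_swarm(swarm, backend, exec_config, trace_con)
    swarm <- out$swarm
    evaluations <- evaluations + out$evaluations
    warnings <- c(warnings, out$warnings)
    full_traj <- c(full_traj, pmin(out$trajectory,
                                   if (r == 1L) Inf else best_energy))
    restart_energies <- c(restart_energies, swarm$gbest_energy)
    if (swarm$gbest_energy < best_energy) {
      best_energy <- swarm$gbest_energy
      best_position <- swarm$gbest_position
      best_swarm <- swarm
    }
    converged <- out$converged
    if (r >= 2L &&
        abs(restart_energies[r] - restart_energies[r - 1L]) <= config$energy_tol) {
      converged <- TRUE  # self-consistency reached
      break
    }
    if (r < config$n_restarts)
      swarm <- reseed_swarm(swarm, best_position)
  }
  best_swarm$gbest_energy <- best_energy
  best_swarm$gbest_position <- best_position
  make_run_result("pso+restart", best_swarm, full_traj, converged,
                  evaluations, restarts_used = length(restart_energies),
                  restart_energies = restart_energies, warnings = warnings)
}
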