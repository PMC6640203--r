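# Comparator searchers: simulated annealing and basin hopping, over the
# same energy-backend contract as the swarm, plus the quasi-Newton local
# minimizer basin hopping requires.

#' Simulated annealing configuration
#'
#' @param T0 Initial temperature (energy units), > 0.
#' @param alpha Geometric cooling factor in (0, 1); the temperature is
#'   multiplied by `alpha` every `steps_per_T` steps, so it "decreases
#'   during the whole course of the process very slowly" for `alpha`
#'   close to 1.
#' @param steps_per_T Steps (accepted or rejected) per temperature stage.
#' @param step_size Half-width (Angstrom / model length units) of the
#'   per-coordinate uniform perturbation.
#' @param max_steps Total number of Metropolis steps.
#' @param seed Random seed.
#' @param cooling `"geometric"` (default) or `"linear"` (T decreases
#'   linearly to ~0 across `max_steps`).
#' @export
sa_config <- function(T0 = 1, alpha = 0.95, steps_per_T = 100,
                      step_size = 0.1, max_steps = 30000L, seed = 1L,
                      cooling = c("geometric", "linear")) {
  cooling <- match.arg(cooling)
  if (T0 <= 0) stop("config error: T0 must be > 0")
  if (alpha <= 0 || alpha >= 1)
    stop("config error: alpha must lie in (0, 1)")
  if (steps_per_T < 1) stop("config error: steps_per_T must be >= 1")
  if (step_size <= 0) stop("config error: step_size must be > 0")
  structure(list(T0 = T0, alpha = alpha,
                 steps_per_T = as.integer(steps_per_T),
                 step_size = step_size, max_steps = as.integer(max_steps),
                 seed = as.integer(seed), cooling = cooling),
            class = "sa_config")
}

#' Basin hopping configuration
#'
#' @param perturb_delta Half-width of the per-coordinate uniform hop
#'   perturbation; it "should be large enough to get out of a local basin".
#' @param accept_T Effective temperature of the Metropolis test applied to
#'   minimized energies.
#' @param max_hops Number of perturb-minimize-accept cycles.
#' @param minimizer_tol Gradient-norm threshold of the local minimizer.
#' @param seed Random seed.
#' @export
bh_config <- function(perturb_delta = 0.4, accept_T = 0.8, max_hops = 100L,
                      minimizer_tol = 1e-6, seed = 1L) {
  if (perturb_delta < 0) stop("config error: perturb_delta must be >= 0")
  if (accept_T <= 0) stop("config error: accept_T must be > 0")
  if (minimizer_tol <= 0) stop("config error: minimizer_tol must be > 0")
  structure(list(perturb_delta = perturb_delta, accept_T = accept_T,
                 max_hops = as.integer(max_hops),
                 minimizer_tol = minimizer_tol, seed = as.integer(seed)),
            class = "bh_config")
}

#' Metropolis acceptance rule
#'
#' A downhill move (`delta_E <= 0`) is always accepted; an uphill move is
#' accepted with Boltzmann probability `exp(-delta_E / T)`.  The `+Inf`
#' penalty sentinel is always rejected.
#'
#' @param delta_E Energy change of the proposed move.
#' @param T Temperature (> 0).
#' @return Logical; consumes one uniform draw only for uphill proposals.
#' @export
sa_accept <- function(delta_E, T) {
  if (T <= 0) stop("T must be > 0")
  if (is.na(delta_E)) return(FALSE)
  if (delta_E <= 0) return(TRUE)
  if (!is.finite(delta_E)) return(FALSE)
  stats::runif(1) < exp(-delta_E / T)
}

#' Simulated annealing search
#'
#' Metropolis random walk: every step all coordinates are perturbed by
#' independent uniforms of half-width `step_size`, the move is accepted by
#' [sa_accept()] at the current temperature, and the temperature is cooled
#' every `steps_per_T` steps.  The best configuration ever visited is
#' returned; penalty energies (backend failures, overlaps) are effectively
#' never accepted over finite energies.
#'
#' @param config An [sa_config()].
#' @param backend An `energy_backend`.
#' @param start Position vector to start from.
#' @param elements Optional element symbols for the returned geometry.
#' @return A `gm_search_result`; `trajectory` is the per-step best-so-far
#'   energy (non-increasing).
#' @export
run_sa <- function(config, backend, start, elements = NULL) {
  stopifnot(inherits(config, "sa_config"),
            inherits(backend, "energy_backend"))
  d <- length(start)
  with_seed_local(config$seed, {
    x <- start
    e <- eval_fast(backend, x)
    best_x <- x
    best_e <- e
    temp <- config$T0
    traj <- numeric(config$max_steps)
    s <- config$step_size
    for (step in seq_len(config$max_steps)) {
      prop <- x + stats::runif(d, -s, s)
      ep <- eval_fast(backend, prop)
      if (sa_accept(ep - e, temp)) {
        x <- prop
        e <- ep
        if (e < best_e) {
          best_e <- e
          best_x <- x
        }
      }
      traj[step] <- best_e
      if (step %% config$steps_per_T == 0L) {
        temp <- if (config$cooling == "geometric") temp * config$alpha
        else max(config$T0 * (1 - step / config$max_steps), 1e-12)
      }
    }
    swarm_like <- list(gbest_position = best_x, gbest_energy = best_e,
                       elements = elements)
    make_run_result("sa", swarm_like, traj, converged = FALSE,
                    evaluations = config$max_steps + 1L)
  })
}

#' Quasi-Newton local minimization
#'
#' BFGS descent with backtracking (Armijo) line search on a differentiable
#' backend, stopping once the gradient norm drops to `tol`.  This is the
#' "minimization of the energy functional" step of basin hopping.  External
#' single-point-only backends carry no gradient and are rejected with a
#' capability error: use the swarm or annealing searchers for those.
#'
#' @param start Position vector.
#' @param backend An `energy_backend` with a `grad_fn`.
#' @param tol Gradient-norm stopping threshold.
#' @param max_iter Iteration cap.
#' @param max_step Cap on the displacement norm of a single line-search
#'   trial (length units); keeps steep or penalized regions from blowing
#'   the cluster apart.
#' @return List with `position`, `energy`, `grad_norm`, `converged`,
#'   `evaluations`.  The returned energy never exceeds the starting energy.
#' @export
local_minimize <- function(start, backend, tol = 1e-6, max_iter = 2000L,
                           max_step = 0.5) {
  stopifnot(inherits(backend, "energy_backend"))
  if (is.null(backend$grad_fn))
    stop("capability error: backend '", backend$name,
         "' provides single-point energies only (no gradient); ",
         "use run_pso() or run_sa() instead")
  d <- length(start)
  x <- start
  f <- eval_fast(backend, x)
  g <- backend$grad_fn(x)
  H <- diag(d)
  scaled <- FALSE
  evals <- 1L
  for (it in seq_len(max_iter)) {
    gn <- sqrt(sum(g * g))
    if (!is.finite(gn) || gn <= tol) break
    p <- -as.vector(H %*% g)
    slope <- sum(g * p)
    if (!is.finite(slope) || slope >= 0) {
      H <- diag(d)
      scaled <- FALSE
      p <- -g
      slope <- -sum(g * g)
    }
    pn <- sqrt(sum(p * p))
    alpha <- min(1, max_step / pn)
    f_new <- Inf
    accepted <- FALSE
    for (ls in 1:50) {
      x_new <- x + alpha * p
      f_new <- eval_fast(backend, x_new)
      evals <- evals + 1L
      if (is.finite(f_new) && f_new <= f + 1e-4 * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted || !(f_new < f)) break  # no further decrease possible
    g_new <- backend$grad_fn(x_new)
    s_vec <- x_new - x
    y_vec <- g_new - g
    sy <- sum(s_vec * y_vec)
    if (is.finite(sy) && sy > 1e-12) {
      if (!scaled) {
        # Shanno initial scaling of the inverse Hessian
        H <- diag(d) * (sy / sum(y_vec * y_vec))
        scaled <- TRUE
      }
      rho <- 1 / sy
      Hy <- as.vector(H %*% y_vec)
      # BFGS inverse-Hessian update
      H <- H - rho * (s_vec %*% t(Hy) + Hy %*% t(s_vec)) +
        (rho^2 * sum(y_vec * Hy) + rho) * (s_vec %*% t(s_vec))
    } else {
      H <- diag(d)
      scaled <- FALSE
    }
    x <- x_new
    f <- f_new
    g <- g_new
  }
  gn <- sqrt(sum(g * g))
  list(position = x, energy = f, grad_norm = gn,
       converged = is.finite(gn) && gn <= tol, evaluations = evals)
}

#' Basin hopping search
#'
#' The classic perturb / locally-minimize / Metropolis-accept loop: each
#' hop perturbs every coordinate uniformly in `+/- perturb_delta`, runs
#' [local_minimize()], and accepts the new basin energy by [sa_accept()] at
#' the fixed temperature `accept_T`.  The lowest minimum ever found is
#' returned.
#'
#' @param config A [bh_config()].
#' @param backend A differentiable `energy_backend`.
#' @param start Position vector.
#' @param elements Optional element symbols for the returned geometry.
#' @return A `gm_search_result`; `trajectory` is the best-so-far basin
#'   energy per hop.
#' @export
run_bh <- function(config, backend, start, elements = NULL) {
  stopifnot(inherits(config, "bh_config"),
            inherits(backend, "energy_backend"))
  d <- length(start)
  with_seed_local(config$seed, {
    m0 <- local_minimize(start, backend, tol = config$minimizer_tol)
    x <- m0$position
    e <- m0$energy
    best_x <- x
    best_e <- e
    evals <- m0$evaluations
    traj <- numeric(config$max_hops)
    hop_energies <- numeric(config$max_hops)
    for (hop in seq_len(config$max_hops)) {
      prop <- x + stats::runif(d, -config$perturb_delta,
                               config$perturb_delta)
      m <- local_minimize(prop, backend, tol = config$minimizer_tol)
      evals <- evals + m$evaluations
      hop_energies[hop] <- m$energy
      if (sa_accept(m$energy - e, config$accept_T)) {
        x <- m$position
        e <- m$energy
        if (e < best_e) {
          best_e <- e
          best_x <- x
        }
      }
      traj[hop] <- best_e
    }
    swarm_like <- list(gbest_position = best_x, gbest_energy = best_e,
                       elements = elements)
    res <- make_run_result("bh", swarm_like, traj, converged = FALSE,
                           evaluations = evals)
    res$hop_energies <- hop_energies
    res
  })
}
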