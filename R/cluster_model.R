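#' Construct a cluster geometry
#'
#' The chemistry-facing view of a candidate structure: a vector of element
#' symbols and an `n x 3` matrix of Cartesian coordinates in Angstrom
#' (reduced model units when used with the built-in pair potentials).
#'
#' @param elements Character vector of chemical symbols, length `n`.
#' @param coords Numeric `n x 3` matrix (or coercible) of coordinates; one
#'   row per atom, columns are x, y, z.
#' @return An object of class `cluster_geometry` with fields `elements`
#'   and `coords`.
#' @examples
#' g <- cluster_geometry(c("C", "C"), rbind(c(0, 0, 0), c(1.3, 0, 0)))
#' flatten_geometry(g)
#' @seealso [flatten_geometry()], [unflatten_geometry()], [read_xyz()]
#' @export
cluster_geometry <- function(elements, coords) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L)
    stop("a cluster needs at least one atom")
  if (ncol(coords) != 3L)
    stop("`coords` must have exactly 3 columns (x, y, z)")
  if (nrow(coords) != length(elements))
    stop(sprintf("`elements` has length %d but `coords` has %d rows",
                 length(elements), nrow(coords)))
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  structure(list(elements = elements, coords = unname(coords)),
            class = "cluster_geometry")
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf("<cluster_geometry> %d atoms (%s)\n",
              length(x$elements), paste(unique(x$elements), collapse = ", ")))
  m <- cbind(format(x$elements), format(round(x$coords, 6)))
  cat(apply(m, 1, paste, collapse = "  "), sep = "\n")
  invisible(x)
}

#' Flatten a geometry into a position vector
#'
#' Encodes an `n`-atom geometry as a flat vector of length `3n` in which
#' atom `i` (0-based) occupies slots `3i`, `3i + 1`, `3i + 2`.  This is the
#' encoding the swarm searches in: each particle's position vector is one
#' full cluster geometry.
#'
#' @param geom A [cluster_geometry()].
#' @return Numeric vector of length `3 * n`.
#' @export
flatten_geometry <- function(geom) {
  stopifnot(inherits(geom, "cluster_geometry"))
  as.vector(t(geom$coords))
}

#' Rebuild a geometry from a position vector
#'
#' Inverse of [flatten_geometry()].
#'
#' @param vec Numeric position vector of length `3 * length(elements)`.
#' @param elements Character vector of chemical symbols.
#' @return A [cluster_geometry()].
#' @export
unflatten_geometry <- function(vec, elements) {
  if (length(vec) %% 3L != 0L)
    stop(sprintf("position vector length %d is not divisible by 3",
                 length(vec)))
  if (length(vec) != 3L * length(elements))
    stop(sprintf("position vector length %d does not match %d atoms",
                 length(vec), length(elements)))
  cluster_geometry(elements, matrix(vec, ncol = 3L, byrow = TRUE))
}

#' Minimum interatomic distance of a position vector
#'
#' Randomly generated particles "might overlap on each other"; this is the
#' quantity the overlap-rejection policy of [evaluate_energy()] tests.
#'
#' @param vec Numeric position vector, length divisible by 3.
#' @return The smallest pairwise Euclidean distance, or `Inf` for a single
#'   atom (no pairs).
#' @export
min_pair_distance <- function(vec) {
  if (length(vec) %% 3L != 0L)
    stop("position vector length must be divisible by 3")
  n <- length(vec) %/% 3L
  if (n < 2L) return(Inf)
  min(stats::dist(matrix(vec, ncol = 3L, byrow = TRUE)))
}

#' Swarm configuration
#'
#' All search controls of the particle swarm optimizer.  The defaults are
#' the published parameterization for small-cluster searches: population 10,
#' inertia descending from 0.8 to 0.4, cognitive and social acceleration
#' coefficients both 2, initial coordinates uniform in (-3, 3), and
#' termination once the global best energy has been unchanged (within
#' `energy_tol`) for 30 successive iterations.
#'
#' @param n_pop Population size (>= 2).  Default 10.
#' @param w_min,w_max Inertia-weight range; the weight descends linearly
#'   from `w_max` at iteration 0 to `w_min` at `max_iter`.  Setting them
#'   equal gives constant-inertia mode.  Defaults 0.4 and 0.8.
#' @param d1 Cognitive (personal-best) acceleration coefficient.  Default 2.
#' @param d2 Social (global-best) acceleration coefficient.  Default 2.
#' @param init_low,init_high Bounds of the uniform box that initial
#'   coordinates are drawn from.  Defaults -3 and 3.  The box constrains
#'   generation only; particles are free to leave it during the search.
#' @param stall_threshold Number of successive iterations the global best
#'   must remain unchanged before the run terminates.  Default 30.
#' @param energy_tol Tolerance within which two energies count as "the
#'   same", both for the stall rule and for restart self-consistency.
#'   Default 1e-6 energy units.
#' @param max_iter Iteration cap per run.  Default 600.
#' @param velocity_clamp Componentwise bound on the magnitude of the updated
#'   velocity, or `NULL` for no clamping.  Default
#'   `0.5 * (init_high - init_low)`.
#' @param n_restarts Cap on the number of restart cycles used by
#'   [restart_search()]; the self-consistency rule usually stops the loop
#'   earlier.  Default 10.
#' @param restart_noise_sigma Standard deviation (same units as
#'   coordinates) of the Gaussian noise applied to the incumbent best
#'   geometry when seeding a restart swarm.  Default 0.3.
#' @param seed Root random seed; it spawns one independent substream per
#'   particle, making runs reproducible and worker-count invariant.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(n_pop = 10L,
                         w_min = 0.4, w_max = 0.8,
                         d1 = 2, d2 = 2,
                         init_low = -3, init_high = 3,
                         stall_threshold = 30L,
                         energy_tol = 1e-6,
                         max_iter = 600L,
                         velocity_clamp = 0.5 * (init_high - init_low),
                         n_restarts = 10L,
                         restart_noise_sigma = 0.3,
                         seed = 1L) {
  cfg <- list(n_pop = as.integer(n_pop),
              w_min = w_min, w_max = w_max,
              d1 = d1, d2 = d2,
              init_low = init_low, init_high = init_high,
              stall_threshold = as.integer(stall_threshold),
              energy_tol = energy_tol,
              max_iter = as.integer(max_iter),
              velocity_clamp = velocity_clamp,
              n_restarts = as.integer(n_restarts),
              restart_noise_sigma = restart_noise_sigma,
              seed = as.integer(seed))
  if (cfg$n_pop < 2L) stop("config error: n_pop must be >= 2")
  if (cfg$w_min > cfg$w_max) stop("config error: w_min must be <= w_max")
  if (!(cfg$init_low < cfg$init_high))
    stop("config error: init_low must be strictly below init_high")
  if (cfg$stall_threshold < 1L) stop("config error: stall_threshold >= 1")
  if (cfg$energy_tol <= 0) stop("config error: energy_tol must be > 0")
  if (cfg$max_iter < 1L) stop("config error: max_iter must be >= 1")
  if (!is.null(cfg$velocity_clamp) && cfg$velocity_clamp <= 0)
    stop("config error: velocity_clamp must be > 0 or NULL")
  if (cfg$n_restarts < 1L) stop("config error: n_restarts must be >= 1")
  class(cfg) <- "swarm_config"
  cfg
}

# One particle: flat position/velocity, personal-best memory, and its own
# RNG substream.  pbest energy starts at the +Inf sentinel so the first
# evaluation always installs a real personal best.
new_particle <- function(id, position, velocity, stream) {
  list(id = id,
       position = position,
       velocity = velocity,
       pbest_position = position,
       pbest_energy = Inf,
       stream = stream)
}

#' Initialize a swarm
#'
#' Draws `n_pop` particles with every position component uniform in
#' `(init_low, init_high)` and every velocity component uniform in
#' `+/- 0.1 * (init_high - init_low)`.  Each particle draws from its own
#' random substream (spawned from `config$seed`), so the swarm is fully
#' determined by the seed and particle `i` is identical across population
#' sizes and evaluation orders.
#'
#' @param config A [swarm_config()].
#' @param n_atoms Number of atoms (search dimension is `3 * n_atoms`).
#' @param elements Optional character vector of element symbols (defaults
#'   to carbon, the reference system for small-cluster searches).
#' @param dim Search-space dimension for non-atomic objective backends;
#'   overrides `n_atoms`.
#' @return An object of class `swarm`.
#' @export
init_swarm <- function(config, n_atoms = NULL, elements = NULL, dim = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  if (is.null(dim)) {
    if (is.null(n_atoms) || n_atoms < 1L)
      stop("n_atoms must be >= 1 (or supply `dim`)")
    n_atoms <- as.integer(n_atoms)
    dim <- 3L * n_atoms
    if (is.null(elements)) elements <- rep("C", n_atoms)
    if (length(elements) != n_atoms)
      stop("`elements` length must equal n_atoms")
  } else {
    dim <- as.integer(dim)
    if (dim < 1L) stop("dim must be >= 1")
    elements <- NULL
  }
  streams <- make_rng_streams(config$seed, config$n_pop + 1L)
  width <- config$init_high - config$init_low
  particles <- vector("list", config$n_pop)
  for (i in seq_len(config$n_pop)) {
    drawn <- stream_eval(streams[[i]], function() {
      list(pos = stats::runif(dim, config$init_low, config$init_high),
           vel = stats::runif(dim, -0.1 * width, 0.1 * width))
    })
    particles[[i]] <- new_particle(i, drawn$value$pos, drawn$value$vel,
                                   drawn$state)
  }
  structure(list(particles = particles,
                 gbest_position = particles[[1L]]$position,
                 gbest_energy = Inf,
                 iteration = 0L,
                 restart = 1L,
                 dim = dim,
                 elements = elements,
                 config = config,
                 coordinator_stream = streams[[config$n_pop + 1L]]),
            class = "swarm")
}

# Rebuild a swarm around an incumbent best position: half the particles are
# the incumbent plus zero-mean Gaussian noise (sd = restart_noise_sigma),
# the other half fresh uniform draws.  Particles keep their substreams, so
# restart randomness never reuses earlier draws.
reseed_swarm <- function(swarm, best_position) {
  config <- swarm$config
  width <- config$init_high - config$init_low
  dim <- swarm$dim
  n_perturb <- config$n_pop %/% 2L
  for (i in seq_len(config$n_pop)) {
    p <- swarm$particles[[i]]
    drawn <- stream_eval(p$stream, function() {
      pos <- if (i <= n_perturb)
        best_position + stats::rnorm(dim, 0, config$restart_noise_sigma)
      else
        stats::runif(dim, config$init_low, config$init_high)
      list(pos = pos,
           vel = stats::runif(dim, -0.1 * width, 0.1 * width))
    })
    p$position <- drawn$value$pos
    p$velocity <- drawn$value$vel
    p$pbest_position <- drawn$value$pos
    p$pbest_energy <- Inf
    p$stream <- drawn$state
    swarm$particles[[i]] <- p
  }
  swarm$gbest_position <- swarm$particles[[1L]]$position
  swarm$gbest_energy <- Inf
  swarm$iteration <- 0L
  swarm$restart <- swarm$restart + 1L
  swarm
}

#' @export
print.swarm <- function(x, ...) {
  cat(sprintf("<swarm> %d particles, dim %d, iteration %d, gbest %s\n",
              length(x$particles), x$dim, x$iteration,
              if (is.finite(x$gbest_energy))
                format(x$gbest_energy, digits = 8) else "unset"))
  invisible(x)
}
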