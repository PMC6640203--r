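# Barrier-synchronized parallel energy evaluation.
#
# One job per particle, at most n_workers concurrent (forked via
# parallel::mclapply).  The call returns only after every job has finished
# — the iteration-end barrier: best/global-best updates cannot proceed
# until all engine invocations of the iteration are complete.  Workers are
# pure functions of their inputs (all randomness is consumed in the
# coordinator before dispatch), so results are identical for any worker
# count.

#' Executor configuration
#'
#' @param n_workers Maximum concurrent evaluation jobs (>= 1).  Worker
#'   processes are forked; results are bit-identical for any value.
#' @param per_job_timeout Wall-clock limit per evaluation job in seconds
#'   (enforced for external engine invocations); `Inf` disables it.
#' @param scratch_root Root directory for per-job scratch space of
#'   file-based backends.
#' @export
executor_config <- function(n_workers = 1L, per_job_timeout = Inf,
                            scratch_root = NULL) {
  n_workers <- as.integer(n_workers)
  if (n_workers < 1L) stop("config error: n_workers must be >= 1")
  structure(list(n_workers = n_workers, per_job_timeout = per_job_timeout,
                 scratch_root = scratch_root),
            class = "executor_config")
}

#' Evaluate every particle of a swarm (with barrier)
#'
#' @param swarm A swarm from [init_swarm()].
#' @param backend An `energy_backend`.
#' @param exec_config An [executor_config()].
#' @return List of `energy_result`, one per particle, in particle order.
#'   A job that times out or errors yields status `engine_failed` with the
#'   penalty energy; the barrier still completes and all other results are
#'   unaffected.
#' @export
evaluate_swarm <- function(swarm, backend,
                           exec_config = executor_config()) {
  stopifnot(inherits(swarm, "swarm"), inherits(backend, "energy_backend"))
  positions <- lapply(swarm$particles, function(p) p$position)
  labels <- sprintf("run_%d_%d_%d", swarm$restart, swarm$iteration,
                    seq_along(positions))
  tmo <- if (is.finite(exec_config$per_job_timeout))
    exec_config$per_job_timeout else NULL
  job <- function(i) {
    evaluate_energy(backend, positions[[i]], label = labels[i],
                    timeout = tmo)
  }
  idx <- seq_along(positions)
  results <- if (exec_config$n_workers == 1L) {
    lapply(idx, job)
  } else {
    parallel::mclapply(idx, job, mc.cores = exec_config$n_workers,
                       mc.preschedule = TRUE)
  }
  lapply(results, function(r) {
    if (inherits(r, "energy_result")) r
    else energy_result("engine_failed", PENALTY_ENERGY, backend$unit,
                       paste("worker failure:",
                             paste(as.character(r), collapse = " ")))
  })
}
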