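# Uniform energy-evaluation contract.
#
# A backend is a list with class "energy_backend" and fields:
#   name              backend identifier
#   energy_fn(vec, label, timeout)   raw energy (numeric) or energy_result
#   grad_fn(vec)      analytic gradient, or NULL (non-differentiable)
#   fast_fn(vec)      numeric-only path with the penalty policy applied,
#                     used in tight searcher loops
#   overlap_threshold minimum pair distance below which evaluation is
#                     refused (0 disables the check)
#   unit              energy unit label travelling with results
#
# Failed or overlap-rejected evaluations score the finite penalty +1e6 so a
# particle survives a bad configuration but never turns it into a personal
# best.

PENALTY_ENERGY <- 1e6

energy_result <- function(status, energy, unit = "model", diagnostics = "") {
  structure(list(status = status, energy = energy, unit = unit,
                 diagnostics = diagnostics),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> %s: %s %s\n", x$status,
              format(x$energy, digits = 10), x$unit))
  invisible(x)
}

pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i, j)
}

coords_of <- function(vec) matrix(vec, ncol = 3L, byrow = TRUE)

#' Lennard-Jones cluster energy
#'
#' Sum over atom pairs of `4 * epsilon * ((sigma/r)^12 - (sigma/r)^6)`.
#' The pair minimum is `-epsilon` at `r = 2^(1/6) * sigma`; with
#' `epsilon = sigma = 1` (reduced units) the three- and four-atom global
#' minima are the equilateral triangle (-3) and regular tetrahedron (-6).
#'
#' @param vec Position vector of length `3n`.
#' @param epsilon Well depth (> 0).
#' @param sigma Zero-crossing length (> 0).
#' @return Total energy (model units).
#' @export
lj_energy <- function(vec, epsilon = 1, sigma = 1) {
  n <- length(vec) %/% 3L
  if (length(vec) %% 3L != 0L) stop("position vector length must be 3n")
  if (n < 2L) return(0)
  r <- as.numeric(stats::dist(coords_of(vec)))
  if (any(r == 0)) stop("overlap error: coincident atoms")
  sr6 <- (sigma / r)^6
  sum(4 * epsilon * (sr6 * sr6 - sr6))
}

#' Analytic gradient of the Lennard-Jones energy
#'
#' @inheritParams lj_energy
#' @return Numeric vector of length `3n`; per-atom force contributions sum
#'   to zero (translation invariance).
#' @export
lj_gradient <- function(vec, epsilon = 1, sigma = 1) {
  n <- length(vec) %/% 3L
  if (n < 2L) return(numeric(length(vec)))
  m <- coords_of(vec)
  idx <- pair_index(n)
  dv <- m[idx[, 1L], , drop = FALSE] - m[idx[, 2L], , drop = FALSE]
  r2 <- rowSums(dv * dv)
  if (any(r2 == 0)) stop("overlap error: coincident atoms")
  sr6 <- (sigma * sigma / r2)^3
  # (dV/dr)/r, applied to the displacement vector of each pair
  coef <- 4 * epsilon * (-12 * sr6 * sr6 + 6 * sr6) / r2
  contrib <- dv * coef
  g <- rowsum(rbind(contrib, -contrib), c(idx[, 1L], idx[, 2L]))
  as.vector(t(g))
}

#' Morse cluster energy and gradient
#'
#' Sum over pairs of `De * ((1 - exp(-a * (r - re)))^2 - 1)`: well depth
#' `De` at separation `re`, stiffness `a`, dissociating to zero.  Finite
#' for all `r > 0`, which makes it a forgiving second analytic backend.
#'
#' @inheritParams lj_energy
#' @param De Well depth (> 0).
#' @param a Stiffness (> 0, inverse length).
#' @param re Equilibrium pair separation (> 0).
#' @export
morse_energy <- function(vec, De = 1, a = 1, re = 1) {
  n <- length(vec) %/% 3L
  if (length(vec) %% 3L != 0L) stop("position vector length must be 3n")
  if (n < 2L) return(0)
  r <- as.numeric(stats::dist(coords_of(vec)))
  if (any(r == 0)) stop("overlap error: coincident atoms")
  u <- 1 - exp(-a * (r - re))
  sum(De * (u * u - 1))
}

#' @rdname morse_energy
#' @export
morse_gradient <- function(vec, De = 1, a = 1, re = 1) {
  n <- length(vec) %/% 3L
  if (n < 2L) return(numeric(length(vec)))
  m <- coords_of(vec)
  idx <- pair_index(n)
  dv <- m[idx[, 1L], , drop = FALSE] - m[idx[, 2L], , drop = FALSE]
  r <- sqrt(rowSums(dv * dv))
  if (any(r == 0)) stop("overlap error: coincident atoms")
  ex <- exp(-a * (r - re))
  coef <- 2 * De * a * ex * (1 - ex) / r
  contrib <- dv * coef
  g <- rowsum(rbind(contrib, -contrib), c(idx[, 1L], idx[, 2L]))
  as.vector(t(g))
}

new_backend <- function(name, energy_fn, grad_fn = NULL, fast_fn = NULL,
                        overlap_threshold = 0, unit = "model", extra = list()) {
  b <- c(list(name = name, energy_fn = energy_fn, grad_fn = grad_fn,
              fast_fn = fast_fn, overlap_threshold = overlap_threshold,
              unit = unit), extra)
  class(b) <- "energy_backend"
  b
}

#' @export
print.energy_backend <- function(x, ...) {
  cat(sprintf("<energy_backend> %s (unit: %s, %s)\n", x$name, x$unit,
              if (is.null(x$grad_fn)) "single-point only"
              else "analytic gradient"))
  invisible(x)
}

#' Built-in analytic backends
#'
#' `lj_backend()` and `morse_backend()` wrap the pair potentials behind the
#' uniform backend contract; both carry analytic gradients, so they work
#' with every searcher including [local_minimize()].  The overlap threshold
#' defaults to `1e-3` times the potential's length scale: below it the
#' potential is mathematically valid but physically meaningless, and the
#' evaluation is refused with the penalty energy instead.
#'
#' @inheritParams lj_energy
#' @inheritParams morse_energy
#' @param overlap_threshold Minimum pair distance accepted (0 disables).
#' @return An `energy_backend`.
#' @export
lj_backend <- function(epsilon = 1, sigma = 1,
                       overlap_threshold = 1e-3 * sigma) {
  if (epsilon <= 0 || sigma <= 0) stop("epsilon and sigma must be positive")
  thr <- overlap_threshold
  fast <- function(vec) {
    n <- length(vec) %/% 3L
    if (n < 2L) return(0)
    r <- as.numeric(stats::dist(coords_of(vec)))
    if (any(r < thr)) return(PENALTY_ENERGY)
    sr6 <- (sigma / r)^6
    e <- sum(4 * epsilon * (sr6 * sr6 - sr6))
    if (!is.finite(e)) PENALTY_ENERGY else e
  }
  new_backend("lennard_jones",
              energy_fn = function(vec, ...) lj_energy(vec, epsilon, sigma),
              grad_fn = function(vec) lj_gradient(vec, epsilon, sigma),
              fast_fn = fast,
              overlap_threshold = thr,
              extra = list(epsilon = epsilon, sigma = sigma,
                           length_scale = sigma))
}

#' @rdname lj_backend
#' @export
morse_backend <- function(De = 1, a = 1, re = 1,
                          overlap_threshold = 1e-3 * re) {
  if (De <= 0 || a <= 0 || re <= 0) stop("De, a, re must be positive")
  thr <- overlap_threshold
  fast <- function(vec) {
    n <- length(vec) %/% 3L
    if (n < 2L) return(0)
    r <- as.numeric(stats::dist(coords_of(vec)))
    if (any(r < thr)) return(PENALTY_ENERGY)
    u <- 1 - exp(-a * (r - re))
    e <- sum(De * (u * u - 1))
    if (!is.finite(e)) PENALTY_ENERGY else e
  }
  new_backend("morse",
              energy_fn = function(vec, ...) morse_energy(vec, De, a, re),
              grad_fn = function(vec) morse_gradient(vec, De, a, re),
              fast_fn = fast,
              overlap_threshold = thr,
              extra = list(De = De, a = a, re = re, length_scale = re))
}

#' Arbitrary-objective backend
#'
#' Exposes any real-valued function of a flat vector as an energy backend,
#' e.g. analytic test functions (sphere, Rosenbrock) for validating the
#' searchers against known minima.  No overlap semantics apply.
#'
#' @param fn Function `vec -> numeric(1)`.
#' @param grad Optional gradient function `vec -> numeric(length(vec))`.
#' @param name Backend label.
#' @export
function_backend <- function(fn, grad = NULL, name = "objective") {
  new_backend(name,
              energy_fn = function(vec, ...) fn(vec),
              grad_fn = grad,
              fast_fn = function(vec) {
                e <- fn(vec)
                if (!is.finite(e)) PENALTY_ENERGY else e
              },
              overlap_threshold = 0)
}

#' Engine input-deck template
#'
#' Describes the coupling to an external quantum-chemistry engine: a text
#' deck template with placeholder tokens, the command that consumes the
#' rendered deck, and a regular expression that captures the single-point
#' energy from the engine log.
#'
#' @param deck_template Deck text containing `{COORDS}` (mandatory) and
#'   optionally `{CHARGE}`, `{MULT}`, `{TITLE}`.
#' @param command Executable invocation; the rendered deck path is appended
#'   as the final argument and standard output is captured as the log.
#' @param energy_pattern PCRE with exactly one capture group matching the
#'   energy; the last match in the log wins (iterative engines print one
#'   energy per cycle and the converged value is final).
#' @param charge Total charge. @param multiplicity Spin multiplicity (>= 1).
#' @param timeout Per-invocation wall-clock limit in seconds.
#' @return An object of class `engine_template`.
#' @examples
#' # A Gaussian-style single-point deck (documentation only; any engine
#' # whose log prints a parsable total energy can be wired the same way):
#' tmpl <- engine_template(
#'   deck_template = paste0(
#'     "%NProcShared=2\n# B3LYP/6-311+G* SP\n\n{TITLE}\n\n",
#'     "{CHARGE} {MULT}\n{COORDS}\n"),
#'   command = "g09",
#'   energy_pattern = "SCF Done:\\s+E\\(.*?\\)\\s*=\\s*(-?\\d+\\.\\d+)")
#' @export
engine_template <- function(deck_template,
                            command = "",
                            energy_pattern = "E_TOTAL\\s*=\\s*(-?\\d+\\.?\\d*)",
                            charge = 0L, multiplicity = 1L, timeout = 300) {
  if (!grepl("{COORDS}", deck_template, fixed = TRUE))
    stop("template error: deck_template must contain {COORDS}")
  known <- c("{COORDS}", "{CHARGE}", "{MULT}", "{TITLE}")
  toks <- regmatches(deck_template,
                     gregexpr("\\{[A-Z]+\\}", deck_template))[[1]]
  bad <- setdiff(unique(toks), known)
  if (length(bad))
    stop("template error: unknown placeholder(s): ",
         paste(bad, collapse = ", "))
  if (multiplicity < 1L) stop("multiplicity must be >= 1")
  structure(list(deck_template = deck_template, command = command,
                 energy_pattern = energy_pattern,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity),
                 timeout = timeout),
            class = "engine_template")
}

#' Render an engine input deck
#'
#' Substitutes `{COORDS}` with one `"symbol x y z"` line per atom
#' (coordinates to 6 decimal places) and fills `{CHARGE}`, `{MULT}`,
#' `{TITLE}`.  Output is byte-stable for identical inputs.
#'
#' @param tmpl An [engine_template()].
#' @param geom A [cluster_geometry()].
#' @param title Free-text title substituted for `{TITLE}`.
#' @return A single deck string.
#' @export
render_deck <- function(tmpl, geom, title = "cluster") {
  stopifnot(inherits(tmpl, "engine_template"),
            inherits(geom, "cluster_geometry"))
  coords <- paste(sprintf("%s %.6f %.6f %.6f", geom$elements,
                          geom$coords[, 1L], geom$coords[, 2L],
                          geom$coords[, 3L]),
                  collapse = "\n")
  out <- tmpl$deck_template
  out <- gsub("{COORDS}", coords, out, fixed = TRUE)
  out <- gsub("{CHARGE}", as.character(tmpl$charge), out, fixed = TRUE)
  out <- gsub("{MULT}", as.character(tmpl$multiplicity), out, fixed = TRUE)
  gsub("{TITLE}", title, out, fixed = TRUE)
}

#' Parse an energy from an engine log
#'
#' Applies `pattern` (one capture group) to the log text; the last match
#' wins.  Absence of any match is not an error: it is reported as status
#' `engine_failed` with the penalty energy, mirroring how a crashed or
#' non-convergent engine run is absorbed by the search.
#'
#' @param log_text Character vector of log lines (or one string).
#' @param pattern PCRE with exactly one capture group.
#' @param unit Unit label attached to the result.
#' @return An `energy_result`.
#' @export
parse_energy <- function(log_text,
                         pattern = "E_TOTAL\\s*=\\s*(-?\\d+\\.?\\d*)",
                         unit = "hartree") {
  txt <- paste(log_text, collapse = "\n")
  m <- regmatches(txt, gregexec(pattern, txt, perl = TRUE))[[1]]
  if (length(m) == 0L || ncol(m) == 0L)
    return(energy_result("engine_failed", PENALTY_ENERGY, unit,
                         "no energy match in engine log"))
  val <- suppressWarnings(as.numeric(m[2L, ncol(m)]))
  if (is.na(val))
    return(energy_result("engine_failed", PENALTY_ENERGY, unit,
                         "energy capture is not numeric"))
  energy_result("ok", val, unit,
                sprintf("last of %d matches", ncol(m)))
}

#' External engine backend
#'
#' Reproduces the system-call coupling used to drive a quantum-chemistry
#' engine: for each evaluation a scratch directory `run_<restart>_<iter>_<particle>`
#' is created, the rendered deck written to `input.deck`, the engine command
#' invoked with the deck path appended and its standard output captured as
#' `output.log`, and the energy parsed from the log.  The directory is
#' removed on success and kept on failure for diagnostics.  Timeouts and
#' non-zero exits yield status `engine_failed` with the penalty energy; the
#' swarm barrier still completes.
#'
#' @param template An [engine_template()].
#' @param elements Element symbols of the cluster being evaluated.
#' @param scratch_root Directory under which per-job scratch dirs are made.
#' @param overlap_threshold Minimum pair distance (Angstrom) below which the
#'   engine is not invoked at all; default 0.5 (engine protection — fused
#'   nuclei make self-consistent field cycles diverge).
#' @return An `energy_backend` (single-point only; no gradient).
#' @export
external_backend <- function(template, elements,
                             scratch_root = tempfile("engine_"),
                             overlap_threshold = 0.5) {
  stopifnot(inherits(template, "engine_template"))
  dir.create(scratch_root, recursive = TRUE, showWarnings = FALSE)
  energy_fn <- function(vec, label = "run_0_0_0", timeout = NULL, ...) {
    tmo <- if (is.null(timeout)) template$timeout else timeout
    job_dir <- file.path(scratch_root, label)
    dir.create(job_dir, recursive = TRUE, showWarnings = FALSE)
    deck_path <- file.path(job_dir, "input.deck")
    log_path <- file.path(job_dir, "output.log")
    writeLines(render_deck(template, unflatten_geometry(vec, elements),
                           title = label), deck_path)
    parts <- strsplit(trimws(template$command), "\\s+")[[1]]
    status <- suppressWarnings(tryCatch(
      system2(parts[1L], args = c(parts[-1L], shQuote(deck_path)),
              stdout = log_path, stderr = log_path,
              timeout = if (is.finite(tmo)) tmo else 0),
      error = function(e) -1L))
    if (!identical(status, 0L) && !identical(status, 0)) {
      return(energy_result("engine_failed", PENALTY_ENERGY, "hartree",
                           sprintf("engine exit status %s (dir kept: %s)",
                                   status, job_dir)))
    }
    res <- parse_energy(readLines(log_path, warn = FALSE),
                        template$energy_pattern, unit = "hartree")
    if (res$status == "ok") unlink(job_dir, recursive = TRUE)
    res
  }
  new_backend("external", energy_fn = energy_fn, grad_fn = NULL,
              fast_fn = NULL, overlap_threshold = overlap_threshold,
              unit = "hartree",
              extra = list(template = template, elements = elements,
                           scratch_root = scratch_root))
}

#' Mock engine backend
#'
#' Exercises the full render-deck / invoke / parse-log pipeline without an
#' external program: the deck is rendered and re-read (so coordinates pass
#' through the 6-decimal deck rounding), the Lennard-Jones energy of the
#' re-read geometry is computed in place of the engine, a log is written and
#' parsed back.  Agreement with direct [lj_energy()] to deck-rounding
#' precision validates the coupling as a pipeline.
#'
#' @inheritParams lj_energy
#' @param scratch_root Directory for deck/log files.
#' @export
mock_engine_backend <- function(epsilon = 1, sigma = 1,
                                scratch_root = tempfile("mock_")) {
  dir.create(scratch_root, recursive = TRUE, showWarnings = FALSE)
  tmpl <- engine_template(
    deck_template = "{TITLE}\n{CHARGE} {MULT}\n{COORDS}\n",
    command = "mock-internal",
    energy_pattern = "E_TOTAL\\s*=\\s*(-?\\d+\\.\\d+)")
  energy_fn <- function(vec, label = "run_0_0_0", ...) {
    n <- length(vec) %/% 3L
    geom <- unflatten_geometry(vec, rep("X", n))
    deck <- render_deck(tmpl, geom, title = label)
    deck_path <- file.path(scratch_root, paste0(label, ".deck"))
    writeLines(deck, deck_path)
    # "engine": re-read the deck, recover rounded coordinates, compute LJ
    lines <- readLines(deck_path, warn = FALSE)
    atom_lines <- grep("^[A-Za-z]+ -?\\d+\\.\\d{6} ", lines, value = TRUE)
    parts <- do.call(rbind, strsplit(atom_lines, "\\s+"))
    coords <- matrix(as.numeric(parts[, 2:4]), ncol = 3L)
    e <- lj_energy(as.vector(t(coords)), epsilon, sigma)
    log_path <- file.path(scratch_root, paste0(label, ".log"))
    writeLines(c("MOCK ENGINE LOG",
                 sprintf("CYCLE 1 E_TOTAL = %.10f", e + 0.5),
                 sprintf("FINAL   E_TOTAL = %.10f", e)), log_path)
    res <- parse_energy(readLines(log_path, warn = FALSE),
                        tmpl$energy_pattern, unit = "model")
    res
  }
  new_backend("mock", energy_fn = energy_fn, grad_fn = NULL,
              fast_fn = NULL, overlap_threshold = 1e-3 * sigma,
              unit = "model",
              extra = list(template = tmpl, scratch_root = scratch_root))
}

#' Evaluate a position vector under a backend
#'
#' The single entry point the searchers use.  If the minimum pair distance
#' falls below the backend's overlap threshold the evaluation is refused
#' with status `overlap_rejected` and the penalty energy `+1e6` — an
#' external engine is never invoked on a fused geometry.  Backend errors
#' and timeouts likewise become status `engine_failed` with the penalty
#' energy, so one bad particle never aborts an iteration.
#'
#' @param backend An `energy_backend`.
#' @param vec Position vector.
#' @param label Scratch label (`run_<restart>_<iter>_<particle>`) used by
#'   file-based backends.
#' @param timeout Optional per-job wall-clock limit (seconds), overriding
#'   the backend's own.
#' @return An `energy_result`.
#' @export
evaluate_energy <- function(backend, vec, label = "run_0_0_0",
                            timeout = NULL) {
  stopifnot(inherits(backend, "energy_backend"))
  if (backend$overlap_threshold > 0 &&
      min_pair_distance(vec) < backend$overlap_threshold) {
    return(energy_result("overlap_rejected", PENALTY_ENERGY, backend$unit,
                         sprintf("min pair distance below %g",
                                 backend$overlap_threshold)))
  }
  out <- tryCatch(backend$energy_fn(vec, label = label, timeout = timeout),
                  error = function(e)
                    energy_result("engine_failed", PENALTY_ENERGY,
                                  backend$unit, conditionMessage(e)))
  if (inherits(out, "energy_result")) return(out)
  if (!is.numeric(out) || length(out) != 1L || !is.finite(out))
    return(energy_result("engine_failed", PENALTY_ENERGY, backend$unit,
                         "non-finite energy"))
  energy_result("ok", out, backend$unit, backend$name)
}

# Numeric-only evaluation for tight loops (SA proposals, line searches):
# returns the energy with the penalty policy already applied.
eval_fast <- function(backend, vec) {
  if (!is.null(backend$fast_fn)) return(backend$fast_fn(vec))
  evaluate_energy(backend, vec)$energy
}
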