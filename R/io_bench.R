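# XYZ I/O, rotation-invariant fingerprints, the multi-start reference
# oracle, run configuration files, and the command-line entry point.

#' Read / write XYZ geometry files
#'
#' Standard XYZ dialect: line 1 the atom count, line 2 a free comment,
#' then one `"symbol x y z"` line per atom (Angstrom).  `write_xyz()`
#' prints coordinates to 6 decimal places, so a write/read round trip is
#' the identity to that precision and the comment is preserved verbatim.
#'
#' @param path File path.
#' @return `read_xyz()` returns a [cluster_geometry()] with the comment in
#'   attribute `"comment"`; `write_xyz()` returns `path` invisibly.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("parse error at line 1: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("parse error at line 1: atom count must be a positive integer")
  if (length(lines) < 2L + n)
    stop(sprintf("parse error: header says %d atoms but only %d atom lines present",
                 n, max(0L, length(lines) - 2L)))
  comment <- lines[2L]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- 2L + i
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) < 4L)
      stop(sprintf("parse error at line %d: expected 'symbol x y z'", ln))
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz)))
      stop(sprintf("parse error at line %d: non-numeric coordinate", ln))
    elements[i] <- parts[1L]
    coords[i, ] <- xyz
  }
  extra <- if (length(lines) > 2L + n)
    trimws(lines[(3L + n):length(lines)]) else character(0)
  if (any(nzchar(extra)))
    stop(sprintf("parse error: header says %d atoms but more atom lines follow",
                 n))
  g <- cluster_geometry(elements, coords)
  attr(g, "comment") <- comment
  g
}

#' @rdname read_xyz
#' @param geom A [cluster_geometry()].
#' @param comment Comment line (line 2) written verbatim.
#' @export
write_xyz <- function(geom, path, comment = "") {
  stopifnot(inherits(geom, "cluster_geometry"))
  lines <- c(as.character(length(geom$elements)),
             comment,
             sprintf("%s %.6f %.6f %.6f", geom$elements,
                     geom$coords[, 1L], geom$coords[, 2L],
                     geom$coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Sorted pair-distance fingerprint
#'
#' All `n (n - 1) / 2` pairwise distances in ascending order: invariant
#' under rigid translation, rotation, reflection and atom relabeling.
#' Serves as a testable stand-in for point-group labels when comparing
#' structures (two geometries are judged equivalent when their
#' fingerprints agree within a tolerance, 1e-3 by convention).
#'
#' @param vec Position vector (length divisible by 3).
#' @return Ascending numeric vector; empty for fewer than 2 atoms.
#' @export
sorted_pair_distances <- function(vec) {
  if (length(vec) %% 3L != 0L)
    stop("position vector length must be divisible by 3")
  n <- length(vec) %/% 3L
  if (n < 2L) return(numeric(0))
  sort(as.numeric(stats::dist(matrix(vec, ncol = 3L, byrow = TRUE))))
}

#' Multi-start reference minima (the oracle)
#'
#' Brute-force reference for desk-scale acceptance checks: at least 1000
#' independent L-BFGS-B minimizations from uniform random starts, keeping
#' only strictly converged (gradient norm below `1e-6`), connected
#' (maximum pair distance below `4 * length scale`) outcomes, and
#' returning the lowest.  Deliberately independent of the package's own
#' searchers and its own BFGS implementation.  For clusters of up to 6
#' atoms the returned energy is reproducible across oracle seeds to 1e-6.
#'
#' @param n_atoms Number of atoms; guarded to `<= 8` (the multi-start
#'   enumeration is a desk-scale instrument, not a production searcher).
#' @param potential `"lennard_jones"` or `"morse"`.
#' @param params Named list of potential parameters (see [lj_backend()]).
#' @param n_starts Number of random starts (default 1000).
#' @param seed Oracle seed.
#' @param box Uniform initialization range for the random starts.
#' @return List with `energy`, `position`, `n_kept` (starts surviving the
#'   convergence/connectivity filter), and `distinct_energies` (distinct
#'   minimum levels found, ascending, merged at 1e-4).
#' @export
reference_minimum <- function(n_atoms,
                              potential = c("lennard_jones", "morse"),
                              params = list(), n_starts = 1000L,
                              seed = 1L, box = c(-3, 3)) {
  potential <- match.arg(potential)
  if (n_atoms > 8L)
    stop("capability error: the oracle is desk-scale only (n_atoms <= 8)")
  if (n_atoms < 2L) stop("n_atoms must be >= 2")
  backend <- do.call(if (potential == "lennard_jones") lj_backend
                     else morse_backend, params)
  scale <- backend$length_scale
  d <- 3L * n_atoms
  fn <- function(x) eval_fast(backend, x)
  gr <- function(x) {
    g <- tryCatch(backend$grad_fn(x), error = function(e) NULL)
    if (is.null(g) || !all(is.finite(g))) numeric(d) else g
  }
  with_seed_local(seed, {
    best_e <- Inf
    best_x <- NULL
    kept <- numeric(0)
    for (k in seq_len(n_starts)) {
      x0 <- stats::runif(d, box[1L], box[2L])
      fit <- tryCatch(
        stats::optim(x0, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = 500, factr = 10, pgtol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      g <- backend$grad_fn(fit$par)
      if (!all(is.finite(g)) || sqrt(sum(g * g)) >= 1e-6) next
      dists <- stats::dist(matrix(fit$par, ncol = 3L, byrow = TRUE))
      if (max(dists) >= 4 * scale) next  # dissociated, not one cluster
      kept <- c(kept, fit$value)
      if (fit$value < best_e) {
        best_e <- fit$value
        best_x <- fit$par
      }
    }
    if (!length(kept))
      stop("oracle failure: no start converged to a connected minimum")
    lv <- sort(kept)
    distinct <- lv[c(TRUE, diff(lv) > 1e-4)]
    list(energy = best_e, position = best_x, n_kept = length(kept),
         distinct_energies = distinct)
  })
}

#' Frozen Lennard-Jones reference minima
#'
#' Connected-cluster minimum energies of LJ-n (reduced units,
#' `epsilon = sigma = 1`), computed with [reference_minimum()] at 5000
#' starts and frozen.  LJ-3 and LJ-4 are the exact analytic values of the
#' equilateral triangle (-3) and regular tetrahedron (-6); LJ-5 has a
#' single connected minimum; LJ-6 has exactly two funnels, the octahedral
#' global minimum and a second deep well 0.41 above it — the desk-scale
#' analogue of a potential surface with two competing deep wells.
#'
#' @param n_atoms Cluster size, 3 to 6.
#' @return Ascending numeric vector of the distinct connected-minimum
#'   energies (length 1 except for `n_atoms = 6`).
#' @export
lj_reference_energies <- function(n_atoms) {
  frozen <- list(`3` = -3.0,
                 `4` = -6.0,
                 `5` = -9.10385242,
                 `6` = c(-12.71206226, -12.30292753))
  key <- as.character(n_atoms)
  if (is.null(frozen[[key]]))
    stop("frozen references cover n_atoms in 3..6")
  sort(frozen[[key]])
}

# ---------------------------------------------------------------------------
# Run configuration files: flat INI-style sections.

parse_ini <- function(lines) {
  out <- list()
  section <- NULL
  for (k in seq_along(lines)) {
    line <- sub("[#;].*$", "", lines[k])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- sub("^\\[([^]]+)\\]$", "\\1", line)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", line, fixed = TRUE)) {
      if (is.null(section))
        stop(sprintf("config parse error at line %d: key outside any [section]", k))
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      out[[section]][[key]] <- val
    } else {
      stop(sprintf("config parse error at line %d: expected 'key = value'", k))
    }
  }
  out
}

ini_num <- function(section, key, default = NULL) {
  v <- section[[key]]
  if (is.null(v)) return(default)
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) stop(sprintf("config error: field '%s' must be numeric", key))
  num
}

#' Read a run configuration file
#'
#' Flat INI-style document with sections `[cluster]` (fields `elements` or
#' `n_atoms`, optional `xyz`, `charge`, `multiplicity`), exactly one method
#' section `[pso]`, `[sa]` or `[bh]` (the respective configuration fields;
#' every published default applies, so a method section may be empty),
#' `[backend]` (`name` plus potential parameters, or `template` path for an
#' external engine), and optional `[executor]` and `[output]` sections.
#'
#' @param path Config file path.
#' @param require_single_method Enforce exactly one enabled method section
#'   (`TRUE` for `search`; `compare` relaxes it).
#' @return Named list with `cluster`, `method`, `method_config`, `backend`,
#'   `exec_config`, `output_dir`, `seed`.
#' @export
read_run_config <- function(path, require_single_method = TRUE) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  ini <- parse_ini(readLines(path, warn = FALSE))
  cl <- ini$cluster
  if (is.null(cl)) stop("config error: missing [cluster] section")
  elements <- NULL
  start <- NULL
  if (!is.null(cl$xyz)) {
    if (!file.exists(cl$xyz))
      stop("config error: field 'xyz' points to a missing file: ", cl$xyz)
    start <- read_xyz(cl$xyz)
    elements <- start$elements
  } else if (!is.null(cl$elements)) {
    elements <- strsplit(trimws(cl$elements), "\\s+")[[1]]
  } else if (!is.null(cl$n_atoms)) {
    elements <- rep("C", as.integer(ini_num(cl, "n_atoms")))
  } else {
    stop("config error: [cluster] needs 'elements', 'n_atoms' or 'xyz'")
  }

  methods_present <- intersect(c("pso", "sa", "bh"), names(ini))
  if (require_single_method && length(methods_present) != 1L)
    stop("config error: exactly one method section ([pso], [sa] or [bh]) must be enabled, found ",
         length(methods_present))

  bk <- ini$backend
  if (is.null(bk) || is.null(bk$name))
    stop("config error: [backend] section with field 'name' is required")
  backend <- switch(bk$name,
    lennard_jones = lj_backend(epsilon = ini_num(bk, "epsilon", 1),
                               sigma = ini_num(bk, "sigma", 1)),
    morse = morse_backend(De = ini_num(bk, "De", 1),
                          a = ini_num(bk, "a", 1),
                          re = ini_num(bk, "re", 1)),
    mock = mock_engine_backend(epsilon = ini_num(bk, "epsilon", 1),
                               sigma = ini_num(bk, "sigma", 1)),
    external = {
      if (is.null(bk$template) || !file.exists(bk$template))
        stop("config error: external backend needs an existing 'template' file")
      tl <- parse_ini(readLines(bk$template, warn = FALSE))$engine
      if (is.null(tl) || is.null(tl$deck) || !file.exists(tl$deck))
        stop("config error: engine template needs [engine] with an existing 'deck' file")
      tmpl <- engine_template(
        deck_template = paste(readLines(tl$deck, warn = FALSE),
                              collapse = "\n"),
        command = tl$command,
        energy_pattern = if (is.null(tl$energy_pattern))
          formals(engine_template)$energy_pattern else tl$energy_pattern,
        charge = ini_num(cl, "charge", 0),
        multiplicity = ini_num(cl, "multiplicity", 1),
        timeout = ini_num(tl, "timeout", 300))
      external_backend(tmpl, elements)
    },
    stop("config error: unknown backend name '", bk$name, "'"))

  build_cfg <- function(method) {
    sec <- if (is.null(ini[[method]])) list() else ini[[method]]
    switch(method,
      pso = swarm_config(
        n_pop = ini_num(sec, "n_pop", 10),
        w_min = ini_num(sec, "w_min", 0.4),
        w_max = ini_num(sec, "w_max", 0.8),
        d1 = ini_num(sec, "d1", 2), d2 = ini_num(sec, "d2", 2),
        init_low = ini_num(sec, "init_low", -3),
        init_high = ini_num(sec, "init_high", 3),
        stall_threshold = ini_num(sec, "stall_threshold", 30),
        energy_tol = ini_num(sec, "energy_tol", 1e-6),
        max_iter = ini_num(sec, "max_iter", 600),
        n_restarts = ini_num(sec, "n_restarts", 5),
        restart_noise_sigma = ini_num(sec, "restart_noise_sigma", 0.3),
        seed = ini_num(sec, "seed", 1)),
      sa = sa_config(
        T0 = ini_num(sec, "T0", 1),
        alpha = ini_num(sec, "alpha", 0.95),
        steps_per_T = ini_num(sec, "steps_per_T", 100),
        step_size = ini_num(sec, "step_size", 0.1),
        max_steps = ini_num(sec, "max_steps", 30000),
        seed = ini_num(sec, "seed", 1)),
      bh = bh_config(
        perturb_delta = ini_num(sec, "perturb_delta", 0.4),
        accept_T = ini_num(sec, "accept_T", 0.8),
        max_hops = ini_num(sec, "max_hops", 100),
        minimizer_tol = ini_num(sec, "minimizer_tol", 1e-8),
        seed = ini_num(sec, "seed", 1)))
  }
  method <- if (length(methods_present) == 1L) methods_present else "pso"
  ex <- if (is.null(ini$executor)) list() else ini$executor
  exec_config <- executor_config(
    n_workers = ini_num(ex, "n_workers", 1),
    per_job_timeout = ini_num(ex, "per_job_timeout", Inf))
  out <- if (is.null(ini$output)) list() else ini$output
  list(cluster = list(elements = elements, start = start),
       method = method,
       method_config = build_cfg(method),
       build_cfg = build_cfg,
       backend = backend,
       exec_config = exec_config,
       output_dir = out$dir,
       seed = ini_num(if (is.null(ini[[method]])) list() else ini[[method]],
                      "seed", 1))
}

# ---------------------------------------------------------------------------
# Command-line entry point.

write_summary <- function(path, fields) {
  writeLines(sprintf("%s = %s", names(fields),
                     vapply(fields, function(v) format(v, digits = 12),
                            character(1))),
             path)
}

run_method <- function(method, method_config, backend, cluster,
                       exec_config, trace_file = NULL) {
  elements <- cluster$elements
  n_atoms <- length(elements)
  if (method == "pso") {
    if (!is.null(cluster$start))
      run_pso(method_config, backend, start = cluster$start,
              exec_config = exec_config, trace_file = trace_file)
    else
      restart_search(method_config, backend, n_atoms = n_atoms,
                     elements = elements, exec_config = exec_config,
                     trace_file = trace_file)
  } else {
    # single-walker methods start from a compact random arrangement
    # (published comparisons started from already-assembled structures)
    start <- if (!is.null(cluster$start)) flatten_geometry(cluster$start)
    else with_seed_local(method_config$seed + 1000L,
                         stats::runif(3L * n_atoms, -1.5, 1.5))
    if (method == "sa") run_sa(method_config, backend, start, elements)
    else run_bh(method_config, backend, start, elements)
  }
}

#' Command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{`search <config> [--seed S] [--out DIR]`}{Run the method enabled
#'     in the config file; writes `best.xyz`, `trajectory.tsv` and
#'     `summary.txt` to the output directory.}
#'   \item{`compare <config> [--seed S] [--out DIR]`}{Run PSO, SA and BH on
#'     the same system and emit one report row per method
#'     (`method  iterations  best_energy  converged`).}
#'   \item{`oracle --n N [--potential P] [--n-starts K] [--seed S]`}{Compute
#'     the multi-start reference minimum.}
#' }
#'
#' @param argv Character vector of arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly: 0 success, 1 runtime failure, 2 invalid
#'   configuration or usage.
#' @export
cli_run <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: search <config> [--seed S] [--out DIR]\n",
        "       compare <config> [--seed S] [--out DIR]\n",
        "       oracle --n N [--potential P] [--n-starts K] [--seed S]\n",
        sep = "")
  }
  opt_val <- function(args, flag, default = NULL) {
    i <- which(args == flag)
    if (!length(i)) return(default)
    if (i[1L] + 1L > length(args)) stop("missing value for ", flag)
    args[i[1L] + 1L]
  }
  if (!length(argv)) {
    usage()
    return(invisible(2L))
  }
  cmd <- argv[1L]
  args <- argv[-1L]
  status <- tryCatch({
    switch(cmd,
      search = {
        cfg <- read_run_config(args[1L])
        seed_opt <- opt_val(args, "--seed")
        if (!is.null(seed_opt))
          cfg$method_config$seed <- as.integer(seed_opt)
        out_dir <- opt_val(args, "--out", cfg$output_dir)
        if (is.null(out_dir)) out_dir <- "."
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        res <- run_method(cfg$method, cfg$method_config, cfg$backend,
                          cfg$cluster, cfg$exec_config,
                          trace_file = file.path(out_dir, "trajectory.tsv"))
        if (cfg$method != "pso")
          utils::write.table(
            data.frame(restart = 1L, iteration = seq_along(res$trajectory),
                       gbest_energy = res$trajectory,
                       evaluations = seq_along(res$trajectory),
                       stall = 0L),
            file.path(out_dir, "trajectory.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
        if (!is.null(res$best_geometry))
          write_xyz(res$best_geometry, file.path(out_dir, "best.xyz"),
                    comment = sprintf("%s best energy %.8f", cfg$method,
                                      res$best_energy))
        write_summary(file.path(out_dir, "summary.txt"),
                      list(method = res$method,
                           seed = cfg$method_config$seed,
                           best_energy = res$best_energy,
                           iterations = res$iterations_used,
                           evaluations = res$evaluations,
                           converged = res$converged))
        cat(sprintf("%s: best energy %.8f (%s)\n", res$method,
                    res$best_energy,
                    if (res$converged) "converged" else "iteration cap"))
        0L
      },
      compare = {
        cfg <- read_run_config(args[1L], require_single_method = FALSE)
        seed_opt <- opt_val(args, "--seed")
        out_dir <- opt_val(args, "--out", cfg$output_dir)
        rows <- lapply(c("pso", "sa", "bh"), function(m) {
          mc <- cfg$build_cfg(m)
          if (!is.null(seed_opt)) mc$seed <- as.integer(seed_opt)
          res <- run_method(m, mc, cfg$backend, cfg$cluster,
                            cfg$exec_config)
          data.frame(method = m, iterations = res$iterations_used,
                     best_energy = res$best_energy,
                     converged = res$converged)
        })
        tab <- do.call(rbind, rows)
        cat("method\titerations\tbest_energy\tconverged\n")
        for (i in seq_len(nrow(tab)))
          cat(sprintf("%s\t%d\t%.8f\t%s\n", tab$method[i],
                      tab$iterations[i], tab$best_energy[i],
                      tab$converged[i]))
        if (!is.null(out_dir)) {
          dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
          utils::write.table(tab, file.path(out_dir, "compare.tsv"),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
        0L
      },
      oracle = {
        n <- as.integer(opt_val(args, "--n"))
        if (is.na(n)) stop("config error: oracle needs --n")
        pot <- opt_val(args, "--potential", "lennard_jones")
        ns <- as.integer(opt_val(args, "--n-starts", "1000"))
        sd <- as.integer(opt_val(args, "--seed", "1"))
        ref <- reference_minimum(n, potential = pot, n_starts = ns,
                                 seed = sd)
        cat(sprintf("oracle %s n=%d: minimum %.8f (%d converged starts, %d distinct levels)\n",
                    pot, n, ref$energy, ref$n_kept,
                    length(ref$distinct_energies)))
        0L
      },
      {
        usage()
        2L
      })
  },
  error = function(e) {
    msg <- conditionMessage(e)
    cat("error:", msg, "\n", file = stderr())
    if (grepl("config error|parse error|file not found|missing", msg)) 2L
    else 1L
  })
  invisible(status)
}
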