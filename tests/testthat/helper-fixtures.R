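# Shared fixtures: random geometries, rigid motions, and a tiny python
# "engine" used to exercise the external-backend coupling.

random_positions <- function(n_atoms, seed, lo = -2, hi = 2) {
  withr::with_seed(seed, runif(3 * n_atoms, lo, hi))
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

apply_rigid <- function(vec, rot, shift) {
  m <- matrix(vec, ncol = 3, byrow = TRUE) %*% t(rot)
  m <- sweep(m, 2, shift, "+")
  as.vector(t(m))
}

# Equilateral triangle in the xy-plane with side s.
triangle_positions <- function(s) {
  c(0, 0, 0,
    s, 0, 0,
    s / 2, s * sqrt(3) / 2, 0)
}

# Regular tetrahedron with edge s.
tetrahedron_positions <- function(s) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  as.vector(t(v * s / (2 * sqrt(2))))
}

# Writes a python script that reads an input deck (atom lines "Sym x y z"),
# computes the reduced-unit Lennard-Jones energy, and prints two E_TOTAL
# lines (per-cycle then final).  When the first x-coordinate exceeds 100 it
# sleeps `sleep_s` seconds first; when it exceeds 500 it prints no energy.
write_python_lj_engine <- function(path, sleep_s = 5) {
  writeLines(c(
    "import sys, time",
    "lines = open(sys.argv[1]).read().splitlines()",
    "coords = []",
    "for ln in lines:",
    "    p = ln.split()",
    "    if len(p) == 4 and p[0].isalpha():",
    "        coords.append(tuple(map(float, p[1:])))",
    sprintf("if coords and 100 < coords[0][0] < 500: time.sleep(%g)",
            sleep_s),
    "if coords and coords[0][0] > 500:",
    "    print('no energy here'); sys.exit(0)",
    "e = 0.0",
    "for i in range(len(coords)):",
    "    for j in range(i + 1, len(coords)):",
    "        r2 = sum((a - b) ** 2 for a, b in zip(coords[i], coords[j]))",
    "        e += 4 * (r2 ** -6 - r2 ** -3)",
    "print('cycle 1 E_TOTAL = %.10f' % (e + 1.0))",
    "print('E_TOTAL = %.10f' % e)"), path)
  path
}

lj_engine_template <- function(engine_path, timeout = 300) {
  engine_template("{TITLE}\n{CHARGE} {MULT}\n{COORDS}\n",
                  command = paste("python", engine_path),
                  energy_pattern = "E_TOTAL\\s*=\\s*(-?\\d+\\.\\d+)",
                  timeout = timeout)
}
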