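# Shared fixtures: canonical parameter sets, random draws, and a tiny
# synthetic PDB writer. All fixtures are built in code at test time.

# Published Yfh1 rows used as generators throughout (dHm, Tm, dCp, printed Tc)
row70 <- function() thermo_params(28.5, 298.2, 3.73)
row61 <- function() thermo_params(19.9, 298.4, 1.58)

default_grid <- function() seq(278, 313, by = 2.5)

# Random physically-plausible parameter draws
random_params <- function(n, seed = 101) {
  set.seed(seed)
  data.frame(dHm = runif(n, 5, 50),
             Tm = runif(n, 280, 320),
             dCp = runif(n, 0.5, 5))
}

# Draws whose population curve is informative enough to fit on the standard
# grid (visible melting inside it and an observable cold side)
fittable_params <- function(n, seed = 202) {
  out <- list()
  set.seed(seed)
  while (length(out) < n) {
    p <- tryCatch(thermo_params(runif(1, 15, 35), runif(1, 292, 306),
                                runif(1, 1.5, 4.5)),
                  error = function(e) NULL)
    if (!is.null(p) && !is.na(p$Tc) && p$Tc > 270) out[[length(out) + 1L]] <- p
  }
  out
}

# Construct Gibbs-Helmholtz parameters with prescribed zeros (Tc, Tm) and
# heat-capacity difference, via the linear form dG = c0 + c1*T - dCp*T*log(T)
params_from_zeros <- function(Tc, Tm, dCp) {
  A <- rbind(c(1, Tc), c(1, Tm))
  b <- dCp * c(Tc * log(Tc), Tm * log(Tm))
  cc <- solve(A, b)
  thermo_params(dHm = cc[1] + dCp * Tm, Tm = Tm, dCp = dCp)
}

pdb_atom_line <- function(i, name, resname, resno, x, y, z, el) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          i, name, resname, resno, x, y, z, el)
}

# n_res-residue poly-Ala chain with backbone + CB; optionally with amide H
write_test_pdb <- function(path, n_res = 3, hydrogens = FALSE) {
  lines <- character(0); i <- 0
  for (r in seq_len(n_res)) {
    ox <- (r - 1) * 3.8
    atoms <- list(c("N", 0, 0, 0, "N"), c("CA", 1.4, 0.5, 0, "C"),
                  c("C", 2.4, -0.5, 0, "C"), c("O", 2.4, -1.7, 0, "O"),
                  c("CB", 1.4, 1.5, 1.2, "C"))
    if (hydrogens) atoms <- c(atoms, list(c("H", -0.5, 0.8, 0, "H")))
    for (a in atoms) {
      i <- i + 1
      lines <- c(lines, pdb_atom_line(i, a[1], "ALA", r,
                                      ox + as.numeric(a[2]),
                                      as.numeric(a[3]), as.numeric(a[4]),
                                      a[5]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# A target atom at the origin surrounded by dense shells of occluding atoms
write_cluster_pdb <- function(path, n_shells = 3) {
  lines <- pdb_atom_line(1, "N", "GLY", 1, 0, 0, 0, "N")
  i <- 1
  for (shell in seq_len(n_shells)) {
    rad <- shell * 2.8
    n_pts <- 20 * shell^2
    golden <- pi * (1 + sqrt(5))
    for (k in seq_len(n_pts)) {
      phi <- acos(1 - 2 * (k - 0.5) / n_pts)
      th <- golden * (k - 0.5)
      i <- i + 1
      lines <- c(lines, pdb_atom_line(i, "C", "DUM", 1 + i,
                                      rad * sin(phi) * cos(th),
                                      rad * sin(phi) * sin(th),
                                      rad * cos(phi), "C"))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Brute-force SASA oracle: independent high-density rejection sampling
brute_force_sasa <- function(s, idx, probe = 1.4, n = 10000, seed = 7) {
  set.seed(seed)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rad <- s$radius + probe
  vapply(idx, function(i) {
    z <- runif(n, -1, 1)
    th <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    p <- cbind(r * cos(th), r * sin(th), z) * rad[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > rad[j]^2
    }
    4 * pi * rad[i]^2 * mean(exposed)
  }, numeric(1))
}

# Noiseless populations for a parameter set on a grid
truth_populations <- function(p, grid = default_grid(), label = "truth") {
  population_series(label, grid, folded_fraction(grid, gibbs_helmholtz(grid, p)))
}
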