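## Van der Waals radii (A) for heavy atoms; hydrogens are never used
## ("no hydrogen atoms added" convention for crystallographic input).
VDW_RADII <- c(N = 1.55, C = 1.70, O = 1.52, S = 1.80)

#' Read a protein structure for burial scoring
#'
#' Parses a PDB-format file (via `bio3d::read.pdb`), keeps heavy atoms only
#' (hydrogens dropped if present) and assigns van der Waals radii from a
#' fixed table (N 1.55, C 1.70, O 1.52, S 1.80 A; other elements default to
#' 1.70 A).
#'
#' @param path path to a PDB file.
#' @param chain optional chain identifier to keep.
#' @return An object of class `structure_model`: a data frame with columns
#'   `element`, `resno`, `resid`, `atom_name`, `x`, `y`, `z`, `radius`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  elem <- toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                         substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1),
                         trimws(a$elesy)))
  keep <- elem != "H" & elem != "D"
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(a) == 0L) stop("structure contains no heavy atoms")
  radius <- unname(VDW_RADII[elem])
  radius[is.na(radius)] <- 1.70
  out <- data.frame(element = elem, resno = a$resno, resid = a$resid,
                    atom_name = trimws(a$elety),
                    x = a$x, y = a$y, z = a$z, radius = radius,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(c(out$x, out$y, out$z))))
    stop("structure contains non-finite coordinates")
  structure(out, source = basename(path),
            class = c("structure_model", "data.frame"))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model '%s': %d heavy atoms, %d residues\n",
              attr(x, "source") %||% "<in memory>",
              nrow(x), length(unique(x$resno))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Shrake-Rupley-style SASA for a subset of atoms (A^2 each). Points on the
## solvent-expanded sphere of each atom are tested against the expanded
## spheres of all other atoms.
atom_sasa <- function(s, idx = seq_len(nrow(s)), probe = 1.4, n_points = 960) {
  pts <- sphere_points(n_points)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rad <- s$radius + probe
  vapply(idx, function(i) {
    ri <- rad[i]
    p <- sweep(pts * ri, 2, xyz[i, ], `+`)
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + rad)^2 & seq_len(nrow(xyz)) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]; dz <- p[, 3] - xyz[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz > rad[j]^2)
      if (!any(exposed)) break
    }
    4 * pi * ri^2 * mean(exposed)
  }, numeric(1))
}

#' Relative accessibility of a backbone amide nitrogen
#'
#' Solvent-accessible surface area (sphere-sampling method, probe 1.4 A,
#' default 960 test points per atom) of the residue's backbone N divided by
#' the summed SASA of all atoms of that residue. Defined as 0 when the whole
#' residue is buried (residue SASA 0).
#'
#' @param s a [read_structure()] model.
#' @param resno residue number.
#' @param probe solvent probe radius, A.
#' @param n_points sphere sample points per atom (>= 960 recommended).
#' @return RA in `[0, 1]`.
#' @export
relative_accessibility <- function(s, resno, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "structure_model"))
  ridx <- which(s$resno == resno)
  if (!length(ridx)) stop("residue ", resno, " not found in structure")
  nidx <- ridx[s$atom_name[ridx] == "N"]
  if (!length(nidx)) {
    warning("residue ", resno, " has no backbone N; skipping")
    return(NA_real_)
  }
  sa <- atom_sasa(s, ridx, probe = probe, n_points = n_points)
  res_sasa <- sum(sa)
  if (res_sasa <= 0) return(0)
  min(1, sa[match(nidx[1L], ridx)] / res_sasa)
}

#' Exteriority index of an atom
#'
#' Normalised depth score in `[0, 1]`: the fraction of quasi-uniform test
#' points on a probe sphere (default radius 4 A) centred on the atom that
#' lie outside the protein's occupied volume (the union of solvent-expanded
#' van der Waals spheres, expansion 1.4 A, which fills interstitial packing
#' gaps). An isolated atom scores 1; an atom deep inside a large body tends
#' to 0. This is a burial index on the same qualitative scale as published
#' atom-depth indices, not a Euclidean depth in Angstrom.
#'
#' @param s a [read_structure()] model.
#' @param atom_idx row index of the atom in `s`.
#' @param r_probe probe-sphere radius, A (must exceed van der Waals contact
#'   distances to sense burial).
#' @param n_points number of test points.
#' @param expand occupancy expansion added to each van der Waals radius, A.
#' @return D in `[0, 1]`.
#' @export
exteriority <- function(s, atom_idx, r_probe = 4, n_points = 960,
                        expand = 1.4) {
  stopifnot(inherits(s, "structure_model"),
            atom_idx >= 1, atom_idx <= nrow(s))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  occ <- s$radius + expand
  ctr <- xyz[atom_idx, ]
  p <- sweep(sphere_points(n_points) * r_probe, 2, ctr, `+`)
  d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  nb <- which(d2 < (r_probe + occ)^2)
  outside <- rep(TRUE, n_points)
  for (j in nb) {
    dx <- p[, 1] - xyz[j, 1]; dy <- p[, 2] - xyz[j, 2]; dz <- p[, 3] - xyz[j, 3]
    outside <- outside & (dx * dx + dy * dy + dz * dz > occ[j]^2)
    if (!any(outside)) break
  }
  mean(outside)
}

#' RAD burial score
#'
#' `RAD = D * RA * 100`: the product of the exteriority index and the
#' relative accessibility of the amide nitrogen, scaled by 100. Small RAD
#' (< 0.1) identifies buried hydrophobic-core reporters whose NMR peaks
#' track the global unfolding transition.
#'
#' @param D exteriority in `[0, 1]`.
#' @param RA relative accessibility in `[0, 1]`.
#' @return RAD in `[0, 100]`, vectorised.
#' @export
compute_rad <- function(D, RA) {
  if (any(D < 0 | D > 1, na.rm = TRUE) || any(RA < 0 | RA > 1, na.rm = TRUE))
    stop("D and RA must lie in [0, 1]")
  D * RA * 100
}

#' RAD records for all amide-bearing residues of a structure
#'
#' @param s a [read_structure()] model.
#' @param resno residues to score (default: all with a backbone N).
#' @inheritParams relative_accessibility
#' @inheritParams exteriority
#' @return a data frame of class `rad_table` with columns `residue_label`,
#'   `resno`, `D`, `RA`, `RAD`.
#' @export
rad_records <- function(s, resno = NULL, probe = 1.4, n_points = 960,
                        r_probe = 4) {
  stopifnot(inherits(s, "structure_model"))
  if (is.null(resno))
    resno <- sort(unique(s$resno[s$atom_name == "N"]))
  rows <- lapply(resno, function(r) {
    nidx <- which(s$resno == r & s$atom_name == "N")
    if (!length(nidx)) {
      warning("residue ", r, " has no backbone N; skipping")
      return(NULL)
    }
    D <- exteriority(s, nidx[1L], r_probe = r_probe, n_points = n_points)
    RA <- relative_accessibility(s, r, probe = probe, n_points = n_points)
    rn <- tolower(s$resid[nidx[1L]])
    lbl <- paste(r, paste0(toupper(substr(rn, 1, 1)), substring(rn, 2)))
    data.frame(residue_label = lbl, resno = r, D = D, RA = RA,
               RAD = compute_rad(D, RA), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rad_table", "data.frame")
  out
}

#' Read a precomputed D/RA (or RAD) table
#'
#' Bypasses structure computation: a TSV with columns `residue_label` and
#' either `D` and `RA` (RAD is recomputed as `D*RA*100`) or a ready-made
#' `RAD` column. This path reproduces published selections exactly when the
#' original burial calculators are not being replicated.
#'
#' @param path TSV file path.
#' @return a `rad_table` data frame.
#' @export
read_rad_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"residue_label" %in% names(df))
    stop("rad table must have a residue_label column")
  if (all(c("D", "RA") %in% names(df))) {
    df$RAD <- compute_rad(df$D, df$RA)
  } else if (!"RAD" %in% names(df)) {
    stop("rad table must have either D and RA columns or a RAD column")
  }
  class(df) <- c("rad_table", "data.frame")
  df
}

#' Select core reporters by RAD threshold
#'
#' Residues whose RAD lies strictly below the threshold, input order
#' preserved; records with undefined RAD are never selected.
#'
#' @param records a `rad_table` (or data frame with `residue_label`, `RAD`).
#' @param threshold selection threshold (default 0.1, the buried-core
#'   criterion; 0.5 marks the exposed-residue exclusion boundary).
#' @return character vector of selected residue labels.
#' @export
select_by_rad <- function(records, threshold = 0.1) {
  stopifnot(is.data.frame(records), "RAD" %in% names(records))
  sel <- !is.na(records$RAD) & records$RAD < threshold
  records$residue_label[sel]
}
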