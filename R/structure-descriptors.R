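# Per-residue structural descriptors: side-chain geometric centers,
# rolling-probe relative solvent accessibility, backbone torsion angles and
# their discrete Ramachandran domains, and inter-residue distances.

#' Compute side-chain geometric centers
#'
#' Sets each residue's side-chain center to the unweighted mean of its heavy
#' side-chain atom coordinates. Glycine, and any residue whose side-chain
#' atoms are not resolved, falls back to the C-alpha position.
#'
#' @param s a [ProteinStructure-class].
#' @return the structure with `scx`, `scy`, `scz` filled in.
#' @export
computeSidechainCenters <- function(s) {
  res <- s@residues
  a <- s@atoms
  akey <- paste(a$chain, a$resno, a$ins)
  rkey <- paste(res$chain, res$resno, res$ins)
  for (i in seq_len(nrow(res))) {
    sel <- akey == rkey[i] & a$sidechain
    if (any(sel)) {
      res$scx[i] <- mean(a$x[sel])
      res$scy[i] <- mean(a$y[sel])
      res$scz[i] <- mean(a$z[sel])
    } else {
      res$scx[i] <- res$CAx[i]
      res$scy[i] <- res$CAy[i]
      res$scz[i] <- res$CAz[i]
    }
  }
  s@residues <- res
  validObject(s)
  s
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# construction), used as test directions by the rolling-probe algorithm.
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atomRadii <- function(elem) {
  r <- .VDW_RADII[elem]
  r[is.na(r)] <- 1.8
  unname(r)
}

#' Compute relative solvent accessibility
#'
#' Rolling-probe (Shrake-Rupley-style) solvent-accessible surface area with
#' a 1.4 Angstrom probe by default: each atom's sphere of radius
#' (vdW + probe) is sampled at `n_sphere_points` quasi-uniform points and a
#' point counts as accessible when it is inside no other atom's expanded
#' sphere. Per-residue absolute areas are normalised by the residue type's
#' reference maximal area and expressed in percent, clipped to [0, 100].
#'
#' @param s a [ProteinStructure-class].
#' @param config configuration list, see [defaultConfig()] (keys
#'   `probe_radius`, `n_sphere_points`, `max_area_table`).
#' @return the structure with the `acc` column filled in.
#' @export
computeAccessibility <- function(s, config = defaultConfig()) {
  a <- s@atoms
  probe <- config$probe_radius
  xyz <- cbind(a$x, a$y, a$z)
  rad <- .atomRadii(a$elem) + probe
  n <- nrow(xyz)
  pts <- .spherePoints(config$n_sphere_points)
  npts <- nrow(pts)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, npts)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj >= rad[j]^2
    }
    area[i] <- sum(free) / npts * 4 * pi * rad[i]^2
  }
  res <- s@residues
  akey <- paste(a$chain, a$resno, a$ins)
  rkey <- paste(res$chain, res$resno, res$ins)
  resArea <- vapply(rkey, function(k) sum(area[akey == k]), numeric(1))
  maxArea <- config$max_area_table[res$aa]
  res$acc <- pmin(100, pmax(0, 100 * resArea / maxArea))
  s@residues <- res
  validObject(s)
  s
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Assign backbone torsion angles and Ramachandran domains
#'
#' Computes phi/psi for every residue whose peptide neighbours are present
#' (consecutive residues are recognised by a C(i-1)-N(i) distance below 2
#' Angstrom) and labels each residue with the first matching (phi, psi)
#' rectangle of the configured partition; residues matching no rectangle get
#' "other", chain termini stay NA.
#'
#' @param s a [ProteinStructure-class].
#' @param config configuration list (key `torsion_domains`).
#' @return the structure with `phi`, `psi` and `tdom` filled in.
#' @export
assignTorsionDomains <- function(s, config = defaultConfig()) {
  res <- s@residues
  n <- nrow(res)
  Nc <- as.matrix(res[, c("Nx", "Ny", "Nz")])
  CA <- as.matrix(res[, c("CAx", "CAy", "CAz")])
  Cc <- as.matrix(res[, c("Cx", "Cy", "Cz")])
  linked <- function(i, j) {   # peptide bond between residue i's C and j's N
    res$chain[i] == res$chain[j] &&
      sqrt(sum((Cc[i, ] - Nc[j, ])^2)) < 2.0
  }
  for (i in seq_len(n)) {
    if (i > 1 && linked(i - 1, i))
      res$phi[i] <- .dihedral(Cc[i - 1, ], Nc[i, ], CA[i, ], Cc[i, ])
    if (i < n && linked(i, i + 1))
      res$psi[i] <- .dihedral(Nc[i, ], CA[i, ], Cc[i, ], Nc[i + 1, ])
  }
  res$tdom <- .torsionDomain(res$phi, res$psi, config$torsion_domains)
  s@residues <- res
  validObject(s)
  s
}

.torsionDomain <- function(phi, psi, domains) {
  out <- rep(NA_character_, length(phi))
  def <- !is.na(phi) & !is.na(psi)
  out[def] <- "other"
  for (k in rev(seq_len(nrow(domains)))) {
    hit <- def & phi >= domains$phiMin[k] & phi < domains$phiMax[k] &
      psi >= domains$psiMin[k] & psi < domains$psiMax[k]
    out[hit] <- domains$name[k]
  }
  out
}

#' Distance between side-chain geometric centers
#'
#' Euclidean distance (Angstrom) between the side-chain centers of two
#' residues of a structure.
#'
#' @param s a [ProteinStructure-class] with centers computed.
#' @param i,j residue row indices.
#' @return distance in Angstrom.
#' @export
residueDistance <- function(s, i, j) {
  res <- s@residues
  if (anyNA(c(res$scx[c(i, j)])))
    stop("side-chain centers not computed; call computeSidechainCenters()")
  sqrt((res$scx[i] - res$scx[j])^2 + (res$scy[i] - res$scy[j])^2 +
         (res$scz[i] - res$scz[j])^2)
}

# Full pairwise side-chain center distance matrix.
.centerDistances <- function(s) {
  m <- as.matrix(s@residues[, c("scx", "scy", "scz")])
  as.matrix(stats::dist(m))
}

#' Compute all structural descriptors
#'
#' Convenience wrapper running [computeSidechainCenters()],
#' [computeAccessibility()] and [assignTorsionDomains()] in order.
#'
#' @param s a [ProteinStructure-class].
#' @param config configuration list.
#' @return the fully annotated structure.
#' @export
computeDescriptors <- function(s, config = defaultConfig()) {
  assignTorsionDomains(
    computeAccessibility(computeSidechainCenters(s), config), config)
}
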