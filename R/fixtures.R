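# Synthetic fixtures: small ideal-geometry PDB-format structures and
# labeled variant tables with a planted stability -> deleteriousness
# signal, so the whole pipeline can be exercised without any downloads.

# Natural-extension-reference-frame placement: position D at `bond` from c,
# with angle b-c-D (degrees) and torsion a-b-c-D (degrees).
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  unit <- function(v) v / sqrt(sum(v^2))
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  bc <- unit(c - b)
  n <- unit(cross(b - a, bc))
  m <- cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Number of side-chain pseudo-atoms per residue type (0 for Gly, up to 4
# for the bulky aromatics), chosen so residue types differ in center and
# occupied volume without any rotamer modeling.
.N_PSEUDO <- c(A = 1, C = 1, S = 1, G = 0, T = 2, V = 2, P = 2, D = 2,
               N = 2, I = 3, L = 3, M = 3, E = 3, Q = 3, K = 3, H = 3,
               R = 4, F = 4, Y = 4, W = 4)

# Backbone geometry (Angstrom / degrees) used by the generator.
.BOND <- c(NCa = 1.458, CaC = 1.525, CN = 1.329, CO = 1.231, CaCb = 1.53)
.ANGLE <- c(NCaC = 111.2, CaCN = 116.2, CNCa = 121.7, CaCO = 120.5,
            NCaCb = 110.5)

.samplePhiPsi <- function(n, geometry) {
  switch(geometry,
    ideal_helix = list(phi = rep(-57, n), psi = rep(-47, n)),
    ideal_strand = list(phi = rep(-120, n), psi = rep(120, n)),
    random_coil = {
      reg <- sample(c("h", "e", "p", "l"), n, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
      list(
        phi = stats::rnorm(n, c(h = -63, e = -120, p = -75, l = 60)[reg],
                           c(h = 8, e = 12, p = 8, l = 8)[reg]),
        psi = stats::rnorm(n, c(h = -43, e = 125, p = 145, l = 40)[reg],
                           c(h = 8, e = 12, p = 8, l = 8)[reg])
      )
    },
    stop("unknown geometry: ", geometry)
  )
}

# Packed strand-helix-strand bundle: segments are built with ideal torsions
# and rigidly stacked side by side, so interface residues are genuinely
# buried. Segment junctions are deliberate chain breaks (no peptide bond),
# which read back as undefined torsions, like real chain breaks.
.buildPacked <- function(aaSeq, gap = 5.2) {
  n <- length(aaSeq)
  len <- diff(round(seq(0, n, length.out = 4)))
  segs <- list()
  start <- 0
  for (i in 1:3) {
    g <- c("ideal_strand", "ideal_helix", "ideal_strand")[i]
    tor <- .samplePhiPsi(len[i], g)
    at <- .buildChain(aaSeq[(start + 1):(start + len[i])], tor$phi, tor$psi)
    at$resno <- at$resno + start
    at$y <- at$y + (i - 1) * gap
    at$z <- at$z + (i %% 2) * 2
    segs[[i]] <- at
    start <- start + len[i]
  }
  do.call(rbind, segs)
}

# Build the atom table of one chain from per-residue torsions and sequence.
.buildChain <- function(aaSeq, phi, psi) {
  n <- length(aaSeq)
  th <- .ANGLE[["NCaC"]] * pi / 180
  N <- matrix(NA_real_, n, 3); CA <- N; Cc <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND[["NCa"]], 0, 0)
  Cc[1, ] <- CA[1, ] + .BOND[["CaC"]] * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], Cc[i - 1, ],
                         .BOND[["CN"]], .ANGLE[["CaCN"]], psi[i - 1])
    CA[i, ] <- .placeAtom(CA[i - 1, ], Cc[i - 1, ], N[i, ],
                          .BOND[["NCa"]], .ANGLE[["CNCa"]], 180)
    Cc[i, ] <- .placeAtom(Cc[i - 1, ], N[i, ], CA[i, ],
                          .BOND[["CaC"]], .ANGLE[["NCaC"]], phi[i])
  }
  for (i in seq_len(n))
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], Cc[i, ],
                         .BOND[["CO"]], .ANGLE[["CaCO"]], psi[i] + 180)
  rows <- list()
  scNames <- c("CB", "CG", "CD", "CE")
  for (i in seq_len(n)) {
    aa <- aaSeq[i]
    res3 <- AA3[match(aa, AA1)]
    add <- function(name, xyz, side) {
      data.frame(chain = "A", resno = i, ins = "", resid = res3, aa = aa,
                 elety = name, elem = substr(name, 1, 1), sidechain = side,
                 x = xyz[1], y = xyz[2], z = xyz[3],
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- add("N", N[i, ], FALSE)
    rows[[length(rows) + 1]] <- add("CA", CA[i, ], FALSE)
    rows[[length(rows) + 1]] <- add("C", Cc[i, ], FALSE)
    rows[[length(rows) + 1]] <- add("O", O[i, ], FALSE)
    np <- .N_PSEUDO[[aa]]
    if (np > 0) {
      cb <- .placeAtom(Cc[i, ], N[i, ], CA[i, ],
                       .BOND[["CaCb"]], .ANGLE[["NCaCb"]], -122.6)
      rows[[length(rows) + 1]] <- add("CB", cb, TRUE)
      if (np > 1) {
        u <- cb - CA[i, ]; u <- u / sqrt(sum(u^2))
        v <- N[i, ] - CA[i, ]
        perp <- v - sum(v * u) * u
        perp <- perp / sqrt(sum(perp^2))
        for (k in 2:np) {
          off <- cb + (k - 1) * 1.45 * u +
            0.45 * (-1)^k * perp
          rows[[length(rows) + 1]] <- add(scNames[k], off, TRUE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic PDB-format structures
#'
#' Builds ideal-geometry backbones (helix phi = -57 / psi = -47, strand
#' phi = -120 / psi = 120, seeded random-coil torsions, or a packed
#' strand-helix-strand bundle for "mixed", whose interface residues are
#' genuinely buried) with one to four side-chain pseudo-atoms per residue
#' type, and renders them as parseable PDB-format text. Deterministic given
#' seed.
#'
#' @param nStructures number of structures.
#' @param chainLength residues per chain (at least 5).
#' @param geometry "ideal_helix", "ideal_strand", "random_coil" or "mixed".
#' @param aaComposition optional probability vector over [AA1] (sums to 1);
#'   default uniform.
#' @param seed integer seed.
#' @param resolution nominal resolution written to the header.
#' @return named list of character vectors (PDB lines), names "synth001"...
#' @export
makeStructures <- function(nStructures = 1L, chainLength = 30L,
                           geometry = c("mixed", "ideal_helix",
                                        "ideal_strand", "random_coil"),
                           aaComposition = NULL, seed = 1L,
                           resolution = 1.8) {
  geometry <- match.arg(geometry)
  if (chainLength < 5) stop("chainLength must be at least 5")
  if (is.null(aaComposition)) aaComposition <- rep(1 / 20, 20)
  if (abs(sum(aaComposition) - 1) > 1e-8)
    stop("aaComposition must sum to 1")
  oldSeed <- globalenv()$.Random.seed
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()), add = TRUE)
  set.seed(seed)
  out <- list()
  for (m in seq_len(nStructures)) {
    aaSeq <- sample(AA1, chainLength, replace = TRUE, prob = aaComposition)
    atoms <- if (geometry == "mixed") {
      .buildPacked(aaSeq)
    } else {
      tor <- .samplePhiPsi(chainLength, geometry)
      .buildChain(aaSeq, tor$phi, tor$psi)
    }
    id <- sprintf("synth%03d", m)
    name <- ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety),
                   atoms$elety)
    lines <- c(
      sprintf("HEADER    SYNTHETIC FIXTURE                       01-JAN-00   %s",
              toupper(substr(id, 1, 4))),
      "EXPDTA    X-RAY DIFFRACTION",
      sprintf("REMARK   2 RESOLUTION. %5.2f ANGSTROMS.", resolution),
      sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              seq_len(nrow(atoms)), name, atoms$resid, atoms$chain,
              atoms$resno, atoms$x, atoms$y, atoms$z, 1, 0, atoms$elem),
      "TER", "END")
    out[[id]] <- lines
  }
  out
}

#' Generate a labeled variant table with a planted stability signal
#'
#' Samples random single-site substitutions on the given annotated
#' structures, computes their true features through the potentials module,
#' and assigns labels from a planted score that mirrors the qualitative
#' structure of real variant sets: deleterious enrichment at both energy
#' extremes (|ddW|), in buried sites (A < 20 percent), and for
#' volume-increasing substitutions outside the surface. The planted score
#'
#'   raw = wDdw * mean_i |ddW_i| * (1 + wBuried * 1[A < 20])
#'         + wVolume * (dVp / 100) * 1[A <= 60]
#'
#' is centred at its (1 - deleteriousFraction) quantile, scaled by its
#' standard deviation, and passed through a logistic of steepness
#' `signalSteepness` to give the label probability; labels are then flipped
#' with probability `labelNoise`. A pseudo-evolutionary score
#' `pro` is drawn as N(-4, 1.5^2) for (pre-noise) deleterious and
#' N(0, 1.5^2) for neutral variants (point-biserial correlation about
#' -0.8); it is generated, not computed, since real conservation scoring is
#' external to the package.
#'
#' @param structures named list of annotated [ProteinStructure-class].
#' @param tables named list of [PotentialTable-class].
#' @param nVariants number of variants.
#' @param deleteriousFraction target deleterious fraction (0.75, the
#'   composition of curated disease-variant sets).
#' @param labelNoise label flip probability.
#' @param weights named numeric (ddw, buried, volume) planted weights.
#' @param signalSteepness logistic slope on the standardized planted score;
#'   large values approach a deterministic threshold rule.
#' @param config configuration list.
#' @param seed integer seed.
#' @return data.frame with columns pdb_id, protein, chain, resno, ins, wt,
#'   mut, label, isDel, pro, plantedScore, plus the feature columns of
#'   [featurizeVariants()].
#' @export
makeVariantTable <- function(structures, tables, nVariants = 500L,
                             deleteriousFraction = 0.75, labelNoise = 0.05,
                             weights = c(ddw = 2, buried = 1, volume = 1),
                             signalSteepness = 50,
                             config = defaultConfig(), seed = 1L) {
  if (deleteriousFraction <= 0 || deleteriousFraction >= 1)
    stop("deleteriousFraction must be in (0, 1)")
  oldSeed <- globalenv()$.Random.seed
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (attempt in 1:5) {
    si <- sample(length(structures), nVariants, replace = TRUE)
    variants <- do.call(rbind, lapply(seq_len(nVariants), function(v) {
      s <- structures[[si[v]]]
      res <- s@residues
      i <- sample(nrow(res), 1)
      data.frame(pdb_id = names(structures)[si[v]],
                 protein = names(structures)[si[v]],
                 chain = res$chain[i], resno = res$resno[i],
                 ins = res$ins[i], wt = res$aa[i],
                 mut = sample(setdiff(AA1, res$aa[i]), 1),
                 stringsAsFactors = FALSE)
    }))
    feats <- featurizeVariants(structures, variants, tables, config)
    # plant the energetic signal on the potential subset the sign-split
    # index consumes, so recovery measures training, not subset mismatch;
    # components are standardized so the weights are comparable, and burial
    # acts multiplicatively (core sites amplify energetic impact)
    nm <- names(config$potentials)[config$ann_subset]
    ddW <- as.matrix(feats[, paste0("ddW.", nm), drop = FALSE])
    u <- rowMeans(abs(ddW))
    u <- u / stats::sd(u)
    v <- feats$dVp / stats::sd(feats$dVp)
    raw <- weights[["ddw"]] * u * (1 + weights[["buried"]] * (feats$A < 20)) +
      weights[["volume"]] * v * (feats$A <= 60)
    thr <- stats::quantile(raw, 1 - deleteriousFraction)
    z <- (raw - thr) / stats::sd(raw)
    clean <- stats::runif(nVariants) < stats::plogis(signalSteepness * z)
    flip <- stats::runif(nVariants) < labelNoise
    isDel <- xor(clean, flip)
    if (length(unique(isDel)) == 2) {
      pro <- stats::rnorm(nVariants, mean = ifelse(clean, -4, 0), sd = 1.5)
      feats$label <- ifelse(isDel, "deleterious", "neutral")
      feats$isDel <- isDel
      feats$pro <- pro
      feats$plantedScore <- raw
      return(feats)
    }
  }
  stop("could not realize both classes; check the planted-signal spec")
}
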