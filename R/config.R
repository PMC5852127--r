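# Constants and run configuration.

#' Standard amino-acid alphabets
#'
#' One- and three-letter codes of the 20 standard amino acids, in a fixed
#' order used for all count-array dimensions.
#' @export
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

#' @rdname AA1
#' @export
AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
         "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "TRP",
         "TYR", "VAL")

# van der Waals radii by element (Angstrom), used by the rolling-probe
# accessibility computation. Unknown elements fall back to 1.8.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90)

# Theoretical maximal accessible surface areas (Gly-X-Gly, A^2),
# Tien et al. 2013, used to normalise absolute SASA to percent.
.MAX_AREA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
               Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
               L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
               S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# Amino-acid side-chain volumes (A^3), Zamyatnin 1972. Mutant-minus-wild-type
# differences define the dV+/dV- Heaviside split: mutating a smaller into a
# larger residue gives positive dV.
.AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                L = 166.7, K = 168.6, M = 162.9, F = 189.9,
                P = 112.7, S = 89.0, T = 116.1, W = 227.8, Y = 193.6,
                V = 140.0)[AA1]

# Default Ramachandran partition: rectangles in the (phi, psi) plane checked
# in order, first match wins; anything else is "other". Termini (undefined
# phi or psi) get NA.
.TORSION_DOMAINS <- data.frame(
  name   = c("alpha", "beta", "ppii", "lalpha", "bridge"),
  phiMin = c(-160, -180,  -90,   20, -180),
  phiMax = c( -20,  -90,  -20,  160,  -20),
  psiMin = c(-120,   90,   90,  -60,   50),
  psiMax = c(  50,  180,  180,   90,   90),
  stringsAsFactors = FALSE
)

.TORSION_LEVELS <- c(.TORSION_DOMAINS$name, "other")

#' Default potential set
#'
#' The 13 descriptor combinations used by default. The original method's
#' supplementary list of 13 potentials is not part of the package inputs;
#' this set is a declared stand-in built from the three descriptor classes
#' (distance, accessibility, torsion, and their mixtures) and is entirely
#' configuration-driven: any list of codes over the alphabet {s, a, t, d}
#' can be substituted.
#'
#' Each entry has `code` (descriptor letters; letters before `d` attach to
#' the first residue of a pair, letters after `d` to the second; for
#' sequence-window codes the first two letters attach to residue i and the
#' third to residue i+offset), `offset` (sequence-window offset) and
#' `minSeqSep` (minimum chain separation for distance pairs).
#'
#' @return named list of descriptor specifications.
#' @export
defaultPotentials <- function() {
  d <- function(code) list(code = code, offset = NA_integer_, minSeqSep = 7L)
  w <- function(code, k) list(code = code, offset = as.integer(k),
                              minSeqSep = NA_integer_)
  s <- function(code) list(code = code, offset = NA_integer_,
                           minSeqSep = NA_integer_)
  list(
    sd   = d("sd"),
    sds  = d("sds"),
    sda  = d("sda"),
    sdt  = d("sdt"),
    sa   = s("sa"),
    st   = s("st"),
    sta  = s("sta"),
    sas  = w("sas", 1),
    sts  = w("sts", 1),
    saa  = w("saa", 1),
    stt  = w("stt", 1),
    sas2 = w("sas", 2),
    sts2 = w("sts", 2)
  )
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline: accessibility backend settings,
#' reference tables, descriptor binning, the potential list and the model
#' subset sizes. Every value can be overridden via [loadConfig()].
#'
#' @return named list of configuration values:
#' \describe{
#'   \item{probe_radius}{rolling-probe radius, Angstrom (1.4).}
#'   \item{n_sphere_points}{sample points per atom for the rolling-probe
#'     accessibility algorithm.}
#'   \item{max_area_table}{reference maximal areas per residue type, A^2.}
#'   \item{volume_table}{residue volumes, A^3.}
#'   \item{acc_bin_edges}{accessibility bin edges, percent (7 bins).}
#'   \item{dist_bin_edges}{side-chain center distance bin edges, Angstrom
#'     (0.2 A bins over [3, 8]); pairs outside are ignored.}
#'   \item{torsion_domains}{data.frame of named (phi, psi) rectangles.}
#'   \item{kT}{thermal energy, kcal/mol (0.593, T = 298 K).}
#'   \item{sigma}{additive pseudocount for count smoothing.}
#'   \item{cap_energy}{energy (kcal/mol) for tuples unobserved at sigma=0.}
#'   \item{potentials}{named list of descriptor specifications.}
#'   \item{dtm_subset}{indices of potentials entering the dTm form (9).}
#'   \item{ann_subset}{indices entering the sign-split index (11).}
#'   \item{pnn_subset}{indices entering the PNN feature vector (6).}
#'   \item{dtm_size_scaling}{(a, b) of the 1/(a Nr + b) prefactor.}
#' }
#' @export
defaultConfig <- function() {
  list(
    probe_radius = 1.4,
    n_sphere_points = 92L,
    max_area_table = .MAX_AREA,
    volume_table = .AA_VOLUME,
    acc_bin_edges = c(0, 5, 15, 30, 45, 60, 80, 100),
    dist_bin_edges = seq(3, 8, by = 0.2),
    torsion_domains = .TORSION_DOMAINS,
    kT = 0.593,
    sigma = 1,
    cap_energy = 2,
    potentials = defaultPotentials(),
    dtm_subset = 1:9,
    ann_subset = 1:11,
    pnn_subset = 1:6,
    dtm_size_scaling = c(a = 0, b = 1)
  )
}

#' Load a configuration file over the defaults
#'
#' Reads a YAML configuration and merges it over [defaultConfig()].
#' Unknown keys are rejected so that typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return configuration list.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    v <- user[[k]]
    if (k == "torsion_domains") v <- as.data.frame(v)
    if (k %in% c("max_area_table", "volume_table")) v <- unlist(v)
    cfg[[k]] <- v
  }
  cfg
}

# Ordered level sets for each descriptor letter under a configuration.
.descriptorLevels <- function(config) {
  accLabs <- .binLabels(config$acc_bin_edges)
  distLabs <- .binLabels(config$dist_bin_edges)
  tdoms <- c(config$torsion_domains$name, "other")
  list(s = AA1, a = accLabs, t = tdoms, d = distLabs)
}

.binLabels <- function(edges) {
  paste0("[", utils::head(edges, -1), ",", utils::tail(edges, -1), ")")
}

# Bin a numeric vector on half-open bins [e1,e2),... ; values outside get NA;
# the top edge is inclusive (accessibility 100 falls in the last bin).
.binIndex <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[!is.na(x) & (x < edges[1] | x > edges[length(edges)])] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}
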