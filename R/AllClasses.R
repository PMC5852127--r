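#' @import methods
NULL

#' Parsed protein structure
#'
#' Holds one parsed PDB-format structure: the heavy-atom table and a
#' per-residue table with backbone coordinates, side-chain geometric centers,
#' relative solvent accessibility (percent), backbone torsion angles and the
#' discrete torsion-angle domain. Residues are identified by author chain id,
#' residue number and insertion code.
#'
#' @slot pdbId identifier of the structure (file stem if unknown).
#' @slot atoms data.frame of heavy atoms (chain, resno, ins, resid, aa,
#'   elety, elem, sidechain, x, y, z).
#' @slot residues data.frame with one row per standard amino-acid residue:
#'   chain, resno, ins, aa (one-letter), backbone coordinates
#'   (Nx..Nz, CAx..CAz, Cx..Cz), side-chain center (scx, scy, scz),
#'   rel. accessibility acc in [0,100], phi, psi (degrees), torsion domain
#'   tdom. Descriptor columns are NA until computed.
#' @slot resolution crystallographic resolution in Angstrom, NA if unknown.
#' @slot experimentalMethod e.g. "X-RAY DIFFRACTION", NA if unknown.
#' @export
setClass("ProteinStructure",
  slots = c(
    pdbId = "character",
    atoms = "data.frame",
    residues = "data.frame",
    resolution = "numeric",
    experimentalMethod = "character"
  )
)

setValidity("ProteinStructure", function(object) {
  res <- object@residues
  msgs <- character()
  if (nrow(res)) {
    key <- paste(res$chain, res$resno, res$ins)
    if (anyDuplicated(key))
      msgs <- c(msgs, "residues must be unique by (chain, resno, ins)")
    acc <- res$acc
    if (any(!is.na(acc) & (acc < 0 | acc > 100)))
      msgs <- c(msgs, "rel. accessibility must lie in [0, 100]")
    if (!all(res$aa %in% AA1))
      msgs <- c(msgs, "residue table contains non-standard amino-acid codes")
  }
  if (length(msgs)) msgs else TRUE
})

#' Occurrence counts for descriptor combinations
#'
#' Joint occurrence counts of sequence/structure element tuples accumulated
#' over a reference set of structures, one multi-dimensional count array per
#' configured potential. Marginals are derived from the joint arrays on
#' demand, so marginal consistency holds by construction.
#'
#' @slot counts named list of count arrays (dimnames = element levels).
#' @slot specs named list of descriptor specifications (see
#'   [defaultPotentials()]).
#' @slot nStructures number of structures counted.
#' @export
setClass("CountsStore",
  slots = c(counts = "list", specs = "list", nStructures = "integer")
)

setValidity("CountsStore", function(object) {
  if (!identical(names(object@counts), names(object@specs)))
    return("counts and specs must share names")
  if (any(vapply(object@counts, function(a) any(a < 0), logical(1))))
    return("counts must be non-negative")
  TRUE
})

#' Mean-force potential table
#'
#' Pseudo-energies (kcal/mol) for every element tuple of one descriptor
#' combination, derived from smoothed occurrence frequencies by the
#' inclusion-exclusion inverse-Boltzmann formula. Positive energies mark
#' unfavourable sequence-structure associations.
#'
#' @slot name short identifier of the potential (e.g. "sd", "sta").
#' @slot spec descriptor specification list (code, offset, minSeqSep).
#' @slot energy numeric array of pseudo-energies with element-level dimnames.
#' @slot kT thermal energy used, kcal/mol.
#' @slot sigma additive pseudocount used for smoothing.
#' @slot capEnergy energy assigned to tuples unobserved at sigma = 0.
#' @export
setClass("PotentialTable",
  slots = c(
    name = "character",
    spec = "list",
    energy = "array",
    kT = "numeric",
    sigma = "numeric",
    capEnergy = "numeric"
  )
)

setValidity("PotentialTable", function(object) {
  if (!all(is.finite(object@energy)))
    return("every energy must be finite (unobserved tuples are capped)")
  TRUE
})

#' Sigmoid accessibility-gated linear model
#'
#' The shared parametric form of the stability predictors: a weighted sum of
#' mutation features in which each weight is a sigmoid function of the
#' mutated residue's solvent accessibility A,
#' alpha(A) = omega / (1 + exp(-nu (A - xi))) + phi.
#'
#' @slot gates 4 x k matrix (rows omega, nu, xi, phi), one column per term.
#' @slot terms character vector naming each term ("ddW.<name>", "dVp",
#'   "dVm", "intercept").
#' @slot kind "ddg" (free-energy form) or "dtm" (melting-temperature form
#'   with 1/(a Nr + b) prefactor on the potential terms only).
#' @slot sizeScaling numeric (a, b) used by the "dtm" kind.
#' @slot trainMse final training mean squared error (NA if untrained).
#' @export
setClass("GatedLinearModel",
  slots = c(
    gates = "matrix",
    terms = "character",
    kind = "character",
    sizeScaling = "numeric",
    trainMse = "numeric"
  )
)

setValidity("GatedLinearModel", function(object) {
  if (!identical(rownames(object@gates), c("omega", "nu", "xi", "phi")))
    return("gate rows must be omega, nu, xi, phi")
  if (ncol(object@gates) != length(object@terms))
    return("number of gates must match number of terms")
  if (!object@kind %in% c("ddg", "dtm"))
    return("kind must be 'ddg' or 'dtm'")
  TRUE
})

#' Sign-split gated pathogenicity index model
#'
#' Gated linear index over the positive and negative parts of the potential
#' terms plus the two volume terms; no intercept. Large index values can
#' arise from strongly stabilizing or strongly destabilizing substitutions.
#'
#' @slot gates 4 x (2m + 2) matrix of sigmoid gate parameters: m gates for
#'   the positive parts, m for the negative parts, then dV+ and dV-.
#' @slot subset integer indices of the potentials entering the index.
#' @slot potentialNames names of the selected potentials.
#' @slot threshold classification threshold psi (index units).
#' @slot trainMse final training mean squared error.
#' @export
setClass("AnnModel",
  slots = c(
    gates = "matrix",
    subset = "integer",
    potentialNames = "character",
    threshold = "numeric",
    trainMse = "numeric"
  )
)

setValidity("AnnModel", function(object) {
  m <- length(object@subset)
  if (ncol(object@gates) != 2 * m + 2)
    return("gate count must be 2 * length(subset) + 2 (no intercept)")
  TRUE
})

#' Probabilistic neural network classifier
#'
#' Kernel-density Bayes classifier: one diagonal-covariance Gaussian kernel
#' per training sample, class densities are class-size-normalised kernel
#' sums weighted by eta1 (deleterious) and eta2 (neutral); a variant is
#' called deleterious when the deleterious density exceeds the neutral one.
#'
#' @slot X training feature matrix (n x p).
#' @slot isDel logical label vector (TRUE = deleterious).
#' @slot sigma p positive per-feature bandwidths (diagonal of Sigma^(1/2)).
#' @slot eta positive class weights (eta1 deleterious, eta2 neutral).
#' @slot featureNames column names of X.
#' @slot looBacc leave-one-out balanced accuracy reached in training.
#' @export
setClass("PnnModel",
  slots = c(
    X = "matrix",
    isDel = "logical",
    sigma = "numeric",
    eta = "numeric",
    featureNames = "character",
    looBacc = "numeric"
  )
)

setValidity("PnnModel", function(object) {
  if (length(object@sigma) != ncol(object@X))
    return("one bandwidth per feature required")
  if (any(object@sigma <= 0) || any(object@eta <= 0))
    return("bandwidths and class weights must be positive")
  if (length(object@isDel) != nrow(object@X))
    return("one label per training sample required")
  TRUE
})

#' Linear meta-combiner of stability index and evolutionary score
#'
#' Affine combination J = gamma1 + gamma2 I + gamma3 PRO of the sign-split
#' stability index I and an external evolutionary conservation score, with a
#' balanced-accuracy-optimal classification threshold and high-confidence
#' bands J >= jD (deleterious) and J <= jN (neutral).
#'
#' @slot gamma numeric length-3 coefficient vector (gamma1..gamma3).
#' @slot threshold classification threshold in J units.
#' @slot jD high-confidence deleterious band edge (default 0.9).
#' @slot jN high-confidence neutral band edge (default 0.5).
#' @slot trainBacc training balanced accuracy.
#' @export
setClass("CombinerModel",
  slots = c(
    gamma = "numeric",
    threshold = "numeric",
    jD = "numeric",
    jN = "numeric",
    trainBacc = "numeric"
  )
)

setValidity("CombinerModel", function(object) {
  if (length(object@gamma) != 3) return("gamma must have length 3")
  if (object@jN > object@jD) return("jN must not exceed jD")
  TRUE
})

#' Cross-validation evaluation report
#'
#' Per-fold and averaged confusion-matrix metrics for a classifier evaluated
#' in k-fold cross-validation, with the threshold selected on training folds
#' only, plus pooled and fold-averaged AUROC.
#'
#' @slot perFold data.frame of per-fold metrics (sensitivity, specificity,
#'   ppv, npv, bacc, threshold, auroc, n).
#' @slot summary named numeric vector of fold-averaged metrics.
#' @slot aurocPooled AUROC over pooled held-out scores.
#' @slot folds integer fold assignment of each variant.
#' @slot level "mutation" or "protein".
#' @export
setClass("EvalReport",
  slots = c(
    perFold = "data.frame",
    summary = "numeric",
    aurocPooled = "numeric",
    folds = "integer",
    level = "character"
  )
)
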