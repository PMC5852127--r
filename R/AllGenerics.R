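#' Accessors for package classes
#'
#' Accessor generics for the core S4 classes: the per-residue table, residue
#' count and chain ids of a [ProteinStructure-class], its accessibility and
#' torsion-domain vectors, and the energy array of a
#' [PotentialTable-class].
#'
#' @param x object.
#' @return `residues`: data.frame; `nResidues`: integer; `chainIds`:
#'   character vector; `accessibility`, `torsionDomains`: per-residue
#'   vectors; `energyTable`: numeric array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("accessibility", function(x) standardGeneric("accessibility"))

#' @rdname accessors
#' @export
setGeneric("torsionDomains", function(x) standardGeneric("torsionDomains"))

#' @rdname accessors
#' @export
setGeneric("energyTable", function(x) standardGeneric("energyTable"))

#' @rdname accessors
#' @export
setMethod("residues", "ProteinStructure", function(x) x@residues)

#' @rdname accessors
#' @export
setMethod("nResidues", "ProteinStructure", function(x) nrow(x@residues))

#' @rdname accessors
#' @export
setMethod("chainIds", "ProteinStructure",
          function(x) unique(x@residues$chain))

#' @rdname accessors
#' @export
setMethod("accessibility", "ProteinStructure", function(x) x@residues$acc)

#' @rdname accessors
#' @export
setMethod("torsionDomains", "ProteinStructure", function(x) x@residues$tdom)

#' @rdname accessors
#' @export
setMethod("energyTable", "PotentialTable", function(x) x@energy)
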