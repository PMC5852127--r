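# show() methods for the S4 classes.

setMethod("show", "ProteinStructure", function(object) {
  res <- object@residues
  cat("ProteinStructure", object@pdbId, "\n")
  cat(" ", nrow(res), "residues in",
      length(unique(res$chain)), "chain(s);",
      nrow(object@atoms), "heavy atoms\n")
  if (!is.na(object@resolution))
    cat("  resolution:", object@resolution, "A;",
        object@experimentalMethod, "\n")
  done <- c(
    if (!all(is.na(res$scx))) "side-chain centers",
    if (!all(is.na(res$acc))) "accessibility",
    if (!all(is.na(res$tdom))) "torsion domains")
  cat("  descriptors:",
      if (length(done)) paste(done, collapse = ", ") else "none", "\n")
})

setMethod("show", "CountsStore", function(object) {
  cat("CountsStore:", length(object@counts), "potentials over",
      object@nStructures, "structure(s)\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-6s N = %g\n", nm, sum(object@counts[[nm]])))
})

setMethod("show", "PotentialTable", function(object) {
  cat("PotentialTable", object@name,
      sprintf("(code %s, kT = %g kcal/mol, sigma = %g)\n",
              object@spec$code, object@kT, object@sigma))
  cat("  ", paste(dim(object@energy), collapse = " x "),
      "element tuples; energy range",
      sprintf("[%.3f, %.3f] kcal/mol\n",
              min(object@energy), max(object@energy)))
})

setMethod("show", "GatedLinearModel", function(object) {
  cat("GatedLinearModel (", object@kind, "form ),",
      ncol(object@gates), "sigmoid gates\n")
  cat("  training MSE:", format(object@trainMse, digits = 4), "\n")
})

setMethod("show", "AnnModel", function(object) {
  cat("Sign-split gated index model:",
      length(object@subset), "potentials x (+/-) + dV terms,",
      ncol(object@gates), "gates\n")
  cat("  threshold psi =", format(object@threshold, digits = 4),
      "; training MSE =", format(object@trainMse, digits = 4), "\n")
})

setMethod("show", "PnnModel", function(object) {
  cat("PNN classifier:", nrow(object@X), "training kernels,",
      ncol(object@X), "features\n")
  cat("  eta =", paste(format(object@eta, digits = 3), collapse = " / "),
      "; LOO BACC =", format(object@looBacc, digits = 4), "\n")
})

setMethod("show", "CombinerModel", function(object) {
  cat("Combiner: J = ",
      sprintf("%.4g + %.4g I + %.4g PRO", object@gamma[1],
              object@gamma[2], object@gamma[3]), "\n")
  cat("  threshold =", format(object@threshold, digits = 4),
      "; bands: J >=", object@jD, "(deleterious), J <=", object@jN,
      "(neutral)\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:", max(object@folds), "-fold CV at the", object@level,
      "level\n")
  s <- object@summary
  cat(sprintf("  Sens %.3f  Spec %.3f  PPV %.3f  NPV %.3f  BACC %.3f  AUROC %.3f (pooled %.3f)\n",
              s["sensitivity"], s["specificity"], s["ppv"], s["npv"],
              s["bacc"], s["auroc"], object@aurocPooled))
})
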