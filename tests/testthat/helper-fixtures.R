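# Shared fixtures, built once per test run.

.world <- new.env(parent = emptyenv())

# Small annotated structure set + derived potential tables.
tinyWorld <- function() {
  if (!is.null(.world$tabs)) return(as.list(.world))
  cfg <- defaultConfig()
  docs <- makeStructures(4, 40, "mixed", seed = 101)
  structs <- lapply(names(docs), function(id)
    computeDescriptors(readStructure(docs[[id]], pdbId = id), cfg))
  names(structs) <- names(docs)
  .world$cfg <- cfg
  .world$structs <- structs
  .world$tabs <- derivePotentials(structs, cfg)
  as.list(.world)
}

# A synthetic feature table (no structures involved): random ddW values for
# the 13 configured potentials plus volume terms and accessibility.
randomFeatures <- function(n, seed = 1, config = defaultConfig()) {
  set.seed(seed)
  nm <- names(config$potentials)
  ddW <- matrix(rnorm(n * length(nm), sd = 0.5), n,
                dimnames = list(NULL, paste0("ddW.", nm)))
  dV <- rnorm(n, sd = 60)
  data.frame(ddW, dVp = pmax(dV, 0), dVm = pmax(-dV, 0),
             A = runif(n, 0, 100), check.names = FALSE)
}

# Minimal PDB text for hand-built residues: `residues` is a list of lists
# with fields resno, resid, atoms = list(name = c(x, y, z)).
handPdb <- function(residues, chain = "A") {
  k <- 0
  lines <- unlist(lapply(residues, function(r) {
    vapply(names(r$atoms), function(an) {
      k <<- k + 1
      xyz <- r$atoms[[an]]
      nm <- if (nchar(an) < 4) paste0(" ", an) else an
      sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              k, nm, r$resid, chain, r$resno, xyz[1], xyz[2], xyz[3],
              1, 0, substr(an, 1, 1))
    }, character(1))
  }))
  c(lines, "TER", "END")
}

# Direct evaluation of the printed two- and three-element potential forms
# from a smoothed joint count array (independent of the package's
# inclusion-exclusion implementation).
directPairPotential <- function(joint, kT) {
  N <- sum(joint)
  Pj <- joint / N
  Ps <- rowSums(joint) / N
  Pc <- colSums(joint) / N
  -kT * log(Pj / outer(Ps, Pc))
}

directTriplePotential <- function(joint, kT) {
  N <- sum(joint)
  P123 <- joint / N
  P1 <- apply(joint, 1, sum) / N
  P2 <- apply(joint, 2, sum) / N
  P3 <- apply(joint, 3, sum) / N
  P12 <- apply(joint, c(1, 2), sum) / N
  P13 <- apply(joint, c(1, 3), sum) / N
  P23 <- apply(joint, c(2, 3), sum) / N
  out <- array(NA_real_, dim(joint))
  for (i in seq_len(dim(joint)[1]))
    for (j in seq_len(dim(joint)[2]))
      for (l in seq_len(dim(joint)[3]))
        out[i, j, l] <- -kT * log(
          P123[i, j, l] * P1[i] * P2[j] * P3[l] /
            (P12[i, j] * P13[i, l] * P23[j, l]))
  out
}

# CountsStore wrapper around an arbitrary count array.
storeFromArray <- function(counts, code) {
  dn <- lapply(dim(counts), function(d) paste0("l", seq_len(d)))
  dimnames(counts) <- dn
  new("CountsStore", counts = list(x = counts),
      specs = list(x = list(code = code, offset = NA_integer_,
                            minSeqSep = NA_integer_)),
      nStructures = 1L)
}

# Brute-force threshold scan over every candidate (naive double loop).
bruteThreshold <- function(scores, isDel, direction = "higher") {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    del <- if (direction == "higher") scores > th else scores < th
    b <- bacc(sum(del & isDel), sum(!del & isDel),
              sum(!del & !isDel), sum(del & !isDel))
    if (is.null(best) || b > best$bacc ||
        (b == best$bacc && th < best$threshold))
      best <- list(threshold = th, bacc = b)
  }
  best
}

# High-precision linear-domain PNN oracle (naive loops, no log tricks).
brutePnn <- function(X, isDel, sigma, eta, query) {
  p <- ncol(X)
  norm <- (2 * pi)^(-p / 2) / prod(sigma)
  t(apply(query, 1, function(q) {
    kern <- vapply(seq_len(nrow(X)), function(j)
      norm * exp(-0.5 * sum(((q - X[j, ]) / sigma)^2)), numeric(1))
    c(PD = eta[1] / sum(isDel) * sum(kern[isDel]),
      PN = eta[2] / sum(!isDel) * sum(kern[!isDel]))
  }))
}
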