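# Knowledge-based mean-force potentials over generic descriptor
# combinations. A descriptor code is a 2-3 letter word over
# {s = amino-acid type, a = accessibility bin, t = torsion domain,
#  d = side-chain center distance bin}; each letter is one element of the
# inverse-Boltzmann inclusion-exclusion formula
#   dW(E) = -kT * sum over nonempty subsets S of E of (-1)^(|E|-|S|) log P(S),
# which reduces to the classical two-element form
#   dW(s,c) = -kT log( P(s,c) / (P(s) P(c)) )
# and, for three elements, to
#   dW(s1,s2,c) = -kT log( P(s1,s2,c) P(s1) P(s2) P(c)
#                          / (P(s1,c) P(s2,c) P(s1,s2)) ).

# Precomputed per-structure descriptor context: residue-level level indices
# and the pairwise distance-bin / chain-separation matrices.
.descriptorContext <- function(s, config) {
  lv <- .descriptorLevels(config)
  res <- s@residues
  n <- nrow(res)
  if (any(is.na(res$scx)) || all(is.na(res$acc)) || all(is.na(res$tdom)))
    stop("structure descriptors not computed; call computeDescriptors()")
  D <- .centerDistances(s)
  dBin <- matrix(.binIndex(as.vector(D), config$dist_bin_edges), n, n)
  diag(dBin) <- NA_integer_
  pos <- stats::ave(seq_len(n), res$chain, FUN = seq_along)
  sameChain <- outer(res$chain, res$chain, "==")
  sep <- abs(outer(pos, pos, "-"))
  sep[!sameChain] <- Inf
  list(
    n = n,
    ai = match(res$aa, AA1),
    bi = .binIndex(res$acc, config$acc_bin_edges),
    ti = match(res$tdom, lv$t),
    dBin = dBin,
    sep = sep,
    sameChain = sameChain,
    levels = lv
  )
}

# Level-index matrix of every contribution of one descriptor spec in a
# structure context. Each row is one element tuple; rows containing NA
# (undefined descriptor, e.g. terminal torsion) are dropped. With `site`,
# only contributions involving that residue row are returned; `aaIdx`
# substitutes the amino-acid level at the site.
.contribIndex <- function(ctx, spec, site = NULL, aaIdx = NULL) {
  letters <- strsplit(spec$code, "")[[1]]
  resVec <- function(l) switch(l, s = ctx$ai, a = ctx$bi, t = ctx$ti)
  n <- ctx$n

  if ("d" %in% letters) {
    ok <- which(!is.na(ctx$dBin) & ctx$sep >= spec$minSeqSep, arr.ind = TRUE)
    i <- ok[, 1]; j <- ok[, 2]          # ordered pairs, both directions
    if (!is.null(site)) {
      keep <- i == site | j == site
      i <- i[keep]; j <- j[keep]
    }
    dpos <- match("d", letters)
    cols <- lapply(seq_along(letters), function(k) {
      if (k == dpos) return(ctx$dBin[cbind(i, j)])
      v <- resVec(letters[k])
      who <- if (k < dpos) i else j
      out <- v[who]
      if (!is.null(aaIdx) && letters[k] == "s")
        out[who == site] <- aaIdx
      out
    })
  } else if (!is.na(spec$offset)) {
    k <- spec$offset
    i <- seq_len(max(0L, n - k))
    j <- i + k
    keep <- ctx$sameChain[cbind(i, j)]
    i <- i[keep]; j <- j[keep]
    if (!is.null(site)) {
      sel <- i == site | j == site
      i <- i[sel]; j <- j[sel]
    }
    who <- list(i, i, j)                # first two letters on i, third on i+k
    cols <- lapply(seq_along(letters), function(m) {
      v <- resVec(letters[m])
      out <- v[who[[m]]]
      if (!is.null(aaIdx) && letters[m] == "s")
        out[who[[m]] == site] <- aaIdx
      out
    })
  } else {
    i <- if (is.null(site)) seq_len(n) else site
    cols <- lapply(letters, function(l) {
      out <- resVec(l)[i]
      if (!is.null(aaIdx) && l == "s") out[i == site] <- aaIdx
      out
    })
  }
  idx <- do.call(cbind, cols)
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  idx[stats::complete.cases(idx), , drop = FALSE]
}

.specDims <- function(spec, levels) {
  letters <- strsplit(spec$code, "")[[1]]
  lapply(seq_along(letters),
         function(k) levels[[letters[k]]])
}

#' Accumulate descriptor occurrence counts
#'
#' Counts every qualifying element tuple of every configured potential over
#' a list of annotated structures: single residues for residue-level codes,
#' sequence-window pairs for offset codes, and both orderings of residue
#' pairs whose side-chain centers fall inside the distance bins (and at
#' least `minSeqSep` apart along the chain) for distance codes. Counts are
#' additive over structures and independent of input order.
#'
#' @param structures list of [ProteinStructure-class] with descriptors
#'   computed (see [computeDescriptors()]).
#' @param config configuration list; `config$potentials` defines the specs.
#' @return a [CountsStore-class].
#' @export
accumulateCounts <- function(structures, config = defaultConfig()) {
  if (!length(structures)) stop("empty structure list")
  specs <- config$potentials
  lv <- .descriptorLevels(config)
  counts <- lapply(specs, function(sp) {
    lvs <- .specDims(sp, lv)
    array(0, dim = vapply(lvs, length, integer(1)), dimnames = lvs)
  })
  for (s in structures) {
    ctx <- .descriptorContext(s, config)
    for (nm in names(specs)) {
      idx <- .contribIndex(ctx, specs[[nm]])
      if (!nrow(idx)) next
      dims <- dim(counts[[nm]])
      lin <- 1 + as.vector((idx - 1) %*% cumprod(c(1, dims[-length(dims)])))
      counts[[nm]] <- counts[[nm]] +
        array(tabulate(lin, prod(dims)), dim = dims,
              dimnames = dimnames(counts[[nm]]))
    }
  }
  new("CountsStore", counts = counts, specs = specs,
      nStructures = length(structures))
}

#' Derive a potential table from counts
#'
#' Applies the inclusion-exclusion inverse-Boltzmann formula to the
#' pseudocount-smoothed frequencies of one descriptor combination. The
#' additive pseudocount sigma is applied to the joint counts and all
#' marginals are rederived from the smoothed joint, so marginal consistency
#' is preserved after smoothing. Tuples whose smoothed probability is zero
#' (possible only at sigma = 0) receive the configured cap energy.
#'
#' @param store a [CountsStore-class].
#' @param name name of the potential in the store.
#' @param config configuration list (keys `kT`, `sigma`, `cap_energy`).
#' @return a [PotentialTable-class].
#' @export
potentialFromCounts <- function(store, name, config = defaultConfig()) {
  if (!name %in% names(store@counts)) stop("unknown potential: ", name)
  joint <- store@counts[[name]] + config$sigma
  N <- sum(joint)
  if (N == 0) stop("no counts accumulated for potential ", name)
  dims <- dim(joint)
  nd <- length(dims)
  idx <- as.matrix(expand.grid(lapply(dims, seq_len)))
  acc <- numeric(nrow(idx))
  for (m in seq_len(2^nd - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(nd) - 1)) > 0)
    marg <- apply(joint, S, sum)
    logP <- log(marg) - log(N)
    vals <- if (length(S) == nd) logP[idx]
            else as.array(logP)[idx[, S, drop = FALSE]]
    acc <- acc + (-1)^(nd - length(S)) * vals
  }
  energy <- array(-config$kT * acc, dim = dims, dimnames = dimnames(joint))
  energy[!is.finite(energy)] <- config$cap_energy
  new("PotentialTable", name = name, spec = store@specs[[name]],
      energy = energy, kT = config$kT, sigma = config$sigma,
      capEnergy = config$cap_energy)
}

#' Derive the full configured potential set
#'
#' @param structures list of annotated [ProteinStructure-class] objects;
#'   descriptors are computed on the fly when missing.
#' @param config configuration list.
#' @return named list of [PotentialTable-class], in configuration order.
#' @export
derivePotentials <- function(structures, config = defaultConfig()) {
  structures <- lapply(structures, function(s) {
    if (all(is.na(s@residues$acc))) computeDescriptors(s, config) else s
  })
  store <- accumulateCounts(structures, config)
  tabs <- lapply(names(store@counts), potentialFromCounts,
                 store = store, config = config)
  names(tabs) <- names(store@counts)
  tabs
}

.lookupEnergy <- function(table, idx) {
  if (!nrow(idx)) return(numeric(0))
  table@energy[idx]
}

#' Total pseudo-energy of a structure under one potential
#'
#' Sums the potential's energy over every element tuple the structure
#' contributes (the same enumeration used for counting).
#'
#' @param s annotated [ProteinStructure-class].
#' @param table a [PotentialTable-class].
#' @param config configuration list.
#' @param ctx optional precomputed descriptor context (internal reuse).
#' @return energy in kcal/mol.
#' @export
structureEnergy <- function(s, table, config = defaultConfig(), ctx = NULL) {
  if (is.null(ctx)) ctx <- .descriptorContext(s, config)
  sum(.lookupEnergy(table, .contribIndex(ctx, table@spec)))
}

.resolveSite <- function(s, chain, resno, ins = "") {
  res <- s@residues
  i <- which(res$chain == chain & res$resno == resno & res$ins == ins)
  if (!length(i))
    stop("unknown residue: chain ", chain, " resno ", resno,
         if (nzchar(ins)) paste0(" ins ", ins))
  i[1]
}

#' Folding pseudo-energy change of a substitution
#'
#' ddW = W(mutant) - W(wild type) for one potential, holding all structure
#' descriptors (accessibility, torsion domain, distances, partner
#' identities) fixed and substituting only the amino-acid type at the
#' mutated site. Only element tuples involving the site are evaluated,
#' which equals the whole-structure energy difference. Positive values are
#' destabilizing.
#'
#' @param s annotated [ProteinStructure-class].
#' @param site residue row index, or the result of matching (chain, resno).
#' @param wt,mut one-letter wild-type and mutant amino-acid codes; `wt`
#'   must match the structure.
#' @param table a [PotentialTable-class].
#' @param config configuration list.
#' @param ctx optional precomputed descriptor context.
#' @return ddW in kcal/mol.
#' @export
mutationDdw <- function(s, site, wt, mut, table, config = defaultConfig(),
                        ctx = NULL) {
  if (is.null(ctx)) ctx <- .descriptorContext(s, config)
  if (site < 1 || site > ctx$n) stop("unknown residue index: ", site)
  if (s@residues$aa[site] != wt)
    stop("wild-type mismatch at residue row ", site, ": structure has ",
         s@residues$aa[site], ", variant says ", wt)
  mutIdx <- match(mut, AA1)
  if (is.na(mutIdx)) stop("unknown amino-acid code: ", mut)
  if (mut == wt) return(0)
  eWt <- sum(.lookupEnergy(table, .contribIndex(ctx, table@spec, site)))
  eMut <- sum(.lookupEnergy(table,
                            .contribIndex(ctx, table@spec, site, mutIdx)))
  eMut - eWt
}

#' Heaviside-split volume difference
#'
#' dV = V(mut) - V(wt); returns the positive and negative parts
#' (dVp = max(dV, 0), dVm = max(-dV, 0)), so mutating a smaller into a
#' larger residue gives a positive dVp.
#'
#' @param wt,mut one-letter amino-acid codes.
#' @param volumes named volume table (A^3), default from [defaultConfig()].
#' @return named numeric c(dVp, dVm).
#' @export
volumeTerms <- function(wt, mut, volumes = defaultConfig()$volume_table) {
  if (!wt %in% names(volumes) || !mut %in% names(volumes))
    stop("unknown amino-acid code: ", wt, "/", mut)
  dV <- volumes[[mut]] - volumes[[wt]]
  c(dVp = max(dV, 0), dVm = max(-dV, 0))
}

#' Feature vector(s) for substitutions
#'
#' Assembles, for every variant row, the ddW values of all configured
#' potentials (in configuration order), the Heaviside volume terms dVp/dVm
#' and the mutated residue's solvent accessibility A.
#'
#' @param structures named list of annotated [ProteinStructure-class]
#'   objects, names matching `variants$pdb_id`.
#' @param variants data.frame with columns pdb_id, chain, resno, wt, mut
#'   (optional ins).
#' @param tables named list of [PotentialTable-class] from
#'   [derivePotentials()].
#' @param config configuration list.
#' @return the variant data.frame with appended columns `ddW.<name>`,
#'   `dVp`, `dVm`, `A`.
#' @export
featurizeVariants <- function(structures, variants, tables,
                              config = defaultConfig()) {
  if (is.null(names(structures))) stop("structures must be a named list")
  if (!"ins" %in% names(variants)) variants$ins <- ""
  variants$ins[is.na(variants$ins)] <- ""
  ctxs <- lapply(structures, .descriptorContext, config = config)
  nt <- length(tables)
  ddW <- matrix(NA_real_, nrow(variants), nt,
                dimnames = list(NULL, paste0("ddW.", names(tables))))
  dVp <- dVm <- A <- numeric(nrow(variants))
  for (v in seq_len(nrow(variants))) {
    id <- variants$pdb_id[v]
    s <- structures[[id]]
    if (is.null(s)) stop("no structure named ", id)
    site <- .resolveSite(s, variants$chain[v], variants$resno[v],
                         variants$ins[v])
    for (k in seq_len(nt))
      ddW[v, k] <- mutationDdw(s, site, variants$wt[v], variants$mut[v],
                               tables[[k]], config, ctxs[[id]])
    vol <- volumeTerms(variants$wt[v], variants$mut[v], config$volume_table)
    dVp[v] <- vol[["dVp"]]; dVm[v] <- vol[["dVm"]]
    A[v] <- s@residues$acc[site]
  }
  cbind(variants, as.data.frame(ddW), dVp = dVp, dVm = dVm, A = A)
}

#' Serialize / read a potential table
#'
#' Tab-separated text with '#'-prefixed header lines (code, offset,
#' sequence separation, kT, sigma, cap) followed by one row per element
#' tuple with its energy at full double precision, so the round-trip is
#' bit-exact.
#'
#' @param table a [PotentialTable-class].
#' @param file output path.
#' @return `writePotentialTable`: the file path, invisibly;
#'   `readPotentialTable`: a [PotentialTable-class].
#' @export
writePotentialTable <- function(table, file) {
  dn <- dimnames(table@energy)
  hdr <- c(
    paste0("# name\t", table@name),
    paste0("# code\t", table@spec$code),
    paste0("# offset\t", table@spec$offset),
    paste0("# minSeqSep\t", table@spec$minSeqSep),
    paste0("# kT\t", sprintf("%.17g", table@kT)),
    paste0("# sigma\t", sprintf("%.17g", table@sigma)),
    paste0("# cap\t", sprintf("%.17g", table@capEnergy)),
    paste0("# levels\t",
           paste(vapply(dn, paste, character(1), collapse = "|"),
                 collapse = "\t"))
  )
  idx <- as.matrix(expand.grid(dn, stringsAsFactors = FALSE))
  rows <- apply(cbind(idx, sprintf("%.17g", as.vector(table@energy))), 1,
                paste, collapse = "\t")
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' @rdname writePotentialTable
#' @export
readPotentialTable <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines, value = TRUE)
  getv <- function(key) sub(paste0("^# ", key, "\t"), "",
                            grep(paste0("^# ", key, "\t"), hdr, value = TRUE))
  dn <- lapply(strsplit(getv("levels"), "\t")[[1]],
               function(x) strsplit(x, "|", fixed = TRUE)[[1]])
  dims <- vapply(dn, length, integer(1))
  body <- lines[!grepl("^# ", lines)]
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  energy <- array(NA_real_, dim = dims, dimnames = dn)
  energy[parts[, seq_along(dims), drop = FALSE]] <-
    as.numeric(parts[, length(dims) + 1])
  off <- suppressWarnings(as.integer(getv("offset")))
  sep <- suppressWarnings(as.integer(getv("minSeqSep")))
  new("PotentialTable", name = getv("name"),
      spec = list(code = getv("code"), offset = off, minSeqSep = sep),
      energy = energy, kT = as.numeric(getv("kT")),
      sigma = as.numeric(getv("sigma")),
      capEnergy = as.numeric(getv("cap")))
}
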