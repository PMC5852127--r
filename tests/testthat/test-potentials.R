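# Potential derivation: counting, the inclusion-exclusion energy formula,
# per-mutation ddW and the feature assembly.

test_that("counting is additive, order-invariant and matches brute force", {
  w <- tinyWorld()
  cfg <- w$cfg
  s1 <- w$structs[[1]]; s2 <- w$structs[[2]]
  c1 <- accumulateCounts(list(s1), cfg)
  c12 <- accumulateCounts(list(s1, s2), cfg)
  c21 <- accumulateCounts(list(s2, s1), cfg)
  cDup <- accumulateCounts(list(s1, s1), cfg)
  for (nm in names(c1@counts)) {
    expect_equal(cDup@counts[[nm]], 2 * c1@counts[[nm]])
    expect_equal(c12@counts[[nm]], c21@counts[[nm]])
  }
  expect_error(accumulateCounts(list(), cfg), "empty")

  # brute-force double loop for the pair code "sd"
  res <- residues(s1)
  ctr <- as.matrix(res[, c("scx", "scy", "scz")])
  edges <- cfg$dist_bin_edges
  brute <- array(0, dim = dim(c1@counts$sd), dimnames = dimnames(c1@counts$sd))
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    if (i == j || abs(i - j) < cfg$potentials$sd$minSeqSep) next
    d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
    if (d < edges[1] || d > edges[length(edges)]) next
    b <- min(findInterval(d, edges, rightmost.closed = TRUE), 25)
    brute[match(res$aa[i], AA1), b] <- brute[match(res$aa[i], AA1), b] + 1
  }
  expect_equal(c1@counts$sd, brute)

  # degenerate single-bin accessibility code: every residue lands in it
  cfg1 <- cfg
  cfg1$acc_bin_edges <- c(0, 100)
  cfg1$potentials <- list(sa = list(code = "sa", offset = NA_integer_,
                                    minSeqSep = NA_integer_))
  polyA <- handPdb(lapply(1:5, function(i)
    list(resno = i, resid = "ALA",
         atoms = list(N = c(3 * i, 0, 0), CA = c(3 * i + 1, 0, 0),
                      C = c(3 * i + 2, 1, 0), CB = c(3 * i + 1, -1, 0)))))
  sA <- computeDescriptors(readStructure(polyA), cfg1)
  cc <- accumulateCounts(list(sA), cfg1)
  expect_equal(sum(cc@counts$sa), 5)
  expect_equal(cc@counts$sa["A", 1], 5, ignore_attr = TRUE)
})

test_that("inclusion-exclusion reduces to the printed pair/triple forms", {
  cfg <- defaultConfig()
  cfg$sigma <- 0
  set.seed(42)
  for (k in 1:25) {
    joint2 <- array(rpois(6 * 5, 8) + 1, c(6, 5))
    t2 <- potentialFromCounts(storeFromArray(joint2, "sa"), "x", cfg)
    expect_equal(as.vector(t2@energy),
                 as.vector(directPairPotential(joint2, cfg$kT)),
                 tolerance = 1e-12)
    joint3 <- array(rpois(4 * 3 * 5, 6) + 1, c(4, 3, 5))
    t3 <- potentialFromCounts(storeFromArray(joint3, "sas"), "x", cfg)
    expect_equal(as.vector(t3@energy),
                 as.vector(directTriplePotential(joint3, cfg$kT)),
                 tolerance = 1e-12)
  }
})

test_that("independent joint tables give zero energy at sigma zero", {
  cfg <- defaultConfig()
  cfg$sigma <- 0
  set.seed(7)
  r <- rpois(8, 20) + 1; c_ <- rpois(6, 15) + 1
  joint <- outer(r, c_)
  t2 <- potentialFromCounts(storeFromArray(joint, "sa"), "x", cfg)
  expect_lt(max(abs(t2@energy)), 1e-12)

  # hand case with kT = 1: P(s,c) = 0.4, P(s) = P(c) = 0.5
  cfg1 <- cfg; cfg1$kT <- 1
  joint <- array(c(40, 10, 10, 40), c(2, 2))
  th <- potentialFromCounts(storeFromArray(joint, "sa"), "x", cfg1)
  expect_equal(th@energy[1, 1], -log(1.6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(th@energy[2, 1], -log(0.1 / 0.25), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("unobserved tuples receive the cap energy at sigma zero", {
  cfg <- defaultConfig()
  cfg$sigma <- 0
  joint <- array(c(5, 0, 3, 2), c(2, 2))
  tb <- potentialFromCounts(storeFromArray(joint, "sa"), "x", cfg)
  expect_equal(tb@energy[2, 1], cfg$cap_energy, ignore_attr = TRUE)
  expect_true(all(is.finite(tb@energy)))
})

test_that("site-local ddW equals the whole-structure energy difference", {
  w <- tinyWorld()
  cfg <- w$cfg
  set.seed(12)
  for (s in w$structs[1:2]) {
    ctx <- VarStab:::.descriptorContext(s, cfg)
    for (k in 1:5) {
      i <- sample(nResidues(s), 1)
      wt <- residues(s)$aa[i]
      mut <- sample(setdiff(AA1, wt), 1)
      s2 <- s
      s2@residues$aa[i] <- mut
      for (nm in c("sd", "sds", "sda", "sta", "sas", "sa", "stt")) {
        tb <- w$tabs[[nm]]
        dd <- mutationDdw(s, i, wt, mut, tb, cfg, ctx)
        oracle <- structureEnergy(s2, tb, cfg) - structureEnergy(s, tb, cfg)
        expect_equal(dd, oracle, tolerance = 1e-10)
        # antisymmetry under reversing the substitution
        expect_equal(mutationDdw(s2, i, mut, wt, tb, cfg), -dd,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("ddW edge cases: identity, closed form, error handling", {
  w <- tinyWorld()
  s <- w$structs[[1]]
  res <- residues(s)
  expect_equal(mutationDdw(s, 3, res$aa[3], res$aa[3], w$tabs$sa, w$cfg), 0)
  expect_error(mutationDdw(s, 3, setdiff(AA1, res$aa[3])[1], "W",
                           w$tabs$sa, w$cfg), "wild-type mismatch")
  expect_error(mutationDdw(s, 999, "A", "W", w$tabs$sa, w$cfg),
               "unknown residue")

  # single-residue code closed form: dW(mut, bin) - dW(wt, bin)
  bin <- VarStab:::.binIndex(res$acc[5], w$cfg$acc_bin_edges)
  mut <- setdiff(AA1, res$aa[5])[3]
  expected <- w$tabs$sa@energy[match(mut, AA1), bin] -
    w$tabs$sa@energy[match(res$aa[5], AA1), bin]
  expect_equal(mutationDdw(s, 5, res$aa[5], mut, w$tabs$sa, w$cfg),
               unname(expected))
})

test_that("volume terms implement the Heaviside split convention", {
  vol <- defaultConfig()$volume_table
  gw <- volumeTerms("G", "W", vol)
  expect_gt(gw[["dVp"]], 0)
  expect_equal(gw[["dVm"]], 0)
  expect_equal(volumeTerms("A", "A", vol), c(dVp = 0, dVm = 0))
  toy <- c(X = 100, Y = 80)
  expect_equal(volumeTerms("X", "Y", toy), c(dVp = 0, dVm = 20))
  expect_error(volumeTerms("A", "?", vol), "unknown")
  # complementarity over all ordered pairs
  for (a in AA1) for (b in AA1) {
    v <- volumeTerms(a, b, vol)
    expect_equal(v[["dVp"]] - v[["dVm"]], vol[[b]] - vol[[a]])
    expect_equal(v[["dVp"]] * v[["dVm"]], 0)
  }
})

test_that("featurize composes mutationDdw and volumeTerms per variant", {
  w <- tinyWorld()
  s <- w$structs[[1]]
  res <- residues(s)
  v <- data.frame(pdb_id = names(w$structs)[1], chain = "A",
                  resno = res$resno[c(4, 9)], wt = res$aa[c(4, 9)],
                  mut = c("W", "G"), stringsAsFactors = FALSE)
  v$mut[v$wt == v$mut] <- "F"
  f <- featurizeVariants(w$structs, v, w$tabs, w$cfg)
  for (r in 1:2) {
    i <- c(4, 9)[r]
    for (nm in names(w$tabs))
      expect_equal(f[[paste0("ddW.", nm)]][r],
                   mutationDdw(s, i, v$wt[r], v$mut[r], w$tabs[[nm]], w$cfg))
    vol <- volumeTerms(v$wt[r], v$mut[r], w$cfg$volume_table)
    expect_equal(f$dVp[r], vol[["dVp"]])
    expect_equal(f$A[r], res$acc[i])
  }
  # identity substitution: all-zero energy and volume features
  vid <- data.frame(pdb_id = names(w$structs)[1], chain = "A",
                    resno = res$resno[4], wt = res$aa[4], mut = res$aa[4])
  fid <- featurizeVariants(w$structs, vid, w$tabs, w$cfg)
  expect_true(all(fid[, paste0("ddW.", names(w$tabs))] == 0))
  expect_equal(fid$dVp + fid$dVm, 0)
})

test_that("potential tables round-trip bit-exactly through serialization", {
  w <- tinyWorld()
  for (nm in c("sd", "sta", "sas")) {
    f <- tempfile(fileext = ".tsv")
    writePotentialTable(w$tabs[[nm]], f)
    back <- readPotentialTable(f)
    expect_identical(back@energy, w$tabs[[nm]]@energy)
    expect_identical(back@kT, w$tabs[[nm]]@kT)
    expect_identical(back@spec$code, w$tabs[[nm]]@spec$code)
  }
})
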