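# Sign-split index, PNN and meta-combiner.

.toyAnnModel <- function(cfg, seed = 42, flatEqual = FALSE) {
  nm <- names(cfg$potentials)[cfg$ann_subset]
  set.seed(seed)
  gates <- matrix(0, 4, 24,
                  dimnames = list(c("omega", "nu", "xi", "phi"), NULL))
  if (flatEqual) {
    w <- abs(rnorm(11, 0.4, 0.1))
    gates["phi", ] <- c(w, w, 0.002, 0.002)  # phi+ = phi-, flat
  } else {
    gates["phi", ] <- abs(rnorm(24, 0.3, 0.15))
    gates["omega", ] <- rnorm(24, 0, 0.2)
    gates["nu", ] <- runif(24, -0.1, 0.1)
    gates["xi", ] <- runif(24, 0, 100)
  }
  new("AnnModel", gates = gates, subset = as.integer(cfg$ann_subset),
      potentialNames = nm, threshold = 0, trainMse = NA_real_)
}

test_that("sign split is an exact invertible decomposition", {
  cfg <- defaultConfig()
  f <- randomFeatures(50, seed = 11)
  sp <- signSplit(f, cfg$ann_subset, cfg)
  nm <- names(cfg$potentials)[cfg$ann_subset]
  pos <- as.matrix(sp[, paste0("pos.", nm)])
  neg <- as.matrix(sp[, paste0("neg.", nm)])
  orig <- as.matrix(f[, paste0("ddW.", nm)])
  expect_equal(unname(pos - neg), unname(orig))
  expect_true(all(pos * neg == 0))
  expect_true(all(pos >= 0) && all(neg >= 0))
  expect_equal(sp$A, f$A)
  expect_error(signSplit(f, c(1, 99), cfg), "bad potential subset")
  # single-value cases
  f1 <- f[1, ]; f1$ddW.sd <- 1.5
  expect_equal(signSplit(f1, cfg$ann_subset, cfg)$pos.sd, 1.5)
  f1$ddW.sd <- -0.3
  s1 <- signSplit(f1, cfg$ann_subset, cfg)
  expect_equal(s1$pos.sd, 0)
  expect_equal(s1$neg.sd, 0.3)
})

test_that("the index is a gated sum with no intercept", {
  cfg <- defaultConfig()
  m <- .toyAnnModel(cfg)
  f0 <- randomFeatures(3, seed = 2)
  f0[grep("^ddW\\.", names(f0))] <- 0
  f0$dVp <- 0; f0$dVm <- 0
  expect_equal(annIndex(m, f0, cfg), rep(0, 3))

  # naive dot-product oracle
  f <- randomFeatures(15, seed = 3)
  I <- annIndex(m, f, cfg)
  sp <- signSplit(f, m@subset, cfg)
  X <- as.matrix(sp[, c(paste0("pos.", m@potentialNames),
                        paste0("neg.", m@potentialNames), "dVp", "dVm")])
  for (i in c(1, 8, 15)) {
    tot <- 0
    for (j in seq_len(24))
      tot <- tot + X[i, j] * gateValue(m@gates["omega", j],
                                       m@gates["nu", j], m@gates["xi", j],
                                       m@gates["phi", j], f$A[i])
    expect_equal(I[i], unname(tot))
  }

  # with equal flat +/- gates, the index is sign-flip invariant
  ms <- .toyAnnModel(cfg, flatEqual = TRUE)
  fFlip <- f
  fFlip[grep("^ddW\\.", names(f))] <- -f[grep("^ddW\\.", names(f))]
  expect_equal(annIndex(ms, fFlip, cfg), annIndex(ms, f, cfg))
})

test_that("training recovers a separable planted index and nulls to chance", {
  cfg <- defaultConfig()
  f <- randomFeatures(800, seed = 41)
  mTrue <- .toyAnnModel(cfg)
  Itrue <- annIndex(mTrue, f, cfg)
  # noiseless planted labels with a margin band removed around the cut
  keep <- Itrue < quantile(Itrue, 0.3) | Itrue > quantile(Itrue, 0.5)
  f2 <- f[keep, ]
  y <- Itrue[keep] > quantile(Itrue, 0.5)
  ann <- trainAnn(f2, y, cfg, seed = 1)
  I <- annIndex(ann, f2, cfg)
  expect_gte(optimizeThreshold(I, y, "higher")$bacc, 0.95)
  # the stored threshold equals the exhaustive scan
  expect_equal(ann@threshold, bruteThreshold(I, y)$threshold)

  expect_error(trainAnn(f2, rep(TRUE, nrow(f2)), cfg), "both classes")

  # permuted labels: cross-validated performance is chance
  set.seed(9)
  f$isDel <- sample(Itrue > quantile(Itrue, 0.4))
  r <- crossValidate(annTrainer(cfg, nRestarts = 1, maxit = 80), f,
                     k = 5, seed = 3)
  expect_gt(r@summary[["bacc"]], 0.4)
  expect_lt(r@summary[["bacc"]], 0.6)
})

test_that("PNN matches the brute-force kernel Bayes oracle", {
  set.seed(17)
  n <- 30; p <- 9
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", 1:p)
  isDel <- rep(c(TRUE, FALSE), length.out = n)
  sigma <- runif(p, 0.5, 2)
  eta <- c(1.3, 0.8)
  m <- new("PnnModel", X = X, isDel = isDel, sigma = sigma, eta = eta,
           featureNames = colnames(X), looBacc = NA_real_)
  Q <- matrix(rnorm(12 * p), 12)
  got <- pnnClassify(m, Q)
  oracle <- brutePnn(X, isDel, sigma, eta, Q)
  expect_equal(got$PD, unname(oracle[, "PD"]), tolerance = 1e-9)
  expect_equal(got$PN, unname(oracle[, "PN"]), tolerance = 1e-9)
  expect_equal(got$call,
               ifelse(oracle[, "PD"] > oracle[, "PN"], "deleterious",
                      "neutral"), ignore_attr = TRUE)
})

test_that("PNN tie and on-sample behaviour follow the decision rule", {
  p <- 3
  X <- rbind(rep(1, p), rep(-1, p))
  colnames(X) <- paste0("f", 1:p)
  m <- new("PnnModel", X = X, isDel = c(TRUE, FALSE), sigma = rep(1, p),
           eta = c(1, 1), featureNames = colnames(X), looBacc = NA_real_)
  # equidistant query: PD == PN, tie goes to neutral
  tie <- pnnClassify(m, matrix(0, 1, p))
  expect_equal(tie$PD, tie$PN)
  expect_equal(tie$call, "neutral")
  # query on a deleterious training sample
  hit <- pnnClassify(m, matrix(1, 1, p, byrow = TRUE))
  expect_equal(hit$call, "deleterious")
})

test_that("PNN training separates planted clouds, nulls, adapts to scale", {
  set.seed(23)
  n <- 120; p <- 9
  X <- rbind(matrix(rnorm(n / 2 * p, 2), n / 2),
             matrix(rnorm(n / 2 * p, -2), n / 2))
  colnames(X) <- paste0("f", 1:p)
  isDel <- rep(c(TRUE, FALSE), each = n / 2)
  m <- trainPnn(X, isDel, seed = 1, nRestarts = 1, maxit = 60)
  expect_gte(m@looBacc, 0.95)
  expect_error(trainPnn(X, rep(TRUE, n)), "both classes")

  # permuted labels: leave-one-out performance near chance
  set.seed(5)
  mNull <- trainPnn(X, sample(isDel), seed = 1, nRestarts = 1, maxit = 60)
  expect_lt(mNull@looBacc, 0.66)

  # bandwidth initialisation absorbs feature rescaling
  X2 <- X; X2[, 1] <- X2[, 1] * 1000
  m2 <- trainPnn(X2, isDel, seed = 1, nRestarts = 1, maxit = 60)
  expect_lte(abs(m2@looBacc - m@looBacc), 0.02)
})

test_that("the combiner index is the affine form with strict inputs", {
  m <- new("CombinerModel", gamma = c(0.2, 0.5, -0.1), threshold = 0,
           jD = 0.9, jN = 0.5, trainBacc = NA_real_)
  expect_equal(combinerIndex(m, 1.0, -2.5), 0.2 + 0.5 + 0.25)
  mI <- new("CombinerModel", gamma = c(0, 1, 0), threshold = 0,
            jD = 0.9, jN = 0.5, trainBacc = NA_real_)
  expect_equal(combinerIndex(mI, c(0.3, 1.2), c(-5, 5)), c(0.3, 1.2))
  mC <- new("CombinerModel", gamma = c(1, 0, 0), threshold = 0,
            jD = 0.9, jN = 0.5, trainBacc = NA_real_)
  expect_equal(combinerIndex(mC, c(0.3, 1.2), c(-5, 5)), c(1, 1))
  expect_error(combinerIndex(mI, 1, NA), "external")
  expect_error(combinerIndex(mI, 1), "external")
})

test_that("combiner training handles single-source and mixed signals", {
  set.seed(31)
  n <- 300
  I <- rnorm(n)
  pro <- rnorm(n)
  # labels fully determined by I
  yI <- I > 0.2
  mI <- trainCombiner(I, pro, yI)
  JI <- combinerIndex(mI, I, pro)
  del <- classifyByThreshold(JI, mI@threshold, "higher") == "deleterious"
  expect_equal(bacc(sum(del & yI), sum(!del & yI),
                    sum(!del & !yI), sum(del & !yI)), 1.0)
  # labels fully determined by the external score (negative = deleterious)
  yP <- pro < -0.1
  mP <- trainCombiner(I, pro, yP)
  JP <- combinerIndex(mP, I, pro)
  delP <- classifyByThreshold(JP, mP@threshold, "higher") == "deleterious"
  expect_equal(bacc(sum(delP & yP), sum(!delP & yP),
                    sum(!delP & !yP), sum(delP & !yP)), 1.0)
  expect_lt(mP@gamma[3], 0)
  expect_error(trainCombiner(I, pro, rep(TRUE, n)), "both classes")

  # planted linear combination with 10 percent flip noise, 5-fold CV
  set.seed(33)
  yMix <- xor(I - 1.5 * pro > 0.5, runif(n) < 0.10)
  folds <- kfoldSplit(n, 5, "mutation", seed = 7)
  baccs <- vapply(1:5, function(f) {
    tr <- folds != f
    m <- trainCombiner(I[tr], pro[tr], yMix[tr])
    J <- combinerIndex(m, I[!tr], pro[!tr])
    del <- classifyByThreshold(J, m@threshold, "higher") == "deleterious"
    bacc(sum(del & yMix[!tr]), sum(!del & yMix[!tr]),
         sum(!del & !yMix[!tr]), sum(del & !yMix[!tr]))
  }, numeric(1))
  expect_gte(mean(baccs), 0.85)
})

test_that("confidence bands use inclusive edges", {
  m <- new("CombinerModel", gamma = c(0, 1, 0), threshold = 0.7,
           jD = 0.9, jN = 0.5, trainBacc = NA_real_)
  expect_equal(confidenceBand(m, 0.95), "high_conf_deleterious")
  expect_equal(confidenceBand(m, 0.9), "high_conf_deleterious")
  expect_equal(confidenceBand(m, 0.5), "high_conf_neutral")
  expect_equal(confidenceBand(m, 0.7), "uncertain")
  expect_equal(confidenceBand(m, c(1, 0.2, 0.6)),
               c("high_conf_deleterious", "high_conf_neutral", "uncertain"))
})
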