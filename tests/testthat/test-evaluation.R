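# Metrics, AUROC, threshold search, cross-validation and dataset filters.

test_that("balanced accuracy follows its defining identity", {
  expect_equal(bacc(10, 0, 10, 0), 1.0)
  expect_equal(bacc(5, 5, 7, 7), 0.5)
  expect_equal(bacc(3, 1, 2, 2), 0.625)
  expect_error(bacc(0, 0, 5, 1), "empty")
  set.seed(13)
  for (k in 1:200) {
    cc <- rpois(4, 10) + c(1, 0, 1, 0)
    m <- basicMetrics(cc[1], cc[2], cc[3], cc[4])
    expect_equal(bacc(cc[1], cc[2], cc[3], cc[4]),
                 (m[["sensitivity"]] + m[["specificity"]]) / 2)
  }
})

test_that("confusion metrics report undefined denominators as NA", {
  m <- basicMetrics(79, 21, 71, 29)
  expect_equal(m[["sensitivity"]], 0.79)
  expect_equal(m[["specificity"]], 0.71)
  expect_equal(basicMetrics(5, 1, 3, 0)[["ppv"]], 1.0)
  expect_true(is.na(basicMetrics(0, 2, 3, 0)[["ppv"]]))
  expect_true(is.na(basicMetrics(3, 0, 0, 2)[["npv"]]))
})

test_that("AUROC: limits, hand case, pair-counting oracle, invariance", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(rocAuroc(c(4, 3, 2, 1), y), 1.0)
  expect_equal(rocAuroc(rep(1, 4), y), 0.5)
  expect_equal(rocAuroc(c(0.9, 0.8, 0.7, 0.1),
                        c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_error(rocAuroc(1:4, rep(TRUE, 4)), "both classes")

  # brute-force pair counting on random score sets, both directions
  set.seed(21)
  for (k in 1:10) {
    n <- 30
    sc <- round(rnorm(n), 1)          # ties on purpose
    y <- runif(n) < 0.4
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(i = which(y), j = which(!y))
    brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                         ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
    expect_equal(rocAuroc(sc, y, "higher"), brute)
    expect_equal(rocAuroc(sc, y, "lower"), 1 - brute)
    # invariance under a strictly monotone transform
    expect_equal(rocAuroc(exp(sc), y, "higher"), brute)
  }
})

test_that("threshold optimization equals exhaustive brute force", {
  # separable: perfect split, smallest qualifying threshold returned
  sc <- c(1, 2, 3, 10, 11, 12)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- optimizeThreshold(sc, y, "higher")
  expect_equal(r$bacc, 1.0)
  expect_equal(r$threshold, 6.5)
  expect_error(optimizeThreshold(sc, rep(TRUE, 6)), "both classes")

  set.seed(31)
  for (k in 1:30) {
    sc <- round(rnorm(20), 1)
    y <- runif(20) < 0.5
    if (length(unique(y)) < 2) next
    for (dir in c("higher", "lower")) {
      got <- optimizeThreshold(sc, y, dir)
      ref <- bruteThreshold(sc, y, dir)
      expect_equal(got$bacc, ref$bacc)
      expect_equal(got$threshold, ref$threshold)
    }
    # scan includes degenerate all-one-class thresholds, so never below 0.5
    expect_gte(optimizeThreshold(sc, sample(y), "higher")$bacc, 0.5)
  }
})

test_that("fold assignment is balanced, deterministic and protein-safe", {
  f <- kfoldSplit(100, 5, "mutation", seed = 3)
  expect_equal(unname(table(f)), rep(20L, 5), ignore_attr = TRUE)
  expect_identical(f, kfoldSplit(100, 5, "mutation", seed = 3))
  expect_false(identical(f, kfoldSplit(100, 5, "mutation", seed = 4)))

  prot <- sample(paste0("P", 1:17), 80, replace = TRUE)
  fp <- kfoldSplit(80, 5, "protein", protein = prot, seed = 2)
  expect_true(all(tapply(fp, prot, function(x) length(unique(x))) == 1))
  expect_error(kfoldSplit(10, 5, "protein", protein = rep("P1", 10),
                          seed = 1), "at least k distinct")
  expect_error(kfoldSplit(10, 1, "mutation"), "at least 2")
})

test_that("cross-validation scores held-out folds with train-only fitting", {
  set.seed(41)
  n <- 200
  data <- data.frame(score = rnorm(n), isDel = runif(n) < 0.6,
                     protein = sample(paste0("P", 1:12), n, replace = TRUE))
  # constant classifier: everything deleterious
  alwaysDel <- function(data, seed) {
    list(score = function(d) rep(1, nrow(d)), threshold = 0,
         direction = "higher")
  }
  r <- suppressWarnings(crossValidate(alwaysDel, data, k = 5, seed = 1))
  expect_equal(r@summary[["sensitivity"]], 1.0)
  expect_equal(r@summary[["specificity"]], 0.0)
  expect_equal(r@summary[["bacc"]], 0.5)

  # the trainer never sees held-out rows
  seen <- new.env(); seen$idx <- list()
  data$row <- seq_len(n)
  spy <- function(data, seed) {
    seen$idx[[length(seen$idx) + 1]] <- data$row
    thr <- optimizeThreshold(data$score, data$isDel, "higher")
    list(score = function(d) d$score, threshold = thr$threshold,
         direction = "higher")
  }
  r2 <- crossValidate(spy, data, k = 5, seed = 6)
  folds <- r2@folds
  for (f in 1:5)
    expect_length(intersect(seen$idx[[f]], which(folds == f)), 0)

  # single-class training fold is an error
  bad <- data[1:10, ]; bad$isDel <- c(TRUE, rep(FALSE, 9))
  expect_error(crossValidate(spy, bad, k = 5, seed = 2),
               "single class|both classes")
})

test_that("dataset filters implement the three exclusion rules", {
  v <- data.frame(
    pdb_id = c("1abc", "1abc", "2xyz", "2xyz", "3def", "3def"),
    chain = "A", resno = c(10, 20, 30, 40, 50, 50),
    wt = "A", mut = c("V", "W", "G", "F", "K", "K"),
    label = c("deleterious", "neutral", "deleterious", "neutral",
              "deleterious", "neutral"),
    resolution = c(1.8, 3.0, 2.0, 2.4, 2.2, 2.2),
    method = c("X-RAY DIFFRACTION", "X-RAY DIFFRACTION",
               "X-RAY DIFFRACTION", "SOLUTION NMR",
               "X-RAY DIFFRACTION", "X-RAY DIFFRACTION"),
    dist_extra_mut = c(NA, NA, 8, 15, NA, NA),
    stringsAsFactors = FALSE)
  out <- applyDatasetFilters(v)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$resno, 10)
  ex <- out$excluded
  expect_equal(ex$reason[ex$resno == 20], "resolution")   # 3.0 A
  expect_equal(ex$reason[ex$resno == 40], "resolution")   # not X-ray
  expect_equal(ex$reason[ex$resno == 30], "proximity")    # 8 A < 10 A
  expect_equal(unique(ex$reason[ex$resno == 50]), "conflict")
  expect_error(applyDatasetFilters(v[, -7]), "missing metadata")
})

test_that("dataset composition counts variants, proteins and labels", {
  v <- data.frame(pdb_id = c("a", "a", "b"),
                  label = c("deleterious", "neutral", "deleterious"))
  comp <- datasetComposition(v)
  expect_equal(comp[["n_variants"]], 3)
  expect_equal(comp[["n_proteins"]], 2)
  expect_equal(comp[["n_deleterious"]], 2)
  expect_equal(comp[["n_neutral"]], 1)
})

test_that("paired bootstrap on AUROC differences behaves sanely", {
  set.seed(51)
  n <- 120
  y <- runif(n) < 0.5
  good <- as.numeric(y) + rnorm(n, sd = 0.4)
  bad <- rnorm(n)
  r <- aurocBootstrapDiff(good, bad, y, nBoot = 200, seed = 2)
  expect_gt(r$diff, 0.2)
  expect_lt(r$p, 0.05)
  same <- aurocBootstrapDiff(good, good + 0, y, nBoot = 100, seed = 2)
  expect_equal(same$diff, 0)
})
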