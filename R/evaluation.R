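# Confusion-matrix metrics, balanced accuracy, ROC/AUROC,
# balanced-accuracy-optimal threshold search, mutation- and protein-level
# k-fold cross-validation, and the dataset filtering rules.

#' Balanced accuracy
#'
#' BACC = TP / (2 (TP + FN)) + TN / (2 (TN + FP)), the mean of sensitivity
#' and specificity. Positive corresponds to deleterious variants.
#'
#' @param TP,FN,TN,FP non-negative confusion counts.
#' @return value in [0, 1].
#' @export
bacc <- function(TP, FN, TN, FP) {
  if (TP + FN == 0 || TN + FP == 0)
    stop("balanced accuracy undefined: one class is empty")
  TP / (2 * (TP + FN)) + TN / (2 * (TN + FP))
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP) and negative predictive value TN/(TN+FN). A metric
#' whose denominator is zero is reported as NA (undefined), never as 0.
#'
#' @param TP,FN,TN,FP non-negative confusion counts.
#' @return named numeric (sensitivity, specificity, ppv, npv).
#' @export
basicMetrics <- function(TP, FN, TN, FP) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  c(sensitivity = safe(TP, TP + FN),
    specificity = safe(TN, TN + FP),
    ppv = safe(TP, TP + FP),
    npv = safe(TN, TN + FN))
}

.confusion <- function(del, isDel) {
  c(TP = sum(del & isDel), FN = sum(!del & isDel),
    TN = sum(!del & !isDel), FP = sum(del & !isDel))
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with ties counted one half,
#' direction-aware: for `direction = "higher"` larger scores indicate
#' deleterious variants.
#'
#' @param scores numeric scores.
#' @param isDel logical labels (TRUE = deleterious).
#' @param direction "higher" or "lower" is deleterious.
#' @return AUROC in [0, 1].
#' @export
rocAuroc <- function(scores, isDel, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  isDel <- as.logical(isDel)
  if (length(unique(isDel)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = isDel, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE),
                 direction = if (direction == "higher") "<" else ">",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Balanced-accuracy-optimal threshold
#'
#' Exhaustive scan over the midpoints of consecutive distinct sorted scores
#' plus below-minimum and above-maximum sentinels; returns the threshold
#' maximising the balanced accuracy of the direction-aware call (ties are
#' neutral). Among equally good thresholds the smallest is returned.
#'
#' @param scores numeric scores.
#' @param isDel logical labels.
#' @param direction "higher" or "lower" is deleterious.
#' @return list(threshold, bacc).
#' @export
optimizeThreshold <- function(scores, isDel,
                              direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  isDel <- as.logical(isDel)
  if (length(unique(isDel)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  nD <- sum(isDel); nN <- sum(!isDel)
  baccs <- vapply(cand, function(th) {
    del <- if (direction == "higher") scores > th else scores < th
    sum(del & isDel) / (2 * nD) + sum(!del & !isDel) / (2 * nN)
  }, numeric(1))
  best <- max(baccs)
  list(threshold = min(cand[baccs == best]), bacc = best)
}

#' k-fold assignment at mutation or protein level
#'
#' Mutation level: uniform random partition of the variants into k folds of
#' near-equal size. Protein level: uniform random partition of the distinct
#' protein identifiers; every variant inherits its protein's fold, so no
#' protein is ever split across folds. Deterministic given seed.
#'
#' @param n number of variants.
#' @param k number of folds.
#' @param level "mutation" or "protein".
#' @param protein protein identifier per variant (required at protein
#'   level).
#' @param seed integer seed.
#' @return integer fold assignment of length n.
#' @export
kfoldSplit <- function(n, k = 5L, level = c("mutation", "protein"),
                       protein = NULL, seed = 1L) {
  level <- match.arg(level)
  if (k < 2) stop("k must be at least 2")
  oldSeed <- globalenv()$.Random.seed
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()), add = TRUE)
  set.seed(seed)
  if (level == "mutation") {
    sample(rep(seq_len(k), length.out = n))
  } else {
    if (is.null(protein)) stop("protein ids required for protein-level folds")
    prots <- unique(protein)
    if (length(prots) < k)
      stop("need at least k distinct proteins for protein-level folds")
    pf <- sample(rep(seq_len(k), length.out = length(prots)))
    pf[match(protein, prots)]
  }
}

#' Cross-validate a trainable classifier
#'
#' For each fold, trains the classifier (including its threshold selection)
#' on the remaining folds only and scores the held-out fold; reports
#' per-fold confusion metrics, their averages, the average threshold, and
#' both the pooled-held-out-score AUROC and the fold-averaged AUROC.
#'
#' @param trainer function(data, seed) returning
#'   list(score = function(data) numeric, threshold, direction); see e.g.
#'   [annTrainer()].
#' @param data variant data.frame with a logical/0-1 `isDel` column (and a
#'   `protein` column at protein level).
#' @param k number of folds.
#' @param level "mutation" or "protein".
#' @param seed integer seed (drives the fold draw and the trainer).
#' @return an [EvalReport-class].
#' @export
crossValidate <- function(trainer, data, k = 5L,
                          level = c("mutation", "protein"), seed = 1L) {
  level <- match.arg(level)
  isDel <- as.logical(data$isDel)
  folds <- kfoldSplit(nrow(data), k, level, protein = data$protein,
                      seed = seed)
  pooledScores <- numeric(nrow(data))
  pooledDir <- "higher"
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(isDel[tr])) < 2)
      stop("training folds for fold ", f, " contain a single class")
    fit <- trainer(data[tr, , drop = FALSE], seed = seed + f)
    sc <- fit$score(data[!tr, , drop = FALSE])
    del <- classifyByThreshold(sc, fit$threshold, fit$direction) ==
      "deleterious"
    cc <- .confusion(del, isDel[!tr])
    auroc <- rocAuroc(sc, isDel[!tr], fit$direction)
    rows[[f]] <- data.frame(
      fold = f,
      t(basicMetrics(cc[["TP"]], cc[["FN"]], cc[["TN"]], cc[["FP"]])),
      bacc = bacc(cc[["TP"]], cc[["FN"]], cc[["TN"]], cc[["FP"]]),
      threshold = fit$threshold, auroc = auroc, n = sum(!tr))
    if (fit$direction == "lower") sc <- -sc   # pool on a common direction
    pooledScores[!tr] <- sc
  }
  perFold <- do.call(rbind, rows)
  summ <- colMeans(perFold[, c("sensitivity", "specificity", "ppv", "npv",
                               "bacc", "threshold", "auroc")])
  new("EvalReport", perFold = perFold, summary = summ,
      aurocPooled = rocAuroc(pooledScores, isDel, pooledDir),
      folds = as.integer(folds), level = level)
}

#' Apply the dataset filtering rules
#'
#' Three rules applied to a variant table with structure metadata:
#' (1) keep only variants on X-ray structures of resolution at most
#' `maxResolution`; (2) keep only variants at an inter-C-alpha distance of
#' at least `minCaDist` from every additional mutation of the structure
#' (column `dist_extra_mut`, NA meaning none); (3) discard variants whose
#' annotations conflict across sources (same variant key, different
#' labels). Every exclusion is logged with its rule.
#'
#' @param variants data.frame with columns pdb_id, chain, resno, wt, mut,
#'   label, resolution, method, dist_extra_mut.
#' @param maxResolution maximal X-ray resolution, Angstrom (2.5).
#' @param minCaDist minimal inter-C-alpha distance to extra mutations,
#'   Angstrom (10).
#' @return list(kept = data.frame, excluded = data.frame with a `reason`
#'   column).
#' @export
applyDatasetFilters <- function(variants, maxResolution = 2.5,
                                minCaDist = 10) {
  need <- c("pdb_id", "chain", "resno", "wt", "mut", "label",
            "resolution", "method", "dist_extra_mut")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(variants))
  badRes <- !grepl("x-ray", variants$method, ignore.case = TRUE) |
    is.na(variants$resolution) | variants$resolution > maxResolution
  reason[badRes] <- "resolution"
  badDist <- !is.na(variants$dist_extra_mut) &
    variants$dist_extra_mut < minCaDist
  reason[is.na(reason) & badDist] <- "proximity"
  key <- paste(variants$pdb_id, variants$chain, variants$resno,
               variants$wt, variants$mut)
  nlab <- tapply(variants$label, key, function(x) length(unique(x)))
  conflict <- nlab[key] > 1
  reason[is.na(reason) & conflict] <- "conflict"
  list(
    kept = variants[is.na(reason), , drop = FALSE],
    excluded = cbind(variants[!is.na(reason), , drop = FALSE],
                     reason = reason[!is.na(reason)])
  )
}

#' Paired bootstrap test for an AUROC difference
#'
#' Generic plumbing: resamples variants with replacement and compares the
#' AUROCs of two paired score vectors; returns the bootstrap distribution
#' of the difference and a two-sided p-value for difference zero.
#'
#' @param scores1,scores2 paired score vectors (same direction).
#' @param isDel logical labels.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return list(diff, p, boot).
#' @export
aurocBootstrapDiff <- function(scores1, scores2, isDel, nBoot = 1000L,
                               seed = 1L) {
  oldSeed <- globalenv()$.Random.seed
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()), add = TRUE)
  set.seed(seed)
  isDel <- as.logical(isDel)
  n <- length(isDel)
  boot <- replicate(nBoot, {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(isDel[i])) < 2) return(NA_real_)
    rocAuroc(scores1[i], isDel[i]) - rocAuroc(scores2[i], isDel[i])
  })
  boot <- boot[!is.na(boot)]
  obs <- rocAuroc(scores1, isDel) - rocAuroc(scores2, isDel)
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(diff = obs, p = min(1, max(p, 1 / length(boot))), boot = boot)
}

#' Composition summary of a variant table
#'
#' Counts of variants, distinct proteins, and per-label totals — the
#' quantities used to describe a curated variant set.
#'
#' @param variants data.frame with `pdb_id` (or `protein`) and `label` (or
#'   logical `isDel`) columns.
#' @return named numeric (n_variants, n_proteins, n_deleterious,
#'   n_neutral).
#' @export
datasetComposition <- function(variants) {
  prot <- if ("protein" %in% names(variants)) variants$protein
          else variants$pdb_id
  isDel <- if ("isDel" %in% names(variants)) as.logical(variants$isDel)
           else variants$label == "deleterious"
  c(n_variants = nrow(variants), n_proteins = length(unique(prot)),
    n_deleterious = sum(isDel), n_neutral = sum(!isDel))
}
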