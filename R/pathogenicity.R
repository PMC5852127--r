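# The three variant classifiers built on the stability features: the
# sign-split gated index I (which can flag both stabilizing and
# destabilizing substitutions as deleterious), the probabilistic neural
# network (kernel-density Bayes classifier), and the affine meta-combiner
# J = gamma1 + gamma2 I + gamma3 PRO with its high-confidence bands.

#' Heaviside sign split of the potential terms
#'
#' Decomposes each selected ddW value into its positive and negative parts,
#' ddW+ = max(ddW, 0) and ddW- = max(-ddW, 0), so that stabilizing and
#' destabilizing contributions can carry separate gated weights. dVp, dVm
#' and A are carried through unchanged.
#'
#' @param features featurized variant data.frame (see
#'   [featurizeVariants()]).
#' @param subset integer indices of the potentials to keep (default: the
#'   configured 11-potential subset).
#' @param config configuration list.
#' @return data.frame with columns `pos.<name>`, `neg.<name>`, `dVp`,
#'   `dVm`, `A`.
#' @export
signSplit <- function(features, subset = defaultConfig()$ann_subset,
                      config = defaultConfig()) {
  potNames <- names(config$potentials)
  if (any(subset < 1 | subset > length(potNames)))
    stop("bad potential subset")
  nm <- potNames[subset]
  cols <- paste0("ddW.", nm)
  miss <- setdiff(cols, names(features))
  if (length(miss)) stop("feature columns missing: ",
                         paste(miss, collapse = ", "))
  W <- as.matrix(features[, cols, drop = FALSE])
  out <- cbind(pmax(W, 0), pmax(-W, 0))
  colnames(out) <- c(paste0("pos.", nm), paste0("neg.", nm))
  data.frame(out, dVp = features$dVp, dVm = features$dVm, A = features$A,
             check.names = FALSE)
}

.annMatrix <- function(split, potNames) {
  .featureMatrix(split, c(paste0("pos.", potNames),
                          paste0("neg.", potNames), "dVp", "dVm"))
}

#' Sign-split gated pathogenicity index
#'
#' I = sum_i phi_i^+(A) ddW_i^+ + sum_i phi_i^-(A) ddW_i^- +
#' phi_dVp(A) dVp + phi_dVm(A) dVm, with every weight a sigmoid gate in the
#' variant's accessibility and no intercept term. Large I can arise from
#' strongly stabilizing or strongly destabilizing substitutions.
#'
#' @param m an [AnnModel-class].
#' @param features featurized variant data.frame; the Heaviside split is
#'   applied internally using the model's potential subset.
#' @param config configuration list.
#' @return numeric index values.
#' @export
annIndex <- function(m, features, config = defaultConfig()) {
  split <- signSplit(features, m@subset, config)
  X <- .annMatrix(split, m@potentialNames)
  .gatedSum(m@gates, X, split$A)
}

#' Train the sign-split gated index
#'
#' Minimises the mean square deviation between the index and the annotated
#' effect (deleterious = 1, neutral = 0) over all gate parameters by
#' multi-restart quasi-Newton descent, then selects the classification
#' threshold psi by exhaustive balanced-accuracy scan over the training
#' scores.
#'
#' @param features featurized variant data.frame.
#' @param isDel logical (or 0/1) label vector, TRUE = deleterious.
#' @param config configuration list (`ann_subset` picks the potentials).
#' @param seed,nRestarts,maxit optimisation controls.
#' @return an [AnnModel-class].
#' @export
trainAnn <- function(features, isDel, config = defaultConfig(),
                     seed = 1L, nRestarts = 4L, maxit = 300L) {
  isDel <- as.logical(isDel)
  if (length(unique(isDel)) < 2)
    stop("both classes must be present")
  subset <- as.integer(config$ann_subset)
  potNames <- names(config$potentials)[subset]
  split <- signSplit(features, subset, config)
  X <- .annMatrix(split, potNames)
  # every restart minimises the MSE cost; among the restart optima, keep
  # the one whose index ranks the training labels best (the threshold is
  # BACC-optimal anyway, so this targets the classifier's real objective)
  fit <- .fitGatedSum(X, split$A, as.numeric(isDel), seed, nRestarts, maxit,
                      selectFn = function(pred)
                        optimizeThreshold(pred, isDel, "higher")$bacc)
  scores <- .gatedSum(fit$gates, X, split$A)
  thr <- optimizeThreshold(scores, isDel, direction = "higher")
  new("AnnModel", gates = fit$gates, subset = subset,
      potentialNames = potNames, threshold = thr$threshold,
      trainMse = fit$mse)
}

# log-density matrix helpers ------------------------------------------------

.logSumExp <- function(M) {
  mx <- apply(M, 1, max)
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Per-class log densities log PD(X), log PN(X) under the kernel model.
# `loo` excludes each training sample's own kernel (only meaningful when
# X are the training samples themselves).
.pnnLogDensities <- function(X, isDel, sigma, eta, query, loo = FALSE) {
  p <- ncol(X)
  Zt <- sweep(X, 2, sigma, "/")
  Zq <- sweep(query, 2, sigma, "/")
  sq <- outer(rowSums(Zq^2), rowSums(Zt^2), "+") - 2 * tcrossprod(Zq, Zt)
  logK <- -0.5 * pmax(sq, 0) - (p / 2) * log(2 * pi) - sum(log(sigma))
  if (loo) diag(logK) <- -Inf
  nD <- sum(isDel); nN <- sum(!isDel)
  if (loo) {
    nDi <- nD - isDel
    nNi <- nN - !isDel
  } else {
    nDi <- rep(nD, nrow(query)); nNi <- rep(nN, nrow(query))
  }
  cbind(
    logPD = log(eta[1]) - log(nDi) +
      .logSumExp(logK[, isDel, drop = FALSE]),
    logPN = log(eta[2]) - log(nNi) +
      .logSumExp(logK[, !isDel, drop = FALSE])
  )
}

.pnnFeatures <- function(features, config) {
  potNames <- names(config$potentials)[config$pnn_subset]
  as.matrix(.featureMatrix(features,
                           c(paste0("ddW.", potNames), "dVp", "dVm", "A")))
}

#' Class densities and call of the probabilistic neural network
#'
#' Computes the class-conditional kernel densities P_D and P_N (class-size
#' normalised, eta-weighted sums of per-sample diagonal Gaussian kernels,
#' evaluated in the log domain) and calls a variant deleterious when
#' P_D > P_N, neutral otherwise (ties included).
#'
#' @param m a [PnnModel-class].
#' @param features featurized variant data.frame, or a numeric matrix with
#'   the model's feature columns.
#' @param config configuration list.
#' @return data.frame with columns PD, PN, call.
#' @export
pnnClassify <- function(m, features, config = defaultConfig()) {
  Q <- if (is.matrix(features)) features else .pnnFeatures(features, config)
  ld <- .pnnLogDensities(m@X, m@isDel, m@sigma, m@eta, Q)
  data.frame(
    PD = exp(ld[, "logPD"]), PN = exp(ld[, "logPN"]),
    call = ifelse(ld[, "logPD"] > ld[, "logPN"], "deleterious", "neutral"),
    stringsAsFactors = FALSE
  )
}

#' Train the probabilistic neural network
#'
#' Optimises the p per-feature bandwidths and the two class weights
#' (eta1, eta2) to maximise the balanced accuracy of the leave-one-out
#' classification of the training samples (each sample's own kernel is
#' excluded, otherwise vanishing bandwidths trivially win) by multi-restart
#' derivative-free search; the objective is piecewise constant, so a
#' Nelder-Mead simplex over log-parameters is used. Bandwidths are
#' initialised from per-feature standard deviations, which makes the fit
#' invariant under feature rescaling.
#'
#' @param features featurized variant data.frame (or numeric matrix).
#' @param isDel logical label vector.
#' @param config configuration list (`pnn_subset` picks the potentials).
#' @param seed,nRestarts,maxit optimisation controls.
#' @return a [PnnModel-class].
#' @export
trainPnn <- function(features, isDel, config = defaultConfig(),
                     seed = 1L, nRestarts = 3L, maxit = 200L) {
  isDel <- as.logical(isDel)
  if (length(unique(isDel)) < 2) stop("both classes must be present")
  X <- if (is.matrix(features)) features else .pnnFeatures(features, config)
  p <- ncol(X)
  n <- nrow(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  base <- log(sds * n^(-1 / (p + 4)))       # Silverman-style reference
  negBacc <- function(theta) {
    sigma <- exp(theta[seq_len(p)])
    eta <- exp(theta[p + 1:2])
    ld <- .pnnLogDensities(X, isDel, sigma, eta, X, loo = TRUE)
    del <- ld[, "logPD"] > ld[, "logPN"]
    -bacc(sum(del & isDel), sum(!del & isDel),
          sum(!del & !isDel), sum(del & !isDel))
  }
  best <- NULL
  oldSeed <- globalenv()$.Random.seed
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (r in seq_len(nRestarts)) {
    theta0 <- c(base, 0, 0) +
      if (r == 1) 0 else stats::rnorm(p + 2, 0, 0.5)
    fit <- stats::optim(theta0, negBacc, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  sigma <- exp(best$par[seq_len(p)])
  names(sigma) <- colnames(X)
  new("PnnModel", X = X, isDel = isDel, sigma = sigma,
      eta = exp(best$par[p + 1:2]), featureNames = colnames(X),
      looBacc = -best$value)
}

#' Meta-combiner index
#'
#' J = gamma1 + gamma2 I + gamma3 PRO: affine combination of the
#' sign-split stability index with an external evolutionary conservation
#' score (Provean-style, negative = conserved/deleterious).
#'
#' @param m a [CombinerModel-class].
#' @param I stability index value(s).
#' @param pro external evolutionary score(s); the combiner refuses missing
#'   scores rather than imputing them.
#' @return numeric J value(s).
#' @export
combinerIndex <- function(m, I, pro) {
  if (missing(pro) || is.null(pro) || anyNA(pro))
    stop("external evolutionary score required")
  m@gamma[1] + m@gamma[2] * I + m@gamma[3] * pro
}

#' Train the meta-combiner
#'
#' Selects gamma3 and the classification threshold maximising the balanced
#' accuracy of the J-based call. The (gamma, threshold) scale degeneracy is
#' resolved by fixing gamma2 = 1 and gamma1 = 0: only the relative weight
#' of the external score and the threshold are free. gamma3 is searched
#' over a sign-symmetric geometric grid scaled by sd(I)/sd(PRO) (plus 0 and
#' score-dominant sentinels); the threshold is an exhaustive
#' balanced-accuracy scan at each candidate. Deterministic; ties keep the
#' earliest (smallest-magnitude) candidate.
#'
#' @param I stability index values.
#' @param pro external evolutionary scores.
#' @param isDel logical label vector.
#' @param seed accepted for interface uniformity (the search is
#'   deterministic).
#' @param jD,jN high-confidence band edges stored in the model.
#' @return a [CombinerModel-class].
#' @export
trainCombiner <- function(I, pro, isDel, seed = 1L, jD = 0.9, jN = 0.5) {
  isDel <- as.logical(isDel)
  if (length(unique(isDel)) < 2) stop("both classes must be present")
  if (anyNA(pro)) stop("external evolutionary score required")
  scale <- stats::sd(I) / max(stats::sd(pro), 1e-12)
  if (!is.finite(scale) || scale == 0) scale <- 1
  mags <- scale * 2^seq(-6, 6, by = 0.5)
  cand <- c(0, as.vector(rbind(mags, -mags)), 1e6 * scale, -1e6 * scale)
  best <- NULL
  for (g3 in cand) {
    J <- I + g3 * pro
    thr <- optimizeThreshold(J, isDel, direction = "higher")
    if (is.null(best) || thr$bacc > best$bacc)
      best <- list(g3 = g3, threshold = thr$threshold, bacc = thr$bacc)
  }
  new("CombinerModel", gamma = c(0, 1, best$g3), threshold = best$threshold,
      jD = jD, jN = jN, trainBacc = best$bacc)
}

#' High-confidence band of a J value
#'
#' Three-way band assignment with inclusive edges: J >= jD is
#' high-confidence deleterious, J <= jN high-confidence neutral, anything
#' between is uncertain.
#'
#' @param m a [CombinerModel-class] (slots jD, jN).
#' @param J index value(s).
#' @return character vector in {"high_conf_deleterious",
#'   "high_conf_neutral", "uncertain"}.
#' @export
confidenceBand <- function(m, J) {
  ifelse(J >= m@jD, "high_conf_deleterious",
         ifelse(J <= m@jN, "high_conf_neutral", "uncertain"))
}
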