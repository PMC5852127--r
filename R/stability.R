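# Sigmoid accessibility-gated linear models: the shared parametric form of
# the free-energy (ddG) and melting-temperature (dTm) predictors and of the
# sign-split pathogenicity index. Each term's weight is
#   alpha(A) = omega / (1 + exp(-nu (A - xi))) + phi,
# a sigmoid in the mutated residue's solvent accessibility A.

#' Evaluate a sigmoid accessibility gate
#'
#' alpha(A) = omega / (1 + exp(-nu (A - xi))) + phi, numerically stable for
#' large |nu (A - xi)|.
#'
#' @param omega amplitude.
#' @param nu steepness (per percent accessibility).
#' @param xi midpoint (percent).
#' @param phi offset.
#' @param A solvent accessibility value(s) in [0, 100].
#' @return gate weight(s).
#' @export
gateValue <- function(omega, nu, xi, phi, A) {
  omega * stats::plogis(nu * (A - xi)) + phi
}

# n x k weight matrix for a 4 x k gate parameter matrix at accessibilities A.
.gateWeights <- function(par, A) {
  sig <- stats::plogis(outer(A, par["xi", ], "-") *
                         rep(par["nu", ], each = length(A)))
  sweep(sig, 2, par["omega", ], "*") +
    matrix(par["phi", ], length(A), ncol(par), byrow = TRUE)
}

.gatedSum <- function(par, X, A) rowSums(X * .gateWeights(par, A))

# Mean squared error of the gated sum and its analytic gradient in the gate
# parameters (used by the quasi-Newton fit).
.gatedMseGrad <- function(theta, X, A, y, k) {
  par <- matrix(theta, 4, k, dimnames = list(c("omega", "nu", "xi", "phi")))
  z <- outer(A, par["xi", ], "-") * rep(par["nu", ], each = length(A))
  sig <- stats::plogis(z)
  W <- sweep(sig, 2, par["omega", ], "*") +
    matrix(par["phi", ], length(A), k, byrow = TRUE)
  r <- rowSums(X * W) - y
  n <- length(y)
  G <- X * (2 * r / n)                       # dMSE/dW, n x k
  dsig <- sig * (1 - sig)
  Ax <- outer(A, par["xi", ], "-")
  grad <- rbind(
    omega = colSums(G * sig),
    nu    = colSums(G * dsig * Ax) * par["omega", ],
    xi    = -colSums(G * dsig) * par["omega", ] * par["nu", ],
    phi   = colSums(G)
  )
  list(mse = mean(r^2), grad = as.vector(grad))
}

# Multi-restart quasi-Newton minimisation of the gated-sum MSE.
# Deterministic given seed; restarts are randomised around a flat linear
# least-squares initialisation (nu = 0 makes the model exactly linear).
# Each restart minimises the MSE; `selectFn(pred)`, when given, picks the
# returned restart (e.g. by training balanced accuracy for classifiers),
# otherwise the lowest-MSE restart wins.
.fitGatedSum <- function(X, A, y, seed = 1L, nRestarts = 5L, maxit = 300L,
                         selectFn = NULL) {
  k <- ncol(X)
  # for fixed (nu, xi) the model is linear in (omega, phi): solve that
  # least-squares problem exactly to seed each restart
  seedFit <- function(nu, xi) {
    sig <- stats::plogis(nu * (A - xi))
    co <- tryCatch(
      suppressWarnings(   # collinear split features: NA coefs zeroed below
        stats::lsfit(cbind(X * sig, X), y, intercept = FALSE)$coefficients),
      error = function(e) rep(0, 2 * k))
    co[!is.finite(co)] <- 0
    as.vector(rbind(omega = co[seq_len(k)], nu = rep(nu, k),
                    xi = rep(xi, k), phi = co[k + seq_len(k)]))
  }
  starts <- list(c(0.05, 40), c(-0.3, 20), c(-0.15, 60), c(0.3, 20),
                 c(0.15, 60))
  best <- NULL
  oldSeed <- globalenv()$.Random.seed
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                        envir = globalenv()), add = TRUE)
  set.seed(seed)
  for (r in seq_len(nRestarts)) {
    theta0 <- if (r <= length(starts))
      seedFit(starts[[r]][1], starts[[r]][2])
    else as.vector(rbind(stats::rnorm(k, 0, 0.5),
                         stats::runif(k, -0.3, 0.3),
                         stats::runif(k, 0, 100),
                         stats::rnorm(k, 0, 0.5)))
    fit <- stats::optim(theta0,
                        fn = function(th) .gatedMseGrad(th, X, A, y, k)$mse,
                        gr = function(th) .gatedMseGrad(th, X, A, y, k)$grad,
                        method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    fit$crit <- if (is.null(selectFn)) -fit$value
    else {
      p <- matrix(fit$par, 4, k,
                  dimnames = list(c("omega", "nu", "xi", "phi")))
      selectFn(.gatedSum(p, X, A))
    }
    if (is.null(best) || fit$crit > best$crit) best <- fit
  }
  par <- matrix(best$par, 4, k,
                dimnames = list(c("omega", "nu", "xi", "phi"), colnames(X)))
  list(gates = par, mse = best$value)
}

.featureMatrix <- function(features, terms) {
  miss <- setdiff(setdiff(terms, "intercept"), names(features))
  if (length(miss))
    stop("feature columns missing: ", paste(miss, collapse = ", "))
  X <- matrix(0, nrow(features), length(terms),
              dimnames = list(NULL, terms))
  for (t in terms)
    X[, t] <- if (t == "intercept") 1 else features[[t]]
  X
}

#' Predict folding free-energy change (ddG form)
#'
#' ddG = sum_i alpha_i(A) ddW_i + alpha_dVp(A) dVp + alpha_dVm(A) dVm +
#' alpha_0(A), every gate evaluated at the variant's accessibility; positive
#' values are destabilizing.
#'
#' @param m a [GatedLinearModel-class] of kind "ddg".
#' @param features data.frame with the model's term columns plus `A`.
#' @return predicted ddG, kcal/mol.
#' @export
predictDdg <- function(m, features) {
  if (m@kind != "ddg") stop("model is not of kind 'ddg'")
  X <- .featureMatrix(features, m@terms)
  .gatedSum(m@gates, X, features$A)
}

#' Predict melting-temperature change (dTm form)
#'
#' dTm = 1/(a Nr + b) * sum_i beta_i(A) ddW_i + beta_dVp(A) dVp +
#' beta_dVm(A) dVm + beta_0(A): only the potential-term sum carries the
#' protein-size prefactor; the volume and intercept terms are added outside
#' it, exactly as the model form is written. Negative values are thermally
#' destabilizing.
#'
#' @param m a [GatedLinearModel-class] of kind "dtm" (slot `sizeScaling`
#'   holds (a, b)).
#' @param features data.frame with the model's term columns plus `A`.
#' @param Nr number of residues of the protein.
#' @return predicted dTm, degrees C.
#' @export
predictDtm <- function(m, features, Nr) {
  if (m@kind != "dtm") stop("model is not of kind 'dtm'")
  a <- m@sizeScaling[[1]]; b <- m@sizeScaling[[2]]
  pref <- a * Nr + b
  if (pref == 0) stop("a * Nr + b is zero")
  X <- .featureMatrix(features, m@terms)
  W <- .gateWeights(m@gates, features$A)
  isPot <- grepl("^ddW\\.", m@terms)
  rowSums((X * W)[, isPot, drop = FALSE]) / pref +
    rowSums((X * W)[, !isPot, drop = FALSE])
}

#' Fit a gated linear stability model
#'
#' Least-squares fit of all sigmoid gate parameters simultaneously by
#' multi-restart quasi-Newton minimisation of the mean squared deviation
#' between predicted and observed targets (analytic gradient). With all
#' steepnesses at zero the model is an ordinary linear least-squares fit,
#' which is used as the first restart's initialisation. Individual gate
#' parameters are not identifiable; recovery is judged on predictions.
#'
#' @param features data.frame with `ddW.*`, `dVp`, `dVm` and `A` columns.
#' @param target numeric vector of observed stability changes.
#' @param kind "ddg" (16 terms: 13 potentials + dVp + dVm + intercept) or
#'   "dtm" (12 terms: 9 potentials + dVp + dVm + intercept; the (a, b) size
#'   scaling is taken from the configuration, and `Nr` must then be given).
#' @param config configuration list.
#' @param Nr protein size(s), required for kind "dtm".
#' @param seed,nRestarts,maxit optimisation controls (deterministic given
#'   seed).
#' @return a fitted [GatedLinearModel-class].
#' @export
fitGatedModel <- function(features, target, kind = c("ddg", "dtm"),
                          config = defaultConfig(), Nr = NULL,
                          seed = 1L, nRestarts = 5L, maxit = 300L) {
  kind <- match.arg(kind)
  # all-zero targets are a legitimate limit; any other constant is degenerate
  if (stats::var(target) == 0 && any(target != 0))
    stop("degenerate targets: zero variance")
  potNames <- names(config$potentials)
  sub <- if (kind == "ddg") seq_along(potNames) else config$dtm_subset
  terms <- c(paste0("ddW.", potNames[sub]), "dVp", "dVm", "intercept")
  X <- .featureMatrix(features, terms)
  if (nrow(X) < 10 * (4 * ncol(X)))
    warning("fewer than 10 samples per parameter; fit may be unstable")
  if (kind == "dtm") {
    if (is.null(Nr)) stop("Nr required for kind 'dtm'")
    a <- config$dtm_size_scaling[[1]]; b <- config$dtm_size_scaling[[2]]
    pref <- a * Nr + b
    if (any(pref == 0)) stop("a * Nr + b is zero")
    isPot <- grepl("^ddW\\.", terms)
    X[, isPot] <- X[, isPot, drop = FALSE] / pref
  }
  fit <- .fitGatedSum(X, features$A, target, seed, nRestarts, maxit)
  new("GatedLinearModel", gates = fit$gates, terms = terms, kind = kind,
      sizeScaling = if (kind == "dtm") config$dtm_size_scaling else c(0, 1),
      trainMse = fit$mse)
}

#' Single-threshold deleterious/neutral call
#'
#' Direction-aware comparison of a stability score with a threshold: for
#' "higher" (the ddG convention) scores strictly above the threshold are
#' deleterious; for "lower" (the dTm convention) scores strictly below it.
#' Ties are called neutral.
#'
#' @param score numeric score(s).
#' @param threshold decision threshold, score units.
#' @param direction "higher" or "lower" is deleterious.
#' @return character vector "deleterious"/"neutral".
#' @export
classifyByThreshold <- function(score, threshold,
                                direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  del <- if (direction == "higher") score > threshold else score < threshold
  ifelse(del, "deleterious", "neutral")
}
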