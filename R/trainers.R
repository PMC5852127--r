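# Trainer factories: each returns a function(data, seed) usable by
# crossValidate(), closing over the configuration and returning the common
# score/threshold/direction interface.

#' Cross-validation trainer factories
#'
#' Each factory returns a `function(data, seed)` for [crossValidate()]:
#' `annTrainer` fits the sign-split gated index and its BACC-optimal
#' threshold; `pnnTrainer` fits the probabilistic neural network (score is
#' the log-density margin log PD - log PN, threshold 0); `combinerTrainer`
#' fits the gated index on the training fold, then the meta-combiner on its
#' index and the `pro` column; `accessibilityTrainer` uses the solvent
#' accessibility alone (lower = more likely deleterious) with a
#' BACC-optimal threshold.
#'
#' @param config configuration list.
#' @param nRestarts,maxit optimisation controls passed through.
#' @return a trainer function(data, seed).
#' @name trainers
NULL

#' @rdname trainers
#' @export
annTrainer <- function(config = defaultConfig(), nRestarts = 4L,
                       maxit = 300L) {
  function(data, seed = 1L) {
    m <- trainAnn(data, data$isDel, config, seed = seed,
                  nRestarts = nRestarts, maxit = maxit)
    list(score = function(d) annIndex(m, d, config),
         threshold = m@threshold, direction = "higher", model = m)
  }
}

#' @rdname trainers
#' @export
pnnTrainer <- function(config = defaultConfig(), nRestarts = 2L,
                       maxit = 150L) {
  function(data, seed = 1L) {
    m <- trainPnn(data, data$isDel, config, seed = seed,
                  nRestarts = nRestarts, maxit = maxit)
    list(
      score = function(d) {
        Q <- .pnnFeatures(d, config)
        ld <- .pnnLogDensities(m@X, m@isDel, m@sigma, m@eta, Q)
        ld[, "logPD"] - ld[, "logPN"]
      },
      threshold = 0, direction = "higher", model = m)
  }
}

#' @rdname trainers
#' @export
combinerTrainer <- function(config = defaultConfig(), nRestarts = 4L,
                            maxit = 300L) {
  function(data, seed = 1L) {
    if (!"pro" %in% names(data))
      stop("external evolutionary score column 'pro' required")
    ann <- trainAnn(data, data$isDel, config, seed = seed,
                    nRestarts = nRestarts, maxit = maxit)
    I <- annIndex(ann, data, config)
    cmb <- trainCombiner(I, data$pro, data$isDel, seed = seed)
    list(
      score = function(d) combinerIndex(cmb, annIndex(ann, d, config),
                                        d$pro),
      threshold = cmb@threshold, direction = "higher",
      model = list(ann = ann, combiner = cmb))
  }
}

#' @rdname trainers
#' @export
accessibilityTrainer <- function(config = defaultConfig()) {
  function(data, seed = 1L) {
    thr <- optimizeThreshold(data$A, data$isDel, direction = "lower")
    list(score = function(d) d$A, threshold = thr$threshold,
         direction = "lower")
  }
}
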