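#' Configuration for the backpropagation network screen
#'
#' A p-hidden-1 feedforward regressor (sigmoidal hidden layer, linear
#' output) is trained per endpoint on min-max scaled inputs and output.
#' Because ~10 batches make a single held-out split near-degenerate, the
#' screen trains an ensemble of `ensemble` seeded restarts (each with its
#' own random 80/20 train/test split) and averages the mean impact values
#' across members to tame initialisation noise.
#'
#' @param hidden Hidden units (default 3, the p-3-1 architecture).
#' @param train_fraction Fraction of batches used for training (default
#'   0.8; the rest form the test set of the fit report).
#' @param maxit Maximum training epochs (default 2000).
#' @param decay Weight decay of the optimiser (default 1e-3; a little
#'   regularisation keeps the tiny-sample fit stable).
#' @param ensemble Number of seeded restarts R (default 20).
#' @param seed Base seed; member i uses `seed + i`.
#' @return List of class `ann_config`.
#' @export
ann_config <- function(hidden = 3, train_fraction = 0.8, maxit = 2000,
                       decay = 1e-3, ensemble = 20, seed = 1L) {
  if (hidden < 1) stop("hidden must be >= 1")
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  if (ensemble < 1) stop("ensemble must be >= 1")
  structure(list(hidden = hidden, train_fraction = train_fraction,
                 maxit = maxit, decay = decay, ensemble = ensemble,
                 seed = as.integer(seed)),
            class = "ann_config")
}

#' Train a single-hidden-layer feedforward network
#'
#' Wraps a gradient-trained sigmoidal-hidden/linear-output regressor
#' (`nnet`) behind min-max input/output scaling. Identical data and seed
#' give identical weights. The fit report carries R-squared on the training
#' split, the held-out test split, and the whole set.
#'
#' @param X Numeric matrix, samples x inputs (original scale).
#' @param y Numeric response (original scale); must have positive variance.
#' @param config An [ann_config()].
#' @param seed Seed for the split and the weight initialisation (default
#'   `config$seed`).
#' @return Object of class `ann_fit`: the underlying network, the scaling,
#'   the split, and `report` (r2_train, r2_test, r2_whole, converged).
#' @export
train_ann <- function(X, y, config = ann_config(), seed = config$seed) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("X and y must be finite")
  if (sd(y) == 0) stop("response has zero variance")
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  scale_x <- function(M) sweep(sweep(M, 2, rng[1, ]), 2, span, "/")
  ymin <- min(y); yspan <- max(y) - ymin
  Xs <- scale_x(X)
  ys <- (y - ymin) / yspan

  set.seed(as.integer(seed))
  train <- sort(sample.int(n, max(2, round(config$train_fraction * n))))
  test <- setdiff(seq_len(n), train)
  net <- nnet::nnet(Xs[train, , drop = FALSE], ys[train],
                    size = config$hidden, linout = TRUE, trace = FALSE,
                    maxit = config$maxit, decay = config$decay,
                    MaxNWts = 100000)
  converged <- isTRUE(net$convergence == 0) || net$value < 1e-8
  if (!converged)
    warning("network did not converge within ", config$maxit,
            " epochs; best-so-far weights kept")
  r2 <- function(idx) {
    if (!length(idx)) return(NA_real_)
    pred <- drop(predict(net, Xs[idx, , drop = FALSE]))
    obs <- ys[idx]
    if (var(obs) == 0) return(NA_real_)
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  structure(list(net = net, rng = rng, span = span, ymin = ymin,
                 yspan = yspan, peaks = colnames(X), train = train,
                 test = test, seed = seed,
                 report = list(r2_train = r2(train), r2_test = r2(test),
                               r2_whole = r2(seq_len(n)),
                               converged = converged)),
            class = "ann_fit")
}

#' @export
predict.ann_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$peaks) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$peaks, drop = FALSE]
  Xs <- sweep(sweep(newdata, 2, object$rng[1, ]), 2, object$span, "/")
  drop(predict(object$net, Xs)) * object$yspan + object$ymin
}

#' Train an ensemble of seeded network restarts
#'
#' @inheritParams train_ann
#' @return List of `ann_fit` objects (length `config$ensemble`).
#' @export
train_ann_ensemble <- function(X, y, config = ann_config()) {
  lapply(seq_len(config$ensemble),
         function(i) train_ann(X, y, config, seed = config$seed + i))
}

#' Mean impact values by input perturbation
#'
#' For each input `j`, two simulation datasets are formed from the
#' *original-scale* data: one with column `j` multiplied by `1 + delta`, one
#' by `1 - delta` (default +/-10%). The impact value of input `j` on sample
#' `i` is the difference of the model predictions on the two perturbed
#' copies; the MIV is the mean over samples, then over ensemble members.
#' Its sign gives the correlation direction, its magnitude the strength.
#'
#' @param models A fitted model or list of fitted models; anything with a
#'   `predict(model, newdata)` method on original-scale matrices works
#'   (`ann_fit` ensembles in the pipeline).
#' @param X Original-scale input matrix (samples x inputs).
#' @param delta Perturbation fraction in (0, 1) (default 0.10).
#' @return Object of class `miv_result`: `miv` (named vector), `iv`
#'   (samples x inputs matrix, ensemble-averaged), `delta`, `reports` (fit
#'   reports when available).
#' @export
miv_scores <- function(models, X, delta = 0.10) {
  if (!identical(class(models), "list")) models <- list(models)
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop("delta must be in (0, 1)")
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  # one stacked prediction per direction and model: rows are p blocks of n
  perturb <- function(fac) {
    blocks <- lapply(seq_len(p), function(j) {
      Z <- X; Z[, j] <- Z[, j] * fac; Z
    })
    do.call(rbind, blocks)
  }
  # data.frames so both matrix-based (ann_fit) and formula-based (lm)
  # predictors accept the perturbed copies
  up <- as.data.frame(perturb(1 + delta))
  dn <- as.data.frame(perturb(1 - delta))
  names(up) <- names(dn) <- colnames(X)
  iv <- matrix(0, n, p, dimnames = list(rownames(X), colnames(X)))
  for (m in models) {
    d <- predict(m, up) - predict(m, dn)
    iv <- iv + matrix(d, n, p)
  }
  iv <- iv / length(models)
  reports <- lapply(models, function(m)
    if (inherits(m, "ann_fit")) m$report else NULL)
  structure(list(miv = colMeans(iv), iv = iv, delta = delta,
                 reports = reports),
            class = "miv_result")
}

#' Select peaks with positive mean impact value
#'
#' Inputs with MIV > 0 are positively correlated with the effect and kept.
#'
#' @param result A `miv_result`.
#' @return Character vector of selected peak ids.
#' @export
miv_select <- function(result) {
  stopifnot(inherits(result, "miv_result"))
  names(result$miv)[result$miv > 0]
}

#' BP-ANN + MIV screen of peaks against each effect endpoint
#'
#' Per endpoint: train the seeded ensemble on the oriented activity, compute
#' ensemble-averaged MIVs with +/-10% perturbation of the original areas,
#' and select peaks with positive MIV.
#'
#' @inheritParams gra_select
#' @param config An [ann_config()]; the per-endpoint base seed is offset so
#'   endpoints do not share initialisations.
#' @param delta Perturbation fraction (default 0.10).
#' @return Object of class `ann_result`: per endpoint `scores` (peak, miv),
#'   `selected`, and the ensemble fit `reports`.
#' @export
ann_screen <- function(matrix, effects, config = ann_config(), delta = 0.10) {
  A <- if (inherits(matrix, "common_peak_matrix")) matrix$areas else matrix
  stopifnot(inherits(effects, "effect_table"))
  out <- list()
  eps <- effects$meta$endpoint
  for (i in seq_along(eps)) {
    e <- eps[i]
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 1000L
    ens <- train_ann_ensemble(A, effects$activity[[e]], cfg)
    mv <- miv_scores(ens, A, delta = delta)
    out[[e]] <- list(
      scores = data.frame(peak = colnames(A), miv = unname(mv$miv),
                          stringsAsFactors = FALSE),
      selected = miv_select(mv),
      reports = mv$reports)
  }
  structure(list(endpoints = out, config = config, delta = delta),
            class = "ann_result")
}

#' @export
print.ann_result <- function(x, ...) {
  cat("BP-ANN + MIV screen (", x$config$hidden, "hidden units, ensemble of",
      x$config$ensemble, ", +/-", x$delta * 100, "% perturbation)\n")
  for (e in names(x$endpoints))
    cat(sprintf("  %-10s %d peaks with MIV > 0\n", e,
                length(x$endpoints[[e]]$selected)))
  invisible(x)
}
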