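#' Normalise sequences for grey relational analysis
#'
#' Raw peak areas and oriented activities differ by orders of magnitude and
#' Deng's grey coefficients are scale-sensitive, so reference and comparison
#' sequences are put on a common footing first. Modes:
#' \describe{
#'   \item{zscore}{centre and scale to unit variance (default for the
#'     screening pipeline: it is both scale- and offset-invariant, which the
#'     orientation-reflected activities require);}
#'   \item{mean}{divide each sequence by its own mean (classical
#'     initial-value style normalisation; scale-free, keeps positivity);}
#'   \item{minmax}{map each sequence onto [0, 1];}
#'   \item{none}{use the sequences as given.}
#' }
#'
#' @param x Numeric vector, or a matrix whose columns are sequences.
#' @param mode Normalisation mode.
#' @return Same shape as `x`.
#' @export
gra_normalize <- function(x, mode = c("zscore", "mean", "minmax", "none")) {
  mode <- match.arg(mode)
  norm1 <- function(v) {
    switch(mode,
      none = v,
      mean = {
        if (mean(v) == 0) stop("zero-mean sequence cannot be mean-normalised")
        v / mean(v)
      },
      minmax = {
        r <- max(v) - min(v)
        if (r == 0) stop("constant sequence cannot be min-max normalised")
        (v - min(v)) / r
      },
      zscore = {
        s <- sd(v)
        if (s == 0) stop("constant sequence cannot be z-score normalised")
        (v - mean(v)) / s
      })
  }
  if (is.matrix(x)) apply(x, 2, norm1) else norm1(x)
}

#' Deng's grey relational coefficients and degree
#'
#' For a reference sequence `x0(k)` and comparison sequences `xi(k)`
#' (columns of `X`), with deltas `D_i(k) = |x0(k) - xi(k)|` and the global
#' minimum `Dmin` and maximum `Dmax` taken jointly over *all* comparison
#' sequences and positions:
#' \deqn{\xi_i(k) = (Dmin + \rho Dmax) / (D_i(k) + \rho Dmax)}
#' \deqn{r_i = (1/N) \sum_k \xi_i(k)}
#' with resolution coefficient `rho` (default 0.5). Coefficients lie in
#' (0, 1]; `r_i = 1` iff `xi` coincides with `x0` and the global minimum
#' delta is 0. Sequences are used as given -- normalise first (see
#' [gra_normalize()]).
#'
#' @param x0 Reference sequence (length N >= 2).
#' @param X Comparison sequences: vector or N x p matrix.
#' @param rho Resolution coefficient in (0, 1].
#' @param global Use the joint min/max over all comparison sequences
#'   (default, following the double min/max of the defining formula); if
#'   `FALSE`, each sequence uses its own min/max deltas.
#' @return List: `xi` (N x p matrix of coefficients), `r` (named vector of
#'   grey relational degrees).
#' @export
grey_degree <- function(x0, X, rho = 0.5, global = TRUE) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  if (length(x0) != nrow(X))
    stop("length mismatch: x0 has ", length(x0), " points, sequences have ",
         nrow(X))
  if (length(x0) < 2) stop("sequences must have length >= 2")
  if (!is.numeric(rho) || rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  D <- abs(X - x0)
  if (global) {
    dmin <- min(D); dmax <- max(D)
    xi <- (dmin + rho * dmax) / (D + rho * dmax)
  } else {
    xi <- apply(D, 2, function(d) (min(d) + rho * max(d)) / (d + rho * max(d)))
  }
  if (any(!is.finite(xi)))
    xi[!is.finite(xi)] <- 1  # all deltas zero: identical sequences
  dimnames(xi) <- dimnames(X)
  list(xi = xi, r = colMeans(xi))
}

#' Grey relational screen of peaks against each effect endpoint
#'
#' For every endpoint, the oriented activity is the reference sequence and
#' every peak's area profile a comparison sequence; peaks whose grey
#' relational degree exceeds the threshold (strict inequality, "over 0.8")
#' are selected.
#'
#' @param matrix A `common_peak_matrix`, or a plain batches x peaks matrix.
#'   Restrict to linearity-retained peaks beforehand (see
#'   [restrict_peaks()]).
#' @param effects An `effect_table` from [assemble_effects()].
#' @param threshold Selection threshold on the degree, in (0, 1].
#' @param rho Resolution coefficient (default 0.5).
#' @param normalize Normalisation mode, see [gra_normalize()].
#' @param global Joint min/max deltas (default) or per-sequence.
#' @return Object of class `gra_result`: per endpoint, a list with `scores`
#'   (data.frame peak, degree) and `selected` (character vector); plus the
#'   parameters used.
#' @export
gra_select <- function(matrix, effects, threshold = 0.8, rho = 0.5,
                       normalize = "zscore", global = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  A <- if (inherits(matrix, "common_peak_matrix")) matrix$areas else matrix
  stopifnot(inherits(effects, "effect_table"))
  An <- gra_normalize(A, mode = normalize)
  out <- list()
  for (e in effects$meta$endpoint) {
    x0 <- gra_normalize(effects$activity[[e]], mode = normalize)
    gd <- grey_degree(x0, An, rho = rho, global = global)
    scores <- data.frame(peak = colnames(A), degree = unname(gd$r),
                         stringsAsFactors = FALSE)
    out[[e]] <- list(scores = scores,
                     selected = scores$peak[scores$degree > threshold])
  }
  structure(list(endpoints = out, threshold = threshold, rho = rho,
                 normalize = normalize, global = global),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat("Grey relational screen (rho =", x$rho, ", threshold >", x$threshold,
      ",", x$normalize, "normalisation)\n")
  for (e in names(x$endpoints))
    cat(sprintf("  %-10s %d peaks selected\n", e,
                length(x$endpoints[[e]]$selected)))
  invisible(x)
}
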