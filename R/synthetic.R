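#' Default effect-endpoint definitions
#'
#' The six endpoints of the study design: DPPH radical scavenging (summarised
#' as an IC50, mg/mL, lower = more active), FRAP ferric-reducing power
#' (umol/L Fe2+ equivalents, higher = more active), A549 cell viability (%,
#' lower = more active), relative wound-healing rate (%, lower = more
#' active), and transwell migrated / invaded cell counts (lower = more
#' active).
#'
#' `enc_a` and `enc_b` parameterise how the latent activity L of a batch is
#' encoded into the raw assay readout by the synthetic generator:
#' `ic50` family uses `raw = enc_a / L`; `concentration` uses
#' `raw = enc_a * L + enc_b`; `percentage` and `count` use the bounded
#' decreasing form `raw = enc_a * exp(-L / enc_b)` (a readout such as a
#' healing rate or a cell count cannot cross zero, so the decreasing
#' families saturate instead of going linear).
#'
#' @return A data.frame with columns `endpoint`, `family`, `unit`,
#'   `larger_raw_more_active`, `enc_a`, `enc_b`.
#' @export
default_endpoints <- function() {
  data.frame(
    endpoint = c("dpph", "frap", "viability", "wound", "migration", "invasion"),
    family = c("ic50", "concentration", "percentage", "percentage",
               "count", "count"),
    unit = c("mg/mL", "umol/L", "%", "%", "cells", "cells"),
    larger_raw_more_active = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    enc_a = c(25, 55, 100, 45, 70, 28),
    enc_b = c(NA, 100, 12, 16, 10, 10),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic spectrum-effect dataset
#'
#' Defines the study conditions a generated dataset emulates: 10 preparation
#' batches profiled over ~70 common LC-MS peaks, with a planted subset of
#' "active" peaks per endpoint whose areas drive that endpoint's latent
#' activity through a linear (or saturating) link, plus assay-level noise.
#'
#' Peak areas are log-normal (positive, right-skewed, heavy dispersion, as
#' LC-MS areas are). Planted active peaks of an endpoint additionally share
#' a latent per-batch extraction factor with loading `co_extraction` on the
#' log scale, emulating constituents of a common herb/fraction whose yield
#' moves together across decoction conditions; this shared variation is what
#' makes individual active peaks track the activity.
#'
#' @param n_batches Number of preparation batches (rows). Default 10.
#' @param n_peaks Number of common peaks (columns). Default 70.
#' @param active_sets Named list, endpoint name -> integer vector of planted
#'   active peak indices (1-based, `< n_peaks`). Default: 8 peaks per
#'   endpoint, sampled from `seed`.
#' @param link Link family from planted areas to latent activity:
#'   `"linear"` (weighted sum of mean-normalised areas) or `"saturating"`
#'   (Michaelis-Menten transform of that sum).
#' @param coefficients Named list, endpoint -> positive link coefficients
#'   (one per planted peak). Default all 1 (equal expected contributions).
#' @param area_meanlog Per-peak log-area locations; default drawn uniformly
#'   on [2, 5] from `seed`.
#' @param area_sdlog Idiosyncratic log-area scale (default 0.5, CV ~ 53%).
#' @param co_extraction Loading of the shared extraction factor on planted
#'   peaks' log areas (default 1.0, ~80% shared log-variance).
#' @param noise_sd Relative (multiplicative, CV-style) assay noise on the
#'   latent activity (default 0.05, i.e. a 5% coefficient of variation).
#' @param batch_effect Standard deviation of an optional multiplicative
#'   per-batch log-scale factor applied to all peaks (default 0 = off).
#' @param endpoints Endpoint definition table, see [default_endpoints()].
#' @param seed Integer seed; identical (spec, seed) pairs reproduce output
#'   bit for bit.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_batches = 10, n_peaks = 70, active_sets = NULL,
                           link = c("linear", "saturating"),
                           coefficients = NULL, area_meanlog = NULL,
                           area_sdlog = 0.5, co_extraction = 1.0,
                           noise_sd = 0.05, batch_effect = 0,
                           endpoints = default_endpoints(), seed = 1L) {
  link <- match.arg(link)
  if (!is.numeric(n_batches) || length(n_batches) != 1 || n_batches < 3)
    stop("n_batches: must be a single count >= 3")
  if (!is.numeric(n_peaks) || length(n_peaks) != 1 || n_peaks < 1)
    stop("n_peaks: must be a single positive count")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd: must be >= 0")
  if (!is.numeric(area_sdlog) || area_sdlog < 0)
    stop("area_sdlog: must be >= 0")
  n_batches <- as.integer(n_batches)
  n_peaks <- as.integer(n_peaks)
  seed <- as.integer(seed)

  set.seed(seed)
  if (is.null(active_sets)) {
    # default planted sets are disjoint across endpoints: each endpoint's
    # ground truth is then unambiguous (a peak planted for two endpoints
    # would respond to two independent extraction factors and track neither
    # cleanly); overlapping sets can still be planted explicitly
    k <- min(8L, n_peaks %/% nrow(endpoints))
    if (k < 1) stop("n_peaks: too few peaks for one active peak per endpoint")
    pool <- sample.int(n_peaks, k * nrow(endpoints))
    active_sets <- lapply(seq_len(nrow(endpoints)), function(i)
      sort(pool[((i - 1) * k + 1):(i * k)]))
    names(active_sets) <- endpoints$endpoint
  }
  if (is.null(names(active_sets)) || any(!nzchar(names(active_sets))))
    stop("active_sets: must be a named list (endpoint -> peak indices)")
  if (!all(names(active_sets) %in% endpoints$endpoint))
    stop("active_sets: unknown endpoint name(s): ",
         paste(setdiff(names(active_sets), endpoints$endpoint), collapse = ", "))
  for (e in names(active_sets)) {
    idx <- active_sets[[e]]
    if (length(idx) == 0 || any(idx < 1) || any(idx > n_peaks) ||
        any(idx != as.integer(idx)))
      stop("active_sets: indices for '", e, "' must be integers in [1, n_peaks]")
    active_sets[[e]] <- sort(as.integer(idx))
  }
  if (is.null(coefficients)) {
    coefficients <- lapply(active_sets, function(idx) rep(1, length(idx)))
  }
  for (e in names(active_sets)) {
    b <- coefficients[[e]]
    if (is.null(b) || length(b) != length(active_sets[[e]]) || any(b <= 0))
      stop("coefficients: '", e, "' needs one positive coefficient per active peak")
  }
  if (is.null(area_meanlog)) area_meanlog <- runif(n_peaks, 2, 5)
  if (length(area_meanlog) != n_peaks)
    stop("area_meanlog: length must equal n_peaks")

  structure(
    list(n_batches = n_batches, n_peaks = n_peaks,
         active_sets = active_sets, link = link, coefficients = coefficients,
         area_meanlog = area_meanlog, area_sdlog = area_sdlog,
         co_extraction = co_extraction, noise_sd = noise_sd,
         batch_effect = batch_effect,
         endpoints = endpoints[endpoints$endpoint %in% names(active_sets), ,
                               drop = FALSE],
         seed = seed),
    class = "synthetic_spec"
  )
}

# Latent activity of each batch from planted areas (before assay encoding).
# Areas are normalised by their expected mean so equal coefficients mean
# equal expected contributions.
.latent_activity <- function(areas, idx, beta, meanlog, sdlog2, link) {
  anorm <- sweep(areas[, idx, drop = FALSE], 2,
                 exp(meanlog[idx] + sdlog2[idx] / 2), "/")
  s <- drop(anorm %*% beta)
  if (link == "saturating") {
    k <- sum(beta)  # half-saturation at the expected signal level
    s <- 2 * k * s / (s + k)
  }
  s
}

# Encode latent activity into the raw readout of one endpoint family.
.encode_raw <- function(L, family, enc_a, enc_b) {
  switch(family,
    ic50 = enc_a / L,
    concentration = enc_a * L + enc_b,
    percentage = enc_a * exp(-L / enc_b),
    count = enc_a * exp(-L / enc_b),
    stop("unknown endpoint family: ", family)
  )
}

#' Generate a synthetic spectrum-effect dataset with known ground truth
#'
#' Draws a common-peak matrix (batches x peaks, strictly positive log-normal
#' areas), computes each endpoint's latent activity as the spec's link
#' applied to the planted peaks' areas, adds assay noise, and encodes the
#' result on each assay's native raw scale (IC50-like endpoints decrease
#' with activity, percentages/counts are bounded and decreasing, FRAP-like
#' concentrations are linear increasing). The returned truth records the
#' planted sets and link coefficients so downstream screens can be graded.
#'
#' The internal-standard peak is a non-active peak given a near-zero
#' dispersion (a spiked reference compound is nominally constant).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `matrix` (a `common_peak_matrix`),
#'   `effects_raw` (data.frame of raw per-batch endpoint values),
#'   `effects` (an `effect_table`, see [assemble_effects()]),
#'   `truth` (class `synthetic_truth`: active sets by peak id and index,
#'   link family and coefficients, latent activities).
#' @export
gen_spectrum_effect <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  set.seed(spec$seed)
  n <- spec$n_batches; p <- spec$n_peaks
  eps <- names(spec$active_sets)

  # peak metadata: consensus RT over the gradient, ion mode, P-numbering
  # within ion-mode blocks (positive block first, each ordered by RT).
  # RTs sit on a jittered grid so neighbouring peaks stay separable at the
  # usual matching tolerance (real common peaks are resolved by definition)
  grid_step <- 46 / max(p, 2)
  rt <- 2 + (seq_len(p) - 0.5) * grid_step +
    runif(p, -0.15, 0.15) * min(grid_step, 1)
  mode <- sample(c("positive", "negative"), p, replace = TRUE)
  ord <- order(mode != "positive", rt)
  rt <- rt[ord]; mode <- mode[ord]
  # area_meanlog stays peak-indexed in the original draw order; reorder too
  meanlog <- spec$area_meanlog
  peak_ids <- paste0("P", seq_len(p))

  # internal standard: a non-active peak, near-constant (spiked reference)
  all_active <- unique(unlist(spec$active_sets))
  is_candidates <- setdiff(seq_len(p), all_active)
  is_idx <- if (length(is_candidates)) is_candidates[1] else 1L

  sdlog <- rep(spec$area_sdlog, p)
  sdlog[is_idx] <- min(sdlog[is_idx], 0.02)

  logA <- matrix(rnorm(n * p), n, p) * rep(sdlog, each = n)
  logA <- sweep(logA, 2, meanlog, "+")
  if (spec$batch_effect > 0)
    logA <- logA + rnorm(n, sd = spec$batch_effect)

  # shared extraction factor per endpoint raises/lowers its planted peaks
  # jointly across batches; peaks active for several endpoints accumulate
  factors <- list()
  for (e in eps) {
    g <- rnorm(n)
    factors[[e]] <- g
    idx <- spec$active_sets[[e]]
    logA[, idx] <- logA[, idx] + spec$co_extraction * g
  }
  areas <- exp(logA)
  batch_ids <- paste0("S", seq_len(n))
  dimnames(areas) <- list(batch_ids, peak_ids)

  # effective log-variance per planted peak (for mean-normalisation in link)
  sdlog2_eff <- sdlog^2
  for (e in eps)
    sdlog2_eff[spec$active_sets[[e]]] <-
      sdlog2_eff[spec$active_sets[[e]]] + spec$co_extraction^2

  edef <- spec$endpoints
  raw <- data.frame(batch = batch_ids, stringsAsFactors = FALSE)
  latent <- list()
  for (e in eps) {
    row <- edef[edef$endpoint == e, ]
    L <- .latent_activity(areas, spec$active_sets[[e]], spec$coefficients[[e]],
                          meanlog, sdlog2_eff, spec$link)
    if (spec$noise_sd > 0)  # multiplicative: a CV-style assay error
      L <- L * (1 + rnorm(n, sd = spec$noise_sd))
    latent[[e]] <- L
    raw[[e]] <- .encode_raw(L, row$family, row$enc_a, row$enc_b)
  }

  mat <- new_common_peak_matrix(
    areas = areas, rt = setNames(rt, peak_ids),
    mode = setNames(mode, peak_ids), is_peak = peak_ids[is_idx]
  )
  truth <- structure(
    list(active_sets = lapply(spec$active_sets, function(i) peak_ids[i]),
         active_index = spec$active_sets,
         coefficients = spec$coefficients, link = spec$link,
         latent_activity = latent, is_peak = peak_ids[is_idx],
         seed = spec$seed),
    class = "synthetic_truth"
  )
  effects <- assemble_effects(raw, endpoints = edef)
  list(matrix = mat, effects_raw = raw, effects = effects, truth = truth)
}

#' Generate QC serial-dilution calibration tables
#'
#' Emulates the linearity check of a fingerprint method: a pooled QC sample
#' is serially diluted and each common peak's area is regressed (as a ratio
#' to the internal standard, which is spiked at constant level into every
#' dilution) against relative concentration `1 / dilution`. Peaks listed in
#' `failing_peaks` get a saturating response so their fitted R-squared falls
#' below the usual 0.99 criterion; all other peaks respond linearly.
#'
#' @param matrix A `common_peak_matrix`; the QC sample is its mean
#'   fingerprint.
#' @param dilution_factors Distinct dilution factors >= 1 (default the
#'   6-point series 2, 4, 8, 16, 32, 64).
#' @param failing_peaks Peak ids (or indices) to make non-linear.
#' @param noise_sd Relative area noise per point (default 0 = exact).
#' @param seed Integer seed for the noise.
#' @return data.frame with columns `peak`, `dilution`, `rel_conc`, `area`,
#'   `is_area`, `ratio`.
#' @export
gen_calibration <- function(matrix, dilution_factors = c(2, 4, 8, 16, 32, 64),
                            failing_peaks = character(), noise_sd = 0,
                            seed = 1L) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  if (length(dilution_factors) == 0)
    stop("dilution_factors: must supply at least one dilution")
  if (any(dilution_factors < 1) || anyDuplicated(dilution_factors))
    stop("dilution_factors: must be distinct and >= 1")
  peaks <- colnames(matrix$areas)
  if (is.numeric(failing_peaks)) failing_peaks <- peaks[failing_peaks]
  if (!all(failing_peaks %in% peaks))
    stop("failing_peaks: unknown peak id(s)")
  set.seed(as.integer(seed))
  qc <- colMeans(matrix$areas)
  is_area <- qc[matrix$is_peak]
  x <- 1 / dilution_factors
  rows <- lapply(peaks, function(pk) {
    if (pk %in% failing_peaks) {
      # saturating response: strongly concave in rel. concentration
      a <- qc[pk] * x / (x + 0.05) / (1 / (1 + 0.05))
    } else {
      a <- qc[pk] * x
    }
    if (noise_sd > 0) a <- a * (1 + rnorm(length(x), sd = noise_sd))
    data.frame(peak = pk, dilution = dilution_factors, rel_conc = x,
               area = a, is_area = unname(is_area),
               ratio = a / unname(is_area), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a four-parameter logistic dose-response table
#'
#' Responses follow `floor + (ceiling - floor) / (1 + (ic50 / c)^hill)`:
#' at `c = ic50` the response is exactly midway between floor and ceiling.
#'
#' @param ic50 Positive half-maximal concentration.
#' @param hill Hill slope (default 1).
#' @param concentrations Concentration grid (>= 4 values; default the
#'   7-point series 0.3125 ... 20 mg/mL).
#' @param floor,ceiling Response asymptotes (default 0 and 100 percent).
#' @param noise_sd Gaussian response noise, absolute units (default 0).
#' @param seed Integer seed.
#' @return data.frame with `concentration` and `response`.
#' @export
gen_dose_response <- function(ic50, hill = 1,
                              concentrations = c(0.3125, 0.625, 1.25, 2.5,
                                                 5, 10, 20),
                              floor = 0, ceiling = 100, noise_sd = 0,
                              seed = 1L) {
  if (!is.numeric(ic50) || length(ic50) != 1 || ic50 <= 0)
    stop("ic50: must be a single positive concentration")
  if (length(concentrations) < 4)
    stop("concentrations: need at least 4 concentrations")
  set.seed(as.integer(seed))
  y <- floor + (ceiling - floor) / (1 + (ic50 / concentrations)^hill)
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  data.frame(concentration = concentrations, response = y)
}

#' Grade a selected peak set against the planted truth
#'
#' @param selected Character vector of selected peak ids (or integer
#'   indices).
#' @param truth A `synthetic_truth` from [gen_spectrum_effect()].
#' @param endpoint Endpoint name present in the truth.
#' @return A one-row data.frame: `endpoint`, `n_selected`, `n_planted`,
#'   `n_hit`, `recall`, `precision` (`NA` when nothing was selected).
#' @export
recovery_metrics <- function(selected, truth, endpoint) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!endpoint %in% names(truth$active_sets))
    stop("unknown endpoint: ", endpoint)
  planted <- truth$active_sets[[endpoint]]
  if (is.numeric(selected)) selected <- paste0("P", selected)
  hit <- length(intersect(selected, planted))
  data.frame(
    endpoint = endpoint,
    n_selected = length(selected), n_planted = length(planted), n_hit = hit,
    recall = hit / length(planted),
    precision = if (length(selected)) hit / length(selected) else NA_real_,
    stringsAsFactors = FALSE
  )
}
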