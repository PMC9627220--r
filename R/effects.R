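#' DPPH radical scavenging rate
#'
#' `[1 - (OD_sample - OD_blank) / OD_control] x 100%`, where the sample OD is
#' read after mixing the test solution with DPPH, the blank replaces DPPH
#' with solvent, and the control replaces the sample with solvent. The value
#' is returned as computed -- pathological inputs can push it outside
#' [0, 100] and are not clamped.
#'
#' @param od_sample,od_blank,od_control Optical densities at 517 nm;
#'   `od_control` must be positive.
#' @return Scavenging rate in percent (vectorised).
#' @export
dpph_rate <- function(od_sample, od_blank, od_control) {
  if (any(od_control <= 0)) stop("od_control must be > 0")
  (1 - (od_sample - od_blank) / od_control) * 100
}

#' Relative wound healing rate
#'
#' `100 * (area_0h - area_24h) / area_0h`. A 24 h area larger than the 0 h
#' area (the wound opening further) yields a negative rate and a warning.
#'
#' @param area_0h Scratch area at 0 h (> 0).
#' @param area_24h Scratch area at 24 h.
#' @return Healing rate in percent (vectorised).
#' @export
healing_rate <- function(area_0h, area_24h) {
  if (any(area_0h <= 0)) stop("area_0h must be > 0")
  if (any(area_24h < 0) || any(area_24h > area_0h))
    warning("area_24h outside [0, area_0h]; rate reported as computed")
  100 * (area_0h - area_24h) / area_0h
}

#' Fit a four-parameter logistic dose-response curve and extract the IC50
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (ic50 / conc)^hill)`
#' on the concentration grid (the log(dose)-vs-response model of standard
#' dose-response software). The IC50 is the concentration at the response
#' midway between the fitted floor and ceiling. The Hill slope may be
#' negative for decreasing curves.
#'
#' @param concentrations Positive concentrations (>= 4 distinct values).
#' @param responses Responses (e.g. percent scavenging or viability).
#' @return List of class `ic50_fit`: `ic50`, `hill`, `bottom`, `top`,
#'   `fitted`, `residual_norm`, `r_squared`.
#' @export
fit_ic50 <- function(concentrations, responses) {
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(concentrations) != length(responses))
    stop("concentrations and responses must have equal length")
  if (sd(responses) < 1e-12 * max(1, abs(mean(responses))))
    stop("no dose dependence: flat response")
  o <- order(concentrations)
  x <- concentrations[o]; y <- responses[o]
  dir <- sign(cor(log(x), y, method = "spearman"))
  if (dir == 0) dir <- 1
  mid <- (max(y) + min(y)) / 2
  model <- function(p) p[1] + (p[2] - p[1]) / (1 + exp(p[4] * (p[3] - log(x))))
  attempt <- function(start) {
    out <- try(minpack.lm::nls.lm(
      par = start, fn = function(p) y - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(out, "try-error") || !out$info %in% 1:4) NULL else out
  }
  starts <- list(c(bottom = min(y), top = max(y),
                   lic50 = log(x[which.min(abs(y - mid))]), hill = dir))
  # coarse grid over (log IC50, hill) with asymptotes profiled out by OLS
  best <- NULL; best_ss <- Inf
  for (l in seq(log(min(x)), log(max(x)), length.out = 25)) {
    for (h in dir * seq(0.25, 4, length.out = 16)) {
      s <- 1 / (1 + exp(h * (l - log(x))))
      g <- lm(y ~ s)
      ss <- sum(resid(g)^2)
      if (ss < best_ss) {
        best_ss <- ss
        best <- c(bottom = unname(coef(g)[1]), top = unname(sum(coef(g))),
                  lic50 = l, hill = h)
      }
    }
  }
  starts <- c(starts, list(best))
  fits <- Filter(Negate(is.null), lapply(starts, attempt))
  if (!length(fits))
    stop("dose-response fit did not converge; residual norm of the best ",
         "grid candidate was ", signif(sqrt(best_ss), 6))
  fit <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  cf <- fit$par
  fitted_y <- model(cf)
  res <- y - fitted_y
  structure(list(
    ic50 = exp(unname(cf["lic50"])), hill = unname(cf["hill"]),
    bottom = unname(cf["bottom"]), top = unname(cf["top"]),
    fitted = fitted_y, residual_norm = sqrt(sum(res^2)),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2)
  ), class = "ic50_fit")
}

#' FRAP standard calibration
#'
#' Ordinary least squares of absorbance (593 nm) on standard Fe2+
#' concentration, e.g. over the 25-800 umol/L ferrous sulfate series.
#'
#' @param standard_concentrations Standard concentrations, umol/L (>= 3).
#' @param absorbances Measured absorbances.
#' @return Object of class `linear_calibration`: `slope`, `intercept`,
#'   `r_squared`.
#' @export
frap_calibrate <- function(standard_concentrations, absorbances) {
  if (length(standard_concentrations) < 3) stop("need at least 3 standards")
  fit <- lm(absorbances ~ standard_concentrations)
  slope <- unname(coef(fit)[2])
  if (abs(slope) < .Machine$double.eps)
    stop("calibration slope is zero")
  sst <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(resid(fit)^2) / sst
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = r2), class = "linear_calibration")
}

#' Invert a FRAP calibration
#'
#' @param absorbance Sample absorbance(s).
#' @param calibration A `linear_calibration` from [frap_calibrate()].
#' @return Fe2+-equivalent concentration, umol/L.
#' @export
frap_value <- function(absorbance, calibration) {
  stopifnot(inherits(calibration, "linear_calibration"))
  (absorbance - calibration$intercept) / calibration$slope
}

#' Assemble raw endpoint values into an orientation-normalised effect table
#'
#' Every endpoint is converted to an *activity* on which "larger = more
#' active" holds, so all three screening methods can treat endpoints
#' uniformly. The transform is fixed per endpoint family:
#' \describe{
#'   \item{ic50}{reciprocal, `1 / raw` (a lower IC50 is a stronger batch);}
#'   \item{concentration}{identity (e.g. FRAP Fe2+ equivalents);}
#'   \item{percentage, lower better}{reflection `100 - raw` (viability,
#'     healing rate);}
#'   \item{count, lower better}{range reflection `(max + min) - raw` per
#'     endpoint (migrated / invaded cells).}
#' }
#' Families whose raw value already increases with activity pass through
#' unchanged. All transforms preserve or exactly reverse the batch ranking
#' according to the orientation flag, and keep activities positive.
#'
#' @param raw data.frame with a `batch` column and one numeric column per
#'   endpoint; every batch must have every endpoint.
#' @param endpoints Endpoint definition table ([default_endpoints()]); only
#'   rows matching `raw`'s columns are used.
#' @return Object of class `effect_table`: `batches`, `raw`, `activity`
#'   (data.frames) and `meta` (endpoint, family, unit,
#'   `larger_raw_more_active`, transform).
#' @export
assemble_effects <- function(raw, endpoints = default_endpoints()) {
  if (!"batch" %in% names(raw)) stop("raw must have a 'batch' column")
  eps <- setdiff(names(raw), "batch")
  unknown <- setdiff(eps, endpoints$endpoint)
  if (length(unknown))
    stop("unknown endpoint(s): ", paste(unknown, collapse = ", "))
  if (anyNA(raw[eps]))
    stop("missing endpoint value(s); every batch needs every endpoint")
  activity <- raw["batch"]
  meta <- data.frame()
  for (e in eps) {
    row <- endpoints[endpoints$endpoint == e, ]
    v <- raw[[e]]
    if (row$larger_raw_more_active) {
      a <- v; transform <- "identity"
    } else if (row$family == "ic50") {
      if (any(v <= 0)) stop("endpoint '", e, "': IC50 must be positive")
      a <- 1 / v; transform <- "reciprocal"
    } else if (row$family == "percentage") {
      a <- 100 - v; transform <- "reflect100"
    } else if (row$family == "count") {
      a <- (max(v) + min(v)) - v; transform <- "reflect_range"
    } else {
      a <- v; transform <- "identity"
    }
    activity[[e]] <- a
    meta <- rbind(meta, data.frame(
      endpoint = e, family = row$family, unit = row$unit,
      larger_raw_more_active = row$larger_raw_more_active,
      transform = transform, stringsAsFactors = FALSE))
  }
  structure(list(batches = raw$batch, raw = raw, activity = activity,
                 meta = meta),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat("Effect table:", length(x$batches), "batches x",
      nrow(x$meta), "endpoints\n")
  print(x$meta, row.names = FALSE)
  invisible(x)
}
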