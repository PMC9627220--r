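#' Restrict a common-peak matrix to a peak subset
#'
#' Typically used to drop peaks that failed the linearity screen before the
#' spectrum-effect screens.
#'
#' @param matrix A `common_peak_matrix`.
#' @param peaks Character vector of peak ids to keep, or a
#'   `linearity_report` whose retained set is used.
#' @return A `common_peak_matrix` over the subset (the internal standard is
#'   kept regardless, as the reference peak).
#' @export
restrict_peaks <- function(matrix, peaks) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  if (inherits(peaks, "linearity_report")) peaks <- peaks$retained
  if (!all(peaks %in% colnames(matrix$areas)))
    stop("unknown peak id(s): ",
         paste(setdiff(peaks, colnames(matrix$areas)), collapse = ", "))
  keep <- colnames(matrix$areas)[colnames(matrix$areas) %in%
                                   union(peaks, matrix$is_peak)]
  new_common_peak_matrix(matrix$areas[, keep, drop = FALSE],
                         matrix$rt[keep], matrix$mode[keep], matrix$is_peak,
                         matrix$rt_obs[, keep, drop = FALSE])
}

# sort peak ids by their P-number
.sort_peaks <- function(ids) {
  num <- suppressWarnings(as.integer(sub("^P", "", ids)))
  if (anyNA(num)) sort(ids) else ids[order(num)]
}

#' Consensus of the three screening methods for one endpoint
#'
#' Exact three-way set intersection of the GRA, PLSR and MIV selections --
#' a peak is a consensus candidate only if all three chemometric routes
#' nominate it.
#'
#' @param gra_set,plsr_set,miv_set Character vectors of peak ids.
#' @param universe Optional peak universe; ids outside it are an error.
#' @return Character vector (sorted by P-number).
#' @export
intersect_per_effect <- function(gra_set, plsr_set, miv_set,
                                 universe = NULL) {
  sets <- list(gra_set, plsr_set, miv_set)
  if (!is.null(universe)) {
    bad <- setdiff(unique(unlist(sets)), universe)
    if (length(bad))
      stop("peak id(s) outside the universe: ", paste(bad, collapse = ", "))
  }
  .sort_peaks(Reduce(intersect, sets))
}

#' Cross-endpoint overlaps of consensus sets
#'
#' All pairwise intersections of the per-endpoint consensus sets, plus the
#' intersection across every endpoint.
#'
#' @param consensus_sets Named list (>= 2 endpoints) of peak-id vectors.
#' @return List with `pairwise` (data.frame: endpoint_a, endpoint_b, n,
#'   peaks as comma-joined string), `pairwise_sets` (named list of vectors),
#'   and `all` (the full intersection).
#' @export
shared_across_effects <- function(consensus_sets) {
  if (length(consensus_sets) < 2) stop("need at least 2 endpoints")
  eps <- names(consensus_sets)
  rows <- list(); psets <- list()
  for (i in seq_along(eps)) for (j in seq_along(eps)) if (i < j) {
    s <- .sort_peaks(intersect(consensus_sets[[i]], consensus_sets[[j]]))
    key <- paste(eps[i], eps[j], sep = ":")
    psets[[key]] <- s
    rows[[key]] <- data.frame(endpoint_a = eps[i], endpoint_b = eps[j],
                              n = length(s),
                              peaks = paste(s, collapse = ","),
                              stringsAsFactors = FALSE)
  }
  list(pairwise = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       pairwise_sets = psets,
       all = .sort_peaks(Reduce(intersect, consensus_sets)))
}

#' Run the full three-method spectrum-effect screen
#'
#' Orchestrates, per endpoint: grey relational analysis, PLS/VIP with
#' leave-one-out Q2, the BP-ANN + MIV ensemble, and the three-way consensus
#' intersection.
#'
#' @param matrix A `common_peak_matrix`, already restricted to
#'   linearity-retained peaks (see [restrict_peaks()]).
#' @param effects An `effect_table`.
#' @param gra_threshold Grey-degree selection threshold (default 0.8).
#' @param rho GRA resolution coefficient (default 0.5).
#' @param gra_normalize GRA normalisation mode (default `"zscore"`).
#' @param vip_threshold VIP threshold (default 1).
#' @param ann An [ann_config()].
#' @param delta MIV perturbation fraction (default 0.10).
#' @param seed Seed forwarded to the network ensemble.
#' @return Object of class `screen_result`: per endpoint the three method
#'   results (`gra`, `plsr`, `miv`: scores + selected) and `consensus`;
#'   plus `overlaps` ([shared_across_effects()] output when >= 2 endpoints)
#'   and the parameter provenance.
#' @export
run_screen <- function(matrix, effects, gra_threshold = 0.8, rho = 0.5,
                       gra_normalize = "zscore", vip_threshold = 1,
                       ann = ann_config(), delta = 0.10, seed = ann$seed) {
  ann$seed <- as.integer(seed)
  gra <- gra_select(matrix, effects, threshold = gra_threshold, rho = rho,
                    normalize = gra_normalize)
  pls <- plsr_screen(matrix, effects, vip_threshold = vip_threshold)
  mivr <- ann_screen(matrix, effects, config = ann, delta = delta)
  universe <- if (inherits(matrix, "common_peak_matrix"))
    colnames(matrix$areas) else colnames(matrix)
  eps <- effects$meta$endpoint
  endpoints <- list()
  for (e in eps) {
    endpoints[[e]] <- list(
      gra = gra$endpoints[[e]],
      plsr = pls$endpoints[[e]],
      miv = mivr$endpoints[[e]],
      consensus = intersect_per_effect(gra$endpoints[[e]]$selected,
                                       pls$endpoints[[e]]$selected,
                                       mivr$endpoints[[e]]$selected,
                                       universe = universe))
  }
  overlaps <- if (length(eps) >= 2)
    shared_across_effects(lapply(endpoints, `[[`, "consensus")) else NULL
  structure(list(
    endpoints = endpoints, overlaps = overlaps,
    params = list(gra_threshold = gra_threshold, rho = rho,
                  gra_normalize = gra_normalize,
                  vip_threshold = vip_threshold, delta = delta,
                  ann_hidden = ann$hidden, ann_ensemble = ann$ensemble,
                  seed = as.integer(seed)),
    universe = universe
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Spectrum-effect screen over", length(x$universe), "peaks\n")
  for (e in names(x$endpoints)) {
    r <- x$endpoints[[e]]
    cat(sprintf("  %-10s GRA %2d | PLSR %2d | MIV %2d -> consensus %2d: %s\n",
                e, length(r$gra$selected), length(r$plsr$selected),
                length(r$miv$selected), length(r$consensus),
                paste(r$consensus, collapse = ", ")))
  }
  invisible(x)
}

#' Machine-readable screening report
#'
#' Serialises a `screen_result` -- per-endpoint method scores and
#' selections, consensus sets, cross-endpoint overlaps, and the parameter
#' provenance -- as deterministic JSON (no timestamps; regenerating from the
#' same result is byte-identical). Missing stages are flagged and a partial
#' report is still emitted.
#'
#' @param result A `screen_result` (possibly with endpoints removed).
#' @param file Optional path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `file` is given.
#' @export
screening_report <- function(result, file = NULL) {
  stopifnot(inherits(result, "screen_result"))
  eps <- lapply(result$endpoints, function(r) {
    missing <- setdiff(c("gra", "plsr", "miv"), names(r)[!vapply(r, is.null,
                                                                 logical(1))])
    out <- list(
      gra = if (!is.null(r$gra)) list(scores = r$gra$scores,
                                      selected = r$gra$selected),
      plsr = if (!is.null(r$plsr)) list(scores = r$plsr$scores,
                                        selected = r$plsr$selected,
                                        model = r$plsr$model),
      miv = if (!is.null(r$miv)) list(scores = r$miv$scores,
                                      selected = r$miv$selected),
      consensus = r$consensus)
    if (length(missing)) out$missing_stages <- missing
    out
  })
  payload <- list(
    peaks = result$universe,
    params = result$params,
    endpoints = eps,
    overlaps = if (!is.null(result$overlaps)) list(
      pairwise = result$overlaps$pairwise,
      all = result$overlaps$all)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(json))
  }
  json
}

#' Published per-endpoint consensus screening sets for QYSLD
#'
#' The per-endpoint consensus candidate sets (three-method intersection)
#' reported for the ten-batch Qi-Yu-San-Long decoction study: 8 peaks for
#' DPPH scavenging, 9 for FRAP, 6 for A549 viability, 22 for wound healing
#' (horizontal migration), 5 for transwell (vertical) migration and 12 for
#' transwell invasion. Used for cross-experiment set algebra.
#'
#' @return Named list of peak-id vectors.
#' @export
qysld_consensus_sets <- function() {
  list(
    dpph = c("P1", "P4", "P24", "P28", "P34", "P62", "P68", "P70"),
    frap = c("P4", "P7", "P10", "P17", "P37", "P39", "P46", "P50", "P67"),
    viability = c("P1", "P4", "P28", "P37", "P44", "P62"),
    wound = c("P2", "P7", "P8", "P13", "P20", "P21", "P23", "P24", "P28",
              "P30", "P34", "P35", "P36", "P42", "P44", "P48", "P49", "P51",
              "P60", "P62", "P68", "P70"),
    migration = c("P24", "P28", "P44", "P62", "P70"),
    invasion = c("P1", "P5", "P7", "P10", "P16", "P21", "P23", "P24", "P28",
                 "P34", "P35", "P70")
  )
}
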