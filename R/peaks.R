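#' Construct a common-peak matrix object
#'
#' Container for the batches x common-peaks area matrix with consensus
#' retention times, ion modes, the designated internal-standard peak, and
#' (optionally) the per-batch observed retention times.
#'
#' @param areas Numeric matrix, batches x peaks, with dimnames.
#' @param rt Named numeric vector of consensus retention times (minutes),
#'   one per peak column.
#' @param mode Named character vector, `"positive"` or `"negative"`.
#' @param is_peak Peak id of the internal standard.
#' @param rt_obs Optional matrix of per-batch retention times (minutes);
#'   defaults to the consensus replicated across batches.
#' @return An object of class `common_peak_matrix`.
#' @export
new_common_peak_matrix <- function(areas, rt, mode, is_peak, rt_obs = NULL) {
  stopifnot(is.matrix(areas), !is.null(colnames(areas)), !is.null(rownames(areas)))
  peaks <- colnames(areas)
  if (anyNA(areas)) stop("areas: missing cells are not allowed")
  if (any(areas < 0)) stop("areas: must be >= 0")
  if (!all(peaks %in% names(rt)) || !all(peaks %in% names(mode)))
    stop("rt and mode must be named for every peak column")
  if (length(is_peak) != 1 || !is_peak %in% peaks)
    stop("is_peak: exactly one internal-standard peak id, present in the matrix")
  if (is.null(rt_obs)) {
    rt_obs <- matrix(rep(rt[peaks], each = nrow(areas)), nrow(areas),
                     dimnames = dimnames(areas))
  }
  structure(list(areas = areas, rt = rt[peaks], mode = mode[peaks],
                 is_peak = is_peak, rt_obs = rt_obs),
            class = "common_peak_matrix")
}

#' @export
print.common_peak_matrix <- function(x, ...) {
  cat("Common-peak matrix:", nrow(x$areas), "batches x", ncol(x$areas),
      "peaks\n")
  cat("  ion modes:", sum(x$mode == "positive"), "positive,",
      sum(x$mode == "negative"), "negative\n")
  cat("  internal standard:", x$is_peak,
      sprintf("(RT %.2f min)\n", x$rt[x$is_peak]))
  invisible(x)
}

#' @export
dim.common_peak_matrix <- function(x) dim(x$areas)

.peak_table_cols <- c("sample", "peak_id", "rt_min", "area", "mode")

#' Read per-batch peak tables
#'
#' Reads delimited peak tables (one sample per file) with the documented
#' header `sample, peak_id, rt_min, area, mode`. Rows must have numeric
#' retention time and a non-negative numeric area; violations are reported
#' with the file and line number.
#'
#' @param paths Character vector of file paths.
#' @param sep Field separator (default tab).
#' @return A list of `peak_table` data.frames sorted by retention time.
#' @export
read_peak_tables <- function(paths, sep = "\t") {
  lapply(paths, function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    missing <- setdiff(.peak_table_cols, names(df))
    if (length(missing))
      stop("parse error in ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
    for (col in c("rt_min", "area")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad))
        stop("parse error in ", path, ", line ", bad[1] + 1,
             ": non-numeric ", col)
      df[[col]] <- v
    }
    neg <- which(df$area < 0)
    if (length(neg))
      stop("parse error in ", path, ", line ", neg[1] + 1,
           ": negative area")
    if (length(unique(df$sample)) != 1)
      stop("parse error in ", path, ": expected a single sample per file")
    df <- df[order(df$rt_min), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("peak_table", "data.frame")
    df
  })
}

#' Write a peak table
#'
#' @param table A `peak_table` data.frame.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_peak_table <- function(table, path, sep = "\t") {
  write.table(table[, .peak_table_cols], path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Explode a common-peak matrix into per-batch peak tables
#'
#' Mostly used to exercise the matching step on synthetic data: emits one
#' `peak_table` per batch, with per-batch retention times jittered around
#' the consensus.
#'
#' @param matrix A `common_peak_matrix`.
#' @param rt_jitter SD of the per-batch retention-time jitter in minutes.
#' @param seed Integer seed.
#' @return List of `peak_table` data.frames.
#' @export
as_peak_tables <- function(matrix, rt_jitter = 0.02, seed = 1L) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  set.seed(as.integer(seed))
  batches <- rownames(matrix$areas)
  peaks <- colnames(matrix$areas)
  lapply(batches, function(b) {
    rt <- matrix$rt[peaks] + if (rt_jitter > 0)
      rnorm(length(peaks), sd = rt_jitter) else 0
    df <- data.frame(sample = b, peak_id = peaks, rt_min = unname(rt),
                     area = unname(matrix$areas[b, peaks]),
                     mode = unname(matrix$mode[peaks]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$rt_min), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("peak_table", "data.frame")
    df
  })
}

# Single-linkage grouping of pooled retention times: split wherever the gap
# between consecutive sorted RTs exceeds the tolerance.
.rt_groups <- function(rt, tol) {
  o <- order(rt)
  gaps <- diff(rt[o])
  grp <- cumsum(c(1, gaps > tol))
  split(o, grp)
}

#' Match peaks across batches into a common-peak matrix
#'
#' A common peak exists iff every batch contributes exactly one peak within
#' `rt_tolerance` minutes of the consensus retention time (the median of the
#' member peaks' RTs), per ion mode. Peaks absent from one or more batches
#' are excluded from the common set and reported via the
#' `"dropped"` attribute; two peaks of one batch inside the tolerance is an
#' ambiguity and an error. Columns are ordered by ion-mode block (positive
#' first) then consensus RT, and labelled P1..Pn.
#'
#' @param tables List of `peak_table` data.frames (>= 2).
#' @param rt_tolerance Retention-time tolerance in minutes (default 0.2).
#' @param is_peak `peak_id` (as appearing in the input tables) of the
#'   internal standard.
#' @return A `common_peak_matrix`; the `"dropped"` attribute lists
#'   non-common retention-time groups.
#' @export
match_common_peaks <- function(tables, rt_tolerance = 0.2, is_peak = NULL) {
  if (length(tables) < 2) stop("need at least 2 peak tables")
  if (!is.numeric(rt_tolerance) || rt_tolerance <= 0)
    stop("rt_tolerance must be > 0")
  samples <- vapply(tables, function(t) t$sample[1], character(1))
  if (anyDuplicated(samples)) stop("duplicate sample ids across tables")
  pooled <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    data.frame(tab = i, peak_id = t$peak_id, rt = t$rt_min, area = t$area,
               mode = t$mode, stringsAsFactors = FALSE)
  }))

  cols <- list(); dropped <- list()
  for (md in unique(pooled$mode)) {
    sub <- pooled[pooled$mode == md, , drop = FALSE]
    for (grp in .rt_groups(sub$rt, rt_tolerance)) {
      g <- sub[grp, , drop = FALSE]
      consensus <- median(g$rt)
      near <- g[abs(g$rt - consensus) <= rt_tolerance, , drop = FALSE]
      counts <- table(factor(near$tab, levels = seq_along(tables)))
      if (any(counts > 1)) {
        b <- which(counts > 1)[1]
        rts <- near$rt[near$tab == b]
        stop(sprintf(
          "ambiguous match in batch %s near RT %.3f min: peaks at %s",
          samples[b], consensus, paste(sprintf("%.3f", rts), collapse = ", ")))
      }
      if (all(counts == 1)) {
        o <- order(near$tab)
        cols[[length(cols) + 1]] <- list(
          rt = consensus, mode = md,
          area = setNames(near$area[o], samples[near$tab[o]]),
          rt_by_batch = setNames(near$rt[o], samples[near$tab[o]]),
          member_ids = near$peak_id
        )
      } else {
        dropped[[length(dropped) + 1]] <-
          data.frame(rt = consensus, mode = md,
                     n_batches = sum(counts > 0), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cols)) stop("no common peaks found")
  ord <- order(vapply(cols, function(cl) cl$mode != "positive", logical(1)),
               vapply(cols, function(cl) cl$rt, numeric(1)))
  cols <- cols[ord]
  peak_ids <- paste0("P", seq_along(cols))
  areas <- sapply(cols, function(cl) cl$area[samples])
  rt_obs <- sapply(cols, function(cl) cl$rt_by_batch[samples])
  dimnames(areas) <- dimnames(rt_obs) <- list(samples, peak_ids)

  is_id <- NULL
  if (!is.null(is_peak)) {
    hit <- which(vapply(cols, function(cl) is_peak %in% cl$member_ids,
                        logical(1)))
    if (length(hit) != 1)
      stop("internal standard '", is_peak, "' not found among common peaks")
    is_id <- peak_ids[hit]
  } else {
    is_id <- peak_ids[1]
  }
  out <- new_common_peak_matrix(
    areas = areas,
    rt = setNames(vapply(cols, function(cl) cl$rt, numeric(1)), peak_ids),
    mode = setNames(vapply(cols, function(cl) cl$mode, character(1)), peak_ids),
    is_peak = is_id, rt_obs = rt_obs
  )
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(rt = numeric(), mode = character(), n_batches = integer())
  out
}

#' Relative retention time and relative peak area
#'
#' Per batch and peak, the ratio of retention time / area to the
#' internal-standard peak's retention time / area of the same batch. The IS
#' peak itself has RRT = RPA = 1 in every batch.
#'
#' @param matrix A `common_peak_matrix` with a designated internal standard.
#' @return List with matrices `rrt` and `rpa` (batches x peaks).
#' @export
relative_to_is <- function(matrix) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  is_area <- matrix$areas[, matrix$is_peak]
  zero <- which(is_area <= 0)
  if (length(zero))
    stop("internal-standard area is zero in batch ",
         rownames(matrix$areas)[zero[1]])
  list(rrt = matrix$rt_obs / matrix$rt_obs[, matrix$is_peak],
       rpa = matrix$areas / is_area)
}

#' Relative standard deviation / coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation. RSD and
#' CV share the formula; `mode` only labels the result.
#'
#' @param values Numeric vector (>= 2 values, non-zero mean).
#' @param mode `"rsd"` or `"cv"`.
#' @return Single percentage, with a `"mode"` attribute.
#' @export
dispersion_stats <- function(values, mode = c("rsd", "cv")) {
  mode <- match.arg(mode)
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; dispersion undefined")
  structure(100 * sd(values) / m, mode = mode)
}

#' Linearity screen of calibration series
#'
#' Ordinary least squares of the analyte/IS area ratio on relative
#' concentration (1 / dilution factor) per peak; peaks whose R-squared falls
#' below the threshold are dropped from the spectrum before screening.
#'
#' @param calibrations data.frame with columns `peak`, `rel_conc`, `ratio`
#'   (the output of [gen_calibration()] qualifies); >= 3 points per peak.
#' @param r2_threshold Minimum R-squared to retain a peak (default 0.99).
#' @return Object of class `linearity_report`: data.frame `stats` (peak,
#'   slope, intercept, r_squared, retained), character vectors `retained`
#'   and `dropped`, and the threshold.
#' @export
linearity_screen <- function(calibrations, r2_threshold = 0.99) {
  need <- c("peak", "rel_conc", "ratio")
  if (!all(need %in% names(calibrations)))
    stop("calibrations must have columns ", paste(need, collapse = ", "))
  res <- lapply(split(calibrations, calibrations$peak), function(d) {
    if (nrow(d) < 3) stop("peak ", d$peak[1], ": need >= 3 calibration points")
    if (length(unique(d$rel_conc)) < 2)
      stop("peak ", d$peak[1], ": degenerate series (all concentrations equal)")
    fit <- lm(ratio ~ rel_conc, data = d)
    sst <- sum((d$ratio - mean(d$ratio))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(resid(fit)^2) / sst
    data.frame(peak = d$peak[1], slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), r_squared = r2,
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, res)
  # keep natural P-number order if peaks are P1..Pn
  num <- suppressWarnings(as.integer(sub("^P", "", stats$peak)))
  if (!anyNA(num)) stats <- stats[order(num), , drop = FALSE]
  rownames(stats) <- NULL
  stats$retained <- stats$r_squared >= r2_threshold
  structure(list(stats = stats,
                 retained = stats$peak[stats$retained],
                 dropped = stats$peak[!stats$retained],
                 threshold = r2_threshold),
            class = "linearity_report")
}

#' @export
print.linearity_report <- function(x, ...) {
  cat("Linearity screen (R^2 >=", x$threshold, "):",
      length(x$retained), "retained,", length(x$dropped), "dropped\n")
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Uncentered cosine similarity between two fingerprints
#'
#' @param a,b Non-negative area vectors of equal length and nonzero norm.
#' @return Cosine similarity in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector")
  sum(a * b) / (na * nb)
}

#' Fingerprint similarity to the reference chromatogram
#'
#' Uncentered cosine (congruence coefficient) between each batch's
#' common-peak area vector and the reference vector, the mean fingerprint
#' across batches -- the documented default behaviour of the legacy TCM
#' fingerprint similarity software. Scale-invariant: a batch proportional to
#' the reference scores exactly 1.
#'
#' @param matrix A `common_peak_matrix`.
#' @param mode `"all"` (default) or restrict to `"positive"` / `"negative"`
#'   ion-mode peaks.
#' @return Named numeric vector of per-batch similarities in [-1, 1], with
#'   the reference construction recorded in the `"reference"` attribute.
#' @export
fingerprint_similarity <- function(matrix, mode = c("all", "positive",
                                                    "negative")) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  mode <- match.arg(mode)
  A <- matrix$areas
  if (mode != "all") A <- A[, matrix$mode == mode, drop = FALSE]
  if (nrow(A) < 2) stop("need at least 2 batches")
  ref <- colMeans(A)
  if (sqrt(sum(ref^2)) == 0) stop("reference vector has zero norm")
  sims <- apply(A, 1, function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("zero-norm batch fingerprint")
    sum(v * ref) / (nv * sqrt(sum(ref^2)))
  })
  attr(sims, "reference") <- "mean fingerprint across batches"
  sims
}

#' Write a fingerprint in the legacy two-block TXT dialect
#'
#' Emits, per batch, the two-block single-byte-encoded text layout used to
#' feed fingerprint data into legacy similarity software: block 1 lists
#' retention time and peak intensity in elution (peak) order; block 2 lists
#' peak height and integrated area ordered by retention time. Without
#' measured chromatogram traces, peak intensity and height default to the
#' integrated area. Numbers are written with 17 significant digits so a
#' read-back reproduces the blocks losslessly.
#'
#' @param matrix A non-empty `common_peak_matrix`.
#' @param traces Optional list per batch with numeric vectors `intensity`
#'   and/or `height` (one value per peak).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_legacy_fingerprint()]
#' @export
write_legacy_fingerprint <- function(matrix, traces = NULL, path) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  if (ncol(matrix$areas) == 0 || nrow(matrix$areas) == 0)
    stop("empty matrix: nothing to write")
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c("#SPECFX-LEGACY 1")
  peaks <- colnames(matrix$areas)
  ord_rt <- order(matrix$rt[peaks])
  for (b in rownames(matrix$areas)) {
    area <- matrix$areas[b, peaks]
    tr <- if (!is.null(traces)) traces[[b]] else NULL
    intensity <- if (!is.null(tr$intensity)) tr$intensity else unname(area)
    height <- if (!is.null(tr$height)) tr$height else unname(area)
    lines <- c(lines,
               paste0("#SAMPLE ", b),
               "#DATASET1 rt intensity",
               paste(fmt(unname(matrix$rt[peaks])), fmt(intensity), sep = "\t"),
               "#DATASET2 height area",
               paste(fmt(height[ord_rt]), fmt(unname(area)[ord_rt]), sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(iconv(lines, to = "latin1"), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a legacy two-block fingerprint TXT
#'
#' @param path Path written by [write_legacy_fingerprint()].
#' @return Named list per sample, each with data.frames `dataset1`
#'   (rt, intensity; elution order) and `dataset2` (height, area; RT order).
#' @export
read_legacy_fingerprint <- function(path) {
  lines <- readLines(path, encoding = "latin1")
  if (!length(lines) || lines[1] != "#SPECFX-LEGACY 1")
    stop("not a legacy fingerprint file: ", path)
  out <- list(); sample <- NULL; block <- NULL
  buf <- list(dataset1 = NULL, dataset2 = NULL)
  flush <- function() {
    if (!is.null(sample)) out[[sample]] <<- buf
  }
  for (ln in lines[-1]) {
    if (startsWith(ln, "#SAMPLE ")) {
      flush()
      sample <- sub("^#SAMPLE ", "", ln)
      buf <- list(dataset1 = NULL, dataset2 = NULL)
    } else if (startsWith(ln, "#DATASET1")) {
      block <- "dataset1"
      buf$dataset1 <- data.frame(rt = numeric(), intensity = numeric())
    } else if (startsWith(ln, "#DATASET2")) {
      block <- "dataset2"
      buf$dataset2 <- data.frame(height = numeric(), area = numeric())
    } else {
      v <- as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])
      buf[[block]] <- rbind(buf[[block]],
                            setNames(as.data.frame(as.list(v)),
                                     names(buf[[block]])))
    }
  }
  flush()
  out
}
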