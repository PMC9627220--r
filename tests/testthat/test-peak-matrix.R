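make_tables <- function(n_batches = 3, rts = c(2.0, 5.5, 9.1, 14.2),
                        offset = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_batches), function(b) {
    df <- data.frame(
      sample = paste0("S", b),
      peak_id = paste0("pk", seq_along(rts)),
      rt_min = rts + if (b > 1) offset else 0,
      area = runif(length(rts), 100, 1000),
      mode = "positive", stringsAsFactors = FALSE)
    class(df) <- c("peak_table", "data.frame")
    df
  })
}

test_that("peak tables round-trip through the delimited format", {
  tabs <- make_tables()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(tabs[[1]], path)
  back <- read_peak_tables(path)[[1]]
  expect_equal(back$rt_min, tabs[[1]]$rt_min)
  expect_equal(back$area, tabs[[1]]$area)
  expect_equal(back$peak_id, tabs[[1]]$peak_id)
})

test_that("malformed peak tables are rejected with file and line cited", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpeak_id\trt_min\tarea\tmode",
               "S1\tpk1\t2.0\t100\tpositive",
               "S1\tpk2\t5.0\t-3\tpositive"), path)
  expect_error(read_peak_tables(path), "line 3.*negative area")
  writeLines(c("sample\tpeak_id\trt_min\tarea\tmode",
               "S1\tpk1\tabc\t100\tpositive"), path)
  expect_error(read_peak_tables(path), "non-numeric rt_min")
  writeLines(c("sample\tpeak_id\tarea", "S1\tpk1\t100"), path)
  expect_error(read_peak_tables(path), "missing column")
})

test_that("matching a set of identical tables keeps every peak and area", {
  tabs <- make_tables(n_batches = 3)
  m <- match_common_peaks(tabs, rt_tolerance = 0.2, is_peak = "pk1")
  expect_equal(ncol(m$areas), 4)
  expect_equal(unname(m$areas["S1", ]), tabs[[1]]$area)
  expect_equal(m$is_peak, "P1")
})

test_that("offset tables match and agree with the nearest-RT oracle", {
  tol <- 0.5
  tabs <- make_tables(n_batches = 2, offset = 0.4 * tol)
  m <- match_common_peaks(tabs, rt_tolerance = tol)
  expect_equal(ncol(m$areas), 4)
  pairs <- oracle_rt_match(tabs[[1]]$rt_min, tabs[[2]]$rt_min, tol)
  for (k in seq_len(nrow(pairs))) {
    col <- which(abs(m$rt_obs["S1", ] - tabs[[1]]$rt_min[pairs[k, 1]]) < 1e-9)
    expect_length(col, 1)
    expect_equal(unname(m$areas["S2", col]),
                 tabs[[2]]$area[pairs[k, 2]])
  }
})

test_that("matching is invariant to batch order up to row order", {
  d <- gen_spectrum_effect(synthetic_spec(n_peaks = 12, seed = 9))
  tabs <- as_peak_tables(d$matrix, rt_jitter = 0.01, seed = 2)
  m1 <- match_common_peaks(tabs, rt_tolerance = 0.2)
  m2 <- match_common_peaks(rev(tabs), rt_tolerance = 0.2)
  expect_equal(m1$areas, m2$areas[rownames(m1$areas), ])
  expect_equal(m1$rt, m2$rt)
})

test_that("ten synthetic batches yield the full common-peak set", {
  d <- gen_spectrum_effect(synthetic_spec(seed = 21))
  tabs <- as_peak_tables(d$matrix, rt_jitter = 0.01, seed = 3)
  m <- match_common_peaks(tabs, rt_tolerance = 0.2)
  expect_equal(dim(m$areas), c(10, 70))
})

test_that("ambiguous duplicates within the tolerance are an error", {
  tabs <- make_tables(n_batches = 2)
  dup <- tabs[[1]][1, ]
  dup$peak_id <- "pk_dup"; dup$rt_min <- dup$rt_min + 0.05
  tabs[[1]] <- rbind(tabs[[1]], dup)
  class(tabs[[1]]) <- c("peak_table", "data.frame")
  expect_error(match_common_peaks(tabs, rt_tolerance = 0.2), "ambiguous.*S1")
})

test_that("peaks absent from one batch are excluded but reported", {
  tabs <- make_tables(n_batches = 3)
  tabs[[2]] <- tabs[[2]][-2, ]
  class(tabs[[2]]) <- c("peak_table", "data.frame")
  m <- match_common_peaks(tabs, rt_tolerance = 0.2)
  expect_equal(ncol(m$areas), 3)
  expect_equal(nrow(attr(m, "dropped")), 1)
})

test_that("RRT and RPA of the internal standard are exactly 1", {
  d <- gen_spectrum_effect(synthetic_spec(seed = 6))
  rel <- relative_to_is(d$matrix)
  expect_true(all(rel$rrt[, d$matrix$is_peak] == 1))
  expect_true(all(rel$rpa[, d$matrix$is_peak] == 1))
  expect_true(all(rel$rpa > 0))
  expect_equal(dispersion_stats(rel$rpa[, d$matrix$is_peak])[1], 0)
})

test_that("RPA is invariant to rescaling a whole batch", {
  d <- gen_spectrum_effect(synthetic_spec(n_peaks = 6, seed = 6))
  m2 <- d$matrix
  m2$areas["S2", ] <- m2$areas["S2", ] * 7
  r1 <- relative_to_is(d$matrix)$rpa
  r2 <- relative_to_is(m2)$rpa
  expect_equal(r1["S2", ], r2["S2", ])
})

test_that("RRT is the plain retention-time ratio", {
  areas <- matrix(c(10, 20, 30, 40), 2,
                  dimnames = list(c("S1", "S2"), c("P1", "P2")))
  m <- new_common_peak_matrix(areas, rt = c(P1 = 5, P2 = 10),
                              mode = c(P1 = "positive", P2 = "positive"),
                              is_peak = "P1")
  expect_equal(unname(relative_to_is(m)$rrt[, "P2"]), c(2, 2))
})

test_that("dispersion stats match the hand-computed RSD", {
  expect_equal(dispersion_stats(c(1, 2, 3))[1], 50)
  expect_equal(dispersion_stats(rep(4, 5))[1], 0)
  x <- runif(10, 1, 5)
  expect_equal(dispersion_stats(3 * x)[1], dispersion_stats(x)[1])
  expect_error(dispersion_stats(1), "at least 2")
  expect_error(dispersion_stats(c(-1, 1)), "mean is zero")
  expect_equal(attr(dispersion_stats(c(1, 2), mode = "cv"), "mode"), "cv")
})

test_that("linearity screen agrees with closed-form OLS on curved series", {
  x <- 1 / c(2, 4, 8, 16, 32, 64)
  curved <- x / (x + 0.05)
  cal <- rbind(
    data.frame(peak = "P1", rel_conc = x, ratio = 2 * x),
    data.frame(peak = "P2", rel_conc = x, ratio = curved))
  rep <- linearity_screen(cal)
  expect_equal(rep$retained, "P1")
  expect_equal(rep$dropped, "P2")
  # closed-form R^2 = cor(x, y)^2 for simple regression
  expect_equal(rep$stats$r_squared[rep$stats$peak == "P2"],
               cor(x, curved)^2, tolerance = 1e-12)
  expect_setequal(c(rep$retained, rep$dropped), c("P1", "P2"))
  expect_error(linearity_screen(
    data.frame(peak = "P1", rel_conc = rep(1, 4), ratio = 1:4)),
    "degenerate")
})

test_that("fingerprint similarity is cosine against the mean reference", {
  areas <- rbind(S1 = c(1, 0), S2 = c(0, 1))
  colnames(areas) <- c("P1", "P2")
  m <- new_common_peak_matrix(areas, rt = c(P1 = 1, P2 = 2),
                              mode = c(P1 = "positive", P2 = "positive"),
                              is_peak = "P1")
  s <- fingerprint_similarity(m)
  # reference is (0.5, 0.5); both batches at 45 degrees
  expect_equal(as.numeric(s), rep(cos(pi / 4), 2), tolerance = 1e-12)
  # orthogonal fingerprints score 0 against each other
  expect_equal(cosine_similarity(areas["S1", ], areas["S2", ]), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")

  # a batch proportional to the reference scores exactly 1
  areas2 <- rbind(S1 = c(2, 4, 6), S2 = c(1, 2, 3), S3 = c(3, 6, 9))
  colnames(areas2) <- paste0("P", 1:3)
  m2 <- new_common_peak_matrix(areas2,
                               rt = setNames(1:3, colnames(areas2)),
                               mode = setNames(rep("positive", 3),
                                               colnames(areas2)),
                               is_peak = "P1")
  expect_equal(as.numeric(fingerprint_similarity(m2)), rep(1, 3),
               tolerance = 1e-12)
  expect_true(all(fingerprint_similarity(m) >= -1 &
                    fingerprint_similarity(m) <= 1))
})

test_that("legacy fingerprint files round-trip losslessly", {
  d <- gen_spectrum_effect(synthetic_spec(n_peaks = 7, seed = 13))
  path <- withr::local_tempfile(fileext = ".txt")
  write_legacy_fingerprint(d$matrix, path = path)
  back <- read_legacy_fingerprint(path)
  expect_setequal(names(back), rownames(d$matrix$areas))
  peaks <- colnames(d$matrix$areas)
  ord <- order(d$matrix$rt[peaks])
  for (b in names(back)) {
    expect_equal(back[[b]]$dataset1$rt, unname(d$matrix$rt[peaks]))
    expect_equal(back[[b]]$dataset1$intensity,
                 unname(d$matrix$areas[b, peaks]))
    expect_equal(back[[b]]$dataset2$area,
                 unname(d$matrix$areas[b, peaks])[ord])
    # block 2 is ordered by ascending retention time
    expect_false(is.unsorted(d$matrix$rt[peaks][ord]))
  }
})

test_that("legacy writer refuses an empty matrix", {
  d <- tiny_dataset(seed = 1, n_peaks = 4, active = 1)
  m <- d$matrix
  m$areas <- m$areas[, 0, drop = FALSE]
  path <- withr::local_tempfile(fileext = ".txt")
  expect_error(write_legacy_fingerprint(m, path = path), "empty")
  expect_false(file.exists(path))
})
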