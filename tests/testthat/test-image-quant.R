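params_for <- function(..., gamma = 0.8) {
  segmentation_params(thresholds = c(...), gamma = gamma)
}

test_that("preprocess preserves endpoints and evaluates gamma correctly", {
  p <- params_for(a = 0)
  r <- matrix(c(0, 5, 10), 1, 3) # normalized 0, 0.5, 1
  out <- preprocess(r, p)
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 3], 255)
  expect_equal(out[1, 2], 146) # round(255 * 0.5^0.8)
})

test_that("gamma 1 reduces preprocess to plain min-max rescale", {
  p <- segmentation_params(thresholds = c(a = 0), gamma = 1)
  withr::with_seed(8, r <- matrix(runif(400, 10, 900), 20, 20))
  out <- preprocess(r, p)
  expect_equal(out, round(255 * (r - min(r)) / (max(r) - min(r))))
})

test_that("preprocess handles constant images and preserves order", {
  p <- params_for(a = 0)
  expect_equal(preprocess(matrix(0, 4, 4), p), matrix(0, 4, 4))
  expect_equal(preprocess(matrix(7, 4, 4), p), matrix(0, 4, 4))
  withr::with_seed(2, r <- matrix(runif(256, 0, 65535), 16, 16))
  out <- preprocess(r, p)
  ord <- order(r)
  expect_true(all(diff(out[ord]) >= 0)) # monotone mapping
  expect_true(all(out >= 0 & out <= 255))
})

test_that("resize is applied and changes raster dimensions", {
  p <- segmentation_params(thresholds = c(a = 0), resize_factor = 0.5)
  withr::with_seed(3, r <- matrix(runif(1024), 32, 32))
  out <- preprocess(r, p)
  expect_equal(dim(out), c(16, 16))
})

test_that("segmentation is strict-greater and idempotent on rendered masks", {
  r <- matrix(0, 10, 10)
  r[1:5, 1:5] <- 200
  m <- segment(r, 128)
  expect_equal(sum(m), 25)
  expect_equal(sum(segment(r, 255)), 0)

  bin <- matrix(c(0, 255), 8, 8)
  expect_equal(segment(bin, 0), bin == 255, ignore_attr = TRUE)
  # re-segmenting a mask rendered as {0,255} at any threshold in [0,254]
  rendered <- (m * 255)
  for (thr in c(0, 1, 127, 254)) {
    expect_equal(segment(rendered, thr), m, ignore_attr = TRUE)
  }
  # ge mode includes the threshold value itself
  expect_equal(sum(segment(r, 200, mode = "ge")), 25)
  expect_equal(sum(segment(r, 200, mode = "gt")), 0)
})

test_that("percent area counts suprathreshold pixels", {
  expect_equal(percent_area(matrix(FALSE, 5, 5)), 0)
  expect_equal(percent_area(matrix(TRUE, 5, 5)), 100)
  m <- matrix(FALSE, 10, 10)
  m[1:5, 1:5] <- TRUE
  expect_equal(percent_area(m), 25)
})

test_that("merged area honors the provided-mask pass-through contract", {
  a <- matrix(FALSE, 6, 6); a[1, 1:2] <- TRUE
  b <- matrix(FALSE, 6, 6); b[3, 1:4] <- TRUE
  expect_equal(sum(merged_area(list(a))), sum(a))
  expect_equal(sum(merged_area(list(a, b))), 6) # disjoint 2 + 4
  prov <- matrix(TRUE, 6, 6)
  expect_identical(merged_area(list(a, b), provided = prov), prov)
  expect_error(merged_area(list(a, matrix(FALSE, 3, 3))), "shape")
  expect_error(merged_area(list(a), provided = matrix(TRUE, 2, 2)), "shape")
})

test_that("overlap metrics use AND area over merged and target denominators", {
  t0 <- matrix(FALSE, 20, 20); t0[1:4, 1:10] <- TRUE  # 40 px
  o <- matrix(FALSE, 20, 20); o[4, 1:10] <- TRUE      # AND = 10 px
  mg <- matrix(FALSE, 20, 20); mg[1:10, 1:20] <- TRUE # 200 px
  res <- overlap_metrics(t0, o, mg)
  expect_equal(res$overlap_pct_merged, 5)
  expect_equal(res$overlap_pct_target, 25)
  expect_equal(res$and_px, 10)

  same <- overlap_metrics(t0, t0, mg)
  expect_equal(same$overlap_pct_target, 100)
  disj <- overlap_metrics(t0, !t0 & mg, mg)
  expect_equal(disj$overlap_pct_merged, 0)
  expect_equal(disj$overlap_pct_target, 0)
})

test_that("zero denominators are undefined, not zero", {
  empty <- matrix(FALSE, 5, 5)
  full <- matrix(TRUE, 5, 5)
  res <- overlap_metrics(empty, full, full)
  expect_true(is.na(res$overlap_pct_target))
  expect_equal(res$overlap_pct_merged, 0)
  res2 <- overlap_metrics(full, full, empty)
  expect_true(is.na(res2$overlap_pct_merged))
})

test_that("membership map counts per-pixel channel membership", {
  e <- matrix(FALSE, 4, 4)
  mm <- membership_map(list(e, e))
  expect_true(all(mm$counts == 0))

  a <- e; a[2, 2] <- TRUE
  mm2 <- membership_map(list(a, a))
  expect_equal(mm2$counts[2, 2], 2)
  expect_equal(sum(mm2$counts), 2)

  b <- e; b[2, 2] <- TRUE; b[1, 1] <- TRUE
  mm3 <- membership_map(list(a, a, b))
  expect_equal(mm3$counts[2, 2], 3)
  expect_equal(mm3$counts[1, 1], 1)
  expect_named(mm3$legend, c("2", "3", "4"))

  expect_error(membership_map(list(a)), "2-4")
  expect_error(membership_map(rep(list(a), 5)), "2-4")
})

test_that("live/dead ratio is the ratio of percent areas", {
  g <- matrix(0, 10, 10); g[1:2, ] <- 200  # 20 %
  r <- matrix(0, 10, 10); r[10, ] <- 200   # 10 %
  p <- params_for(green = 100, red = 100, gamma = 1)
  res <- live_dead_ratio(g, r, p)
  expect_equal(res$ratio, 2)
  expect_false(res$undefined)

  same <- live_dead_ratio(g, g, p)
  expect_equal(same$ratio, 1)

  res0 <- live_dead_ratio(g, matrix(0, 10, 10), p)
  expect_true(res0$undefined)
  expect_error(live_dead_ratio(g, matrix(0, 3, 3), p), "shapes")
})

test_that("aggregate averages technical replicates with pairwise NA removal", {
  mk_report <- function(pct, ov = 50, well = "w1") {
    f <- matrix(FALSE, 10, 10)
    structure(list(
      channel_area = tibble::tibble(channel = "a", area_px = pct,
                                    pct_field = pct, pct_merged = pct),
      overlaps = tibble::tibble(target = "a", other = "b",
                                overlap_pct_merged = ov,
                                overlap_pct_target = ov, and_px = 1),
      merged_area_px = 1, n_px = 100, masks = list(), merged_mask = f,
      field_id = paste0("f", pct), well_id = well,
      condition = list(dose_mM = 0, status = "Diff")
    ), class = "area_report")
  }
  s <- aggregate_fields(list(mk_report(10), mk_report(20), mk_report(30)))
  row <- s[s$metric == "pct_field", ]
  expect_equal(row$mean, 20)
  expect_equal(row$sd, 10)
  expect_equal(row$n_fields, 3)

  one <- aggregate_fields(list(mk_report(10)))
  expect_true(is.na(one$sd[one$metric == "pct_field"]))

  ident <- aggregate_fields(list(mk_report(10), mk_report(10)))
  expect_true(all(ident$sd == 0))

  # undefined overlap in one field: excluded pairwise, n recorded
  s2 <- aggregate_fields(list(mk_report(10, ov = NA), mk_report(20, ov = 40)))
  ovr <- s2[s2$metric == "overlap_pct_target", ]
  expect_equal(ovr$mean, 40)
  expect_equal(ovr$n_fields, 1)

  expect_error(aggregate_fields(list()), "no field reports")
  expect_error(aggregate_fields(list(mk_report(10), mk_report(10, well = "w2"))),
               "more than one well")
})

test_that("raising a threshold never increases percent area", {
  withr::with_seed(14, {
    for (i in 1:5) {
      r <- matrix(runif(900, 0, 255), 30, 30)
      thr <- sort(runif(4, 0, 255))
      areas <- vapply(thr, function(t) percent_area(segment(r, t)),
                      numeric(1))
      expect_true(all(diff(areas) <= 0))
    }
  })
})

test_that("quantifying the same field twice is bit-identical", {
  fg <- generate_field(15, c(64, 64),
                       channels = list(channel_spec("a", radius = 3),
                                       channel_spec("b", radius = 3)),
                       coloc = c("a|b" = 0.4), seed = 6)
  p <- params_for(a = 10, b = 10)
  r1 <- quantify_field(fg$field, p)
  r2 <- quantify_field(fg$field, p)
  expect_identical(r1$channel_area, r2$channel_area)
  expect_identical(r1$overlaps, r2$overlaps)
})

test_that("quantify_field requires a threshold per channel and uses the
           provided merged mask", {
  fg <- generate_field(10, c(64, 64),
                       channels = list(channel_spec("a", radius = 3),
                                       channel_spec("b", radius = 3)),
                       seed = 7)
  expect_error(quantify_field(fg$field, params_for(a = 10)), "threshold")

  fld <- fg$field
  fld$merged_mask <- matrix(TRUE, 64, 64)
  rep_prov <- quantify_field(fld, params_for(a = 10, b = 10))
  expect_equal(rep_prov$merged_area_px, 64 * 64)
  rep_union <- quantify_field(fld, params_for(a = 10, b = 10),
                              merged_policy = "union")
  expect_lt(rep_union$merged_area_px, 64 * 64)
})

test_that("small-field metrics equal the naive pixel-loop oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      nr <- sample(4:32, 1); nc <- sample(4:32, 1)
      a <- random_mask(nr, nc); b <- random_mask(nr, nc)
      mg <- merged_area(list(a, b))
      expect_identical(sum(a), oracle_count(a))
      expect_identical(percent_area(a), oracle_percent_area(a))
      expect_identical(unname(mg), oracle_union(list(a, b)))
      om <- overlap_metrics(a, b, mg)
      expect_identical(om$and_px, oracle_and_count(a, b))
    }
  })
})

test_that("area report long form and CSV export carry every metric", {
  fg <- generate_field(10, c(64, 64),
                       channels = list(channel_spec("a", radius = 3),
                                       channel_spec("b", radius = 3)),
                       seed = 9)
  rep1 <- quantify_field(fg$field, params_for(a = 10, b = 10))
  long <- area_report_long(rep1)
  expect_setequal(unique(long$metric),
                  c("pct_field", "pct_merged", "overlap_pct_merged",
                    "overlap_pct_target"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep1, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(long))
})
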