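make_ct_fixture <- function() {
  # hand-built 3-replicate table: one target, one housekeeping gene
  tibble::tibble(
    gene = rep(c("NRXN1a", "B-ACTIN"), each = 6),
    group = rep(rep(c("UnDiff", "Diff"), each = 3), 2),
    dose_mM = 0,
    replicate = rep(1:3, 4),
    ct = c(25, 26, 27, 24, 25, 26, # target
           20, 20, 20, 19, 20, 21) # housekeeping
  )
}

test_that("delta_ct pairs target and reference within replicate", {
  tab <- make_ct_fixture()
  dct <- delta_ct(tab, "B-ACTIN")
  expect_equal(nrow(dct), 6)
  ud <- dct[dct$group == "UnDiff", ]
  expect_equal(ud$dct[order(ud$replicate)], c(5, 6, 7))
  di <- dct[dct$group == "Diff", ]
  expect_equal(di$dct[order(di$replicate)], c(5, 5, 5))
})

test_that("rows without a matching reference replicate are dropped loudly", {
  tab <- make_ct_fixture()
  tab <- tab[!(tab$gene == "B-ACTIN" & tab$group == "UnDiff" &
                 tab$replicate == 3), ]
  expect_warning(dct <- delta_ct(tab, "B-ACTIN"), "dropped")
  expect_equal(nrow(dct), 5)
  expect_error(delta_ct(tab, "NOPE"), "not present")
})

test_that("fold change follows 2^-ddCt and is 1 at the calibrator mean", {
  expect_equal(fold_change(5, calibrator_mean_dct = 5)$fold_change, 1)
  expect_equal(fold_change(6, calibrator_mean_dct = 5)$fold_change, 0.5)
  expect_equal(fold_change(3, calibrator_mean_dct = 5)$fold_change, 4)
  # evaluated at the calibrator group's own mean: exactly 1
  dcts <- c(4.2, 5.1, 5.7)
  expect_identical(fold_change(mean(dcts), mean(dcts))$fold_change, 1)
  # alternative summary
  expect_equal(
    fold_change(c(4, 6), 5, summary = "fc_of_mean")$fold_change, 1)
  expect_equal(
    fold_change(c(4, 6), 5, summary = "mean_fc")$fold_change, 1.25)
  # configurable efficiency
  expect_equal(fold_change(6, 5, efficiency = 1.9)$fold_change, 1 / 1.9)
})

test_that("calibrator conventions select the stated group means", {
  tab <- make_ct_fixture()
  tab2 <- tab
  tab2$dose_mM <- 35
  tab2$ct <- tab2$ct + 1
  dct <- delta_ct(dplyr::bind_rows(tab, tab2), "B-ACTIN")

  cross <- select_calibrator(dct, "cross")
  expect_equal(cross$calibrator_mean_dct, 6) # mean of (5,6,7), UnDiff 0 mM

  within <- select_calibrator(dct, "within")
  expect_equal(
    within$calibrator_mean_dct[within$group == "Diff"], 5)
  expect_equal(
    within$calibrator_mean_dct[within$group == "UnDiff"], 6)

  no_cal <- dct[!(dct$group == "UnDiff" & dct$dose_mM == 0), ]
  expect_error(select_calibrator(no_cal, "cross"), "NRXN1a")
})

test_that("zero-noise synthetic tables round-trip fold changes exactly", {
  fcs <- c("NRXN1a.Diff.35" = 0.25, "NRXN1a.UnDiff.7" = 3,
           "NRXN2b.Diff.7" = 0.8, "NRXN3b.UnDiff.35" = 1.7)
  truth <- ct_ground_truth(fold_change = fcs, replicate_sd = 0, seed = 11)
  tab <- generate_ct_table(truth, n_reps = 3)
  res <- ddct_quantify(tab, hk_gene = "B-ACTIN", convention = "cross")
  for (nm in names(fcs)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    got <- res$fold_change[res$gene == parts[1] & res$group == parts[2] &
                             res$dose_mM == as.numeric(parts[3])]
    expect_equal(got, unname(fcs[nm]))
  }
  # all unspecified cells stay at 1
  expect_true(all(abs(res$fold_change[!paste(res$gene, res$group,
                                             res$dose_mM, sep = ".") %in%
                                        names(fcs)] - 1) < 1e-12))
})

test_that("within-status convention renormalizes each status to its 0 mM", {
  truth <- ct_ground_truth(
    fold_change = c("NRXN1a.Diff.0" = 1, "NRXN1a.Diff.35" = 0.5),
    replicate_sd = 0, seed = 2, convention = "cross"
  )
  tab <- generate_ct_table(truth, n_reps = 3)
  res <- ddct_quantify(tab, hk_gene = "B-ACTIN", convention = "within")
  expect_equal(
    res$fold_change[res$gene == "NRXN1a" & res$group == "Diff" &
                      res$dose_mM == 35], 0.5)
  # both 0 mM cells are their own calibrators -> exactly 1
  expect_equal(res$fold_change[res$dose_mM == 0],
               rep(1, sum(res$dose_mM == 0)))
})

test_that("fold changes are invariant to a constant Ct shift of one gene", {
  truth <- ct_ground_truth(fold_change = c("NRXN1a.Diff.35" = 0.3),
                           replicate_sd = 0.2, seed = 4)
  tab <- generate_ct_table(truth, n_reps = 3)
  res1 <- ddct_quantify(tab, hk_gene = "B-ACTIN", convention = "cross")
  tab2 <- tab
  tab2$ct[tab2$gene == "NRXN1a"] <- tab2$ct[tab2$gene == "NRXN1a"] + 3.7
  res2 <- ddct_quantify(tab2, hk_gene = "B-ACTIN", convention = "cross")
  expect_equal(res1$fold_change, res2$fold_change)
})

test_that("noisy estimates concentrate around truth at large n_reps", {
  truth <- ct_ground_truth(genes = "NRXN1a",
                           fold_change = c("NRXN1a.Diff.35" = 0.5),
                           replicate_sd = 0.2, seed = 21)
  tab <- generate_ct_table(truth, n_reps = 50)
  res <- ddct_quantify(tab, hk_gene = "B-ACTIN", convention = "cross")
  got <- res$fold_change[res$gene == "NRXN1a" & res$group == "Diff" &
                           res$dose_mM == 35]
  expect_gt(got, 0.45)
  expect_lt(got, 0.55)
  # all target-gene cells within 10% of truth at this noise level
  res_t <- res[res$gene %in% truth$genes, ]
  key <- paste(res_t$gene, res_t$group, res_t$dose_mM, sep = ".")
  expect_true(all(abs(res_t$fold_change / truth$fold_change[key] - 1) < 0.1))
})

test_that("ct table validation and CSV round trip", {
  tab <- make_ct_fixture()
  expect_error(as_ct_table(tab[, -5]), "missing columns")
  bad <- tab; bad$ct[1] <- -1
  expect_error(as_ct_table(bad), "positive")
  p <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(tab, p)
  back <- read_ct_table(p)
  expect_equal(back$ct, tab$ct)
  expect_equal(back$gene, tab$gene)
})

test_that("generator validates its ground truth", {
  expect_error(ct_ground_truth(fold_change = c("NRXN1a.Diff.35" = -2)),
               "positive")
  expect_error(ct_ground_truth(fold_change = c("NRXN1a.UnDiff.0" = 2)),
               "calibrator")
  expect_error(ct_ground_truth(fold_change = c("BOGUS.Diff.35" = 2)),
               "unknown")
  truth <- ct_ground_truth(seed = 1)
  expect_error(generate_ct_table(truth, n_reps = 1), "n_reps")
})

test_that("ct generator is deterministic given its seed", {
  truth <- ct_ground_truth(replicate_sd = 0.3, seed = 77)
  t1 <- generate_ct_table(truth, n_reps = 3)
  t2 <- generate_ct_table(truth, n_reps = 3)
  expect_identical(t1, t2)
  t3 <- generate_ct_table(ct_ground_truth(replicate_sd = 0.3, seed = 78),
                          n_reps = 3)
  expect_false(identical(t1$ct, t3$ct))
})
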