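test_that("calibration fits recover a known line and flag short designs", {
  lv <- c(1, 2, 5, 10, 25, 50, 100, 250)
  cal <- fit_calibration(data.frame(conc = lv, ratio = 0.02 * lv))
  expect_equal(cal$slope, 0.02, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$range, c(1, 250))
  set.seed(31)
  noisy <- fit_calibration(data.frame(
    conc = lv, ratio = 0.02 * lv * (1 + rnorm(length(lv), 0, 0.01))))
  expect_gte(noisy$r_squared, 0.98)
  expect_error(fit_calibration(data.frame(conc = c(1, 10), ratio = c(1, 2))),
               "at least 3")
})

test_that("detection limits follow the blank-statistics formulas", {
  lim <- compute_lod_loq(0, 0.07, 0.02)
  expect_equal(lim[["loq"]] / lim[["lod"]], 10 / 3, tolerance = 1e-12)
  # a blank SD tuned to LOD 7.7 gives LOQ 25.7 at one decimal
  sd77 <- 0.02 * 7.7 / 3
  lim2 <- compute_lod_loq(0, sd77, 0.02)
  expect_equal(round(lim2[["lod"]], 1), 7.7)
  expect_equal(round(lim2[["loq"]], 1), 25.7)
  # nonzero blank signal shifts both limits additively
  lim3 <- compute_lod_loq(0.01, 0.07, 0.02)
  expect_equal(lim3[["lod"]] - lim[["lod"]], 0.5, tolerance = 1e-12)
  expect_true(all(compute_lod_loq(0.3, 0.1, 0.05)[["loq"]] >=
                    compute_lod_loq(0.3, 0.1, 0.05)[["lod"]]))
  expect_error(compute_lod_loq(0, 0.1, 0), "positive")
})

test_that("recovery and blank adjustments rescale the LOQ", {
  expect_equal(adjust_loq_for_recovery(10, 0.5), 20)
  expect_equal(adjust_loq_for_recovery(10, 1.0), 10)
  expect_equal(adjust_loq_for_recovery(10, 0.61), 10)   # above threshold
  expect_error(adjust_loq_for_recovery(10, 0), "positive")
  expect_equal(blank_adjusted_loq(4.2, 92.7), 278.1)
  expect_equal(blank_adjusted_loq(1.5, 3.3), 9.9)
  expect_equal(blank_adjusted_loq(3.3, 0), 3.3)
  expect_error(blank_adjusted_loq(3.3, 1, factor = 0), "positive")
})

test_that("isotope dilution cancels matrix suppression", {
  lv <- c(1, 5, 25, 100, 250)
  curve <- fit_calibration(data.frame(conc = lv, ratio = 0.015 * lv))
  # 50 ng/g with 40% suppression hitting analyte and surrogate alike
  supp <- 0.6
  q <- isotope_dilution_quantify(50 * 1500 * supp, 100 * 1000 * supp, curve)
  expect_equal(q$conc, 50, tolerance = 1e-9)
  q0 <- isotope_dilution_quantify(0, 1e5, curve)
  expect_equal(q0$conc, 0)
  expect_error(isotope_dilution_quantify(100, 0, curve), "positive")
  neg <- fit_calibration(data.frame(conc = lv, ratio = 0.015 * lv + 0.1))
  fl <- isotope_dilution_quantify(0, 1e5, neg)
  expect_equal(fl$flag, "floored")
})

test_that("quantification recovers simulated concentrations to under 2%", {
  set.seed(32)
  lv <- c(1, 2, 5, 10, 25, 50, 100, 250)
  curve <- fit_calibration(data.frame(conc = lv, ratio = 0.012 * lv))
  n <- 200
  truth <- exp(runif(n, log(1), log(250)))
  supp <- runif(n, 0.5, 1)
  noise <- function(n) exp(rnorm(n, 0, 0.01))
  analyte <- truth * 1200 * supp * noise(n)
  surrogate <- 100 * 1000 * supp * noise(n)
  est <- isotope_dilution_quantify(analyte, surrogate, curve)$conc
  expect_lt(stats::median(abs(est - truth) / truth), 0.02)
})

test_that("reporting labels respect the limits and the blank rule", {
  expect_equal(classify_detection(6.5, 0.6, 2.1), "quantified")
  expect_equal(classify_detection(2.0, 1.0, 3.5), "<LOQ")
  expect_equal(classify_detection(0.5, 1.0, 3.5), "n.d.")
  # signal above LOD but under 3x a contaminated blank
  expect_equal(classify_detection(100, 1.2, 4.2, blank_conc = 92.7), "n.r.")
  expect_equal(classify_detection(300, 1.2, 4.2, blank_conc = 92.7),
               "quantified")
  expect_error(classify_detection(1, 5, 2), "LOD")
})

test_that("the label ordering is monotone in concentration", {
  rank_of <- c("n.d." = 1, "n.r." = 2, "<LOQ" = 2, "quantified" = 3)
  grid <- expand.grid(blank = c(0, 2), conc = seq(0, 30, by = 0.25))
  for (b in unique(grid$blank)) {
    labs <- vapply(grid$conc[grid$blank == b], function(cc)
      classify_detection(cc, 1.0, 3.3, blank_conc = b), character(1))
    expect_true(all(diff(rank_of[labs]) >= 0))
  }
})

test_that("group summaries count detections and sum quantified means only", {
  tab <- data.frame(
    analyte = c("A", "B", "C", "D"), group = "WAS", n = 3,
    mean = c(10, 1.5, 8, 50), rsd = 5, lod = 1, loq = 3,
    adjusted_loq = 3, blank_conc = 0,
    label = c("quantified", "<LOQ", "n.r.", "quantified"),
    stringsAsFactors = FALSE)
  s <- summarize_quantification(tab)
  expect_equal(s$total_pfas, 60)
  expect_equal(s$n_detections, 4)
  expect_equal(s$n_quantified, 2)
  # invariant to row order and to the presence of non-quantified labels
  s2 <- summarize_quantification(tab[sample(nrow(tab)), ])
  expect_equal(s2$total_pfas, s$total_pfas)
  s3 <- summarize_quantification(tab[tab$label == "quantified", ])
  expect_equal(s3$total_pfas, s$total_pfas)
})

test_that("replicate statistics handle degenerate cases", {
  tf <- generate_targeted_fixture(fixture_config(seed = 5, rsd_was = 0,
                                                 rsd_ps = 0))
  q <- quantify_targets(tf$samples, tf$calibration, tf$blank_stats)
  sub <- q$table[q$table$analyte == "PFOS" & q$table$group == "WAS", ]
  expect_equal(sub$rsd, 0, tolerance = 1e-6)
  one <- tf$samples[tf$samples$sample %in% c("WAS1", "blank1") &
                      tf$samples$analyte == "PFOS", ]
  q1 <- quantify_targets(one, tf$calibration, tf$blank_stats)
  expect_true(is.na(q1$table$rsd[1]))
})

test_that("single-point suspect estimates round-trip the simulated truth", {
  expect_equal(estimate_suspect_concentration(500, 500, 100)$conc, 100)
  sf <- generate_suspect_fixture()
  ref <- sf$ground_truth$reference
  was1 <- sf$features[sf$features$sample == "WAS1", ]
  area <- was1$area[abs(was1$mz - 341.0044) < 1e-6]
  est <- estimate_suspect_concentration(area, ref$area, ref$conc)
  expect_equal(est$conc, 35.9, tolerance = 1e-6)
  expect_true(est$semi_quantitative)
  expect_error(estimate_suspect_concentration(100, 0, 100), "positive")
})

test_that("missing calibration or surrogate areas become named errors", {
  tf <- generate_targeted_fixture()
  cal <- tf$calibration[tf$calibration$analyte != "PFOA", ]
  q <- quantify_targets(tf$samples, cal, tf$blank_stats)
  expect_true(any(grepl("PFOA", q$errors)))
  smp <- tf$samples
  smp$surrogate_area[smp$analyte == "PFOS" & smp$group == "WAS"] <- 0
  q2 <- quantify_targets(smp, tf$calibration, tf$blank_stats)
  expect_true(any(grepl("PFOS", q2$errors)))
})
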