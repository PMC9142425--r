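curated_suspects <- function() {
  blacklist_nonionizable(curate_suspects(default_suspect_list())$kept)
}

test_that("precursor matching applies the ppm window and merges isomers", {
  sus <- curated_suspects()
  ft <- make_features(c(341.0044, 341.0100))
  m <- match_precursors(ft, sus)
  expect_equal(nrow(m), 1)                       # 341.0100 is ~17 ppm off
  expect_equal(m$suspect_ids, "53FTCA")
  expect_lt(abs(m$ppm), 5)
  # two suspects sharing a formula collapse into one isomer set
  iso <- sus[sus$id %in% c("PFOA", "PFOS"), ]
  iso$formula <- "C8HF15O2"
  iso$mz_mh <- anion_mz("C8HF15O2")
  m2 <- match_precursors(make_features(iso$mz_mh[1]), iso)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$isomer_n, 2)
})

test_that("precursor matching agrees with an exhaustive all-pairs oracle", {
  sus <- curated_suspects()
  active <- sus[!sus$excluded, ]
  set.seed(21)
  mz <- c(runif(150, 80, 1200),
          sample(active$mz_mh, 50, replace = TRUE) *
            (1 + runif(50, -8e-6, 8e-6)))
  ft <- make_features(mz)
  got <- match_precursors(ft, sus)
  got_pairs <- unlist(lapply(seq_len(nrow(got)), function(i)
    paste(got$feature_idx[i],
          strsplit(got$suspect_ids[i], ";")[[1]])))
  want_pairs <- character(0)
  for (i in seq_along(mz))
    for (j in seq_len(nrow(active)))
      if (abs((mz[i] - active$mz_mh[j]) / active$mz_mh[j] * 1e6) <= 5)
        want_pairs <- c(want_pairs, paste(i, active$id[j]))
  expect_setequal(got_pairs, want_pairs)
})

test_that("fragment annotation matches rules uniquely and bounds fragments", {
  rules <- default_fragment_rules()
  prec <- anion_mz("C6H7F5O2")
  ann <- annotate_fragments(spectrum_of(205.0293, c(118.9937, 161.0407)),
                            prec, rules)
  expect_setequal(ann$label, c("C2F5", "M-CO2"))
  expect_true(all(abs(ann$ppm) <= 10))
  # phosphate fragment
  ann2 <- annotate_fragments(spectrum_of(726.9583, 78.9596),
                             anion_mz("C14H6F25O3P"), rules)
  expect_equal(ann2$label, "PO3")
  # a fragment above the precursor is never annotated
  ann3 <- annotate_fragments(spectrum_of(205.0293, 500.0), prec, rules)
  expect_equal(nrow(ann3), 0)
  expect_equal(nrow(annotate_fragments(NULL, prec, rules)), 0)
  # one annotation per observed fragment even when two rules are close
  expect_lte(max(table(ann$observed_mz)), 1)
})

test_that("the mass-defect rule distinguishes windowed, flagged and failed", {
  expect_equal(apply_mass_defect_rule(370.0546, "C11H12F7NO5"), "in_window")
  # positive defect outside the window on a partially fluorinated formula
  expect_equal(apply_mass_defect_rule(463.1337, "C17H25F9O2S"), "flagged")
  expect_equal(apply_mass_defect_rule(463.1337, "C17H25F9O2S",
    screening_config(partial_fluorination_override = FALSE)), "fail")
  # below the window with no exception
  expect_equal(apply_mass_defect_rule(250.70, "C8HF15O2"), "fail")
})

test_that("homologous-series detection recovers CF2 ladders", {
  pfca <- vapply(4:9, function(n)
    anion_mz(sprintf("C%dHF%dO2", n, 2 * n - 1)), numeric(1))
  ft <- make_features(pfca)
  s <- detect_homologous_series(ft)
  expect_equal(length(unique(s$series_id)), 1)
  expect_equal(sort(s$feature_idx), 1:6)
  expect_true(all(abs(s$kmd - s$series_kmd) <= 0.002))
  # decoy at a distant KMD is excluded
  decoy <- 413.31
  s2 <- detect_homologous_series(make_features(c(pfca, decoy)))
  expect_false((length(pfca) + 1) %in% s2$feature_idx)
  # two members at minimum length three: no series
  s3 <- detect_homologous_series(make_features(pfca[1:2]))
  expect_equal(nrow(s3), 0)
})

test_that("confidence levels follow the evidence hierarchy", {
  sf <- generate_suspect_fixture()
  run <- function(refs = sf$references, lib = sf$library)
    screen_suspects(sf$features, sf$suspects, references = refs,
                    library = lib)
  res <- run()
  cand <- res$candidates
  expect_equal(cand$level[cand$suspect_ids == "53FTCA"], "1")
  expect_equal(cand$level[cand$suspect_ids == "62diPAP"], "2a")
  expect_equal(sum(cand$level == "3"), 5)
  # removing the library record demotes the diPAP to 2b (its chain
  # fragment is structure-specific); removing the standard demotes FTCA
  res2 <- run(lib = NULL)
  expect_equal(res2$candidates$level[res2$candidates$suspect_ids == "62diPAP"],
               "2b")
  res3 <- run(refs = NULL)
  lv <- res3$candidates$level[res3$candidates$suspect_ids == "53FTCA"]
  expect_false(identical(lv, "1"))
})

test_that("the screening report is sorted, blacklists FTOH and kills decoys", {
  sf <- generate_suspect_fixture()
  res <- screen_suspects(sf$features, sf$suspects,
                         references = sf$references, library = sf$library)
  cand <- res$candidates
  expect_equal(nrow(cand), 7)
  expect_equal(cand$mz, sort(cand$mz))
  expect_false("82FTOH" %in% unlist(strsplit(cand$suspect_ids, ";")))
  truth_ids <- sf$ground_truth$injected$id
  expect_setequal(unlist(strsplit(cand$suspect_ids, ";")), truth_ids)
  # empty input gives an empty report
  empty <- suppressWarnings(
    screen_suspects(sf$features[0, ], sf$suspects,
                    references = sf$references, library = sf$library))
  expect_equal(nrow(empty$candidates), 0)
})

test_that("random out-of-window decoys are never reported", {
  sus <- curated_suspects()
  set.seed(22)
  n <- 1000
  mz <- numeric(0)
  while (length(mz) < n) {
    x <- runif(n, 80, 1200)
    md <- mass_defect(x)
    mz <- c(mz, x[md < -0.25 | md > 0.1])
  }
  mz <- mz[1:n]
  ft <- rbind(make_features(mz, rt = runif(n, 1, 28)),
              make_features(900.555, sample = "B1", role = "blank"))
  res <- screen_suspects(ft, sus)
  expect_equal(nrow(res$candidates), 0)
})

test_that("tightening tolerances never adds candidates", {
  sf <- generate_suspect_fixture()
  base <- screen_suspects(sf$features, sf$suspects,
                          references = sf$references, library = sf$library)
  tighter <- list(
    screening_config(precursor_ppm = 2),
    screening_config(fragment_ppm = 3),
    screening_config(md_window = c(-0.1, 0.05)),
    screening_config(min_fragments = 2),
    screening_config(min_fragments = 3))
  for (cfg in tighter) {
    res <- screen_suspects(sf$features, sf$suspects,
                           references = sf$references,
                           library = sf$library, config = cfg)
    expect_lte(nrow(res$candidates), nrow(base$candidates))
  }
})

test_that("reported evidence only cites annotations inside the tolerance", {
  sf <- generate_suspect_fixture()
  res <- screen_suspects(sf$features, sf$suspects,
                         references = sf$references, library = sf$library)
  for (ann in res$annotations) {
    if (!nrow(ann)) next
    expect_true(all(abs(ann$ppm) <= res$config$fragment_ppm))
    # brute-force recheck against every (fragment, rule) pair
    rules <- default_fragment_rules()
    for (r in seq_len(nrow(ann))) {
      expect_lte(abs(ppm_error(ann$observed_mz[r], ann$theoretical_mz[r])),
                 res$config$fragment_ppm)
    }
  }
})
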