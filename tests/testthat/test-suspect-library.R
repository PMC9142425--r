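write_suspects_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("id,name,cas,formula,smiles,class", rows), path)
  path
}

test_that("suspect lists load with recomputed masses", {
  path <- write_suspects_csv(c(
    "PFOA,Perfluorooctanoic acid,335-67-1,C8HF15O2,,PFCA",
    "PFOS,Perfluorooctanesulfonic acid,1763-23-1,C8HF17O3S,,PFSA",
    "53FTCA,5:3 FTCA,,C8H5F11O2,,FTCA"))
  sus <- read_suspect_list(path)
  expect_equal(nrow(sus), 3)
  expect_equal(sus$neutral_mass[sus$id == "PFOA"], 413.9737, tolerance = 1e-4)
  expect_false(any(is.na(sus$mz_mh)))
  expect_false(any(sus$excluded))
})

test_that("loading rejects duplicates and bad schemas, skips bad formulas", {
  dup <- write_suspects_csv(c("A,x,,C2F5H,,PFCA", "A,y,,C3F7H,,PFCA"))
  expect_error(read_suspect_list(dup), "duplicate.*A")
  nocol <- tempfile(fileext = ".csv")
  writeLines(c("id,name", "A,x"), nocol)
  expect_error(read_suspect_list(nocol), "mandatory column")
  bad <- write_suspects_csv(c("A,x,,C2F5H,,PFCA", "B,y,,NotAFormula!,,PFCA"))
  expect_warning(sus <- read_suspect_list(bad), "skipped")
  expect_equal(sus$id, "A")
})

test_that("curation removes out-of-range and salt entries with reasons", {
  path <- write_suspects_csv(c(
    "PFOA,free acid,,C8HF15O2,,PFCA",
    "NaPFOA,sodium salt,,C8F15O2Na,,other",
    "BIG,polymer,,C30H4F58O4,,other",
    "KPFBS,potassium salt no free acid,,C4F9O3SK,,PFSA"))
  sus <- read_suspect_list(path)
  cur <- curate_suspects(sus)
  expect_setequal(cur$removed$id, c("NaPFOA", "BIG"))
  expect_equal(cur$removed$reason[cur$removed$id == "NaPFOA"], "salt adduct")
  expect_equal(cur$removed$reason[cur$removed$id == "BIG"], "above scan range")
  # the potassium salt had no free-acid twin: normalized and kept
  kp <- cur$kept[cur$kept$id == "KPFBS", ]
  expect_equal(kp$formula, "C4HF9O3S")
  expect_equal(kp$mz_mh, anion_mz("C4HF9O3S"), tolerance = 1e-9)
  expect_true(all(cur$kept$mz_mh <= 1200))
  # idempotent
  again <- curate_suspects(cur$kept)
  expect_equal(again$kept, cur$kept)
  expect_equal(nrow(again$removed), 0)
})

test_that("curation and blacklisting commute on disjoint criteria", {
  sus <- default_suspect_list()
  a <- blacklist_nonionizable(curate_suspects(sus)$kept)
  b <- curate_suspects(blacklist_nonionizable(sus))$kept
  expect_equal(a[order(a$id), ], b[order(b$id), ], ignore_attr = TRUE)
})

test_that("blacklisting excludes poorly ionizable classes but keeps rows", {
  sus <- default_suspect_list()
  bl <- blacklist_nonionizable(sus)
  expect_true(all(bl$excluded[bl$class == "FTOH"]))
  expect_false(any(bl$excluded[bl$class == "PFCA"]))
  expect_equal(nrow(bl), nrow(sus))
  expect_false(any(blacklist_nonionizable(sus, character(0))$excluded))
  expect_error(blacklist_nonionizable(sus, "NOT_A_CLASS"), "unknown class")
})

test_that("default fragment rules reproduce the annotated fragment ions", {
  rules <- default_fragment_rules()
  expect_false(anyDuplicated(rules$label) > 0)
  prod <- function(lbl) rules$mz[rules$label == lbl]
  expect_lt(abs(ppm_error(168.9905, prod("C3F7"))), 10)
  expect_lt(abs(ppm_error(78.9596, prod("PO3"))), 10)
  # CO2 neutral loss from the pentafluoro-methylpentanoate precursor
  prec <- anion_mz("C6H7F5O2")
  loss <- prec - rules$neutral_mass[rules$label == "M-CO2"]
  expect_equal(loss, 161.0395, tolerance = 1e-4)
  expect_lt(abs(ppm_error(161.0407, loss)), 10)
})

test_that("fragment rules load from CSV with derived masses", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("label,kind,formula,classes",
               "CF3,product,CF3,PFCA",
               "M-CO2,loss,CO2,PFCA"), path)
  rules <- read_fragment_rules(path)
  expect_equal(rules$mz[1], anion_mz("CF3", "anion"))
  expect_equal(rules$neutral_mass[2], monoisotopic_mass("CO2"))
  expect_false(any(rules$structure_specific))
  dup <- tempfile(fileext = ".csv")
  writeLines(c("label,kind,formula,classes", "A,product,CF3,PFCA",
               "A,loss,CO2,PFCA"), dup)
  expect_error(read_fragment_rules(dup), "duplicate")
})

test_that("MGF round-trips spectra and the library rescales intensities", {
  spec <- list(
    a = spectrum_of(341.0044, c(216.9894, 236.9963), c(500, 250)),
    b = spectrum_of(788.9751, c(78.9596, 442.9750), c(60, 100)))
  spec$a$title <- "a"; spec$b$title <- "b"
  path <- tempfile(fileext = ".mgf")
  write_mgf(spec, path)
  back <- read_mgf(path)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a$precursor_mz, 341.0044)
  expect_equal(back$a$peaks[, "mz"], spec$a$peaks[, "mz"],
               ignore_attr = TRUE)
  lib <- read_spectral_library(path)
  expect_equal(max(lib$b$peaks[, "intensity"]), 1)
})
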