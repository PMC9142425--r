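# Deterministic, seeded generators for the full study fixture: calibration
# sets, sample/blank replicates carrying the targeted panel, suspect
# features with their fragmentation spectra, CF2 homologous series and
# matrix decoys. Every non-noise feature is recorded in the accompanying
# ground truth, which is the oracle for the recovery tests.

#' Fixture generator configuration
#'
#' Study-design parameters of the synthetic fixtures. Defaults emulate the
#' biosolids study the workflow is built around: triplicate waste-activated
#' sludge (WAS), lime-stabilized primary solids (PS) and extraction blanks;
#' tight WAS replicates (8% RSD) against heterogeneous PS replicates
#' (45% RSD, modelling contaminant hot spots in the drier matrix);
#' calibration from 1 to 250 ng/g; matrix suppression applied equally to
#' analyte and co-extracted surrogate so that isotope dilution cancels it.
#' Measurement (area) noise is off by default; replicate spread models
#' sample heterogeneity, not instrument error.
#'
#' @param seed Integer random seed; fixed seed gives identical fixtures.
#' @param replicates Replicates per sample group.
#' @param rsd_was,rsd_ps,rsd_blank Replicate relative standard deviations
#'   (fractions) for the WAS, PS and blank groups.
#' @param n_decoys Number of random matrix decoy peaks in the suspect
#'   fixture.
#' @param suppression_range Per-sample matrix suppression factor range.
#' @param area_rsd Multiplicative measurement noise on individual areas.
#' @param surrogate_spike Surrogate spike amount, ng/g.
#' @param surrogate_rf Surrogate response factor (area per ng/g).
#' @param calibration_levels Calibration concentrations, ng/g.
#' @param calibration_rsd Relative noise on calibration responses.
#' @param scan_range Usable m/z range.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(seed = 42L, replicates = 3L,
                           rsd_was = 0.08, rsd_ps = 0.45, rsd_blank = 0.05,
                           n_decoys = 30L,
                           suppression_range = c(0.7, 1.0),
                           area_rsd = 0,
                           surrogate_spike = 100,
                           surrogate_rf = 900,
                           calibration_levels = c(1, 2, 5, 10, 25, 50, 100, 250),
                           calibration_rsd = 0,
                           scan_range = c(80, 1200)) {
  stopifnot(seed == as.integer(seed), replicates >= 1,
            rsd_was >= 0, rsd_ps >= 0, rsd_blank >= 0, n_decoys >= 0,
            length(calibration_levels) >= 3)
  structure(as.list(environment()), class = "fixture_config")
}

#' Bundled targeted-analysis panel
#'
#' The 26-analyte targeted PFAS panel the quantification fixture is built
#' on: analyte, class, molecular formula, method LOD/LOQ (ng/g),
#' method-blank concentration, per-group mean concentrations with their
#' reporting labels (`q` quantified, `lt_loq` between LOD and LOQ, `nr`
#' non-reportable over blank contamination, `nd` not detected) and
#' surrogate recovery fraction.
#'
#' @return Data frame, one row per analyte.
#' @export
default_target_panel <- function() {
  path <- system.file("extdata", "target_panel.csv",
                      package = "fluoroscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled suspect list
#'
#' A 40-entry mini suspect list in the package's suspect schema: the 26
#' targeted analytes, the seven screening compounds of the suspect
#' fixture, and decoy entries (an FTOH, ether PFAS absent from the
#' samples, a sodium salt and an above-scan-range polymer segment) that
#' exercise curation and blacklisting. It is a synthetic stand-in shaped
#' like the EPA PFAS Master List schema, not a copy of it.
#'
#' @return Suspect data frame (see [read_suspect_list()]).
#' @export
default_suspect_list <- function() {
  path <- system.file("extdata", "suspect_list.csv",
                      package = "fluoroscreen", mustWork = TRUE)
  read_suspect_list(path)
}

# log-normal replicate factors rescaled to mean exactly 1, so generated
# replicate groups hit their target mean concentration exactly.
replicate_factors <- function(n, rsd) {
  if (rsd <= 0 || n == 1) return(rep(1, n))
  sdlog <- sqrt(log(1 + rsd^2))
  f <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  f / mean(f)
}

area_noise <- function(n, rsd) {
  if (rsd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rsd^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}

#' Generate the targeted-quantification fixture
#'
#' Builds calibration tables, blank statistics and WAS/PS/blank replicate
#' area tables whose true group means equal the bundled panel's
#' concentrations: quantified entries at their reported value, `lt_loq`
#' entries at the LOD-LOQ midpoint, `nr` entries at 60% of three times
#' the blank level (detectable but failing the blank rule) and `nd`
#' entries at zero. Concentrations become areas through per-analyte
#' response factors and per-sample suppression applied equally to analyte
#' and surrogate; blank contamination is injected at the panel's
#' method-blank levels.
#'
#' @param config A [fixture_config()].
#' @return List with `samples`, `calibration`, `blank_stats`, `recovery`,
#'   `panel` and `ground_truth`.
#' @export
generate_targeted_fixture <- function(config = fixture_config()) {
  set.seed(config$seed)
  panel <- default_target_panel()
  n <- nrow(panel)
  rf <- 800 + 40 * seq_len(n)                    # analyte response factors
  slope <- rf / (config$surrogate_spike * config$surrogate_rf)
  true_conc <- function(mean, label, lod, loq, blank) {
    switch(label,
           q = mean,
           lt_loq = (lod + loq) / 2,
           nr = 0.6 * 3 * blank,
           nd = 0)
  }
  truth_was <- mapply(true_conc, panel$was, panel$was_label, panel$lod,
                      panel$loq, panel$blank)
  truth_ps <- mapply(true_conc, panel$ps, panel$ps_label, panel$lod,
                     panel$loq, panel$blank)

  groups <- list(WAS = list(truth = truth_was, rsd = config$rsd_was),
                 PS = list(truth = truth_ps, rsd = config$rsd_ps),
                 blank = list(truth = panel$blank, rsd = config$rsd_blank))
  rows <- list()
  truth_rows <- list()
  for (g in names(groups)) {
    supp <- stats::runif(config$replicates, config$suppression_range[1],
                        config$suppression_range[2])
    for (i in seq_len(n)) {
      f <- replicate_factors(config$replicates, groups[[g]]$rsd)
      conc <- groups[[g]]$truth[i] * f
      a_noise <- area_noise(config$replicates, config$area_rsd)
      s_noise <- area_noise(config$replicates, config$area_rsd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paste0(g, seq_len(config$replicates)),
        group = g, analyte = panel$analyte[i],
        analyte_area = conc * rf[i] * supp * a_noise,
        surrogate_area = config$surrogate_spike * config$surrogate_rf *
          supp * s_noise,
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample = paste0(g, seq_len(config$replicates)), group = g,
        analyte = panel$analyte[i], conc = conc,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)

  cal <- list()
  for (i in seq_len(n)) {
    lv <- config$calibration_levels
    noise <- area_noise(length(lv), config$calibration_rsd)
    cal[[i]] <- data.frame(
      analyte = panel$analyte[i], conc = lv,
      analyte_area = lv * rf[i] * noise,
      surrogate_area = config$surrogate_spike * config$surrogate_rf,
      stringsAsFactors = FALSE)
  }
  calibration <- do.call(rbind, cal)

  blank_stats <- data.frame(analyte = panel$analyte, mean_signal = 0,
                            sd_signal = slope * panel$lod / 3,
                            n = config$replicates,
                            stringsAsFactors = FALSE)
  recovery <- data.frame(analyte = panel$analyte,
                         recovery = panel$recovery,
                         stringsAsFactors = FALSE)
  ground_truth <- list(
    concentrations = do.call(rbind, truth_rows),
    group_means = data.frame(analyte = panel$analyte, WAS = truth_was,
                             PS = truth_ps, blank = panel$blank),
    response_factors = data.frame(analyte = panel$analyte, rf = rf,
                                  slope = slope),
    labels = data.frame(analyte = panel$analyte, WAS = panel$was_label,
                        PS = panel$ps_label),
    seed = config$seed)
  list(samples = samples, calibration = calibration,
       blank_stats = blank_stats, recovery = recovery, panel = panel,
       ground_truth = ground_truth)
}

# The seven suspect-screening compounds: observed precursor m/z and
# retention times as reported, fragment lists as annotated on the ddMS2
# spectra; precursors not reported are reconstructed from fragment plus
# neutral-loss mass or taken at the theoretical [M-H]-.
suspect_truth_table <- function() {
  data.frame(
    id = c("53FTCA", "62diPAP", "MPFPA", "BSPFPH", "PFBGEE", "NFHSUA",
           "122PFPA"),
    mz = c(341.0044, 788.9751, 205.0293, 316.0185, 370.0546, 463.1337,
           726.9583),
    rt = c(20.0, 23.6, 3.4, 21.9, 15.0, 18.3, 22.0),
    groups = c("WAS;PS", "WAS;PS", "WAS;PS", "WAS;PS", "WAS", "WAS;PS",
               "WAS"),
    conc_was = c(35.9, 1.36, 8.0, 5.0, 6.0, 12.0, 9.0),
    conc_ps = c(13.8, 12.12, 4.0, 2.5, 0, 6.0, 0),
    fragments = c("216.9894;236.9963",
                  "442.9750;78.9596",
                  "118.9937;161.0407",
                  "68.9959;246.0147",
                  "326.0647;306.0585",
                  "168.9905;118.9932",
                  "78.9596;68.9959;118.9937;168.9905;218.9872"),
    stringsAsFactors = FALSE)
}

#' Generate the suspect-screening fixture
#'
#' Injects the seven suspect compounds at their observed precursor m/z,
#' retention times and annotated fragment lists into WAS/PS replicates,
#' together with decoys: an FTOH feature (blacklisted class), an
#' out-of-tolerance mass decoy 20 ppm off a real suspect, blank
#' contamination peaks present in blanks and below three times the blank
#' level in samples, and `n_decoys` random matrix peaks with mass defects
#' outside the PFAS window and no MS2. Also builds the 5:3 FTCA
#' reference-standard record (single-level 100 ng/g injection) and the
#' local spectral-library record for 6:2 diPAP. Fragment intensities are
#' a decreasing geometric profile (they are not part of the evidence
#' rules).
#'
#' @param config A [fixture_config()].
#' @return List with `features` (feature data frame), `references`
#'   (reference-standard table with attached spectra), `library`
#'   (spectral-library records), `suspects` (the bundled suspect list)
#'   and `ground_truth`.
#' @export
generate_suspect_fixture <- function(config = fixture_config()) {
  set.seed(config$seed + 1L)
  truth <- suspect_truth_table()
  suspects <- default_suspect_list()
  reps <- config$replicates
  rf <- 1000
  samples <- c(paste0("WAS", seq_len(reps)), paste0("PS", seq_len(reps)))
  grp <- rep(c("WAS", "PS"), each = reps)

  feat <- list()
  ms2 <- list()
  add <- function(sample, role, mz, rt, area, spec, group) {
    feat[[length(feat) + 1L]] <<- data.frame(
      sample = sample, role = role, mz = mz, rt = rt, area = area,
      group = group, stringsAsFactors = FALSE)
    ms2[length(ms2) + 1L] <<- list(spec)   # list() keeps NULL spectra
  }
  spec_of <- function(title, prec, frags) {
    ints <- 0.6^(seq_along(frags) - 1)
    s <- order(frags)
    list(title = title, precursor_mz = prec, rt = NA_real_,
         peaks = cbind(mz = frags[s], intensity = ints[s]))
  }
  for (i in seq_len(nrow(truth))) {
    frags <- as.numeric(strsplit(truth$fragments[i], ";")[[1]])
    in_groups <- strsplit(truth$groups[i], ";")[[1]]
    for (j in seq_along(samples)) {
      if (!(grp[j] %in% in_groups)) next
      conc <- if (grp[j] == "WAS") truth$conc_was[i] else truth$conc_ps[i]
      add(samples[j], "sample", truth$mz[i], truth$rt[i], conc * rf,
          spec_of(sprintf("%s_%s", truth$id[i], samples[j]),
                  truth$mz[i], frags), grp[j])
    }
  }
  # decoy 1: FTOH (class-blacklisted suspect), fragments and all
  ftoh_mz <- suspects$mz_mh[suspects$id == "82FTOH"]
  for (j in seq_along(samples))
    add(samples[j], "sample", ftoh_mz, 19.0, 5e4,
        spec_of(paste0("FTOH_", samples[j]), ftoh_mz, c(68.9959)), grp[j])
  # decoy 2: 20 ppm off PFOA's theoretical precursor - outside +-5 ppm
  off_mz <- suspects$mz_mh[suspects$id == "PFOA"] * (1 + 20e-6)
  for (j in seq_along(samples))
    add(samples[j], "sample", off_mz, 10.0, 4e4,
        spec_of(paste0("offtol_", samples[j]), off_mz, c(168.9905)), grp[j])
  # decoy 3: blank contamination, sample signal under 3x the blank level
  for (b in seq_len(reps))
    add(paste0("blank", b), "blank", 500.1234, 12.0, 1e5, NULL, "blank")
  for (j in seq_along(samples))
    add(samples[j], "sample", 500.1234, 12.0, 2e5, NULL, grp[j])
  # random matrix decoys: mass defect outside the PFAS window, no MS2,
  # and at least 20 ppm away from every suspect
  md_out <- function(mz) {
    md <- mass_defect(mz)
    md < -0.25 || md > 0.1
  }
  clear <- function(mz) {
    all(abs(mz - suspects$mz_mh) / mz * 1e6 > 20, na.rm = TRUE)
  }
  n_dec <- 0L
  decoy_mz <- numeric(0)
  while (n_dec < config$n_decoys) {
    mz <- stats::runif(1, config$scan_range[1], config$scan_range[2])
    if (!md_out(mz) || !clear(mz)) next
    n_dec <- n_dec + 1L
    decoy_mz <- c(decoy_mz, mz)
    add(samples[1 + (n_dec %% length(samples))], "sample", mz,
        stats::runif(1, 1, 28), stats::rlnorm(1, log(2e4), 0.5), NULL,
        grp[1 + (n_dec %% length(samples))])
  }
  features <- do.call(rbind, feat)
  features$ms2 <- I(ms2)
  rownames(features) <- NULL

  # 5:3 FTCA reference standard: 100 ng/g single-level injection
  ref_area <- 100 * rf
  references <- data.frame(id = "53FTCA", formula = "C8H5F11O2",
                           rt_min = 20.1, conc = 100, area = ref_area,
                           stringsAsFactors = FALSE)
  attr(references, "spectra") <- list(
    "53FTCA" = spec_of("53FTCA", 341.0044, c(216.9894, 236.9963)))
  library <- list(
    "62diPAP" = list(title = "62diPAP", precursor_mz = 788.9751,
                     rt = NA_real_,
                     peaks = cbind(mz = c(78.9596, 442.9750),
                                   intensity = c(0.6, 1.0))))
  ground_truth <- list(
    injected = truth,
    decoys = list(ftoh_mz = ftoh_mz, off_tolerance_mz = off_mz,
                  blank_contamination_mz = 500.1234,
                  matrix_decoy_mz = decoy_mz),
    reference = list(id = "53FTCA", conc = 100, area = ref_area,
                     response_factor = rf),
    seed = config$seed)
  list(features = features, references = references, library = library,
       suspects = suspects, ground_truth = ground_truth)
}

#' Generate a homologous-series fixture
#'
#' Builds `n_series` CF2-spaced series from random anchor masses plus
#' uniformly distributed decoy peaks. Anchors and decoys are kept clear
#' of each other's Kendrick mass defects, so the injected memberships
#' are recoverable exactly and serve as the oracle for
#' [detect_homologous_series()].
#'
#' @param n_series Number of series.
#' @param members Members per series.
#' @param n_decoys Number of uniform decoy peaks.
#' @param seed Random seed.
#' @param kmd_tol Grouping tolerance the fixture guarantees separation
#'   against (default 0.002).
#' @return List with `features` and `ground_truth` (`series_id` 0 for
#'   decoys).
#' @export
generate_homolog_fixture <- function(n_series = 3, members = 5,
                                     n_decoys = 50, seed = 7L,
                                     kmd_tol = 0.002) {
  set.seed(seed)
  cf2 <- monoisotopic_mass("CF2")
  kmd_of <- function(mz) kendrick_transform(mz)$kmd
  anchors <- numeric(0)
  while (length(anchors) < n_series) {
    a <- stats::runif(1, 150, 600)
    if (all(abs(kmd_of(a) - vapply(anchors, kmd_of, numeric(1))) >
            4 * kmd_tol) || !length(anchors))
      anchors <- c(anchors, a)
  }
  mz <- c(t(outer(anchors, (seq_len(members) - 1) * cf2, `+`)))
  series_id <- rep(seq_len(n_series), each = members)
  dec <- numeric(0)
  while (length(dec) < n_decoys) {
    d <- stats::runif(1, 80, 1200)
    if (all(abs(kmd_of(d) - vapply(anchors, kmd_of, numeric(1))) >
            2 * kmd_tol))
      dec <- c(dec, d)
  }
  all_mz <- c(mz, dec)
  features <- new_feature_table(
    sample = rep("S1", length(all_mz)), role = "sample",
    mz = all_mz, rt = stats::runif(length(all_mz), 1, 28),
    area = stats::rlnorm(length(all_mz), log(1e5), 0.3))
  ground_truth <- data.frame(mz = all_mz,
                             series_id = c(series_id,
                                           rep(0L, length(dec))))
  list(features = features, ground_truth = ground_truth)
}

#' Render a feature table to a centroided mzML file
#'
#' Writes each feature as a Gaussian chromatographic profile of
#' centroided MS1 scans, plus one MS2 scan near the apex for features
#' carrying a spectrum. Exercises [extract_features_from_mzml()]
#' round-trip.
#'
#' @param features Feature data frame.
#' @param file Output mzML path.
#' @param scan_interval MS1 scan spacing, minutes.
#' @param peak_width Chromatographic peak sigma, minutes.
#' @param scan_range Usable m/z range; features outside it are an error.
#' @return `file`, invisibly.
#' @export
write_fixture_mzml <- function(features, file, scan_interval = 0.02,
                               peak_width = 0.05,
                               scan_range = c(80, 1200)) {
  if (nrow(features) &&
      any(features$mz < scan_range[1] | features$mz > scan_range[2]))
    stop("feature m/z outside scan range")
  empty_hdr_row <- function(seq, rt, lvl, npeaks, tic, bp, bpint,
                            prec = 0) {
    data.frame(seqNum = seq, acquisitionNum = seq, msLevel = lvl,
               polarity = 0L, peaksCount = npeaks, totIonCurrent = tic,
               retentionTime = rt * 60, basePeakMZ = bp,
               basePeakIntensity = bpint, collisionEnergy = NA_real_,
               ionisationEnergy = 0, lowMZ = scan_range[1],
               highMZ = scan_range[2], precursorScanNum = 0L,
               precursorMZ = prec, precursorCharge = 0L,
               precursorIntensity = 0, mergedScan = 0L,
               mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
               mergedResultEndScanNum = 0L, injectionTime = 0,
               filterString = NA_character_,
               spectrumId = paste0("scan=", seq), centroided = TRUE,
               ionMobilityDriftTime = NA_real_,
               isolationWindowTargetMZ = NA_real_,
               isolationWindowLowerOffset = NA_real_,
               isolationWindowUpperOffset = NA_real_,
               scanWindowLowerLimit = scan_range[1],
               scanWindowUpperLimit = scan_range[2])
  }
  scans <- list()
  hdr <- list()
  if (nrow(features)) {
    t0 <- min(features$rt) - 4 * peak_width
    t1 <- max(features$rt) + 4 * peak_width
    times <- seq(t0, t1, by = scan_interval)
  } else {
    times <- 0
  }
  seq_no <- 0L
  for (t in times) {
    act <- which(abs(features$rt - t) <= 4 * peak_width)
    pk <- if (length(act)) {
      int <- features$area[act] * scan_interval /
        (peak_width * sqrt(2 * pi)) *
        exp(-(t - features$rt[act])^2 / (2 * peak_width^2))
      m <- cbind(mz = features$mz[act], intensity = int)
      m[order(m[, 1]), , drop = FALSE]
    } else {
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    seq_no <- seq_no + 1L
    scans[[seq_no]] <- pk
    hdr[[seq_no]] <- empty_hdr_row(
      seq_no, t, 1L, nrow(pk), sum(pk[, 2]),
      if (nrow(pk)) pk[which.max(pk[, 2]), 1] else 0,
      if (nrow(pk)) max(pk[, 2]) else 0)
    # MS2 scans for features whose apex this scan just passed
    trig <- which(!vapply(features$ms2, is.null, logical(1)) &
                    features$rt >= t - scan_interval / 2 &
                    features$rt < t + scan_interval / 2)
    for (i in trig) {
      sp <- features$ms2[[i]]$peaks
      seq_no <- seq_no + 1L
      scans[[seq_no]] <- sp
      hdr[[seq_no]] <- empty_hdr_row(
        seq_no, t + scan_interval / 4, 2L, nrow(sp), sum(sp[, 2]),
        sp[which.max(sp[, 2]), 1], max(sp[, 2]), prec = features$mz[i])
    }
  }
  header <- do.call(rbind, hdr)
  mzR::writeMSData(scans, file, header = header)
  invisible(file)
}
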