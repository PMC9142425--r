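#' Screening configuration
#'
#' Tolerances and thresholds of the suspect-screening decision procedure.
#' Defaults follow the acquisition-and-review settings the workflow is
#' built around: precursor match at ±5 ppm, fragment annotation at
#' ±10 ppm, retention-time confirmation against a reference standard at
#' ±0.2 min, and a PFAS mass-defect window of \[-0.25, 0.1\] amu with an
#' override retaining partially fluorinated matches whose positive defect
#' falls outside it.
#'
#' `min_fragments` is the minimum number of evidence-bearing MS2 fragments
#' (rule annotations plus reference-standard or library matches) a
#' candidate needs to enter the report. The confidence-level definitions
#' themselves require at least one diagnostic fragment, and that per-level
#' criterion is the default entry rule (`min_fragments = 1`); raise it to
#' 2 to enforce the stricter "more than one fragment" headline reading.
#'
#' @param precursor_ppm Precursor match tolerance, ppm.
#' @param fragment_ppm Fragment annotation tolerance, ppm.
#' @param rt_tol Retention-time tolerance for level-1 confirmation, min.
#' @param md_window Mass-defect acceptance window, amu.
#' @param partial_fluorination_override Retain (flagged) out-of-window
#'   candidates whose matched formula is partially fluorinated (H >= 2).
#' @param min_fragments Minimum evidence-bearing fragments for candidacy.
#' @param homolog_min_length Minimum members for a homologous series.
#' @param kmd_tol Kendrick-mass-defect grouping tolerance.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(precursor_ppm = 5, fragment_ppm = 10,
                             rt_tol = 0.2, md_window = c(-0.25, 0.1),
                             partial_fluorination_override = TRUE,
                             min_fragments = 1L,
                             homolog_min_length = 3L, kmd_tol = 0.002) {
  stopifnot(precursor_ppm > 0, fragment_ppm > 0, rt_tol > 0,
            md_window[1] < md_window[2], min_fragments >= 1,
            homolog_min_length >= 1, kmd_tol > 0)
  structure(list(precursor_ppm = precursor_ppm, fragment_ppm = fragment_ppm,
                 rt_tol = rt_tol, md_window = md_window,
                 partial_fluorination_override = partial_fluorination_override,
                 min_fragments = as.integer(min_fragments),
                 homolog_min_length = as.integer(homolog_min_length),
                 kmd_tol = kmd_tol),
            class = "screening_config")
}

#' Match features against the suspect list
#'
#' For each feature, finds all non-excluded suspects whose theoretical
#' deprotonated-molecule m/z lies within the precursor tolerance. Suspects
#' sharing one molecular formula (positional isomers) are merged into a
#' single isomer set per feature.
#'
#' @param features Feature data frame.
#' @param suspects Curated, blacklisted suspect data frame.
#' @param config A [screening_config()].
#' @return Data frame of raw matches: `feature_idx`, `mz`, `rt`, `area`,
#'   `formula`, `suspect_ids` (semicolon-joined isomer set), `isomer_n`,
#'   `mz_theoretical`, `ppm`.
#' @export
match_precursors <- function(features, suspects, config = screening_config()) {
  active <- suspects[!suspects$excluded & !is.na(suspects$mz_mh), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(features))) {
    ppm <- (features$mz[i] - active$mz_mh) / active$mz_mh * 1e6
    hit <- which(abs(ppm) <= config$precursor_ppm)
    if (!length(hit)) next
    for (f in unique(active$formula[hit])) {
      sel <- hit[active$formula[hit] == f]
      out[[length(out) + 1L]] <- data.frame(
        feature_idx = i, mz = features$mz[i], rt = features$rt[i],
        area = features$area[i], formula = f,
        suspect_ids = paste(active$id[sel], collapse = ";"),
        isomer_n = length(sel),
        mz_theoretical = active$mz_mh[sel][1],
        ppm = ppm[sel][1], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_idx = integer(), mz = numeric(), rt = numeric(),
                      area = numeric(), formula = character(),
                      suspect_ids = character(), isomer_n = integer(),
                      mz_theoretical = numeric(), ppm = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Annotate MS2 fragments of a candidate
#'
#' Tests every observed fragment against (a) each product-ion rule's
#' theoretical anion m/z and (b) each neutral-loss rule applied to the
#' candidate's theoretical precursor. Matches within the fragment
#' tolerance become annotations; an observed fragment carries at most one
#' annotation (smallest absolute ppm error wins). Fragments above the
#' precursor m/z are rejected.
#'
#' @param ms2 MS2 spectrum (list with `peaks` matrix) or `NULL`.
#' @param precursor_theoretical Theoretical precursor m/z of the match.
#' @param rules Fragment-rule table ([default_fragment_rules()]).
#' @param config A [screening_config()].
#' @return Data frame of annotations: `label`, `kind`, `observed_mz`,
#'   `theoretical_mz`, `ppm`, `structure_specific`.
#' @export
annotate_fragments <- function(ms2, precursor_theoretical, rules,
                               config = screening_config()) {
  empty <- data.frame(label = character(), kind = character(),
                      observed_mz = numeric(), theoretical_mz = numeric(),
                      ppm = numeric(), structure_specific = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(ms2) || !nrow(ms2$peaks)) return(empty)
  theo <- ifelse(rules$kind == "product", rules$mz,
                 precursor_theoretical - rules$neutral_mass)
  ok_rule <- theo > 0
  out <- list()
  for (j in seq_len(nrow(ms2$peaks))) {
    obs <- ms2$peaks[j, "mz"]
    if (obs > precursor_theoretical * (1 + config$fragment_ppm * 1e-6)) next
    ppm <- (obs - theo) / theo * 1e6
    hit <- which(ok_rule & abs(ppm) <= config$fragment_ppm)
    if (!length(hit)) next
    best <- hit[which.min(abs(ppm[hit]))]
    out[[length(out) + 1L]] <- data.frame(
      label = rules$label[best], kind = rules$kind[best],
      observed_mz = obs, theoretical_mz = theo[best], ppm = ppm[best],
      structure_specific = rules$structure_specific[best],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Apply the PFAS mass-defect rule
#'
#' A candidate's mass defect (computed on the observed precursor m/z)
#' must fall in the configured window. Matches outside the window whose
#' formula is partially fluorinated (hydrogen count >= 2: hydrogens beyond
#' the acid proton outweigh fluorine's negative defect) are retained with
#' an out-of-window flag when the override is enabled.
#'
#' @param mz Observed precursor m/z.
#' @param formula Matched suspect formula.
#' @param config A [screening_config()].
#' @return One of `"in_window"`, `"flagged"`, `"fail"`.
#' @export
apply_mass_defect_rule <- function(mz, formula, config = screening_config()) {
  md <- mass_defect(mz)
  if (md >= config$md_window[1] && md <= config$md_window[2])
    return("in_window")
  comp <- parse_formula(formula)
  h <- if (is.na(comp["H"])) 0L else comp[["H"]]
  if (config$partial_fluorination_override && h >= 2L) "flagged" else "fail"
}

#' Detect CF2 homologous series
#'
#' Groups features by Kendrick mass defect (CF2 base) with single-linkage
#' clustering on the sorted KMDs at the grouping tolerance; within a
#' group, members whose Kendrick masses differ by integer multiples of
#' the base nominal mass (50 for CF2) form one series. Series shorter
#' than the minimum length are discarded.
#'
#' @param features Feature data frame.
#' @param config A [screening_config()].
#' @param base Repeat-unit formula (default `"CF2"`).
#' @return Data frame with one row per series member: `series_id`,
#'   `feature_idx`, `mz`, `kendrick_mass`, `kmd`, `series_kmd` (mean),
#'   `n_members`.
#' @export
detect_homologous_series <- function(features, config = screening_config(),
                                     base = "CF2") {
  empty <- data.frame(series_id = integer(), feature_idx = integer(),
                      mz = numeric(), kendrick_mass = numeric(),
                      kmd = numeric(), series_kmd = numeric(),
                      n_members = integer())
  if (!nrow(features)) return(empty)
  kt <- kendrick_transform(features$mz, base)
  ord <- order(kt$kmd)
  grp <- cumsum(c(1, diff(kt$kmd[ord]) > config$kmd_tol))
  out <- list()
  sid <- 0L
  for (g in split(ord, grp)) {
    if (length(g) < config$homolog_min_length) next
    # sub-series: identical residue of the rounded Kendrick mass mod nominal
    resid <- round(kt$kendrick_mass[g]) %% kt$base_nominal
    for (sub in split(g, resid)) {
      # one member per nominal slot; isobaric duplicates share the slot
      if (length(unique(round(kt$kendrick_mass[sub]))) <
          config$homolog_min_length) next
      sid <- sid + 1L
      out[[sid]] <- data.frame(
        series_id = sid, feature_idx = sub, mz = features$mz[sub],
        kendrick_mass = kt$kendrick_mass[sub], kmd = kt$kmd[sub],
        series_kmd = mean(kt$kmd[sub]), n_members = length(sub))
    }
  }
  if (!sid) return(empty)
  do.call(rbind, out)
}

#' Assign a Schymanski identification-confidence level
#'
#' Level rules, applied in order:
#' * **1** - a reference standard for the matched suspect exists, its
#'   retention time agrees within the tolerance, and at least one observed
#'   MS2 fragment matches the standard's spectrum within the fragment
#'   tolerance;
#' * **2a** - a local spectral-library record for the suspect shares at
#'   least two fragments with the observed spectrum within tolerance;
#' * **2b** - at least one diagnostic fragment annotation, the mass-defect
#'   rule satisfied, a single-structure isomer set and at least one
#'   structure-specific annotation;
#' * **3** - as 2b, but the structure is ambiguous: the isomer set has
#'   more than one member, or every annotation is class-generic;
#' * otherwise `"below_threshold"`.
#'
#' @param candidate One-row match record (from [match_precursors()]) with
#'   observed `rt`.
#' @param annotations Annotation data frame from [annotate_fragments()].
#' @param md_status Mass-defect status from [apply_mass_defect_rule()].
#' @param ms2 Observed MS2 spectrum or `NULL`.
#' @param references Reference-standard table (`id`, `rt_min`) with an
#'   attached named list of spectra in `attr(references, "spectra")`, or
#'   `NULL`.
#' @param library Named list of spectral-library records or `NULL`.
#' @param config A [screening_config()].
#' @return List with `level` (`"1"`, `"2a"`, `"2b"`, `"3"`,
#'   `"below_threshold"`), `evidence_n` (distinct evidence-bearing
#'   fragments) and `evidence` (character narrative).
#' @export
assign_confidence <- function(candidate, annotations, md_status, ms2,
                              references = NULL, library = NULL,
                              config = screening_config()) {
  ids <- strsplit(candidate$suspect_ids, ";", fixed = TRUE)[[1]]
  obs_frags <- if (is.null(ms2)) numeric(0) else ms2$peaks[, "mz"]
  shared_with <- function(peaks) {
    if (!length(obs_frags) || !nrow(peaks)) return(numeric(0))
    obs_frags[vapply(obs_frags, function(f)
      any(abs(f - peaks[, "mz"]) / peaks[, "mz"] * 1e6 <= config$fragment_ppm),
      logical(1))]
  }
  std_shared <- numeric(0)
  lib_shared <- numeric(0)
  evidence <- character(0)

  # level 1: reference standard with matching RT and shared fragmentation
  if (!is.null(references) && nrow(references)) {
    hit <- which(references$id %in% ids)
    for (r in hit) {
      sp <- attr(references, "spectra")[[references$id[r]]]
      if (is.null(sp)) next
      rt_ok <- abs(candidate$rt - references$rt_min[r]) <= config$rt_tol
      sh <- shared_with(sp$peaks)
      if (rt_ok && length(sh) >= 1) {
        std_shared <- sh
        evidence <- c(evidence, sprintf(
          "retention time matches reference standard %s within %.2f min; %d shared fragment(s)",
          references$id[r], config$rt_tol, length(sh)))
      }
    }
  }
  # level 2a: local spectral-library record with >= 2 shared fragments
  if (!is.null(library)) {
    for (id in intersect(ids, names(library))) {
      sh <- shared_with(library[[id]]$peaks)
      if (length(sh) >= 2) {
        lib_shared <- sh
        evidence <- c(evidence, sprintf(
          "%d fragments shared with spectral-library record %s",
          length(sh), id))
      }
    }
  }
  if (nrow(annotations))
    evidence <- c(evidence, sprintf("%s at %.4f (%+.1f ppm)",
                                    annotations$label,
                                    annotations$observed_mz,
                                    annotations$ppm))
  ev_frags <- unique(c(annotations$observed_mz, std_shared, lib_shared))
  md_ok <- md_status %in% c("in_window", "flagged")
  level <-
    if (length(std_shared)) "1"
    else if (length(lib_shared)) "2a"
    else if (nrow(annotations) >= 1 && md_ok && candidate$isomer_n == 1 &&
             any(annotations$structure_specific)) "2b"
    else if (nrow(annotations) >= 1 && md_ok) "3"
    else "below_threshold"
  list(level = level, evidence_n = length(ev_frags),
       evidence = paste(evidence, collapse = "; "))
}

#' Run the suspect-screening pipeline
#'
#' Blank subtraction, precursor matching, fragment annotation, mass-defect
#' filtering, homologous-series detection and confidence assignment, in
#' that order. A candidate enters the report when it reaches confidence
#' level 1, 2a, 2b or 3 and carries at least `min_fragments`
#' evidence-bearing fragments. Candidates are unique per isomer set (the
#' highest-area feature per compound across samples is reported, with the
#' number of samples it was seen in) and sorted by ascending precursor
#' m/z.
#'
#' @param features Feature data frame (samples and blanks).
#' @param suspects Suspect data frame (curated and blacklisted; if not yet
#'   curated, [curate_suspects()] and [blacklist_nonionizable()] are
#'   applied with defaults).
#' @param rules Fragment-rule table (default [default_fragment_rules()]).
#' @param references Optional reference-standard table (see
#'   [assign_confidence()]).
#' @param library Optional spectral library ([read_spectral_library()]).
#' @param config A [screening_config()].
#' @return Object of class `pfas_screen`: list with `candidates` (report
#'   data frame), `series` (homologous series), `stage_counts`, `config`
#'   and `annotations` (per-candidate list).
#' @export
screen_suspects <- function(features, suspects,
                            rules = default_fragment_rules(),
                            references = NULL, library = NULL,
                            config = screening_config()) {
  stage <- c(features_loaded = nrow(features))
  # idempotent: curating an already-curated list changes nothing
  suspects <- curate_suspects(suspects)$kept
  suspects <- blacklist_nonionizable(suspects)
  bs <- blank_subtract(features, mz_tol_ppm = config$precursor_ppm,
                       rt_tol = config$rt_tol)
  work <- bs$kept[bs$kept$role == "sample", , drop = FALSE]
  stage <- c(stage, after_blank_subtraction = nrow(work))
  matches <- match_precursors(work, suspects, config)
  stage <- c(stage, precursor_matched = nrow(matches))
  series <- detect_homologous_series(work, config)

  cands <- list()
  annots <- list()
  for (i in seq_len(nrow(matches))) {
    cand <- matches[i, , drop = FALSE]
    ms2 <- work$ms2[[cand$feature_idx]]
    ann <- annotate_fragments(ms2, cand$mz_theoretical, rules, config)
    md <- apply_mass_defect_rule(cand$mz, cand$formula, config)
    conf <- assign_confidence(cand, ann, md, ms2, references, library, config)
    sid <- series$series_id[match(cand$feature_idx, series$feature_idx)]
    cand$mass_defect <- mass_defect(cand$mz)
    cand$md_status <- md
    cand$n_annotations <- nrow(ann)
    cand$evidence_n <- conf$evidence_n
    cand$level <- conf$level
    cand$evidence <- conf$evidence
    cand$series_id <- if (is.na(sid)) NA_integer_ else sid
    cands[[i]] <- cand
    annots[[i]] <- ann
  }
  report <- if (length(cands)) do.call(rbind, cands) else matches[0, ]
  stage <- c(stage, fragment_supported = sum(report$evidence_n >= 1))
  keep <- report$level %in% c("1", "2a", "2b", "3") &
    report$evidence_n >= config$min_fragments
  report <- report[keep, , drop = FALSE]
  annots <- annots[keep]
  # one row per compound (isomer set): keep the highest-area occurrence
  if (nrow(report)) {
    n_samples <- as.vector(table(report$suspect_ids)[report$suspect_ids])
    report$n_samples <- n_samples
    ord <- order(report$suspect_ids, -report$area)
    report <- report[ord, , drop = FALSE]
    annots <- annots[ord]
    first <- !duplicated(report$suspect_ids)
    report <- report[first, , drop = FALSE]
    annots <- annots[first]
    ord <- order(report$mz)
    report <- report[ord, , drop = FALSE]
    annots <- annots[ord]
    rownames(report) <- NULL
  }
  stage <- c(stage, reported = nrow(report))
  structure(list(candidates = report, series = series,
                 stage_counts = stage, config = config,
                 annotations = annots),
            class = "pfas_screen")
}

#' @export
print.pfas_screen <- function(x, ...) {
  cat("PFAS suspect-screening report\n")
  cat("Stage counts:\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-24s %d\n", nm, x$stage_counts[[nm]]))
  if (nrow(x$candidates)) {
    cat("\nCandidates (by ascending precursor m/z):\n")
    print(x$candidates[, c("suspect_ids", "mz", "rt", "ppm", "mass_defect",
                           "level", "evidence_n", "n_samples")],
          row.names = FALSE, digits = 7)
  } else cat("\nNo candidates reported.\n")
  invisible(x)
}

#' Kendrick mass-defect plot
#'
#' Plots Kendrick mass defect against Kendrick nominal mass for a feature
#' table, highlighting detected homologous series. Members of a CF2 series
#' fall on one horizontal line.
#'
#' @param features Feature data frame.
#' @param series Optional series table from [detect_homologous_series()].
#' @param base Repeat-unit formula, default `"CF2"`.
#' @param ... Passed to [plot()].
#' @export
plot_kendrick <- function(features, series = NULL, base = "CF2", ...) {
  kt <- kendrick_transform(features$mz, base)
  graphics::plot(round(kt$kendrick_mass), kt$kmd,
       xlab = sprintf("Kendrick nominal mass (%s)", kt$base),
       ylab = "Kendrick mass defect", pch = 1, col = "grey40", ...)
  if (!is.null(series) && nrow(series)) {
    cols <- seq_len(max(series$series_id)) + 1L
    graphics::points(round(series$kendrick_mass), series$kmd,
           pch = 19, col = cols[series$series_id])
  }
  invisible(NULL)
}
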