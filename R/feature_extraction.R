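# Feature tables are plain data frames with columns
#   sample, role, mz, rt, area  (+ list-column ms2 of spectra or NULL)
# role is one of "sample", "blank", "standard", "calibration"; an optional
# `group` column (WAS / PS / blank) carries replicate structure.

FEATURE_ROLES <- c("sample", "blank", "standard", "calibration")

new_feature_table <- function(sample = character(), role = character(),
                              mz = numeric(), rt = numeric(),
                              area = numeric(), ms2 = NULL,
                              group = NULL) {
  df <- data.frame(sample = sample, role = role, mz = mz, rt = rt,
                   area = area, stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  df$ms2 <- if (is.null(ms2)) I(rep(list(NULL), nrow(df))) else I(ms2)
  df
}

#' Read a feature table
#'
#' Reads pre-extracted chromatographic features from CSV with columns
#' `sample,role,mz,rt,area` and an optional `ms2_ref` column whose values
#' resolve into the `TITLE`s of an MGF file of MS2 spectra. Features
#' outside the scan range are dropped with a reported count.
#'
#' @param file CSV path.
#' @param mgf Optional path to an MGF file resolving `ms2_ref` values.
#' @param scan_range Usable m/z range, default `c(80, 1200)`.
#' @return Feature data frame; attribute `n_out_of_range` counts dropped
#'   rows.
#' @export
read_feature_table <- function(file, mgf = NULL, scan_range = c(80, 1200)) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample", "role", "mz", "rt", "area")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$area < 0)) stop("negative peak area in feature table")
  if (any(tab$rt < 0)) stop("negative retention time in feature table")
  if (!all(tab$role %in% FEATURE_ROLES))
    stop("unknown sample role(s): ",
         paste(setdiff(tab$role, FEATURE_ROLES), collapse = ", "))
  inr <- tab$mz >= scan_range[1] & tab$mz <= scan_range[2]
  n_out <- sum(!inr)
  if (n_out) message(n_out, " feature(s) outside scan range dropped")
  tab <- tab[inr, , drop = FALSE]
  spectra <- NULL
  if (!is.null(tab$ms2_ref) && !is.null(mgf)) spectra <- read_mgf(mgf)
  ms2 <- rep(list(NULL), nrow(tab))
  if (!is.null(tab$ms2_ref)) {
    has <- !is.na(tab$ms2_ref) & nzchar(tab$ms2_ref)
    if (any(has)) {
      if (is.null(spectra))
        stop("feature table references MS2 spectra but no MGF file given")
      bad <- setdiff(tab$ms2_ref[has], names(spectra))
      if (length(bad))
        stop("unresolvable ms2_ref(s): ", paste(bad, collapse = ", "))
      ms2[has] <- spectra[tab$ms2_ref[has]]
    }
    tab$ms2_ref <- NULL
  }
  out <- new_feature_table(tab$sample, tab$role, tab$mz, tab$rt, tab$area,
                           ms2 = ms2, group = tab$group)
  attr(out, "n_out_of_range") <- n_out
  out
}

#' Extract features from a centroided mzML file
#'
#' A deliberately simple greedy centroid-clustering stage for full-scan
#' MS1 data: centroids across scans agreeing within `mz_tol_ppm` (and not
#' separated by more than `rt_gap` in time) are pooled into one feature
#' whose m/z is the intensity-weighted mean, retention time the apex scan
#' time and area the summed intensity. MS2 scans are attached to the
#' feature nearest their precursor within the tolerance. Pre-extracted
#' CSV feature tables remain the canonical tested input; this reader
#' exists so the pipeline can start from raw centroided spectra.
#'
#' @param file mzML path (centroided MS1, negative mode).
#' @param min_intensity Minimum summed intensity for a cluster to become a
#'   feature.
#' @param mz_tol_ppm Centroid clustering tolerance in ppm.
#' @param rt_gap Maximum retention-time gap (min) inside one feature.
#' @param sample,role Sample id and role assigned to the returned features.
#' @return Feature data frame.
#' @export
extract_features_from_mzml <- function(file, min_intensity = 0,
                                       mz_tol_ppm = 10, rt_gap = 0.5,
                                       sample = basename(file),
                                       role = "sample") {
  handle <- mzR::openMSfile(file)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!nrow(hdr))
    return(new_feature_table())
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) && any(!hdr$centroided[ms1], na.rm = TRUE))
    stop("profile-mode spectra found: centroid the data first")
  pts <- do.call(rbind, lapply(ms1, function(i) {
    p <- mzR::peaks(handle, i)
    if (!nrow(p)) return(NULL)
    cbind(mz = p[, 1], intensity = p[, 2], rt = hdr$retentionTime[i] / 60)
  }))
  feats <- new_feature_table()
  if (!is.null(pts) && nrow(pts)) {
    rownames(pts) <- NULL
    ord <- order(pts[, "mz"])
    pts <- pts[ord, , drop = FALSE]
    gap_ppm <- c(Inf, diff(pts[, "mz"]) / pts[-nrow(pts), "mz"] * 1e6)
    cl <- cumsum(gap_ppm > mz_tol_ppm)
    # split clusters further on retention-time gaps
    ids <- character(nrow(pts))
    for (idx in split(seq_len(nrow(pts)), cl)) {
      idx <- idx[order(pts[idx, "rt"])]
      sub <- cumsum(c(0, diff(pts[idx, "rt"]) > rt_gap))
      ids[idx] <- paste(cl[idx[1]], sub, sep = ".")
    }
    rows <- lapply(split(seq_len(nrow(pts)), ids), function(idx) {
      int <- pts[idx, "intensity"]
      if (sum(int) < min_intensity) return(NULL)
      c(mz = sum(pts[idx, "mz"] * int) / sum(int),
        rt = pts[idx, "rt"][which.max(int)],
        area = sum(int))
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(rows) && nrow(rows)) {
      rows <- rows[order(rows[, "mz"]), , drop = FALSE]
      feats <- new_feature_table(rep(sample, nrow(rows)),
                                 rep(role, nrow(rows)),
                                 rows[, "mz"], rows[, "rt"], rows[, "area"])
    }
  }
  # attach MS2 scans to the nearest-precursor feature
  ms2 <- which(hdr$msLevel == 2L)
  for (i in ms2) {
    prec <- hdr$precursorMZ[i]
    if (!nrow(feats) || is.na(prec) || prec <= 0) next
    d <- abs(feats$mz - prec) / prec * 1e6
    j <- which.min(d)
    if (d[j] <= mz_tol_ppm) {
      p <- mzR::peaks(handle, i)
      colnames(p) <- c("mz", "intensity")
      sp <- list(title = sprintf("%s_scan%d", sample, i),
                 precursor_mz = prec,
                 rt = hdr$retentionTime[i], peaks = p)
      old <- feats$ms2[[j]]
      feats$ms2[[j]] <- if (is.null(old)) sp else old  # keep first trigger
    }
  }
  feats
}

#' Blank subtraction
#'
#' Removes sample features whose signal is not clearly above the
#' extraction blanks: a sample feature matched by a blank feature within
#' both tolerances is removed when its area is below
#' `factor x mean(matched blank areas)` (the mean is taken across blank
#' replicates). Removed features are returned for audit; the kept and
#' removed sets partition the input sample features.
#'
#' @param features Feature data frame containing both sample and blank
#'   roles.
#' @param factor Blank multiplier (default 3, must be > 0).
#' @param mz_tol_ppm Match tolerance in ppm (default 5).
#' @param rt_tol Match tolerance in minutes (default 0.2).
#' @return List with `kept` and `removed` feature data frames (blank
#'   features are carried through in `kept`).
#' @export
blank_subtract <- function(features, factor = 3, mz_tol_ppm = 5,
                           rt_tol = 0.2) {
  if (factor <= 0) stop("blank factor must be positive")
  is_blank <- features$role == "blank"
  blanks <- features[is_blank, , drop = FALSE]
  samples <- features[!is_blank, , drop = FALSE]
  if (!nrow(blanks)) {
    warning("no blank features present; blank subtraction skipped")
    return(list(kept = features, removed = features[0, , drop = FALSE]))
  }
  remove <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    hit <- abs(blanks$mz - samples$mz[i]) / samples$mz[i] * 1e6 <= mz_tol_ppm &
      abs(blanks$rt - samples$rt[i]) <= rt_tol
    if (any(hit) && samples$area[i] < factor * mean(blanks$area[hit]))
      remove[i] <- TRUE
  }
  list(kept = rbind(samples[!remove, , drop = FALSE], blanks),
       removed = samples[remove, , drop = FALSE])
}
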