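#' Load a suspect list
#'
#' Reads a suspect table in the schema
#' `id,name,cas,formula,smiles,class` (CSV, header row; `cas`, `smiles`
#' and `class` optional) and derives the neutral monoisotopic mass and
#' theoretical deprotonated-molecule m/z from the formula. Derived masses
#' are always recomputed from the formula, never trusted from the file.
#' Rows whose formula fails to parse are skipped with a warning; duplicate
#' identifiers are an error.
#'
#' @param file Path to the CSV file.
#' @return A data frame of suspect entries with columns `id`, `name`,
#'   `cas`, `formula`, `smiles`, `class`, `neutral_mass`, `mz_mh`
#'   (theoretical `[M-H]-` m/z, `NA` for hydrogen-free formulas) and
#'   `excluded` (logical, set by [blacklist_nonionizable()]).
#' @export
read_suspect_list <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "name", "formula")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("suspect list missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (opt in c("cas", "smiles", "class"))
    if (is.null(tab[[opt]])) tab[[opt]] <- NA_character_
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    stop("duplicate suspect identifier(s): ", paste(unique(dup), collapse = ", "))
  n0 <- nrow(tab)
  parsed <- lapply(tab$formula, function(f) tryCatch(parse_formula(f),
                                                     error = function(e) NULL))
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    warning(sum(!ok), " row(s) skipped: unparsable formula (",
            paste(tab$id[!ok], collapse = ", "), ")")
  tab <- tab[ok, , drop = FALSE]
  parsed <- parsed[ok]
  tab$neutral_mass <- vapply(parsed, monoisotopic_mass, numeric(1))
  tab$mz_mh <- vapply(parsed, function(p) {
    if (is.na(p["H"]) || p["H"] < 1L) NA_real_ else anion_mz(p)
  }, numeric(1))
  tab$class[is.na(tab$class) | !nzchar(tab$class)] <- "unknown"
  tab$excluded <- FALSE
  attr(tab, "n_skipped") <- n0 - nrow(tab)
  tab
}

#' Curate a suspect list for negative-mode screening
#'
#' Removes entries outside the acquisition's usable mass range and salt
#' forms, mirroring the curation an inclusion list needs before
#' data-dependent acquisition:
#' * entries whose theoretical `[M-H]-` exceeds `scan_upper` are removed
#'   (reason `"above scan range"`);
#' * formulas carrying Na or K counterions are normalized to the free acid
#'   (strip one Na/K, add one H); if the free acid is already present the
#'   salt row is dropped as a duplicate, otherwise the normalized entry is
#'   kept; formulas with more than one Na/K are removed outright.
#'
#' Curation is total (never errors) and idempotent.
#'
#' @param entries Suspect data frame from [read_suspect_list()].
#' @param scan_upper Upper m/z limit of the scan range (default 1200).
#' @return A list with `kept` (curated data frame) and `removed`
#'   (data frame of `id`, `reason`).
#' @export
curate_suspects <- function(entries, scan_upper = 1200) {
  removed <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids))
      removed <<- rbind(removed, data.frame(id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
  }
  # Salt normalization first, so the range check sees free-acid masses.
  comps <- lapply(entries$formula, parse_formula)
  n_salt <- vapply(comps, function(p) {
    sum(p[intersect(c("Na", "K"), names(p))])
  }, numeric(1))
  drop(entries$id[n_salt > 1], "multiple counterions")
  keep <- n_salt <= 1
  entries <- entries[keep, , drop = FALSE]
  comps <- comps[keep]
  n_salt <- n_salt[keep]
  is_salt <- n_salt == 1
  if (any(is_salt)) {
    freed <- vapply(comps[is_salt], function(p) {
      counter <- intersect(c("Na", "K"), names(p)[p > 0])[1]
      p[counter] <- p[counter] - 1L
      p["H"] <- (if (is.na(p["H"])) 0L else p["H"]) + 1L
      formula_string(p)
    }, character(1))
    dup <- freed %in% entries$formula[!is_salt]
    salt_rows <- which(is_salt)
    drop(entries$id[salt_rows[dup]], "salt adduct")
    for (k in which(!dup)) {
      i <- salt_rows[k]
      entries$formula[i] <- freed[k]
      p <- parse_formula(entries$formula[i])
      entries$neutral_mass[i] <- monoisotopic_mass(p)
      entries$mz_mh[i] <- anion_mz(p)
    }
    keep_salt <- rep(TRUE, nrow(entries))
    keep_salt[salt_rows[dup]] <- FALSE
    entries <- entries[keep_salt, , drop = FALSE]
  }
  high <- !is.na(entries$mz_mh) & entries$mz_mh > scan_upper
  drop(entries$id[high], "above scan range")
  entries <- entries[!high, , drop = FALSE]
  rownames(entries) <- NULL
  list(kept = entries, removed = removed)
}

#' Flag suspect classes that do not ionize as \[M-H\]-
#'
#' Classes such as fluorotelomer alcohols (FTOH) ionize poorly as the
#' deprotonated molecule in negative electrospray and are excluded from
#' precursor matching. Flagged entries stay in the table (with
#' `excluded = TRUE`) for reporting; [match_precursors()] skips them.
#' Entries with unknown class are never blacklisted.
#'
#' @param entries Suspect data frame.
#' @param blocked Character vector of blocked class tags (default `"FTOH"`).
#' @return The data frame with `excluded` updated.
#' @export
blacklist_nonionizable <- function(entries, blocked = "FTOH") {
  if (length(blocked)) {
    unknown <- setdiff(blocked, unique(entries$class))
    # A blocked class absent from this particular list is legitimate, but a
    # class outside the closed vocabulary is a configuration error.
    vocab <- c("PFCA", "PFSA", "FTS", "FTCA", "FTOH", "FASA", "FASAA",
               "diPAP", "phosphonic", "ether", "other", "unknown")
    bad <- setdiff(blocked, vocab)
    if (length(bad))
      stop("unknown class name(s) in blocked set: ", paste(bad, collapse = ", "))
    entries$excluded <- entries$excluded | entries$class %in% blocked
  }
  entries
}

#' Default PFAS diagnostic-fragment and neutral-loss rules
#'
#' The rule table used to annotate data-dependent MS2 spectra. Product-ion
#' rules carry the formula of the charged fragment; neutral-loss rules
#' carry the formula of the lost neutral, applied to the candidate's
#' theoretical precursor m/z. `classes` notes which PFAS classes each rule
#' supports (e.g. the CO2 loss indicating a carboxylate). All shipped
#' rules are class-generic (`structure_specific = FALSE`): they support a
#' compound class, not one positional isomer, which is what separates
#' confidence level 2b from level 3.
#'
#' @return Data frame with columns `label`, `kind` (`"product"` or
#'   `"loss"`), `formula`, `classes`, `structure_specific`, and for
#'   product rules the theoretical anion m/z `mz`.
#' @export
default_fragment_rules <- function() {
  rules <- data.frame(
    label = c("CF3", "C2F5", "C3F7", "C4F9", "PO3", "SO3", "FSO3",
              "6:2monoPAP",
              "M-CO2", "M-HF", "M-CO2-HF", "M-2HF", "M-H2O"),
    kind = c(rep("product", 8), rep("loss", 5)),
    formula = c("CF3", "C2F5", "C3F7", "C4F9", "PO3", "SO3", "FSO3",
                "C8H5F13O4P",
                "CO2", "HF", "CO2HF", "H2F2", "H2O"),
    classes = c("PFCA;PFSA;FTS;FTCA;phosphonic", "PFCA;PFSA;FTS;FTCA;phosphonic",
                "PFCA;PFSA;FTS;FTCA;phosphonic", "PFCA;PFSA;FTS;FTCA;phosphonic",
                "diPAP;phosphonic", "PFSA;FTS", "PFSA;FTS",
                "diPAP",
                "PFCA;FTCA", "PFCA;FTCA;FTS", "PFCA;FTCA", "FTS;FTCA", "FTCA"),
    # the ether-cleavage chain fragment of a 6:2 fluorotelomer phosphate
    # ester pins down the chain, so it is structure-specific; alkyl chain
    # segments and small losses only support a compound class
    structure_specific = c(rep(FALSE, 7), TRUE, rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
  rules$mz <- ifelse(rules$kind == "product",
                     vapply(rules$formula, function(f) anion_mz(f, "anion"),
                            numeric(1)),
                     NA_real_)
  rules$neutral_mass <- ifelse(rules$kind == "loss",
                               vapply(rules$formula, monoisotopic_mass,
                                      numeric(1)),
                               NA_real_)
  rules
}

#' Read fragment rules from CSV
#'
#' Editable alternative to [default_fragment_rules()]; schema
#' `label,kind,formula,classes[,structure_specific]`.
#'
#' @param file Path to the CSV.
#' @return Rule data frame in the same layout as [default_fragment_rules()].
#' @export
read_fragment_rules <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("label", "kind", "formula", "classes")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("fragment rule table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("duplicate rule label(s)")
  if (!all(tab$kind %in% c("product", "loss")))
    stop("rule kind must be 'product' or 'loss'")
  if (is.null(tab$structure_specific)) tab$structure_specific <- FALSE
  tab$mz <- ifelse(tab$kind == "product",
                   vapply(tab$formula, function(f) anion_mz(f, "anion"),
                          numeric(1)),
                   NA_real_)
  tab$neutral_mass <- ifelse(tab$kind == "loss",
                             vapply(tab$formula, monoisotopic_mass, numeric(1)),
                             NA_real_)
  tab
}

# ---------------------------------------------------------------------------
# MGF input/output. MGF is the plain-text exchange format used here both for
# MS2 spectra referenced from feature tables and for the local spectral
# library backing level-2a matching (one entry per compound, TITLE = id).

#' Read an MGF file
#'
#' @param file Path to a Mascot generic format file.
#' @return Named list of spectra; each element carries `title`,
#'   `precursor_mz`, `rt` (seconds, `NA` if absent) and `peaks` (two-column
#'   matrix `mz`, `intensity` sorted by m/z).
#' @export
read_mgf <- function(file) {
  lines <- readLines(file, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- vector("list", length(starts))
  titles <- character(length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    title <- vals[match("TITLE", keys)]
    pep <- vals[match("PEPMASS", keys)]
    rt <- vals[match("RTINSECONDS", keys)]
    pk <- block[!kv & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), function(x)
        as.numeric(x[1:2])))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, 1]), , drop = FALSE]
    } else {
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    titles[i] <- if (is.na(title)) paste0("spectrum_", i) else title
    out[[i]] <- list(title = titles[i],
                     precursor_mz = if (is.na(pep)) NA_real_ else
                       as.numeric(strsplit(pep, "[ \t]+")[[1]][1]),
                     rt = if (is.na(rt)) NA_real_ else as.numeric(rt),
                     peaks = peaks)
  }
  stats::setNames(out, titles)
}

#' Write spectra to an MGF file
#'
#' @param spectra Named list as returned by [read_mgf()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_mgf <- function(spectra, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz))
      writeLines(paste0("PEPMASS=", format(sp$precursor_mz, digits = 10)), con)
    if (!is.null(sp$rt) && !is.na(sp$rt))
      writeLines(paste0("RTINSECONDS=", format(sp$rt, digits = 8)), con)
    if (nrow(sp$peaks))
      writeLines(paste(format(sp$peaks[, 1], digits = 10),
                       format(sp$peaks[, 2], digits = 6)), con)
    writeLines("END IONS", con)
  }
  invisible(file)
}

#' Read a local spectral library
#'
#' Loads an MGF spectral library for level-2a matching. Each record is one
#' compound; `TITLE` must be the suspect identifier. Records with empty
#' peak lists are rejected; intensities are rescaled to (0, 1].
#'
#' @param file Path to the MGF library.
#' @return Named list of library records.
#' @export
read_spectral_library <- function(file) {
  recs <- read_mgf(file)
  for (nm in names(recs)) {
    if (!nrow(recs[[nm]]$peaks))
      stop("spectral-library record '", nm, "' has no fragments")
    mx <- max(recs[[nm]]$peaks[, "intensity"])
    recs[[nm]]$peaks[, "intensity"] <- recs[[nm]]$peaks[, "intensity"] / mx
  }
  recs
}
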