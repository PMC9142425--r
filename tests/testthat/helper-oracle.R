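# Independent exact-mass oracle: a second, separately written summation
# over published monoisotopic masses (CIAAW/NIST), parsed by character
# scanning rather than the package's regex tokenizer. Used to cross-check
# monoisotopic_mass on random formulas.
ORACLE_MASSES <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  F = 18.99840322, Na = 22.9897692809, Si = 27.9769265325,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268, K = 38.96370668,
  Br = 78.9183371, I = 126.904473)
ORACLE_ELECTRON <- 0.00054857990907

oracle_mass <- function(formula) {
  chars <- strsplit(formula, "")[[1]]
  total <- 0
  i <- 1
  n <- length(chars)
  while (i <= n) {
    sym <- chars[i]
    i <- i + 1
    if (i <= n && grepl("[a-z]", chars[i])) {
      sym <- paste0(sym, chars[i])
      i <- i + 1
    }
    digits <- ""
    while (i <= n && grepl("[0-9]", chars[i])) {
      digits <- paste0(digits, chars[i])
      i <- i + 1
    }
    count <- if (nzchar(digits)) as.integer(digits) else 1L
    if (!sym %in% names(ORACLE_MASSES)) stop("oracle: unknown symbol ", sym)
    total <- total + ORACLE_MASSES[[sym]] * count
  }
  total
}

# random Hill-ish formula for property tests
random_formula <- function() {
  els <- sample(names(ORACLE_MASSES), sample(2:5, 1))
  paste0(els, sample(1:20, length(els), replace = TRUE), collapse = "")
}

# feature table constructor shared across tests
make_features <- function(mz, rt = 10, area = 1e5, sample = "S1",
                          role = "sample", ms2 = NULL, group = NULL) {
  n <- length(mz)
  df <- data.frame(sample = rep_len(sample, n), role = rep_len(role, n),
                   mz = mz, rt = rep_len(rt, n), area = rep_len(area, n),
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- rep_len(group, n)
  df$ms2 <- if (is.null(ms2)) I(rep(list(NULL), n)) else I(ms2)
  df
}

spectrum_of <- function(precursor, frag_mz, intensity = NULL) {
  if (is.null(intensity)) intensity <- rev(seq_along(frag_mz)) / length(frag_mz)
  s <- order(frag_mz)
  list(title = "test", precursor_mz = precursor, rt = NA_real_,
       peaks = cbind(mz = frag_mz[s], intensity = intensity[s]))
}
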