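# Monoisotopic masses of the most abundant isotopes (Da), standard
# reference values to >= 6 decimals. The proton is an H atom minus an
# electron. Coverage is the CHNOPS + common-salt space of small-molecule
# metabolomics.
.monoisotopic <- c(
  H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Si = 27.9769265325, Se = 79.9165213)
.electron_mass <- 0.00054857990946
.proton_mass <- .monoisotopic[["H"]] - .electron_mass

#' Parse a molecular formula
#'
#' Accepts the plain dialect (`C11H12N2O2`) and the underscored dialect
#' (`C_11_H_12_N_2_O_2`); an omitted count means 1.
#'
#' @param text formula string.
#' @return named integer vector of element counts (class
#'   `element_counts`).
#' @export
parse_formula <- function(text) {
  if (!nzchar(text)) stop("empty formula")
  s <- gsub("_", "", text)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
    stop("cannot parse formula: ", text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  parts <- regmatches(s, list(m))[[1]]
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    k <- sub("^[A-Za-z]+", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    if (!el %in% names(.monoisotopic)) stop("unknown element symbol: ", el)
    if (k == 0) stop("zero count for element ", el)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + k
  }
  structure(counts, class = "element_counts")
}

#' Monoisotopic (exact) mass of a formula
#'
#' Sum of most-abundant-isotope masses.
#'
#' @param formula an `element_counts` (from [parse_formula()]) or a
#'   formula string.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(.monoisotopic[names(formula)] * as.numeric(formula))
}

.adducts <- list(
  "[M+H]+"  = list(nM = 1, dm = +1),
  "[M-H]-"  = list(nM = 1, dm = -1),
  "[2M+H]+" = list(nM = 2, dm = +1),
  "[2M-H]-" = list(nM = 2, dm = -1))

.norm_adduct <- function(adduct) {
  a <- gsub("−|–", "-", adduct)  # unicode minus/en-dash
  if (!a %in% names(.adducts)) stop("unsupported adduct: ", adduct)
  a
}

#' Theoretical m/z of an adduct ion
#'
#' Supported adducts: `[M+H]+`, `[M-H]-` and the proton-bound dimers
#' `[2M+H]+`, `[2M-H]-`. The proton mass is the hydrogen-atom mass minus
#' the electron mass.
#'
#' @param formula neutral formula (`element_counts` or string).
#' @param adduct adduct label.
#' @return theoretical m/z in Th.
#' @export
ion_mz <- function(formula, adduct) {
  a <- .adducts[[.norm_adduct(adduct)]]
  M <- monoisotopic_mass(formula)
  a$nM * M + a$dm * .proton_mass
}

#' Relative mass error in ppm
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical m/z values (Th); theoretical > 0.
#' @return signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Ring-and-double-bond equivalents of an adduct ion
#'
#' RDB (degree of unsaturation) of the ion formula — the neutral formula
#' gains or loses one H per protonation/deprotonation — using the valence
#' rule `C - H/2 + N/2 + P/2 + 1` (O and S contribute nothing).
#' Even-electron ions therefore give half-integers.
#'
#' @param formula neutral formula (`element_counts` or string).
#' @param adduct adduct label (determines the H shift).
#' @return RDB value (integer or half-integer).
#' @export
rdb_equivalents <- function(formula, adduct) {
  if (is.character(formula)) formula <- parse_formula(formula)
  allowed <- c("C", "H", "N", "O", "S", "P")
  bad <- setdiff(names(formula), allowed)
  if (length(bad))
    stop("RDB valence rule undefined for element(s): ",
         paste(bad, collapse = ", "))
  a <- .adducts[[.norm_adduct(adduct)]]
  cnt <- function(el) if (el %in% names(formula)) a$nM * formula[[el]] else 0
  h <- cnt("H") + a$dm
  cnt("C") - h / 2 + cnt("N") / 2 + cnt("P") / 2 + 1
}

#' Load an annotation candidate list
#'
#' @param path CSV with columns `name`, `formula`, `adduct`.
#' @return data frame of candidates.
#' @export
load_candidates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "formula", "adduct")
  if (!all(req %in% names(d)))
    stop("candidate list needs columns: ", paste(req, collapse = ", "))
  d
}

#' Annotate a feature m/z against a candidate list
#'
#' Computes each candidate's theoretical adduct m/z, keeps those within
#' `tol_ppm` of the observed value (matching the polarity of the adduct),
#' and returns fully populated records sorted by absolute ppm error.
#'
#' @param mz observed m/z (Th).
#' @param polarity `"positive"` or `"negative"`.
#' @param candidates data frame `name`, `formula`, `adduct`.
#' @param tol_ppm match tolerance in ppm.
#' @return data frame of annotation records: `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `exact_mass`, `delta_ppm`, `rdb`; zero rows if no
#'   candidate matches.
#' @export
annotate_feature <- function(mz, polarity = c("positive", "negative"),
                             candidates, tol_ppm = 5) {
  polarity <- match.arg(polarity)
  if (!nrow(candidates)) stop("empty candidate list")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    ad <- .norm_adduct(candidates$adduct[i])
    pol <- if (grepl("\\+$", ad)) "positive" else "negative"
    if (pol != polarity) return(NULL)
    fo <- parse_formula(candidates$formula[i])
    tmz <- ion_mz(fo, ad)
    dppm <- ppm_error(mz, tmz)
    if (abs(dppm) > tol_ppm) return(NULL)
    data.frame(name = candidates$name[i],
               formula = candidates$formula[i], adduct = ad,
               theoretical_mz = tmz, exact_mass = monoisotopic_mass(fo),
               delta_ppm = dppm, rdb = rdb_equivalents(fo, ad),
               observed_mz = mz, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(name = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      exact_mass = numeric(0), delta_ppm = numeric(0),
                      rdb = numeric(0), observed_mz = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$delta_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
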