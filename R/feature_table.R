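#' Construct a feature table
#'
#' A feature table couples a samples x features intensity matrix with
#' per-feature metadata (m/z, retention time, polarity, biofluid of origin).
#' Intensities are raw (non-negative) abundances; missing measurements are
#' `NA`, never zero — zero is a valid measured intensity.
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#'   Row names are sample ids, column names feature ids.
#' @param feature_meta data frame with columns `feature_id`, `mz` (Th, > 0),
#'   `rt` (minutes, >= 0) and optionally `polarity`
#'   (`"positive"`/`"negative"`) and `matrix_origin` (`"serum"`/`"urine"`).
#' @param validate check invariants (unique ids, non-negative intensities,
#'   consistent dimensions). Set `FALSE` for transformed/centred matrices.
#' @return an object of class `feature_table`: a list with elements
#'   `intensities`, `feature_meta`, `sample_ids`, `feature_ids`.
#' @export
feature_table <- function(intensities, feature_meta, validate = TRUE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  feature_meta <- as.data.frame(feature_meta)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("S", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- feature_meta$feature_id
  ft <- structure(
    list(intensities = intensities,
         feature_meta = feature_meta,
         sample_ids = rownames(intensities),
         feature_ids = colnames(intensities)),
    class = "feature_table")
  if (validate) validate_feature_table(ft)
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; %d missing cells\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Validate feature-table invariants
#'
#' Checks id uniqueness, matrix/metadata consistency, non-negative
#' intensities and positive m/z. Called by [feature_table()] and the loader.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly; stops with an informative error on violation.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  dup_s <- unique(ft$sample_ids[duplicated(ft$sample_ids)])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  dup_f <- unique(ft$feature_ids[duplicated(ft$feature_ids)])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  if (!identical(colnames(ft$intensities), as.character(ft$feature_meta$feature_id)))
    stop("feature_meta$feature_id does not match intensity matrix columns")
  neg <- which(ft$intensities < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative intensity at sample '%s', feature '%s'",
                 rownames(ft$intensities)[neg[1, 1]],
                 colnames(ft$intensities)[neg[1, 2]]))
  }
  if (any(ft$feature_meta$mz <= 0)) stop("feature m/z must be > 0")
  if (any(ft$feature_meta$rt < 0)) stop("feature rt must be >= 0")
  invisible(ft)
}

.meta_cols <- c("mz", "rt", "polarity", "matrix_origin")

#' Write a feature table to CSV/TSV
#'
#' On disk features are rows: `feature_id`, `mz`, `rt`, `polarity`
#' (and `matrix_origin` if present), then one column per sample id.
#' Missing cells are written as empty fields, so missingness survives a
#' round trip ([load_feature_table()] restores them as `NA`).
#'
#' @param ft a `feature_table`.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  meta <- ft$feature_meta
  keep <- intersect(c("feature_id", .meta_cols), names(meta))
  out <- cbind(meta[keep], as.data.frame(t(ft$intensities)))
  utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, na = "", qmethod = "double")
  invisible(path)
}

#' Load a feature table from CSV/TSV
#'
#' Auto-detects orientation by the reserved `mz`/`rt` header names: if they
#' appear as columns, features are rows on disk (the native layout written
#' by [write_feature_table()]); if they appear as entries of the first
#' column, the file is transposed (samples as rows). Empty cells become
#' `NA` (missing), never zero.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param validate enforce raw-scale invariants (non-negative
#'   intensities); set `FALSE` when reloading transformed/centred tables.
#' @return a validated `feature_table`.
#' @export
load_feature_table <- function(path, dialect = c("csv", "tsv"),
                               validate = TRUE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = "")
  if (all(c("mz", "rt") %in% names(raw))) {
    meta <- raw[intersect(c("feature_id", .meta_cols), names(raw))]
    samp_cols <- setdiff(names(raw), c("feature_id", .meta_cols))
    X <- t(as.matrix(raw[samp_cols]))
    colnames(X) <- as.character(meta$feature_id)
    rownames(X) <- samp_cols
  } else if (all(c("mz", "rt") %in% raw[[1]])) {
    key <- raw[[1]]
    body <- as.matrix(raw[-1])
    meta <- data.frame(feature_id = colnames(body))
    for (mc in .meta_cols) {
      if (mc %in% key) meta[[mc]] <- unname(body[match(mc, key), ])
    }
    meta$mz <- as.numeric(meta$mz)
    meta$rt <- as.numeric(meta$rt)
    X <- body[!key %in% .meta_cols, , drop = FALSE]
    storage.mode(X) <- "double"
    rownames(X) <- key[!key %in% .meta_cols]
  } else {
    stop("cannot detect orientation: no 'mz'/'rt' columns or rows found")
  }
  storage.mode(X) <- "double"
  feature_table(X, meta, validate = validate)
}

#' Load a crossover study design
#'
#' Reads the per-sample metadata table: `sample_id`, `subject`, `phase`
#' (`baseline`/`placebo`/`oleuropein`), `week` (1/2), `day` (1-2 for
#' baseline days, 1-5 for administration days), `injection_order`
#' (positive, unique) and `is_qc`. QC rows may leave subject/phase/week/day
#' empty.
#'
#' @param path CSV file path.
#' @return a `study_design` data frame.
#' @export
load_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  req <- c("sample_id", "subject", "phase", "week", "day",
           "injection_order", "is_qc")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing design column(s): ", paste(miss, collapse = ", "))
  d$is_qc <- as.logical(d$is_qc)
  study_design(d)
}

#' Construct/validate a study design
#'
#' @param d data frame with the columns documented in [load_design()].
#' @return `d` with class `study_design` prepended.
#' @export
study_design <- function(d) {
  ok_phase <- c("baseline", "placebo", "oleuropein")
  bad <- which(!d$is_qc & !(d$phase %in% ok_phase))
  if (length(bad))
    stop(sprintf("unknown phase label '%s' in row %d", d$phase[bad[1]], bad[1]))
  if (anyDuplicated(d$injection_order))
    stop("injection_order values must be unique")
  if (any(d$injection_order < 1)) stop("injection_order must be positive")
  key <- interaction(d$subject, d$phase, d$week, d$day, drop = TRUE)
  dup <- which(!d$is_qc)[duplicated(key[!d$is_qc])]
  if (length(dup))
    stop("duplicate (subject, phase, week, day) at row ", dup[1])
  class(d) <- unique(c("study_design", class(d)))
  d
}

#' Write a study design to CSV
#' @param design a `study_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate the crossover balance of a design
#'
#' Checks that every subject appears in both weeks, receives each treatment
#' exactly once across the two crossover periods, and has the complete
#' daily series (baseline days plus administration days) in each week.
#' Problems are reported, never raised.
#'
#' @param design a `study_design`.
#' @param n_baseline_days,n_admin_days expected day counts per week.
#' @return a `validation_report` list: `n_subjects`, `n_samples_expected`,
#'   `n_samples_found`, `balance_ok`, `issues`. `balance_ok` is `TRUE` iff
#'   `issues` is empty.
#' @export
validate_crossover <- function(design, n_baseline_days = 2, n_admin_days = 5) {
  d <- design[!design$is_qc, , drop = FALSE]
  subjects <- sort(unique(d$subject))
  weeks <- sort(unique(d$week))
  issues <- character()
  n_expected <- length(subjects) * length(weeks) * (n_baseline_days + n_admin_days)
  for (s in subjects) {
    ds <- d[d$subject == s, , drop = FALSE]
    if (!all(weeks %in% ds$week)) {
      issues <- c(issues, sprintf("subject %s missing week %s", s,
                                  paste(setdiff(weeks, ds$week), collapse = ",")))
      next
    }
    trt <- vapply(weeks, function(w) {
      ph <- unique(ds$phase[ds$week == w & ds$phase != "baseline"])
      if (length(ph) == 1) ph else NA_character_
    }, character(1))
    if (anyNA(trt)) {
      issues <- c(issues, sprintf(
        "subject %s: ambiguous or missing treatment in a week", s))
    } else if (!setequal(trt, c("placebo", "oleuropein"))) {
      issues <- c(issues, sprintf(
        "subject %s does not receive both treatments across weeks (%s)",
        s, paste(trt, collapse = "/")))
    }
    for (w in weeks) {
      bd <- sort(as.integer(ds$day[ds$week == w & ds$phase == "baseline"]))
      ad <- sort(as.integer(ds$day[ds$week == w & ds$phase != "baseline"]))
      if (!identical(bd, seq_len(n_baseline_days)))
        issues <- c(issues, sprintf(
          "subject %s week %s: incomplete baseline days", s, w))
      if (!identical(ad, seq_len(n_admin_days)))
        issues <- c(issues, sprintf(
          "subject %s week %s: incomplete administration days", s, w))
    }
  }
  structure(list(n_subjects = length(subjects),
                 n_samples_expected = n_expected,
                 n_samples_found = nrow(d),
                 balance_ok = length(issues) == 0L,
                 issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d subjects, %d/%d samples, balance_ok=%s\n",
              x$n_subjects, x$n_samples_found, x$n_samples_expected,
              x$balance_ok))
  if (length(x$issues)) cat(paste0(" - ", x$issues, collapse = "\n"), "\n")
  invisible(x)
}
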