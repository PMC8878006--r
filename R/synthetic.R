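#' Specification of a synthetic crossover study
#'
#' The generator emulates the variance structure of a two-period crossover
#' intervention: on the log scale, every intensity is the sum of a feature
#' baseline, a between-subject offset, a week offset, a day offset, a
#' treatment contribution (only on affected features under the active arm)
#' and analytical noise. The treatment contribution is modulated by a
#' per-day profile so that a decaying profile reproduces the "metabolome
#' reset" geometry: the active-arm shift shrinks over consecutive
#' administration days, and a profile ending at 0 makes day-5 treated
#' samples indistinguishable in expectation from placebo.
#'
#' Defaults encode the study layout of a 9-subject, 2-week crossover with
#' 2 baseline and 5 administration days per week (126 samples per matrix),
#' with between-subject variation dominating the treatment effect — the
#' regime in which multilevel analysis is needed at all.
#'
#' @param n_subjects number of subjects (default 9).
#' @param n_features number of LC-MS features.
#' @param n_affected number of treatment-responsive features.
#' @param effect_size log-scale mean shift of affected features under the
#'   active arm (before day modulation). Default `log(1.8)`, i.e. a
#'   fold change of ~1.8, the middle of the range typically reported for
#'   candidate metabolites in such studies.
#' @param sigma_between SD of per-(subject, feature) random offsets.
#' @param sigma_week SD of per-(week, feature) offsets (shared across
#'   subjects: week effects model common causes such as environment and
#'   sample handling).
#' @param sigma_day SD of per-(week, day, feature) offsets, shared across
#'   subjects.
#' @param sigma_error SD of analytical noise per cell.
#' @param reset_profile length-5 vector in \[0, 1\] multiplying the
#'   treatment effect on administration days 1-5.
#' @param baseline_log_mean,baseline_log_sd mean and SD of per-feature
#'   log-scale baselines.
#' @param missing_rate fraction of cells to censor (in \[0, 1)); applied by
#'   [inject_missing()] downstream, not by [generate_crossover()].
#' @param drift_slope fractional intensity change per injection; applied by
#'   [apply_drift()] downstream.
#' @param mz_range,rt_range ranges for simulated feature m/z and retention
#'   time metadata.
#' @param seed default RNG seed used by [generate_crossover()].
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 9, n_features = 300,
                           n_affected = ceiling(0.1 * n_features),
                           effect_size = log(1.8),
                           sigma_between = 0.8, sigma_week = 0.3,
                           sigma_day = 0.15, sigma_error = 0.2,
                           reset_profile = c(1, 0.9, 0.7, 0.4, 0.1),
                           baseline_log_mean = 9, baseline_log_sd = 1,
                           missing_rate = 0.05, drift_slope = 0.002,
                           mz_range = c(80, 800), rt_range = c(0.5, 25),
                           seed = 1L) {
  spec <- as.list(environment())
  sds <- c(spec$sigma_between, spec$sigma_week, spec$sigma_day,
           spec$sigma_error, spec$baseline_log_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (spec$n_affected < 0 || spec$n_affected > spec$n_features)
    stop("n_affected must be between 0 and n_features")
  if (length(spec$reset_profile) != 5 ||
      any(spec$reset_profile < 0 | spec$reset_profile > 1))
    stop("reset_profile must be 5 values in [0, 1]")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(spec, class = "synthetic_spec")
}

# Crossover treatment assignment: balanced as far as an odd roster allows,
# deterministic under the generator seed (drawn inside generate_crossover).
.assign_arms <- function(subjects) {
  n <- length(subjects)
  first <- sample(subjects, ceiling(n / 2))
  w1 <- ifelse(subjects %in% first, "oleuropein", "placebo")
  w2 <- ifelse(w1 == "oleuropein", "placebo", "oleuropein")
  data.frame(subject = subjects, week1 = w1, week2 = w2,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic crossover feature table with known ground truth
#'
#' Draws log intensities as
#' `baseline_f + subject(s,f) + week(w,f) + day(w,d,f) +
#'  I(active arm, f affected) * effect_size * reset_profile[day] + noise`,
#' then exponentiates. All realised components are returned so tests can
#' verify the additive decomposition exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return list with elements `table` (a `feature_table`), `design`
#'   (a `study_design`, injection order = acquisition order), and `truth`
#'   (a `ground_truth` list of realised components and
#'   `affected_feature_ids`).
#' @export
generate_crossover <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  subjects <- LETTERS[seq_len(spec$n_subjects)]
  arms <- .assign_arms(subjects)

  rows <- list()
  for (w in 1:2) {
    for (d in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects, phase = "baseline", week = w, day = d)
    }
    for (d in 1:5) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects,
        phase = if (w == 1) arms$week1 else arms$week2,
        week = w, day = d)
    }
  }
  design <- do.call(rbind, rows)
  # acquisition order: week, then day-slot (baseline first), then subject
  slot <- ifelse(design$phase == "baseline", design$day, design$day + 2L)
  design <- design[order(design$week, slot, design$subject), ]
  design$sample_id <- sprintf("%s_w%d_%s%d", design$subject, design$week,
                              ifelse(design$phase == "baseline", "b", "a"),
                              design$day)
  design$injection_order <- seq_len(nrow(design))
  design$is_qc <- FALSE
  design <- study_design(
    design[c("sample_id", "subject", "phase", "week", "day",
             "injection_order", "is_qc")])

  p <- spec$n_features
  n <- nrow(design)
  fid <- sprintf("F%04d", seq_len(p))
  affected <- fid[seq_len(spec$n_affected)]

  baseline <- stats::rnorm(p, spec$baseline_log_mean, spec$baseline_log_sd)
  subj_off <- matrix(stats::rnorm(spec$n_subjects * p, 0, spec$sigma_between),
                     spec$n_subjects, p, dimnames = list(subjects, NULL))
  week_off <- matrix(stats::rnorm(2 * p, 0, spec$sigma_week), 2, p)
  slots <- expand.grid(week = 1:2, slot = 1:7)
  day_off <- matrix(stats::rnorm(nrow(slots) * p, 0, spec$sigma_day),
                    nrow(slots), p)
  rownames(day_off) <- paste(slots$week, slots$slot, sep = ".")

  slot_of <- ifelse(design$phase == "baseline", design$day, design$day + 2L)
  subj_comp <- subj_off[design$subject, , drop = FALSE]
  week_comp <- week_off[design$week, , drop = FALSE]
  day_comp <- day_off[paste(design$week, slot_of, sep = "."), , drop = FALSE]

  treat_comp <- matrix(0, n, p)
  is_o <- design$phase == "oleuropein"
  aff_idx <- match(affected, fid)
  if (length(aff_idx) && any(is_o)) {
    treat_comp[is_o, aff_idx] <-
      spec$effect_size * spec$reset_profile[design$day[is_o]]
  }
  noise <- matrix(stats::rnorm(n * p, 0, spec$sigma_error), n, p)

  logx <- sweep(subj_comp + week_comp + day_comp + treat_comp + noise,
                2, baseline, "+")
  dimnames(logx) <- list(design$sample_id, fid)

  meta <- data.frame(
    feature_id = fid,
    mz = round(stats::runif(p, spec$mz_range[1], spec$mz_range[2]), 4),
    rt = round(stats::runif(p, spec$rt_range[1], spec$rt_range[2]), 2),
    polarity = "positive", matrix_origin = "urine",
    stringsAsFactors = FALSE)

  truth <- structure(list(
    affected_feature_ids = affected,
    baseline = stats::setNames(baseline, fid),
    subject_offset = subj_comp, week_offset = week_comp,
    day_offset = day_comp, treatment = treat_comp, noise = noise),
    class = "ground_truth")

  list(table = feature_table(exp(logx), meta),
       design = design, truth = truth)
}

#' Add pooled-QC injections to a run
#'
#' Emulates the standard QC scheme: `n_lead` pooled-QC injections at the
#' start of the batch, one QC after every `qc_every` study samples
#' throughout, and `n_tail` at the end. The pooled QC is the feature-wise
#' mean of all study samples (a physical pool made before acquisition, so
#' it is computed from drift-free intensities). Injection orders are
#' reassigned to the full interleaved sequence.
#'
#' @param table a `feature_table` of study samples.
#' @param design matching `study_design`.
#' @param qc_every insert one QC after every this many study samples.
#' @param n_lead,n_tail QC injections at batch start/end.
#' @return list `table`, `design` including QC rows (`is_qc = TRUE`).
#' @export
make_qc_series <- function(table, design, qc_every = 10, n_lead = 5, n_tail = 5) {
  if (qc_every < 1) stop("qc_every must be >= 1")
  if (nrow(table$intensities) == 0) stop("empty feature table")
  X <- table$intensities
  design <- design[order(design$injection_order), , drop = FALSE]
  X <- X[design$sample_id, , drop = FALSE]
  pool <- colMeans(X, na.rm = TRUE)
  n <- nrow(X)
  n_interior <- n %/% qc_every
  n_qc <- n_lead + n_interior + n_tail
  qc_ids <- sprintf("QC%03d", seq_len(n_qc))

  seq_ids <- character(0)
  qi <- 0
  add_qc <- function(k) {
    ids <- qc_ids[qi + seq_len(k)]
    qi <<- qi + k
    ids
  }
  seq_ids <- c(seq_ids, add_qc(n_lead))
  for (i in seq_len(n)) {
    seq_ids <- c(seq_ids, design$sample_id[i])
    if (i %% qc_every == 0) seq_ids <- c(seq_ids, add_qc(1))
  }
  seq_ids <- c(seq_ids, add_qc(n_tail))

  Xqc <- matrix(rep(pool, each = n_qc), n_qc, ncol(X),
                dimnames = list(qc_ids, colnames(X)))
  Xall <- rbind(X, Xqc)[seq_ids, , drop = FALSE]

  dqc <- data.frame(sample_id = qc_ids, subject = NA_character_,
                    phase = NA_character_, week = NA_integer_,
                    day = NA_integer_, injection_order = NA_integer_,
                    is_qc = TRUE, stringsAsFactors = FALSE)
  dall <- rbind(as.data.frame(design), dqc)
  dall <- dall[match(seq_ids, dall$sample_id), , drop = FALSE]
  dall$injection_order <- seq_len(nrow(dall))
  rownames(dall) <- NULL
  list(table = feature_table(Xall, table$feature_meta),
       design = study_design(dall))
}

#' Apply linear injection-order drift
#'
#' Multiplies every intensity by `1 + drift_slope * (injection_order - 1)`:
#' a deterministic, analytically invertible model of instrument response
#' drift over a run.
#'
#' @param table a `feature_table`.
#' @param design matching `study_design` carrying `injection_order`.
#' @param drift_slope fractional change per injection.
#' @return drifted `feature_table`.
#' @export
apply_drift <- function(table, design, drift_slope) {
  ord <- design$injection_order[match(table$sample_ids, design$sample_id)]
  if (anyNA(ord)) stop("injection order missing for some samples")
  mult <- 1 + drift_slope * (ord - 1)
  if (any(mult <= 0))
    stop("drift multiplier <= 0 at injection ", ord[which(mult <= 0)[1]])
  feature_table(table$intensities * mult, table$feature_meta)
}

#' Censor cells to missing
#'
#' `mcar` censors every cell independently with probability `rate`.
#' `low_intensity` censors preferentially below an intensity quantile,
#' mimicking values lost near the detection limit: cells below the
#' `3*rate` quantile are censored with high probability, others with low,
#' calibrated so the expected overall rate is `rate`.
#'
#' @param table a `feature_table`.
#' @param rate target missing fraction in \[0, 1).
#' @param mechanism `"mcar"` or `"low_intensity"`.
#' @param seed RNG seed.
#' @return `feature_table` with `NA`s inserted.
#' @export
inject_missing <- function(table, rate, mechanism = c("mcar", "low_intensity"),
                           seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(table)
  set.seed(seed)
  X <- table$intensities
  obs <- !is.na(X)
  if (mechanism == "mcar") {
    hit <- obs & matrix(stats::runif(length(X)) < rate, nrow(X))
  } else {
    qcut <- stats::quantile(X[obs], min(1, 3 * rate))
    low <- obs & X <= qcut
    # split the budget so low cells carry most of the censoring
    p_low <- min(0.9, rate * length(which(obs)) * 0.8 / max(1, sum(low)))
    p_high <- max(0, (rate * sum(obs) - p_low * sum(low)) /
                    max(1, sum(obs & !low)))
    pr <- matrix(p_high, nrow(X), ncol(X))
    pr[low] <- p_low
    hit <- obs & matrix(stats::runif(length(X)), nrow(X)) < pr
  }
  # never remove a feature entirely: keep one observed value per feature
  for (j in seq_len(ncol(X))) {
    if (all(hit[obs[, j], j])) {
      keep <- which(obs[, j])[1]
      hit[keep, j] <- FALSE
    }
  }
  X[hit] <- NA_real_
  feature_table(X, table$feature_meta)
}
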