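#' Intraclass correlation, two-way mixed effects, single measure
#'
#' Repeatability of a measurement repeated in fixed sessions on random
#' subjects: the consistency ICC from the two-way mixed-effects model in
#' which subject effects are random and session (measure) effects are fixed,
#' single-measure form
#' \deqn{ICC(3,1) = (MS_S - MS_E) / (MS_S + (k - 1) MS_E)}
#' with \eqn{MS_S} the subject mean square, \eqn{MS_E} the residual mean
#' square of the subjects x sessions ANOVA without replication, and k the
#' number of sessions.
#'
#' @param values complete numeric matrix, rows = subjects (>= 2), columns =
#'   repeated sessions (>= 2).
#' @return The ICC, a number in (-1, 1].
#' @export
icc_two_way_mixed <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    onh_error("onhquant_parameter_error", "the measurement matrix must be complete")
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) {
    onh_error("onhquant_parameter_error", "need >= 2 subjects and >= 2 sessions")
  }
  if (stats::var(as.vector(values)) == 0) {
    onh_error("onhquant_degenerate_error", "zero total variance; ICC undefined")
  }
  d <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    session = factor(rep(seq_len(k), each = n))
  )
  # suppressWarnings: anova warns about F-tests on perfect fits; only the
  # mean squares are used here
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ subject + session, data = d)))
  ms_s <- tab["subject", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  (ms_s - ms_e) / (ms_s + (k - 1) * ms_e)
}

#' Rank-based ROC area under the curve
#'
#' The probability that a randomly chosen patient value exceeds a randomly
#' chosen control value, ties counted half — the Mann-Whitney estimate of
#' the ROC AUC, computed by the rank-sum formula (equivalent to exhaustive
#' enumeration of all cross-group pairs).
#'
#' @param patient,control numeric vectors of measurements, both non-empty.
#' @return AUC in \[0, 1\].
#' @export
mann_whitney_auc <- function(patient, control) {
  if (!length(patient) || !length(control)) {
    onh_error("onhquant_parameter_error", "both groups must be non-empty")
  }
  np <- length(patient); nc <- length(control)
  r <- rank(c(patient, control))
  w <- sum(r[seq_len(np)]) - np * (np + 1) / 2  # exact half-integer win count
  n_pairs <- np * nc
  # evaluated from the smaller tail so that swapping the groups returns
  # exactly 1 - AUC in floating point
  if (w <= n_pairs / 2) w / n_pairs else 1 - (n_pairs - w) / n_pairs
}

#' Normative percentile cutoff
#'
#' q-th percentile of a control distribution by linear interpolation between
#' closest ranks (base R `quantile()` type 7), the rule used to define a
#' normative cutoff such as "ONHV above the 95th percentile of the control
#' group". When a comparison sample is supplied, the count and fraction of
#' its values exceeding the cutoff are attached as attributes `n_exceed`
#' and `frac_exceed`.
#'
#' @param control_values numeric vector (>= 2 values).
#' @param q percentile in (0, 100).
#' @param compare optional vector to compare against the cutoff.
#' @return The cutoff value.
#' @export
normative_percentile <- function(control_values, q, compare = NULL) {
  if (length(control_values) < 2L) {
    onh_error("onhquant_parameter_error", "need >= 2 control values")
  }
  if (q <= 0 || q >= 100) {
    onh_error("onhquant_parameter_error", "q must be strictly between 0 and 100")
  }
  cutoff <- unname(stats::quantile(control_values, q / 100, type = 7, names = FALSE))
  if (!is.null(compare)) {
    attr(cutoff, "n_exceed") <- sum(compare > cutoff)
    attr(cutoff, "frac_exceed") <- mean(compare > cutoff)
  }
  cutoff
}

#' Lumbar-puncture distance weight
#'
#' Weighting factor for pairing an OCT measurement with an intracranial
#' pressure (lumbar puncture) measurement taken `distance_months` apart:
#' `100 / (distance_months + 1)`, so closer measurement pairs weigh more.
#'
#' @param distance_months non-negative distance in months (vectorized).
#' @return Numeric weight(s).
#' @export
lp_weight <- function(distance_months) {
  if (any(distance_months < 0)) {
    onh_error("onhquant_parameter_error", "distance_months must be >= 0")
  }
  100 / (distance_months + 1)
}

#' Cohort-level evaluation statistics
#'
#' Computes the evaluation battery on a per-eye measurement table:
#' repeatability ICCs over repeated sessions (when `session` has >= 2
#' levels per eye), the ROC AUC between the labelled groups, and the
#' normative percentile cutoff of the control group with the count of
#' patient eyes exceeding it. Eye-level clustering is carried in the table
#' (`subject_id`, `eye`) for export to external statistics environments;
#' marginal models (GEE) are not fit here.
#'
#' @param table data frame with columns `subject_id`, `eye`, `session`,
#'   `group` (`"patient"`/`"control"`), `onhv_mm3`, `onhh_mm`.
#' @param q normative percentile (default 95).
#' @return Named list with `icc_onhv`, `icc_onhh` (NA if single session),
#'   `auc_onhv`, `auc_onhh` (NA if single group), `cutoff_onhv_mm3`,
#'   `n_above_cutoff`, `frac_above_cutoff`.
#' @export
cohort_stats <- function(table, q = 95) {
  need <- c("subject_id", "eye", "session", "group", "onhv_mm3", "onhh_mm")
  if (!all(need %in% names(table))) {
    onh_error("onhquant_format_error",
              sprintf("table needs columns: %s", paste(need, collapse = ", ")))
  }
  eye_id <- interaction(table$subject_id, table$eye, drop = TRUE)
  out <- list(icc_onhv = NA_real_, icc_onhh = NA_real_,
              auc_onhv = NA_real_, auc_onhh = NA_real_,
              cutoff_onhv_mm3 = NA_real_, n_above_cutoff = NA_integer_,
              frac_above_cutoff = NA_real_)
  sessions <- sort(unique(table$session))
  if (length(sessions) >= 2L) {
    complete <- all(table(eye_id, table$session) == 1L)
    if (complete) {
      for (v in c("onhv_mm3", "onhh_mm")) {
        m <- do.call(cbind, lapply(sessions, function(s) {
          x <- table[table$session == s, ]
          x[[v]][order(interaction(x$subject_id, x$eye, drop = TRUE))]
        }))
        key <- if (v == "onhv_mm3") "icc_onhv" else "icc_onhh"
        out[[key]] <- icc_two_way_mixed(m)
      }
    }
  }
  # discrimination and cutoff use the first session only
  first <- table[table$session == sessions[1L], ]
  pat <- first$group == "patient"
  if (any(pat) && any(!pat)) {
    out$auc_onhv <- mann_whitney_auc(first$onhv_mm3[pat], first$onhv_mm3[!pat])
    out$auc_onhh <- mann_whitney_auc(first$onhh_mm[pat], first$onhh_mm[!pat])
    cut <- normative_percentile(first$onhv_mm3[!pat], q, compare = first$onhv_mm3[pat])
    out$cutoff_onhv_mm3 <- as.numeric(cut)
    out$n_above_cutoff <- attr(cut, "n_exceed")
    out$frac_above_cutoff <- attr(cut, "frac_exceed")
  }
  out
}
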