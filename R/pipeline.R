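# Classify sampling days into phases relative to the altitude sojourn:
# SL days before the first HA day are "pre", SL days after the last HA day
# are "post". Day order is taken from the factor levels (design order).
.day_phases <- function(table) {
  days <- levels(factor(table$day_label,
                        levels = unique(as.character(table$day_label))))
  cond <- vapply(days, function(d) {
    as.character(table$condition[table$day_label == d][1])
  }, character(1))
  ha_idx <- which(cond == "HA")
  phase <- rep("ha", length(days))
  phase[cond == "SL" & seq_along(days) < min(ha_idx)] <- "pre"
  phase[cond == "SL" & seq_along(days) > max(ha_idx)] <- "post"
  data.frame(day_label = days, condition = cond, phase = phase,
             stringsAsFactors = FALSE)
}

# Per-subject means over two sets of days, then a paired t-test.
.paired_contrast <- function(table, days_a, days_b, label, value_col) {
  subjects <- unique(table$subject_id)
  mean_over <- function(s, days) {
    v <- table[[value_col]][table$subject_id == s &
                              as.character(table$day_label) %in% days]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  a <- vapply(subjects, mean_over, numeric(1), days = days_a)
  b <- vapply(subjects, mean_over, numeric(1), days = days_b)
  bad <- subjects[is.na(a) | is.na(b)]
  if (length(bad))
    stop("missing pairing for contrast '", label, "' in subjects: ",
         paste(bad, collapse = ", "))
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps * max(1, abs(mean(d)))) {
    # degenerate case: every subject shows the identical difference
    est <- mean(d)
    return(data.frame(contrast = label, estimate = est,
                      t = if (est == 0) NaN else Inf * sign(est),
                      df = length(d) - 1,
                      p_value = if (est == 0) 1 else 0,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  data.frame(contrast = label,
             estimate = unname(tt$estimate),
             t = unname(tt$statistic),
             df = unname(tt$parameter),
             p_value = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Cohort analysis: condition summaries and within-subject contrasts
#'
#' Summarises GSH, GSSG and the half-cell potential per condition and
#' computes four within-subject contrasts as paired t-tests on per-subject
#' day means:
#' 1. high altitude vs pre-sojourn sea level;
#' 2. first vs last high-altitude day;
#' 3. pre-sojourn vs post-descent sea level;
#' 4. first post-descent day vs the later post-descent days.
#'
#' This is a deliberate simplification of a repeated-measures ANOVA with
#' subject as a random factor: each contrast collapses the relevant days
#' to a per-subject mean and tests the paired difference. Contrasts that
#' the design cannot support (e.g. no post-descent days) are omitted.
#' P-values are unadjusted by default; Holm adjustment is available.
#'
#' @param table a cohort sample table as from [generate_cohort()] (columns
#'   `subject_id`, `day_label`, `condition`, `gsh_umol_per_gHb`,
#'   `gssg_umol_per_gHb`, and optionally `ehc_mV`).
#' @param value_col column to analyse in the contrasts (default GSH).
#' @param adjust `"none"` (default) or `"holm"`.
#'
#' @return An object of class `cohort_analysis`: a list with `summary`
#'   (per-condition means/SDs) and `contrasts` (one row per computable
#'   contrast).
#' @export
run_cohort_analysis <- function(table, value_col = "gsh_umol_per_gHb",
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(table),
            all(c("subject_id", "day_label", "condition", value_col)
                %in% names(table)))
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2) stop("at least 2 subjects are required")
  both <- vapply(subjects, function(s) {
    cs <- table$condition[table$subject_id == s]
    all(c("SL", "HA") %in% cs)
  }, logical(1))
  if (!all(both))
    stop("subjects lacking both conditions: ",
         paste(subjects[!both], collapse = ", "))

  num_cols <- intersect(c("gsh_umol_per_gHb", "gssg_umol_per_gHb", "ehc_mV",
                          "so2_percent", "hb_g_per_L"), names(table))
  summary <- do.call(rbind, lapply(c("SL", "HA"), function(cd) {
    sub <- table[table$condition == cd, num_cols, drop = FALSE]
    data.frame(condition = cd,
               variable = num_cols,
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  ph <- .day_phases(table)
  pre_days <- ph$day_label[ph$phase == "pre"]
  ha_days <- ph$day_label[ph$phase == "ha"]
  post_days <- ph$day_label[ph$phase == "post"]
  if (!length(pre_days) || !length(ha_days))
    stop("the design must contain pre-sojourn sea-level and high-altitude days")

  contrasts <- list(
    .paired_contrast(table, ha_days, pre_days, "HA vs SL(pre)", value_col)
  )
  if (length(ha_days) >= 2)
    contrasts <- c(contrasts, list(
      .paired_contrast(table, ha_days[1], ha_days[length(ha_days)],
                       "HA early vs late", value_col)))
  if (length(post_days) >= 1)
    contrasts <- c(contrasts, list(
      .paired_contrast(table, pre_days, post_days, "pre vs post", value_col)))
  if (length(post_days) >= 2)
    contrasts <- c(contrasts, list(
      .paired_contrast(table, post_days[1], post_days[-1],
                       "post early vs late", value_col)))
  contrasts <- do.call(rbind, contrasts)
  if (adjust == "holm")
    contrasts$p_adjusted <- stats::p.adjust(contrasts$p_value, "holm")

  structure(list(summary = summary, contrasts = contrasts,
                 value_col = value_col),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Per-condition summary:\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("\nWithin-subject paired contrasts on %s:\n", x$value_col))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Tonometry analysis: release threshold and pocket occupancy
#'
#' Chains the unit conversions, the threshold estimator and the occupancy
#' fit on a (saturation, GSH) series: saturations are converted from
#' percent to fractions, GSH from umol/g Hb to mmol/L cell water, then
#' [estimate_threshold()] and [fit_phi()] are run.
#'
#' @param table a data frame with columns `so2_percent` and
#'   `gsh_umol_per_gHb` (at least 10 rows).
#' @param comp an [rbc_composition()].
#' @param linkage a [gsh_linkage()].
#' @param params an [mwc_params()].
#' @param alpha significance level for the threshold existence test.
#'
#' @return An object of class `tonometry_analysis`: a list with the
#'   `threshold` fit, the `phi` fit, a one-row `results` data frame
#'   (`threshold_so2_percent`, `phi`, `baseline_mM`,
#'   `baseline_umol_per_gHb`), and a `curve` data frame with the fitted
#'   release curve on the observed saturations.
#' @export
run_tonometry_analysis <- function(table,
                                   comp = rbc_composition(),
                                   linkage = gsh_linkage(),
                                   params = mwc_params(),
                                   alpha = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("so2_percent", "gsh_umol_per_gHb") %in% names(table)))
  if (nrow(table) < 10) stop("at least 10 points are required")
  so2 <- table$so2_percent / 100
  gsh_mM <- per_gHb_to_cellwater(table$gsh_umol_per_gHb, comp)
  hb_mM <- hb_mass_to_molar(comp$mchc_g_per_L, comp)

  thr <- estimate_threshold(so2, table$gsh_umol_per_gHb, alpha = alpha)
  phi_fit <- fit_phi(so2, gsh_mM, hb_mM, linkage, params)

  results <- data.frame(
    threshold_so2_percent = 100 * thr$threshold,
    threshold_found = thr$threshold_found,
    phi = phi_fit$phi,
    baseline_mM = phi_fit$baseline_mM,
    baseline_umol_per_gHb = cellwater_to_per_gHb(max(phi_fit$baseline_mM, 0),
                                                 comp)
  )
  ord <- order(so2)
  curve <- data.frame(
    so2_percent = 100 * so2[ord],
    gsh_umol_per_gHb = table$gsh_umol_per_gHb[ord],
    fitted_umol_per_gHb = cellwater_to_per_gHb(pmax(phi_fit$fitted[ord], 0),
                                               comp)
  )
  structure(list(threshold = thr, phi = phi_fit,
                 results = results, curve = curve),
            class = "tonometry_analysis")
}

#' @export
print.tonometry_analysis <- function(x, ...) {
  print(x$threshold)
  cat(sprintf("Pocket occupancy phi = %.3f, oxygenated baseline %.3g mM (%.3g umol/g Hb)\n",
              x$results$phi, x$results$baseline_mM,
              x$results$baseline_umol_per_gHb))
  invisible(x)
}

#' Batch one-site analysis of titration traces
#'
#' Fits [fit_one_site()] to each trace and tabulates the full
#' thermodynamic decomposition, one row per trace, input order preserved.
#'
#' @param traces a single trace data frame or a (optionally named) list of
#'   them.
#' @param protocol the common [itc_protocol()].
#' @param ... passed to [fit_one_site()].
#'
#' @return A data frame with columns `trace`, `n_sites`, `ka_per_M`,
#'   `kd_uM`, `dH_kJ_per_mol`, `dG_kJ_per_mol`, `TdS_kJ_per_mol`,
#'   `dilution_offset_uJ`, `sse`, `converged`.
#' @export
run_itc_analysis <- function(traces, protocol = itc_protocol(), ...) {
  if (is.data.frame(traces)) traces <- list(traces)
  stopifnot(is.list(traces), length(traces) >= 1)
  nm <- names(traces)
  if (is.null(nm)) nm <- as.character(seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    fit <- fit_one_site(traces[[i]], protocol, ...)
    th <- fit$thermo
    data.frame(trace = nm[i],
               n_sites = th$n_sites,
               ka_per_M = th$ka,
               kd_uM = th$kd * 1e6,
               dH_kJ_per_mol = th$dH,
               dG_kJ_per_mol = th$dG,
               TdS_kJ_per_mol = th$TdS,
               dilution_offset_uJ = fit$dilution_offset_uJ,
               sse = fit$sse,
               converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write the package's CSV tables
#'
#' Thin wrappers fixing the dialect used throughout: UTF-8,
#' comma-separated, header row required, `.` decimal separator, no row
#' names. Percent-valued columns carry a `_percent` suffix.
#'
#' @param table a data frame.
#' @param path file path.
#' @return `read_sample_csv()` returns a data frame; `write_sample_csv()`
#'   invisibly returns `path`.
#' @export
write_sample_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}
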