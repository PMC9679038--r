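# Named pseudo-random streams: each generator derives its own seed from the
# user seed, so adding a generator never perturbs the draws of another.
.stream_offsets <- c(cohort = 101L, tonometry = 211L, itc = 307L,
                     additions = 401L)

.stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offset <- .stream_offsets[[stream]]
  as.integer((abs(seed) * 8191 + offset) %% 2147483647)
}

# Positive draws by redraw-on-violation (keeps the distribution smooth near
# zero instead of piling mass at the boundary).
.rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

.rnorm_range <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Design of a high-altitude sojourn cohort
#'
#' Subjects are sampled repeatedly over a sojourn: baseline days at sea
#' level (SL), days at high altitude (HA), and days after descent. The
#' default mirrors a 7-day sampling scheme: two baseline days, two
#' high-altitude days (day 3 and day 18 of the sojourn), and three
#' post-descent days.
#'
#' @param n_subjects number of subjects (at least 2).
#' @param day_labels labels of the sampling days, in chronological order.
#' @param condition condition at each day, `"SL"` or `"HA"`; at least one
#'   of each must be present.
#'
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 12,
                          day_labels = c("PRE1", "PRE2", "HA03", "HA18",
                                         "POST1", "POST7", "POST14"),
                          condition = c("SL", "SL", "HA", "HA",
                                        "SL", "SL", "SL")) {
  stopifnot(n_subjects >= 2, length(day_labels) == length(condition),
            all(condition %in% c("SL", "HA")),
            any(condition == "SL"), any(condition == "HA"),
            !anyDuplicated(day_labels))
  structure(list(n_subjects = n_subjects, day_labels = day_labels,
                 condition = condition),
            class = "cohort_design")
}

#' Distribution parameters for the synthetic cohort
#'
#' GSH means and SDs reflect in-vivo observations: about 3.4 +/- 0.65
#' umol/g Hb at sea level rising to 4.6 +/- 0.64 umol/g Hb at altitude.
#' The GSSG, venous oxygen saturation, hemoglobin and between-subject
#' parameters are plausible invented defaults (the quantities are only
#' reported graphically in this literature) and should be treated as
#' adjustable scenario knobs, not reference values.
#'
#' @param gsh_mean_sl,gsh_sd_sl GSH mean/SD at sea level, umol/g Hb.
#' @param gsh_mean_ha,gsh_sd_ha GSH mean/SD at high altitude, umol/g Hb.
#' @param gssg_mean,gssg_sd GSSG mean/SD (condition-independent), umol/g Hb
#'   (invented defaults).
#' @param so2_mean_sl,so2_mean_ha venous oxygen saturation means, percent
#'   (invented defaults).
#' @param so2_sd venous oxygen saturation SD, percent.
#' @param hb_mean_sl,hb_mean_ha blood hemoglobin means, g/L (invented
#'   defaults; hemoglobin rises at altitude).
#' @param hb_sd blood hemoglobin SD, g/L.
#' @param subject_sd SD of the per-subject random intercept on GSH,
#'   umol/g Hb.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(gsh_mean_sl = 3.4, gsh_sd_sl = 0.65,
                          gsh_mean_ha = 4.6, gsh_sd_ha = 0.64,
                          gssg_mean = 0.8, gssg_sd = 0.15,
                          so2_mean_sl = 70, so2_mean_ha = 45, so2_sd = 4,
                          hb_mean_sl = 145, hb_mean_ha = 160, hb_sd = 8,
                          subject_sd = 0.3) {
  vals <- list(gsh_mean_sl = gsh_mean_sl, gsh_sd_sl = gsh_sd_sl,
               gsh_mean_ha = gsh_mean_ha, gsh_sd_ha = gsh_sd_ha,
               gssg_mean = gssg_mean, gssg_sd = gssg_sd,
               so2_mean_sl = so2_mean_sl, so2_mean_ha = so2_mean_ha,
               so2_sd = so2_sd, hb_mean_sl = hb_mean_sl,
               hb_mean_ha = hb_mean_ha, hb_sd = hb_sd,
               subject_sd = subject_sd)
  means <- c(gsh_mean_sl, gsh_mean_ha, gssg_mean, so2_mean_sl, so2_mean_ha,
             hb_mean_sl, hb_mean_ha)
  sds <- c(gsh_sd_sl, gsh_sd_ha, gssg_sd, so2_sd, hb_sd, subject_sd)
  stopifnot(all(means > 0), all(sds >= 0))
  structure(vals, class = "cohort_params")
}

#' Generate a synthetic cohort sample table
#'
#' Draws one row per subject and sampling day: a per-subject random
#' intercept on GSH plus the condition mean plus Gaussian noise, GSSG
#' independent of condition, venous oxygen saturation and hemoglobin per
#' condition. Concentration draws are redrawn when non-positive (and
#' saturations when outside `[0, 100]`). The GSH/GSSG half-cell potential
#' is appended via [add_ehc()]. Identical seeds give identical tables.
#'
#' @param design a [cohort_design()].
#' @param params a [cohort_params()].
#' @param seed integer seed (required; the cohort generator uses its own
#'   derived random stream).
#' @param comp an [rbc_composition()] for the redox-potential conversion.
#'
#' @return A data frame with columns `subject_id`, `day_label`,
#'   `condition`, `so2_percent`, `hb_g_per_L`, `gsh_umol_per_gHb`,
#'   `gssg_umol_per_gHb`, `ehc_mV`.
#' @export
generate_cohort <- function(design = cohort_design(),
                            params = cohort_params(),
                            seed,
                            comp = rbc_composition()) {
  stopifnot(inherits(design, "cohort_design"), inherits(params, "cohort_params"))
  set.seed(.stream_seed(seed, "cohort"))
  n_days <- length(design$day_labels)
  n <- design$n_subjects
  intercepts <- stats::rnorm(n, 0, params$subject_sd)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    is_ha <- design$condition == "HA"
    gsh_mean <- ifelse(is_ha, params$gsh_mean_ha, params$gsh_mean_sl) +
      intercepts[i]
    gsh_sd <- ifelse(is_ha, params$gsh_sd_ha, params$gsh_sd_sl)
    gsh <- vapply(seq_len(n_days),
                  function(j) .rnorm_pos(1, gsh_mean[j], gsh_sd[j]),
                  numeric(1))
    gssg <- .rnorm_pos(n_days, params$gssg_mean, params$gssg_sd)
    so2 <- vapply(seq_len(n_days), function(j) {
      .rnorm_range(1, if (is_ha[j]) params$so2_mean_ha else params$so2_mean_sl,
                   params$so2_sd, 0, 100)
    }, numeric(1))
    hb <- vapply(seq_len(n_days), function(j) {
      .rnorm_pos(1, if (is_ha[j]) params$hb_mean_ha else params$hb_mean_sl,
                 params$hb_sd)
    }, numeric(1))
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%02d", i),
      day_label = factor(design$day_labels, levels = design$day_labels),
      condition = design$condition,
      so2_percent = so2,
      hb_g_per_L = hb,
      gsh_umol_per_gHb = gsh,
      gssg_umol_per_gHb = gssg
    )
  }
  add_ehc(do.call(rbind, rows), comp)
}

#' Tonometry experiment scenario
#'
#' Describes a controlled deoxygenation series of a red-cell suspension:
#' the saturation grid, the measurement noise, and the pharmacological
#' mode. `"control"` follows the oxygen-linked release model; `"BSO"`
#' (de novo GSH synthesis inhibited) is identical in distribution to the
#' control, encoding that the deoxygenation-induced rise does not depend
#' on synthesis; `"NEM"` (all reduced thiols alkylated) yields flat
#' near-zero free GSH at every saturation.
#'
#' @param mode `"control"`, `"BSO"` or `"NEM"`.
#' @param so2_grid_percent saturation grid in percent, within `[0, 100]`
#'   (default 98 down to 5).
#' @param noise_sd measurement noise SD, umol/g Hb.
#' @param baseline_umol_per_gHb free GSH at full oxygenation, umol/g Hb.
#' @param nem_level_umol_per_gHb residual apparent GSH in NEM mode.
#' @param comp an [rbc_composition()] (sets the intracellular hemoglobin
#'   concentration and the unit conversions).
#' @param linkage a [gsh_linkage()].
#' @param params an [mwc_params()].
#'
#' @return An object of class `tonometry_scenario`.
#' @export
tonometry_scenario <- function(mode = c("control", "BSO", "NEM"),
                               so2_grid_percent = seq(98, 5, by = -3),
                               noise_sd = 0.2,
                               baseline_umol_per_gHb = 2.5,
                               nem_level_umol_per_gHb = 0.2,
                               comp = rbc_composition(),
                               linkage = gsh_linkage(),
                               params = mwc_params()) {
  mode <- match.arg(mode)
  stopifnot(all(so2_grid_percent >= 0 & so2_grid_percent <= 100),
            noise_sd >= 0, baseline_umol_per_gHb >= 0,
            nem_level_umol_per_gHb >= 0)
  structure(
    list(mode = mode, so2_grid_percent = so2_grid_percent,
         noise_sd = noise_sd,
         baseline_umol_per_gHb = baseline_umol_per_gHb,
         nem_level_umol_per_gHb = nem_level_umol_per_gHb,
         comp = comp, linkage = linkage, params = params),
    class = "tonometry_scenario"
  )
}

#' Generate a synthetic tonometry series
#'
#' Control and BSO modes draw GSH around the oxygen-linked prediction of
#' [predicted_free_gsh()] (converted to umol/g Hb); with the same seed
#' their output is identical, by construction. NEM mode draws flat
#' near-zero values. Noise is Gaussian with redraw at non-positive values.
#'
#' @param scenario a [tonometry_scenario()].
#' @param seed integer seed (required; tonometry uses its own derived
#'   random stream, shared across modes).
#'
#' @return A data frame with columns `so2_percent`, `gsh_umol_per_gHb`,
#'   `mode`.
#' @export
generate_tonometry <- function(scenario = tonometry_scenario(), seed) {
  stopifnot(inherits(scenario, "tonometry_scenario"))
  set.seed(.stream_seed(seed, "tonometry"))
  so2 <- scenario$so2_grid_percent
  n <- length(so2)
  if (scenario$mode == "NEM") {
    mean_umol <- rep(scenario$nem_level_umol_per_gHb, n)
  } else {
    hb_mM <- hb_mass_to_molar(scenario$comp$mchc_g_per_L, scenario$comp)
    baseline_mM <- per_gHb_to_cellwater(scenario$baseline_umol_per_gHb,
                                        scenario$comp)
    pred_mM <- predicted_free_gsh(so2 / 100, baseline_mM, hb_mM,
                                  scenario$linkage, scenario$params)
    mean_umol <- cellwater_to_per_gHb(pred_mM, scenario$comp)
  }
  gsh <- vapply(mean_umol,
                function(m) .rnorm_pos(1, m, scenario$noise_sd),
                numeric(1))
  data.frame(so2_percent = so2, gsh_umol_per_gHb = gsh,
             mode = scenario$mode)
}

#' Generate a noisy titration trace
#'
#' [simulate_trace()] plus i.i.d. Gaussian noise on each injection heat.
#'
#' @param protocol an [itc_protocol()].
#' @param thermo an [itc_thermo()].
#' @param noise_sd_uJ noise SD on the injection heats, uJ.
#' @param seed integer seed (its own derived random stream).
#'
#' @return A data frame as from [simulate_trace()].
#' @export
generate_itc <- function(protocol = itc_protocol(), thermo,
                         noise_sd_uJ = 0, seed) {
  stopifnot(noise_sd_uJ >= 0)
  trace <- simulate_trace(protocol, thermo)
  set.seed(.stream_seed(seed, "itc"))
  trace$heat_uJ <- trace$heat_uJ +
    stats::rnorm(nrow(trace), 0, noise_sd_uJ)
  trace
}

#' Generate a standard-additions series
#'
#' Equally spaced additions starting at zero, with intensities
#' `slope * (m0 + a_k)` plus Gaussian noise.
#'
#' @param m0_umol true initial amount, umol.
#' @param slope response per umol (positive).
#' @param n number of points (at least 3).
#' @param step_umol spacing of the additions, umol.
#' @param noise_sd intensity noise SD.
#' @param seed integer seed (its own derived random stream).
#'
#' @return A data frame with columns `added_umol`, `intensity`.
#' @export
generate_standard_additions <- function(m0_umol, slope, n = 6,
                                        step_umol = 0.5, noise_sd = 0,
                                        seed) {
  stopifnot(n >= 3, slope > 0, step_umol > 0, noise_sd >= 0, m0_umol >= 0)
  set.seed(.stream_seed(seed, "additions"))
  added <- (seq_len(n) - 1) * step_umol
  intensity <- slope * (m0_umol + added) + stats::rnorm(n, 0, noise_sd)
  data.frame(added_umol = added, intensity = intensity)
}
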