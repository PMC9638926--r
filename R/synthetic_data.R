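# Synthetic observation tables with the statistical structure of the
# gel-quantified release experiments: background release in untreated cells,
# break accumulation during a 45-min treatment, and a saturating
# ATP-dependent release phase (with a rifampicin-sensitive transcription
# component) after the treatment is removed.

#' A strain scenario for the synthetic-data generator
#'
#' The generative truth for one strain: nucleoid geometry (`a` scaffold
#' attachments), break load at the end of treatment (`b_treated`, scaled by
#' `extra_break_factor` for hyper-breaking repair mutants), the ATP-dependent
#' release kinetics (`atp_A`, `atp_k`), its transcription share, and the
#' untreated background release.
#'
#' Defaults describe the wild-type stated world: a ~475-attachment nucleoid
#' accumulating ~100 breaks over 45 min of treatment on a 2% background,
#' followed by a ~9% ATP-dependent rise (two-thirds transcription-driven)
#' with half the increment in the first 15 min (k ~ 0.0406/min).
#'
#' @param strain Strain label.
#' @param a Scaffold attachment count.
#' @param b_treated Breaks at treatment end (before `extra_break_factor`).
#' @param extra_break_factor Break multiplier (e.g. 10 for a
#'   base-excision-repair-deficient hyper-breaking mutant).
#' @param atp_A Asymptotic ATP-dependent release increment.
#' @param atp_k First-order rate of the ATP-dependent phase, per minute.
#' @param transcription_share_true Fraction of `atp_A` that is
#'   transcription-driven (removed under rifampicin).
#' @param background Untreated background release fraction, in `[0, 0.1]`.
#' @return Object of class `strain_scenario`.
#' @export
strain_scenario <- function(strain = "WT", a = 475, b_treated = 100,
                            extra_break_factor = 1,
                            atp_A = 0.09, atp_k = 0.0406,
                            transcription_share_true = 2 / 3,
                            background = 0.02) {
  stopifnot(a >= 0, b_treated >= 0, extra_break_factor >= 0,
            atp_A >= 0, atp_k >= 0,
            transcription_share_true >= 0, transcription_share_true <= 1)
  if (background < 0 || background > 0.1)
    stop("background must lie in [0, 0.1]", call. = FALSE)
  structure(list(strain = strain, a = a, b_treated = b_treated,
                 extra_break_factor = extra_break_factor,
                 atp_A = atp_A, atp_k = atp_k,
                 transcription_share_true = transcription_share_true,
                 background = background),
            class = "strain_scenario")
}

# breaks present at time t: linear ramp 0 -> b_final over the treatment
breaks_at_time <- function(scen, time_min, treatment_duration) {
  b_final <- scen$b_treated * scen$extra_break_factor
  b_final * pmin(pmax(time_min, 0), treatment_duration) / treatment_duration
}

# noiseless expected observation for one strain/condition/time
true_release <- function(scen, time_min, condition, treatment_duration) {
  b_t <- breaks_at_time(scen, time_min, treatment_duration)
  f <- scen$background + expected_release_closed_form(scen$a, round(b_t))
  if (time_min > treatment_duration && condition != "treated") {
    dt <- time_min - treatment_duration
    A <- scen$atp_A
    if (condition == "recovery_rif")
      A <- A * (1 - scen$transcription_share_true)
    f <- f + A * (1 - exp(-scen$atp_k * dt))
  }
  min(f, 1)
}

#' Generate a synthetic release-observation table
#'
#' For each strain and time point the noiseless truth is background +
#' closed-form model release at that strain's `(a, b(t))` — with breaks
#' ramping linearly over the treatment — plus, for post-treatment times, the
#' saturating ATP-dependent term (reduced to its non-transcription component
#' under the `recovery_rif` condition). Observations are replicate means of
#' truncated-Gaussian draws in `[0, 1]`; replicate SEMs are emitted.
#'
#' Times at or before `treatment_duration` are labelled `untreated` (t = 0)
#' or `treated`; later times generate a `recovery` row and, when
#' `include_rifampicin` and the scenario has an ATP phase, a `recovery_rif`
#' row.
#'
#' @param scenarios List of [strain_scenario()] objects (a single scenario
#'   is accepted).
#' @param times Time points in minutes (treatment starts at 0).
#' @param n_replicates Replicates per observation (default 3).
#' @param noise_sd Per-replicate Gaussian SD on the fraction scale
#'   (default 0.01, matching gel-quantification error bars).
#' @param rng_seed Integer seed.
#' @param treatment_duration Treatment length, minutes (default 45).
#' @param include_rifampicin Emit `recovery_rif` rows (default TRUE).
#' @return data.frame with columns `strain`, `condition`, `time_min`,
#'   `released_fraction` (replicate mean), `sem`, `true_fraction`,
#'   `n_replicates`.
#' @export
generate_release_table <- function(scenarios, times = c(0, 15, 30, 45, 60,
                                                        75, 90, 105),
                                   n_replicates = 3, noise_sd = 0.01,
                                   rng_seed = NULL, treatment_duration = 45,
                                   include_rifampicin = TRUE) {
  if (inherits(scenarios, "strain_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1, noise_sd >= 0, n_replicates >= 1)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  rows <- list()
  for (scen in scenarios) {
    stopifnot(inherits(scen, "strain_scenario"))
    for (t in sort(times)) {
      conds <- if (t == 0) "untreated"
               else if (t <= treatment_duration) "treated"
               else if (include_rifampicin && scen$atp_A > 0)
                 c("recovery", "recovery_rif")
               else "recovery"
      for (cond in conds) {
        mu <- true_release(scen, t, cond, treatment_duration)
        reps <- rtrunc_norm(n_replicates, mu, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = scen$strain, condition = cond, time_min = t,
          released_fraction = mean(reps),
          sem = if (n_replicates > 1) stats::sd(reps) / sqrt(n_replicates)
                else 0,
          true_fraction = mu, n_replicates = n_replicates,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# truncated-Gaussian draws on [0, 1] by rejection (means are far from the
# bounds at the modelled noise levels, so rejection is cheap)
rtrunc_norm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0 | out > 1
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0 | out > 1
  }
  out
}

#' Generate a synthetic gel/fragmentation table
#'
#' Per time point, simulates the linearly accumulating random break load,
#' runs the gel partition and probe hybridization, and reports the
#' fragmentation fraction, mean fragment size and ori:ter smear ratio —
#' the quantities read off fragmentation-kinetics and probe gels.
#'
#' @param scenario A [strain_scenario()].
#' @param times Time points in minutes.
#' @param rng_seed Integer seed.
#' @param genome A [circular_genome()].
#' @param gel A [gel_model()].
#' @param treatment_duration Treatment length, minutes.
#' @return data.frame with `time_min`, `n_breaks`, `fragmentation_fraction`,
#'   `mean_fragment_bp`, `ori_ter_smear_ratio`.
#' @export
generate_gel_table <- function(scenario, times = c(0, 15, 30, 45),
                               rng_seed = NULL,
                               genome = circular_genome(),
                               gel = gel_model(),
                               treatment_duration = 45) {
  stopifnot(inherits(scenario, "strain_scenario"))
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  rows <- lapply(sort(times), function(t) {
    b_t <- round(breaks_at_time(scenario, t, treatment_duration))
    bs <- random_breaks(genome, b_t)
    fr <- fragments_from_breaks(genome, bs)
    sig <- probe_signals(fr, genome, gel)
    data.frame(time_min = t, n_breaks = length(bs$cut_positions),
               fragmentation_fraction = sig$fragmentation_fraction,
               mean_fragment_bp = if (nrow(fr$arcs))
                 mean(fr$arcs$length) else NA_real_,
               ori_ter_smear_ratio = sig$smear_ori_ter_ratio)
  })
  do.call(rbind, rows)
}
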