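#' Pre-release mitigation specification
#'
#' Larviciding and/or thermal fogging applied to the wild population just
#' before a release. Efficacy is the fraction of the targeted stage removed:
#' larviciding scales the wild larval compartment by `1 - larvae`, fogging
#' scales the wild adult compartments by `1 - adults`. Eggs are untouched,
#' and released infected mosquitoes are never affected.
#'
#' @param larvae Fraction of wild larvae/pupae removed, in `[0, 1]`.
#' @param adults Fraction of wild adults removed, in `[0, 1]`.
#' @return A list of class `wolb_mitigation`.
#' @export
mitigation_spec <- function(larvae = 0, adults = 0) {
  stopifnot(larvae >= 0, larvae <= 1, adults >= 0, adults <= 1)
  structure(list(larvae = larvae, adults = adults),
            class = "wolb_mitigation")
}

#' Release plan for infected adults
#'
#' A release of `release_factor * Fu0` infected females **and** the same
#' number of infected males per unit factor, where `Fu0` is the wild female
#' population at the disease-free equilibrium (the per-sex convention:
#' factor 1 means one female per wild female plus one male per wild
#' female). The total is split into `n_batches` equal batches at regular
#' intervals: batch `i` is released at
#' `start_day + (i - 1) * window / n_batches`, so five batches over 60
#' days leave a 12-day gap.
#'
#' @param release_factor Release size relative to `Fu0` (per sex).
#' @param n_batches Number of equal batches.
#' @param window Days over which the batches are spread (ignored for a
#'   single batch).
#' @param start_day Day of the first batch.
#' @return A list of class `wolb_release_plan`.
#' @export
release_plan <- function(release_factor, n_batches = 1, window = 60,
                         start_day = 0) {
  stopifnot(release_factor >= 0, n_batches >= 1,
            n_batches == round(n_batches), window > 0)
  structure(list(release_factor = release_factor,
                 n_batches = as.integer(n_batches),
                 window = window, start_day = start_day),
            class = "wolb_release_plan")
}

#' Impulse schedule for a release plan
#'
#' @param plan A [release_plan()].
#' @param Fu0_ref Reference wild female population (usually `Fu` at the
#'   disease-free equilibrium).
#' @return A data frame with columns `time`, `Fw`, `Mw` (counts added per
#'   batch), suitable for [simulate_invasion()].
#' @export
release_impulses <- function(plan, Fu0_ref) {
  stopifnot(inherits(plan, "wolb_release_plan"), Fu0_ref > 0)
  n <- plan$n_batches
  per_batch <- plan$release_factor * Fu0_ref / n
  data.frame(
    time = plan$start_day + (seq_len(n) - 1) * plan$window / n,
    Fw = per_batch,
    Mw = per_batch
  )
}

#' Apply pre-release mitigation to the disease-free state
#'
#' Scales the wild larval compartment by `1 - larvae` efficacy and the wild
#' adult compartments (`Fu`, `Mu`) by `1 - adults` efficacy. Egg
#' compartments are left unchanged (eggs are not targeted by larvicides or
#' fogging), and infected compartments are zero at the disease-free state
#' anyway.
#'
#' @param dfe A [wolb_state()] vector, normally from
#'   [disease_free_equilibrium()].
#' @param spec A [mitigation_spec()].
#' @return The mitigated [wolb_state()] vector.
#' @export
apply_mitigation <- function(dfe, spec) {
  stopifnot(inherits(spec, "wolb_mitigation"))
  out <- dfe
  out[["Lu"]] <- (1 - spec$larvae) * out[["Lu"]]
  out[["Fu"]] <- (1 - spec$adults) * out[["Fu"]]
  out[["Mu"]] <- (1 - spec$adults) * out[["Mu"]]
  out
}

#' Simulate a mitigated, batched release
#'
#' Starts from the disease-free equilibrium, applies pre-release
#' mitigation, and integrates the model with the plan's release impulses
#' added to the infected adult compartments. The release factor is always
#' referenced to the **unmitigated** wild female population `Fu0`.
#'
#' @param params A [wolb_params()] object.
#' @param spec A [mitigation_spec()] (defaults to no mitigation).
#' @param plan A [release_plan()].
#' @param forcing Optional [fit_seasonal_curve()].
#' @param t_end Horizon in days; long enough for the bistable outcome to
#'   resolve.
#' @param init Optional starting state overriding the mitigated
#'   disease-free equilibrium (used by the seasonal experiment, where the
#'   pre-release state is the seasonal attractor).
#' @param Fu0_ref Optional reference female population for the release
#'   factor, overriding `Fu` at the disease-free equilibrium.
#' @param dt Output grid spacing (days).
#' @param rtol,atol Integrator tolerances.
#' @return A `wolb_traj` tibble (see [simulate_invasion()]); the release
#'   start day is stored in the `"release_start"` attribute.
#' @examples
#' p <- wolb_params()
#' traj <- run_release(p, plan = release_plan(2), t_end = 300)
#' time_to_fraction(traj, 0.9) # about 141 days
#' @export
run_release <- function(params, spec = mitigation_spec(), plan,
                        forcing = NULL, t_end = 3000, init = NULL,
                        Fu0_ref = NULL, dt = 0.5,
                        rtol = 1e-8, atol = 1e-6) {
  stopifnot(inherits(plan, "wolb_release_plan"))
  dfe <- disease_free_equilibrium(params)
  if (is.null(Fu0_ref)) Fu0_ref <- dfe[["Fu"]]
  if (is.null(init)) init <- apply_mitigation(dfe, spec)
  impulses <- release_impulses(plan, Fu0_ref)
  traj <- simulate_invasion(params, init, t_end = t_end, forcing = forcing,
                            impulses = impulses, t0 = min(plan$start_day, 0),
                            dt = dt, rtol = rtol, atol = atol)
  attr(traj, "release_start") <- plan$start_day
  traj
}

#' Time to reach a target infection fraction
#'
#' First time (measured from the release start) at which the female
#' infected fraction crosses the target from below, located by linear
#' interpolation on the trajectory grid. A trajectory that starts at or
#' above the target and never dips below it gets time 0; if the fraction
#' dips below the target (e.g. the wild cohort rebounds from its egg and
#' larval pipeline after a massive release), the recovery crossing counts.
#' Returns `NA` when the target is never (re)attained.
#'
#' @param traj A `wolb_traj` tibble.
#' @param target Target fraction (default 0.9).
#' @param metric `"female"` (default, the metric of the bistability
#'   threshold) or `"adult"`.
#' @return Days from the release start, or `NA`.
#' @export
time_to_fraction <- function(traj, target = 0.9,
                             metric = c("female", "adult")) {
  metric <- match.arg(metric)
  start <- attr(traj, "release_start")
  if (is.null(start)) start <- traj$t[1]
  keep <- traj$t >= start
  tt <- traj$t[keep]
  fr <- if (metric == "female") traj$frac_female[keep] else
    traj$frac_adult[keep]
  below <- fr < target
  if (!any(below)) return(0)
  i0 <- which(below)[1]
  i <- which(!below & seq_along(fr) > i0)[1]
  if (is.na(i)) return(NA_real_)
  stats::approx(fr[(i - 1):i], tt[(i - 1):i], xout = target)$y - start
}

#' Does a release scenario establish the infection?
#'
#' The system is bistable, so trajectories separate cleanly toward either
#' the disease-free or the complete-infection state; establishment is read
#' off as a final female infected fraction above 0.5 at the horizon. A
#' fraction still in `[0.4, 0.6]` at the horizon means the trajectory has
#' not resolved: the horizon is doubled once, after which an unresolved
#' outcome is an error.
#'
#' @param params A [wolb_params()] object.
#' @param spec A [mitigation_spec()].
#' @param plan A [release_plan()].
#' @param t_end Classification horizon (days).
#' @param ... Passed to [run_release()].
#' @return `TRUE` or `FALSE`.
#' @export
establishes <- function(params, spec = mitigation_spec(), plan,
                        t_end = 3000, ...) {
  verdict <- function(horizon) {
    traj <- run_release(params, spec, plan, t_end = horizon,
                        dt = horizon / 200, ...)
    female_infection_fraction(final_state(traj))
  }
  fr <- verdict(t_end)
  if (fr >= 0.4 && fr <= 0.6) fr <- verdict(2 * t_end)
  if (fr >= 0.4 && fr <= 0.6) {
    stop("establishment unresolved at extended horizon", call. = FALSE)
  }
  fr > 0.5
}

#' Threshold release factor by bisection
#'
#' Smallest single-batch release factor that establishes the infection
#' (`time_limit = NULL`), or that brings the female infected fraction to
#' 90% within `time_limit` days of the release. The factor is bisected to
#' the requested resolution inside `[0, upper]`.
#'
#' @param params A [wolb_params()] object.
#' @param spec A [mitigation_spec()].
#' @param time_limit Days allowed to reach 90% infection, or `NULL` for
#'   establishment without a time limit.
#' @param resolution Bisection resolution on the factor.
#' @param upper Upper end of the initial bracket.
#' @param target Fraction defining success under a time limit.
#' @return The threshold release factor (midpoint of the final bracket).
#' @examples
#' \donttest{
#' threshold_release_factor(wolb_params()) # about 1.13
#' }
#' @export
threshold_release_factor <- function(params, spec = mitigation_spec(),
                                     time_limit = NULL, resolution = 0.005,
                                     upper = 20, target = 0.9) {
  stopifnot(inherits(spec, "wolb_mitigation"))
  predicate <- if (is.null(time_limit)) {
    function(f) establishes(params, spec, release_plan(f))
  } else {
    function(f) {
      traj <- run_release(params, spec, release_plan(f),
                         t_end = time_limit + 30)
      tt <- time_to_fraction(traj, target = target)
      !is.na(tt) && tt <= time_limit
    }
  }
  lo <- 0; hi <- upper
  if (predicate(lo)) return(0)
  if (!predicate(hi)) {
    stop("no establishment even at release factor ", upper, call. = FALSE)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (predicate(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Establishment-time grid over release sizes and batch counts
#'
#' For each combination of total release size and number of batches
#' (spread over a fixed window), the days from the first release until 90%
#' female infection. Captures the trade-off driving multi-batch design:
#' without mitigation the larval habitat is full, so dumping all infected
#' adults at once wastes part of the release against the carrying
#' capacity, and a roughly two-week spacing (4--5 batches in two months)
#' is fastest for large releases; after strong mitigation the habitat gap
#' makes a single immediate release optimal.
#'
#' @param params A [wolb_params()] object.
#' @param spec A [mitigation_spec()].
#' @param sizes Vector of total release factors.
#' @param batch_counts Vector of batch counts.
#' @param window Days over which batches are spread.
#' @param t_end Simulation horizon.
#' @return A tibble with columns `size`, `n_batches`, `days_to_90`
#'   (`NA` where the infection fails to establish).
#' @export
batch_grid <- function(params, spec = mitigation_spec(), sizes,
                       batch_counts, window = 60, t_end = 1500) {
  stopifnot(all(sizes > 0), all(batch_counts >= 1))
  grid <- tidyr::expand_grid(size = sizes, n_batches = batch_counts)
  grid$days_to_90 <- purrr::pmap_dbl(grid, function(size, n_batches) {
    plan <- release_plan(size, n_batches = n_batches, window = window)
    traj <- run_release(params, spec, plan, t_end = t_end)
    time_to_fraction(traj, target = 0.9)
  })
  grid
}
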