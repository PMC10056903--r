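state_names <- c("Mu", "Mw", "Fu", "Fw", "Eu", "Ew", "Lu", "Lw")

#' Construct a model state vector
#'
#' A state is a named numeric vector of the eight compartment abundances:
#' adult males (`Mu`, `Mw`), adult females (`Fu`, `Fw`), eggs (`Eu`, `Ew`)
#' and larvae/pupae (`Lu`, `Lw`). Abundances are continuous counts and must
#' be nonnegative; the combined larval load may not exceed the carrying
#' capacity at initialization, which keeps the logistic factor
#' `K = 1 - (Lu + Lw)/K_l` inside `[0, 1]` along trajectories.
#'
#' @param Mu,Mw,Fu,Fw,Eu,Ew,Lu,Lw Compartment abundances.
#' @param params Optional [wolb_params()]; when supplied, the larval-load
#'   guard `Lu + Lw <= K_l` is enforced.
#' @return A named numeric vector of length 8.
#' @export
wolb_state <- function(Mu = 0, Mw = 0, Fu = 0, Fw = 0,
                       Eu = 0, Ew = 0, Lu = 0, Lw = 0, params = NULL) {
  y <- c(Mu = Mu, Mw = Mw, Fu = Fu, Fw = Fw,
         Eu = Eu, Ew = Ew, Lu = Lu, Lw = Lw)
  validate_state(y, params)
  y
}

validate_state <- function(y, params = NULL) {
  if (!is.numeric(y) || length(y) != 8) {
    stop("state must be a numeric vector of length 8", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("state has non-finite components",
                               call. = FALSE)
  if (any(y < 0)) stop("state has negative components", call. = FALSE)
  if (!is.null(params) && y[["Lu"]] + y[["Lw"]] > params$K_l) {
    stop("larval load Lu + Lw exceeds carrying capacity K_l", call. = FALSE)
  }
  invisible(y)
}

#' Derived mixing fractions and the logistic crowding factor
#'
#' Computes the probability that a randomly encountered male is uninfected
#' or infected, and the logistic factor `K = 1 - (Lu + Lw)/K_l` that throttles
#' the egg-to-larva inflow as the aquatic habitat fills. When no males are
#' present both mating probabilities are degenerate; by convention the
#' infected-male fraction is reported as 0 (all birth terms vanish in that
#' case, so the convention does not alter the dynamics).
#'
#' @param state A [wolb_state()] vector.
#' @param params A [wolb_params()] object.
#' @param K_l_t Optional instantaneous carrying capacity overriding
#'   `params$K_l` (used with seasonal forcing).
#' @return A list with `male_uninfected_fraction`, `male_infected_fraction`
#'   and `K`.
#' @examples
#' p <- wolb_params()
#' s <- wolb_state(Mu = 100, Mw = 100, Lu = p$K_l / 2)
#' derived_fractions(s, p)
#' @export
derived_fractions <- function(state, params, K_l_t = NULL) {
  total_m <- state[["Mu"]] + state[["Mw"]]
  if (total_m > 0) {
    mw <- state[["Mw"]] / total_m
    mu <- state[["Mu"]] / total_m
  } else {
    mw <- 0
    mu <- 1
  }
  Kl <- if (is.null(K_l_t)) params$K_l else K_l_t
  list(
    male_uninfected_fraction = mu,
    male_infected_fraction = mw,
    K = 1 - (state[["Lu"]] + state[["Lw"]]) / Kl
  )
}

# Right-hand side of the eight ODEs. The uninfected-egg birth term is
# phi_u * (m_u + (1 - c_i) * m_w) * Fu + v_u * phi_w * Fw: a wild female
# mated to an infected male lays viable eggs only if CI fails (fraction
# 1 - c_i), while an infected female leaks a fraction v_u of uninfected
# offspring. At c_i = 1 the term reduces to phi_u * m_u * Fu.
rhs_core <- function(t, y, params, s_fun = NULL) {
  if (!all(is.finite(y))) {
    stop("non-finite state at t = ", t, " (integrator blow-up?)",
         call. = FALSE)
  }
  Kl <- if (is.null(s_fun)) params$K_l else params$K_l * s_fun(t)
  total_m <- y[[1]] + y[[2]]
  if (total_m > 0) {
    m_u <- y[[1]] / total_m
    m_w <- y[[2]] / total_m
  } else {
    m_u <- 1
    m_w <- 0
  }
  K <- 1 - (y[[7]] + y[[8]]) / Kl
  v_u <- 1 - params$v_w
  b_m <- 1 - params$b_f
  with(params, {
    dMu <- b_m * psi * y[[7]] - mu_mu * y[[1]]
    dMw <- b_m * psi * y[[8]] - mu_mw * y[[2]]
    dFu <- b_f * psi * y[[7]] - mu_fu * y[[3]]
    dFw <- b_f * psi * y[[8]] - mu_fw * y[[4]]
    dEu <- phi_u * (m_u + (1 - c_i) * m_w) * y[[3]] + v_u * phi_w * y[[4]] -
      (delta + mu_eu) * y[[5]]
    dEw <- v_w * phi_w * y[[4]] - (delta + mu_ew) * y[[6]]
    dLu <- delta * K * y[[5]] - (psi + mu_l) * y[[7]]
    dLw <- delta * K * y[[6]] - (psi + mu_l) * y[[8]]
    c(dMu, dMw, dFu, dFw, dEu, dEw, dLu, dLw)
  })
}

#' Evaluate the model right-hand side
#'
#' Time-derivatives of the eight compartments at a given state. With a
#' [fit_seasonal_curve()] object the carrying capacity becomes
#' `K_l(t) = K_l * s(t)`.
#'
#' @param t Time in days (only used with time-varying forcing).
#' @param state A [wolb_state()] vector.
#' @param params A [wolb_params()] object.
#' @param forcing Optional [fit_seasonal_curve()] object, or `NULL` for a
#'   constant carrying capacity.
#' @return Named numeric vector of the eight derivatives (counts per day).
#' @export
wolb_rhs <- function(t, state, params, forcing = NULL) {
  s_fun <- if (is.null(forcing)) NULL else forcing_fun(forcing)
  d <- rhs_core(t, as.numeric(state[state_names]), params, s_fun)
  stats::setNames(d, state_names)
}

#' Integrate the invasion model
#'
#' Integrates the eight-compartment system with the stiff-capable `lsoda`
#' integrator from \pkg{deSolve}. Release impulses (instantaneous additions
#' of infected adults) are applied exactly: the integrator stops at each
#' impulse time, the released counts are added to `Fw` and `Mw`, and the
#' integration restarts. Impulses scheduled at `t0` are folded into the
#' initial state before integration starts so that the first output row is
#' the post-release state.
#'
#' @param params A [wolb_params()] object.
#' @param init Initial [wolb_state()] vector.
#' @param t_end Final time (days).
#' @param forcing Optional [fit_seasonal_curve()] for a time-varying carrying
#'   capacity.
#' @param impulses Optional data frame with columns `time`, `Fw`, `Mw`
#'   giving the released infected females/males at each impulse (see
#'   [release_plan()] and [release_impulses()]).
#' @param t0 Start time (days).
#' @param dt Output grid spacing (days); dense enough to interpolate
#'   threshold crossings to about 0.1 day.
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @return A `wolb_traj` tibble with columns `t`, the eight compartments,
#'   and the derived series `frac_female` (`Fw / (Fu + Fw)`) and
#'   `frac_adult` (`(Fw + Mw) / (Fu + Fw + Mu + Mw)`), both reported as 0
#'   when their denominator population is empty.
#' @examples
#' p <- wolb_params()
#' traj <- simulate_invasion(p, disease_free_equilibrium(p), t_end = 50)
#' tail(traj)
#' @export
simulate_invasion <- function(params, init, t_end, forcing = NULL,
                              impulses = NULL, t0 = 0, dt = 0.5,
                              rtol = 1e-8, atol = 1e-6) {
  stopifnot(is_wolb_params(params), t_end > t0)
  y0 <- as.numeric(init[state_names])
  names(y0) <- state_names
  validate_state(y0)
  s_fun <- if (is.null(forcing)) NULL else forcing_fun(forcing)
  times <- seq(t0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  events <- NULL
  if (!is.null(impulses) && nrow(impulses) > 0) {
    stopifnot(all(c("time", "Fw", "Mw") %in% names(impulses)))
    if (any(impulses$time < t0 | impulses$time > t_end)) {
      stop("impulse times must lie within [t0, t_end]", call. = FALSE)
    }
    at_start <- impulses$time <= t0
    if (any(at_start)) {
      y0[["Fw"]] <- y0[["Fw"]] + sum(impulses$Fw[at_start])
      y0[["Mw"]] <- y0[["Mw"]] + sum(impulses$Mw[at_start])
    }
    later <- impulses[!at_start, , drop = FALSE]
    if (nrow(later) > 0) {
      ev <- data.frame(
        var = rep(c("Fw", "Mw"), each = nrow(later)),
        time = rep(later$time, 2),
        value = c(later$Fw, later$Mw),
        method = "add"
      )
      ev <- ev[order(ev$time, ev$var), ]
      events <- list(data = ev)
      times <- sort(unique(c(times, later$time)))
    }
  }

  derivs <- function(t, y, parms) list(rhs_core(t, y, params, s_fun))
  sol <- deSolve::ode(
    y = y0, times = times, func = derivs, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol, events = events
  )
  scale <- max(abs(y0), params$K_l)
  if (min(sol[, state_names]) < -1e-6 * scale) {
    stop("trajectory breached nonnegativity beyond tolerance", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out)[1] <- "t"
  out$frac_female <- frac_series(out$Fw, out$Fu + out$Fw)
  out$frac_adult <- frac_series(out$Fw + out$Mw,
                                out$Fu + out$Fw + out$Mu + out$Mw)
  new_wolb_traj(out, params)
}

frac_series <- function(num, den) ifelse(den > 0, num / den, 0)

new_wolb_traj <- function(df, params) {
  structure(df, params = params,
            class = c("wolb_traj", class(tibble::tibble())))
}

#' Infection fractions of a state
#'
#' `female_infection_fraction()` is `Fw / (Fu + Fw)`; this is the metric in
#' which the bistability threshold is expressed (34% at baseline).
#' `adult_infection_fraction()` is `(Fw + Mw) / (Fu + Fw + Mu + Mw)`. Both
#' return 0 on an empty denominator.
#'
#' @param state A [wolb_state()] vector.
#' @return A fraction in `[0, 1]`.
#' @export
female_infection_fraction <- function(state) {
  den <- state[["Fu"]] + state[["Fw"]]
  if (den > 0) state[["Fw"]] / den else 0
}

#' @rdname female_infection_fraction
#' @export
adult_infection_fraction <- function(state) {
  den <- state[["Fu"]] + state[["Fw"]] + state[["Mu"]] + state[["Mw"]]
  if (den > 0) (state[["Fw"]] + state[["Mw"]]) / den else 0
}

#' Final state of a trajectory
#'
#' @param traj A `wolb_traj` tibble from [simulate_invasion()].
#' @return A [wolb_state()] vector at the last time point.
#' @export
final_state <- function(traj) {
  last <- traj[nrow(traj), ]
  vapply(state_names, function(nm) last[[nm]], numeric(1))
}
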