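#' Normalized relative sensitivity index (elasticity)
#'
#' The index `S = (p/q) * dq/dp` measures the percentage change in a
#' quantity of interest `q` per percent change in a parameter `p`,
#' evaluated at the baseline. The derivative is taken by central finite
#' differences with a relative step (default `1e-3`), or one-sided
#' downward at a parameter's upper domain boundary (relevant for
#' `v_w = 1`, which cannot be perturbed upward). The pseudo-parameter
#' `"mu_adults"` perturbs all four adult death rates
#' (`mu_fu`, `mu_fw`, `mu_mu`, `mu_mw`) by the same relative amount
#' simultaneously, emulating an environmental change that hits infected
#' and uninfected adults alike.
#'
#' @param qoi_fn Function of a [wolb_params()] object returning a scalar.
#' @param param_name One of the model parameter names, or `"mu_adults"`.
#' @param params Baseline [wolb_params()] object.
#' @param rel_step Relative perturbation size.
#' @return The elasticity (dimensionless scalar).
#' @examples
#' sensitivity_index(basic_reproductive_number, "mu_ew", wolb_params())
#' @export
sensitivity_index <- function(qoi_fn, param_name, params, rel_step = 1e-3) {
  stopifnot(is_wolb_params(params))
  joint <- identical(param_name, "mu_adults")
  if (!joint && !param_name %in% param_names) {
    stop("unknown parameter: ", param_name, call. = FALSE)
  }
  perturb <- function(fac) {
    if (joint) {
      update_params(params,
                    mu_fu = params$mu_fu * fac, mu_fw = params$mu_fw * fac,
                    mu_mu = params$mu_mu * fac, mu_mw = params$mu_mw * fac)
    } else {
      args <- stats::setNames(list(params[[param_name]] * fac), param_name)
      do.call(update_params, c(list(params), args))
    }
  }
  q0 <- qoi_fn(params)
  if (!is.finite(q0) || q0 == 0) {
    stop("QOI is zero or undefined at baseline; elasticity undefined",
         call. = FALSE)
  }
  # fractions capped at 1 can only be perturbed downward from the boundary
  at_upper <- !joint && param_name %in% fraction_names &&
    params[[param_name]] * (1 + rel_step) > 1
  if (at_upper) {
    qm <- qoi_fn(perturb(1 - rel_step))
    dq_dp_rel <- (q0 - qm) / rel_step
  } else {
    qp <- qoi_fn(perturb(1 + rel_step))
    qm <- qoi_fn(perturb(1 - rel_step))
    dq_dp_rel <- (qp - qm) / (2 * rel_step)
  }
  dq_dp_rel / q0
}

#' Closed-form elasticities of the basic reproductive number
#'
#' `R0 = v_w * mu_fu * phi_w * (delta + mu_eu) /
#'       (mu_fw * phi_u * (delta + mu_ew))`
#' is a product of powers in most parameters, so its elasticities are exact
#' constants: +1 for `v_w`, `phi_w`, `mu_fu`; -1 for `phi_u`, `mu_fw`;
#' `mu_eu/(delta + mu_eu)` for `mu_eu`; `-mu_ew/(delta + mu_ew)` for
#' `mu_ew`; `delta * (1/(delta + mu_eu) - 1/(delta + mu_ew))` for `delta`;
#' and exactly 0 for `psi`, `mu_l`, `mu_mu`, `mu_mw` (which cancel out of
#' the ratio `G0w/G0u`). The joint `mu_adults` perturbation is 0 because
#' the `mu_fu` and `mu_fw` elasticities are equal and opposite.
#'
#' @param params A [wolb_params()] object.
#' @return A tibble with columns `parameter` and `S`.
#' @export
r0_sensitivities_analytic <- function(params) {
  stopifnot(is_wolb_params(params))
  with(params, tibble::tibble(
    parameter = c("v_w", "phi_w", "phi_u", "mu_fw", "mu_fu",
                  "mu_ew", "mu_eu", "delta",
                  "psi", "mu_mu", "mu_mw", "mu_l", "mu_adults"),
    S = c(1, 1, -1, -1, 1,
          -mu_ew / (delta + mu_ew),
          mu_eu / (delta + mu_eu),
          delta * (1 / (delta + mu_eu) - 1 / (delta + mu_ew)),
          0, 0, 0, 0, 0)
  ))
}

#' Local sensitivity table for the invasion quantities of interest
#'
#' Elasticities of up to three quantities with respect to the thirteen
#' parameters of interest (twelve model rates/fractions plus the joint
#' `mu_adults` perturbation):
#' \describe{
#'   \item{`R0`}{the basic reproductive number (closed-form elasticities,
#'     see [r0_sensitivities_analytic()]).}
#'   \item{`threshold`}{the threshold female infection fraction at the
#'     unstable coexistence state (finite differences on the closed form).}
#'   \item{`time_to_90`}{days from the first release until the female
#'     infected fraction reaches 90%, for a reference release scenario:
#'     pre-release mitigation at 60% efficacy on both larvae and adults,
#'     total release size 2 (relative to the wild female population at the
#'     disease-free state) split into five equal batches over 60 days.}
#' }
#' The time QOI requires one ODE solve per perturbation; a perturbed
#' scenario in which the infection fails to establish yields an `NA` index
#' with a warning rather than being dropped silently.
#'
#' @param params Baseline [wolb_params()] object.
#' @param qois Character subset of `c("R0", "threshold", "time_to_90")`.
#' @param rel_step Relative finite-difference step.
#' @param scenario Release scenario for the time QOI, as a list with
#'   elements `mitigation` ([mitigation_spec()]) and `plan`
#'   ([release_plan()]).
#' @return A tibble with columns `qoi`, `parameter`, `S`, ordered by
#'   decreasing `|S|` of the threshold row's ranking.
#' @export
sensitivity_table <- function(params,
                              qois = c("R0", "threshold", "time_to_90"),
                              rel_step = 1e-3,
                              scenario = NULL) {
  stopifnot(is_wolb_params(params))
  qois <- match.arg(qois, several.ok = TRUE)
  pois <- c("v_w", "phi_w", "phi_u", "mu_fw", "mu_fu", "mu_ew", "mu_eu",
            "delta", "psi", "mu_mu", "mu_mw", "mu_l", "mu_adults")
  out <- list()
  if ("R0" %in% qois) {
    an <- r0_sensitivities_analytic(params)
    out$R0 <- tibble::tibble(qoi = "R0",
                             parameter = pois,
                             S = an$S[match(pois, an$parameter)])
  }
  if ("threshold" %in% qois) {
    out$threshold <- tibble::tibble(
      qoi = "threshold", parameter = pois,
      S = vapply(pois, function(nm) {
        sensitivity_index(threshold_female_fraction, nm, params, rel_step)
      }, numeric(1))
    )
  }
  if ("time_to_90" %in% qois) {
    if (is.null(scenario)) {
      scenario <- list(
        mitigation = mitigation_spec(larvae = 0.6, adults = 0.6),
        plan = release_plan(release_factor = 2, n_batches = 5, window = 60)
      )
    }
    time_qoi <- function(p) {
      traj <- run_release(p, scenario$mitigation, scenario$plan,
                          t_end = 1500)
      time_to_fraction(traj, target = 0.9)
    }
    out$time_to_90 <- tibble::tibble(
      qoi = "time_to_90", parameter = pois,
      S = vapply(pois, function(nm) {
        s <- tryCatch(sensitivity_index(time_qoi, nm, params, rel_step),
                      error = function(e) NA_real_)
        if (is.na(s)) {
          warning("time-to-90% undefined when perturbing '", nm,
                  "'; index flagged as NA", call. = FALSE)
        }
        s
      }, numeric(1))
    )
  }
  dplyr::bind_rows(out)
}
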