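#' Next-generation numbers of the uninfected and infected cohorts
#'
#' The next-generation number of a cohort is the expected number of new
#' adult females produced per female over one full life cycle: lifetime
#' fecundity `phi / mu_f`, times the egg-survival probability
#' `delta / (delta + mu_e)`, times the probability
#' `b_f * psi / (psi + mu_l)` that a larva emerges as an adult female. The
#' infected number carries the maternal-transmission factor `v_w` since only
#' that fraction of an infected female's eggs is infected.
#'
#' @param params A [wolb_params()] object.
#' @return Named numeric vector `c(G0u, G0w)`.
#' @examples
#' next_generation_numbers(wolb_params())
#' @export
next_generation_numbers <- function(params) {
  stopifnot(is_wolb_params(params))
  emerge <- params$b_f * params$psi / (params$psi + params$mu_l)
  G0u <- emerge * params$delta / (params$delta + params$mu_eu) *
    params$phi_u / params$mu_fu
  G0w <- params$v_w * emerge * params$delta / (params$delta + params$mu_ew) *
    params$phi_w / params$mu_fw
  c(G0u = G0u, G0w = G0w)
}

#' Basic reproductive number of the Wolbachia infection
#'
#' Spectral radius of the next-generation matrix of the infected subsystem
#' linearized at the disease-free equilibrium:
#' `R0 = v_w * mu_fu * phi_w * (delta + mu_eu) /
#'       (mu_fw * phi_u * (delta + mu_ew))`.
#' It equals the ratio `G0w / G0u` of the next-generation numbers: the
#' average number of infected offspring per infected individual introduced
#' near the disease-free state. A fitness cost of infection puts `R0 < 1`,
#' so a small introduction dies out and establishment requires exceeding a
#' threshold infection level.
#'
#' @param params A [wolb_params()] object.
#' @return `R0` (dimensionless).
#' @examples
#' basic_reproductive_number(wolb_params()) # about 0.68
#' @export
basic_reproductive_number <- function(params) {
  stopifnot(is_wolb_params(params))
  with(params, v_w * mu_fu * phi_w * (delta + mu_eu) /
         (mu_fw * phi_u * (delta + mu_ew)))
}

#' Disease-free equilibrium
#'
#' The steady state with no infected mosquitoes. The wild larval load is
#' `Lu0 = K_l * (1 - 1/G0u)`, with the adult and egg compartments following
#' from the stage balance. Requires `G0u > 1` for a positive population;
#' otherwise the wild population cannot sustain itself and the origin is
#' returned with a warning.
#'
#' @param params A [wolb_params()] object.
#' @return A [wolb_state()] vector.
#' @export
disease_free_equilibrium <- function(params) {
  stopifnot(is_wolb_params(params))
  G0u <- next_generation_numbers(params)[["G0u"]]
  if (G0u <= 1) {
    warning("G0u <= 1: the wild population is not viable; ",
            "returning the extinction state", call. = FALSE)
    return(wolb_state())
  }
  Lu0 <- params$K_l * (1 - 1 / G0u)
  with(params, wolb_state(
    Mu = (1 - b_f) * psi / mu_mu * Lu0,
    Fu = b_f * psi / mu_fu * Lu0,
    Eu = b_f * psi / mu_fu * phi_u / (delta + mu_eu) * Lu0,
    Lu = Lu0
  ))
}

#' Complete-infection equilibrium
#'
#' The steady state in which every mosquito is infected. It exists only
#' under perfect maternal transmission (`v_w = 1`); with leakage
#' (`v_w < 1`) infected females keep producing uninfected offspring and the
#' appropriate coexistence state is [endemic_equilibrium()]. The infected
#' larval load is `Lwc = K_l * (1 - 1/G0w)`.
#'
#' @param params A [wolb_params()] object with `v_w = 1` and `G0w > 1`.
#' @return A [wolb_state()] vector.
#' @export
complete_infection_equilibrium <- function(params) {
  stopifnot(is_wolb_params(params))
  if (params$v_w < 1) {
    stop("the complete-infection equilibrium is undefined for v_w < 1; ",
         "use endemic_equilibrium()", call. = FALSE)
  }
  G0w <- next_generation_numbers(params)[["G0w"]]
  if (G0w <= 1) {
    warning("G0w <= 1: the infected population is not viable; ",
            "returning the extinction state", call. = FALSE)
    return(wolb_state())
  }
  Lwc <- params$K_l * (1 - 1 / G0w)
  with(params, wolb_state(
    Mw = (1 - b_f) * psi / mu_mw * Lwc,
    Fw = b_f * psi / mu_fw * Lwc,
    Ew = b_f * psi / mu_fw * phi_w / (delta + mu_ew) * Lwc,
    Lw = Lwc
  ))
}

#' Infected-to-uninfected larval ratio at coexistence
#'
#' At a coexistence (endemic) equilibrium the ratio `r = Lw*/Lu*` satisfies
#' the quadratic
#' `a r^2 + (a - 1) r + (1 - R0)/R0 = 0` with
#' `a = (v_u/v_w) * (delta + mu_ew)/(delta + mu_eu)`,
#' derived under equal male death rates (`mu_mu = mu_mw`). Under perfect
#' maternal transmission the quadratic degenerates to the linear relation
#' `r = (1 - R0)/R0`. When two positive roots exist, the root that remains
#' finite as `v_w -> 1` (the smaller one) is the continuation of the
#' threshold branch of the bifurcation diagram; the other diverges in that
#' limit.
#'
#' @param params A [wolb_params()] object (requires `mu_mu == mu_mw`).
#' @return A tibble with columns `rwu`, `threshold_branch` (logical) and
#'   `residual` (value of the quadratic at the root); zero rows when no
#'   positive real root exists.
#' @export
endemic_ratio <- function(params) {
  stopifnot(is_wolb_params(params))
  # the quadratic is derived under equal male death rates; the male rates
  # cancel from its coefficients, so small imbalances are harmless, but a
  # grossly unequal pair voids the underlying equilibrium construction
  if (abs(params$mu_mu - params$mu_mw) > 1e-2 * params$mu_mu) {
    warning("endemic_ratio() assumes equal male death rates ",
            "(mu_mu == mu_mw); results are approximate", call. = FALSE)
  }
  R0 <- basic_reproductive_number(params)
  if (R0 <= 0) return(tibble::tibble(rwu = numeric(0),
                                     threshold_branch = logical(0),
                                     residual = numeric(0)))
  cq <- (1 - R0) / R0
  if (params$v_w >= 1) {
    roots <- cq
  } else {
    a <- (1 - params$v_w) / params$v_w *
      (params$delta + params$mu_ew) / (params$delta + params$mu_eu)
    disc <- (a - 1)^2 - 4 * a * cq
    if (disc < 0) {
      roots <- numeric(0)
    } else {
      # smaller root first: it is the one continuous with the v_w = 1 limit
      roots <- sort(((1 - a) + c(-1, 1) * sqrt(disc)) / (2 * a))
    }
  }
  roots <- roots[roots > 0]
  resid <- vapply(roots, function(r) {
    if (params$v_w >= 1) -r + cq
    else {
      a <- (1 - params$v_w) / params$v_w *
        (params$delta + params$mu_ew) / (params$delta + params$mu_eu)
      a * r^2 + (a - 1) * r + cq
    }
  }, numeric(1))
  tibble::tibble(
    rwu = roots,
    threshold_branch = seq_along(roots) == 1,
    residual = resid
  )
}

#' Coexistence (endemic) equilibrium for a given larval ratio
#'
#' Builds the full eight-compartment steady state from the larval ratio
#' `rwu = Lw*/Lu*`. The combined larval load is `K_l * (1 - 1/G0w)`
#' regardless of `rwu`, split as `Lu* = (1/(1 + rwu)) * K_l * (1 - 1/G0w)`.
#' The state is an exact equilibrium only when `rwu` solves the
#' [endemic_ratio()] quadratic.
#'
#' @param params A [wolb_params()] object.
#' @param rwu Positive larval ratio, normally a root from [endemic_ratio()].
#' @return A [wolb_state()] vector.
#' @export
endemic_equilibrium <- function(params, rwu) {
  stopifnot(is_wolb_params(params), rwu > 0)
  G0w <- next_generation_numbers(params)[["G0w"]]
  Lu <- 1 / (1 + rwu) * params$K_l * (1 - 1 / G0w)
  v_u <- 1 - params$v_w
  with(params, wolb_state(
    Mu = (1 - b_f) * psi / mu_mu * Lu,
    Mw = rwu * (1 - b_f) * psi / mu_mw * Lu,
    Fu = b_f * psi / mu_fu * Lu,
    Fw = rwu * b_f * psi / mu_fw * Lu,
    Eu = b_f * psi / (delta + mu_eu) *
      (phi_u / mu_fu * 1 / (1 + rwu) + v_u * phi_w / mu_fw * rwu) * Lu,
    Ew = rwu * b_f * psi / (delta + mu_ew) * v_w * phi_w / mu_fw * Lu,
    Lu = Lu,
    Lw = rwu * Lu
  ))
}

#' Threshold female infection fraction
#'
#' The female infected fraction at the unstable coexistence equilibrium:
#' the minimum infection level among females that must be exceeded (under a
#' natural distribution of infection across stages) for the infection to
#' take over rather than die out. In closed form it is
#' `c * r / (1 + c * r)` with `c = mu_fu/mu_fw` and `r` the
#' threshold-branch root of [endemic_ratio()]. At baseline it evaluates to
#' about 0.347 (the "34%" invasion threshold).
#'
#' @param params A [wolb_params()] object with `0 < R0 < 1`.
#' @return A fraction in `[0, 1]`, or `NA` if no threshold branch exists.
#' @examples
#' threshold_female_fraction(wolb_params())
#' @export
threshold_female_fraction <- function(params) {
  roots <- endemic_ratio(params)
  if (nrow(roots) == 0) return(NA_real_)
  r <- roots$rwu[roots$threshold_branch][1]
  cc <- params$mu_fu / params$mu_fw
  cc * r / (1 + cc * r)
}

#' Full equilibrium and threshold report
#'
#' Computes the next-generation numbers, the basic reproductive number, the
#' three equilibria (disease-free, complete-infection when `v_w = 1`, and
#' coexistence states for every positive root of the ratio quadratic), the
#' invasion threshold, and eigenvalue-based stability verdicts for each
#' equilibrium.
#'
#' @param params A [wolb_params()] object.
#' @return An object of class `wolb_equilibria` with fields `params`,
#'   `G0u`, `G0w`, `R0`, `dfe`, `cie`, `rwu`, `ee`,
#'   `threshold_female_fraction` and `stability`. Use [tidy()] for the
#'   equilibria as a tibble and [glance()] for the scalar summary.
#' @examples
#' rep <- equilibrium_report(wolb_params())
#' glance(rep)
#' @export
equilibrium_report <- function(params) {
  stopifnot(is_wolb_params(params))
  gg <- next_generation_numbers(params)
  R0 <- basic_reproductive_number(params)
  dfe <- disease_free_equilibrium(params)
  cie <- if (params$v_w >= 1 && gg[["G0w"]] > 1) {
    complete_infection_equilibrium(params)
  } else NULL
  roots <- endemic_ratio(params)
  ee <- lapply(roots$rwu, function(r) endemic_equilibrium(params, r))
  states <- c(list(dfe = dfe),
              if (!is.null(cie)) list(cie = cie),
              stats::setNames(ee, paste0("ee", seq_along(ee))))
  stability <- lapply(states, function(s) classify_equilibrium(params, s))
  structure(
    list(
      params = params,
      G0u = gg[["G0u"]], G0w = gg[["G0w"]], R0 = R0,
      dfe = dfe, cie = cie, rwu = roots, ee = ee,
      threshold_female_fraction = threshold_female_fraction(params),
      stability = stability
    ),
    class = "wolb_equilibria"
  )
}

#' @export
print.wolb_equilibria <- function(x, ...) {
  cat("<wolb_equilibria>\n")
  cat(sprintf("  G0u = %.4f, G0w = %.4f, R0 = %.4f\n", x$G0u, x$G0w, x$R0))
  if (!is.na(x$threshold_female_fraction)) {
    cat(sprintf("  threshold female infection fraction = %.4f\n",
                x$threshold_female_fraction))
  }
  for (nm in names(x$stability)) {
    cat(sprintf("  %-4s: %s (max Re eigenvalue = %.3g)\n", nm,
                x$stability[[nm]]$classification,
                x$stability[[nm]]$max_real_part))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the equilibria of a report
#'
#' @param x A `wolb_equilibria` object.
#' @param ... Unused.
#' @return A tibble with one row per (equilibrium, compartment) pair plus
#'   per-equilibrium stability labels.
#' @export
tidy.wolb_equilibria <- function(x, ...) {
  states <- c(list(dfe = x$dfe),
              if (!is.null(x$cie)) list(cie = x$cie),
              stats::setNames(x$ee, paste0("ee", seq_along(x$ee))))
  purrr::map_dfr(names(states), function(nm) {
    tibble::tibble(
      equilibrium = nm,
      compartment = state_names,
      abundance = as.numeric(states[[nm]][state_names]),
      stability = x$stability[[nm]]$classification
    )
  })
}

#' One-row scalar summary of an equilibrium report
#'
#' @param x A `wolb_equilibria` object.
#' @param ... Unused.
#' @return A one-row tibble with `G0u`, `G0w`, `R0`, the threshold female
#'   fraction, and the number of coexistence states.
#' @export
glance.wolb_equilibria <- function(x, ...) {
  tibble::tibble(
    G0u = x$G0u, G0w = x$G0w, R0 = x$R0,
    threshold_female_fraction = x$threshold_female_fraction,
    n_endemic = length(x$ee)
  )
}
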