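#' Jacobian of the model right-hand side
#'
#' Analytic 8x8 matrix of partial derivatives at a state, in compartment
#' order `Mu, Mw, Fu, Fw, Eu, Ew, Lu, Lw`. The only nonlinearities are the
#' male-mixing fractions in the uninfected-egg birth term and the logistic
#' crowding factor in the larval inflow. A central finite-difference
#' approximation is available via `method = "numeric"` as a cross-check.
#'
#' @param params A [wolb_params()] object.
#' @param state A [wolb_state()] vector.
#' @param method `"analytic"` (default) or `"numeric"` (central differences
#'   with a relative step of `1e-6` of the state scale).
#' @return An 8x8 matrix with dimnames set to the compartment names.
#' @export
wolb_jacobian <- function(params, state, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  y <- as.numeric(state[state_names])
  if (method == "numeric") {
    scale <- max(abs(y), params$K_l * 1e-3)
    h <- 1e-6 * scale
    J <- matrix(0, 8, 8)
    for (j in 1:8) {
      yp <- y; ym <- y
      yp[j] <- yp[j] + h
      # central differences even at the boundary: the rhs is an algebraic
      # expression that tolerates slightly negative compartments
      ym[j] <- ym[j] - h
      J[, j] <- (rhs_core(0, yp, params) - rhs_core(0, ym, params)) /
        (2 * h)
    }
    dimnames(J) <- list(state_names, state_names)
    return(J)
  }

  Mu <- y[1]; Mw <- y[2]; Fu <- y[3]; Fw <- y[4]
  Eu <- y[5]; Ew <- y[6]; Lu <- y[7]; Lw <- y[8]
  J <- matrix(0, 8, 8, dimnames = list(state_names, state_names))
  b_m <- 1 - params$b_f
  with(params, {
    K <- 1 - (Lu + Lw) / K_l
    total_m <- Mu + Mw
    if (total_m > 0) {
      g <- (Mu + (1 - c_i) * Mw) / total_m
      dg_dMu <- c_i * Mw / total_m^2
      dg_dMw <- -c_i * Mu / total_m^2
    } else {
      g <- 1; dg_dMu <- 0; dg_dMw <- 0
    }
    J["Mu", "Lu"] <- b_m * psi;  J["Mu", "Mu"] <- -mu_mu
    J["Mw", "Lw"] <- b_m * psi;  J["Mw", "Mw"] <- -mu_mw
    J["Fu", "Lu"] <- b_f * psi;  J["Fu", "Fu"] <- -mu_fu
    J["Fw", "Lw"] <- b_f * psi;  J["Fw", "Fw"] <- -mu_fw
    J["Eu", "Mu"] <- phi_u * Fu * dg_dMu
    J["Eu", "Mw"] <- phi_u * Fu * dg_dMw
    J["Eu", "Fu"] <- phi_u * g
    J["Eu", "Fw"] <- (1 - v_w) * phi_w
    J["Eu", "Eu"] <- -(delta + mu_eu)
    J["Ew", "Fw"] <- v_w * phi_w
    J["Ew", "Ew"] <- -(delta + mu_ew)
    J["Lu", "Eu"] <- delta * K
    J["Lu", "Lu"] <- -delta * Eu / K_l - (psi + mu_l)
    J["Lu", "Lw"] <- -delta * Eu / K_l
    J["Lw", "Ew"] <- delta * K
    J["Lw", "Lw"] <- -delta * Ew / K_l - (psi + mu_l)
    J["Lw", "Lu"] <- -delta * Ew / K_l
    J
  })
}

#' Eigenvalue-based stability classification of an equilibrium
#'
#' Computes the eigenvalues of the Jacobian at a (near-)equilibrium state
#' and classifies it as `"stable"` (all real parts below `-tol`),
#' `"unstable"` (some real part above `tol`), or `"marginal"` when the
#' leading real part lies inside the tolerance band. A marginal verdict is
#' reported honestly rather than rounded to stable, since eigenvalues cross
#' zero exactly at bifurcation points.
#'
#' @param params A [wolb_params()] object.
#' @param state A [wolb_state()] vector; must satisfy the equilibrium
#'   residual check unless `check = FALSE`.
#' @param tol Stability tolerance on the leading real part.
#' @param check Verify that `state` is an equilibrium (relative residual
#'   below `1e-6`).
#' @return A list with `eigenvalues` (8 complex numbers sorted by
#'   decreasing real part), `max_real_part` and `classification`.
#' @export
classify_equilibrium <- function(params, state, tol = 1e-9, check = TRUE) {
  y <- as.numeric(state[state_names])
  if (check) {
    resid <- rhs_core(0, y, params)
    scale <- max(abs(y), 1)
    if (max(abs(resid)) > 1e-6 * scale) {
      stop("state is not an equilibrium (relative residual ",
           signif(max(abs(resid)) / scale, 3), ")", call. = FALSE)
    }
  }
  ev <- eigen(wolb_jacobian(params, state), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  mrp <- max(Re(ev))
  cls <- if (mrp < -tol) "stable" else if (mrp > tol) "unstable" else "marginal"
  list(eigenvalues = ev, max_real_part = mrp, classification = cls)
}

#' Mixed initial state with a natural distribution of infection
#'
#' Componentwise convex combination `(1 - p) * DFE + p * CIE`. At this state
#' the infected fraction equals `p` in every stage simultaneously (up to the
#' lifespan weighting of the stage totals), which is the construction that
#' makes "p percent infection, naturally distributed" well defined across
#' all compartments.
#'
#' @param params A [wolb_params()] object with `v_w = 1`.
#' @param p Infection level in `[0, 1]`.
#' @return A [wolb_state()] vector.
#' @export
mixed_state <- function(params, p) {
  stopifnot(p >= 0, p <= 1)
  dfe <- disease_free_equilibrium(params)
  cie <- complete_infection_equilibrium(params)
  (1 - p) * dfe + p * cie
}

#' Basin-boundary infection level by ODE bisection
#'
#' Independent dynamical check of [threshold_female_fraction()] that never
#' touches the closed-form equilibrium algebra. The mixing level `p` of
#' [mixed_state()] is bisected until the long-run outcome flips between
#' extinction and fixation; the basin boundary (the separatrix) is the
#' stable manifold of the unstable coexistence equilibrium, so the
#' near-boundary trajectory rides the separatrix and stalls at that
#' equilibrium before committing to either stable state. The returned value
#' is the female infected fraction at the stall point -- the time of
#' minimal relative motion among trajectory points at least 5% away from
#' both stable equilibria.
#'
#' @param params A [wolb_params()] object with `v_w = 1` and `0 < R0 < 1`.
#' @param tol_p Bisection resolution on the mixing level; must be tight so
#'   that the midpoint trajectory tracks the separatrix long enough to
#'   stall.
#' @param t_end Horizon used to classify the outcome (days).
#' @param rtol,atol Integrator tolerances (tighter than the package default
#'   because the bisection resolves mixing differences near `tol_p`).
#' @return The female infected fraction at the basin boundary.
#' @export
basin_threshold_fraction <- function(params, tol_p = 1e-9, t_end = 4000,
                                     rtol = 1e-10, atol = 1e-8) {
  lo <- 0; hi <- 1
  outcome <- function(p) {
    init <- mixed_state(params, p)
    traj <- simulate_invasion(params, init, t_end = t_end, dt = t_end / 100,
                              rtol = rtol, atol = atol)
    female_infection_fraction(final_state(traj)) > 0.5
  }
  if (outcome(lo) || !outcome(hi)) {
    stop("bisection bracket invalid: system is not bistable here",
         call. = FALSE)
  }
  while (hi - lo > tol_p) {
    mid <- (lo + hi) / 2
    if (outcome(mid)) hi <- mid else lo <- mid
  }
  boundary <- simulate_invasion(params, mixed_state(params, (lo + hi) / 2),
                                t_end = 2500, dt = 5,
                                rtol = rtol, atol = atol)
  dfe <- disease_free_equilibrium(params)
  cie <- complete_infection_equilibrium(params)
  M <- as.matrix(boundary[, state_names])
  reldist <- function(ref) {
    apply(M, 1, function(s) max(abs(s - ref)) / max(ref))
  }
  far <- reldist(dfe) > 0.05 & reldist(cie) > 0.05
  if (!any(far)) {
    stop("boundary trajectory never separated from the stable equilibria; ",
         "tighten tol_p", call. = FALSE)
  }
  speed <- vapply(seq_len(nrow(M)), function(i) {
    max(abs(rhs_core(0, M[i, ], params))) / max(M[i, ])
  }, numeric(1))
  idx <- which(far)
  boundary$frac_female[idx[which.min(speed[idx])]]
}

#' Bifurcation scan over the wild egg-laying rate
#'
#' Traces the backward-bifurcation diagram: for each value of `phi_u` on a
#' grid the scan records `R0`, the stable branches (female infected
#' fraction 0 at the disease-free state and 1 at the complete-infection
#' state) with their stability, and where `0 < R0 < 1` the unstable
#' interior branch at the threshold fraction. Scanning `phi_u` moves `R0`
#' inversely (`R0` is proportional to `1/phi_u`) while leaving the infected
#' cohort's parameters untouched.
#'
#' @param params A [wolb_params()] object with `v_w = 1` (the diagram is
#'   drawn under perfect maternal transmission).
#' @param phi_u_grid Grid of wild egg-laying rates; the default is 60
#'   log-spaced points spanning `R0` from roughly 0.3 to 1.5.
#' @return A tibble with columns `phi_u`, `R0`, `dfe_fraction`,
#'   `dfe_stability`, `cie_fraction`, `cie_stability`,
#'   `threshold_fraction` (NA where the interior branch does not exist)
#'   and `threshold_exists`.
#' @export
bifurcation_scan <- function(params, phi_u_grid = NULL) {
  stopifnot(is_wolb_params(params))
  if (is.null(phi_u_grid)) {
    R0_base <- basic_reproductive_number(params)
    # R0 scales as 1/phi_u, so the grid endpoints map R0 onto [0.3, 1.5]
    phi_u_grid <- exp(seq(log(params$phi_u * R0_base / 1.5),
                          log(params$phi_u * R0_base / 0.3),
                          length.out = 60))
  }
  purrr::map_dfr(phi_u_grid, function(phi) {
    p <- update_params(params, phi_u = phi)
    gg <- next_generation_numbers(p)
    R0 <- basic_reproductive_number(p)
    dfe_ok <- gg[["G0u"]] > 1
    dfe_stab <- if (!dfe_ok) NA_character_
      else classify_equilibrium(p, disease_free_equilibrium(p))$classification
    cie_ok <- p$v_w >= 1 && gg[["G0w"]] > 1
    cie_stab <- if (!cie_ok) NA_character_
      else classify_equilibrium(p, complete_infection_equilibrium(p))$classification
    thr <- if (R0 > 0 && R0 < 1 && gg[["G0w"]] > 1) {
      threshold_female_fraction(p)
    } else NA_real_
    tibble::tibble(
      phi_u = phi, R0 = R0,
      dfe_fraction = 0, dfe_stability = dfe_stab,
      cie_fraction = 1, cie_stability = cie_stab,
      threshold_fraction = thr,
      threshold_exists = !is.na(thr)
    )
  })
}
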