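# literal transcription of the eight equations as printed for complete CI
# (c_i = 1), used as an independent oracle for the generalized rhs
literal_rhs_ci1 <- function(state, p) {
  m_u <- if (state[["Mu"]] + state[["Mw"]] > 0) {
    state[["Mu"]] / (state[["Mu"]] + state[["Mw"]])
  } else 1
  K <- 1 - (state[["Lu"]] + state[["Lw"]]) / p$K_l
  v_u <- 1 - p$v_w
  c(
    Mu = (1 - p$b_f) * p$psi * state[["Lu"]] - p$mu_mu * state[["Mu"]],
    Mw = (1 - p$b_f) * p$psi * state[["Lw"]] - p$mu_mw * state[["Mw"]],
    Fu = p$b_f * p$psi * state[["Lu"]] - p$mu_fu * state[["Fu"]],
    Fw = p$b_f * p$psi * state[["Lw"]] - p$mu_fw * state[["Fw"]],
    Eu = p$phi_u * m_u * state[["Fu"]] + p$phi_w * v_u * state[["Fw"]] -
      (p$delta + p$mu_eu) * state[["Eu"]],
    Ew = p$v_w * p$phi_w * state[["Fw"]] -
      (p$delta + p$mu_ew) * state[["Ew"]],
    Lu = p$delta * K * state[["Eu"]] - (p$psi + p$mu_l) * state[["Lu"]],
    Lw = p$delta * K * state[["Ew"]] - (p$psi + p$mu_l) * state[["Lw"]]
  )
}

random_state <- function(p, seed) {
  withr::with_seed(seed, {
    y <- stats::runif(8, 0, 1e5)
    larv <- stats::runif(2, 0, p$K_l / 2)
    wolb_state(Mu = y[1], Mw = y[2], Fu = y[3], Fw = y[4],
               Eu = y[5], Ew = y[6], Lu = larv[1], Lw = larv[2])
  })
}

test_that("derived fractions: symmetry, degenerate males, saturation", {
  p <- baseline
  d <- derived_fractions(wolb_state(Mu = 100, Mw = 100, Lu = p$K_l / 2), p)
  expect_equal(d$male_infected_fraction, 0.5)
  expect_equal(d$K, 0.5)

  d <- derived_fractions(wolb_state(Mu = 50), p)
  expect_equal(d$male_infected_fraction, 0)
  expect_equal(d$male_uninfected_fraction, 1)

  d <- derived_fractions(wolb_state(Lu = p$K_l), p)
  expect_equal(d$K, 0)
  # no males at all: convention m_w = 0
  expect_equal(derived_fractions(wolb_state(), p)$male_infected_fraction, 0)
})

test_that("rhs matches the literal complete-CI transcription exactly", {
  for (seed in 1:5) {
    s <- random_state(baseline, seed)
    expect_identical(wolb_rhs(0, s, baseline), literal_rhs_ci1(s, baseline))
  }
})

test_that("CI fraction generalizes the uninfected-egg birth term", {
  p0 <- update_params(baseline, c_i = 0)
  # all males infected but no CI: wild females still lay at phi_u
  s <- wolb_state(Mw = 500, Fu = 120)
  expect_equal(wolb_rhs(0, s, p0)[["Eu"]], p0$phi_u * 120)
  # complete CI and only infected males: no viable uninfected eggs
  expect_equal(wolb_rhs(0, s, baseline)[["Eu"]], 0)
  # intermediate CI interpolates linearly in c_i at fixed mixing
  s2 <- wolb_state(Mu = 300, Mw = 100, Fu = 80)
  for (ci in c(0.25, 0.5, 0.9)) {
    pc <- update_params(baseline, c_i = ci)
    expect_equal(wolb_rhs(0, s2, pc)[["Eu"]],
                 baseline$phi_u * (0.75 + (1 - ci) * 0.25) * 80)
  }
})

test_that("rhs vanishes at the disease-free equilibrium", {
  dfe <- disease_free_equilibrium(baseline)
  expect_lt(rhs_residual_rel(baseline, dfe), 1e-8)
})

test_that("rhs rejects non-finite states", {
  s <- disease_free_equilibrium(baseline)
  s[["Fu"]] <- NaN
  expect_error(wolb_rhs(0, s, baseline), "non-finite")
})

test_that("equilibria are fixed points of the integrator", {
  dfe <- disease_free_equilibrium(baseline)
  traj <- simulate_invasion(baseline, dfe, t_end = 1000, dt = 10)
  expect_lt(max(abs(final_state(traj) - dfe)) / max(dfe), 1e-6)

  cie <- complete_infection_equilibrium(baseline)
  traj <- simulate_invasion(baseline, cie, t_end = 1000, dt = 10)
  expect_lt(max(abs(final_state(traj) - cie)) / max(cie), 1e-6)
})

test_that("a single infected female dies out at baseline (R0 < 1)", {
  init <- disease_free_equilibrium(baseline)
  init[["Fw"]] <- 1
  traj <- simulate_invasion(baseline, init, t_end = 2000, dt = 10)
  expect_lt(female_infection_fraction(final_state(traj)), 1e-6)
})

test_that("piecewise integration equals one-shot integration", {
  init <- mixed_state(baseline, 0.2)
  one <- simulate_invasion(baseline, init, t_end = 200, dt = 1)
  half <- simulate_invasion(baseline, init, t_end = 100, dt = 1)
  rest <- simulate_invasion(baseline, final_state(half), t_end = 200,
                            t0 = 100, dt = 1)
  expect_equal(final_state(rest), final_state(one), tolerance = 1e-6)
})

test_that("compartments stay nonnegative over long horizons", {
  inits <- list(
    mixed_state(baseline, 0.05),
    mixed_state(baseline, 0.9),
    wolb_state(Mu = 10, Fu = 10, Fw = 5, Mw = 5)
  )
  for (init in inits) {
    # absolute tolerance scaled to the population so that the integrator
    # noise floor sits below the nonnegativity band being asserted
    traj <- simulate_invasion(baseline, init, t_end = 1e4, dt = 50,
                              atol = 1e-10 * max(abs(init), 1))
    lows <- vapply(c("Mu", "Mw", "Fu", "Fw", "Eu", "Ew", "Lu", "Lw"),
                   function(nm) min(traj[[nm]]), numeric(1))
    expect_gt(min(lows), -1e-9 * max(abs(init), 1))
  }
})

test_that("infection fraction metrics and empty-population conventions", {
  s <- wolb_state(Fu = 30, Fw = 30, Mu = 100, Mw = 20)
  expect_equal(female_infection_fraction(s), 0.5)
  expect_equal(adult_infection_fraction(s), 50 / 180)
  expect_equal(female_infection_fraction(wolb_state()), 0)
  expect_equal(adult_infection_fraction(wolb_state()), 0)
  cie <- complete_infection_equilibrium(baseline)
  expect_equal(female_infection_fraction(cie), 1)
})

test_that("release impulses are exact stop-add-restart additions", {
  dfe <- disease_free_equilibrium(baseline)
  imp <- data.frame(time = 50, Fw = 1000, Mw = 2000)
  traj <- simulate_invasion(baseline, dfe, t_end = 60, impulses = imp, dt = 0.5)
  before <- traj[traj$t == 49.5, ]
  # half a day after the impulse the additions are present, reduced only
  # by adult mortality (about 3% for females, 7% for males)
  after <- traj[traj$t == 50.5, ]
  expect_lt(before$Fw, 1)
  expect_gt(after$Fw, 1000 * exp(-baseline$mu_fw * 0.5) - 1)
  expect_gt(after$Mw, 2000 * exp(-baseline$mu_mw * 0.5) - 1)
  # day-0 impulses are folded into the initial state
  traj0 <- simulate_invasion(baseline, dfe, t_end = 10,
                             impulses = data.frame(time = 0, Fw = 500, Mw = 0))
  expect_equal(traj0$Fw[1], 500)
})
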