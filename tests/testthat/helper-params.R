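baseline <- wolb_params()

# random parameter draws over field-plausible ranges; v_w = 1 and c_i = 1
# (the wAlbB assumptions) unless overridden
random_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      mu_m <- stats::runif(1, 0.08, 0.2)
      wolb_params(
        delta = stats::runif(1, 0.15, 0.5),
        psi = stats::runif(1, 0.03, 0.1),
        mu_fu = stats::runif(1, 0.05, 0.12),
        mu_fw = stats::runif(1, 0.05, 0.12),
        mu_mu = mu_m, mu_mw = mu_m,
        mu_eu = stats::runif(1, 0.05, 0.3),
        mu_ew = stats::runif(1, 0.05, 0.4),
        mu_l = stats::runif(1, 0.005, 0.04),
        phi_u = stats::runif(1, 1.5, 6),
        phi_w = stats::runif(1, 1.5, 6),
        K_l = 2e5
      )
    })
  })
}

rhs_residual_rel <- function(params, state) {
  max(abs(wolb_rhs(0, state, params))) / max(abs(state), 1)
}
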