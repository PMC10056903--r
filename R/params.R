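#' Model parameters for the Wolbachia invasion model
#'
#' Constructs and validates the full parameter set of the two-sex,
#' stage-structured mosquito model. Defaults are the baseline estimates for
#' *Anopheles* mosquitoes carrying the *wAlbB* strain: a lab-derived lifetime
#' fecundity of about 50 eggs per female spread over the adult lifespan,
#' reduced egg survivorship in the infected cohort, perfect maternal
#' transmission and complete cytoplasmic incompatibility (CI).
#'
#' All rates are per day. The model compartments are adult males (`Mu`,
#' `Mw`), adult females (`Fu`, `Fw`), eggs (`Eu`, `Ew`) and combined
#' larvae/pupae (`Lu`, `Lw`), with `u`/`w` marking the uninfected and
#' *Wolbachia*-infected cohorts.
#'
#' @param delta Egg hatching rate (1/mean days to hatch).
#' @param psi Larval emergence rate (1/mean days from first instar to adult).
#' @param mu_fu,mu_fw Death rates of uninfected / infected adult females.
#' @param mu_mu,mu_mw Death rates of uninfected / infected adult males.
#' @param mu_eu,mu_ew Death rates of uninfected / infected eggs.
#' @param mu_l Death rate of larvae/pupae.
#' @param phi_u,phi_w Per-capita egg-laying rates of uninfected / infected
#'   females (eggs per female per day).
#' @param v_w Maternal transmission fraction: the proportion of an infected
#'   female's eggs that inherit the infection (`v_u = 1 - v_w`).
#' @param c_i Cytoplasmic incompatibility fraction: the proportion of
#'   uninfected females mated to infected males whose eggs are nonviable.
#' @param b_f Fraction of emerging adults that are female (`b_m = 1 - b_f`).
#' @param K_l Carrying capacity of the combined larval/pupal stage (count).
#'
#' @return A named list of class `wolb_params`.
#' @examples
#' p <- wolb_params()
#' basic_reproductive_number(p)
#' @export
wolb_params <- function(delta = 1 / 3,
                        psi = 1 / 18,
                        mu_fu = 1 / 13,
                        mu_fw = 1 / 15,
                        mu_mu = 1 / 7,
                        mu_mw = 1 / 7,
                        mu_eu = 0.12,
                        mu_ew = 0.33,
                        mu_l = 0.01,
                        phi_u = 3.8,
                        phi_w = 3.3,
                        v_w = 1,
                        c_i = 1,
                        b_f = 0.5,
                        K_l = 2e5) {
  p <- list(
    delta = delta, psi = psi,
    mu_fu = mu_fu, mu_fw = mu_fw, mu_mu = mu_mu, mu_mw = mu_mw,
    mu_eu = mu_eu, mu_ew = mu_ew, mu_l = mu_l,
    phi_u = phi_u, phi_w = phi_w,
    v_w = v_w, c_i = c_i, b_f = b_f, K_l = K_l
  )
  validate_params(p)
  structure(p, class = "wolb_params")
}

#' @rdname wolb_params
#' @param x Object to test or print.
#' @export
is_wolb_params <- function(x) inherits(x, "wolb_params")

rate_names <- c(
  "delta", "psi", "mu_fu", "mu_fw", "mu_mu", "mu_mw",
  "mu_eu", "mu_ew", "mu_l", "phi_u", "phi_w"
)
fraction_names <- c("v_w", "c_i", "b_f")
param_names <- c(rate_names, fraction_names, "K_l")

validate_params <- function(p) {
  stopifnot(is.list(p))
  missing <- setdiff(param_names, names(p))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in param_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  # egg-laying rates may be scanned down to 0; death/transition rates must
  # stay strictly positive for the lifetime algebra to make sense
  for (nm in setdiff(rate_names, c("phi_u", "phi_w"))) {
    if (p[[nm]] <= 0) stop("rate '", nm, "' must be > 0", call. = FALSE)
  }
  for (nm in c("phi_u", "phi_w")) {
    if (p[[nm]] < 0) stop("rate '", nm, "' must be >= 0", call. = FALSE)
  }
  for (nm in fraction_names) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("fraction '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$K_l <= 0) stop("carrying capacity 'K_l' must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.wolb_params <- function(x, ...) {
  cat("<wolb_params>\n")
  df <- tibble::tibble(
    parameter = param_names,
    value = vapply(param_names, function(nm) x[[nm]], numeric(1))
  )
  print(df, n = Inf)
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named parameters replaced and the
#' result re-validated. Convenient for sensitivity perturbations and
#' bifurcation scans.
#'
#' @param params A [wolb_params()] object.
#' @param ... Named parameter replacements, e.g. `phi_u = 4.2`.
#' @return A `wolb_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(is_wolb_params(params))
  repl <- list(...)
  unknown <- setdiff(names(repl), param_names)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_params(p)
  structure(p, class = "wolb_params")
}

#' Load a parameter/scenario configuration file
#'
#' Reads a flat key--value file (YAML syntax, no nesting required) of model
#' parameter overrides. Keys must be model parameter names or the integrator
#' settings `rtol` / `atol`; unknown keys are an error so that typos cannot
#' silently fall back to defaults. An empty file yields the full baseline
#' parameter set.
#'
#' @param path Path to the configuration file.
#' @param quiet If `FALSE`, echo every parameter with its source
#'   (default or override).
#' @return A list with elements `params` (a [wolb_params()] object),
#'   `rtol`, `atol`, and `overrides` (names of overridden keys).
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a flat key-value mapping",
                          call. = FALSE)
  # YAML 1.1 reads exponent forms like 1.0e5 (no sign) as strings;
  # coerce any numeric-looking scalar
  raw <- lapply(raw, function(v) {
    if (is.character(v) && length(v) == 1 &&
        !is.na(suppressWarnings(as.numeric(v)))) as.numeric(v) else v
  })
  known <- c(param_names, "rtol", "atol")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  overrides <- intersect(names(raw), param_names)
  params <- do.call(wolb_params, raw[overrides])
  rtol <- if (!is.null(raw$rtol)) raw$rtol else 1e-8
  atol <- if (!is.null(raw$atol)) raw$atol else 1e-6
  if (!quiet) {
    for (nm in param_names) {
      src <- if (nm %in% overrides) "override" else "default"
      message(sprintf("  %-6s = %-12g [%s]", nm, params[[nm]], src))
    }
    message(sprintf("  rtol = %g, atol = %g", rtol, atol))
  }
  list(params = params, rtol = rtol, atol = atol, overrides = overrides)
}
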