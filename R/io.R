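traj_columns <- c("t", "Mu", "Mw", "Fu", "Fw", "Eu", "Ew", "Lu", "Lw",
                  "frac_female", "frac_adult")

#' Write and read trajectory CSV files
#'
#' Trajectories are stored as tidy CSV with the fixed column order
#' `t, Mu, Mw, Fu, Fw, Eu, Ew, Lu, Lw, frac_female, frac_adult`.
#'
#' @param traj A `wolb_traj` tibble.
#' @param path Output file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(all(traj_columns %in% names(traj)))
  utils::write.csv(as.data.frame(traj)[, traj_columns], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write a JSON result report
#'
#' Serializes a result list together with the full parameter set that
#' produced it and a hash of that parameter echo, so any saved report can
#' be traced back to its exact configuration. Field order is
#' deterministic.
#'
#' @param results A named list of results (scalars, vectors, data frames).
#' @param params The [wolb_params()] object used.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, params, path) {
  stopifnot(is_wolb_params(params))
  echo <- lapply(stats::setNames(param_names, param_names),
                 function(nm) params[[nm]])
  hash <- digest_params(params)
  out <- c(list(params = echo, config_hash = hash), results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# deterministic short hash of the parameter echo (no external digest
# dependency: serialize to canonical text, then fold into hex)
digest_params <- function(params) {
  txt <- paste(vapply(param_names,
                      function(nm) sprintf("%s=%.17g", nm, params[[nm]]),
                      character(1)),
               collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
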