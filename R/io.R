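# File I/O: CSV dialects (comma-separated, header required, UTF-8, '.'
# decimal, units embedded in column names), YAML run configuration, and
# per-event loading-rate estimation from raw force-time segments.

.rip_csv_cols <- c(molecule_id = "molecule_id",
                   condition = "condition",
                   rip_force = "rip_force_pN",
                   loading_rate = "loading_rate_pN_s",
                   delta_extension = "delta_extension_nm",
                   trap_velocity = "trap_velocity_nm_s",
                   censored = "censored")

#' Write rupture events to CSV
#'
#' Columns: `molecule_id,condition,rip_force_pN,loading_rate_pN_s,`
#' `delta_extension_nm,trap_velocity_nm_s,censored`. Floats are written
#' with fixed 8-significant-digit formatting so output is deterministic.
#'
#' @param events A [rip_events()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rip_events <- function(events, path) {
  events <- rip_events(as.data.frame(events))
  out <- data.frame(
    molecule_id = if (is.null(events$molecule_id)) "" else
      events$molecule_id,
    condition = if (is.null(events$condition)) "" else events$condition,
    rip_force_pN = sprintf("%.8g", events$rip_force),
    loading_rate_pN_s = sprintf("%.8g", events$loading_rate),
    delta_extension_nm = if (is.null(events$delta_extension))
      "" else sprintf("%.8g", events$delta_extension),
    trap_velocity_nm_s = if (is.null(events$trap_velocity))
      "" else sprintf("%.8g", events$trap_velocity),
    censored = tolower(as.character(events$censored)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read rupture events from CSV
#'
#' Reads the dialect written by [write_rip_events()]. A missing or empty
#' `loading_rate_pN_s` column is permitted when `trap_velocity_nm_s` is
#' present and a trap `stiffness` is supplied; the loading rate is then
#' reconstructed as stiffness x velocity.
#'
#' @param path CSV file path.
#' @param stiffness Optional trap stiffness in pN/nm.
#' @return A [rip_events()] table.
#' @export
read_rip_events <- function(path, stiffness = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- .rip_csv_cols[["rip_force"]]
  if (!need %in% names(raw)) {
    stop("malformed rip CSV (", path, "): missing column ", need)
  }
  df <- data.frame(rip_force = as.numeric(raw$rip_force_pN))
  for (nm in c("molecule_id", "condition")) {
    if (!is.null(raw[[nm]])) df[[nm]] <- raw[[nm]]
  }
  lr <- raw[["loading_rate_pN_s"]]
  if (is.null(lr) || all(is.na(lr)) || all(lr == "")) {
    if (is.null(raw[["trap_velocity_nm_s"]]) || is.null(stiffness)) {
      stop("no loading rate in ", path,
           " and no trap_velocity + stiffness to reconstruct it")
    }
    df$loading_rate <- stiffness * as.numeric(raw$trap_velocity_nm_s)
  } else {
    df$loading_rate <- as.numeric(lr)
  }
  if (!is.null(raw[["delta_extension_nm"]])) {
    df$delta_extension <- as.numeric(raw$delta_extension_nm)
  }
  if (!is.null(raw[["trap_velocity_nm_s"]])) {
    df$trap_velocity <- as.numeric(raw$trap_velocity_nm_s)
  }
  df$censored <- if (is.null(raw$censored)) FALSE else
    as.logical(toupper(as.character(raw$censored)))
  bad <- which(!is.finite(df$rip_force) | !is.finite(df$loading_rate))
  if (length(bad)) {
    stop("malformed rip CSV (", path, "): non-numeric force or loading ",
         "rate at data line(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  rip_events(df)
}

#' Write a luminescence trace to CSV with a YAML sidecar
#'
#' The CSV holds `time_s,rlu`; the sidecar (`<path>.yaml`) holds
#' `t_dtt_s`, `condition` and `replicate_id`.
#'
#' @param trace A [luminescence_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "luminescence_trace"))
  out <- data.frame(time_s = sprintf("%.8g", trace$time),
                    rlu = sprintf("%.8g", trace$rlu))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  yaml::write_yaml(list(t_dtt_s = trace$t_dtt,
                        condition = trace$condition,
                        replicate_id = trace$replicate_id),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a luminescence trace from CSV (+ optional YAML sidecar)
#'
#' @param path CSV path with columns `time_s,rlu`.
#' @param meta Optional path to the YAML sidecar; defaults to
#'   `<path>.yaml` when that file exists.
#' @return A [luminescence_trace()].
#' @export
read_trace <- function(path, meta = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("time_s", "rlu") %in% names(raw))) {
    stop("malformed trace CSV (", path, "): need columns time_s, rlu")
  }
  if (is.null(meta) && file.exists(paste0(path, ".yaml"))) {
    meta <- paste0(path, ".yaml")
  }
  md <- if (is.null(meta)) list() else yaml::read_yaml(meta)
  luminescence_trace(time = as.numeric(raw$time_s),
                     rlu = as.numeric(raw$rlu),
                     t_dtt = md$t_dtt_s %||% 0,
                     condition = md$condition %||% "unknown",
                     replicate_id = md$replicate_id %||% "r1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_defaults <- function() {
  list(thermal_energy = KBT_ROOM,
       nu = 2 / 3,
       polymer = list(persistence_length = 0.65,
                      contour_per_residue = 0.36,
                      native_end_to_end = 1.6),
       fit = list(n_bootstrap = 200L, seed = 1L,
                  lower = list(log10_tau0 = 0, dx_ddagger = 0.05,
                               dG_ddagger = 1),
                  upper = list(log10_tau0 = 12, dx_ddagger = 10,
                               dG_ddagger = 50)))
}

#' Assemble a validated run configuration
#'
#' Merges user settings over the package defaults; unknown keys at either
#' level are rejected with a message naming them.
#'
#' @param ... Named settings among `thermal_energy`, `nu`, `polymer`
#'   (list), `fit` (list).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  defaults <- .config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      sub_unknown <- setdiff(names(user[[nm]]), names(defaults[[nm]]))
      if (length(sub_unknown)) {
        stop("unknown configuration key(s) under '", nm, "': ",
             paste(sub_unknown, collapse = ", "))
      }
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  stopifnot(cfg$thermal_energy > 0)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Save a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Estimate the loading rate from a force-time segment
#'
#' Least-squares slope of force against time over the trailing window
#' ending at the rupture, i.e. the local ramp steepness the molecule
#' experienced just before unfolding.
#'
#' @param time Time stamps in s.
#' @param force Forces in pN, same length.
#' @param window Window length in s before the last sample. Default 1.
#' @return List with `loading_rate` (pN/s), `residual_sd` (pN), `n`
#'   (points used), and `flagged` (TRUE for a non-positive slope).
#' @export
estimate_loading_rate <- function(time, force, window = 1) {
  stopifnot(length(time) == length(force))
  sel <- time >= max(time) - window
  if (sum(sel) < 5) stop("need at least 5 samples in the trailing window")
  fit <- stats::lm(force[sel] ~ time[sel])
  slope <- unname(stats::coef(fit)[2])
  flagged <- slope <= 0
  if (flagged) warning("non-positive loading-rate slope")
  list(loading_rate = slope,
       residual_sd = stats::sd(stats::residuals(fit)),
       n = sum(sel), flagged = flagged)
}
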