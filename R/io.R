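# delimited-text interchange: TSV with named, unit-suffixed headers.
# times are hours, concentrations uM (monomer basis), intensities a.u.

read_tsv_checked <- function(path, required) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- tryCatch(read.delim(path, sep = "\t", check.names = FALSE),
                 error = function(e) stop_kaicdyn(
                   sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                   "kaicdyn_parse_error"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_kaicdyn(sprintf("%s: missing column(s) %s", path,
                         paste(missing, collapse = ", ")),
                 "kaicdyn_format_error")
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop_kaicdyn(sprintf("%s: column '%s' has a non-numeric or missing value (row %d)",
                           path, col, ifelse(is.na(bad), 1L, bad)),
                   "kaicdyn_format_error")
    }
  }
  df
}

check_time_column <- function(df, path) {
  t <- df$time_h
  if (any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1] + 1L
    stop_kaicdyn(sprintf("%s: time_h not strictly increasing at row %d", path, i),
                 "kaicdyn_format_error")
  }
  t
}

#' Read / write phosphoform abundance tables
#'
#' TSV with columns `time_h` and the four states in canonical order
#' (`S_pT`, `pS_pT`, `pS_T`, `S_T`).
#'
#' @param path File path.
#' @param tol Row-sum tolerance for measured/noisy abundances (default
#'   1e-6).
#' @return For `read_abundances`, a [phospho_abundances()]; for
#'   `write_abundances`, `path` invisibly.
#' @export
read_abundances <- function(path, tol = 1e-6) {
  df <- read_tsv_checked(path, c("time_h", phospho_state_cols()))
  t <- check_time_column(df, path)
  phospho_abundances(t, as.matrix(df[, phospho_state_cols()]), tol = tol)
}

#' @rdname read_abundances
#' @param ab A [phospho_abundances()] object.
#' @export
write_abundances <- function(ab, path) {
  df <- data.frame(time_h = ab$times, ab$A, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write fluorescence time courses
#'
#' TSV with columns `time_h` and `fi_app`.
#'
#' @param path File path.
#' @param variant,condition Metadata attached on read.
#' @return For `read_timecourse`, a [fluor_timecourse()]; for
#'   `write_timecourse`, `path` invisibly.
#' @export
read_timecourse <- function(path, variant = "WT",
                            condition = "auto-dephosphorylation, 30 degC") {
  df <- read_tsv_checked(path, c("time_h", "fi_app"))
  t <- check_time_column(df, path)
  fluor_timecourse(t, df$fi_app, variant = variant, condition = condition)
}

#' @rdname read_timecourse
#' @param tc A [fluor_timecourse()] object.
#' @export
write_timecourse <- function(tc, path) {
  write.table(data.frame(time_h = tc$times, fi_app = tc$fi_app),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write relaxation curves and titration profiles
#'
#' Relaxation curves are TSV with columns `time_h`, `fi_app`;
#' titration profiles are TSV with columns `kaib_uM`,
#' `inv_t_half_per_h`, `amplitude`.
#'
#' @param path File path.
#' @return For readers, the corresponding object; for writers, `path`
#'   invisibly.
#' @export
read_profile <- function(path) {
  df <- read_tsv_checked(path, c("kaib_uM", "inv_t_half_per_h", "amplitude"))
  as_kobs_profile(df$kaib_uM, df$inv_t_half_per_h, df$amplitude)
}

#' @rdname read_profile
#' @param profile A `kobs_profile` data frame.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(kaib_uM = profile$b_um,
                         inv_t_half_per_h = profile$inv_t_half,
                         amplitude = profile$amplitude),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_profile
#' @param curve A `relaxation_curve` (or list with `times`, `fi_app`).
#' @export
write_relaxation <- function(curve, path) {
  write.table(data.frame(time_h = curve$times, fi_app = curve$fi_app),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_profile
#' @export
read_relaxation <- function(path) {
  df <- read_tsv_checked(path, c("time_h", "fi_app"))
  t <- check_time_column(df, path)
  list(times = t, fi_app = df$fi_app)
}

#' Write / read a per-phosphoform intensity record (JSON)
#'
#' JSON record with fields `variant`, `fi` (4 values, canonical order),
#' `se`, `rss`, `n_replicates`.
#'
#' @param x A `state_intensities` object.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   `state_intensities` object.
#' @export
write_intensities <- function(x, path) {
  jsonlite::write_json(
    list(variant = x$variant, fi = as.numeric(x$fi), se = as.numeric(x$se),
         rss = x$rss, n_replicates = x$n_replicates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  state_intensities(as.numeric(rec$fi), as.numeric(rec$se), rec$rss,
                    rec$n_replicates, rec$variant)
}

# documented defaults for the run configuration; unknown keys are rejected
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    verbosity = 1L,
    binding = list(mode = "CS", k_cf = 0.5, k_cr = 0.05, k_on = 100,
                   k_off = 0.5, k_bf = 2, k_br = 2,
                   fi_free = 1, fi_bound = 0.2,
                   c_total = 3.5, b_grid = seq(0.9, 10.5, length.out = 5),
                   t_max = 18, dt = 5 / 60),
    dephospho = list(k1 = 0.55, k2 = 0.45, k3 = 0.30, k4 = 0,
                     initial = c(0.35, 0.45, 0.15, 0.05),
                     t_max = 20, dt = 1,
                     truth_fi = c(1.0, 2.5, 1.8, 0.7)),
    noise = list(fi_sigma = 0.01, densitometry_sigma = 0.01),
    structure = list(probe = 1.4, n_points = 960, include_het = FALSE)
  )
}

#' Read / write a run configuration (YAML)
#'
#' Configurations are YAML mappings over the documented defaults (see
#' `default_run_config()` in the sources); unknown keys are rejected,
#' known keys override defaults, and a written configuration reads back
#' to an identical object.
#'
#' @param path File path.
#' @return For the reader, the merged configuration list; for the
#'   writer, `path` invisibly.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  check_keys <- function(u, d, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop_kaicdyn(sprintf("unknown configuration key(s): %s",
                           paste0(prefix, unknown, collapse = ", ")),
                   "kaicdyn_config_error")
    for (k in names(u))
      if (is.list(d[[k]]) && !is.null(names(d[[k]])))
        check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
  }
  check_keys(user, defaults)
  merge <- function(d, u) {
    for (k in names(u))
      d[[k]] <- if (is.list(d[[k]]) && !is.null(names(d[[k]])))
        merge(d[[k]], u[[k]]) else u[[k]]
    d
  }
  merge(defaults, user)
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}
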