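#' Analysis configuration
#'
#' All tunable numeric defaults of the pipeline in one flat list.  The only
#' constant fixed by the method itself is `n_harmonics = 15`, the harmonic
#' cutoff of the filtered fourth pressure derivative; the rest are
#' implementation tolerances.
#'
#' @param n_harmonics harmonics kept by [fourier_truncate()] (default 15).
#' @param rr_tol relative RR deviation for beat exclusion (default 0.05).
#' @param v_floor_frac loop-point volume floor as a fraction of SV
#'   (default 0.02).
#' @param iso_ptol,iso_maxiter isovolumic optimiser settings.
#' @param iso_n_tpk,iso_n_C isovolumic profiled-grid resolution.
#' @param er_nq,er_nv elastance-resistance grid-search resolution.
#' @param er_factr L-BFGS-B `factr` for the elastance-resistance refinement.
#' @param fs default sampling rate for synthetic data, Hz.
#' @param flow_onset_frac measured-flow ejection window threshold as a
#'   fraction of peak flow.
#'
#' @return A named list of class `lv_config`.
#' @export
lv_config <- function(n_harmonics = 15L, rr_tol = 0.05, v_floor_frac = 0.02,
                      iso_ptol = 1e-8, iso_maxiter = 500L,
                      iso_n_tpk = 40L, iso_n_C = 21L,
                      er_nq = 24L, er_nv = 24L, er_factr = 10,
                      fs = 1000, flow_onset_frac = 0.02) {
  structure(
    list(n_harmonics = as.integer(n_harmonics), rr_tol = rr_tol,
         v_floor_frac = v_floor_frac, iso_ptol = iso_ptol,
         iso_maxiter = as.integer(iso_maxiter),
         iso_n_tpk = as.integer(iso_n_tpk), iso_n_C = as.integer(iso_n_C),
         er_nq = as.integer(er_nq), er_nv = as.integer(er_nv),
         er_factr = er_factr, fs = fs, flow_onset_frac = flow_onset_frac),
    class = "lv_config")
}

#' Write a configuration to a flat key = value text file
#'
#' @param config an [lv_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "lv_config"))
  lines <- vapply(names(config), function(nm)
    sprintf("%s = %s", nm, format(config[[nm]], digits = 17)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path path to a flat key = value file.
#' @return An [lv_config].
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(
    lapply(kv, function(x) as.numeric(x[2])),
    vapply(kv, `[[`, "", 1))
  bad <- setdiff(names(args), names(formals(lv_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(lv_config, args)
}
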