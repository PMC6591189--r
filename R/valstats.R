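#' Simple linear regression of one estimate on another
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination as the squared Pearson correlation and a two-sided t test
#' on the slope.  Used to correlate pressure-only (`triQ`) parameter
#' estimates with their measured-flow (`mQ`) counterparts.
#'
#' @param x,y numeric vectors (n >= 3, finite, `var(x) > 0`).
#' @return An object of class `lv_regression`: `slope`, `intercept`, `r2`,
#'   `n`, `p_slope`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0) stop("var(x) = 0: regression undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::var(y) == 0) 0 else stats::cor(x, y)^2
  sm <- suppressWarnings(summary(fit))$coefficients
  p_slope <- if (nrow(sm) < 2L || !is.finite(sm[2L, 4L])) 0 else sm[2L, 4L]
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r2 = r2, n = length(x), p_slope = p_slope),
            class = "lv_regression")
}

#' @export
print.lv_regression <- function(x, ...) {
  cat(sprintf("<lv_regression> y = %.4f + %.4f x (r2 = %.4f, n = %d, p = %.3g)\n",
              x$intercept, x$slope, x$r2, x$n, x$p_slope))
  invisible(x)
}

#' Bland-Altman agreement between two methods
#'
#' Differences `a - b` with their mean, sample standard deviation (n - 1
#' denominator) and 95% limits of agreement, mean difference +/- 1.96 SD.
#'
#' @param a,b numeric vectors of paired measurements (equal length, n >= 2).
#' @return An object of class `lv_agreement`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `diffs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch: ", length(a), " vs ",
                                   length(b))
  stopifnot(length(a) >= 2L, all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d), diffs = d),
            class = "lv_agreement")
}

#' @export
print.lv_agreement <- function(x, ...) {
  cat(sprintf("<lv_agreement> mean diff = %.4g, LoA [%.4g, %.4g] (n = %d)\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Validate the pressure-only pipeline against measured flow on a cohort
#'
#' Analyses every record of a synthetic cohort with the measured flow
#' attached, so that each beat yields both the measured-flow (`mQ`) and the
#' pressure-only triangular-flow (`triQ`) estimates, then regresses each
#' `triQ` parameter on its `mQ` counterpart and computes Bland-Altman
#' agreement — the comparison design of the method's validation.  Records
#' whose analysis fails are listed; the run aborts only when fewer than 80%
#' succeed.
#'
#' @param cohort a cohort list from [generate_cohort()], or a directory
#'   containing its CSV records and `truth.csv`.
#' @param config an [lv_config].
#' @param out optional path for a JSON report.
#' @return A report list: `n`, `n_ok`, `failed` (ids and messages),
#'   `estimates` (data frame of per-record `mQ`/`triQ` values), and per
#'   parameter (`Q_max`, `V_eed`, `E_max`) a `regression` and an
#'   `agreement` block, plus descriptive medians (and IQRs) per preset and
#'   the E_es-vs-E_max relative differences.
#' @export
run_validation <- function(cohort, config = lv_config(), out = NULL) {
  if (is.character(cohort)) {
    manifest <- utils::read.csv(file.path(cohort, "truth.csv"))
    beats <- lapply(manifest$id, function(id) {
      tr <- read_record(file.path(cohort, paste0(id, ".csv")))
      list(beat = pressure_beat(tr$p_lv), flow = tr$q_ao)
    })
    HRs <- manifest$HR; COs <- manifest$CO
  } else {
    manifest <- cohort$manifest
    beats <- lapply(cohort$beats, function(b)
      list(beat = b$beat, flow = b$flow))
    HRs <- manifest$HR; COs <- manifest$CO
  }
  n <- length(beats)
  rows <- vector("list", n)
  failed <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      an <- analyze_beat(beats[[i]]$beat, CO = COs[i], HR = HRs[i],
                         flow = beats[[i]]$flow, config = config)
      data.frame(id = manifest$id[i], preset = manifest$preset[i],
                 Q_max_mQ = an$results$mQ$er$Q_max,
                 Q_max_triQ = an$results$triQ$er$Q_max,
                 V_eed_mQ = an$results$mQ$er$V_eed,
                 V_eed_triQ = an$results$triQ$er$V_eed,
                 E_max_mQ = an$results$mQ$er$E_max,
                 E_max_triQ = an$results$triQ$er$E_max,
                 E_es_mQ = an$results$mQ$es$E_es,
                 E_es_triQ = an$results$triQ$es$E_es,
                 r2_mQ = an$results$mQ$er$r2,
                 r2_triQ = an$results$triQ$er$r2)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failed[[manifest$id[i]]] <- res
    else rows[[i]] <- res
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || nrow(est) < 0.8 * n)
    stop("validation failed on ", n - NROW(est), " of ", n, " records")

  per_param <- function(param) {
    xm <- est[[paste0(param, "_mQ")]]
    xt <- est[[paste0(param, "_triQ")]]
    list(regression = unclass(linear_regression(xm, xt)),
         agreement = unclass(bland_altman(xt, xm))[
           c("mean_diff", "sd_diff", "loa_low", "loa_high", "n")])
  }
  med_iqr <- function(v) {
    stats::aggregate(v, list(preset = est$preset), function(z)
      c(median = stats::median(z), IQR = stats::IQR(z)))
  }
  report <- list(
    schema_version = "1.0",
    n = n, n_ok = nrow(est), failed = failed,
    Q_max = per_param("Q_max"),
    V_eed = per_param("V_eed"),
    E_max = per_param("E_max"),
    es_vs_emax = list(
      median_rel_diff_mQ = stats::median(
        abs(est$E_es_mQ - est$E_max_mQ) / est$E_max_mQ),
      median_rel_diff_triQ = stats::median(
        abs(est$E_es_triQ - est$E_max_triQ) / est$E_max_triQ)),
    by_preset = list(E_max_triQ = med_iqr(est$E_max_triQ),
                     Q_max_triQ = med_iqr(est$Q_max_triQ)),
    estimates = est)
  if (!is.null(out)) {
    writeLines(jsonlite::toJSON(report[setdiff(names(report), "by_preset")],
                                auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = TRUE),
               out)
  }
  report
}
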