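# Per-excipient mean binding affinity and its linear relation to the
# melting temperature.

#' Mean binding affinity of a set of pose energies
#'
#' Arithmetic mean, reported at two decimals (half rounded away from
#' zero), the convention used for per-excipient average binding
#' affinities.
#'
#' @param e_values numeric vector of per-pose binding energies (kcal/mol).
#' @return mean energy rounded to 2 decimals.
#' @export
mean_binding <- function(e_values) {
  if (length(e_values) == 0L) stop("empty energy list", call. = FALSE)
  stopifnot(is.numeric(e_values), all(is.finite(e_values)))
  round_half_up(mean(e_values), 2)
}

#' Assemble per-excipient stability records
#'
#' Joins a per-pose energy table with a melting-temperature table and
#' computes each excipient's mean binding affinity.
#'
#' @param energies data.frame with columns `excipient` and `e_binding`.
#' @param tm data.frame with columns `excipient` and `tm_c`.
#' @param exclude character vector of excipients flagged as excluded from
#'   correlation (e.g. a negative control acting by a different
#'   mechanism).
#' @return data.frame (excipient, tm_c, n_poses, mean_e, excluded);
#'   excipients without both energies and a Tm are dropped.
#' @export
stability_records <- function(energies, tm, exclude = character(0)) {
  stopifnot(all(c("excipient", "e_binding") %in% names(energies)),
            all(c("excipient", "tm_c") %in% names(tm)))
  common <- intersect(unique(energies$excipient), tm$excipient)
  if (length(common) == 0L) {
    stop("no excipient appears in both the energy and Tm tables", call. = FALSE)
  }
  out <- do.call(rbind, lapply(common, function(x) {
    ev <- energies$e_binding[energies$excipient == x]
    data.frame(excipient = x,
               tm_c = tm$tm_c[match(x, tm$excipient)],
               n_poses = length(ev),
               mean_e = mean_binding(ev),
               excluded = x %in% exclude,
               stringsAsFactors = FALSE)
  }))
  out[order(out$excipient), , drop = FALSE]
}

#' Linear fit of melting temperature on mean binding affinity
#'
#' Ordinary least squares of Tm on mean binding energy over the
#' non-excluded records.
#'
#' @param records data.frame from [stability_records()] (columns `mean_e`,
#'   `tm_c`, optional logical `excluded`).
#' @return object of class `xd_correlation`: list with `slope`,
#'   `intercept`, `pearson_r`, `r_squared` (= pearson_r^2), `n_used`,
#'   `excluded` (names dropped from the fit).
#' @export
fit_linear <- function(records) {
  stopifnot(all(c("mean_e", "tm_c") %in% names(records)))
  excl <- if (!is.null(records$excluded)) records$excluded else
    rep(FALSE, nrow(records))
  use <- records[!excl, , drop = FALSE]
  if (nrow(use) < 2L) stop("need at least two non-excluded records", call. = FALSE)
  if (stats::sd(use$mean_e) == 0) {
    stop("zero variance in mean binding energies; fit undefined", call. = FALSE)
  }
  fit <- stats::lm(tm_c ~ mean_e, data = use)
  r <- stats::cor(use$mean_e, use$tm_c)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = r,
    r_squared = r^2,
    n_used = nrow(use),
    excluded = if (!is.null(records$excipient)) records$excipient[excl] else which(excl)
  ), class = "xd_correlation")
}

#' @export
print.xd_correlation <- function(x, ...) {
  cat(sprintf("Tm = %.3f + %.3f * E_mean  (r = %.3f, R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$pearson_r, x$r_squared, x$n_used))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bundled Fab A33 excipient reference data
#'
#' `fab_a33_binding_energies()` returns the per-pose binding affinities of
#' the commercial-excipient screen against Fab A33 (columns excipient,
#' pose, e_binding, hotspot); `fab_a33_tm()` returns the melting
#' temperatures measured for Fab A33 alone and with each excipient
#' (columns excipient, concentration, tm_c). Both ship as plain-text CSVs
#' with the package.
#'
#' @return data.frame.
#' @export
fab_a33_binding_energies <- function() {
  utils::read.csv(system.file("extdata", "fab_a33_hotspot_energies.csv",
                              package = "excidock"),
                  stringsAsFactors = FALSE)
}

#' @rdname fab_a33_binding_energies
#' @export
fab_a33_tm <- function() {
  utils::read.csv(system.file("extdata", "fab_a33_tm.csv",
                              package = "excidock"),
                  stringsAsFactors = FALSE)
}
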