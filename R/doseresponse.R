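## Dose-response computations used on the validation side: conversion of
## raw plate signal to percent activity, two-parameter log-logistic IC50
## fitting with fixed asymptotes (0% bottom, 100% top), and Cheng-Prusoff
## conversion of competition IC50 into an inhibition constant Ki.

#' Convert raw signal to percent activity
#'
#' `100 * (raw - low) / (high - low)`, with the high and low controls
#' defining 100% and 0%. Values outside `[0, 100]` are kept (not clipped);
#' the constrained asymptotes of the fit absorb them.
#'
#' @param raw Numeric vector of raw responses.
#' @param high_control,low_control Control signal scalars (must differ).
#' @return Percent vector.
#' @export
to_percent <- function(raw, high_control, low_control) {
  if (high_control == low_control) stop("controls must differ")
  100 * (raw - low_control) / (high_control - low_control)
}

## the 2-parameter log-logistic: bottom 0, top 100
.ll2 <- function(x, b, log_e) 100 / (1 + exp(b * (log(x) - log_e)))

#' Fit a two-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(x) = 100 / (1 + exp(b * (ln x - ln e)))` — the
#' log-logistic with the bottom constrained to 0% and the top to 100% — by
#' multi-start Levenberg-Marquardt over five log-spaced midpoint
#' initializations spanning the dosed concentration range. The fitted
#' midpoint `e` is the IC50.
#'
#' @param concentrations Strictly positive molar concentrations, at least 4
#'   distinct values.
#' @param percent Percent responses (from [to_percent()]), same length.
#' @return Object of class `ll2_fit`: `b` (slope), `e` (IC50, molar),
#'   `rss`, `converged`.
#' @export
fit_ll2 <- function(concentrations, percent) {
  if (length(concentrations) != length(percent)) {
    stop("concentrations and responses must have equal length")
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(concentrations)) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  resid_fn <- function(par) percent - .ll2(concentrations, par[1], par[2])
  starts <- seq(min(log(concentrations)), max(log(concentrations)),
                length.out = 5)
  best <- NULL
  for (s in starts) {
    for (b0 in c(0.5, 1.5)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(b = b0, log_e = s), fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        grad_norm <- sqrt(sum(
          (2 * t(fit$fvec) %*% .ll2_jac(concentrations, fit$par))^2))
        best <- list(b = unname(fit$par["b"]),
                     e = exp(unname(fit$par["log_e"])), rss = rss,
                     converged = fit$info %in% 1:3 && grad_norm < 1e-4)
      }
    }
  }
  if (is.null(best)) {
    best <- list(b = NA_real_, e = NA_real_, rss = Inf, converged = FALSE)
  }
  structure(best, class = "ll2_fit")
}

.ll2_jac <- function(x, par) {
  b <- par[1]; log_e <- par[2]
  u <- exp(b * (log(x) - log_e))
  f <- 100 / (1 + u)
  d_db <- -f^2 / 100 * u * (log(x) - log_e)
  d_dle <- f^2 / 100 * u * b
  cbind(d_db, d_dle)
}

#' @export
print.ll2_fit <- function(x, ...) {
  cat(sprintf("<ll2_fit> b = %.3g, IC50 = %.3g M, rss = %.3g (%s)\n",
              x$b, x$e, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` for a competition binding assay with
#' radioligand concentration `L` and radioligand dissociation constant
#' `Kd`.
#'
#' @param ic50 Fitted IC50 (molar, > 0).
#' @param ligand_conc Radioligand concentration (molar, >= 0).
#' @param ligand_kd Radioligand Kd (molar, > 0).
#' @return Ki (molar).
#' @export
cheng_prusoff <- function(ic50, ligand_conc, ligand_kd) {
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  if (any(ligand_conc < 0)) stop("ligand concentration must be >= 0")
  if (any(ligand_kd <= 0)) stop("ligand Kd must be positive")
  ic50 / (1 + ligand_conc / ligand_kd)
}

#' Classify a binding hit from its Ki
#'
#' `"confirmed"` below the confirmation threshold (default 15 uM),
#' `"ambiguous"` up to the ambiguity ceiling (default 50 uM), otherwise
#' `"disproved"`.
#'
#' @param ki Ki in molar (> 0); vectorized.
#' @param confirmed Upper bound for a confirmed hit (default `15e-6`).
#' @param ambiguous_upper Upper bound for an ambiguous call (default
#'   `50e-6`).
#' @return Character vector of labels.
#' @export
classify_hit <- function(ki, confirmed = 15e-6, ambiguous_upper = 50e-6) {
  if (any(ki <= 0)) stop("Ki must be positive")
  ifelse(ki < confirmed, "confirmed",
         ifelse(ki < ambiguous_upper, "ambiguous", "disproved"))
}
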