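# Post-screen hit triage: inhibition-ratio arithmetic, RU / inhibition
# thresholding, densitometry quantification and 4PL dose-response fitting.

#' MMP-2 inhibition ratio from gel densitometry
#'
#' `(1 - gray_treatment / gray_control) * 100`, the percent suppression of
#' MMP-2 secretion relative to control. Vectorized over treatments.
#'
#' @param gray_treatment Band gray value(s) under treatment (>= 0).
#' @param gray_control Control band gray value (> 0).
#' @return Inhibition ratio(s) in percent (100 when treatment is 0, negative
#'   when treatment exceeds control).
#' @export
inhibition_ratio <- function(gray_treatment, gray_control) {
  if (any(gray_control <= 0)) abort("gray_control must be positive.")
  if (any(gray_treatment < 0)) abort("gray_treatment must be non-negative.")
  (1 - gray_treatment / gray_control) * 100
}

#' Triage screen records on RU and inhibition thresholds
#'
#' Applies the strict thresholds `ru > ru_min` (surface-plasmon-resonance
#' response units) and `inhibition > inh_min` (percent MMP-2 secretion
#' inhibited), returning the two hit lists and their intersection in input
#' order.
#'
#' @param records Tibble/data frame with columns `compound_id`, `ru`,
#'   `inhibition`.
#' @param ru_min RU threshold (default 20; strict `>`).
#' @param inh_min Inhibition threshold in percent (default 30; strict `>`).
#' @return A `triage_result`: list with `ru_hits`, `inh_hits`,
#'   `intersection` (character vectors of compound ids), `counts` (tibble)
#'   and the thresholds.
#' @export
#' @examples
#' triage_hits(cd147_candidates())
triage_hits <- function(records, ru_min = 20, inh_min = 30) {
  records <- as_tibble(records)
  need <- c("compound_id", "ru", "inhibition")
  if (!all(need %in% names(records))) {
    abort(sprintf("records must have columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("records is empty.")
  ru_hits <- records$compound_id[records$ru > ru_min]
  inh_hits <- records$compound_id[records$inhibition > inh_min]
  inter <- records$compound_id[records$ru > ru_min & records$inhibition > inh_min]
  structure(
    list(
      ru_hits = ru_hits, inh_hits = inh_hits, intersection = inter,
      counts = tibble(
        stage = c("records", "ru_hits", "inh_hits", "intersection"),
        n = c(nrow(records), length(ru_hits), length(inh_hits), length(inter))
      ),
      ru_min = ru_min, inh_min = inh_min, records = records
    ),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf(
    "<triage_result> %d records: %d with RU > %g, %d with inhibition > %g%%, %d in both\n",
    nrow(x$records), length(x$ru_hits), x$ru_min, length(x$inh_hits), x$inh_min,
    length(x$intersection)
  ))
  if (length(x$intersection) > 0) {
    cat("  intersection:", paste(x$intersection, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Densitometry dimer quantification
#'
#' `dimer_fraction` is `dimer / (dimer + monomer)` from band gray values;
#' `relative_dimerization` normalizes a treated pair to a control pair.
#'
#' @param monomer_gray,dimer_gray Band gray values (>= 0, not both zero).
#' @return `dimer_fraction`: fraction in `[0, 1]`.
#' @export
dimer_fraction <- function(monomer_gray, dimer_gray) {
  if (any(monomer_gray < 0) || any(dimer_gray < 0)) {
    abort("Gray values must be non-negative.")
  }
  tot <- monomer_gray + dimer_gray
  if (any(tot == 0)) abort("monomer and dimer gray values are both zero.")
  dimer_gray / tot
}

#' @rdname dimer_fraction
#' @param monomer_control,dimer_control Control pair gray values.
#' @return `relative_dimerization`: treated dimer fraction over control dimer
#'   fraction.
#' @export
relative_dimerization <- function(monomer_gray, dimer_gray,
                                  monomer_control, dimer_control) {
  fc <- dimer_fraction(monomer_control, dimer_control)
  if (any(fc == 0)) abort("Control dimer fraction is zero.")
  dimer_fraction(monomer_gray, dimer_gray) / fc
}

# ---- 4PL dose-response ------------------------------------------------------

fourpl <- function(dose, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x/ic50)^hill)`
#' by Levenberg-Marquardt (via minpack.lm), from the fixed initialization
#' bottom = min(y), top = max(y), hill = 1, ic50 = geometric-mean dose.
#' ic50 is log-parameterized internally so it stays positive; if the fitted
#' bottom exceeds the top the parameters are normalized by swapping them and
#' negating the hill (the curve is unchanged). IC50 is the dose at
#' half-maximal response.
#'
#' @param data Data frame with columns `dose` (> 0) and `response`.
#' @param max_iter Maximum optimizer iterations (default 200).
#' @param tol Convergence tolerance (default 1e-10).
#' @return A `dose_response_fit`: list with `bottom`, `top`, `hill`, `ic50`,
#'   `rss`, `converged`, `n`, and the input data. Supports [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @export
#' @examples
#' d <- make_dose_response(bottom = 0, top = 100, hill = 1, ic50 = 10)
#' fit <- fit_4pl(d)
#' glance(fit)
fit_4pl <- function(data, max_iter = 200, tol = 1e-10) {
  data <- as_tibble(data)
  if (!all(c("dose", "response") %in% names(data))) {
    abort("data must have columns dose and response.")
  }
  if (any(data$dose <= 0)) abort("Doses must be positive.")
  if (length(unique(data$dose)) < 4) {
    abort("At least 4 distinct doses are required for a 4PL fit.")
  }
  y <- data$response
  x <- data$dose
  lx <- log(x)
  start <- c(
    bottom = min(y), top = max(y), hill = 1,
    lic50 = mean(log(x)) # log of the geometric-mean dose
  )
  residual <- function(par) {
    y - (par[1] + (par[2] - par[1]) / (1 + exp(par[3] * (lx - par[4]))))
  }
  # raw Levenberg-Marquardt: unlike the nls-object wrappers it also handles
  # exact (zero-residual) data
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = residual,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = tol, ptol = tol
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    # degenerate input (e.g. constant responses): report a flat curve,
    # unconverged, with the geometric-mean dose standing in for ic50
    out <- list(
      bottom = mean(y), top = mean(y), hill = 0,
      ic50 = exp(mean(log(x))), rss = sum((y - mean(y))^2),
      converged = FALSE, n = nrow(data), data = data, fit = fit
    )
    return(structure(out, class = "dose_response_fit"))
  }
  cf <- fit$par
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"]); ic50 <- exp(unname(cf["lic50"]))
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  conv <- fit$info %in% 1:3 && top > bottom
  out <- list(
    bottom = bottom, top = top, hill = hill, ic50 = ic50,
    rss = sum(fit$fvec^2), converged = conv, n = nrow(data),
    data = data, fit = fit
  )
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> ic50 %.4g, hill %.3f, bottom %.3f, top %.3f (rss %.4g, %s)\n",
    x$ic50, x$hill, x$bottom, x$top, x$rss,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  fourpl(dose, object$bottom, object$top, object$hill, object$ic50)
}

#' Tidy a 4PL fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(
    term = c("bottom", "top", "hill", "ic50"),
    estimate = c(x$bottom, x$top, x$hill, x$ic50)
  )
}

#' One-row summary of a 4PL fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `ic50`, `hill`, `bottom`, `top`, `rss`, `n`,
#'   `converged`.
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(
    ic50 = x$ic50, hill = x$hill, bottom = x$bottom, top = x$top,
    rss = x$rss, n = x$n, converged = x$converged
  )
}

#' Plot a 4PL fit
#'
#' Observed responses and the fitted curve on a log dose axis.
#'
#' @param object A `dose_response_fit`.
#' @param n_grid Curve resolution (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(dose = exp(seq(
    log(min(object$data$dose)), log(max(object$data$dose)),
    length.out = n_grid
  )))
  grid$response <- predict(object, grid)
  ggplot(object$data, aes(x = .data$dose, y = .data$response)) +
    geom_point() +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(
      x = "dose", y = "response",
      title = sprintf("4PL fit: IC50 = %.3g", object$ic50)
    ) +
    theme_minimal()
}

#' Plot screen records against triage thresholds
#'
#' Scatter of RU versus inhibition ratio with the threshold lines, the view
#' used to pick dual hits from a primary screen.
#'
#' @param object A `triage_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triage_result
#' @export
autoplot.triage_result <- function(object, ...) {
  rec <- object$records
  rec$hit <- rec$ru > object$ru_min & rec$inhibition > object$inh_min
  ggplot(rec, aes(x = .data$ru, y = .data$inhibition, colour = .data$hit)) +
    geom_point() +
    ggplot2::geom_vline(xintercept = object$ru_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$inh_min, linetype = 2) +
    labs(x = "SPR response (RU)", y = "MMP-2 inhibition (%)", colour = "dual hit") +
    theme_minimal()
}

#' Experimental readouts for the five CD147 candidate compounds
#'
#' The five compounds that emerged from the published CD147 virtual screen,
#' with their Specs ids, molecular weights, minimized-pose binding energies,
#' SPR response units, and MMP-2 secretion inhibition ratios. AC-73 is
#' AN-465/42834501. Useful as a worked example for [triage_hits()].
#'
#' @return A tibble: `compound_id`, `mw`, `binding_energy`, `ru`,
#'   `inhibition`.
#' @export
cd147_candidates <- function() {
  tibble(
    compound_id = c(
      "AF-399/15392135", "AN-979/15448127", "AN-465/42834501",
      "AG-205/13358154", "AG-205/12140154"
    ),
    mw = c(416.493958, 348.352051, 319.36942, 413.463562, 431.354523),
    binding_energy = c(-69.44051, -61.51612, -72.24657, -125.36821, -89.75615),
    ru = c(22, 43, 63, 9, 13),
    inhibition = c(17.47725, 11.15524, 55.72601, 39.42461, 41.13764)
  )
}
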