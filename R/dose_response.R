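# Median-effect (Chou) dose-response fitting of well-score curves:
# amplitude/baseline estimation, linearized (Dm, s) initialization and
# damped-least-squares (Levenberg-Marquardt) refinement of
#   score(D) = A * f(D) + B,   f(D) = 1 / (1 + (Dm/D)^s).

#' Estimate score amplitude and baseline from a response curve
#'
#' `B` is the curve minimum (score baseline at zero drug) and `A` the
#' maximum minus minimum (score amplitude at saturating drug). A constant
#' curve gives `A = 0` and is flagged non-responsive.
#'
#' @param scores well scores along the dose series.
#' @return list with `A`, `B` and `responsive` (logical, `A > 0`).
#' @export
estimate_amplitude_baseline <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2)
    stop_pheno("need >= 2 scores to estimate amplitude and baseline")
  B <- min(scores)
  A <- max(scores) - B
  if (A == 0)
    warning("constant score curve: amplitude 0, flagged non-responsive",
            call. = FALSE)
  list(A = A, B = B, responsive = A > 0)
}

#' Normalize scores to fractional effects
#'
#' `f = (score - B) / A`, clipped into `[delta, 1 - delta]` so the
#' linearization `log(1/f - 1)` stays finite. The raw (unclipped) values are
#' returned alongside, and clipped points are flagged so the linear
#' initializer can exclude them (the nonlinear fit uses all points).
#'
#' @param scores well scores.
#' @param A amplitude (> 0).
#' @param B baseline.
#' @param delta clip margin (default 0.01).
#' @return list with `f` (clipped), `f_raw` and `clipped` (logical).
#' @export
normalize_effect <- function(scores, A, B, delta = 0.01) {
  if (!is.finite(A) || A <= 0)
    stop_pheno("amplitude A must be > 0 (got %g); curve is non-responsive", A)
  f_raw <- (scores - B) / A
  f <- pmin(pmax(f_raw, delta), 1 - delta)
  list(f = f, f_raw = f_raw, clipped = f != f_raw)
}

#' Linearized median-effect estimate
#'
#' The median-effect law linearizes as `log(1/f - 1) = s * log(Dm / D)`:
#' regressing `log(1/f - 1)` on `log D` gives slope `-s` and intercept
#' `s * log Dm`. Exact on noiseless data; used to initialize the nonlinear
#' fit.
#'
#' @param doses positive doses.
#' @param f fractional effects strictly inside (0, 1).
#' @return list with `Dm` and `s`.
#' @export
linearized_median_effect <- function(doses, f) {
  ok <- is.finite(doses) & is.finite(f) & doses > 0 & f > 0 & f < 1
  if (sum(ok) < 2)
    stop_pheno("need >= 2 points with f strictly inside (0,1); have %d",
               sum(ok))
  y <- log(1 / f[ok] - 1)
  x <- log(doses[ok])
  # closed-form least squares (lm() warns on perfect two-point fits)
  vx <- sum((x - mean(x))^2)
  if (vx == 0) stop_pheno("all usable doses coincide; cannot linearize")
  slope <- sum((x - mean(x)) * (y - mean(y))) / vx
  intercept <- mean(y) - slope * mean(x)
  s <- -slope
  if (!is.finite(s) || s == 0)
    stop_pheno("degenerate linearization (slope %g)", slope)
  list(Dm = exp(intercept / s), s = s)
}

median_effect_scores <- function(doses, A, B, Dm, s) {
  A * fractional_effect(doses, Dm, s) + B
}

#' Fit the median-effect model to a dose-score curve
#'
#' Averages duplicate doses, estimates `(A, B)` from the curve extremes,
#' initializes `(Dm, s)` from the linearized equation (clipped points
#' excluded), then refines all four parameters by bounded
#' Levenberg-Marquardt least squares on
#' `score = A / (1 + (Dm/D)^s) + B` (all points included). The refinement
#' never ends with a larger residual sum of squares than its
#' initialization.
#'
#' @param doses positive doses.
#' @param scores matching well scores.
#' @param delta clip margin for the linearization (default 0.01).
#' @param average_duplicates average scores at identical doses before
#'   fitting (default TRUE).
#' @param max_iter maximum LM iterations (default 200).
#' @return object of class `median_effect_fit`: `A`, `B`, `Dm`, `s`, `rss`,
#'   `converged`, `n_points`, `responsive`, `low_confidence` (fewer than 4
#'   points or under 2 dose decades) and the input curve.
#' @export
fit_median_effect <- function(doses, scores, delta = 0.01,
                              average_duplicates = TRUE, max_iter = 200) {
  stopifnot(length(doses) == length(scores))
  ok <- is.finite(doses) & is.finite(scores)
  doses <- doses[ok]; scores <- scores[ok]
  if (any(doses <= 0)) stop_pheno("doses must be > 0")
  if (average_duplicates && anyDuplicated(doses)) {
    agg <- tapply(scores, doses, mean)
    doses <- as.numeric(names(agg)); scores <- as.numeric(agg)
  }
  ord <- order(doses)
  doses <- doses[ord]; scores <- scores[ord]
  n <- length(doses)
  low_confidence <- n < 4 ||
    log10(max(doses) / min(doses)) < 2
  ab <- estimate_amplitude_baseline(scores)
  if (!ab$responsive) {
    return(structure(list(A = 0, B = ab$B, Dm = NA_real_, s = NA_real_,
                          rss = sum((scores - ab$B)^2), converged = FALSE,
                          n_points = n, responsive = FALSE,
                          low_confidence = TRUE, doses = doses,
                          scores = scores),
                     class = "median_effect_fit"))
  }
  nf <- normalize_effect(scores, ab$A, ab$B, delta = delta)
  init <- if (sum(!nf$clipped) >= 2)
    linearized_median_effect(doses[!nf$clipped], nf$f[!nf$clipped])
  else  # all points at the clip bounds: fall back to the clipped values
    linearized_median_effect(doses, nf$f)
  if (!is.finite(init$s) || init$s <= 0) init$s <- 1
  rng <- ab$A
  lower <- c(A = 0, B = min(scores) - rng, Dm = min(doses) / 100, s = 0.1)
  upper <- c(A = 10 * rng, B = min(scores) + rng, Dm = max(doses) * 100,
             s = 10)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  par0 <- clamp(c(A = ab$A, B = ab$B, Dm = init$Dm, s = init$s))
  resid_fn <- function(p) {
    scores - median_effect_scores(doses, p[["A"]], p[["B"]], p[["Dm"]],
                                  p[["s"]])
  }
  if (n >= 4) {
    # damped least squares needs at least as many points as parameters
    fit <- nls.lm(par = par0, lower = lower, upper = upper, fn = resid_fn,
                  control = nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                           ptol = 1e-12))
    par <- clamp(coef(fit))
    converged <- fit$info %in% 1:4
  } else {
    par <- par0
    converged <- FALSE
  }
  rss <- sum(resid_fn(par)^2)
  rss0 <- sum(resid_fn(par0)^2)
  if (rss > rss0) { par <- par0; rss <- rss0 }
  structure(list(A = par[["A"]], B = par[["B"]], Dm = par[["Dm"]],
                 s = par[["s"]], rss = rss,
                 converged = converged, n_points = n,
                 responsive = TRUE, low_confidence = low_confidence,
                 doses = doses, scores = scores),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  if (!x$responsive) {
    cat("Median-effect fit: non-responsive (A = 0)\n")
  } else {
    cat(sprintf(
      "Median-effect fit: A=%.4g B=%.4g Dm=%.4g s=%.4g (rss %.3g, %d points%s%s)\n",
      x$A, x$B, x$Dm, x$s, x$rss, x$n_points,
      if (x$converged) "" else ", NOT converged",
      if (x$low_confidence) ", low confidence" else ""))
  }
  invisible(x)
}

#' Predict scores or fractional effects from a median-effect fit
#'
#' @param object a `median_effect_fit`.
#' @param doses doses to evaluate (default the fitted ones).
#' @param type `"score"` (`A f + B`) or `"fraction"` (`f`).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.median_effect_fit <- function(object, doses = object$doses,
                                      type = c("score", "fraction"), ...) {
  type <- match.arg(type)
  f <- fractional_effect(doses, object$Dm, object$s)
  if (type == "fraction") f else object$A * f + object$B
}

#' Serialize a median-effect fit to JSON
#'
#' @param fit a `median_effect_fit` (or named list of them).
#' @param path JSON path.
#' @export
write_median_effect_fit <- function(fit, path) {
  pick <- function(f) f[c("A", "B", "Dm", "s", "rss", "converged",
                          "n_points", "responsive", "low_confidence")]
  out <- if (inherits(fit, "median_effect_fit")) pick(fit) else
    lapply(fit, pick)
  write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
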