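# Binary drug-combination analysis: Loewe-additivity and Bliss-independence
# predictions over dose-pair matrices, combination-index maps, single-agent
# edge fits, joint 4-parameter surface fits and residual/synergy summaries.

#' Bliss-model combination effect
#'
#' The default convention multiplies the two single-agent effect fractions,
#' `f_comb = f1 * f2` with `f_i = 1 / (1 + (Dmi/Di)^si)`; under it a zero
#' partner dose gives `f_comb = 0` (the zero factor), not the single-agent
#' curve. The conventional independence form
#' `f1 + f2 - f1 * f2` is available via `convention = "independence"`.
#'
#' @param D1,D2 doses (vectors or matrices, >= 0; recycled).
#' @param Dm1,s1,Dm2,s2 per-drug median-effect parameters.
#' @param convention `"product"` (default) or `"independence"`.
#' @return combination fractional effect, same shape as `D1`/`D2`.
#' @export
bliss_predict <- function(D1, D2, Dm1, s1, Dm2, s2,
                          convention = c("product", "independence")) {
  convention <- match.arg(convention)
  f1 <- fractional_effect(D1, Dm1, s1)
  f2 <- fractional_effect(D2, Dm2, s2)
  if (convention == "product") f1 * f2 else f1 + f2 - f1 * f2
}

loewe_condition <- function(f, D1, D2, Dm1, s1, Dm2, s2) {
  t1 <- (f / (1 - f))^(1 / s1)
  t2 <- (f / (1 - f))^(1 / s2)
  D1 / (Dm1 * t1) + D2 / (Dm2 * t2) - 1
}

#' Loewe-additivity combination effect
#'
#' Solves the Loewe isobole condition
#' `D1 / (Dm1 [f/(1-f)]^(1/s1)) + D2 / (Dm2 [f/(1-f)]^(1/s2)) = 1`
#' for the combination fraction `f` by bracketed bisection on (0, 1); the
#' left side is strictly decreasing in `f`, so the solution is unique. At a
#' zero partner dose the prediction reduces exactly to the remaining
#' single-agent curve, and for identical drugs (`Dm1 = Dm2`, `s1 = s2`) to
#' the dose-additive closed form `1 / (1 + (Dm/(D1+D2))^s)`.
#'
#' @inheritParams bliss_predict
#' @param tol root tolerance on the condition residual (default 1e-10).
#' @return combination fractional effect(s).
#' @export
loewe_predict <- function(D1, D2, Dm1, s1, Dm2, s2, tol = 1e-10) {
  n <- max(length(D1), length(D2))
  d1 <- rep_len(as.numeric(D1), n); d2 <- rep_len(as.numeric(D2), n)
  if (any(d1 < 0) || any(d2 < 0)) stop_pheno("doses must be >= 0")
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (d1[i] + d2[i] == 0) { out[i] <- 0; next }
    if (d2[i] == 0) { out[i] <- fractional_effect(d1[i], Dm1, s1); next }
    if (d1[i] == 0) { out[i] <- fractional_effect(d2[i], Dm2, s2); next }
    g <- function(f) loewe_condition(f, d1[i], d2[i], Dm1, s1, Dm2, s2)
    lo <- 1e-12; hi <- 1 - 1e-12
    glo <- g(lo); ghi <- g(hi)
    if (!is.finite(glo) || !is.finite(ghi) || glo < 0 || ghi > 0) {
      if (is.finite(glo) && glo < 0) { out[i] <- 0; next }  # negligible dose
      stop_pheno("no bracket for the Loewe condition at (D1=%g, D2=%g); degenerate parameters (Dm1=%g, s1=%g, Dm2=%g, s2=%g)",
                 d1[i], d2[i], Dm1, s1, Dm2, s2)
    }
    r <- uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.9,
                 maxiter = 1000)
    if (abs(g(r$root)) > tol)
      stop_pheno("Loewe root residual %.3g exceeds tolerance %.1g",
                 abs(g(r$root)), tol)
    out[i] <- r$root
  }
  if (is.matrix(D1)) out <- matrix(out, nrow(D1), ncol(D1))
  if (is.matrix(D2) && !is.matrix(D1)) out <- matrix(out, nrow(D2), ncol(D2))
  out
}

#' Combination index at an observed effect
#'
#' `CI = D1/Dx1 + D2/Dx2` with `Dxi = Dmi * [f/(1-f)]^(1/si)` the
#' single-agent dose producing the observed fraction `f`. `CI = 1` is
#' Loewe-additive, `CI < 1` synergy, `CI > 1` antagonism; halving both doses
#' at fixed `f` halves CI.
#'
#' @param D1,D2 applied doses.
#' @param f_observed observed combination fraction, strictly inside (0, 1).
#' @param Dm1,s1,Dm2,s2 single-agent median-effect parameters.
#' @return combination index (same shape as inputs).
#' @export
combination_index <- function(D1, D2, f_observed, Dm1, s1, Dm2, s2) {
  if (any(f_observed <= 0 | f_observed >= 1))
    stop_pheno("f_observed must be strictly inside (0, 1)")
  Dx1 <- Dm1 * (f_observed / (1 - f_observed))^(1 / s1)
  Dx2 <- Dm2 * (f_observed / (1 - f_observed))^(1 / s2)
  D1 / Dx1 + D2 / Dx2
}

#' Construct a combination matrix
#'
#' Container for a duplicate-averaged dose-pair grid: per-drug ladders,
#' the observed fraction grid (rows = drug 1, columns = drug 2) and the
#' single-agent edge curves on the score scale used to fit each drug alone.
#'
#' @param doses_1,doses_2 strictly positive, strictly increasing ladders.
#' @param observed_f matrix `length(doses_1) x length(doses_2)` of observed
#'   fractions in `[0, 1]`.
#' @param edge_scores_1,edge_scores_2 data.frames (`dose`, `score`) of the
#'   single-agent edges; default the matching rows/columns of `observed_f`
#'   treated as already-normalized scores.
#' @return object of class `combination_matrix`.
#' @export
combination_matrix <- function(doses_1, doses_2, observed_f,
                               edge_scores_1 = NULL, edge_scores_2 = NULL) {
  stopifnot(all(doses_1 > 0), all(doses_2 > 0),
            !is.unsorted(doses_1, strictly = TRUE),
            !is.unsorted(doses_2, strictly = TRUE))
  observed_f <- as.matrix(observed_f)
  if (!identical(dim(observed_f),
                 as.integer(c(length(doses_1), length(doses_2)))))
    stop_pheno("observed_f must be %d x %d", length(doses_1),
               length(doses_2))
  if (any(observed_f < 0 | observed_f > 1, na.rm = TRUE))
    stop_pheno("observed fractions must lie in [0, 1]")
  if (is.null(edge_scores_1))
    edge_scores_1 <- data.frame(dose = doses_1, score = observed_f[, 1])
  if (is.null(edge_scores_2))
    edge_scores_2 <- data.frame(dose = doses_2, score = observed_f[1, ])
  structure(list(doses_1 = doses_1, doses_2 = doses_2,
                 observed_f = observed_f, edge_scores_1 = edge_scores_1,
                 edge_scores_2 = edge_scores_2),
            class = "combination_matrix")
}

#' Build a combination matrix from virtual-plate scores
#'
#' Takes the duplicate-averaged output of [assemble_virtual_plate()] for a
#' [build_combination_layout()] block and normalizes scores to fractions:
#' baseline `B` from the control group (falling back to the block minimum)
#' and amplitude `A` from the block maximum. Single-agent edge groups become
#' the raw-score edge curves.
#'
#' @param vp a `virtual_plate` data.frame covering one combination block.
#' @return a `combination_matrix`.
#' @export
as_combination_matrix <- function(vp) {
  stopifnot(is.data.frame(vp))
  core <- vp[!is.na(vp$drug_1) & !is.na(vp$drug_2), , drop = FALSE]
  if (!nrow(core))
    stop_pheno("virtual plate lacks a combination core")
  id1 <- unique(core$drug_1); id2 <- unique(core$drug_2)
  if (length(id1) != 1 || length(id2) != 1)
    stop_pheno("expected exactly one drug per axis, got (%s) x (%s)",
               paste(id1, collapse = ","), paste(id2, collapse = ","))
  # single-agent wells carry their drug in the first slot
  single <- vp[!is.na(vp$drug_1) & is.na(vp$drug_2) & vp$role == "treated",
               , drop = FALSE]
  e1 <- single[single$drug_1 == id1, , drop = FALSE]
  e2 <- single[single$drug_1 == id2, , drop = FALSE]
  if (!nrow(e1) || !nrow(e2))
    stop_pheno("virtual plate lacks a single-drug edge for %s",
               if (nrow(e1)) id2 else id1)
  d1 <- sort(unique(core$conc_1)); d2 <- sort(unique(core$conc_2))
  ctrl <- vp$score[vp$role == "control"]
  B <- if (length(ctrl)) mean(ctrl) else min(vp$score)
  A <- max(vp$score) - B
  if (A <= 0) stop_pheno("combination block has zero score amplitude")
  grid <- matrix(NA_real_, length(d1), length(d2))
  for (r in seq_len(nrow(core))) {
    i <- match(core$conc_1[r], d1); j <- match(core$conc_2[r], d2)
    grid[i, j] <- (core$score[r] - B) / A
  }
  grid <- pmin(pmax(grid, 0), 1)
  combination_matrix(
    d1, d2, grid,
    edge_scores_1 = data.frame(dose = e1$conc_1, score = e1$score),
    edge_scores_2 = data.frame(dose = e2$conc_1, score = e2$score))
}

#' Fit the single-agent edges of a combination matrix
#'
#' Delegates each drug's single-agent edge curve to [fit_median_effect()].
#'
#' @param matrix a `combination_matrix`.
#' @return list with `fit_1` and `fit_2` (`median_effect_fit` objects).
#' @export
fit_single_drug_edges <- function(matrix) {
  stopifnot(inherits(matrix, "combination_matrix"))
  if (nrow(matrix$edge_scores_1) < 2 || nrow(matrix$edge_scores_2) < 2)
    stop_pheno("combination matrix is missing a single-drug edge")
  list(fit_1 = fit_median_effect(matrix$edge_scores_1$dose,
                                 matrix$edge_scores_1$score),
       fit_2 = fit_median_effect(matrix$edge_scores_2$dose,
                                 matrix$edge_scores_2$score))
}

combo_predict <- function(model, D1, D2, p, convention = "product") {
  if (model == "bliss")
    bliss_predict(D1, D2, p[["Dm1"]], p[["s1"]], p[["Dm2"]], p[["s2"]],
                  convention = convention)
  else
    loewe_predict(D1, D2, p[["Dm1"]], p[["s1"]], p[["Dm2"]], p[["s2"]])
}

#' Joint four-parameter combination fit
#'
#' Least-squares fit of `(Dm1, Dm2, s1, s2)` to every cell of the observed
#' fraction grid simultaneously under the chosen null-surface model,
#' initialized from the single-agent edge fits and bounded as in
#' [fit_median_effect()].
#'
#' @param matrix a `combination_matrix`.
#' @param model `"loewe"` or `"bliss"`.
#' @param convention Bliss convention, see [bliss_predict()].
#' @param init optional named vector `c(Dm1, s1, Dm2, s2)` overriding the
#'   edge-fit initialization.
#' @param max_iter LM iteration cap.
#' @return object of class `combination_fit`: `model`, `Dm1`, `s1`, `Dm2`,
#'   `s2`, `rss`, `converged`, `source` (`"joint"`), `n_cells`.
#' @export
fit_combination_joint <- function(matrix, model = c("loewe", "bliss"),
                                  convention = "product", init = NULL,
                                  max_iter = 200) {
  stopifnot(inherits(matrix, "combination_matrix"))
  model <- match.arg(model)
  cm <- matrix
  obs <- cm$observed_f
  D1 <- base::matrix(cm$doses_1, nrow(obs), ncol(obs))
  D2 <- t(base::matrix(cm$doses_2, ncol(obs), nrow(obs)))
  keep <- is.finite(obs)
  if (sum(keep) < 8)
    stop_pheno("need >= 8 informative grid cells, have %d", sum(keep))
  if (is.null(init)) {
    ef <- fit_single_drug_edges(cm)
    init <- c(Dm1 = ef$fit_1$Dm, s1 = ef$fit_1$s,
              Dm2 = ef$fit_2$Dm, s2 = ef$fit_2$s)
    if (anyNA(init))
      stop_pheno("edge fits are non-responsive; supply `init` explicitly")
  }
  lower <- c(Dm1 = min(cm$doses_1) / 100, s1 = 0.1,
             Dm2 = min(cm$doses_2) / 100, s2 = 0.1)
  upper <- c(Dm1 = max(cm$doses_1) * 100, s1 = 10,
             Dm2 = max(cm$doses_2) * 100, s2 = 10)
  par0 <- pmin(pmax(init[names(lower)], lower), upper)
  resid_fn <- function(p) {
    pred <- combo_predict(model, D1, D2, p, convention)
    (obs - pred)[keep]
  }
  fit <- nls.lm(par = par0, lower = lower, upper = upper, fn = resid_fn,
                control = nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                         ptol = 1e-12))
  par <- pmin(pmax(coef(fit), lower), upper)
  rss <- sum(resid_fn(par)^2)
  if (rss > sum(resid_fn(par0)^2)) { par <- par0; rss <- sum(resid_fn(par0)^2) }
  structure(list(model = model, convention = convention,
                 Dm1 = par[["Dm1"]], s1 = par[["s1"]], Dm2 = par[["Dm2"]],
                 s2 = par[["s2"]], rss = rss,
                 converged = fit$info %in% 1:4, source = "joint",
                 n_cells = sum(keep)),
            class = "combination_fit")
}

#' @export
print.combination_fit <- function(x, ...) {
  cat(sprintf(
    "Combination fit (%s, %s): Dm1=%.4g s1=%.4g Dm2=%.4g s2=%.4g (rss %.3g over %d cells)\n",
    x$model, x$source, x$Dm1, x$s1, x$Dm2, x$s2, x$rss, x$n_cells))
  invisible(x)
}

#' Residual and synergy summary of a combination matrix
#'
#' Compares the observed fraction grid with the fitted null surface:
#' per-cell residuals (observed minus predicted), mean signed residual,
#' the largest absolute residual and its grid position, a combination-index
#' map over interior cells, and a seeded sign-flip randomization p-value for
#' the hypothesis that the mean residual is zero (synergy shifts it
#' negative or positive coherently).
#'
#' @param matrix a `combination_matrix`.
#' @param fit a `combination_fit` (or named parameter vector).
#' @param n_perm randomization draws (default 1000).
#' @param seed randomization seed.
#' @return object of class `synergy_report`: `residuals`, `mean_residual`,
#'   `max_abs_residual`, `max_cell` (`c(i, j)`), `ci_map`, `p_value`,
#'   `model`.
#' @export
synergy_report <- function(matrix, fit, n_perm = 1000, seed = 1) {
  stopifnot(inherits(matrix, "combination_matrix"),
            inherits(fit, "combination_fit"))
  cm <- matrix
  obs <- cm$observed_f
  D1 <- base::matrix(cm$doses_1, nrow(obs), ncol(obs))
  D2 <- t(base::matrix(cm$doses_2, ncol(obs), nrow(obs)))
  p <- c(Dm1 = fit$Dm1, s1 = fit$s1, Dm2 = fit$Dm2, s2 = fit$s2)
  pred <- combo_predict(fit$model, D1, D2, p, fit$convention)
  res <- obs - pred
  keep <- is.finite(res)
  r <- res[keep]
  mx <- which(abs(res) == max(abs(r)), arr.ind = TRUE)[1, ]
  interior <- keep & obs > 0 & obs < 1
  ci <- base::matrix(NA_real_, nrow(obs), ncol(obs))
  ci[interior] <- combination_index(D1[interior], D2[interior],
                                    obs[interior], fit$Dm1, fit$s1,
                                    fit$Dm2, fit$s2)
  tstat <- abs(mean(r))
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    abs(mean(r * (2 * rbinom(length(r), 1, 0.5) - 1)))
  }, numeric(1)))
  p_value <- (1 + sum(perm >= tstat)) / (n_perm + 1)
  structure(list(residuals = res, predicted = pred,
                 mean_residual = mean(r), max_abs_residual = max(abs(r)),
                 max_cell = mx, ci_map = ci, p_value = p_value,
                 model = fit$model, n_perm = n_perm, seed = seed),
            class = "synergy_report")
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf(
    "Synergy report (%s null): mean residual %+.4g, max |residual| %.4g at (%d,%d), p = %.3g\n",
    x$model, x$mean_residual, x$max_abs_residual, x$max_cell[1],
    x$max_cell[2], x$p_value))
  invisible(x)
}
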