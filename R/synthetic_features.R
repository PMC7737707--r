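# Ground-truthed simulation of correlated per-cell feature populations with
# dose-dependent Hill-type shifts, the feature-level half of the synthetic
# data module.

#' Canonical per-cell attribute names
#'
#' The attribute vector quantified per segmented cell: cell and nucleus
#' morphology, background-subtracted channel intensities (`_Bck` suffix),
#' fiber measures and texture.
#'
#' @return character vector of 16 attribute names.
#' @export
attribute_names <- function() {
  c("Cell_Area", "Cell_LongAxis", "Nuc_Area", "Nuc_TotInt", "Nuc_AvgInt",
    "Act_TotInt_Bck", "Act_AvgInt_Bck", "Act_CelInt_Bck",
    "Act_Fib_CelInt_Bck", "Act_Fib_Len", "Tub_TotInt_Bck", "Tub_AvgInt_Bck",
    "Tub_CelInt_Bck", "Tub_Fib_Len", "Tub_Texture", "Nuc_Cyto_Ratio")
}

#' Specify a feature-population simulation
#'
#' Defines the multivariate control population and the dose law for treated
#' cells. The control covariance is specified as low-rank loading factors
#' plus independent noise variances, `Sigma = L L' + diag(psi)`, which is
#' positive semi-definite by construction and imitates correlated attribute
#' families (cell size with total intensities, staining level across
#' channels). Treated populations shift the `effect_attributes` by
#' `max_shift` (in control-SD units) times the fractional effect
#' `f(D) = 1 / (1 + (dm_true/D)^s_true)`.
#'
#' @param attribute_names ordered attribute labels.
#' @param control_mean numeric vector of control means.
#' @param loadings matrix (`n_attr` x k) of covariance factors; may have 0
#'   columns for a diagonal covariance.
#' @param noise_var independent per-attribute noise variances, >= 0.
#' @param effect_attributes names (or indices) of attributes the drug shifts.
#' @param max_shift saturating shift per effect attribute, in control-SD
#'   units (signed).
#' @param dm_true true median-effect concentration (> 0).
#' @param s_true true Hill exponent (> 0).
#' @param well_noise_sd sd of the optional multiplicative lognormal
#'   well-level noise (default 0.05) used by the plate simulator.
#' @return object of class `feature_sim_spec` with the assembled `covariance`.
#' @seealso [default_feature_spec()] for the packaged realistic default.
#' @export
feature_sim_spec <- function(attribute_names, control_mean, loadings,
                             noise_var, effect_attributes, max_shift,
                             dm_true, s_true, well_noise_sd = 0.05) {
  p <- length(attribute_names)
  stopifnot(length(control_mean) == p, length(noise_var) == p)
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != p && ncol(loadings) == 0)
    loadings <- matrix(0, p, 0)
  stopifnot(nrow(loadings) == p)
  if (any(noise_var < 0))
    stop_pheno("noise variances must be >= 0 (covariance would not be PSD)")
  if (is.character(effect_attributes)) {
    idx <- match(effect_attributes, attribute_names)
    if (anyNA(idx))
      stop_pheno("unknown effect attribute(s): %s",
                 paste(effect_attributes[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(effect_attributes)
  stopifnot(all(idx >= 1 & idx <= p), length(max_shift) == length(idx))
  check_number(dm_true, "dm_true", positive = TRUE)
  check_number(s_true, "s_true", positive = TRUE)
  covariance <- tcrossprod(loadings) + diag(noise_var, p)
  structure(list(attribute_names = attribute_names,
                 control_mean = setNames(control_mean, attribute_names),
                 loadings = loadings, noise_var = noise_var,
                 covariance = covariance,
                 control_sd = sqrt(diag(covariance)),
                 effect_attributes = idx,
                 max_shift = max_shift, dm_true = dm_true, s_true = s_true,
                 well_noise_sd = well_noise_sd),
            class = "feature_sim_spec")
}

#' Default feature-simulation specification
#'
#' A 16-attribute control population at the scale of the synthetic image
#' fields, with three correlated families (cell size, staining level, fiber
#' content) expressed through low-rank loadings. The default treatment
#' emulates a microtubule-depolymerizing drug: tubulin total/cytoplasmic
#' intensity and fiber length drop by up to 2.5-3 control SDs while nuclear
#' DNA content rises (cell-cycle arrest), with median-effect concentration
#' `dm_true = 0.3` (micromolar scale) and Hill exponent 1.5.
#'
#' @param dm_true,s_true override the dose-law parameters.
#' @return a `feature_sim_spec`.
#' @export
default_feature_spec <- function(dm_true = 0.3, s_true = 1.5) {
  an <- attribute_names()
  mu <- c(1200, 55, 220, 66000, 300, 180000, 150, 150000, 40000, 180,
          180000, 150, 150000, 160, 0.35, 2.5)
  sd <- c(250, 8, 40, 12000, 30, 40000, 20, 35000, 12000, 50,
          40000, 20, 35000, 45, 0.06, 0.4)
  # loading fractions per factor: size, stain, fibers (row sumsq < 1)
  phi <- matrix(0, 16, 3)
  rownames(phi) <- an
  phi[c("Cell_Area", "Cell_LongAxis", "Nuc_Area"), 1] <- c(0.8, 0.6, 0.5)
  phi[c("Act_TotInt_Bck", "Tub_TotInt_Bck", "Nuc_TotInt"), 1] <- 0.5
  phi[c("Act_TotInt_Bck", "Act_AvgInt_Bck", "Act_CelInt_Bck"), 2] <-
    c(0.5, 0.7, 0.5)
  phi[c("Tub_TotInt_Bck", "Tub_AvgInt_Bck", "Tub_CelInt_Bck"), 2] <-
    c(0.5, 0.7, 0.5)
  phi[c("Nuc_TotInt", "Nuc_AvgInt"), 2] <- c(0.4, 0.6)
  phi[c("Act_Fib_CelInt_Bck", "Act_Fib_Len", "Tub_Fib_Len"), 3] <-
    c(0.6, 0.7, 0.5)
  loadings <- sd * phi
  noise_var <- sd^2 * pmax(1 - rowSums(phi^2), 0.05)
  feature_sim_spec(
    attribute_names = an, control_mean = mu, loadings = loadings,
    noise_var = noise_var,
    effect_attributes = c("Tub_TotInt_Bck", "Tub_CelInt_Bck", "Tub_Fib_Len",
                          "Tub_AvgInt_Bck", "Nuc_TotInt"),
    max_shift = c(-3, -2.5, -2.5, -2, 1.5),
    dm_true = dm_true, s_true = s_true)
}

#' Fractional effect under the median-effect (Hill) dose law
#'
#' `f(D) = 1 / (1 + (Dm/D)^s)`, with `f(0) = 0`; `f(Dm) = 0.5` exactly and
#' `0 <= f < 1` for finite dose.
#'
#' @param dose dose(s), >= 0.
#' @param dm median-effect dose (> 0).
#' @param s Hill exponent (> 0).
#' @return fractional effect in `[0, 1)`.
#' @export
fractional_effect <- function(dose, dm, s) {
  check_number(dm, "dm", positive = TRUE)
  check_number(s, "s", positive = TRUE)
  if (any(dose < 0)) stop_pheno("dose must be >= 0")
  ifelse(dose == 0, 0, 1 / (1 + (dm / dose)^s))
}

#' Simulate a control cell population
#'
#' Draws `n` cells from the multivariate normal control distribution of a
#' [feature_sim_spec()]. Reproducible for a fixed seed.
#'
#' @param spec a `feature_sim_spec`.
#' @param n number of cells (>= 1).
#' @param seed integer seed.
#' @return data.frame of `n` rows, one column per attribute.
#' @export
simulate_control_population <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "feature_sim_spec"))
  check_number(n, "n", min = 1)
  with_seed(seed, {
    x <- mvrnorm(n, mu = spec$control_mean, Sigma = spec$covariance)
    if (n == 1) x <- matrix(x, nrow = 1)
  })
  colnames(x) <- spec$attribute_names
  as.data.frame(x)
}

#' Simulate a treated cell population at one dose
#'
#' Effect attributes are shifted by `max_shift * control_sd * f(dose)` with
#' `f` the median-effect law of the spec; all other attributes and the full
#' covariance are those of the control population.
#'
#' @inheritParams simulate_control_population
#' @param dose drug dose (>= 0) on the spec's `dm_true` scale.
#' @return list with `records` (data.frame as in
#'   [simulate_control_population()]) and `truth` (list: `dose`, `f`,
#'   `shift` = named vector of applied mean shifts).
#' @export
simulate_treated_population <- function(spec, dose, n, seed = 1) {
  stopifnot(inherits(spec, "feature_sim_spec"))
  if (!is.numeric(dose) || length(dose) != 1 || dose < 0)
    stop_pheno("`dose` must be a single number >= 0")
  f <- fractional_effect(dose, spec$dm_true, spec$s_true)
  shift <- numeric(length(spec$attribute_names))
  shift[spec$effect_attributes] <-
    spec$max_shift * spec$control_sd[spec$effect_attributes] * f
  mu <- spec$control_mean + shift
  with_seed(seed, {
    x <- mvrnorm(n, mu = mu, Sigma = spec$covariance)
    if (n == 1) x <- matrix(x, nrow = 1)
  })
  colnames(x) <- spec$attribute_names
  list(records = as.data.frame(x),
       truth = list(dose = dose, f = f,
                    shift = setNames(shift, spec$attribute_names)))
}

#' Simulate per-cell features for a whole plate
#'
#' Control wells draw from the control population, treated wells from the
#' dose-shifted population at the well's concentration (wells carrying two
#' drugs use the dose-additive total `conc_1 + conc_2`). Per-well seeds are
#' derived deterministically from `(seed, plate_id, well)`, so duplicates
#' get distinct draws from the same distribution and the whole plate is
#' reproducible from one experiment seed.
#'
#' @param spec a `feature_sim_spec`.
#' @param layout a `plate_layout`.
#' @param cells_per_well cells simulated per well.
#' @param seed experiment seed.
#' @param dose_scale multiplies layout concentrations before applying the
#'   dose law (use to express molar layout doses on the spec's `dm_true`
#'   scale; default 1).
#' @return list with `cells` (data.frame: `well`, `role`,
#'   `replicate_group`, attribute columns) and `truth` (data.frame per well:
#'   `well`, `dose`, `f`).
#' @export
simulate_dose_response_plate <- function(spec, layout, cells_per_well = 100,
                                         seed = 1, dose_scale = 1) {
  stopifnot(inherits(spec, "feature_sim_spec"),
            inherits(layout, "plate_layout"))
  w <- layout$wells[layout$wells$role != "empty", , drop = FALSE]
  cells <- vector("list", nrow(w))
  truth <- vector("list", nrow(w))
  for (i in seq_len(nrow(w))) {
    ws <- derive_seed(seed, layout$plate_id, w$well[i])
    if (w$role[i] == "control") {
      rec <- simulate_control_population(spec, cells_per_well, seed = ws)
      dose <- 0
    } else {
      dose <- (w$conc_1[i] + ifelse(is.na(w$conc_2[i]), 0, w$conc_2[i])) *
        dose_scale
      tr <- simulate_treated_population(spec, dose, cells_per_well,
                                        seed = ws)
      rec <- tr$records
    }
    cells[[i]] <- cbind(data.frame(well = w$well[i], role = w$role[i],
                                   replicate_group = w$replicate_group[i],
                                   stringsAsFactors = FALSE), rec)
    truth[[i]] <- data.frame(
      well = w$well[i], dose = dose,
      f = fractional_effect(dose, spec$dm_true, spec$s_true),
      stringsAsFactors = FALSE)
  }
  list(cells = do.call(rbind, cells), truth = do.call(rbind, truth))
}

#' Simulate a well-score dose-response curve
#'
#' Generates scores from the median-effect law `A f(D) + B` with optional
#' multiplicative lognormal noise, the well-level generative model used for
#' fitter recovery studies.
#'
#' @param doses positive doses.
#' @param A amplitude, `B` baseline of the score scale.
#' @param B baseline score at zero dose.
#' @param dm,s median-effect dose and Hill exponent.
#' @param noise_sd sd of `log`-scale multiplicative noise (0 = noiseless).
#' @param seed seed used when `noise_sd > 0`.
#' @return numeric vector of scores, one per dose.
#' @export
simulate_score_curve <- function(doses, A, B, dm, s, noise_sd = 0,
                                 seed = 1) {
  mu <- A * fractional_effect(doses, dm, s) + B
  if (noise_sd > 0)
    mu <- with_seed(seed, mu * exp(rnorm(length(mu), 0, noise_sd)))
  mu
}
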