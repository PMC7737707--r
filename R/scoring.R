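# Robust-PCA control hyper-ellipsoid, per-cell Mahalanobis scores,
# per-attribute contributions, outlier rejection and well/plate aggregation.

# Extract the attribute matrix from a record data.frame (or matrix),
# optionally aligning to a model's attribute order.
attribute_matrix <- function(records, names = NULL) {
  if (is.matrix(records)) {
    x <- records
  } else {
    stopifnot(is.data.frame(records))
    cand <- names %||% intersect(attribute_names(), colnames(records))
    if (!length(cand))
      cand <- colnames(records)[vapply(records, is.numeric, TRUE)]
    miss <- setdiff(cand, colnames(records))
    if (length(miss))
      stop_pheno("records lack model attribute(s): %s",
                 paste(miss, collapse = ", "))
    x <- as.matrix(records[, cand, drop = FALSE])
  }
  if (!is.null(names)) {
    x <- x[, names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}

pca_fit <- function(x, variance_floor, consistency = 1) {
  mu <- colMeans(x)
  e <- eigen(cov(x), symmetric = TRUE)
  lambda <- pmax(e$values, 0) * consistency
  retained <- which(lambda > variance_floor * mean(lambda))
  list(center = mu, axes = e$vectors, variances = lambda,
       retained = retained)
}

# Consistency factor for a covariance estimated from points inside the
# chi-square(q) trimming radius: a multivariate normal truncated at squared
# radius k has covariance Sigma * pchisq(k, d + 2) / pchisq(k, d), so the
# trimmed estimate is inflated back by the reciprocal. 1 when q = 1.
trim_consistency <- function(trim_quantile, d) {
  if (trim_quantile >= 1) return(1)
  k <- qchisq(trim_quantile, df = d)
  pchisq(k, df = d) / pchisq(k, df = d + 2)
}

sq_distance <- function(x, fit) {
  xc <- sweep(x, 2, fit$center)
  y <- xc %*% fit$axes[, fit$retained, drop = FALSE]
  rowSums(sweep(y^2, 2, fit$variances[fit$retained], "/"))
}

#' Fit the robust-PCA control hyper-ellipsoid
#'
#' Fits center, principal axes and per-axis variances to the control-cell
#' population by PCA, robustified by iterative chi-square trimming: points
#' whose squared Mahalanobis distance exceeds the chi-square quantile (at
#' `trim_quantile`, with the retained dimensionality as degrees of freedom)
#' are excluded and the model refit, until the inlier set stabilizes or
#' `max_iter` is reached. Axes with variance below
#' `variance_floor * mean(variance)` are dropped from the retained set, so
#' rank-deficient (perfectly correlated) attribute sets reduce the model
#' dimension instead of exploding distances.
#'
#' Attributes are standardized by their control standard deviation before
#' the PCA: Mahalanobis distances are invariant to per-attribute rescaling
#' (full-rank case), and standardization makes the relative eigenvalue
#' floor meaningful when attributes live on very different scales
#' (areas in pixels next to intensity sums).
#'
#' @param controls control-cell records (data.frame with attribute columns,
#'   or numeric matrix).
#' @param trim_quantile chi-square probability beyond which a point is
#'   trimmed (default 0.975).
#' @param variance_floor relative eigenvalue floor (default 1e-6).
#' @param max_iter maximum trimming iterations (default 10).
#' @return object of class `control_model`: `attribute_names`, `center`,
#'   `axes` (orthonormal columns), `variances` (descending), `retained`
#'   (number of kept axes), `n_used`, `n_trimmed`, `trim_history`
#'   (trimmed count per iteration) and the fitting parameters.
#' @export
fit_control_model <- function(controls, trim_quantile = 0.975,
                              variance_floor = 1e-6, max_iter = 10) {
  x <- attribute_matrix(controls)
  n <- nrow(x); p <- ncol(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop_pheno("zero-variance attribute(s): %s",
               paste(colnames(x)[sds == 0], collapse = ", "))
  if (n <= p)
    stop_pheno("need more controls (%d) than attributes (%d)", n, p)
  x <- sweep(x, 2, sds, "/")
  inlier <- rep(TRUE, n)
  history <- integer()
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    if (sum(inlier) <= p)
      stop_pheno("trimming left %d controls for %d attributes; too few",
                 sum(inlier), p)
    consistency <- if (iter == 1) 1 else
      trim_consistency(trim_quantile, fit$d_prev %||% ncol(x))
    fit <- pca_fit(x[inlier, , drop = FALSE], variance_floor, consistency)
    fit$d_prev <- length(fit$retained)
    d2 <- sq_distance(x, fit)
    cutoff <- qchisq(trim_quantile, df = length(fit$retained))
    new_inlier <- d2 <= cutoff
    history <- c(history, sum(!new_inlier))
    if (identical(new_inlier, inlier)) break
    inlier <- new_inlier
  }
  structure(list(attribute_names = colnames(x), scale = sds,
                 center = fit$center,
                 axes = fit$axes, variances = fit$variances,
                 retained = length(fit$retained),
                 retained_idx = fit$retained,
                 trim_quantile = trim_quantile,
                 variance_floor = variance_floor,
                 trim_iterations = length(history),
                 n_used = sum(inlier), n_trimmed = sum(!inlier),
                 trim_history = history),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf(
    "Control model: %d attributes, %d retained axes; %d/%d controls used (%d trimmed in %d iterations)\n",
    length(x$attribute_names), x$retained, x$n_used,
    x$n_used + x$n_trimmed, x$n_trimmed, x$trim_iterations))
  invisible(x)
}

#' Mahalanobis score of cells against the control model
#'
#' Projects each record onto the retained principal axes and measures the
#' distance in axis-variance units:
#' `D = sqrt(sum_k y_k^2 / lambda_k)` with `y = V' (x - mu)`. Being a
#' distance, scores are always non-negative; a cell identical to the control
#' center scores 0.
#'
#' @param records cell records (data.frame or matrix) whose attributes match
#'   the model's.
#' @param model a [fit_control_model()] result.
#' @param squared return `D^2` instead of `D`.
#' @return numeric vector of distances.
#' @export
mahalanobis_score <- function(records, model, squared = FALSE) {
  stopifnot(inherits(model, "control_model"))
  x <- attribute_matrix(records, model$attribute_names)
  x <- sweep(x, 2, model$scale, "/")
  d2 <- sq_distance(x, list(center = model$center, axes = model$axes,
                            variances = model$variances,
                            retained = model$retained_idx))
  if (squared) d2 else sqrt(d2)
}

#' Per-attribute contributions to a cell's score
#'
#' Decomposes the squared Mahalanobis distance additively over attributes:
#' with `g = Sigma^+ (x - mu)` (pseudo-inverse through the retained axes),
#' the signed contribution of attribute j is
#' `c_j = (x - mu)_j * g_j / D^2`, and `sum_j c_j = 1` identically.
#' Ranking by `|c_j|` identifies the attributes a treatment changed most.
#'
#' @param record a single cell record (one-row data.frame, or named/plain
#'   numeric vector in model attribute order).
#' @param model a `control_model`.
#' @return named numeric vector of signed contributions summing to 1, with
#'   attribute `distance` carrying D.
#' @export
attribute_contributions <- function(record, model) {
  stopifnot(inherits(model, "control_model"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    x <- drop(attribute_matrix(record, model$attribute_names))
  } else {
    if (!is.null(names(record))) record <- record[model$attribute_names]
    x <- as.numeric(record)
  }
  if (length(x) != length(model$attribute_names) || anyNA(x))
    stop_pheno("record does not match the model's %d attributes",
               length(model$attribute_names))
  d <- x / model$scale - model$center
  V <- model$axes[, model$retained_idx, drop = FALSE]
  lam <- model$variances[model$retained_idx]
  g <- V %*% ((t(V) %*% d) / lam)
  d2 <- sum(d * g)
  # below ~1e-24 the record is the control center up to floating-point
  # round-off; a genuine distance of 1e-12 is already unmeasurably small
  if (d2 <= 1e-24)
    stop_pheno("record coincides with the control center (distance 0); contributions undefined")
  contr <- setNames(as.numeric(d * g) / d2, model$attribute_names)
  attr(contr, "distance") <- sqrt(d2)
  contr
}

#' Rank attribute contributions
#'
#' @param contributions result of [attribute_contributions()].
#' @return data.frame sorted by `|contribution|` descending.
#' @export
rank_contributions <- function(contributions) {
  ord <- order(abs(contributions), decreasing = TRUE)
  data.frame(attribute = names(contributions)[ord],
             contribution = as.numeric(contributions)[ord],
             stringsAsFactors = FALSE)
}

#' Flag outlier cells
#'
#' A record is flagged when its squared distance exceeds the chi-square
#' quantile (degrees of freedom = retained model dimension) at `quantile`.
#' Flags mark technical artifacts (bubbles, dead cells, clumps); records are
#' never deleted.
#'
#' @param records cell records.
#' @param model a `control_model`.
#' @param quantile flagging probability (default 0.999).
#' @return logical vector.
#' @export
flag_outliers <- function(records, model, quantile = 0.999) {
  d2 <- mahalanobis_score(records, model, squared = TRUE)
  d2 > qchisq(quantile, df = model$retained)
}

#' Aggregate cell scores to a well score
#'
#' Well score = median Mahalanobis distance over non-outlier cells (robust
#' to residual artifacts); dispersion = MAD. Outlier rejection targets
#' technical artifacts (bubbles, dead cells, clumps), which can only affect
#' a minority of a well's cells; when the chi-square rule would flag more
#' than half the well — a coherent treatment effect, not an artifact — the
#' median is taken over all cells instead, so saturating drug responses are
#' scored, not discarded.
#'
#' @param records the well's cell records.
#' @param model a `control_model`.
#' @param outlier_quantile passed to [flag_outliers()].
#' @param well well name carried through (optional).
#' @return one-row data.frame: `well`, `score`, `dispersion`, `n_cells`
#'   (non-outlier), `n_outliers`, `empty` (no usable cells; score `NA`).
#' @export
score_well <- function(records, model, outlier_quantile = 0.999,
                       well = NA_character_) {
  d <- mahalanobis_score(records, model)
  out <- d^2 > qchisq(outlier_quantile, df = model$retained)
  if (sum(out) > length(d) / 2) out[] <- FALSE
  keep <- d[!out]
  data.frame(well = well,
             score = if (length(keep)) median(keep) else NA_real_,
             dispersion = if (length(keep)) mad(keep) else NA_real_,
             n_cells = length(keep), n_outliers = sum(out),
             empty = length(keep) == 0, stringsAsFactors = FALSE)
}

#' Score every well of a plate against its pooled controls
#'
#' Fits the control model on the pooled cells of the layout's control wells
#' and scores all wells. Control pooling is per plate: each plate carries
#' its own controls.
#'
#' @param plate_records data.frame of cell records with a `well` column plus
#'   attribute columns (e.g. from [simulate_dose_response_plate()] or
#'   stacked [compute_attributes()] outputs).
#' @param layout the plate's `plate_layout`.
#' @param trim_quantile,variance_floor,max_iter control-model parameters.
#' @param outlier_quantile per-cell outlier flagging quantile.
#' @return object of class `plate_scores`: list with `model`, `well_scores`
#'   (data.frame, one row per scored well) and `grid` (plate-shaped score
#'   matrix aligned to the layout, NA where unscored).
#' @export
score_plate <- function(plate_records, layout, trim_quantile = 0.975,
                        variance_floor = 1e-6, max_iter = 10,
                        outlier_quantile = 0.999) {
  stopifnot(inherits(layout, "plate_layout"), "well" %in%
              colnames(plate_records))
  ctrl_wells <- layout$wells$well[layout$wells$role == "control"]
  if (!length(ctrl_wells))
    stop_pheno("layout has no control wells; cannot fit a control model")
  ctrl <- plate_records[plate_records$well %in% ctrl_wells, , drop = FALSE]
  if (!nrow(ctrl))
    stop_pheno("no cell records found in the %d control wells",
               length(ctrl_wells))
  model <- fit_control_model(ctrl, trim_quantile = trim_quantile,
                             variance_floor = variance_floor,
                             max_iter = max_iter)
  wells <- intersect(layout$wells$well, unique(plate_records$well))
  ws <- do.call(rbind, lapply(wells, function(w) {
    score_well(plate_records[plate_records$well == w, , drop = FALSE],
               model, outlier_quantile = outlier_quantile, well = w)
  }))
  grid <- matrix(NA_real_, layout$plate_rows, layout$plate_cols,
                 dimnames = list(LETTERS[seq_len(layout$plate_rows)],
                                 seq_len(layout$plate_cols)))
  pw <- parse_well(ws$well, layout$plate_rows, layout$plate_cols)
  grid[cbind(pw$row, pw$column)] <- ws$score
  structure(list(model = model, well_scores = ws, grid = grid,
                 plate_id = layout$plate_id),
            class = "plate_scores")
}

#' @export
print.plate_scores <- function(x, ...) {
  cat(sprintf("Plate scores '%s': %d wells scored, %d retained axes\n",
              x$plate_id, nrow(x$well_scores), x$model$retained))
  invisible(x)
}

#' Export a plate score grid as a heatmap PNG
#'
#' Spectral-palette heatmap of the plate-format score grid; the color-scale
#' bounds are returned and recorded so figures are comparable across plates.
#'
#' @param grid plate-shaped score matrix (e.g. `plate_scores$grid`).
#' @param path output PNG path.
#' @param zlim color-scale bounds (default data range).
#' @param main title.
#' @return list with `path` and `zlim`, invisibly.
#' @export
plot_plate_heatmap <- function(grid, path, zlim = NULL, main = "") {
  rng <- range(grid, na.rm = TRUE)
  zlim <- zlim %||% rng
  png(path, width = 900, height = 600)
  on.exit(dev.off())
  z <- t(grid)[, rev(seq_len(nrow(grid))), drop = FALSE]
  image(x = seq_len(ncol(grid)), y = seq_len(nrow(grid)), z = z,
        zlim = zlim, col = hcl.colors(64, "Spectral", rev = TRUE),
        xlab = "column", ylab = "", axes = FALSE, main = main)
  axis(1, at = seq_len(ncol(grid)))
  axis(2, at = seq_len(nrow(grid)), labels = rev(rownames(grid)), las = 1)
  box()
  invisible(list(path = path, zlim = zlim))
}

#' Serialize a control model to JSON
#'
#' Stores center, axes, variances, retained dimension and trim history;
#' [read_control_model()] restores a scoring-equivalent model.
#'
#' @param model a `control_model`.
#' @param path JSON path.
#' @return `read_control_model()` returns a `control_model`.
#' @export
write_control_model <- function(model, path) {
  stopifnot(inherits(model, "control_model"))
  write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  j <- read_json(path, simplifyVector = TRUE)
  p <- length(j$attribute_names)
  j$axes <- matrix(as.numeric(j$axes), p, p)
  j$center <- setNames(as.numeric(j$center), j$attribute_names)
  structure(j, class = "control_model")
}
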