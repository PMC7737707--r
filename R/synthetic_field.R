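# Rendered toy image fields: convex (elliptical) cells with bright concentric
# nuclei and line-segment fibers on a noisy background, with full ground
# truth, so segmentation and feature extraction are testable without raw
# screen images.

#' Specify a synthetic image field
#'
#' @param field_size `c(height, width)` in pixels.
#' @param n_cells number of cells to place (>= 0).
#' @param cell_radius_range `c(min, max)` semi-major axis in pixels.
#' @param nucleus_radius_fraction nucleus disk radius as a fraction of the
#'   cell's semi-minor axis.
#' @param eccentricity_max maximum ellipse eccentricity (default 0.8).
#' @param fiber_count_range `c(min, max)` fibers per cell per cytoskeletal
#'   channel.
#' @param channel_intensities named amplitudes above background:
#'   `nucleus` (nucleus disk in the nucleus channel), `cyto` (cell body in
#'   actin/tubulin and, attenuated, in the nucleus channel), `fiber`
#'   (added on fiber pixels).
#' @param background_level background intensity.
#' @param noise_sd Gaussian pixel noise sd (0 = noiseless).
#' @param margin minimum gap in pixels between cell boundaries (cells are
#'   placed without overlap).
#' @param max_retries placement retries per cell before the packing is
#'   declared infeasible.
#' @return object of class `image_sim_spec`.
#' @export
image_sim_spec <- function(field_size = c(256, 256), n_cells = 8,
                           cell_radius_range = c(14, 22),
                           nucleus_radius_fraction = 0.4,
                           eccentricity_max = 0.8,
                           fiber_count_range = c(2, 5),
                           channel_intensities = c(nucleus = 400,
                                                   cyto = 250, fiber = 250),
                           background_level = 100, noise_sd = 2,
                           margin = 3, max_retries = 200) {
  stopifnot(length(field_size) == 2, all(field_size >= 16),
            n_cells >= 0, cell_radius_range[1] > 0,
            cell_radius_range[2] >= cell_radius_range[1],
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            eccentricity_max >= 0, eccentricity_max < 1,
            all(channel_intensities >= 0), background_level >= 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "image_sim_spec")
}

# Pixels inside a rotated ellipse; coordinates are 1-based (row, col).
ellipse_pixels <- function(cx, cy, a, b, theta, H, W) {
  x0 <- max(1L, floor(cx - a)); x1 <- min(W, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(H, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(ys, times = length(xs))[keep],
        col = rep(xs, each = length(ys))[keep])
}

# Rasterize a thick segment: pixels within `halfwidth` of the segment
# p0 + t*dir, t in [t0, t1].
segment_pixels <- function(px, py, dx, dy, t0, t1, halfwidth, H, W) {
  x0 <- px + t0 * dx; y0 <- py + t0 * dy
  x1 <- px + t1 * dx; y1 <- py + t1 * dy
  xr <- c(max(1, floor(min(x0, x1) - halfwidth)),
          min(W, ceiling(max(x0, x1) + halfwidth)))
  yr <- c(max(1, floor(min(y0, y1) - halfwidth)),
          min(H, ceiling(max(y0, y1) + halfwidth)))
  if (xr[1] > xr[2] || yr[1] > yr[2]) return(cbind(row = integer(), col = integer()))
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  t <- pmin(pmax((gx - x0) * (x1 - x0) + (gy - y0) * (y1 - y0), 0),
            (x1 - x0)^2 + (y1 - y0)^2)
  len2 <- (x1 - x0)^2 + (y1 - y0)^2
  tt <- if (len2 > 0) t / len2 else 0
  dist2 <- (gx - (x0 + tt * (x1 - x0)))^2 + (gy - (y0 + tt * (y1 - y0)))^2
  keep <- dist2 <= halfwidth^2
  cbind(row = gy[keep], col = gx[keep])
}

#' Render a synthetic three-channel field with ground truth
#'
#' Places `n_cells` non-overlapping elliptical cells, draws each as a filled
#' body in the cytoplasmic channels with a brighter concentric nucleus disk
#' in the nucleus channel and random line-segment fibers in the actin and
#' tubulin channels, then adds Gaussian noise. The returned ground truth
#' holds disjoint per-cell label masks and per-cell true geometry,
#' fiber lengths and background-free channel intensities.
#'
#' @param spec an [image_sim_spec()].
#' @param seed integer seed; fixed `(spec, seed)` gives bit-identical output.
#' @return object of class `synthetic_field`: list with `channels`
#'   (`nucleus`, `actin`, `tubulin` matrices), `masks` (`cells`, `nuclei`
#'   integer label matrices), `truth` (per-cell data.frame) and `seed`.
#' @export
render_synthetic_field <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "image_sim_spec"))
  H <- spec$field_size[1]; W <- spec$field_size[2]
  amp <- spec$channel_intensities
  with_seed(seed, {
    cells <- matrix(0L, H, W)
    nuclei <- matrix(0L, H, W)
    ch0 <- list(nucleus = matrix(0, H, W), actin = matrix(0, H, W),
                tubulin = matrix(0, H, W))
    truth <- list()
    placed <- 0L
    for (k in seq_len(spec$n_cells)) {
      ok <- FALSE
      for (try in seq_len(spec$max_retries)) {
        a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        e <- runif(1, 0, spec$eccentricity_max)
        b <- a * sqrt(1 - e^2)
        theta <- runif(1, 0, pi)
        cx <- runif(1, a + 2, W - a - 1)
        cy <- runif(1, a + 2, H - a - 1)
        px <- ellipse_pixels(cx, cy, a + spec$margin, b + spec$margin,
                             theta, H, W)
        if (any(cells[px] != 0L)) next
        body <- ellipse_pixels(cx, cy, a, b, theta, H, W)
        cells[body] <- k
        rn <- spec$nucleus_radius_fraction * b
        nuc <- ellipse_pixels(cx, cy, rn, rn, 0, H, W)
        nuclei[nuc] <- k
        ch0$nucleus[body] <- ch0$nucleus[body] + 0.15 * amp[["nucleus"]]
        ch0$nucleus[nuc] <- ch0$nucleus[nuc] + amp[["nucleus"]]
        ch0$actin[body] <- ch0$actin[body] + amp[["cyto"]]
        ch0$tubulin[body] <- ch0$tubulin[body] + amp[["cyto"]]
        fib_len <- c(actin = 0, tubulin = 0)
        for (chn in c("actin", "tubulin")) {
          nf <- sample(spec$fiber_count_range[1]:spec$fiber_count_range[2], 1)
          for (f in seq_len(nf)) {
            phi <- runif(1, 0, pi)
            rr <- runif(1, 0, 0.5)
            pu <- rr * a * cos(runif(1, 0, 2 * pi))
            pv <- rr * b * sin(runif(1, 0, 2 * pi))
            fx <- cx + pu * cos(theta) - pv * sin(theta)
            fy <- cy + pu * sin(theta) + pv * cos(theta)
            # clip the line (fx,fy) + t*(cos phi, sin phi) to the ellipse
            du <- cos(phi) * cos(theta) + sin(phi) * sin(theta)
            dv <- -cos(phi) * sin(theta) + sin(phi) * cos(theta)
            u0 <- (fx - cx) * cos(theta) + (fy - cy) * sin(theta)
            v0 <- -(fx - cx) * sin(theta) + (fy - cy) * cos(theta)
            A2 <- (du / a)^2 + (dv / b)^2
            B2 <- 2 * (u0 * du / a^2 + v0 * dv / b^2)
            C2 <- (u0 / a)^2 + (v0 / b)^2 - 1
            disc <- B2^2 - 4 * A2 * C2
            if (disc <= 0) next
            t1 <- (-B2 - sqrt(disc)) / (2 * A2)
            t2 <- (-B2 + sqrt(disc)) / (2 * A2)
            # keep the fiber inside the body with a 1 px margin
            t1 <- t1 * 0.95; t2 <- t2 * 0.95
            seg <- segment_pixels(fx, fy, cos(phi), sin(phi), t1, t2, 1, H, W)
            seg <- seg[cells[seg] == k, , drop = FALSE]
            ch0[[chn]][seg] <- ch0[[chn]][seg] + amp[["fiber"]]
            fib_len[[chn]] <- fib_len[[chn]] + (t2 - t1)
          }
        }
        truth[[k]] <- data.frame(
          cell = k, cx = cx, cy = cy, semi_major = a, semi_minor = b,
          theta = theta, long_axis = 2 * a, area = nrow(body),
          nuc_area = nrow(nuc), act_fib_len = fib_len[["actin"]],
          tub_fib_len = fib_len[["tubulin"]])
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok)
        stop_pheno("could not place cell %d of %d after %d retries (packing infeasible)",
                   k, spec$n_cells, spec$max_retries)
    }
    truth <- if (placed) do.call(rbind, truth) else NULL
    # background-free true intensities from the noiseless render
    if (placed) {
      for (chn in names(ch0)) {
        truth[[paste0(substr(chn, 1, 3), "_totint")]] <- vapply(
          seq_len(placed),
          function(k) sum(ch0[[chn]][cells == k]), numeric(1))
      }
    }
    channels <- lapply(ch0, function(m) {
      m <- m + spec$background_level
      if (spec$noise_sd > 0)
        m <- pmax(m + matrix(rnorm(H * W, 0, spec$noise_sd), H, W), 0)
      m
    })
  })
  structure(list(channels = channels,
                 masks = list(cells = cells, nuclei = nuclei),
                 truth = truth, spec = spec, seed = seed),
            class = "synthetic_field")
}

#' Write a synthetic field as 16-bit TIFFs plus a ground-truth sidecar
#'
#' One single-channel 16-bit TIFF per channel
#' (`<prefix>_<channel>.tif`) and a JSON sidecar
#' (`<prefix>_truth.json`) holding the seed, rendering parameters and the
#' per-cell ground-truth table.
#'
#' @param field a `synthetic_field`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"field"`).
#' @param scale intensity mapped to the 16-bit ceiling (default 4095,
#'   a 12-bit camera range).
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic_field <- function(field, dir, prefix = "field",
                                  scale = 4095) {
  stopifnot(inherits(field, "synthetic_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (chn in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, chn))
    writeTIFF(pmin(field$channels[[chn]] / scale, 1), p,
              bits.per.sample = 16)
    paths[chn] <- p
  }
  tp <- file.path(dir, sprintf("%s_truth.json", prefix))
  write_json(list(seed = field$seed, scale = scale,
                  field_size = field$spec$field_size,
                  n_cells = field$spec$n_cells,
                  background_level = field$spec$background_level,
                  noise_sd = field$spec$noise_sd,
                  truth = field$truth),
             tp, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tp
  invisible(paths)
}
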