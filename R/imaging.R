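# Segmentation of nuclei and whole cells from three-channel fields and
# per-cell attribute quantification. Strategies follow the field's standard
# recipe: smoothed Otsu threshold + distance-transform watershed for nuclei,
# nucleus-seeded propagation on the cytoplasmic channel for cells, top-hat
# ridge enhancement + skeletonization for fibers.

#' Construct a three-channel field image
#'
#' @param nucleus,actin,tubulin numeric matrices of equal shape with finite,
#'   non-negative intensities.
#' @param pixel_size physical pixel size (optional, carried as metadata).
#' @param plate,well,field provenance labels.
#' @return object of class `field_image`.
#' @export
field_image <- function(nucleus, actin, tubulin, pixel_size = NA_real_,
                        plate = NA_character_, well = NA_character_,
                        field = NA_integer_) {
  ch <- list(nucleus = nucleus, actin = actin, tubulin = tubulin)
  dims <- lapply(ch, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop_pheno("channels must share one shape")
  for (nm in names(ch))
    if (!all(is.finite(ch[[nm]])) || any(ch[[nm]] < 0))
      stop_pheno("channel '%s' must be finite and >= 0", nm)
  structure(list(channels = ch, pixel_size = pixel_size,
                 provenance = list(plate = plate, well = well,
                                   field = field)),
            class = "field_image")
}

#' Read a field image from TIFF files
#'
#' Accepts either one path per channel (single-channel TIFFs) or a single
#' multi-page TIFF with a page index per channel.
#'
#' @param nucleus,actin,tubulin file paths, or page indices when `path` is
#'   given.
#' @param path optional multi-page TIFF holding all channels.
#' @param scale factor mapping the TIFF's `[0, 1]` sample range back to
#'   intensities (default 4095; use the value recorded by
#'   [write_synthetic_field()]).
#' @param ... provenance arguments passed to [field_image()].
#' @return a `field_image`.
#' @export
read_field_image <- function(nucleus, actin, tubulin, path = NULL,
                             scale = 4095, ...) {
  get1 <- function(x) {
    if (is.null(path)) {
      m <- readTIFF(x)
    } else {
      pages <- readTIFF(path, all = TRUE)
      m <- pages[[x]]
    }
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * scale
  }
  field_image(get1(nucleus), get1(actin), get1(tubulin), ...)
}

#' Estimate the field background of a channel
#'
#' The per-field, per-channel background subtracted from `_Bck` attributes:
#' the median intensity over pixels outside every segmented cell (label 0).
#' The median is robust to dim halos around cells.
#'
#' @param channel intensity matrix.
#' @param cell_mask integer label mask (0 = background).
#' @return background intensity (scalar).
#' @export
estimate_background <- function(channel, cell_mask) {
  stopifnot(identical(dim(channel), dim(cell_mask)))
  bg <- channel[cell_mask == 0]
  if (length(bg) == 0)
    stop_pheno("no background pixels (mask covers the whole field)")
  median(bg)
}

normalize01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0
}

relabel_mask <- function(m, keep = NULL) {
  labs <- sort(unique(m[m > 0]))
  if (!is.null(keep)) labs <- labs[labs %in% keep]
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_along(labs)) out[m == labs[i]] <- i
  out
}

#' Segment nuclei from the nucleus channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, a
#' distance-transform watershed to split touching nuclei, and an area filter.
#'
#' @param nucleus_channel intensity matrix.
#' @param min_area,max_area retained object area range in pixels.
#' @param sigma Gaussian smoothing sd in pixels (default 2).
#' @param tolerance watershed tolerance (default 1).
#' @return integer label mask (`0` = background, labels contiguous from 1).
#' @export
segment_nuclei <- function(nucleus_channel, min_area = 50, max_area = 5000,
                           sigma = 2, tolerance = 1) {
  xn <- normalize01(nucleus_channel)
  sm <- as.matrix(EBImage::gblur(xn, sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  # a fluorescence-free field must come back empty: Otsu always splits the
  # histogram, so require the threshold to clear the background mode by
  # three noise MADs in raw units before accepting any object
  rng <- range(nucleus_channel)
  thr_raw <- thr * (rng[2] - rng[1]) + rng[1]
  if (thr_raw <= median(nucleus_channel) + 3 * mad(nucleus_channel))
    return(matrix(0L, nrow(nucleus_channel), ncol(nucleus_channel)))
  bin <- sm > thr
  bin <- as.matrix(EBImage::fillHull(EBImage::Image(bin * 1)))
  if (!any(bin > 0)) return(matrix(0L, nrow(bin), ncol(bin)))
  dm <- EBImage::distmap(EBImage::Image(bin))
  wt <- as.matrix(EBImage::watershed(dm, tolerance = tolerance, ext = 1))
  areas <- tabulate(wt[wt > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  relabel_mask(wt, keep)
}

#' Segment whole cells by nucleus-seeded propagation
#'
#' Grows one cell region per nucleus seed over an above-background
#' foreground mask of the cytoplasmic channel (diffuse monomer fluorescence
#' covers the whole cell), so abutting cells in dense islands are divided
#' along intensity valleys. Every retained nucleus yields exactly one cell
#' region that contains it.
#'
#' @param cyto_channel cytoplasmic intensity matrix (actin, tubulin or their
#'   sum).
#' @param nucleus_labels label mask from [segment_nuclei()].
#' @param sigma smoothing sd for the foreground threshold (default 1:
#'   light smoothing keeps the thresholded boundary close to the true cell
#'   edge; heavier smoothing biases the global threshold when bright
#'   fibers add a third intensity mode and erodes small cells).
#' @param lambda regularization of the propagation metric (weight of
#'   geometric distance against intensity difference).
#' @return integer label mask sharing the nucleus labels; nuclei whose seed
#'   fell mostly outside the foreground are flagged in
#'   `attr(, "flagged_nuclei")` (their region is still grown, not dropped).
#' @export
segment_cells <- function(cyto_channel, nucleus_labels, sigma = 1,
                          lambda = 1e-4) {
  stopifnot(identical(dim(cyto_channel), dim(nucleus_labels)))
  if (!any(nucleus_labels > 0)) {
    out <- matrix(0L, nrow(cyto_channel), ncol(cyto_channel))
    attr(out, "flagged_nuclei") <- integer()
    return(out)
  }
  xn <- normalize01(cyto_channel)
  sm <- as.matrix(EBImage::gblur(xn, sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  fg <- sm > thr
  labs <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  frac_in <- vapply(labs, function(k) mean(fg[nucleus_labels == k]),
                    numeric(1))
  flagged <- labs[frac_in < 0.5]
  fg <- fg | nucleus_labels > 0   # seeds always belong to their own cell
  cells <- EBImage::propagate(EBImage::Image(sm),
                              seeds = EBImage::Image(nucleus_labels),
                              mask = EBImage::Image(fg * 1) > 0,
                              lambda = lambda)
  out <- matrix(as.integer(as.matrix(cells)), nrow(cyto_channel),
                ncol(cyto_channel))
  attr(out, "flagged_nuclei") <- as.integer(flagged)
  out
}

# Zhang-Suen binary thinning; input/output logical matrices.
thin_mask <- function(mask, max_iter = 200) {
  p <- mask
  H <- nrow(p); W <- ncol(p)
  pad <- function(m) {
    out <- matrix(FALSE, H + 2, W + 2)
    out[2:(H + 1), 2:(W + 1)] <- m
    out
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (sub in 1:2) {
      q <- pad(p)
      idx <- 2:(H + 1); jdx <- 2:(W + 1)
      p2 <- q[idx - 1, jdx];     p3 <- q[idx - 1, jdx + 1]
      p4 <- q[idx, jdx + 1];     p5 <- q[idx + 1, jdx + 1]
      p6 <- q[idx + 1, jdx];     p7 <- q[idx + 1, jdx - 1]
      p8 <- q[idx, jdx - 1];     p9 <- q[idx - 1, jdx - 1]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- p & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- p & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

# Path length of a skeleton: orthogonal links count 1, diagonal links
# sqrt(2); diagonal links short-circuited by an orthogonal neighbour are not
# double counted. Thinning erodes roughly one pixel from each fiber end, so
# each skeleton endpoint (exactly one 8-neighbour) gets a +1 px correction.
skeleton_length <- function(s) {
  H <- nrow(s); W <- ncol(s)
  if (!any(s)) return(0)
  h <- sum(s[, -W] & s[, -1])
  v <- sum(s[-H, ] & s[-1, ])
  d1 <- s[-H, -W] & s[-1, -1]
  d1 <- d1 & !(s[-1, -W] | s[-H, -1])
  d2 <- s[-1, -W] & s[-H, -1]
  d2 <- d2 & !(s[-H, -W] | s[-1, -1])
  q <- matrix(FALSE, H + 2, W + 2)
  q[2:(H + 1), 2:(W + 1)] <- s
  idx <- 2:(H + 1); jdx <- 2:(W + 1)
  nb <- q[idx - 1, jdx] + q[idx + 1, jdx] + q[idx, jdx - 1] +
    q[idx, jdx + 1] + q[idx - 1, jdx - 1] + q[idx - 1, jdx + 1] +
    q[idx + 1, jdx - 1] + q[idx + 1, jdx + 1]
  endpoints <- sum(s & nb == 1)
  h + v + sqrt(2) * (sum(d1) + sum(d2)) + endpoints
}

#' Extract cytoskeletal fibers per cell
#'
#' Ridge-like thin bright structures are enhanced with a white top-hat
#' filter, thresholded robustly at `median + k * MAD` of the response
#' inside cells (floored at 30% of the 99th-percentile response, so
#' fiber-dense cells where fibers dominate the response distribution are
#' still segmented at the single-fiber plateau), skeletonized, and
#' summarized per cell as total skeleton length (diagonal steps weighted
#' sqrt(2)) and summed background-subtracted fiber-pixel intensity.
#'
#' @param channel intensity matrix (actin or tubulin).
#' @param cell_mask integer cell label mask.
#' @param background background level; estimated with
#'   [estimate_background()] when `NULL`.
#' @param brush_size top-hat structuring-element diameter in pixels
#'   (default 7, suppressing structures wider than ~3 px scales).
#' @param k threshold offset in response-MAD units (default 3).
#' @return data.frame with `cell`, `fiber_len` (pixels), `fiber_int`
#'   (background-subtracted summed intensity over fiber pixels).
#' @export
extract_fibers <- function(channel, cell_mask, background = NULL,
                           brush_size = 7, k = 3) {
  stopifnot(identical(dim(channel), dim(cell_mask)))
  labs <- sort(unique(cell_mask[cell_mask > 0]))
  if (!length(labs))
    return(data.frame(cell = integer(), fiber_len = numeric(),
                      fiber_int = numeric()))
  bg <- background %||% estimate_background(channel, cell_mask)
  xn <- normalize01(channel)
  resp <- as.matrix(EBImage::whiteTopHat(
    EBImage::Image(xn), EBImage::makeBrush(brush_size, "disc")))
  inside <- cell_mask > 0
  r_in <- resp[inside]
  thr <- max(median(r_in) + k * mad(r_in),
             0.3 * quantile(r_in, 0.99), 1e-9)
  fib <- resp > thr & inside
  skel <- thin_mask(fib)
  out <- lapply(labs, function(lab) {
    sel <- cell_mask == lab
    fl <- skeleton_length(skel & sel)
    fpx <- fib & sel
    data.frame(cell = lab, fiber_len = fl,
               fiber_int = sum(channel[fpx]) - bg * sum(fpx))
  })
  do.call(rbind, out)
}

#' Quantify the per-cell attribute vector
#'
#' Computes, for every cell region, the full attribute vector used by the
#' scoring module: morphology (area, long axis of the best-fit ellipse from
#' second moments), nucleus morphology and intensity, background-subtracted
#' total/average/cytoplasmic intensities per cytoskeletal channel, fiber
#' length and intensity, tubulin texture (within-cell coefficient of
#' variation) and the nucleus/cytoplasm intensity ratio in the nucleus
#' channel.
#'
#' @param cells integer cell label mask.
#' @param nuclei integer nucleus label mask sharing the cell labels.
#' @param field a [field_image()].
#' @return data.frame with provenance columns (`plate`, `well`, `field`,
#'   `cell`), one attribute column per [attribute_names()] entry, and flag
#'   columns `flag_no_nucleus` and `flag_negative` (background-subtracted
#'   mean below minus three noise SDs). Cells without a nucleus are flagged,
#'   not dropped.
#' @export
compute_attributes <- function(cells, nuclei, field) {
  stopifnot(inherits(field, "field_image"),
            identical(dim(cells), dim(field$channels$nucleus)))
  labs <- sort(unique(cells[cells > 0]))
  an <- attribute_names()
  if (!length(labs)) {
    out <- cbind(data.frame(plate = character(), well = character(),
                            field = integer(), cell = integer()),
                 as.data.frame(matrix(numeric(), 0, length(an),
                                      dimnames = list(NULL, an))),
                 data.frame(flag_no_nucleus = logical(),
                            flag_negative = logical()))
    return(out)
  }
  ch <- field$channels
  bg <- lapply(ch, estimate_background, cell_mask = cells)
  noise <- lapply(ch, function(m) mad(m[cells == 0]))
  fib_act <- extract_fibers(ch$actin, cells, background = bg$actin)
  fib_tub <- extract_fibers(ch$tubulin, cells, background = bg$tubulin)
  rows <- lapply(labs, function(lab) {
    sel <- cells == lab
    nsel <- nuclei == lab & sel
    csel <- sel & !nsel          # cytoplasm = cell minus nucleus
    area <- sum(sel)
    ij <- which(sel, arr.ind = TRUE)
    long_axis <- 4 * sqrt(max(eigen(cov(ij), symmetric = TRUE,
                                    only.values = TRUE)$values))
    has_nuc <- any(nsel)
    a <- setNames(rep(NA_real_, length(an)), an)
    a["Cell_Area"] <- area
    a["Cell_LongAxis"] <- long_axis
    if (has_nuc) {
      a["Nuc_Area"] <- sum(nsel)
      a["Nuc_TotInt"] <- sum(ch$nucleus[nsel])
      a["Nuc_AvgInt"] <- mean(ch$nucleus[nsel])
      a["Nuc_Cyto_Ratio"] <- mean(ch$nucleus[nsel]) /
        mean(ch$nucleus[csel])
    }
    for (pre in c("Act", "Tub")) {
      m <- if (pre == "Act") ch$actin else ch$tubulin
      b <- if (pre == "Act") bg$actin else bg$tubulin
      a[paste0(pre, "_TotInt_Bck")] <- sum(m[sel]) - b * area
      a[paste0(pre, "_AvgInt_Bck")] <- a[paste0(pre, "_TotInt_Bck")] / area
      a[paste0(pre, "_CelInt_Bck")] <- sum(m[csel]) - b * sum(csel)
    }
    a["Act_Fib_Len"] <- fib_act$fiber_len[fib_act$cell == lab]
    a["Act_Fib_CelInt_Bck"] <- fib_act$fiber_int[fib_act$cell == lab]
    a["Tub_Fib_Len"] <- fib_tub$fiber_len[fib_tub$cell == lab]
    a["Tub_Texture"] <- sd(ch$tubulin[sel]) / mean(ch$tubulin[sel])
    flag_neg <- isTRUE(a["Act_AvgInt_Bck"] < -3 * noise$actin ||
                         a["Tub_AvgInt_Bck"] < -3 * noise$tubulin)
    cbind(data.frame(plate = field$provenance$plate,
                     well = field$provenance$well,
                     field = field$provenance$field, cell = lab,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(a)),
          data.frame(flag_no_nucleus = !has_nuc, flag_negative = flag_neg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write per-cell record tables
#'
#' CSV with provenance columns first, then the attribute columns.
#'
#' @param records data.frame from [compute_attributes()] or the simulators.
#' @param path CSV path.
#' @return `read_cell_records()` returns the data.frame.
#' @export
write_cell_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
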