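# Plate-layout modelling for 384-well screens: dilution series, duplicate
# geometry, control wells, binary-combination matrices and "virtual plate"
# assembly with duplicate averaging.

PLATE_ROW_LETTERS <- LETTERS[1:16]

#' Well addresses
#'
#' Wells are addressed `"A1"`..`"P24"` on the default 384-well (16 x 24)
#' plate. `well_name()` builds names from row/column indices and
#' `parse_well()` inverts it.
#'
#' @param row integer row index (1 = A) or letter.
#' @param column integer column index (1-based).
#' @param plate_rows,plate_cols plate dimensions (default 16 x 24 = 384).
#' @return `well_name()`: character; `parse_well()`: data.frame with `row`
#'   and `column` integer columns.
#' @examples
#' well_name(1, 1)       # "A1"
#' parse_well("P24")
#' @export
well_name <- function(row, column, plate_rows = 16, plate_cols = 24) {
  if (is.character(row)) row <- match(toupper(row), LETTERS)
  if (any(is.na(row)) || any(row < 1) || any(row > plate_rows))
    stop_pheno("row out of bounds for a %d-row plate", plate_rows)
  if (any(column < 1) || any(column > plate_cols))
    stop_pheno("column out of bounds for a %d-column plate", plate_cols)
  paste0(LETTERS[row], column)
}

#' @rdname well_name
#' @param well character vector of well names such as `"B12"`.
#' @export
parse_well <- function(well, plate_rows = 16, plate_cols = 24) {
  m <- regmatches(well, regexec("^([A-Pa-p])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop_pheno("malformed well name(s): %s",
               paste(well[bad], collapse = ", "))
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS)
  column <- as.integer(vapply(m, `[`, "", 3L))
  if (any(row > plate_rows) || any(column > plate_cols))
    stop_pheno("well outside the %dx%d plate: %s", plate_rows, plate_cols,
               paste(well[row > plate_rows | column > plate_cols],
                     collapse = ", "))
  data.frame(well = well, row = row, column = column,
             stringsAsFactors = FALSE)
}

#' Build a serial dilution series
#'
#' A dilution series starts at `start` and divides by `fold` at each of
#' `n_levels` levels, the geometry used throughout the screen (ten 3-fold
#' dilutions per drug row; five 2-fold dilutions per combination ladder).
#'
#' @param start starting (highest) concentration, > 0. Unitless from the
#'   function's point of view; the `unit` attribute is carried along.
#' @param fold dilution factor between consecutive levels, > 1.
#' @param n_levels number of levels, >= 1.
#' @param unit concentration unit label (default `"uM"`).
#' @return An object of class `dilution_series`: list with `start`, `fold`,
#'   `n_levels`, `unit` and `concentrations` (strictly decreasing,
#'   `concentrations[k] = start / fold^(k-1)`).
#' @examples
#' build_dilution_series(4, 2, 5)$concentrations  # 4 2 1 0.5 0.25
#' @export
build_dilution_series <- function(start, fold, n_levels, unit = "uM") {
  check_number(start, "start", positive = TRUE)
  check_number(fold, "fold")
  if (fold <= 1) stop_pheno("`fold` must be > 1, got %g", fold)
  check_number(n_levels, "n_levels", min = 1)
  n_levels <- as.integer(n_levels)
  structure(list(start = start, fold = fold, n_levels = n_levels,
                 unit = unit,
                 concentrations = start / fold^(seq_len(n_levels) - 1)),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Dilution series: %d levels, %g-fold, %g..%g %s\n",
              x$n_levels, x$fold, x$start,
              x$concentrations[x$n_levels], x$unit))
  invisible(x)
}

#' Screen annotation for one drug
#'
#' Carries the reference GI50 scale used to anchor screening doses, the
#' starting multiple (the screen starts each dilution row at
#' `start_multiple * gi50`, default 10) and optionally the column index of
#' half effect used by [column_to_concentration()].
#'
#' @param drug_id drug label.
#' @param gi50 reference GI50 concentration (molar), > 0.
#' @param start_multiple starting dose as a multiple of GI50 (default 10).
#' @param dm_column optional column index of half effect (>= 1).
#' @return An object of class `screen_annotation`.
#' @export
screen_annotation <- function(drug_id, gi50, start_multiple = 10,
                              dm_column = NULL) {
  check_number(gi50, "gi50", positive = TRUE)
  check_number(start_multiple, "start_multiple", positive = TRUE)
  if (!is.null(dm_column)) check_number(dm_column, "dm_column", min = 1)
  structure(list(drug_id = as.character(drug_id), gi50 = gi50,
                 start_multiple = start_multiple, dm_column = dm_column),
            class = "screen_annotation")
}

#' Convert a half-effect column index to a concentration
#'
#' Screens that arrange 3-fold dilution series in duplicate columns report
#' the median-effect position as a column index Dm; the corresponding
#' concentration is `10 * GI50 * 3^(1 - Dm/2)`.
#'
#' @param annotation a [screen_annotation()] with `gi50` and `dm_column` set.
#' @return concentration on the GI50 scale (same units as `gi50`).
#' @examples
#' column_to_concentration(screen_annotation("x", 1, dm_column = 2))  # 10
#' @export
column_to_concentration <- function(annotation) {
  stopifnot(inherits(annotation, "screen_annotation"))
  if (is.null(annotation$dm_column))
    stop_pheno("annotation for '%s' has no `dm_column`", annotation$drug_id)
  10 * annotation$gi50 * 3^(1 - annotation$dm_column / 2)
}

new_plate_layout <- function(plate_id, wells, plate_rows, plate_cols) {
  layout <- structure(list(plate_id = plate_id, plate_rows = plate_rows,
                           plate_cols = plate_cols, wells = wells),
                      class = "plate_layout")
  validate_plate_layout(layout)
}

validate_plate_layout <- function(layout) {
  w <- layout$wells
  need <- c("well", "row", "column", "role", "drug_1", "conc_1",
            "drug_2", "conc_2", "replicate_group")
  if (!all(need %in% names(w)))
    stop_pheno("layout table missing column(s): %s",
               paste(setdiff(need, names(w)), collapse = ", "))
  if (anyDuplicated(w$well))
    stop_pheno("wells assigned more than once: %s",
               paste(unique(w$well[duplicated(w$well)]), collapse = ", "))
  if (any(w$row < 1 | w$row > layout$plate_rows |
          w$column < 1 | w$column > layout$plate_cols))
    stop_pheno("well outside the %dx%d plate", layout$plate_rows,
               layout$plate_cols)
  if (!all(w$role %in% c("control", "treated", "empty")))
    stop_pheno("unknown role(s): %s",
               paste(setdiff(unique(w$role), c("control", "treated", "empty")),
                     collapse = ", "))
  tr <- w$role == "treated"
  if (any(tr & (is.na(w$drug_1) | is.na(w$conc_1) | w$conc_1 <= 0)))
    stop_pheno("treated wells must name a drug with a positive concentration")
  if (any(tr & !is.na(w$drug_2) & (is.na(w$conc_2) | w$conc_2 <= 0)))
    stop_pheno("second drug present without a positive concentration")
  ctrl <- w$role == "control"
  if (any(ctrl & (!is.na(w$drug_1) | !is.na(w$drug_2))))
    stop_pheno("control wells must carry no drug")
  if (any(!is.na(w$replicate_group) & !nzchar(w$replicate_group)))
    stop_pheno("empty replicate_group label")
  layout
}

#' @export
print.plate_layout <- function(x, ...) {
  tab <- table(x$wells$role)
  cat(sprintf("Plate layout '%s' (%dx%d): %s\n", x$plate_id, x$plate_rows,
              x$plate_cols,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  invisible(x)
}

#' Build a single-agent screening layout
#'
#' Arranges one dilution series per drug along a plate row, each
#' concentration replicated in `duplicates` adjacent columns, with the listed
#' control wells. Drug `i` occupies row `i`; level `k` occupies columns
#' `(k-1)*duplicates + 1 .. k*duplicates`.
#'
#' @param drugs list of [screen_annotation()] objects (possibly empty).
#' @param fold dilution factor (default 3).
#' @param n_levels dilution levels per drug (default 10).
#' @param duplicates replicate wells per concentration (default 2).
#' @param control_wells character vector of well names to mark as controls.
#' @param plate_id plate label.
#' @param plate_rows,plate_cols plate dimensions.
#' @param gi50_unit unit in which annotation `gi50` values are expressed
#'   (default molar); concentrations are stored in molar.
#' @return a `plate_layout`.
#' @export
build_screen_layout <- function(drugs, fold = 3, n_levels = 10,
                                duplicates = 2, control_wells = character(),
                                plate_id = "plate1", plate_rows = 16,
                                plate_cols = 24, gi50_unit = "M") {
  stopifnot(all(vapply(drugs, inherits, TRUE, "screen_annotation")))
  n_drugs <- length(drugs)
  series_wells <- n_levels * duplicates
  if (series_wells > plate_cols)
    stop_pheno("a series of %d levels x %d duplicates needs %d columns; the plate has %d",
               n_levels, duplicates, series_wells, plate_cols)
  if (n_drugs > plate_rows)
    stop_pheno("%d drugs need %d rows; the plate has %d (capacity %d treated wells)",
               n_drugs, n_drugs, plate_rows, plate_rows * series_wells)
  rows <- list()
  for (i in seq_len(n_drugs)) {
    ann <- drugs[[i]]
    series <- build_dilution_series(
      to_molar(ann$start_multiple * ann$gi50, gi50_unit), fold, n_levels,
      unit = "M")
    for (k in seq_len(n_levels)) {
      cols <- (k - 1) * duplicates + seq_len(duplicates)
      rows[[length(rows) + 1L]] <- data.frame(
        well = well_name(i, cols, plate_rows, plate_cols),
        row = i, column = cols, role = "treated",
        drug_1 = ann$drug_id, conc_1 = series$concentrations[k],
        drug_2 = NA_character_, conc_2 = NA_real_,
        replicate_group = sprintf("%s_L%02d", ann$drug_id, k),
        stringsAsFactors = FALSE)
    }
  }
  treated <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(), row = integer(), column = integer(),
               role = character(), drug_1 = character(), conc_1 = numeric(),
               drug_2 = character(), conc_2 = numeric(),
               replicate_group = character(), stringsAsFactors = FALSE)
  if (length(control_wells)) {
    pw <- parse_well(control_wells, plate_rows, plate_cols)
    clash <- intersect(pw$well, treated$well)
    if (length(clash))
      stop_pheno("control wells collide with %d treated wells (%s); %d treated + %d controls requested",
                 length(clash), paste(head(clash, 4), collapse = ", "),
                 nrow(treated), length(control_wells))
    ctrl <- data.frame(well = pw$well, row = pw$row, column = pw$column,
                       role = "control", drug_1 = NA_character_,
                       conc_1 = NA_real_, drug_2 = NA_character_,
                       conc_2 = NA_real_, replicate_group = "control",
                       stringsAsFactors = FALSE)
    treated <- rbind(treated, ctrl)
  }
  new_plate_layout(plate_id, treated, plate_rows, plate_cols)
}

#' Build a binary-combination layout
#'
#' Lays out one two-drug combination block: an `n_levels` x `n_levels` core
#' matrix of dose pairs, each pair replicated `duplicates` times along the
#' column axis (the screen's 5x5 matrices occupy 10x5 wells including
#' duplicates), plus single-agent edge wells at every level of each drug and
#' control wells. Ladders are `fold`-wise dilutions; by default they span
#' `fold^(n_levels-1)` symmetrically around each drug's center concentration,
#' or run down from an explicit `start`.
#'
#' @param drugA,drugB [screen_annotation()] objects (rows = drug A,
#'   columns = drug B).
#' @param centerA,centerB center (median-effect) concentrations.
#' @param fold fold between ladder levels (default 2).
#' @param n_levels ladder levels per drug (default 5, >= 2).
#' @param duplicates replicates per dose pair (default 2).
#' @param startA,startB optional explicit top concentrations overriding the
#'   centered ladder.
#' @param n_controls control wells appended after the drug-B edge (default 4).
#' @param origin `c(row, column)` of the block's top-left corner.
#' @param conc_unit unit of the supplied concentrations (default `"uM"`).
#' @param plate_id,plate_rows,plate_cols as in [build_screen_layout()].
#' @return a `plate_layout`; treated wells carry both drugs in the core and a
#'   single drug on the edges. Replicate groups are `"A<i>xB<j>"`, `"A<i>x-"`,
#'   `"-xB<j>"` and `"control"`.
#' @export
build_combination_layout <- function(drugA, drugB, centerA, centerB,
                                     fold = 2, n_levels = 5, duplicates = 2,
                                     startA = NULL, startB = NULL,
                                     n_controls = 4, origin = c(1, 1),
                                     conc_unit = "uM", plate_id = "combo1",
                                     plate_rows = 16, plate_cols = 24) {
  stopifnot(inherits(drugA, "screen_annotation"),
            inherits(drugB, "screen_annotation"))
  check_number(n_levels, "n_levels", min = 2)
  check_number(centerA, "centerA", positive = TRUE)
  check_number(centerB, "centerB", positive = TRUE)
  ladder <- function(center, start) {
    if (is.null(start)) start <- center * fold^((n_levels - 1) / 2)
    to_molar(build_dilution_series(start, fold, n_levels)$concentrations,
             conc_unit)
  }
  concA <- ladder(centerA, startA)
  concB <- ladder(centerB, startB)
  r0 <- origin[1]; c0 <- origin[2]
  # block geometry: row r0 = drug-B single-agent edge + controls;
  # rows r0+1..r0+n_levels = core (drug-A level i) with the drug-A
  # single-agent edge in the columns after the core.
  need_rows <- n_levels + 1
  need_cols <- n_levels * duplicates + max(duplicates, n_controls)
  if (r0 + need_rows - 1 > plate_rows || c0 + need_cols - 1 > plate_cols)
    stop_pheno("combination block needs %d rows x %d columns from (%d,%d); plate is %dx%d",
               need_rows, need_cols, r0, c0, plate_rows, plate_cols)
  rows <- list()
  add <- function(r, cc, role, d1, x1, d2, x2, grp) {
    rows[[length(rows) + 1L]] <<- data.frame(
      well = well_name(r, cc, plate_rows, plate_cols), row = r, column = cc,
      role = role, drug_1 = d1, conc_1 = x1, drug_2 = d2, conc_2 = x2,
      replicate_group = grp, stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_levels)) {       # drug-B alone, duplicated
    cols <- c0 + (j - 1) * duplicates + seq_len(duplicates) - 1
    add(r0, cols, "treated", drugB$drug_id, concB[j], NA_character_,
        NA_real_, sprintf("-xB%d", j))
  }
  ctrl_cols <- c0 + n_levels * duplicates + seq_len(n_controls) - 1
  if (n_controls > 0)
    add(r0, ctrl_cols, "control", NA_character_, NA_real_, NA_character_,
        NA_real_, "control")
  for (i in seq_len(n_levels)) {
    r <- r0 + i
    for (j in seq_len(n_levels)) {     # core dose pairs
      cols <- c0 + (j - 1) * duplicates + seq_len(duplicates) - 1
      add(r, cols, "treated", drugA$drug_id, concA[i], drugB$drug_id,
          concB[j], sprintf("A%dxB%d", i, j))
    }
    cols <- c0 + n_levels * duplicates + seq_len(duplicates) - 1
    add(r, cols, "treated", drugA$drug_id, concA[i], NA_character_,
        NA_real_, sprintf("A%dx-", i))  # drug-A alone, duplicated
  }
  new_plate_layout(plate_id, do.call(rbind, rows), plate_rows, plate_cols)
}

#' Assemble a virtual plate by duplicate averaging
#'
#' Re-keys per-well scores from physical well positions to (condition, dose)
#' replicate groups, averaging duplicates, the "virtual plate" presentation
#' used for dose-response and combination analysis.
#'
#' @param well_scores named numeric vector (names = wells) or a data.frame
#'   with `well` and `score` columns.
#' @param layout a `plate_layout`; every non-empty layout well must have a
#'   score.
#' @return data.frame of class `virtual_plate` with one row per replicate
#'   group: `replicate_group`, `role`, `drug_1`, `conc_1`, `drug_2`,
#'   `conc_2`, `n_wells`, `score` (arithmetic mean over duplicates).
#' @export
assemble_virtual_plate <- function(well_scores, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  if (is.data.frame(well_scores))
    well_scores <- setNames(well_scores$score, well_scores$well)
  w <- layout$wells[layout$wells$role != "empty", , drop = FALSE]
  if (nrow(w) == 0) stop_pheno("layout has no non-empty wells")
  missing <- setdiff(w$well, names(well_scores))
  if (length(missing))
    stop_pheno("no score for well(s): %s", paste(missing, collapse = ", "))
  w$score <- unname(well_scores[w$well])
  grp <- split(w, w$replicate_group)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(replicate_group = g$replicate_group[1], role = g$role[1],
               drug_1 = g$drug_1[1], conc_1 = g$conc_1[1],
               drug_2 = g$drug_2[1], conc_2 = g$conc_2[1],
               n_wells = nrow(g), score = mean(g$score),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$role, out$drug_1, out$drug_2, -xtfrm(out$conc_1)), ]
  class(out) <- c("virtual_plate", "data.frame")
  out
}

#' Read and write plate layouts
#'
#' Layouts round-trip through CSV (columns `well, role, drug_1, conc_1,
#' drug_2, conc_2, replicate_group`; concentrations in molar) and JSON.
#' Reading re-validates all layout invariants.
#'
#' @param layout a `plate_layout`.
#' @param path file path (`.csv` or `.json`).
#' @param plate_id,plate_rows,plate_cols plate metadata for CSV files (JSON
#'   stores them).
#' @return `read_plate_layout()` returns a validated `plate_layout`.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  cols <- c("well", "role", "drug_1", "conc_1", "drug_2", "conc_2",
            "replicate_group")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    write_json(list(plate_id = layout$plate_id,
                    plate_rows = layout$plate_rows,
                    plate_cols = layout$plate_cols,
                    wells = layout$wells[cols]),
               path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.csv(layout$wells[cols], path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path, plate_id = NULL, plate_rows = 16,
                              plate_cols = 24) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- read_json(path, simplifyVector = TRUE)
    w <- as.data.frame(j$wells, stringsAsFactors = FALSE)
    plate_id <- plate_id %||% j$plate_id
    plate_rows <- j$plate_rows; plate_cols <- j$plate_cols
  } else {
    w <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(well = "character", role = "character",
                                 drug_1 = "character", drug_2 = "character",
                                 replicate_group = "character"))
    w$drug_1[!nzchar(w$drug_1) | is.na(w$drug_1)] <- NA_character_
    w$drug_2[!nzchar(w$drug_2) | is.na(w$drug_2)] <- NA_character_
  }
  pw <- parse_well(w$well, plate_rows, plate_cols)
  w$row <- pw$row; w$column <- pw$column
  new_plate_layout(plate_id %||% "plate", w, plate_rows, plate_cols)
}
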