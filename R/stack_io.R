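#' Calibrated slice stack
#'
#' Container for an ordered stack of calibrated 2-D density maps (mg/cm^3)
#' with the metadata every pipeline stage needs: isotropic in-plane pixel
#' spacing, inter-slice interval d, and inclusive slice ranges for the
#' labelled vertebrae.
#'
#' @param slices list of numeric matrices, all of identical dimensions.
#' @param pixel_spacing in-plane pixel spacing, cm/pixel (isotropic).
#' @param slice_interval_d inter-slice interval d, cm.
#' @param vertebra_labels named list, each element `c(first, last)` slice
#'   indices (inclusive); ranges must be disjoint and within bounds.
#' @return an object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(slices, pixel_spacing, slice_interval_d,
                             vertebra_labels = list()) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  dims <- dim(slices[[1L]])
  for (i in seq_along(slices)) {
    if (!is.matrix(slices[[i]]) || !identical(dim(slices[[i]]), dims)) {
      stop("slice ", i, " does not match the dimensions of slice 1 (",
           dims[1], " x ", dims[2], ")")
    }
  }
  if (!(pixel_spacing > 0) || !(slice_interval_d > 0)) {
    stop("pixel_spacing and slice_interval_d must be positive")
  }
  validate_labels(vertebra_labels, length(slices))
  structure(list(slices = slices, pixel_spacing = pixel_spacing,
                 slice_interval_d = slice_interval_d,
                 vertebra_labels = vertebra_labels),
            class = "calibrated_stack")
}

validate_labels <- function(labels, n_slices) {
  if (length(labels) == 0L) return(invisible(labels))
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("vertebra_labels must be a named list")
  }
  rng <- lapply(labels, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > n_slices) {
      stop("label range must be c(first, last) within 1..", n_slices)
    }
    r
  })
  nm <- names(rng)
  ord <- order(vapply(rng, `[`, integer(1), 1L))
  for (k in seq_along(ord)[-1L]) {
    a <- rng[[ord[k - 1L]]]
    b <- rng[[ord[k]]]
    if (b[1] <= a[2]) {
      stop("vertebra label ranges overlap: ",
           nm[ord[k - 1L]], "/", nm[ord[k]], " overlap")
    }
  }
  invisible(labels)
}

#' @export
print.calibrated_stack <- function(x, ...) {
  dims <- dim(x$slices[[1L]])
  cat("calibrated_stack:", length(x$slices), "slices of", dims[1], "x",
      dims[2], "px,", x$pixel_spacing, "cm/px, d =", x$slice_interval_d,
      "cm\n")
  if (length(x$vertebra_labels)) {
    for (v in names(x$vertebra_labels)) {
      r <- x$vertebra_labels[[v]]
      cat(" ", v, ": slices", r[1], "-", r[2], "\n")
    }
  }
  invisible(x)
}

#' Write a calibrated stack as 16-bit TIFF slices plus a JSON sidecar
#'
#' Each slice becomes a single-channel 16-bit TIFF; the sidecar records the
#' linear calibration (`density = density_slope * value + density_intercept`),
#' the spacings, the vertebra labels and the slice file order. Densities are
#' clamped to the representable range and quantized to the calibration step.
#'
#' @param stack a [calibrated_stack()].
#' @param path directory to create/fill.
#' @param slope,intercept linear calibration of the 16-bit values.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, slope = 0.05, intercept = 0) {
  stopifnot(inherits(stack, "calibrated_stack"), slope > 0)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("slice_%03d.tif", seq_along(stack$slices))
  for (i in seq_along(stack$slices)) {
    v <- round((stack$slices[[i]] - intercept) / slope)
    v <- pmin(pmax(v, 0), 65535)
    tiff::writeTIFF(v / 65535, file.path(path, files[i]),
                    bits.per.sample = 16L, compression = "none")
  }
  sidecar <- list(
    pixel_spacing_cm = stack$pixel_spacing,
    slice_interval_cm = stack$slice_interval_d,
    density_slope = slope,
    density_intercept = intercept,
    vertebra_labels = lapply(names(stack$vertebra_labels), function(v) {
      r <- stack$vertebra_labels[[v]]
      list(name = v, first_slice = r[1], last_slice = r[2])
    }),
    slice_files = files)
  jsonlite::write_json(sidecar, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibrated stack written by [write_stack()]
#'
#' @param path stack directory containing `stack.json` and the TIFFs it
#'   references.
#' @return a [calibrated_stack()].
#' @export
read_stack <- function(path) {
  sidecar_path <- file.path(path, "stack.json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("pixel_spacing_cm", "slice_interval_cm", "density_slope",
            "density_intercept", "slice_files")
  miss <- setdiff(need, names(sc))
  if (length(miss)) {
    stop("sidecar ", sidecar_path, " lacks fields: ",
         paste(miss, collapse = ", "))
  }
  slices <- vector("list", length(sc$slice_files))
  dims <- NULL
  for (i in seq_along(sc$slice_files)) {
    f <- file.path(path, sc$slice_files[i])
    if (!file.exists(f)) stop("missing slice file: ", f)
    img <- tiff::readTIFF(f)
    if (is.null(dims)) {
      dims <- dim(img)
    } else if (!identical(dim(img), dims)) {
      stop("inconsistent slice dimensions in file ", sc$slice_files[i])
    }
    slices[[i]] <- sc$density_slope * round(img * 65535) +
      sc$density_intercept
  }
  labels <- list()
  vl <- sc$vertebra_labels
  if (!is.null(vl) && NROW(vl)) {
    vl <- as.data.frame(vl)
    labels <- stats::setNames(
      lapply(seq_len(nrow(vl)),
             function(i) c(vl$first_slice[i], vl$last_slice[i])),
      vl$name)
  }
  calibrated_stack(slices, pixel_spacing = sc$pixel_spacing_cm,
                   slice_interval_d = sc$slice_interval_cm,
                   vertebra_labels = labels)
}

study_table_columns <- c("subject_id", "group", "day", "bmd",
                         "mineral_content", "volume", "cortical_thickness",
                         "body_height", "body_width", "min_moment",
                         "polar_moment")

#' Write a per-animal, per-day morphometry table as CSV
#'
#' Enforces the shared on-disk contract of the study table: a stable column
#' order, one row per (subject, day), and full-precision numeric formatting
#' so that a read-back is numerically exact.
#'
#' @param records data frame with the study-table columns (subject_id,
#'   group, day, bmd, mineral_content, volume, cortical_thickness,
#'   body_height, body_width, min_moment, polar_moment).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame")
  }
  miss <- setdiff(study_table_columns, names(records))
  if (length(miss)) {
    stop("records lack columns: ", paste(miss, collapse = ", "))
  }
  key <- paste(records$subject_id, records$day)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, day) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  out <- records[, study_table_columns]
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      out[[cn]] <- sprintf("%.17g", out[[cn]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return data frame with numeric morphometry columns.
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(study_table_columns, names(df))
  if (length(miss)) {
    stop("study table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  }
  num <- setdiff(study_table_columns, c("subject_id", "group"))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df
}
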