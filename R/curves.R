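#' Signal-time curve for one region of interest
#'
#' @param roi_id identifier for the region (lesion, aorta slice, ...).
#' @param times acquisition times in seconds, strictly increasing; negative
#'   times are pre-contrast.
#' @param values mean scanner signal per frame (arbitrary units, non-negative).
#' @param n_baseline number of leading pre-contrast frames used to estimate
#'   the baseline signal S0.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(roi_id, times, values, n_baseline) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    dce_validation_error("times and values must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    dce_validation_error(sprintf("times for ROI '%s' are not strictly increasing", roi_id))
  if (any(!is.finite(values)) || any(values < 0))
    dce_validation_error(sprintf("signal values for ROI '%s' must be finite and non-negative", roi_id))
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L || n_baseline > length(times))
    dce_validation_error(sprintf("ROI '%s': n_baseline must be in [1, n frames]", roi_id))
  structure(list(roi_id = as.character(roi_id), times = times, values = values,
                 n_baseline = n_baseline),
            class = "signal_curve")
}

#' Concentration-time curve
#'
#' Tracer concentration expressed as relative signal enhancement
#' \eqn{S(t)/S_0 - 1} (dimensionless), the concentration proxy used throughout
#' the package. `kind` records what the curve represents: tissue, arterial
#' blood, or arterial plasma.
#'
#' @param roi_id region identifier.
#' @param times seconds, strictly increasing.
#' @param values relative enhancement values (finite).
#' @param kind one of `"tissue"`, `"arterial_blood"`, `"arterial_plasma"`.
#' @return An object of class `conc_curve`.
#' @export
conc_curve <- function(roi_id, times, values,
                       kind = c("tissue", "arterial_blood", "arterial_plasma")) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    dce_validation_error("times and values must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    dce_validation_error("times must be strictly increasing")
  if (any(!is.finite(values)))
    dce_validation_error("concentration values must be finite")
  structure(list(roi_id = as.character(roi_id), times = times, values = values,
                 kind = kind),
            class = "conc_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat("<signal_curve> ROI ", x$roi_id, ": ", length(x$times), " frames, ",
      x$n_baseline, " baseline\n", sep = "")
  invisible(x)
}

#' @export
print.conc_curve <- function(x, ...) {
  cat("<conc_curve:", x$kind, "> ROI ", x$roi_id, ": ", length(x$times),
      " frames, peak ", signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Read signal curves from a CSV table
#'
#' Expects columns `roi_id,time_s,signal,is_baseline` (comma-separated, UTF-8,
#' header required; `is_baseline` is logical or 0/1 and flags pre-contrast
#' frames). Rows are grouped by `roi_id` and sorted by time.
#'
#' @param path CSV file path.
#' @return Named list of [signal_curve()] objects, one per ROI.
#' @export
read_curve_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "time_s", "signal", "is_baseline")
  miss <- setdiff(need, names(d))
  if (length(miss))
    dce_format_error(paste0("curve table is missing column(s): ",
                            paste(miss, collapse = ", ")))
  d$is_baseline <- as.logical(d$is_baseline)
  curves <- lapply(split(d, d$roi_id), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    if (anyDuplicated(g$time_s))
      dce_validation_error(sprintf("ROI '%s' has duplicated times", g$roi_id[1]))
    nb <- sum(g$is_baseline)
    if (nb < 1L)
      dce_validation_error(sprintf(
        "ROI '%s' has no baseline frames (cannot estimate S0)", g$roi_id[1]))
    if (!all(g$is_baseline[seq_len(nb)]))
      dce_validation_error(sprintf(
        "ROI '%s': baseline frames must precede all post-contrast frames", g$roi_id[1]))
    signal_curve(g$roi_id[1], g$time_s, g$signal, nb)
  })
  curves[order(names(curves))]
}

#' Write signal curves to a CSV table
#'
#' Inverse of [read_curve_table()]; a write/read round trip reproduces the
#' curves exactly (up to numeric printing precision of 15 significant digits).
#'
#' @param curves list of [signal_curve()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(curves, path) {
  if (inherits(curves, "signal_curve")) curves <- list(curves)
  d <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(roi_id = cv$roi_id,
               time_s = cv$times,
               signal = cv$values,
               is_baseline = seq_along(cv$times) <= cv$n_baseline)
  }))
  utils::write.csv(format(d, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract mean ROI curves from a 4D volume
#'
#' Averages the signal over all voxels of each mask label at every frame,
#' i.e. takes the whole lesion volume as one region.
#'
#' @param image_4d numeric 4D array (x, y, z, frame) or a NIfTI file path.
#' @param masks integer 3D array of ROI labels (0 = background) or a NIfTI
#'   file path; spatial dimensions must match `image_4d`.
#' @param schedule an [acq_schedule()] giving the frame times; the number of
#'   pre-contrast frames is taken from it.
#' @return Named list of [signal_curve()] objects, one per mask label
#'   (names `"roi_<label>"`).
#' @export
extract_roi_curves <- function(image_4d, masks, schedule) {
  if (is.character(image_4d) || is.character(masks)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      dce_stop("reading NIfTI paths requires the RNifti package",
               "dce_dependency_error")
    if (is.character(image_4d)) image_4d <- as.array(RNifti::readNifti(image_4d))
    if (is.character(masks)) masks <- as.array(RNifti::readNifti(masks))
  }
  di <- dim(image_4d); dm <- dim(masks)
  if (length(di) != 4L || length(dm) != 3L || !all(di[1:3] == dm))
    dce_validation_error("image must be 4D and masks 3D with matching spatial dimensions")
  nt <- di[4]
  if (length(schedule$frame_times) != nt)
    dce_validation_error("schedule frame count does not match 4th image dimension")
  labels <- sort(unique(masks[masks >= 1]))
  if (!length(labels)) dce_validation_error("mask contains no labels >= 1")
  flat <- matrix(image_4d, ncol = nt) # voxels x frames
  nb <- n_baseline_frames(schedule)
  out <- lapply(labels, function(lb) {
    idx <- which(masks == lb)
    if (!length(idx))
      dce_validation_error(sprintf("mask label %s selects no voxels", lb))
    signal_curve(paste0("roi_", lb), schedule$frame_times,
                 colMeans(flat[idx, , drop = FALSE]), nb)
  })
  names(out) <- paste0("roi_", labels)
  out
}

#' Build a block-phantom 4D image from known curves
#'
#' Minimal synthetic image builder: each curve is broadcast into the voxels of
#' the corresponding mask label. Intended for validating
#' [extract_roi_curves()], not for simulating anatomy.
#'
#' @param curves list of [signal_curve()] objects (all on the same time grid).
#' @param dims spatial dimensions (length-3 integer).
#' @param background constant background signal.
#' @return List with `image` (4D array) and `mask` (3D label array); label i
#'   corresponds to `curves[[i]]`.
#' @export
phantom_image <- function(curves, dims = c(8L, 8L, 4L), background = 0) {
  nt <- length(curves[[1]]$times)
  mask <- array(0L, dims)
  nvox <- prod(dims)
  per <- max(1L, floor(nvox / (2L * length(curves))))
  pos <- 1L
  for (i in seq_along(curves)) {
    mask[pos:(pos + per - 1L)] <- i
    pos <- pos + per
  }
  img <- array(background, c(dims, nt))
  flat <- matrix(img, ncol = nt)
  for (i in seq_along(curves)) {
    flat[which(mask == i), ] <- matrix(curves[[i]]$values, nrow = sum(mask == i),
                                       ncol = nt, byrow = TRUE)
  }
  list(image = array(flat, c(dims, nt)), mask = mask)
}
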