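# Isoscape rasters: construction, calibration, discrimination, alignment.

#' Create an isoscape raster
#'
#' An isoscape is a georeferenced grid of predicted tissue or environmental
#' stable-isotope values (per mil). The grid uses geographic lon/lat degrees,
#' a cell-center coordinate convention, and is stored north-up: row 1 is the
#' northernmost row, column 1 the westernmost column. Missing cells (ocean,
#' outside the assignment extent) are \code{NA}.
#'
#' @param values numeric matrix of isotope values (\code{NA} = missing),
#'   row 1 = north.
#' @param extent numeric length-4 vector \code{c(xmin, xmax, ymin, ymax)} of
#'   the outer cell edges, degrees.
#' @param sigma assignment standard deviation (per mil) attached to this
#'   isotope when the surface is used in probabilistic assignment.
#' @param isotope label, e.g. \code{"d2H"} or \code{"d13C"}.
#' @param calibrated logical; \code{TRUE} once a tissue calibration or
#'   discrimination has been applied (guards against double application).
#' @return an object of class \code{"isoscape"}.
#' @export
isoscape <- function(values, extent, sigma = NA_real_, isotope = "d2H",
                     calibrated = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid must be non-empty")
  if (length(extent) != 4 || !is.numeric(extent)) {
    stop("extent must be c(xmin, xmax, ymin, ymax)")
  }
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("degenerate extent: xmax must exceed xmin and ymax exceed ymin")
  }
  if (!is.na(sigma) && sigma <= 0) stop("sigma must be > 0")
  structure(
    list(values = values,
         extent = as.numeric(extent),
         sigma = sigma,
         isotope = isotope,
         calibrated = isTRUE(calibrated)),
    class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf("isoscape [%s%s]: %d x %d cells, %d unmasked\n",
              x$isotope, if (x$calibrated) ", calibrated" else "",
              nrow(x$values), ncol(x$values), n_ok))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]; cell %g x %g deg\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4],
              cell_size(x)[1], cell_size(x)[2]))
  if (!is.na(x$sigma)) cat(sprintf("  assignment sigma: %g permil\n", x$sigma))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: %.2f to %.2f permil\n", rng[1], rng[2]))
  invisible(x)
}

# Cell size (dx, dy) in degrees.
cell_size <- function(iso) {
  c((iso$extent[2] - iso$extent[1]) / ncol(iso$values),
    (iso$extent[4] - iso$extent[3]) / nrow(iso$values))
}

#' Cell-center coordinates of an isoscape grid
#'
#' @param iso an \code{isoscape}.
#' @return list with \code{lon} (by column, west to east) and \code{lat}
#'   (by row, north to south, matching the row order of \code{values}).
#' @export
iso_coords <- function(iso) {
  cs <- cell_size(iso)
  list(lon = iso$extent[1] + (seq_len(ncol(iso$values)) - 0.5) * cs[1],
       lat = iso$extent[4] - (seq_len(nrow(iso$values)) - 0.5) * cs[2])
}

#' @export
as.data.frame.isoscape <- function(x, ...) {
  co <- iso_coords(x)
  data.frame(lon = rep(co$lon, each = nrow(x$values)),
             lat = rep(co$lat, times = ncol(x$values)),
             value = as.vector(x$values))
}

#' Calibration and discrimination parameters
#'
#' Defaults are the known-origin songbird calibration for converting a
#' growing-season precipitation deuterium isoscape into a feather isoscape,
#' feather = -6.77 + 1.42 * precipitation (per mil, VSMOW), and the +2 per
#' mil carbon-13 discrimination between plants and the herbivorous insects
#' that feathers are grown on.
#'
#' @param intercept calibration intercept, per mil.
#' @param slope calibration slope (dimensionless, must be nonzero).
#' @param c_discrimination diet-to-consumer carbon offset, per mil.
#' @return a list of class \code{"calibration_params"}.
#' @export
calibration_params <- function(intercept = -6.77, slope = 1.42,
                               c_discrimination = 2.0) {
  if (slope == 0) stop("calibration slope must be nonzero")
  structure(list(intercept = intercept, slope = slope,
                 c_discrimination = c_discrimination),
            class = "calibration_params")
}

#' Calibrate a precipitation deuterium isoscape to feather values
#'
#' Applies the affine tissue calibration per cell, preserving the mask. A
#' surface already flagged as calibrated is refused, preventing accidental
#' double calibration.
#'
#' @param precip precipitation \code{isoscape} (per mil VSMOW).
#' @param params \code{\link{calibration_params}}.
#' @return feather \code{isoscape} with \code{calibrated = TRUE}.
#' @export
calibrate_h <- function(precip, params = calibration_params()) {
  stopifnot(inherits(precip, "isoscape"))
  if (precip$calibrated) {
    stop("surface is already calibrated; refusing to calibrate twice")
  }
  out <- precip
  out$values <- params$intercept + params$slope * precip$values
  out$calibrated <- TRUE
  out
}

#' Apply diet-to-consumer carbon discrimination
#'
#' Adds the discrimination offset to every unmasked cell of a plant carbon
#' isoscape, giving the expected consumer (feather) surface.
#'
#' @param plant plant \code{isoscape} (per mil VPDB).
#' @param params \code{\link{calibration_params}}.
#' @return consumer \code{isoscape} with \code{calibrated = TRUE}.
#' @export
discriminate_c <- function(plant, params = calibration_params()) {
  stopifnot(inherits(plant, "isoscape"))
  if (plant$calibrated) {
    stop("surface is already discriminated; refusing to apply twice")
  }
  out <- plant
  out$values <- plant$values + params$c_discrimination
  out$calibrated <- TRUE
  out
}

#' Align isoscapes onto one grid and mask to a bounding box
#'
#' Resamples every surface onto the grid of the first (nearest-neighbour,
#' which conserves cell values for the cell-wise assignment), then masks, in
#' all outputs, every cell whose center falls outside the bounding box or
#' that is missing in any input. The output unmasked set is therefore a
#' subset of every input's unmasked set intersected with the box.
#'
#' @param surfaces list of \code{isoscape} objects.
#' @param bbox numeric \code{c(xmin, xmax, ymin, ymax)} in degrees, or
#'   \code{NULL} to keep the full shared extent.
#' @return list of aligned \code{isoscape} objects sharing one grid and mask.
#' @export
align_and_mask <- function(surfaces, bbox = NULL) {
  stopifnot(length(surfaces) >= 1,
            all(vapply(surfaces, inherits, logical(1), "isoscape")))
  ref <- surfaces[[1]]
  co <- iso_coords(ref)
  aligned <- lapply(surfaces, function(s) {
    if (identical(s$extent, ref$extent) &&
        all(dim(s$values) == dim(ref$values))) {
      return(s)
    }
    cs <- cell_size(s)
    col_idx <- floor((co$lon - s$extent[1]) / cs[1]) + 1
    row_idx <- floor((s$extent[4] - co$lat) / cs[2]) + 1
    ok_c <- col_idx >= 1 & col_idx <= ncol(s$values)
    ok_r <- row_idx >= 1 & row_idx <= nrow(s$values)
    v <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
    for (j in which(ok_c)) {
      v[ok_r, j] <- s$values[row_idx[ok_r], col_idx[j]]
    }
    out <- s
    out$values <- v
    out$extent <- ref$extent
    out
  })
  keep <- Reduce(`&`, lapply(aligned, function(s) !is.na(s$values)))
  if (!is.null(bbox)) {
    stopifnot(length(bbox) == 4)
    in_box <- outer(co$lat > bbox[3] & co$lat < bbox[4],
                    co$lon > bbox[1] & co$lon < bbox[2], `&`)
    keep <- keep & in_box
  }
  if (!any(keep)) stop("empty intersection: no unmasked cells remain")
  lapply(aligned, function(s) {
    s$values[!keep] <- NA_real_
    s
  })
}
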