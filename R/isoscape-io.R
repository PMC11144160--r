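# Raster I/O: ESRI ASCII grid (.asc), a standard single-band georeferenced
# plain-text format (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value
# header, then rows north to south). Square cells are required by the format.

#' Write an isoscape to an ESRI ASCII grid file
#'
#' @param iso an \code{isoscape}.
#' @param path output file path.
#' @param nodata value written for masked cells (default -9999).
#' @return \code{path}, invisibly.
#' @export
write_isoscape <- function(iso, path, nodata = -9999) {
  stopifnot(inherits(iso, "isoscape"))
  cs <- cell_size(iso)
  if (abs(cs[1] - cs[2]) > 1e-9) {
    stop("ASCII grid requires square cells; got dx=", cs[1], ", dy=", cs[2])
  }
  v <- iso$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", iso$extent[1]),
           sprintf("yllcorner %.10g", iso$extent[3]),
           sprintf("cellsize %.10g", cs[1]),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1, function(r) paste(sprintf("%.8g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an isoscape from an ESRI ASCII grid file
#'
#' Cells equal to the file's nodata tag become masked (\code{NA}). A raster
#' with no usable cells is read but flagged with a warning.
#'
#' @param path input file path.
#' @param sigma assignment standard deviation to attach (per mil).
#' @param isotope isotope label to attach.
#' @param calibrated whether the stored surface is already tissue-calibrated.
#' @return an \code{isoscape}.
#' @export
read_isoscape <- function(path, sigma = NA_real_, isotope = "d2H",
                          calibrated = FALSE) {
  if (!file.exists(path)) stop("isoscape file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else {
      break
    }
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% names(header))) {
    stop("malformed ASCII grid header (missing geotransform): ", path,
         " lacks ", paste(setdiff(needed, names(header)), collapse = ", "))
  }
  nodata <- if ("nodata_value" %in% names(header)) {
    header$nodata_value
  } else -9999
  body <- lines[(i + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != header$nrows) {
    stop("ASCII grid body has ", length(body), " rows, header declares ",
         header$nrows)
  }
  vals <- lapply(body, function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  if (any(lengths(vals) != header$ncols)) {
    stop("ASCII grid row length does not match declared ncols")
  }
  m <- do.call(rbind, vals)
  m[m == nodata] <- NA_real_
  if (all(is.na(m))) {
    warning("isoscape has no usable (non-nodata) cells: ", path)
  }
  ext <- c(header$xllcorner,
           header$xllcorner + header$ncols * header$cellsize,
           header$yllcorner,
           header$yllcorner + header$nrows * header$cellsize)
  isoscape(m, ext, sigma = sigma, isotope = isotope, calibrated = calibrated)
}
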