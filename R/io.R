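#' @include accessors.R
NULL

#' Write a layer or surface as an ESRI ASCII grid
#'
#' Single-band plain-text raster (.asc): a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values from north to south. Readable by common GIS tools.
#'
#' @param x an \linkS4class{EnvLayer}, \linkS4class{SuitabilitySurface},
#'   \linkS4class{ClassifiedMap} or a plain numeric matrix (then \code{grid}
#'   is required)
#' @param path output file path
#' @param grid required when \code{x} is a bare matrix
#' @param digits significant digits written (default 10)
#' @return \code{path}, invisibly
#' @export
writeAsciiGrid <- function(x, path, grid = NULL, digits = 10) {
  if (is(x, "EnvLayer") || is(x, "SuitabilitySurface")) {
    grid <- x@grid; vals <- x@values
  } else if (is(x, "ClassifiedMap")) {
    grid <- x@grid; vals <- x@classes
  } else {
    if (is.null(grid)) stop("grid required for a bare matrix")
    vals <- x
  }
  nodata <- -9999
  vals[is.na(vals)] <- nodata
  hdr <- c(
    paste("ncols", grid@nCols),
    paste("nrows", grid@nRows),
    paste("xllcorner", format(grid@origin[1], digits = 12)),
    paste("yllcorner",
          format(grid@origin[2] - grid@nRows * grid@cellSize, digits = 12)),
    paste("cellsize", format(grid@cellSize, digits = 12)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(vals, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as an EnvLayer
#'
#' @param path .asc file written by \code{\link{writeAsciiGrid}} or any GIS
#' @param variableName,units metadata for the returned layer
#' @param crsId CRS identifier to record
#' @return an \linkS4class{EnvLayer} (nodata cells masked)
#' @export
readAsciiGrid <- function(path, variableName = basename(path), units = "",
                          crsId = "EPSG:4326") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != nr * nc) stop("ASCII grid body size mismatch")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mask <- m == nodata
  m[mask] <- NA_real_
  grid <- RasterGrid(nr, nc,
                     origin = c(hdr$xllcorner,
                                hdr$yllcorner + nr * hdr$cellsize),
                     cellSize = hdr$cellsize, crsId = crsId,
                     nodataMask = mask)
  EnvLayer(grid, m, variableName = variableName, units = units)
}

#' Read / write occurrence CSV files
#'
#' The on-disk format is a plain CSV with header \code{lon,lat,species}.
#'
#' @param x an \linkS4class{OccurrenceSet}
#' @param path file path
#' @return \code{writeOccurrencesCsv}: \code{path} invisibly;
#'   \code{readOccurrencesCsv}: an \linkS4class{OccurrenceSet}
#' @export
writeOccurrencesCsv <- function(x, path) {
  df <- data.frame(lon = x@points[, "lon"], lat = x@points[, "lat"],
                   species = x@speciesLabel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeOccurrencesCsv
#' @export
readOccurrencesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df)))
    stop("occurrence CSV must have lon and lat columns")
  lab <- if ("species" %in% names(df) && nrow(df) > 0)
    as.character(df$species[1]) else "sp"
  OccurrenceSet(df$lon, df$lat, speciesLabel = lab,
                provenance = paste0("file:", basename(path)))
}
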