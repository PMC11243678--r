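#' Georeferencing metadata for a grid
#'
#' Describes the geometry of a regular north-up raster grid: pixel edge
#' length in metres, map coordinates of the top-left (north-west) corner,
#' a coordinate-reference-system label, and the grid dimensions. Two grids
#' are *aligned* if and only if all fields are equal; every multi-grid
#' operation in the package refuses misaligned inputs rather than
#' resampling.
#'
#' @param rows,cols positive integer grid dimensions; row 1 is the
#'   northernmost row.
#' @param pixel_size edge length of a square pixel in metres (default 30,
#'   the Landsat convention; pixel area is `pixel_size^2`).
#' @param origin numeric length-2, map coordinates `c(x, y)` of the
#'   top-left corner of the top-left pixel.
#' @param crs text label of the coordinate reference system, treated as
#'   opaque (never parsed or reprojected).
#' @return an object of class `geo_meta`.
#' @export
geo_meta <- function(rows, cols, pixel_size = 30, origin = c(0, 0),
                     crs = "unknown") {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 1L || length(cols) != 1L || is.na(rows) || is.na(cols) ||
      rows < 1L || cols < 1L)
    stop("rows and cols must be positive integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive number")
  if (!is.numeric(origin) || length(origin) != 2L)
    stop("origin must be numeric of length 2")
  structure(list(rows = rows, cols = cols,
                 pixel_size = as.numeric(pixel_size),
                 origin = as.numeric(origin), crs = as.character(crs)),
            class = "geo_meta")
}

#' Test whether two grids (or geo_meta objects) are aligned
#'
#' @param a,b `geo_meta` or `dune_grid` objects.
#' @return `TRUE` if every geo_meta field matches, else `FALSE`.
#' @export
is_aligned <- function(a, b) {
  ma <- if (inherits(a, "dune_grid")) a$meta else a
  mb <- if (inherits(b, "dune_grid")) b$meta else b
  identical(ma$rows, mb$rows) && identical(ma$cols, mb$cols) &&
    isTRUE(all.equal(ma$pixel_size, mb$pixel_size)) &&
    isTRUE(all.equal(ma$origin, mb$origin)) &&
    identical(ma$crs, mb$crs)
}

stop_if_misaligned <- function(a, b, what = "grids") {
  ma <- if (inherits(a, "dune_grid")) a$meta else a
  mb <- if (inherits(b, "dune_grid")) b$meta else b
  if (!is_aligned(ma, mb)) {
    fields <- c("rows", "cols", "pixel_size", "origin", "crs")
    bad <- fields[!vapply(fields, function(f)
      isTRUE(all.equal(ma[[f]], mb[[f]])), logical(1))]
    stop(sprintf("%s are not aligned; mismatched fields: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a grid (2-D field with a validity mask)
#'
#' The package-wide NoData contract: `valid_mask` marks cells carrying an
#' observation; every statistic ignores cells where it is `FALSE`, and no
#' arithmetic ever reads a NoData cell. `NA` entries in `values` are
#' always treated as NoData.
#'
#' @param values numeric matrix (rows x cols), row 1 northernmost.
#' @param valid_mask logical matrix of the same shape, or `NULL` to
#'   derive it as `!is.na(values)`.
#' @param meta a [geo_meta()]; defaults to a 30 m grid at origin (0, 0).
#' @return an object of class `dune_grid` with fields `values`,
#'   `valid_mask`, `meta`.
#' @export
grid_new <- function(values, valid_mask = NULL, meta = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (is.null(meta)) meta <- geo_meta(nrow(values), ncol(values))
  if (nrow(values) != meta$rows || ncol(values) != meta$cols)
    stop("values shape does not match meta rows/cols")
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(values)))
    stop("valid_mask must be a logical matrix with the shape of values")
  valid_mask <- valid_mask & !is.na(values)
  mode(values) <- "numeric"
  structure(list(values = values, valid_mask = valid_mask, meta = meta),
            class = "dune_grid")
}

#' @export
print.dune_grid <- function(x, ...) {
  cat(sprintf("<dune_grid> %d x %d, %.6g m pixels, %d/%d valid, crs '%s'\n",
              x$meta$rows, x$meta$cols, x$meta$pixel_size,
              sum(x$valid_mask), length(x$valid_mask), x$meta$crs))
  invisible(x)
}

#' Valid values of a grid as a vector
#' @param g a `dune_grid`.
#' @return numeric vector of observed values.
#' @export
grid_values <- function(g) g$values[g$valid_mask]

#' Read a grid from an ESRI ASCII raster file
#'
#' Reads the standard ESRI ASCII Grid format (header lines `ncols`,
#' `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' optional `NODATA_value`, then rows north to south). Cells equal to the
#' file's NoData value come back with `valid_mask` `FALSE`. A `.prj`
#' sidecar next to the file, if present, supplies the CRS label.
#'
#' @param path path to a `.asc` file.
#' @param band_label optional label recorded as an attribute
#'   (one of the conventional `"red"`, `"nir"`, `"qa"`, `"index"`, or any
#'   text).
#' @return a [grid_new()] object.
#' @export
read_grid <- function(path, band_label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, n = 7L, warn = FALSE)
  hdr <- list(); nhdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2]); nhdr <- nhdr + 1L
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop(sprintf("not an ESRI ASCII grid (missing %s): %s",
                 paste(setdiff(req, names(hdr)), collapse = "/"), path))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("expected %d cells, found %d in %s",
                 nrows * ncols, length(vals), path))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  # llcorner -> top-left origin (row 1 is the northern edge)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else 0
  crs <- "unknown"
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  if (file.exists(prj)) crs <- paste(readLines(prj, warn = FALSE), collapse = "\n")
  meta <- geo_meta(nrows, ncols, hdr$cellsize,
                   origin = c(xll, yll + nrows * hdr$cellsize), crs = crs)
  g <- grid_new(m, meta = meta)
  if (!is.null(band_label)) attr(g, "band_label") <- band_label
  g
}

#' Write a grid to an ESRI ASCII raster file
#'
#' NoData cells are written as the `nodata` sentinel (default -9999 for
#' real-valued grids; use 0 for category maps whose codes are 1-5, keeping
#' a 0-valued index distinct from NoData). Values are printed at full
#' double precision, so real grids round-trip bit-exactly through
#' [read_grid()]. A `.prj` sidecar records the CRS label when it is not
#' `"unknown"`.
#'
#' @param g a `dune_grid`.
#' @param path output path (`.asc` conventional).
#' @param nodata sentinel written for NoData cells; must not collide with
#'   any valid value.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "dune_grid"))
  vals <- g$values
  if (any(vals[g$valid_mask] == nodata, na.rm = TRUE))
    stop(sprintf("nodata sentinel %g collides with a valid cell value", nodata))
  vals[!g$valid_mask] <- nodata
  m <- g$meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", m$cols),
               sprintf("nrows %d", m$rows),
               sprintf("xllcorner %.17g", m$origin[1]),
               sprintf("yllcorner %.17g", m$origin[2] - m$rows * m$pixel_size),
               sprintf("cellsize %.17g", m$pixel_size),
               sprintf("NODATA_value %.17g", nodata)), con)
  for (i in seq_len(m$rows))
    writeLines(paste(sprintf("%.17g", vals[i, ]), collapse = " "), con)
  if (!identical(m$crs, "unknown"))
    writeLines(m$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Assemble aligned monthly grids into a time-ordered stack
#'
#' @param entries a list of lists/rows with fields `year`, `month`,
#'   `grid`; alternatively pass `grids`, `years`, `months` directly.
#' @param grids,years,months parallel vectors/list used when `entries` is
#'   `NULL`.
#' @param band_label one of `"red"`, `"nir"`, `"qa"`, `"index"`.
#' @return an object of class `scene_stack` with fields `grids` (list),
#'   `timestamps` (data.frame of year, month, sorted strictly
#'   increasing), `band_label`.
#' @export
assemble_stack <- function(entries = NULL, grids = NULL, years = NULL,
                           months = NULL, band_label = "index") {
  if (!is.null(entries)) {
    years <- vapply(entries, function(e) as.integer(e$year), integer(1))
    months <- vapply(entries, function(e) as.integer(e$month), integer(1))
    grids <- lapply(entries, `[[`, "grid")
  }
  years <- as.integer(years); months <- as.integer(months)
  if (length(grids) == 0L) stop("empty stack")
  if (length(grids) != length(years) || length(years) != length(months))
    stop("grids, years, months must have equal length")
  if (any(months < 1L | months > 12L)) stop("months must be in 1..12")
  key <- years * 12L + months
  if (anyDuplicated(key))
    stop(sprintf("duplicate timestamp(s): %s",
                 paste(unique(sprintf("(%d, %d)", years[duplicated(key)],
                                      months[duplicated(key)])), collapse = ", ")))
  for (g in grids) stop_if_misaligned(grids[[1]], g, "stack grids")
  o <- order(key)
  structure(list(grids = grids[o],
                 timestamps = data.frame(year = years[o], month = months[o]),
                 band_label = band_label),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  ts <- x$timestamps
  cat(sprintf("<scene_stack> %d scenes [%s], %d-%02d .. %d-%02d, %d x %d\n",
              nrow(ts), x$band_label, ts$year[1], ts$month[1],
              ts$year[nrow(ts)], ts$month[nrow(ts)],
              x$grids[[1]]$meta$rows, x$grids[[1]]$meta$cols))
  invisible(x)
}

#' Number of scenes in a stack
#' @param stack a `scene_stack`.
#' @return integer scene count.
#' @export
stack_length <- function(stack) length(stack$grids)

# 3-D array view (rows x cols x time) with NA at NoData; internal workhorse
stack_array <- function(stack) {
  m <- stack$grids[[1]]$meta
  a <- array(NA_real_, c(m$rows, m$cols, length(stack$grids)))
  for (k in seq_along(stack$grids)) {
    g <- stack$grids[[k]]
    v <- g$values
    v[!g$valid_mask] <- NA_real_
    a[, , k] <- v
  }
  a
}

#' Area represented by the valid cells of a grid, in hectares
#'
#' One pixel covers `pixel_size^2` square metres (900 m2 = 0.09 ha at the
#' 30 m Landsat pixel).
#'
#' @param g a `dune_grid`.
#' @return area in hectares.
#' @export
grid_area_ha <- function(g) sum(g$valid_mask) * g$meta$pixel_size^2 / 1e4
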