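#' @useDynLib clutchscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats median quantile sd setNames approx lm coef predict
#'   ks.test kruskal.test cor.test rnorm runif rpois rbinom rmultinom
#'   complete.cases fft mvfft
#' @importFrom utils head tail modifyList
#' @importFrom grDevices chull colorRampPalette
#' @importFrom graphics image
NULL

.loc_cols <- c("x", "y", "z", "frame", "channel", "wx", "wy", "photons")

#' Construct a localization table
#'
#' The universal currency of the pipeline: one row per fitted emitter
#' position, coordinates in nanometres.
#'
#' @param x,y Lateral coordinates (nm). Required, finite.
#' @param z Axial coordinate (nm), optional.
#' @param frame Acquisition frame index (integer, >= 0), optional.
#' @param channel Channel label, optional.
#' @param wx,wy Fitted elliptical PSF widths (nm, > 0), optional.
#' @param photons Photon count, optional.
#' @param provenance Free-text source tag.
#' @return A `data.frame` of class `loc_table` with a `units` attribute fixed
#'   to `"nm"`.
#' @export
loc_table <- function(x, y, z = NULL, frame = NULL, channel = NULL,
                      wx = NULL, wy = NULL, photons = NULL,
                      provenance = "constructed") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("x and y must be finite")
  df <- data.frame(x = x, y = y)
  if (!is.null(z)) df$z <- as.numeric(z)
  if (!is.null(frame)) {
    frame <- as.integer(frame)
    if (length(frame) && any(frame < 0, na.rm = TRUE))
      stop("frame indices must be >= 0")
    df$frame <- frame
  }
  if (!is.null(channel)) df$channel <- as.character(channel)
  if (!is.null(wx)) {
    wx <- as.numeric(wx)
    if (any(wx <= 0, na.rm = TRUE)) stop("wx must be > 0")
    df$wx <- wx
  }
  if (!is.null(wy)) {
    wy <- as.numeric(wy)
    if (any(wy <= 0, na.rm = TRUE)) stop("wy must be > 0")
    df$wy <- wy
  }
  if (!is.null(photons)) df$photons <- as.numeric(photons)
  structure(df, class = c("loc_table", "data.frame"),
            units = "nm", provenance = provenance)
}

.as_loc <- function(df, provenance = "derived") {
  loc_table(df$x, df$y, z = df[["z"]], frame = df[["frame"]],
            channel = df[["channel"]], wx = df[["wx"]], wy = df[["wy"]],
            photons = df[["photons"]], provenance = provenance)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations [%s], columns: %s\n",
              nrow(x), attr(x, "units"), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Column-mapping dialect for localization files
#'
#' Maps the package's canonical column names to the headers of a delimited
#' localization file. The default dialect is a headered CSV with columns
#' `x, y, z, frame, channel, wx, wy, photons` in nm. If `pixel_size` is set,
#' `x`, `y` (and `wx`, `wy`) in the file are taken to be in pixels and are
#' converted to nm on read.
#'
#' @param x,y,z,frame,channel,wx,wy,photons Header names in the file.
#' @param sep Field separator.
#' @param pixel_size Pixel size in nm if lateral coordinates are stored in
#'   pixels; `NULL` (default) means the file is already in nm.
#' @return A `loc_dialect` list.
#' @export
loc_dialect <- function(x = "x", y = "y", z = "z", frame = "frame",
                        channel = "channel", wx = "wx", wy = "wy",
                        photons = "photons", sep = ",", pixel_size = NULL) {
  structure(list(x = x, y = y, z = z, frame = frame, channel = channel,
                 wx = wx, wy = wy, photons = photons, sep = sep,
                 pixel_size = pixel_size),
            class = "loc_dialect")
}

#' Read a localization table from delimited text
#'
#' @param path File path.
#' @param dialect A [loc_dialect()] mapping canonical columns to file headers.
#' @return A [loc_table()]. Unknown columns are ignored; row order preserved.
#' @export
read_localizations <- function(path, dialect = loc_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = dialect$sep, header = TRUE,
                          data.table = FALSE)
  for (req in c("x", "y")) {
    if (!(dialect[[req]] %in% names(dt)))
      stop(sprintf("format error: required column '%s' (mapped to '%s') missing",
                   req, dialect[[req]]))
  }
  out <- list()
  for (col in .loc_cols) {
    hdr <- dialect[[col]]
    if (!is.null(hdr) && hdr %in% names(dt)) out[[col]] <- dt[[hdr]]
  }
  for (col in c("x", "y", "z", "wx", "wy", "photons")) {
    if (is.null(out[[col]])) next
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric '%s' at row %d", col, bad[1]))
    out[[col]] <- v
  }
  if (!is.null(dialect$pixel_size)) {
    ps <- dialect$pixel_size
    for (col in c("x", "y", "wx", "wy"))
      if (!is.null(out[[col]])) out[[col]] <- out[[col]] * ps
  }
  loc_table(out$x, out$y, z = out$z, frame = out$frame, channel = out$channel,
            wx = out$wx, wy = out$wy, photons = out$photons,
            provenance = path)
}

#' Write a localization table to delimited text
#'
#' Round-trips through [read_localizations()] with coordinate deviation
#' below 1e-6 nm (15 significant digits are written).
#'
#' @param table A [loc_table()].
#' @param path Output path.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    if (is.integer(v)) v else signif(v, 15)
  })
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Select an axial slice of localizations
#'
#' Retains records with `|z - z_center| <= thickness / 2`, the pipeline's
#' default being the 120 nm slice centred at the focal plane (z = 0) used for
#' all 2D co-structure analysis.
#'
#' @param table A [loc_table()] whose records all carry `z`.
#' @param z_center Slice centre (nm).
#' @param thickness Slice thickness (nm, > 0; `Inf` keeps everything).
#' @return The filtered [loc_table()], order preserved.
#' @export
select_slice <- function(table, z_center = 0, thickness = 120) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (is.null(table$z) || anyNA(table$z))
    stop("select_slice requires z on every record")
  keep <- abs(table$z - z_center) <= thickness / 2
  .as_loc(table[keep, , drop = FALSE], provenance = attr(table, "provenance"))
}

# --- nuclear masks ----------------------------------------------------------

.poly_ccw <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) >= 2 &&
      all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3) stop("polygon needs >= 3 vertices")
  if (cpp_polygon_area(m) < 0) m <- m[nrow(m):1, , drop = FALSE]
  m
}

.poly_self_intersects <- function(m) {
  n <- nrow(m)
  seg <- function(i) rbind(m[i, ], m[if (i == n) 1 else i + 1, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, jmax)) {
      if (j > n) break
      a <- seg(i); b <- seg(j)
      d1 <- cross(b[1, ], b[2, ], a[1, ]); d2 <- cross(b[1, ], b[2, ], a[2, ])
      d3 <- cross(a[1, ], a[2, ], b[1, ]); d4 <- cross(a[1, ], a[2, ], b[2, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Construct a nuclear mask
#'
#' A simple closed boundary polygon (the nuclear periphery) plus zero or more
#' exclusion polygons (nucleoli) strictly inside it. All tessellations,
#' density computations and radial profiles are clipped to the usable region
#' boundary minus exclusions.
#'
#' @param boundary An n x 2 matrix of vertices (nm). Closed or open rings
#'   accepted; stored open, counter-clockwise.
#' @param exclusions A list of polygon matrices.
#' @return A `nuclear_mask` object.
#' @export
nuclear_mask <- function(boundary, exclusions = list()) {
  boundary <- .poly_ccw(boundary)
  if (.poly_self_intersects(boundary)) stop("boundary polygon self-intersects")
  exclusions <- lapply(exclusions, .poly_ccw)
  usable <- cpp_polygon_area(boundary) -
    sum(vapply(exclusions, cpp_polygon_area, numeric(1)))
  if (usable <= 0) stop("mask has zero usable area")
  structure(list(boundary = boundary, exclusions = exclusions),
            class = "nuclear_mask")
}

#' @export
print.nuclear_mask <- function(x, ...) {
  cat(sprintf("<nuclear_mask> usable area %.4g nm^2 (%d exclusion%s)\n",
              mask_usable_area(x), length(x$exclusions),
              if (length(x$exclusions) == 1) "" else "s"))
  invisible(x)
}

#' Usable area of a nuclear mask
#' @param mask A [nuclear_mask()].
#' @return Area in nm^2 (boundary minus exclusions).
#' @export
mask_usable_area <- function(mask) {
  cpp_polygon_area(mask$boundary) -
    sum(vapply(mask$exclusions, cpp_polygon_area, numeric(1)))
}

.mask_polys <- function(mask) c(list(mask$boundary), mask$exclusions)

.mask_bbox <- function(mask, pad = 0) {
  b <- mask$boundary
  c(xlo = min(b[, 1]) - pad, xhi = max(b[, 1]) + pad,
    ylo = min(b[, 2]) - pad, yhi = max(b[, 2]) + pad)
}

#' Read / write a nuclear mask as JSON
#'
#' Vertex lists in nm; exact enough for deterministic re-clipping (17
#' significant digits).
#' @param path JSON file path.
#' @param mask A [nuclear_mask()].
#' @return `read_mask` returns a [nuclear_mask()].
#' @export
read_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_poly <- function(p) {
    m <- do.call(rbind, lapply(p, function(row) unlist(row)))
    matrix(as.numeric(m), ncol = 2)
  }
  nuclear_mask(as_poly(obj$boundary), lapply(obj$exclusions, as_poly))
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  as_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])
  obj <- list(boundary = as_rows(mask$boundary),
              exclusions = lapply(mask$exclusions, as_rows))
  jsonlite::write_json(obj, path, digits = I(17))
  invisible(path)
}

#' Clip localizations to a nuclear mask
#'
#' Retains records inside the boundary and outside all exclusions. Points
#' within 1e-9 nm of the boundary count as inside (deterministic
#' point-in-polygon behaviour); points within 1e-9 nm of an exclusion edge
#' count as excluded.
#'
#' @param table A [loc_table()].
#' @param mask A [nuclear_mask()].
#' @return The clipped [loc_table()].
#' @export
clip_to_mask <- function(table, mask) {
  if (mask_usable_area(mask) <= 0) stop("degenerate mask")
  tol <- 1e-9
  keep <- cpp_points_in_polygon(table$x, table$y, mask$boundary, tol)
  for (ex in mask$exclusions)
    keep <- keep & !cpp_points_in_polygon(table$x, table$y, ex, tol)
  .as_loc(table[keep, , drop = FALSE], provenance = attr(table, "provenance"))
}

#' Render localizations as a Gaussian-sum super-resolution image
#'
#' Each localization contributes a unit-mass isotropic Gaussian of standard
#' deviation `sigma` (default 20 nm), integrated over the pixel grid. The
#' alternative 9 nm rendering width used for some display figures is
#' selectable via `sigma`.
#'
#' @param table A [loc_table()] (may be empty).
#' @param sigma Gaussian standard deviation (nm, > 0).
#' @param pixel_size Pixel size (nm, > 0).
#' @param extent Optional `c(xlo, xhi, ylo, yhi)` image extent in nm; default
#'   is the data bounding box padded by 5 sigma.
#' @return A `rendered_image`: list with `values` (matrix, rows = y),
#'   `pixel_size`, `origin`.
#' @export
render_gaussian <- function(table, sigma = 20, pixel_size = 10, extent = NULL) {
  stopifnot(sigma > 0, pixel_size > 0)
  if (is.null(extent)) {
    if (nrow(table) == 0) extent <- c(0, pixel_size, 0, pixel_size)
    else extent <- c(min(table$x) - 5 * sigma, max(table$x) + 5 * sigma,
                     min(table$y) - 5 * sigma, max(table$y) + 5 * sigma)
  }
  nx <- max(1L, as.integer(ceiling((extent[2] - extent[1]) / pixel_size)))
  ny <- max(1L, as.integer(ceiling((extent[4] - extent[3]) / pixel_size)))
  vals <- cpp_render_gaussian(table$x, table$y, sigma, pixel_size,
                              extent[1], extent[3], nx, ny)
  structure(list(values = vals, pixel_size = pixel_size,
                 origin = c(extent[1], extent[3])),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d px @ %g nm, total mass %.4g\n",
              ncol(x$values), nrow(x$values), x$pixel_size, sum(x$values)))
  invisible(x)
}

#' Write a rendered image as a 32-bit float TIFF
#'
#' Minimal single-strip little-endian baseline TIFF (SampleFormat = IEEE
#' float), readable by ImageJ/Fiji, scikit-image and tifffile. No external
#' imaging library is required.
#'
#' @param image A [render_gaussian()] result (or any numeric matrix).
#' @param path Output path.
#' @export
write_tiff <- function(image, path) {
  m <- if (inherits(image, "rendered_image")) image$values else as.matrix(image)
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); wr2(42L); wr4(8L)      # header, IFD at 8
  n_tags <- 8L
  data_off <- 8L + 2L + n_tags * 12L + 4L                # pixel data offset
  tag <- function(id, type, count, value) { wr2(id); wr2(type); wr4(count); wr4(value) }
  wr2(n_tags)
  tag(256L, 3L, 1L, w)                 # ImageWidth
  tag(257L, 3L, 1L, h)                 # ImageLength
  tag(258L, 3L, 1L, 32L)               # BitsPerSample
  tag(259L, 3L, 1L, 1L)                # Compression = none
  tag(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
  tag(273L, 4L, 1L, data_off)          # StripOffsets
  tag(279L, 4L, 1L, 4L * w * h)        # StripByteCounts
  tag(339L, 3L, 1L, 3L)                # SampleFormat = IEEE float
  wr4(0L)                              # no next IFD
  # row-major pixel data, top row first
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}
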