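# Astigmatic z-calibration / assignment and the two-channel STORM+PAINT
# registration workflow: second-order polynomial warp, fiducial grouping,
# drift estimation/correction, affine refinement, rigid z translation.

#' Fit an astigmatic z-calibration from a bead scan
#'
#' Fits third-order polynomials Wx(z) and Wy(z) to the elliptical widths of
#' beads scanned through focus (the reference acquisition moves the stage in
#' 10 nm steps over a 1.6 um range). The calibration is rejected when
#' Wx(z) - Wy(z) is not monotone over the requested range, since the width
#' pair then does not identify a unique z.
#'
#' @param bead_scan A [loc_table()] with columns `wx`, `wy` and `z` (known
#'   stage z per record, nm).
#' @param z_range Validity interval (nm); default the scan's range.
#' @return A `z_calibration`: cubic coefficients `cx`, `cy` (intercept
#'   first), `z_range`, and fit RMS residuals.
#' @export
fit_z_calibration <- function(bead_scan, z_range = range(bead_scan$z)) {
  z <- bead_scan$z; wx <- bead_scan$wx; wy <- bead_scan$wy
  if (is.null(z) || is.null(wx) || is.null(wy))
    stop("bead scan must carry z, wx, wy")
  if (length(unique(z)) < 20) stop("scan must cover >= 20 distinct z positions")
  if (any(wx <= 0) || any(wy <= 0)) stop("widths must be positive")
  X <- cbind(1, z, z^2, z^3)
  cx <- qr.solve(X, wx)
  cy <- qr.solve(X, wy)
  rms <- c(x = sqrt(mean((X %*% cx - wx)^2)), y = sqrt(mean((X %*% cy - wy)^2)))
  calib <- structure(list(cx = unname(cx), cy = unname(cy),
                          z_range = as.numeric(z_range), rms = rms),
                     class = "z_calibration")
  zz <- seq(z_range[1], z_range[2], length.out = 201)
  dwd <- diff(.calib_wx(calib, zz) - .calib_wy(calib, zz))
  if (!(all(dwd > 0) || all(dwd < 0)))
    stop("calibration rejected: Wx(z) - Wy(z) not monotone over z_range ",
         "(z is not identifiable from the width pair)")
  if (any(.calib_wx(calib, zz) <= 0) || any(.calib_wy(calib, zz) <= 0))
    stop("calibration rejected: fitted widths not positive over z_range")
  calib
}

.calib_wx <- function(calib, z) calib$cx[1] + calib$cx[2] * z +
  calib$cx[3] * z^2 + calib$cx[4] * z^3
.calib_wy <- function(calib, z) calib$cy[1] + calib$cy[2] * z +
  calib$cy[3] * z^2 + calib$cy[4] * z^3

#' @export
print.z_calibration <- function(x, ...) {
  cat(sprintf("<z_calibration> z in [%g, %g] nm, fit RMS (%.3g, %.3g) nm\n",
              x$z_range[1], x$z_range[2], x$rms[1], x$rms[2]))
  invisible(x)
}

#' Assign axial positions from elliptical widths
#'
#' Inverts the astigmatic calibration by grid search: each record receives
#' the z in `z_range` minimizing
#' `D(z) = (sqrt(wx) - sqrt(Wx(z)))^2 + (sqrt(wy) - sqrt(Wy(z)))^2`
#' on a 1 nm grid. Records whose minimum distance exceeds `reject` (in
#' sqrt-nm units) and records with non-positive widths are dropped; the
#' number dropped is attached as attribute `n_rejected`.
#'
#' @param table A [loc_table()] with `wx`, `wy`.
#' @param calib A [fit_z_calibration()] result.
#' @param grid_step Grid resolution (nm).
#' @param reject Rejection threshold on sqrt-width distance (sqrt-nm).
#' @return The table with a `z` column.
#' @export
assign_z <- function(table, calib, grid_step = 1, reject = 0.5) {
  if (is.null(table$wx) || is.null(table$wy)) stop("widths required")
  zz <- seq(calib$z_range[1], calib$z_range[2], by = grid_step)
  sx <- sqrt(.calib_wx(calib, zz))
  sy <- sqrt(.calib_wy(calib, zz))
  ok <- table$wx > 0 & table$wy > 0
  n <- nrow(table)
  zhat <- rep(NA_real_, n)
  dmin <- rep(Inf, n)
  idx <- which(ok)
  chunk <- 5000L
  for (s in seq(1, length(idx), by = chunk)) {
    ii <- idx[s:min(s + chunk - 1L, length(idx))]
    dx <- outer(sqrt(table$wx[ii]), sx, "-")
    dy <- outer(sqrt(table$wy[ii]), sy, "-")
    D <- dx * dx + dy * dy
    j <- max.col(-D, ties.method = "first")
    zhat[ii] <- zz[j]
    dmin[ii] <- sqrt(D[cbind(seq_along(ii), j)])
  }
  keep <- ok & dmin <= reject
  out <- table[keep, , drop = FALSE]
  out$z <- zhat[keep]
  out <- .as_loc(out, provenance = attr(table, "provenance"))
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Regroup acquisition frames
#'
#' Emulates, at the localization level, the raw-image summation of `group`
#' sequential frames used to form the effective PAINT exposure (default 5,
#' i.e. 5 x 20 ms = 100 ms): frame indices are replaced by
#' `floor(frame / group)`. Coordinates are unchanged.
#'
#' @param table A [loc_table()] with frames.
#' @param group Frames per effective exposure (integer >= 1).
#' @return The regrouped [loc_table()].
#' @export
regroup_frames <- function(table, group = 5) {
  stopifnot(group >= 1)
  if (is.null(table$frame)) stop("frame column required")
  out <- table
  out$frame <- as.integer(table$frame %/% as.integer(group))
  out
}

# --- polynomial warp --------------------------------------------------------

.poly2_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Fit a second-order polynomial channel warp
#'
#' Least-squares full second-order bivariate polynomial mapping matched bead
#' centers of channel a onto channel b; the single surface transfer function
#' that removes residual chromatic aberration between the two colors.
#'
#' @param beads_a,beads_b Matched n x 2 matrices of bead centers (nm).
#' @return A `poly_warp` with 6 coefficients per axis and residual RMS.
#' @export
fit_polynomial_warp <- function(beads_a, beads_b) {
  beads_a <- as.matrix(beads_a); beads_b <- as.matrix(beads_b)
  n <- nrow(beads_a)
  if (n < 6 || nrow(beads_b) != n) stop("need >= 6 matched bead pairs")
  X <- .poly2_design(beads_a[, 1], beads_a[, 2])
  if (qr(X)$rank < 6) stop("rank-deficient bead configuration")
  cx <- qr.solve(X, beads_b[, 1])
  cy <- qr.solve(X, beads_b[, 2])
  res <- cbind(X %*% cx - beads_b[, 1], X %*% cy - beads_b[, 2])
  structure(list(coeff_x = unname(cx), coeff_y = unname(cy),
                 rms = sqrt(mean(res^2))),
            class = "poly_warp")
}

#' Apply a polynomial warp to coordinates
#' @param warp A [fit_polynomial_warp()] result.
#' @param table A [loc_table()] (or an n x 2 matrix).
#' @return Object of the same type with warped x, y.
#' @export
apply_warp <- function(warp, table) {
  m <- if (is.matrix(table)) table else cbind(table$x, table$y)
  X <- .poly2_design(m[, 1], m[, 2])
  xn <- drop(X %*% warp$coeff_x)
  yn <- drop(X %*% warp$coeff_y)
  if (is.matrix(table)) {
    out <- table
    out[, 1] <- xn; out[, 2] <- yn
    return(out)
  }
  out <- table
  out$x <- xn; out$y <- yn
  out
}

#' Check warp invertibility over a field of view
#'
#' Evaluates the Jacobian determinant of the warp on a test grid; an
#' invertible warp has a determinant of constant sign and bounded away from
#' zero over the field.
#' @param warp A `poly_warp`.
#' @param extent `c(xlo, xhi, ylo, yhi)` in nm.
#' @param n Grid points per axis.
#' @return TRUE/FALSE.
#' @export
warp_invertible <- function(warp, extent, n = 21) {
  gx <- seq(extent[1], extent[2], length.out = n)
  gy <- seq(extent[3], extent[4], length.out = n)
  g <- expand.grid(x = gx, y = gy)
  cx <- warp$coeff_x; cy <- warp$coeff_y
  dxdx <- cx[2] + 2 * cx[4] * g$x + cx[5] * g$y
  dxdy <- cx[3] + cx[5] * g$x + 2 * cx[6] * g$y
  dydx <- cy[2] + 2 * cy[4] * g$x + cy[5] * g$y
  dydy <- cy[3] + cy[5] * g$x + 2 * cy[6] * g$y
  dets <- dxdx * dydy - dxdy * dydx
  all(dets > 1e-12) || all(dets < -1e-12)
}

# --- fiducial grouping and drift --------------------------------------------

#' Group fiducial localizations into per-bead clusters
#'
#' Chains localizations across frames by spatial proximity (single linkage at
#' `radius`); clusters seen in fewer than `min_persistence` of the dataset's
#' frames are discarded (transient emitters are not fiducials).
#'
#' @param table A [loc_table()] with frames.
#' @param radius Chaining radius (nm).
#' @param min_persistence Minimum fraction of frames a bead must appear in.
#' @return A `bead_set`: list with `beads` (list of loc_tables) and
#'   `frame_range`.
#' @export
group_fiducials <- function(table, radius = 100, min_persistence = 0.5) {
  if (is.null(table$frame)) stop("frame column required")
  if (nrow(table) == 0) stop("no localizations: registration cannot proceed")
  lab <- cpp_single_linkage(table$x, table$y, radius)
  fr <- range(table$frame)
  nframes <- fr[2] - fr[1] + 1
  beads <- list()
  for (l in sort(unique(lab))) {
    sub <- table[lab == l, , drop = FALSE]
    if (length(unique(sub$frame)) >= min_persistence * nframes)
      beads[[length(beads) + 1]] <- .as_loc(sub, provenance = "bead")
  }
  if (!length(beads))
    stop("zero persistent fiducials: registration cannot proceed")
  structure(list(beads = beads, frame_range = fr), class = "bead_set")
}

#' Bead reference positions (mean over frames)
#' @param bead_set A [group_fiducials()] result.
#' @return n_beads x 2 (or x 3 when z present) matrix.
#' @export
bead_centers <- function(bead_set) {
  t(vapply(bead_set$beads, function(b) {
    if (!is.null(b$z)) c(mean(b$x), mean(b$y), mean(b$z))
    else c(mean(b$x), mean(b$y), NA_real_)
  }, numeric(3)))
}

#' Estimate the drift trajectory from bead clusters
#'
#' Per frame, the displacement is the mean over beads of the bead's position
#' in that frame minus its reference position; the raw track is smoothed with
#' a centred moving average (default 50 frames), linearly interpolated across
#' gaps, extrapolated as constant beyond the observed range, and re-zeroed at
#' the reference frame.
#'
#' @param bead_set A [group_fiducials()] result.
#' @param frames Integer range `c(first, last)` the trajectory must cover.
#' @param window Moving-average window (frames).
#' @param reference_frame Frame at which the displacement is zero (default:
#'   first frame of `frames`).
#' @return A `drift_trajectory`: data.frame `frame, dx, dy, dz` plus
#'   attributes `reference_frame` and `n_extrapolated`.
#' @export
estimate_drift <- function(bead_set, frames = bead_set$frame_range,
                           window = 50, reference_frame = frames[1]) {
  allfr <- seq(frames[1], frames[2])
  has_z <- all(vapply(bead_set$beads, function(b) !is.null(b$z), logical(1)))
  per_axis <- function(axis) {
    acc <- matrix(NA_real_, nrow = length(allfr), ncol = length(bead_set$beads))
    for (k in seq_along(bead_set$beads)) {
      b <- bead_set$beads[[k]]
      v <- tapply(b[[axis]], factor(b$frame, levels = allfr), mean)
      acc[, k] <- as.numeric(v) - mean(b[[axis]])
    }
    rowMeans(acc, na.rm = TRUE)
  }
  axes <- c("x", "y", if (has_z) "z")
  raw <- lapply(axes, per_axis)
  smooth_interp <- function(v) {
    obs <- which(!is.nan(v) & !is.na(v))
    if (!length(obs)) return(list(v = rep(0, length(v)), nex = length(v)))
    vi <- approx(allfr[obs], v[obs], xout = allfr, rule = 2)$y
    w <- max(1L, as.integer(window))
    half <- w %/% 2
    nfr <- length(vi)
    cs <- cumsum(c(0, vi))
    lo <- pmax(1L, seq_len(nfr) - half)
    hi <- pmin(nfr, seq_len(nfr) + half)
    sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    list(v = sm,
         nex = sum(allfr < allfr[obs[1]] | allfr > allfr[obs[length(obs)]]))
  }
  sm <- lapply(raw, smooth_interp)
  traj <- data.frame(frame = allfr,
                     dx = sm[[1]]$v, dy = sm[[2]]$v,
                     dz = if (has_z) sm[[3]]$v else 0)
  # zero at reference frame
  ri <- match(reference_frame, allfr)
  if (is.na(ri)) ri <- 1L
  traj$dx <- traj$dx - traj$dx[ri]
  traj$dy <- traj$dy - traj$dy[ri]
  traj$dz <- traj$dz - traj$dz[ri]
  structure(traj, class = c("drift_trajectory", "data.frame"),
            reference_frame = allfr[ri],
            n_extrapolated = sum(vapply(sm, function(s) s$nex, numeric(1))))
}

.traj_lookup <- function(traj, frame) {
  i <- findInterval(frame, traj$frame, all.inside = TRUE)
  i[frame <= traj$frame[1]] <- 1L
  i[frame >= traj$frame[nrow(traj)]] <- nrow(traj)
  i
}

#' Correct localizations for drift
#'
#' Translates each record by minus the trajectory displacement at its frame.
#' @param table A [loc_table()] with frames.
#' @param traj A [estimate_drift()] result (or compatible data.frame).
#' @return The corrected [loc_table()].
#' @export
correct_drift <- function(table, traj) {
  i <- .traj_lookup(traj, table$frame)
  out <- table
  out$x <- table$x - traj$dx[i]
  out$y <- table$y - traj$dy[i]
  if (!is.null(table$z)) out$z <- table$z - traj$dz[i]
  out
}

#' Apply a drift trajectory (for simulation / round-trip testing)
#' @inheritParams correct_drift
#' @return The drifted [loc_table()].
#' @export
apply_drift <- function(table, traj) {
  i <- .traj_lookup(traj, table$frame)
  out <- table
  out$x <- table$x + traj$dx[i]
  out$y <- table$y + traj$dy[i]
  if (!is.null(table$z)) out$z <- table$z + traj$dz[i]
  out
}

# --- affine refinement, rigid z, report -------------------------------------

#' Refine lateral alignment with a linear affine transform
#'
#' Least-squares 2D affine (2x2 linear part + translation) mapping matched
#' bead positions of channel a onto channel b; applied after the coarse
#' polynomial warp.
#'
#' @param beads_a,beads_b Matched n x 2 matrices (n >= 3, non-collinear).
#' @return An `affine2d` with `A` (2x2), `t` (length 2) and residual RMS.
#' @export
refine_affine <- function(beads_a, beads_b) {
  beads_a <- as.matrix(beads_a); beads_b <- as.matrix(beads_b)
  n <- nrow(beads_a)
  if (n < 3 || nrow(beads_b) != n) stop("need >= 3 matched bead pairs")
  X <- cbind(beads_a[, 1], beads_a[, 2], 1)
  if (qr(X)$rank < 3) stop("collinear bead configuration")
  cx <- qr.solve(X, beads_b[, 1])
  cy <- qr.solve(X, beads_b[, 2])
  A <- rbind(cx[1:2], cy[1:2])
  tv <- c(cx[3], cy[3])
  res <- X %*% cbind(cx, cy) - beads_b
  structure(list(A = unname(A), t = unname(tv), rms = sqrt(mean(res^2))),
            class = "affine2d")
}

#' Apply an affine transform
#' @param aff An [refine_affine()] result.
#' @param table A [loc_table()] or n x 2 matrix.
#' @return Same type, transformed.
#' @export
apply_affine <- function(aff, table) {
  m <- if (is.matrix(table)) table else cbind(table$x, table$y)
  mn <- m %*% t(aff$A)
  mn[, 1] <- mn[, 1] + aff$t[1]
  mn[, 2] <- mn[, 2] + aff$t[2]
  if (is.matrix(table)) {
    out <- table
    out[, 1] <- mn[, 1]; out[, 2] <- mn[, 2]
    return(out)
  }
  out <- table
  out$x <- mn[, 1]; out$y <- mn[, 2]
  out
}

#' Rigid axial alignment between channels
#'
#' The z offset applied to channel b is the mean over matched beads of
#' `z_a - z_b`.
#' @param beads_a_z,beads_b_z Matched numeric vectors of bead z positions.
#' @return Offset in nm.
#' @export
align_z_rigid <- function(beads_a_z, beads_b_z) {
  if (!length(beads_a_z) || length(beads_a_z) != length(beads_b_z))
    stop("no matched beads with z")
  mean(beads_a_z - beads_b_z)
}

#' Registration quality report
#'
#' Per-bead 3D Euclidean residual distance after full alignment, with
#' mean +/- sd summary.
#' @param beads_a,beads_b_aligned Matched n x 3 (or n x 2) matrices.
#' @param z_offset Rigid z offset that was applied (recorded for provenance).
#' @return A `registration_report`: residuals, mean, sd, z_offset.
#' @export
registration_report <- function(beads_a, beads_b_aligned, z_offset = NA_real_) {
  a <- as.matrix(beads_a); b <- as.matrix(beads_b_aligned)
  d <- sqrt(rowSums((a - b)^2))
  structure(list(residuals = d, mean = mean(d), sd = stats::sd(d),
                 z_offset = z_offset),
            class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> %d beads, residual %.2f +/- %.2f nm\n",
              length(x$residuals), x$mean,
              ifelse(is.na(x$sd), 0, x$sd)))
  invisible(x)
}

#' Match beads across channels by mutual nearest neighbours
#'
#' After the coarse warp, channel offsets are small relative to bead spacing;
#' two beads are matched when each is the other's nearest neighbour and the
#' distance is below `max_dist`.
#' @param centers_a,centers_b n x 2 (or n x 3; matching uses x, y) matrices.
#' @param max_dist Maximum lateral match distance (nm).
#' @return Two-column matrix of matched row indices (a, b).
#' @export
match_beads <- function(centers_a, centers_b, max_dist = 500) {
  a <- as.matrix(centers_a); b <- as.matrix(centers_b)
  na <- nrow(a); nb <- nrow(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  ab <- apply(d2, 1, which.min)
  ba <- apply(d2, 2, which.min)
  keep <- which(ba[ab] == seq_len(na) &
                  sqrt(d2[cbind(seq_len(na), ab)]) <= max_dist)
  cbind(a = keep, b = ab[keep])
}

#' Run the full two-channel registration workflow
#'
#' Sequences the alignment steps on two channels of bead-bearing data:
#' coarse polynomial warp of channel b onto channel a (from pre-imaged bead
#' maps or the embedded fiducials), per-channel drift correction, affine
#' refinement and rigid z alignment.
#'
#' @param table_a,table_b Localization tables of the two channels, both
#'   containing fiducials.
#' @param warp Optional pre-fit [fit_polynomial_warp()] mapping b onto a; if
#'   `NULL`, fit from the matched fiducials.
#' @param drift_window Moving-average window for [estimate_drift()].
#' @return List with the aligned `table_b`, drift-corrected `table_a`,
#'   transforms (`warp`, `affine`, `z_offset`, drift trajectories) and a
#'   [registration_report()].
#' @export
register_channels <- function(table_a, table_b, warp = NULL,
                              drift_window = 50) {
  beads_a <- group_fiducials(table_a)
  beads_b <- group_fiducials(table_b)
  ca <- bead_centers(beads_a)
  cb <- bead_centers(beads_b)
  if (is.null(warp)) {
    m <- match_beads(ca, cb)
    if (nrow(m) < 6) stop("too few matched beads for polynomial warp")
    warp <- fit_polynomial_warp(cb[m[, 2], 1:2, drop = FALSE],
                                ca[m[, 1], 1:2, drop = FALSE])
  }
  table_b <- apply_warp(warp, table_b)
  # re-derive channel-b beads in warped coordinates
  beads_b <- group_fiducials(table_b)
  traj_a <- estimate_drift(beads_a, window = drift_window)
  traj_b <- estimate_drift(beads_b, window = drift_window)
  table_a <- correct_drift(table_a, traj_a)
  table_b <- correct_drift(table_b, traj_b)
  beads_a <- group_fiducials(table_a)
  beads_b <- group_fiducials(table_b)
  ca <- bead_centers(beads_a)
  cb <- bead_centers(beads_b)
  m <- match_beads(ca, cb)
  if (nrow(m) < 3) stop("too few matched beads for affine refinement")
  aff <- refine_affine(cb[m[, 2], 1:2, drop = FALSE],
                       ca[m[, 1], 1:2, drop = FALSE])
  table_b <- apply_affine(aff, table_b)
  cb2 <- cb
  cb2[, 1:2] <- apply_affine(aff, cb[, 1:2, drop = FALSE])
  zoff <- if (!anyNA(ca[m[, 1], 3]) && !anyNA(cb2[m[, 2], 3]))
    align_z_rigid(ca[m[, 1], 3], cb2[m[, 2], 3]) else NA_real_
  if (!is.na(zoff) && !is.null(table_b$z)) table_b$z <- table_b$z + zoff
  bb <- cb2[m[, 2], , drop = FALSE]
  if (!is.na(zoff)) bb[, 3] <- bb[, 3] + zoff
  aa <- ca[m[, 1], , drop = FALSE]
  if (anyNA(aa[, 3]) || anyNA(bb[, 3])) { aa <- aa[, 1:2]; bb <- bb[, 1:2] }
  rep <- registration_report(aa, bb, z_offset = zoff)
  list(table_a = table_a, table_b = table_b,
       transforms = list(warp = warp, affine = aff, z_offset = zoff,
                         drift_a = traj_a, drift_b = traj_b),
       report = rep)
}

# --- transform serialization ------------------------------------------------

#' Write / read registration transforms as JSON
#'
#' Full-precision (17 significant digits) serialization: reloading a
#' transform reproduces its outputs bit-identically.
#' @param transforms A list as produced by [register_channels()]
#'   (`warp`, `affine`, `z_offset`, `drift_a`, `drift_b`; any subset).
#' @param path JSON path.
#' @return `read_transforms` returns the transforms list.
#' @export
write_transforms <- function(transforms, path) {
  ser <- list()
  if (!is.null(transforms$warp))
    ser$warp <- list(coeff_x = transforms$warp$coeff_x,
                     coeff_y = transforms$warp$coeff_y,
                     rms = transforms$warp$rms)
  if (!is.null(transforms$affine))
    ser$affine <- list(A = as.vector(transforms$affine$A),
                       t = transforms$affine$t,
                       rms = transforms$affine$rms)
  if (!is.null(transforms$z_offset)) ser$z_offset <- transforms$z_offset
  for (dn in c("drift_a", "drift_b")) {
    if (!is.null(transforms[[dn]]))
      ser[[dn]] <- list(frame = transforms[[dn]]$frame,
                        dx = transforms[[dn]]$dx,
                        dy = transforms[[dn]]$dy,
                        dz = transforms[[dn]]$dz,
                        reference_frame = attr(transforms[[dn]],
                                               "reference_frame"))
  }
  jsonlite::write_json(ser, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(ser$warp))
    out$warp <- structure(list(coeff_x = ser$warp$coeff_x,
                               coeff_y = ser$warp$coeff_y,
                               rms = ser$warp$rms), class = "poly_warp")
  if (!is.null(ser$affine))
    out$affine <- structure(list(A = matrix(ser$affine$A, 2, 2),
                                 t = ser$affine$t, rms = ser$affine$rms),
                            class = "affine2d")
  if (!is.null(ser$z_offset)) out$z_offset <- ser$z_offset
  for (dn in c("drift_a", "drift_b")) {
    if (!is.null(ser[[dn]])) {
      df <- data.frame(frame = ser[[dn]]$frame, dx = ser[[dn]]$dx,
                       dy = ser[[dn]]$dy, dz = ser[[dn]]$dz)
      out[[dn]] <- structure(df, class = c("drift_trajectory", "data.frame"),
                             reference_frame = ser[[dn]]$reference_frame)
    }
  }
  out
}
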