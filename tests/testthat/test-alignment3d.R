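test_that("z calibration recovers generative cubics and rejects degeneracy", {
  z <- seq(-800, 800, by = 10)  # reference scan: 10 nm steps over 1.6 um
  calib0 <- true_z_calibration()
  scan <- loc_table(rep(0, length(z)), rep(0, length(z)), z = z,
                    wx = clutchscope:::.calib_wx(calib0, z),
                    wy = clutchscope:::.calib_wy(calib0, z))
  fit <- fit_z_calibration(scan)
  expect_equal(fit$cx, calib0$cx, tolerance = 1e-6)
  expect_equal(fit$cy, calib0$cy, tolerance = 1e-6)

  sym <- scan
  sym$wy <- sym$wx  # Wx == Wy everywhere: z not identifiable
  expect_error(fit_z_calibration(sym), "monotone")
  expect_error(fit_z_calibration(scan[1:10, ]), "20 distinct")
})

test_that("assign_z inverts the width curves", {
  calib <- true_z_calibration()
  set.seed(5)
  z0 <- runif(300, -700, 700)
  tab <- loc_table(runif(300), runif(300),
                   wx = clutchscope:::.calib_wx(calib, z0),
                   wy = clutchscope:::.calib_wy(calib, z0))
  out <- assign_z(tab, calib)
  expect_equal(nrow(out), 300)
  expect_lte(max(abs(out$z - z0)), 1)  # grid tolerance

  # z at the symmetric midpoint (Wx == Wy) maps to 0
  mid <- loc_table(0, 0, wx = clutchscope:::.calib_wx(calib, 0),
                   wy = clutchscope:::.calib_wy(calib, 0))
  expect_equal(assign_z(mid, calib)$z, 0)

  # noisy widths: median error bounded and growing with noise
  err <- vapply(c(2, 8), function(s) {
    noisy <- tab
    noisy$wx <- pmax(noisy$wx + rnorm(300, 0, s), 1)
    noisy$wy <- pmax(noisy$wy + rnorm(300, 0, s), 1)
    median(abs(assign_z(noisy, calib, reject = Inf)$z - z0))
  }, numeric(1))
  expect_lt(err[1], err[2])
  expect_lt(err[2], 60)
})

test_that("regroup_frames floors frame indices", {
  tab <- loc_table(1:10, 1:10, frame = 0:9)
  expect_equal(unique(regroup_frames(tab, 5)$frame), c(0L, 1L))
  expect_equal(regroup_frames(tab, 1)$frame, 0:9)
  expect_equal(regroup_frames(tab, 5)$x, tab$x)
})

test_that("polynomial warp fits exactly and reports noise residuals", {
  set.seed(6)
  g <- as.matrix(expand.grid(x = seq(0, 4000, len = 5),
                             y = seq(0, 4000, len = 5)))
  w0 <- true_poly_warp()
  target <- apply_warp(w0, g)
  fit <- fit_polynomial_warp(g, target)
  expect_equal(fit$coeff_x, w0$coeff_x, tolerance = 1e-9)
  expect_equal(fit$coeff_y, w0$coeff_y, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  expect_true(warp_invertible(fit, c(0, 4000, 0, 4000)))

  idfit <- fit_polynomial_warp(g, g)
  expect_equal(apply_warp(idfit, g), g, tolerance = 1e-9)

  # least-squares residual under isotropic noise: rms ~ sigma * sqrt(1 - p/n)
  noisy <- target + rnorm(length(target), 0, 2)
  nfit <- fit_polynomial_warp(g, noisy)
  expect_equal(nfit$rms, 2 * sqrt(1 - 6 / 25), tolerance = 0.35)
  expect_error(fit_polynomial_warp(g[1:4, ], target[1:4, ]), "6")
})

test_that("fiducial grouping finds persistent beads only", {
  set.seed(7)
  frames <- 1000
  mk <- function(cx, cy, frac) {
    fr <- sort(sample.int(frames, round(frac * frames)))
    loc_table(cx + rnorm(length(fr), 0, 5), cy + rnorm(length(fr), 0, 5),
              frame = fr)
  }
  tab <- rbind(mk(0, 0, 1), mk(10000, 0, 1), mk(0, 10000, 1),
               mk(5000, 5000, 0.1))
  beads <- group_fiducials(clutchscope:::.as_loc(tab))
  expect_equal(length(beads$beads), 3)  # the 10% transient is discarded
  sizes <- vapply(beads$beads, nrow, integer(1))
  expect_true(all(sizes > 900))
  expect_error(group_fiducials(clutchscope:::.as_loc(mk(0, 0, 0.2))),
               "persistent")
})

test_that("drift is estimated and corrected against generative truth", {
  set.seed(8)
  frames <- 2000
  traj0 <- make_drift(frames, rate = c(0.1, 0, 0))
  bead_pos <- cbind(runif(5, 0, 1e4), runif(5, 0, 1e4))
  idx <- rep(1:5, each = frames)
  beads <- loc_table(bead_pos[idx, 1] + rnorm(5 * frames, 0, 5),
                     bead_pos[idx, 2] + rnorm(5 * frames, 0, 5),
                     frame = rep(0:(frames - 1), 5))
  drifted <- apply_drift(beads, traj0)
  est <- estimate_drift(group_fiducials(drifted))
  # compare recovered trajectory shape to truth (both zeroed at frame 0)
  rmse <- sqrt(mean((est$dx - traj0$dx)^2 + (est$dy - traj0$dy)^2))
  expect_lt(rmse, 2)

  # correct_drift(apply_drift(t)) == t for exact trajectories
  back <- correct_drift(apply_drift(beads, traj0), traj0)
  expect_equal(back$x, beads$x, tolerance = 1e-9)
  # zero drift -> near-zero trajectory
  est0 <- estimate_drift(group_fiducials(beads))
  expect_lt(max(abs(est0$dx)), 2)
  # corrected bead cluster sd returns to the localization noise level
  corr <- correct_drift(drifted, est)
  b1 <- corr[1:frames, ]  # rows are bead-major; first bead
  expect_equal(sd(b1$x), 5, tolerance = 0.12)
})

test_that("affine refinement and rigid z alignment recover truth", {
  set.seed(9)
  a <- cbind(runif(8, 0, 5000), runif(8, 0, 5000))
  th <- 0.5 * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  b <- a %*% t(Rm) + matrix(c(10, -7), 8, 2, byrow = TRUE)
  fit <- refine_affine(a, b)
  expect_equal(fit$A, Rm, tolerance = 1e-9)
  expect_equal(fit$t, c(10, -7), tolerance = 1e-9)
  idf <- refine_affine(a, a)
  expect_equal(idf$A, diag(2), tolerance = 1e-12)
  expect_equal(idf$t, c(0, 0), tolerance = 1e-9)
  noisy <- b + rnorm(16, 0, 3)
  expect_equal(refine_affine(a, noisy)$rms, 3, tolerance = 0.8)
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(refine_affine(coll, coll), "collinear")

  expect_equal(align_z_rigid(c(100, 100), c(60, 60)), 40)
  expect_equal(align_z_rigid(c(100, 100), c(62, 58)), 40)
  set.seed(10)
  za <- rnorm(10, 50, 10); zb <- za - 40 + rnorm(10, 0, 10)
  expect_lt(abs(align_z_rigid(za, zb) - 40), 2 * 10 * sqrt(2) / sqrt(10) + 5)
})

test_that("registration_report summarizes residuals", {
  a <- cbind(1:3, 1:3, 1:3)
  expect_equal(registration_report(a, a)$mean, 0)
  b <- a; b[, 1] <- b[, 1] + 5
  rep <- registration_report(a, b)
  expect_equal(rep$mean, 5)
  expect_equal(rep$sd, 0)
})

test_that("transforms serialize bit-identically", {
  set.seed(11)
  tr <- list(warp = true_poly_warp(),
             affine = structure(list(A = matrix(rnorm(4), 2), t = rnorm(2),
                                     rms = 0.1), class = "affine2d"),
             z_offset = 40.123456789,
             drift_a = make_drift(50, c(0.03, 0.02, 0.01)))
  path <- withr::local_tempfile(fileext = ".json")
  write_transforms(tr, path)
  back <- read_transforms(path)
  pts <- cbind(runif(20, 0, 5000), runif(20, 0, 5000))
  expect_identical(apply_warp(back$warp, pts), apply_warp(tr$warp, pts))
  expect_identical(apply_affine(back$affine, pts), apply_affine(tr$affine, pts))
  expect_identical(back$z_offset, tr$z_offset)
  expect_identical(back$drift_a$dx, tr$drift_a$dx)
})
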