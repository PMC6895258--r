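test_that("clutch voronoi tiles the usable mask", {
  m <- square_mask(1000)
  quad <- data.frame(id = 1:4, x = c(250, 750, 750, 250),
                     y = c(250, 250, 750, 750))
  cp <- clutch_voronoi(quad, m)
  expect_equal(cp$areas, rep(250000, 4))

  set.seed(23)
  hole <- ellipse_mask(900, 700, exclusions = list(
    rbind(c(-150, -150), c(150, -150), c(150, 150), c(-150, 150))))
  cl <- uniform_locs(60, hole)
  cp2 <- clutch_voronoi(data.frame(id = 1:60, x = cl$x, y = cl$y), hole)
  expect_equal(sum(cp2$areas), mask_usable_area(hole), tolerance = 1e-6)
  out <- data.frame(id = 1:5, x = c(400, -400, 400, -400, 5000),
                    y = c(400, 400, -400, -400, 0))
  expect_warning(cp3 <- clutch_voronoi(out, hole), "outside")
  expect_equal(length(cp3$ids), 4)
})

test_that("assign_dna conserves counts and follows polygon areas", {
  set.seed(24)
  m <- ellipse_mask(900, 700)
  cl <- uniform_locs(40, m)
  cp <- clutch_voronoi(data.frame(id = 1:40, x = cl$x, y = cl$y), m)
  dna <- uniform_locs(20000, m)
  asg <- assign_dna(dna, cp)
  expect_equal(length(asg), nrow(dna))
  expect_false(anyNA(asg))
  counts <- tabulate(asg, 40)
  expect_equal(sum(counts), nrow(dna))
  # multinomial oracle: chi-square against area proportions
  p <- cp$areas / sum(cp$areas)
  chi <- sum((counts - 20000 * p)^2 / (20000 * p))
  expect_lt(chi, qchisq(0.999, df = 39))
})

test_that("radial profiles match Poisson and geometric oracles", {
  set.seed(25)
  m <- ellipse_mask(1500, 1200)
  cl <- uniform_locs(25, m)
  cp <- clutch_voronoi(data.frame(id = 1:25, x = cl$x, y = cl$y), m)
  dna <- uniform_locs(60000, m)
  pr <- radial_profile(cp, dna, dr = 10, r_max = 200)
  lam <- nrow(dna) / mask_usable_area(m)
  # cumulative density ~ lambda at every radius (within 3 sd of counting)
  for (j in c(3, 10, 20)) {
    n_tot <- sum(pr$count[, j]); a_tot <- sum(pr$area[, j])
    expect_lt(abs(n_tot / a_tot - lam), 3 * sqrt(lam * a_tot) / a_tot + 1e-12)
  }
  # counts nondecreasing in r; area bounded by pi r^2 and polygon area
  expect_true(all(apply(pr$count, 1, function(v) all(diff(v) >= 0))))
  for (j in seq_along(pr$radii)) {
    expect_true(all(pr$area[, j] <= pi * pr$radii[j]^2 + 1e-6))
    expect_true(all(pr$area[, j] <= vapply(seq_len(25), function(i)
      clutchscope:::cpp_polygon_area(cp$cells[[i]]), numeric(1)) + 1e-6))
  }
  # disk fully inside a big polygon: clipped area = pi r^2 to <= 0.1%
  big <- square_mask(4000)
  cpb <- clutch_voronoi(data.frame(id = 1:4, x = c(1000, 3000, 1000, 3000),
                                   y = c(1000, 1000, 3000, 3000)), big)
  prb <- radial_profile(cpb, loc_table(numeric(), numeric()), 10, 200)
  expect_equal(prb$area[1, 20], pi * 200^2, tolerance = 1e-3)
  expect_true(all(prb$count == 0))
})

test_that("associated fraction matches the area-ratio oracle and is monotone", {
  set.seed(26)
  m <- ellipse_mask(1500, 1200)
  cl <- uniform_locs(30, m)
  cp <- clutch_voronoi(data.frame(id = 1:30, x = cl$x, y = cl$y), m)
  dna <- uniform_locs(40000, m)
  pr <- radial_profile(cp, dna, 10, 200)
  af <- associated_fraction(pr, 120)
  oracle <- 100 * sum(pr$area[, 12]) / sum(cp$areas)
  expect_equal(af$percent, oracle, tolerance = 0.05)
  # monotone nondecreasing in r
  curve <- vapply(seq(10, 200, 10), function(r)
    associated_fraction(pr, r)$percent, numeric(1))
  expect_true(all(diff(curve) >= 0))
  # all DNA close to centroids -> 100%
  near <- loc_table(rep(cl$x, 3) + rnorm(90, 0, 3),
                    rep(cl$y, 3) + rnorm(90, 0, 3))
  prn <- radial_profile(cp, clip_to_mask(near, m), 10, 200)
  expect_equal(associated_fraction(prn, 120)$percent, 100)
})

test_that("colocalized clutch fraction uses a strict count threshold", {
  m <- square_mask(2000)
  cp <- clutch_voronoi(data.frame(id = 1:4, x = c(500, 1500, 500, 1500),
                                  y = c(500, 500, 1500, 1500)), m)
  # clutch 1: 6 DNA (counted); clutch 2: exactly 5 (not counted: strict >)
  dna <- loc_table(c(rep(500, 6), rep(1500, 5)) + (1:11) * 0.1,
                   c(rep(500, 6), rep(500, 5)))
  pr <- radial_profile(cp, dna, 10, 200)
  expect_equal(colocalized_clutch_fraction(pr, 120, 5), 25)
})

test_that("similarity matrix is symmetric, label-invariant, and finds steps", {
  set.seed(27)
  m <- ellipse_mask(9000, 6750)
  # well-separated centroids so background annuli stay exchangeable
  cand <- uniform_locs(600, m)
  hc <- clutchscope:::cpp_single_linkage(cand$x, cand$y, 450)
  cl <- cand[!duplicated(hc), ][1:150, ]
  cp <- clutch_voronoi(data.frame(id = 1:150, x = cl$x, y = cl$y), m)
  # step profile: dense within 50 nm of centroids over uniform background
  n_in <- 9000
  th <- runif(n_in, 0, 2 * pi); r <- 50 * sqrt(runif(n_in))
  pick <- sample.int(150, n_in, TRUE)
  n_bg <- round(0.0053 * mask_usable_area(m))
  dna <- rbind(data.frame(x = cl$x[pick] + r * cos(th),
                          y = cl$y[pick] + r * sin(th)),
               as.data.frame(uniform_locs(n_bg, m))[, c("x", "y")])
  dna <- clip_to_mask(loc_table(dna$x, dna$y), m)
  pr <- radial_profile(cp, dna, 10, 200)
  sm <- similarity_matrix(pr)
  expect_true(all(is.na(diag(sm$p))))
  expect_equal(sm$p, t(sm$p))
  expect_true(all(sm$p > 0 & sm$p <= 1, na.rm = TRUE))
  # pairs straddling the 50 nm step are strongly dissimilar
  lo <- sm$radii <= 50; hi <- sm$radii > 50
  expect_lt(max(sm$p[lo, hi]), 1e-4)
  expect_equal(transition_radius(sm), 50)

  # permuting clutch order leaves the matrix unchanged
  perm <- sample.int(150)
  pr2 <- pr
  pr2$area <- pr$area[perm, ]; pr2$count <- pr$count[perm, ]
  pr2$cum_density <- pr$cum_density[perm, ]
  pr2$total_count <- pr$total_count[perm]; pr2$ids <- pr$ids[perm]
  pr2$cell_id <- pr$cell_id[perm]
  sm2 <- similarity_matrix(pr2)
  expect_equal(sm2$p, sm$p)

  # uniform DNA: no stable structure; the sub-alpha pair fraction stays at
  # the false-positive level (the literal switch rule can still return a
  # spurious radius from isolated 5%-level pairs, so the radius itself is
  # not asserted)
  pru <- radial_profile(cp, uniform_locs(round(0.0053 * mask_usable_area(m)), m),
                        10, 200)
  smu <- similarity_matrix(pru)
  expect_lt(mean(smu$p[upper.tri(smu$p)] < 0.05, na.rm = TRUE), 0.25)
})

test_that("nnd matches the all-pairs oracle and respects islands", {
  d <- data.frame(id = 1:2, x = c(0, 300), y = c(0, 0), island = c(1L, 1L))
  cs <- list(clutches = d, eps = 40)
  class(cs) <- "clutch_set"
  out <- nnd(cs)
  expect_equal(out$nnd, c(300, 300))

  g <- expand.grid(x = seq(0, 400, 100), y = seq(0, 400, 100))
  cs2 <- list(clutches = data.frame(id = seq_len(nrow(g)), x = g$x, y = g$y,
                                    island = 1L), eps = 40)
  class(cs2) <- "clutch_set"
  expect_true(all(nnd(cs2)$nnd == 100))

  set.seed(28)
  n <- 300
  cs3 <- list(clutches = data.frame(id = 1:n, x = runif(n, 0, 5000),
                                    y = runif(n, 0, 5000),
                                    island = rep(1:30, 10)), eps = 40)
  class(cs3) <- "clutch_set"
  out3 <- nnd(cs3)
  dm <- as.matrix(dist(cbind(cs3$clutches$x, cs3$clutches$y)))
  diag(dm) <- Inf
  expect_equal(out3$nnd, unname(apply(dm, 1, min)))
  # same-island restriction: neighbor always from the same island
  ri <- nnd(cs3, same_island_only = TRUE)
  isl <- cs3$clutches$island[match(ri$neighbor, cs3$clutches$id)]
  expect_true(all(isl == cs3$clutches$island[match(ri$id, cs3$clutches$id)]))
})

test_that("density_vs_nnd is flat when density is independent of NND", {
  set.seed(29)
  m <- ellipse_mask(2500, 2000)
  profs <- list(); nnds <- list()
  for (cell in 1:3) {
    cl <- uniform_locs(120, m)
    cp <- clutch_voronoi(data.frame(id = 1:120, x = cl$x, y = cl$y), m)
    pr <- radial_profile(cp, uniform_locs(30000, m), 10, 100,
                         cell_id = cell)
    profs[[cell]] <- pr
    cs <- list(clutches = data.frame(id = 1:120, x = cl$x, y = cl$y,
                                     island = 1L), eps = 40)
    class(cs) <- "clutch_set"
    nnds[[cell]] <- nnd(cs, same_island_only = TRUE)
  }
  curve <- density_vs_nnd(profs, nnds, r = 70, bin = 50, max_nnd = 500)
  lam <- 30000 / mask_usable_area(m)
  good <- curve$n_cells >= 2
  expect_true(any(good))
  expect_true(all(abs(curve$mean[good] - lam) < 0.6 * lam))
  # no systematic trend: correlation of bin mean with NND is weak
  ct <- cor.test(curve$nnd_mid[good], curve$mean[good])
  expect_gt(ct$p.value, 0.01)
})

test_that("density_vs_size reports rank correlations under null and trend", {
  set.seed(30)
  m <- ellipse_mask(2500, 2000)
  cl <- uniform_locs(150, m)
  cp <- clutch_voronoi(data.frame(id = 1:150, x = cl$x, y = cl$y), m)
  pr <- radial_profile(cp, uniform_locs(30000, m), 10, 100)
  cs <- list(clutches = data.frame(id = 1:150, x = cl$x, y = cl$y,
                                   area = runif(150, 1000, 20000)), eps = 40)
  class(cs) <- "clutch_set"
  res <- density_vs_size(pr, cs, radii = c(50, 100))
  # size-independent packing: null correlation
  expect_true(all(abs(res$correlation$rho) < 0.25))
  expect_true(all(res$correlation$p.value > 0.001))

  # alternative: density increases with declared area
  ord <- rank(cs$clutches$area)
  pr2 <- pr
  pr2$count <- pr$count * (1 + 3 * (ord / 150))  # inflate counts with area
  pr2$cum_density <- pr2$count / pr2$area
  res2 <- density_vs_size(pr2, cs, radii = c(50))
  expect_gt(res2$correlation$rho[1], 0.3)
  expect_lt(res2$correlation$p.value[1], 0.001)
})

test_that("shift and subsample controls behave as documented", {
  set.seed(31)
  tab <- loc_table(runif(100), runif(100))
  expect_equal(shift_control(tab, 0), tab)
  sh <- shift_control(tab, 20)
  expect_equal(sh$x, tab$x + 20)
  expect_equal(sh$y, tab$y + 20)

  cs <- segment_clutches(clutch_points(cbind(seq(0, 9000, 1000), 0)),
                         eps = 10, min_size = 3)
  expect_identical(subsample_control(cs, 1), cs)
  s1 <- subsample_control(cs, 0.5, seed = 99)
  s2 <- subsample_control(cs, 0.5, seed = 99)
  expect_identical(s1$clutches$id, s2$clutches$id)
  expect_equal(nrow(s1$clutches), 5)
})

test_that("plot_similarity renders without error", {
  set.seed(32)
  m <- ellipse_mask(2000, 1500)
  cl <- uniform_locs(30, m)
  cp <- clutch_voronoi(data.frame(id = 1:30, x = cl$x, y = cl$y), m)
  sm <- similarity_matrix(radial_profile(cp, uniform_locs(5000, m), 10, 100))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot_similarity(sm))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
})
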