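test_that("tessellation matches analytic cells on symmetric configurations", {
  m <- square_mask(100)
  tab <- loc_table(c(25, 75, 75, 25), c(25, 25, 75, 75))
  vm <- tessellate(tab, m, 2)
  expect_equal(vm$cells$measure, rep(2500, 4))
  expect_equal(vm$cells$density, rep(4e-4, 4))

  # two points split a rectangle by the perpendicular bisector
  m2 <- nuclear_mask(rbind(c(0, 0), c(200, 0), c(200, 100), c(0, 100)))
  two <- loc_table(c(40, 160), c(50, 50), provenance = "t")
  jit <- loc_table(c(40, 160, 40, 160), c(50, 50, 20, 80))
  vm2 <- tessellate(jit, m2, 2)
  expect_equal(sum(vm2$cells$measure), 20000, tolerance = 1e-9)
})

test_that("cell measures are conserved and scale-equivariant", {
  set.seed(12)
  m <- ellipse_mask(900, 600, exclusions = list(
    rbind(c(-100, -100), c(100, -100), c(100, 100), c(-100, 100))))
  tab <- uniform_locs(2000, m)
  vm <- tessellate(tab, m, 2)
  expect_equal(sum(vm$cells$measure), mask_usable_area(m),
               tolerance = 1e-6)
  expect_equal(mean(vm$cells$density), 2000 / mask_usable_area(m),
               tolerance = 0.15)

  # scaling coordinates by s scales areas by s^2, densities by s^-2
  s <- 3
  ms <- nuclear_mask(m$boundary * s, lapply(m$exclusions, function(e) e * s))
  tabs <- loc_table(tab$x * s, tab$y * s)
  vms <- tessellate(tabs, ms, 2)
  expect_equal(vms$cells$measure, vm$cells$measure * s^2, tolerance = 1e-9)

  # duplicates are jittered deterministically, not fatal
  dup <- loc_table(c(tab$x, tab$x[1:5]), c(tab$y, tab$y[1:5]))
  vmd <- tessellate(dup, m, 2)
  expect_equal(sum(vmd$cells$measure), mask_usable_area(m), tolerance = 1e-6)
})

test_that("3D tessellation conserves the slab volume", {
  set.seed(13)
  m <- ellipse_mask(700, 500)
  tab <- uniform_locs(600, m, z = c(-60, 60))
  vm <- tessellate(tab, m, 3, z_slab = c(-60, 60))
  expect_equal(sum(vm$cells$measure), mask_usable_area(m) * 120,
               tolerance = 1e-6)
})

test_that("compaction fold matches a brute-force percentile oracle", {
  set.seed(14)
  m <- ellipse_mask(900, 650)
  vm <- tessellate(uniform_locs(3000, m), m, 2)
  fold <- compaction_fold(vm)
  # brute force on the same cells
  a <- vm$cells$measure[vm$cells$measure > 0]
  oracle <- mean(1 / a[a <= quantile(a, 0.15)]) /
    mean(1 / a[a >= quantile(a, 0.85)])
  expect_equal(fold, oracle)
  expect_gt(fold, 2)    # intrinsic Poisson-Voronoi spread + edge clipping
  expect_lt(fold, 15)

  # two-component mixture with 7x intensity contrast, equal counts: jittered
  # lattices make the percentile classes capture the region densities
  half <- nuclear_mask(rbind(c(0, 0), c(2000, 0), c(2000, 1000), c(0, 1000)))
  gd <- expand.grid(x = seq(12.5, 500, 25), y = seq(12.5, 1000, 25))
  gs <- expand.grid(x = seq(533, 2000, 66.14), y = seq(33, 1000, 66.14))
  pts <- rbind(gd, gs)
  vm7 <- tessellate(loc_table(pts$x + runif(nrow(pts), -1, 1),
                              pts$y + runif(nrow(pts), -1, 1)), half, 2)
  expect_equal(compaction_fold(vm7), 7, tolerance = 0.1)
})

test_that("density distributions bin, stack and compare correctly", {
  set.seed(15)
  m <- ellipse_mask(800, 600)
  maps <- lapply(1:3, function(i) tessellate(uniform_locs(1500, m), m, 2))
  dd <- density_distribution(maps)
  expect_equal(length(dd$edges), 300)
  expect_equal(dd$edges[1], 0.1e-9)
  expect_equal(dd$edges[300], 0.94)
  expect_true(all(diff(dd$median) >= 0))
  expect_true(all(dd$median >= dd$q25 - 1e-12 & dd$median <= dd$q75 + 1e-12))
  expect_equal(max(dd$cumulative), 1)

  one <- density_distribution(maps[[1]])
  expect_equal(one$median, one$q25)
  expect_equal(one$median, one$q75)

  idc <- compare_distributions(dd, dd)
  expect_equal(idc$statistic, 0)
  expect_equal(idc$p.value, 1)
  d3 <- density_distribution(tessellate(uniform_locs(400, m, z = c(-60, 60)),
                                        m, 3, z_slab = c(-60, 60)))
  expect_equal(d3$edges[1], 5e-7)
  expect_equal(d3$edges[300], 0.0025)
  expect_error(compare_distributions(dd, d3), "bins")
  expect_true(compare_distributions(dd, d3 <- density_distribution(
    maps, bin_lo = 0.1e-9, bin_hi = 0.94))$p.value >= 0)
})

test_that("compare_distributions detects generative density shifts", {
  set.seed(16)
  m <- ellipse_mask(800, 600)
  ctrl <- lapply(1:6, function(i) tessellate(uniform_locs(1500, m), m, 2))
  tsa <- lapply(1:6, function(i) tessellate(uniform_locs(750, m), m, 2))
  # the median-curve KS measures the horizontal (log-density) offset in
  # curve-bin units, so it only resolves order-of-magnitude shifts; the
  # pooled per-cell KS detects the 2x shift easily
  res <- compare_distributions(density_distribution(ctrl),
                               density_distribution(tsa),
                               maps_a = ctrl, maps_b = tsa)
  expect_lt(res$pooled_p.value, 1e-6)
  expect_gte(res$p.value, 0)
  # symmetry of the median-curve statistic
  res2 <- compare_distributions(density_distribution(tsa),
                                density_distribution(ctrl))
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p.value, res$p.value)
  # a large (20x) shift is resolved by the median-curve KS as well
  big <- lapply(1:6, function(i) tessellate(uniform_locs(6000, m), m, 2))
  tiny <- lapply(1:6, function(i) tessellate(uniform_locs(300, m), m, 2))
  res3 <- compare_distributions(density_distribution(big),
                                density_distribution(tiny))
  expect_lt(res3$p.value, 0.05)
})

test_that("colorize maps the density scale and blacks the area tail", {
  set.seed(17)
  m <- ellipse_mask(800, 600)
  vm <- tessellate(uniform_locs(1000, m), m, 2)
  col <- colorize(vm)
  expect_equal(sum(col$black), floor(0.005 * 1000))
  ord <- order(-vm$cells$measure)
  expect_true(all(col$black[ord[1:5]]))
  # saturation at the scale ends
  hi <- vm$cells$density >= 0.02 & !col$black
  expect_true(all(col$value[hi] == 1))
  lo <- vm$cells$density <= 0.001 & !col$black
  expect_true(all(col$value[lo] == 0))
})
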