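test_that("segment_clutches recovers generative blobs and obeys min_size", {
  set.seed(18)
  n <- 200
  blob <- function(cx) cbind(rnorm(n, cx, 48), rnorm(n, 0, 48))
  pts <- rbind(blob(0), blob(10000))
  cs <- segment_clutches(loc_table(pts[, 1], pts[, 2]), eps = 40, min_size = 10)
  expect_equal(nrow(cs$clutches), 2)
  expect_lt(min(abs(cs$clutches$x - 0), abs(cs$clutches$x - 10000)), 10)
  expect_true(all(cs$clutches$n_locs >= 190))  # stray tail points may detach
  expect_true(all(abs(cs$clutches$y) < 10))

  # lattice spaced 3x eps: no components of size >= 2
  g <- expand.grid(x = seq(0, 1200, by = 120), y = seq(0, 1200, by = 120))
  cs0 <- segment_clutches(loc_table(g$x, g$y), eps = 40, min_size = 2)
  expect_equal(nrow(cs0$clutches), 0)
  expect_equal(nrow(segment_clutches(loc_table(numeric(), numeric()))$clutches), 0)
})

test_that("segment_clutches equals the brute-force linkage oracle", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(100:600, 1)
    x <- runif(n, 0, 2000); y <- runif(n, 0, 2000)
    eps <- runif(1, 30, 120)
    lab <- clutchscope:::cpp_single_linkage(x, y, eps)
    oracle <- brute_components(x, y, eps)
    # identical partitions (labels may differ)
    expect_equal(length(unique(lab)), length(unique(oracle)))
    expect_true(all(tapply(oracle, lab, function(v) length(unique(v))) == 1))
  }
})

test_that("islands group by member proximity with transitive closure", {
  # chain of three clutches, each within link of the next only
  centers <- rbind(c(0, 0), c(100, 0), c(200, 0))
  cs <- segment_clutches(clutch_points(centers), eps = 10, min_size = 3)
  expect_equal(nrow(cs$clutches), 3)
  isl <- group_islands(cs, link = 110)
  expect_equal(length(unique(isl$clutches$island)), 1)
  expect_equal(attr(isl, "islands")$clusters_per_island, 3)

  far <- group_islands(cs, link = 50)
  expect_equal(length(unique(far$clutches$island)), 3)
  expect_equal(attr(far, "islands")$percent_isolated, 100)

  # islands of 4 clutches at 60 nm spacing, islands far apart
  quad <- function(ox) rbind(c(ox, 0), c(ox + 60, 0), c(ox, 60), c(ox + 60, 60))
  cs4 <- segment_clutches(clutch_points(rbind(quad(0), quad(10000))),
                          eps = 10, min_size = 3)
  isl4 <- group_islands(cs4, link = 90)
  expect_equal(attr(isl4, "islands")$clusters_per_island, 4)
})

test_that("occupancy follows exact bin arithmetic", {
  m <- square_mask(1600)
  inside <- loc_table(rep(5, 20), rep(5, 20))  # one fine bin, one coarse bin
  expect_equal(occupancy(inside, m), 100 * 400 / 25600)
  # every fine bin of one coarse bin occupied -> 100%
  g <- expand.grid(x = seq(10, 150, by = 20), y = seq(10, 150, by = 20))
  expect_equal(occupancy(loc_table(g$x, g$y), m), 100)
  # invariance under translation by whole coarse pixels
  shifted <- loc_table(g$x + 320, g$y + 160)
  expect_equal(occupancy(shifted, m), 100)
})

test_that("nyquist metric implements the cube-root sampling formula", {
  side <- sqrt(2.7307e6)
  m <- square_mask(side)
  set.seed(20)
  tab <- loc_table(runif(10000, 0, side), runif(10000, 0, side))
  ny <- nyquist_metric(tab, m, slab = 120)
  expect_equal(unname(ny["mask"]), (2.7307e6 / 10000 * 120)^(1 / 3),
               tolerance = 1e-9)
  expect_equal(unname(ny["mask"]), 32.0, tolerance = 0.01)
  # doubling n divides the metric by 2^(1/3) exactly at fixed mask
  tab2 <- loc_table(runif(20000, 0, side), runif(20000, 0, side))
  ny2 <- nyquist_metric(tab2, m, slab = 120)
  expect_equal(unname(ny2["mask"] / ny["mask"]), 2^(-1 / 3), tolerance = 1e-9)
})

test_that("localization precision recovers emitter noise from frame runs", {
  set.seed(21)
  n_em <- 60
  pos <- cbind(runif(n_em, 0, 2e4), runif(n_em, 0, 2e4))
  idx <- rep(1:n_em, each = 8)
  tab <- loc_table(pos[idx, 1] + rnorm(length(idx), 0, 10),
                   pos[idx, 2] + rnorm(length(idx), 0, 10),
                   frame = rep(0:7, n_em) + rep((1:n_em) * 100, each = 8))
  prec <- localization_precision(tab, min_consecutive = 5)
  expect_equal(prec$n_clouds, n_em)
  expect_equal(prec$median, 10, tolerance = 0.1 * 10)

  # noiseless repeats -> precision 0
  tab0 <- loc_table(rep(5, 6), rep(5, 6), frame = 0:5)
  expect_equal(localization_precision(tab0)$median, 0)

  # emitters visible 3 frames only are excluded
  tab3 <- loc_table(pos[rep(1:n_em, each = 3), 1],
                    pos[rep(1:n_em, each = 3), 2],
                    frame = rep(0:2, n_em) + rep((1:n_em) * 100, each = 3))
  expect_warning(p3 <- localization_precision(tab3), "no qualifying")
  expect_equal(p3$n_clouds, 0L)
})

test_that("FRC finds structure scale and ignores uncorrelated noise", {
  set.seed(22)
  # pure uniform noise: no correlated structure above DC
  noise <- loc_table(runif(4000, 0, 5000), runif(4000, 0, 5000))
  res <- frc_resolution(noise, pixel = 20, seed = 1)
  # either no determinable resolution, or only the trivial field-envelope
  # correlation at near-field-of-view scales
  expect_true(is.na(res$resolution) || res$resolution > 300)

  # clutch field with 10 nm localization noise
  ncl <- 150
  cpos <- cbind(runif(ncl, 200, 4800), runif(ncl, 200, 4800))
  idx <- rep(1:ncl, each = 80)
  field <- loc_table(cpos[idx, 1] + rnorm(length(idx), 0, 25),
                     cpos[idx, 2] + rnorm(length(idx), 0, 25))
  r1 <- frc_resolution(field, pixel = 20, seed = 1)
  expect_false(is.na(r1$resolution))
  expect_gt(r1$resolution, 25)
  expect_lt(r1$resolution, 200)
  # resolution improves (or stays) with more localizations
  idx2 <- rep(1:ncl, each = 20)
  sparse <- loc_table(cpos[idx2, 1] + rnorm(length(idx2), 0, 25),
                      cpos[idx2, 2] + rnorm(length(idx2), 0, 25))
  r2 <- frc_resolution(sparse, pixel = 20, seed = 1)
  expect_true(is.na(r2$resolution) || r2$resolution >= r1$resolution * 0.8)
  expect_error(frc_resolution(noise[1:500, ]), "1000")
})

test_that("qc_gate applies strict condition-specific thresholds", {
  ok_ctrl <- list(occupancy = 40, clustered_area = 20, clusters_per_island = 4)
  expect_true(qc_gate(ok_ctrl, "control", nyquist_max = NULL)$pass)
  bad <- list(occupancy = 24, clustered_area = 12, clusters_per_island = 2)
  g <- qc_gate(bad, "treated", nyquist_max = NULL)
  expect_false(g$pass)
  expect_length(g$failed, 1)  # fails occupancy only
  expect_match(g$failed, "occupancy")
  # exactly at thresholds: strict inequality fails all three
  at <- list(occupancy = 35, clustered_area = 15, clusters_per_island = 3)
  expect_length(qc_gate(at, "control", nyquist_max = NULL)$failed, 3)
  at_t <- list(occupancy = 25, clustered_area = 10, clusters_per_island = 1.5)
  expect_length(qc_gate(at_t, "treated", nyquist_max = NULL)$failed, 3)
  # nyquist gate is inclusive at 32
  ny <- c(ok_ctrl, list(nyquist = c(mask = 32, occupied = 32)))
  expect_true(qc_gate(ny, "control")$pass)
  ny$nyquist["mask"] <- 32.1
  expect_false(qc_gate(ny, "control")$pass)
})
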