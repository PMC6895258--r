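test_that("read/write round-trips localization tables losslessly", {
  set.seed(1)
  tab <- loc_table(runif(1000, 0, 5e4), runif(1000, 0, 5e4),
                   z = runif(1000, -300, 300),
                   frame = sample(0:9999, 1000, TRUE),
                   wx = runif(1000, 300, 600), wy = runif(1000, 300, 600))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, path)
  back <- read_localizations(path)
  expect_equal(nrow(back), 1000)
  for (col in c("x", "y", "z", "wx", "wy"))
    expect_lt(max(abs(back[[col]] - tab[[col]])), 1e-6)
  expect_identical(back$frame, tab$frame)

  # empty table -> header-only file
  e <- loc_table(numeric(), numeric())
  write_localizations(e, path)
  expect_equal(nrow(read_localizations(path)), 0)
})

test_that("dialects map headers and convert pixel units", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,frame", "1.5,2.5,0", "3,4,1", "5,6,2"), path)
  d <- loc_dialect(x = "x_nm", y = "y_nm")
  tab <- read_localizations(path, d)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$frame, 0:2)

  writeLines(c("x_px,y_px", "2.0,1.0"), path)
  tab <- read_localizations(path, loc_dialect(x = "x_px", y = "y_px",
                                              pixel_size = 160))
  expect_equal(tab$x, 320)
  expect_equal(tab$y, 160)

  writeLines(c("x,z", "1,2"), path)
  expect_error(read_localizations(path), "'y'")
  writeLines(c("x,y", "1,abc"), path)
  expect_error(read_localizations(path), "row 1")
})

test_that("select_slice keeps the axial window and is monotone", {
  set.seed(2)
  tab <- loc_table(runif(20000), runif(20000), z = runif(20000, -300, 300))
  sl <- select_slice(tab, 0, 120)
  expect_true(all(abs(sl$z) <= 60))
  expect_equal(nrow(sl) / nrow(tab), 0.2, tolerance = 0.05)
  expect_equal(nrow(select_slice(tab, 0, Inf)), nrow(tab))
  # monotone nesting over window sizes
  for (h in c(50, 120, 400)) {
    a <- select_slice(tab, 10, h)
    b <- select_slice(tab, 10, h + 100)
    expect_true(all(a$z %in% b$z))
  }
  expect_error(select_slice(loc_table(1, 1), 0, 120), "z")
})

test_that("clip_to_mask respects boundary, exclusions and is idempotent", {
  m <- square_mask(1000)
  tab <- loc_table(c(500, 1500), c(500, 500))
  expect_equal(nrow(clip_to_mask(tab, m)), 1)

  hole <- nuclear_mask(square_mask(1000)$boundary,
                       list(rbind(c(400, 400), c(600, 400),
                                  c(600, 600), c(400, 600))))
  expect_equal(nrow(clip_to_mask(loc_table(500, 500), hole)), 0)

  set.seed(3)
  tab <- loc_table(runif(20000, 0, 1000), runif(20000, 0, 1000))
  kept <- clip_to_mask(tab, hole)
  expect_equal(nrow(kept) / 20000, mask_usable_area(hole) / 1e6,
               tolerance = 0.03)
  expect_equal(nrow(clip_to_mask(kept, hole)), nrow(kept))
})

test_that("mask JSON round-trips and degenerate masks are rejected", {
  m <- ellipse_mask(800, 500, exclusions = list(
    rbind(c(0, 0), c(100, 0), c(100, 80), c(0, 80))))
  path <- withr::local_tempfile(fileext = ".json")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_equal(mask_usable_area(m2), mask_usable_area(m))
  expect_equal(m2$boundary, m$boundary)
  expect_error(nuclear_mask(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) * 0),
               "area")
  # bow-tie self-intersection
  expect_error(nuclear_mask(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersect")
})

test_that("render_gaussian deposits unit mass and is linear", {
  tab <- loc_table(100, 100)
  img <- render_gaussian(tab, sigma = 20, pixel_size = 5,
                         extent = c(-100, 300, -100, 300))
  expect_equal(sum(img$values), 1, tolerance = 1e-6)
  peak <- which(img$values == max(img$values), arr.ind = TRUE)
  cx <- img$origin[1] + (peak[1, 2] - 0.5) * img$pixel_size
  expect_lt(abs(cx - 100), img$pixel_size)

  two <- loc_table(c(100, 100), c(100, 100))
  img2 <- render_gaussian(two, sigma = 20, pixel_size = 5,
                          extent = c(0, 200, 0, 200))
  img1 <- render_gaussian(tab, sigma = 20, pixel_size = 5,
                          extent = c(0, 200, 0, 200))
  expect_equal(img2$values, 2 * img1$values)

  # superposition on a random split
  set.seed(4)
  tab <- loc_table(runif(200, 0, 500), runif(200, 0, 500))
  ext <- c(-100, 600, -100, 600)
  whole <- render_gaussian(tab, 20, 10, ext)
  half <- sample.int(200, 100)
  a <- render_gaussian(clutchscope:::.as_loc(tab[half, ]), 20, 10, ext)
  b <- render_gaussian(clutchscope:::.as_loc(tab[-half, ]), 20, 10, ext)
  expect_equal(whole$values, a$values + b$values, tolerance = 1e-12)

  empty <- render_gaussian(loc_table(numeric(), numeric()), 20, 10,
                           extent = c(0, 100, 0, 100))
  expect_true(all(empty$values == 0))
})

test_that("write_tiff emits a valid float TIFF", {
  img <- render_gaussian(loc_table(c(50, 120), c(60, 100)), sigma = 20,
                         pixel_size = 10, extent = c(0, 200, 0, 200))
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(img, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(rawToChar(readBin(con, "raw", 2)), "II")
  expect_equal(readBin(con, "integer", 1, 2, endian = "little"), 42L)
  ifd <- readBin(con, "integer", 1, 4, endian = "little")
  seek(con, ifd)
  n_tags <- readBin(con, "integer", 1, 2, endian = "little")
  tags <- matrix(0L, n_tags, 3)
  for (i in seq_len(n_tags)) {
    id <- readBin(con, "integer", 1, 2, endian = "little")
    readBin(con, "integer", 1, 2, endian = "little")
    readBin(con, "integer", 1, 4, endian = "little")
    val <- readBin(con, "integer", 1, 4, endian = "little")
    tags[i, ] <- c(id, 0L, val)
  }
  dims <- tags[match(c(256L, 257L), tags[, 1]), 3]
  expect_equal(dims, c(ncol(img$values), nrow(img$values)))
  seek(con, tags[match(273L, tags[, 1]), 3])
  px <- readBin(con, "numeric", prod(dims), 4, endian = "little")
  expect_equal(sum(px), sum(img$values), tolerance = 1e-6)
})
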