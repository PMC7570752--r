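test_that("wavenumber axis enforces ascending uniform grids", {
  ax <- wavenumber_axis(seq(900, 1800, by = 2))
  expect_equal(axis_spacing(ax), 2)
  expect_error(wavenumber_axis(c(1000, 998, 1002)), "ascending")
  expect_error(wavenumber_axis(c(1000, 1002, 1005)), "uniformly spaced")
  expect_error(wavenumber_axis(1000), "two points")
})

test_that("spectral image validates its invariants", {
  ax <- seq(1000, 1198, by = 2)
  cube <- array(runif(4 * 5 * 100), c(4, 5, 100))
  img <- spectral_image(cube, ax, pixel_size = 25)
  expect_equal(dim(img), c(4, 5, 100))
  expect_true(all(img$mask))
  expect_error(spectral_image(cube, ax[-1]), "bands")
  expect_error(spectral_image(cube, ax, mask = matrix(TRUE, 3, 5)), "mask shape")
  bad <- cube; bad[1, 1, 5] <- NaN
  expect_error(spectral_image(bad, ax), "non-finite")
  # NaN at a masked-out pixel is allowed
  msk <- matrix(TRUE, 4, 5); msk[1, 1] <- FALSE
  expect_s3_class(spectral_image(bad, ax, mask = msk), "spectral_image")
})

test_that("crop_range keeps exactly the closed-interval bands", {
  ax <- seq(650, 4000, by = 2)
  img <- spectral_image(array(rnorm(2 * 2 * length(ax)), c(2, 2, length(ax))), ax)
  cr <- crop_range(img, 900, 1800)
  expect_true(all(cr$axis >= 900 & cr$axis <= 1800))
  # enumeration oracle on a coarse grid
  ax2 <- seq(1000, 2000, by = 2)
  img2 <- spectral_image(array(0, c(1, 1, length(ax2))), ax2)
  cr2 <- crop_range(img2, 1040, 1425)
  expect_equal(length(cr2$axis), sum(ax2 >= 1040 & ax2 <= 1425))
  # closed ends are inclusive
  cr3 <- crop_range(img2, 1000, 1010)
  expect_equal(as.numeric(cr3$axis), c(1000, 1002, 1004, 1006, 1008, 1010))
  # identity and idempotence
  cr4 <- crop_range(img, min(img$axis), max(img$axis))
  expect_equal(cr4$cube, img$cube)
  expect_equal(crop_range(cr, 900, 1800)$cube, cr$cube)
  expect_error(crop_range(img, 5000, 6000), "lo < hi|overlap")
  expect_error(crop_range(img, 4500, 5000), "overlap")
})

test_that("write/read round-trips are lossless for every format", {
  ph <- tiny_phantom(seed = 42, H = 8, W = 9)
  img <- ph$tissue
  img$group <- "hcc"
  for (fmt in c("hdf5", "envi", "csv")) {
    ext <- c(hdf5 = ".h5", envi = ".hdr", csv = ".csv")[[fmt]]
    path <- withr::local_tempfile(fileext = ext)
    write_cube(img, path, fmt)
    back <- read_cube(path, fmt)
    valid <- array(rep(img$mask, length(img$axis)), dim(img$cube))
    expect_lt(max(abs((back$cube - img$cube)[valid])), 1e-9)
    expect_identical(back$mask, img$mask)
    expect_equal(as.numeric(back$axis), as.numeric(img$axis))
    expect_equal(back$pixel_size, img$pixel_size)
    expect_equal(back$sample_id, img$sample_id)
    expect_equal(back$group, img$group)
  }
})

test_that("descending-axis files are normalized on read", {
  ax <- seq(1000, 1098, by = 2)
  cube <- array(rnorm(3 * 3 * length(ax)), c(3, 3, length(ax)))
  img <- spectral_image(cube, ax)
  path <- withr::local_tempfile(fileext = ".h5")
  # hand-write a descending-axis file
  rhdf5::h5createFile(path)
  rhdf5::h5write(img$cube[, , rev(seq_along(ax))], path, "cube")
  rhdf5::h5write(rev(ax), path, "axis")
  rhdf5::h5closeAll()
  back <- read_cube(path, "hdf5")
  expect_equal(as.numeric(back$axis), ax)
  expect_equal(back$cube, img$cube)
  # read - write - read is the identity
  path2 <- withr::local_tempfile(fileext = ".h5")
  write_cube(back, path2, "hdf5")
  again <- read_cube(path2, "hdf5")
  expect_equal(again$cube, back$cube)
  expect_equal(as.numeric(again$axis), as.numeric(back$axis))
})

test_that("malformed files raise format errors naming the field", {
  p <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(p)
  rhdf5::h5write(array(0, c(2, 2, 5)), p, "cube")
  rhdf5::h5closeAll()
  expect_error(read_cube(p, "hdf5"), "axis")
  p2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(p2)
  rhdf5::h5write(array(0, c(2, 2, 5)), p2, "cube")
  rhdf5::h5write(1:4, p2, "axis")
  rhdf5::h5closeAll()
  expect_error(read_cube(p2, "hdf5"), "axis length")
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("row,col,absorbance\n0,0,1", p3)
  expect_error(read_cube(p3, "csv"), "wavenumber")
  p4 <- withr::local_tempfile(fileext = ".hdr")
  writeLines(c("ENVI", "samples = 2", "lines = 2"), p4)
  writeBin(numeric(8), sub("hdr$", "raw", p4), size = 8)
  expect_error(read_cube(p4, "envi"), "bands")
})

test_that("rgb images round-trip through png", {
  px <- array(sample(0:255, 5 * 4 * 3, replace = TRUE), c(5, 4, 3))
  img <- rgb_image(px, scale = 2.7)
  path <- withr::local_tempfile(fileext = ".png")
  write_rgb(img, path)
  back <- read_rgb(path, scale = 2.7)
  expect_equal(unclass(back)[], unclass(img)[])
  expect_error(rgb_image(array(300, c(2, 2, 3))), "0, 255")
})
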