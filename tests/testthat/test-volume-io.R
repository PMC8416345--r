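test_that("MetaImage write/read round-trips volumes and masks bit-exactly", {
  set.seed(42)
  v <- OCTVolume(round(array(runif(4 * 8 * 8), c(4, 8, 8)) * 65535) / 65535,
                 spacingUm = c(46.875, 2.2599, 11.71875))
  for (ext in c(".mha", ".mhd")) {
    p <- tempfile(fileext = ext)
    writeMetaImage(v, p)
    v2 <- readMetaImage(p)
    expect_identical(voxels(v2), voxels(v))
    expect_equal(spacingUm(v2), spacingUm(v), tolerance = 1e-12)
  }
  m <- LabelMask(array(sample(0:2, 4 * 8 * 8, replace = TRUE), c(4, 8, 8)),
                 spacingUm = c(46.875, 2.2599, 11.71875))
  p <- tempfile(fileext = ".mha")
  writeMetaImage(m, p)
  m2 <- readLabelMask(p)
  expect_identical(labels3d(m2), labels3d(m))
  expect_identical(tabulate(labels3d(m2) + 1L, 3), tabulate(labels3d(m) + 1L, 3))

  z <- OCTVolume(array(0, c(2, 8, 8)), c(1, 1, 1))
  pz <- tempfile(fileext = ".mha")
  writeMetaImage(z, pz)
  expect_true(all(voxels(readMetaImage(pz)) == 0))
})

test_that("spacing is taken from the header of a hand-written fixture", {
  # header written here by hand, independent of the package's writer
  dir <- tempfile(); dir.create(dir)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "Offset = 0 0 0",
           "ElementSpacing = 0.01171875 0.0022599 0.046875",
           "DimSize = 4 6 2", "ElementType = MET_UCHAR",
           "ElementDataFile = vol.raw")
  writeLines(hdr, file.path(dir, "vol.mhd"))
  writeBin(as.raw(seq_len(4 * 6 * 2)), file.path(dir, "vol.raw"))
  v <- readMetaImage(file.path(dir, "vol.mhd"))
  expect_equal(spacingUm(v), c(46.875, 2.2599, 11.71875), tolerance = 1e-9)
  expect_equal(dim(v), c(2L, 6L, 4L))
  # (b=1, z=1, x=1..4) is the fastest-varying run of the raw stream
  expect_equal(voxels(v)[1, 1, ] * 255, 1:4)
})

test_that("written headers preserve spacing to at least 6 significant digits", {
  v <- OCTVolume(array(0, c(2, 8, 8)), spacingUm = c(46.875, 2.2599, 11.71875))
  p <- tempfile(fileext = ".mhd")
  writeMetaImage(v, p)
  hdr <- readLines(p)
  sp <- hdr[grepl("^ElementSpacing", hdr)]
  vals <- as.numeric(strsplit(sub(".*= *", "", sp), " +")[[1]])
  expect_equal(vals * 1000, rev(c(46.875, 2.2599, 11.71875)),
               tolerance = 1e-6)
})

test_that("compressed data blocks are supported on read", {
  set.seed(7)
  dir <- tempfile(); dir.create(dir)
  vals <- as.raw(sample(0:255, 2 * 4 * 4, replace = TRUE))
  comp <- memCompress(vals, type = "gzip")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "CompressedData = True",
           "ElementSpacing = 1 1 1", "DimSize = 4 4 2",
           "ElementType = MET_UCHAR", "ElementDataFile = vol.raw")
  writeLines(hdr, file.path(dir, "vol.mhd"))
  writeBin(comp, file.path(dir, "vol.raw"))
  v <- readMetaImage(file.path(dir, "vol.mhd"))
  expect_equal(as.vector(aperm(voxels(v), c(3, 2, 1))) * 255,
               as.numeric(as.integer(vals)))
})

test_that("malformed inputs are rejected with the offending field named", {
  expect_error(readMetaImage(tempfile(fileext = ".mhd")), "not found")
  dir <- tempfile(); dir.create(dir)
  writeLines(c("ObjectType = Image", "NDims = 2", "DimSize = 4 4",
               "ElementType = MET_UCHAR", "ElementDataFile = x.raw"),
             file.path(dir, "flat.mhd"))
  expect_error(readMetaImage(file.path(dir, "flat.mhd")), "NDims")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"),
             file.path(dir, "bad.mhd"))
  expect_error(readMetaImage(file.path(dir, "bad.mhd")), "MET_DOUBLE")
})

test_that("spacing derives from extent/shape and rejects degenerate input", {
  sp <- spacingFromExtent(c(6, 2, 6), c(128, 885, 512))
  expect_equal(sp, c(46.875, 2000 / 885, 11.71875), tolerance = 1e-12)
  expect_equal(spacingFromExtent(c(1, 1, 1), c(1000, 1000, 1000)), c(1, 1, 1))
  expect_error(spacingFromExtent(c(6, 2, 6), c(128, 0, 512)), "positive")
  expect_error(spacingFromExtent(c(-6, 2, 6), c(128, 885, 512)), "positive")
})

test_that("default Topcon geometry gives the expected in-plane pixel area", {
  sp <- topconSpacing()
  # independent multiplication: axial x lateral spacing
  expect_equal(sp[2] * sp[3], (2000 / 885) * (6000 / 512), tolerance = 1e-12)
  expect_equal(sp[2] * sp[3], 26.48305, tolerance = 1e-5)
})

test_that("OCTVolume and LabelMask validity catches bad geometry", {
  expect_error(OCTVolume(matrix(0, 2, 2), c(1, 1, 1)), "3-D")
  expect_error(OCTVolume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(OCTVolume(array(c(NA, rep(0, 7)), c(2, 2, 2)), c(1, 1, 1)),
               "finite")
  expect_error(LabelMask(array(3L, c(2, 2, 2)), c(1, 1, 1)), "labels")
})
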