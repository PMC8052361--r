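test_that("MRC round trip preserves dims, origin, spacing and values", {
  cx <- tiny_complex()
  m <- simulate_map(cx, 6)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  m2 <- read_map(p)
  expect_identical(dim(m2$values), dim(m$values))
  expect_equal(m2$origin, m$origin)
  expect_equal(m2$spacing, m$spacing)
  # values survive the float32 representation on disk
  expect_lt(max(abs(m2$values - m$values)), 1e-5 * max(abs(m$values)))
})

test_that("read_map errors are distinct and informative", {
  expect_error(read_map(file.path(tempdir(), "no_such_map.mrc")), "not found")

  p <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(100), p)
  expect_error(read_map(p), "truncated")

  # valid header but MODE 1 (int16): unsupported volume mode
  m <- density_map(array(1:8 / 8, c(2, 2, 2)))
  p2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p2)
  con <- file(p2, "r+b")
  seek(con, 12, rw = "write")
  writeBin(1L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_map(p2), "mode")
})

test_that("axis permutation in the header is normalized to x,y,z on read", {
  set.seed(2)
  d <- c(3L, 4L, 5L)
  vals <- array(runif(prod(d)), dim = d)
  m <- density_map(vals, origin = c(1, 2, 3))
  p_can <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p_can)

  # the same volume stored section-major permuted: data dims (z, x, y) with
  # MAPC/MAPR/MAPS = 3,1,2
  p_perm <- withr::local_tempfile(fileext = ".mrc")
  write_map(density_map(aperm(vals, c(3, 1, 2)), origin = c(1, 2, 3)), p_perm)
  con <- file(p_perm, "r+b")
  seek(con, 64, rw = "write")                 # MAPC MAPR MAPS (words 17-19)
  writeBin(c(3L, 1L, 2L), con, size = 4, endian = "little")
  close(con)

  a <- read_map(p_can); b <- read_map(p_perm)
  expect_identical(dim(b$values), dim(a$values))
  expect_equal(b$values, a$values, tolerance = 1e-7)
})

test_that("an independent MRC reader agrees on the written volume", {
  cx <- tiny_complex(seed = 3)
  m <- simulate_map(cx, 7)
  p <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, p)
  script <- paste0(
    "import gemmi, numpy as np\n",
    "m = gemmi.read_ccp4_map('", p, "')\n",
    "a = np.array(m.grid, copy=False)\n",
    "print(a.shape[0], a.shape[1], a.shape[2])\n",
    "print(repr(float(a.sum())))\n",
    "print(repr(float(a[2, 3, 4])))\n")
  out <- system2("python", "-", input = script, stdout = TRUE)
  dims <- as.integer(strsplit(out[1], " ")[[1]])
  expect_identical(dims, dim(m$values))
  expect_equal(as.numeric(out[2]), sum(m$values), tolerance = 1e-5)
  expect_equal(as.numeric(out[3]), m$values[3, 4, 5], tolerance = 1e-5)
})

test_that("trilinear resampling is exact on affine fields and idempotent", {
  d <- c(8L, 7L, 6L)
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  # physical coords at 2 A spacing, origin (1,-3,2)
  org <- c(1, -3, 2)
  f <- function(x, y, z) 2 * x + 3 * y - z
  vals <- array(f(org[1] + 2 * g$x, org[2] + 2 * g$y, org[3] + 2 * g$z), dim = d)
  m <- density_map(vals, origin = org, spacing = c(2, 2, 2))
  r <- resample_to_unit_grid(m)
  expect_equal(r$spacing, c(1, 1, 1))
  rg <- expand.grid(x = 0:(dim(r$values)[1] - 1), y = 0:(dim(r$values)[2] - 1),
                    z = 0:(dim(r$values)[3] - 1))
  want <- f(r$origin[1] + rg$x, r$origin[2] + rg$y, r$origin[3] + rg$z)
  expect_lt(max(abs(as.vector(r$values) - want)), 1e-9)

  r2 <- resample_to_unit_grid(r)
  expect_identical(r2$values, r$values)

  # a map already on the canonical grid is untouched, bit for bit
  m1 <- density_map(array(runif(27), c(3, 3, 3)), origin = c(0, 1, 2))
  expect_identical(resample_to_unit_grid(m1)$values, m1$values)

  # constant maps stay constant
  mc <- density_map(array(4.2, c(4, 4, 4)), spacing = c(1.7, 1.7, 1.7))
  expect_true(all(abs(resample_to_unit_grid(mc)$values - 4.2) < 1e-12 |
                    resample_to_unit_grid(mc)$values == 0))

  expect_error(resample_to_unit_grid(density_map(array(1:2, c(1, 1, 2)))),
               "degenerate")
})

test_that("normalization follows the simulated and experimental conventions", {
  v <- array(c(0, 1, 2.5, 5, 3, 4, 0.5, 2), c(2, 2, 2))
  m <- density_map(v)
  s <- normalize_map(m, "simulated")
  expect_equal(min(s$values), 0)
  expect_equal(max(s$values), 1)
  expect_equal(s$values[2, 2, 1], 1)          # raw 5 -> 1
  expect_equal(s$values[1, 1, 1], 0)          # raw 0 -> 0

  # experimental: negatives clamped, contour level becomes the minimum
  ve <- array(c(-0.2, 0.3, 0.3, 0.8, 1.2, 0.5, -0.1, 2), c(2, 2, 2))
  me <- density_map(ve, contour_level = 0.3)
  e <- normalize_map(me, "experimental")
  expect_equal(e$values[1, 1, 1], 0)          # -0.2 clamped then below contour
  expect_equal(e$values[2, 1, 1], 0)          # exactly at the contour -> 0
  expect_equal(e$values[2, 2, 2], 1)          # map max -> 1
  expect_true(all(e$values >= 0 & e$values <= 1))

  # monotone: v1 <= v2 => v1' <= v2'
  o <- order(as.vector(ve))
  expect_true(all(diff(as.vector(e$values)[o]) >= 0))

  expect_error(normalize_map(density_map(array(2, c(2, 2, 2))), "simulated"),
               "flat")
  expect_error(normalize_map(density_map(ve), "experimental"), "contour")
})

test_that("cross-correlation behaves like Pearson correlation on grids", {
  set.seed(9)
  m <- density_map(array(runif(60), c(3, 4, 5)))
  expect_equal(cross_correlation(m, m), 1.0)
  neg <- m; neg$values <- -m$values
  expect_equal(cross_correlation(m, neg), -1.0)

  # symmetry and affine invariance
  b <- density_map(array(runif(60), c(3, 4, 5)))
  expect_equal(cross_correlation(m, b), cross_correlation(b, m))
  b2 <- b; b2$values <- 3.5 * b$values + 1.2
  expect_equal(cross_correlation(m, b2), cross_correlation(m, b))
  b3 <- b; b3$values <- -2 * b$values
  expect_equal(cross_correlation(m, b3), -cross_correlation(m, b))

  # independent noise maps of 1e4 voxels decorrelate
  set.seed(10)
  n1 <- density_map(array(rnorm(10^4), c(25, 20, 20)))
  n2 <- density_map(array(rnorm(10^4), c(25, 20, 20)))
  expect_lt(abs(cross_correlation(n1, n2)), 0.05)

  expect_error(cross_correlation(m, density_map(array(1:8 / 8, c(2, 2, 2)))),
               "mismatch")
  flat <- density_map(array(1, c(3, 4, 5)))
  expect_error(cross_correlation(m, flat), "variance")
})
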