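random_map <- function(dm = c(16, 16, 16), voxel = 1, seed = 1, quantize = TRUE) {
  set.seed(seed)
  v <- array(rnorm(prod(dm)), dim = dm)
  if (quantize) v <- array(quantize_f32(v), dim = dm)
  density_map(v, voxel, origin = c(-3, 2, 5), resolution = 6)
}

test_that("MRC write/read round trip is bit-exact in values and geometry", {
  m <- random_map(seed = 3)
  p <- tempfile(fileext = ".mrc")
  write_map(m, p)
  m2 <- read_map(p)
  expect_identical(m2$values, m$values)
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-4)
})

test_that("permuted axis order is normalized on read", {
  m <- random_map(dm = c(6, 8, 10), seed = 4)
  p <- tempfile(fileext = ".mrc")
  # write a file whose fastest axis is y (MAPC,MAPR,MAPS = 2,3,1)
  perm <- c(2L, 3L, 1L)
  A <- aperm(m$values, perm)
  con <- file(p, "wb")
  writeBin(as.integer(c(dim(A), 2L, 0L, 0L, 0L, dim(m$values))), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(dim(m$values) * m$voxel_size, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(perm, con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(A), max(A), mean(A))), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")
  writeBin(integer(25L), con, size = 4L, endian = "little")
  writeBin(as.numeric(m$origin), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  writeBin(0, con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(raw(800L), con)
  writeBin(as.numeric(A), con, size = 4L, endian = "little")
  close(con)
  m2 <- read_map(p)
  expect_identical(m2$values, m$values)
})

test_that("truncated and non-MRC files raise format errors", {
  m <- random_map()
  p <- tempfile(fileext = ".mrc")
  write_map(m, p)
  bytes <- readBin(p, "raw", n = file.size(p))
  p2 <- tempfile(fileext = ".mrc")
  writeBin(bytes[1:2000], p2)
  expect_error(read_map(p2), "truncated")
  p3 <- tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(1, 2048)), p3)
  expect_error(read_map(p3), "format")
})

test_that("anisotropic voxels are rejected with an explicit message", {
  m <- random_map(dm = c(8, 8, 8))
  p <- tempfile(fileext = ".mrc")
  write_map(m, p)
  # patch CELLA so y-spacing differs
  con <- file(p, "r+b")
  seek(con, 40, rw = "write")
  writeBin(as.numeric(8 * 1.5), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_map(p), "anisotropic")
})

test_that("Butterworth filter leaves constants unchanged and is linear", {
  m <- density_map(array(3.7, dim = c(12, 12, 12)), 1)
  f <- butterworth_lowpass(m, 5)
  expect_lt(max(abs(f$values - 3.7)), 1e-9)
  a <- random_map(dm = c(12, 12, 12), seed = 5, quantize = FALSE)
  b <- random_map(dm = c(12, 12, 12), seed = 6, quantize = FALSE)
  fa <- butterworth_lowpass(a, 5)$values
  fb <- butterworth_lowpass(b, 5)$values
  comb <- a; comb$values <- 2.5 * a$values - 1.3 * b$values
  fc_ <- butterworth_lowpass(comb, 5)$values
  expect_lt(max(abs(fc_ - (2.5 * fa - 1.3 * fb))), 1e-9)
})

test_that("Butterworth gain at the cutoff frequency is 2^(-1/2) for orders 2, 4, 8", {
  n <- 32L
  voxel <- 1.0
  k <- 4L                       # probe frequency k/(n*voxel)
  cutoff_res <- n * voxel / k   # place the cutoff exactly at the probe
  x <- (0:(n - 1))
  probe <- array(0, dim = c(n, n, n))
  for (i in seq_len(n)) probe[i, , ] <- sin(2 * pi * k * x[i] / n)
  m <- density_map(probe, voxel)
  for (ord in c(2L, 4L, 8L)) {
    f <- butterworth_lowpass(m, cutoff_res, order = ord)
    gain <- max(abs(f$values)) / max(abs(m$values))
    expect_equal(gain, 2^(-1 / 2), tolerance = 1e-6)
  }
})

test_that("cutoffs beyond Nyquist are rejected", {
  m <- random_map(dm = c(8, 8, 8))
  expect_error(butterworth_lowpass(m, 1.5), "Nyquist")
})

test_that("an atom at a voxel center deposits all mass in that voxel", {
  box <- list(origin = c(0, 0, 0), dim = c(9L, 9L, 9L))
  m <- simulate_map(matrix(c(4, 4, 4), 1), 1.0, resolution = NA, box = box)
  expect_equal(m$values[5, 5, 5], 1)
  expect_equal(sum(m$values), 1)
})

test_that("simulation is equivariant under lattice translations", {
  box <- list(origin = c(0, 0, 0), dim = c(16L, 16L, 16L))
  p <- c(4.3, 5.7, 6.2)
  m1 <- simulate_map(matrix(p, 1), 1.0, resolution = NA, box = box)
  m2 <- simulate_map(matrix(p + c(2, 3, 1), 1), 1.0, resolution = NA, box = box)
  shifted <- array(0, dim = c(16, 16, 16))
  shifted[(1:16) > 2, (1:16) > 3, (1:16) > 1] <- m1$values[1:14, 1:13, 1:15]
  expect_lt(max(abs(m2$values - shifted)), 1e-12)
})

test_that("filtering conserves total deposited mass (unit DC gain)", {
  set.seed(9)
  pts <- matrix(runif(60, 8, 16), ncol = 3)
  raw <- simulate_map(pts, 1.0, resolution = NA, box = list(origin = c(0, 0, 0), dim = c(25L, 25L, 25L)))
  filt <- simulate_map(pts, 1.0, resolution = 8, box = list(origin = c(0, 0, 0), dim = c(25L, 25L, 25L)))
  expect_equal(sum(filt$values), sum(raw$values), tolerance = 1e-6)
  expect_equal(sum(raw$values), nrow(pts), tolerance = 1e-9)
})

test_that("atoms outside the box error by default and clip on request", {
  box <- list(origin = c(0, 0, 0), dim = c(8L, 8L, 8L))
  expect_error(simulate_map(matrix(c(30, 0, 0), 1), 1.0, NA, box = box), "outside")
  m <- simulate_map(rbind(c(30, 0, 0), c(3, 3, 3)), 1.0, NA, box = box, out_of_box = "clip")
  expect_equal(sum(m$values), 1)
})

test_that("the minimal box contains every native-segment atom", {
  for (L in c(5, 11, 17, 25)) {
    fix <- make_gap_fixture("loop", L, seed = 100 + L, n_decoys = 0)
    box <- minimal_box(fix$gap, fix$map)
    nat <- cs_xyz(fix$gap$native_interior)
    ub <- box$origin + (dim(box$values) - 1) * box$voxel_size
    expect_true(all(sweep(nat, 2, box$origin, `-`) >= 0))
    expect_true(all(sweep(nat, 2, ub, `-`) <= 0))
  }
})

test_that("minimal box grows monotonically with segment length", {
  fix5 <- make_gap_fixture("loop", 5, seed = 200, n_decoys = 0, flank = 8)
  fix10 <- make_gap_fixture("loop", 10, seed = 200, n_decoys = 0, flank = 8)
  b5 <- dim(minimal_box(fix5$gap, fix5$map)$values)
  b10 <- dim(minimal_box(fix10$gap, fix10$map)$values)
  # compare physical box volumes (different maps, same voxel size)
  expect_gte(prod(b10), prod(b5) * 0.99)
})

test_that("sub-volume extraction preserves world coordinates", {
  fix <- make_gap_fixture("helix", 7, seed = 31, n_decoys = 0)
  box <- minimal_box(fix$gap, fix$map)
  i <- c(3L, 4L, 5L)
  world <- box$origin + (i - 1L) * box$voxel_size
  j <- round((world - fix$map$origin) / fix$map$voxel_size) + 1L
  expect_equal(box$values[i[1], i[2], i[3]],
               fix$map$values[j[1], j[2], j[3]])
})

test_that("normalization is exact, idempotent and affine-invariant", {
  m <- random_map(seed = 12, quantize = FALSE)
  nm <- normalize_map(m)
  expect_lt(abs(mean(nm$values)), 1e-9)
  expect_lt(abs(sd(nm$values) - 1), 1e-9)
  nm2 <- normalize_map(nm)
  expect_lt(max(abs(nm2$values - nm$values)), 1e-9)
  aff <- m; aff$values <- 4.2 * m$values + 17
  expect_lt(max(abs(normalize_map(aff)$values - nm$values)), 1e-9)
  expect_error(normalize_map(density_map(array(1, dim = c(4, 4, 4)), 1)), "constant")
})

test_that("subtracting an identically simulated context cancels the box", {
  fix <- make_gap_fixture("helix", 9, seed = 33, n_decoys = 0)
  ctx <- fragfitr:::context_coords(fix$gap)
  box <- minimal_box(fix$gap, fix$map)
  ub <- box$origin + (dim(box$values) - 1) * box$voxel_size
  P <- cs_xyz(ctx)
  inside <- P[, 1] >= box$origin[1] & P[, 1] <= ub[1] &
    P[, 2] >= box$origin[2] & P[, 2] <= ub[2] &
    P[, 3] >= box$origin[3] & P[, 3] <= ub[3]
  exp_box <- simulate_map(P[inside, , drop = FALSE], box$voxel_size, 8,
                          box = box, out_of_box = "clip")
  resid <- subtract_context(exp_box, ctx, 8)
  expect_lt(abs(mean(resid$values)), 1e-6)
  expect_lt(sd(resid$values), 1e-6)
})

test_that("empty context leaves the box untouched", {
  m <- random_map(seed = 14)
  expect_message(out <- subtract_context(m, NULL, 6), "unchanged")
  expect_identical(out$values, m$values)
  far <- coord_set("CA", 1L, matrix(c(1000, 1000, 1000), 1))
  expect_message(out2 <- subtract_context(m, far, 6), "unchanged")
  expect_identical(out2$values, m$values)
})

test_that("context subtraction raises the correlation with the missing segment", {
  fix <- make_gap_fixture("helix", 9, seed = 34, n_decoys = 0)
  box <- minimal_box(fix$gap, fix$map)
  nat_sim <- simulate_map(fix$gap$native_interior, box$voxel_size, 8,
                          box = box, out_of_box = "clip")
  resid <- subtract_context(normalize_map(box), fragfitr:::context_coords(fix$gap), 8)
  ccc_raw <- pearson_ccc(normalize_map(box), nat_sim)
  ccc_resid <- pearson_ccc(resid, nat_sim)
  expect_gt(ccc_resid, ccc_raw)
})

test_that("Pearson CCC matches the direct covariance formula and its symmetries", {
  m <- random_map(seed = 15, quantize = FALSE)
  expect_equal(pearson_ccc(m, m), 1.0, tolerance = 1e-12)
  neg <- m; neg$values <- -m$values
  expect_equal(pearson_ccc(m, neg), -1.0, tolerance = 1e-12)
  set.seed(16)
  for (i in 1:50) {
    a <- density_map(array(rnorm(8), dim = c(2, 2, 2)), 1)
    b <- density_map(array(rnorm(8), dim = c(2, 2, 2)), 1)
    expect_equal(pearson_ccc(a, b), direct_pearson(a$values, b$values), tolerance = 1e-12)
    expect_equal(pearson_ccc(a, b), pearson_ccc(b, a), tolerance = 1e-15)
    a2 <- a; a2$values <- runif(1, 0.1, 5) * a$values + rnorm(1)
    b2 <- b; b2$values <- runif(1, 0.1, 5) * b$values + rnorm(1)
    expect_equal(pearson_ccc(a2, b2), pearson_ccc(a, b), tolerance = 1e-9)
  }
  small <- density_map(array(rnorm(27), dim = c(3, 3, 3)), 1)
  expect_error(pearson_ccc(m, small), "shape")
  const <- density_map(array(1, dim = c(16, 16, 16)), 1, origin = m$origin)
  expect_error(pearson_ccc(m, const), "variance")
})
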