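rand_stack <- function(dims = c(6, 5, 4), vs = c(1, 1, 1)) {
  voxel_stack(array(runif(prod(dims), 0, 1000), dim = dims), vs)
}

test_that("mirror averaging flips and averages a single stack", {
  a <- array(0, dim = c(4, 1, 1))
  a[1, 1, 1] <- 10
  out <- mirror_average(voxel_stack(a))
  expect_equal(out$intensities[1, 1, 1], 5)
  expect_equal(out$intensities[4, 1, 1], 5)
  expect_equal(sum(out$intensities), 10)
})

test_that("mirror averaging is a fixed point on symmetric input and is
           exactly symmetric and idempotent on random stacks", {
  set.seed(24)
  a <- array(runif(4 * 3 * 2), dim = c(4, 3, 2))
  sym <- (a + a[4:1, , , drop = FALSE]) / 2
  out <- mirror_average(voxel_stack(sym))
  expect_equal(out$intensities, sym)

  for (rep in 1:10) {
    stacks <- lapply(1:3, function(i) rand_stack())
    out <- mirror_average(stacks)
    flipped <- out$intensities[dim(out$intensities)[1]:1, , ,
                               drop = FALSE]
    expect_identical(flipped, out$intensities)       # exact symmetry
    again <- mirror_average(out)
    expect_identical(again$intensities, out$intensities)  # idempotent
  }
})

test_that("mirror averaging refuses mismatched stacks", {
  expect_error(mirror_average(list(rand_stack(c(4, 4, 4)),
                                   rand_stack(c(5, 4, 4)))),
               "shapes differ")
  expect_error(mirror_average(list(rand_stack(vs = c(1, 1, 1)),
                                   rand_stack(vs = c(2, 1, 1)))),
               "voxel sizes")
})

test_that("threshold volume counts supra-threshold voxels times voxel
           volume", {
  a <- array(0, dim = c(10, 10, 10))
  a[sample(1000, 100)] <- 1000
  st <- voxel_stack(a, c(1, 1, 1))
  v <- threshold_volume(st, 800)
  expect_equal(v$voxels, 100)
  expect_equal(v$volume_um3, 100)

  zero <- voxel_stack(array(0, dim = c(5, 5, 5)))
  expect_equal(threshold_volume(zero, 800)$volume_um3, 0)

  aniso <- voxel_stack(a, c(0.5, 0.5, 2))
  expect_equal(threshold_volume(aniso, 800)$volume_um3, 100 * 0.5)
})

test_that("volume is monotone under threshold sweeps and additive over
           disjoint masks", {
  set.seed(25)
  st <- rand_stack(c(12, 10, 8))
  sweeps <- vapply(seq(0, 1100, by = 100), function(th)
    threshold_volume(st, th)$voxels, numeric(1))
  expect_true(all(diff(sweeps) <= 0))
  expect_equal(sweeps[1], prod(dim(st$intensities)))  # threshold 0 = all
  expect_equal(sweeps[length(sweeps)], 0)             # above max = none

  half1 <- array(FALSE, dim(st$intensities)); half1[1:6, , ] <- TRUE
  v_all <- threshold_volume(st, 500)$voxels
  v1 <- threshold_volume(st, 500, half1)$voxels
  v2 <- threshold_volume(st, 500, !half1)$voxels
  expect_equal(v1 + v2, v_all)

  expect_warning(threshold_volume(st, 500,
                                  array(FALSE, dim(st$intensities))),
                 "empty mask")
})

test_that("simulated blob stacks recover exact volumes at zero noise", {
  st <- simulate_voxel_stack(list(list(center = c(8, 8, 8), radius = 0,
                                       intensity = 1000)),
                             shape = c(16, 16, 16))
  expect_equal(threshold_volume(st, 800)$voxels, 1)

  st <- simulate_voxel_stack(list(list(center = c(8, 8, 8), radius = 4,
                                       intensity = 1000)),
                             shape = c(16, 16, 16))
  truth <- attr(st, "true_voxels")
  expect_equal(threshold_volume(st, 800)$voxels, truth$union)

  # two disjoint spheres: additive
  st <- simulate_voxel_stack(list(list(center = c(6, 10, 10), radius = 3,
                                       intensity = 1000),
                                  list(center = c(16, 10, 10), radius = 3,
                                       intensity = 1000)),
                             shape = c(22, 20, 20))
  truth <- attr(st, "true_voxels")
  expect_equal(sum(truth$per_blob), truth$union)
  expect_equal(threshold_volume(st, 800)$voxels, truth$union)
})

test_that("NRRD raw and ascii encodings round-trip exactly", {
  set.seed(26)
  st <- voxel_stack(array(sample(0:4095, 4 * 3 * 5, replace = TRUE),
                          dim = c(4, 3, 5)), c(0.38, 0.38, 1))
  for (enc in c("raw", "ascii")) {
    path <- tempfile(fileext = ".nrrd")
    write_nrrd(st, path, enc)
    back <- read_nrrd(path)
    expect_equal(back$intensities, st$intensities, info = enc)
    expect_equal(back$voxel_size, st$voxel_size, info = enc)
  }
  # doubles survive the raw double path
  stf <- voxel_stack(array(runif(24), dim = c(2, 3, 4)), c(1, 2, 3))
  path <- tempfile(fileext = ".nrrd")
  write_nrrd(stf, path, "raw")
  expect_equal(read_nrrd(path)$intensities, stf$intensities)
})

test_that("NRRD reader refuses malformed or ambiguous headers", {
  path <- tempfile(fileext = ".nrrd")
  writeLines(c("NOTNRRD", ""), path)
  expect_error(read_nrrd(path), "bad magic")

  writeLines(c("NRRD0004", "type: unsigned short", "dimension: 3",
               "sizes: 2 2 2", "encoding: raw", "endian: little", ""),
             path)
  expect_error(read_nrrd(path), "shorter than sizes")

  writeLines(c("NRRD0004", "type: unsigned short", "dimension: 3",
               "sizes: 2 2 2", "encoding: ascii",
               "space directions: (1,0.2,0) (0,1,0) (0,0,1)", "",
               paste(rep(1, 8), collapse = " ")), path)
  expect_error(read_nrrd(path), "refusing to reorder")

  writeLines(c("NRRD0004", "type: unsigned short", "dimension: 2",
               "sizes: 2 2", "encoding: ascii", "",
               paste(rep(1, 4), collapse = " ")), path)
  expect_error(read_nrrd(path), "only 3-D")
})

test_that("volume_report tabulates labeled structures", {
  a <- array(0, dim = c(6, 6, 6))
  a[1:2, 1:2, 1:2] <- 1000
  a[5:6, 5:6, 5:6] <- 900
  labels <- array(0L, dim = dim(a))
  labels[1:2, 1:2, 1:2] <- 1L
  labels[5:6, 5:6, 5:6] <- 2L
  rep <- volume_report(voxel_stack(a, c(2, 2, 2)), labels, 800, "s1")
  expect_equal(rep$voxels, c(8, 8))
  expect_equal(rep$volume_um3, c(64, 64))
  expect_equal(rep$structure, c(1, 2))
})
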