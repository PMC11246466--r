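test_that("packaged default disk has the expected structure", {
  m <- load_default_disk()
  expect_s3_class(m, "tissue_mesh")
  expect_identical(n_cells(m), 73L)
  expect_identical(n_walls(m), 348L)
  expect_identical(n_vertices(m), 276L)   # Euler: V = E - C + 1
  expect_true(all(m$aux == 0))
  expect_true(all(m$cuc == 0))
  expect_equal(m$walls$rest, wall_lengths(m), tolerance = 1e-12)
  expect_length(validate_mesh(m), 0L)
})

test_that("build_disk produces valid disks of requested size", {
  m1 <- build_disk(1, 5, seed = 3)
  expect_identical(n_cells(m1), 1L)
  expect_true(all(is.na(m1$walls$c2)))    # all walls are boundary walls

  for (target in c(20L, 73L)) {
    m <- build_disk(target, 24, seed = 7)
    expect_length(validate_mesh(m), 0L)
    expect_lte(abs(n_cells(m) - target), ceiling(0.1 * target))
    expect_identical(n_vertices(m) - n_walls(m) + n_cells(m), 1L)
  }
  expect_error(build_disk(0, 24), "target_cells")
  expect_error(build_disk(10, -1), "radius")
})

test_that("build_disk is deterministic in its seed", {
  a <- build_disk(40, 20, seed = 11)
  b <- build_disk(40, 20, seed = 11)
  expect_identical(a, b)
  c <- build_disk(40, 20, seed = 12)
  expect_false(identical(a$pos, c$pos))
})

test_that("cell_area matches closed forms", {
  expect_equal(cell_area(1, rect_mesh(1, 1)), 1)
  expect_equal(cell_area(1, rect_mesh(10, 4)), 40)
  expect_equal(cell_area(1, ngon_mesh(6, 1)), 3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("split_long_walls subdivides into ceiling(len/max) equal parts", {
  m <- rect_mesh(2.5, 0.8)
  m <- init_pin(m)  # single cell: no interior walls, all PIN zero
  m2 <- split_long_walls(m, max_len = 1)
  len <- wall_lengths(m2)
  expect_true(all(len <= 1 + 1e-12))
  # the two 2.5 walls give 3 segments each, the 0.8 walls stay whole
  expect_identical(n_walls(m2), 8L)
  expect_length(validate_mesh(m2), 0L)
  expect_equal(cell_area(1, m2), 2, tolerance = 1e-12)
})

test_that("split_long_walls apportions PIN by length and conserves cell sums", {
  m <- two_cell_mesh()
  # stretch the shared wall beyond max_len so it splits
  m$pos <- m$pos * 2
  m$walls$rest <- wall_lengths(m)
  m <- init_pin(m)
  sums_before <- meristemsim:::pin_sums(m)
  shared <- which(!is.na(m$walls$c2))
  pin_before <- m$walls$pin1[shared]
  m2 <- split_long_walls(m, max_len = 1)
  expect_length(validate_mesh(m2), 0L)
  shared2 <- which(!is.na(m2$walls$c2))
  expect_identical(length(shared2), 2L)                 # 2 um wall -> 2 halves
  expect_equal(m2$walls$pin1[shared2], rep(pin_before / 2, 2))
  expect_equal(meristemsim:::pin_sums(m2), sums_before, tolerance = 1e-12)
  expect_equal(sum(cell_areas(m2)), sum(cell_areas(m)), tolerance = 1e-12)
})

test_that("noise-free division of a rectangle uses the minimal wall", {
  m <- rect_mesh(10, 4)
  m$aux <- 3; m$cuc <- 1.5; m$delta <- 0.7
  set.seed(1)
  m2 <- divide_cell(m, 1L, noise = division_noise(0, 0, 0))
  expect_identical(n_cells(m2), 2L)
  ar <- cell_areas(m2)
  expect_equal(sort(ar), c(20, 20), tolerance = 1e-9)   # daughters 5 x 4
  # the new wall is the one shared by the daughters, length 4
  shared <- which(!is.na(m2$walls$c2))
  expect_length(shared, 1L)
  expect_equal(wall_lengths(m2)[shared], 4, tolerance = 1e-9)
  # daughters inherit parent chemistry unchanged
  expect_equal(m2$aux, c(3, 3))
  expect_equal(m2$cuc, c(1.5, 1.5))
  expect_equal(m2$delta, c(0.7, 0.7))
  expect_length(validate_mesh(m2), 0L)
})

test_that("noise-free division is equivariant under grid rotations", {
  m <- rect_mesh(10, 4)
  set.seed(1)
  d0 <- divide_cell(m, 1L, noise = division_noise(0, 0, 0))
  mr <- rotate_mesh(m, 30)
  set.seed(1)
  dr <- divide_cell(mr, 1L, noise = division_noise(0, 0, 0))
  # rotating the divided mesh must equal dividing the rotated mesh
  d0r <- rotate_mesh(d0, 30)
  expect_equal(dr$pos, d0r$pos, tolerance = 1e-9)
  expect_identical(dr$loops, d0r$loops)
})

test_that("noisy division conserves area, PIN sums and the Euler relation", {
  m <- load_default_disk()
  m <- init_pin(m)
  set.seed(42)
  area0 <- sum(cell_areas(m))
  for (cc in c(5L, 20L, 60L)) m <- divide_cell(m, cc)
  expect_identical(n_cells(m), 76L)
  expect_equal(sum(cell_areas(m)), area0, tolerance = 1e-9)
  expect_identical(n_vertices(m) - n_walls(m) + n_cells(m), 1L)
  expect_equal(meristemsim:::pin_sums(m), rep(1, 76), tolerance = 1e-12)
  expect_length(validate_mesh(m), 0L)
})

test_that("division never cuts off sliver daughters", {
  # scale the disk so many cells exceed the 50 um^2 threshold, then run a
  # simulation-like division pass; every daughter must stay well above the
  # transport stability floor (~2 um^2)
  m <- load_default_disk()
  m$pos <- m$pos * 2
  m$walls$rest <- m$walls$rest * 2
  m <- split_long_walls(init_pin(m), 1)   # as in the simulation loop
  set.seed(99)
  over <- which(cell_areas(m) > 50)
  expect_gt(length(over), 20L)
  for (cc in over) m <- divide_cell(m, cc)
  new_cells <- c(over, seq.int(74L, n_cells(m)))
  # >= 20% of the parent minus what the junction jitter can shave off
  expect_gt(min(cell_areas(m)[new_cells]), 4)
  expect_length(validate_mesh(m), 0L)
})

test_that("validate_mesh reports specific violations", {
  m <- load_default_disk()
  expect_length(validate_mesh(m), 0L)
  bad <- m
  bad$walls$v2[5L] <- n_vertices(m) + 50L
  expect_true(any(grepl("missing vertex", validate_mesh(bad))))
  bad2 <- m
  bad2$walls$rest[1L] <- -1
  expect_true(any(grepl("rest length", validate_mesh(bad2))))
  bad3 <- m
  bad3$walls <- bad3$walls[-1L, ]
  expect_true(any(grepl("Euler|no wall", validate_mesh(bad3))))
})
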