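test_that("IsoData finds the intermeans fixed point on bimodal input", {
  x <- c(rep(0, 5000), rep(1000, 5000))
  thr <- isodata_threshold(x)
  expect_lt(abs(thr - 500), 1000 / 256 + 1e-9)   # within one bin
  # two Gaussian modes at 100 and 900, equal mass
  set.seed(21)
  x2 <- c(rnorm(5000, 100, 10), rnorm(5000, 900, 10))
  thr2 <- isodata_threshold(x2)
  expect_gt(thr2, 450)
  expect_lt(thr2, 550)
  expect_error(isodata_threshold(rep(5, 100)), "degenerate")
})

test_that("the corrected threshold multiplies IsoData and masks clutter", {
  ph <- noiseless_phantom()
  raw <- compute_threshold(ph$volume, correction = 1)
  expect_equal(compute_threshold(ph$volume, correction = 0.73), raw * 0.73)
  # bright clutter outside the outline must not move the threshold
  outline <- project(ph$volume, "max", 2) > 0
  thr_clean <- compute_threshold(ph$volume, outline, correction = 0.73)
  dirty <- ph$volume
  n1 <- dim(dirty$intensities)[1]
  stopifnot(!any(outline[n1, ]))      # bottom rows lie outside the fish
  dirty$intensities[n1, , ] <- 60000  # clutter sheet outside the outline
  thr_dirty <- compute_threshold(dirty, outline, correction = 0.73)
  expect_equal(thr_dirty, thr_clean)
  # varying the clutter intensity leaves it unchanged too
  dirty$intensities[n1, , ] <- 30000
  expect_equal(compute_threshold(dirty, outline, correction = 0.73),
               thr_clean)
  expect_error(compute_threshold(ph$volume, outline & FALSE), "empty outline")
})

test_that("binarize is an inclusive threshold", {
  v <- array(c(0, 1, 2, 3, 4, 5, 6, 7), c(2, 2, 2))
  expect_equal(sum(binarize(v, 0)), 8)       # all voxels (>= 0)
  expect_equal(sum(binarize(v, 4)), 4)
  expect_equal(sum(binarize(v, 100)), 0)
  expect_error(binarize(v, Inf), "finite")
})

test_that("seed separation splits bridged cubes into two full labels", {
  m <- bridged_cubes()
  seeds <- seed_lines(x1 = c(6, 6, 6), y1 = rep(12, 3), z1 = c(1.5, 13.5, 25),
                      x2 = c(19, 19, 19), y2 = rep(12, 3),
                      z2 = c(1.5, 13.5, 25))
  vm <- separate_vertebrae(m, seeds)
  counts <- table(vm$labels[vm$labels > 0])
  expect_equal(vm$n_vertebrae, 2L)
  expect_length(counts, 2)
  # each cube keeps its 1000 voxels minus any bridge/plane voxels
  expect_true(all(counts >= 995 & counts <= 1005))
})

test_that("already-disjoint components separate with zero extension", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:15, 5:15, 2:8] <- TRUE
  m[5:15, 5:15, 12:18] <- TRUE
  seeds <- seed_lines(x1 = c(4, 4, 4), y1 = rep(10, 3), z1 = c(1, 10, 19.5),
                      x2 = c(16, 16, 16), y2 = rep(10, 3),
                      z2 = c(1, 10, 19.5))
  vm <- separate_vertebrae(m, seeds)
  expect_equal(unname(vm$extents[2]), 0)
  expect_equal(sort(unique(as.vector(vm$labels[vm$labels > 0]))), c(1L, 2L))
})

test_that("a too-short seed line is extended until the bridge is cut", {
  m <- bridged_cubes()
  # middle seed too short to reach the bridge row (12) initially
  seeds <- seed_lines(x1 = c(6, 4, 6), y1 = rep(12, 3), z1 = c(1.5, 13.5, 25),
                      x2 = c(19, 8, 19), y2 = rep(12, 3),
                      z2 = c(1.5, 13.5, 25))
  vm <- separate_vertebrae(m, seeds)
  expect_gt(vm$extents[2], 0)
  expect_equal(length(table(vm$labels[vm$labels > 0])), 2L)
})

test_that("separation errors identify the failing seed", {
  # a persistent plurality tie: the anterior side holds two equal-sized
  # components, so no extension can ever produce distinct winners and the
  # line runs off the volume
  m <- array(FALSE, c(30, 10, 24))
  m[2:7, 4:7, 3:10] <- TRUE             # anterior blob 1
  m[13:18, 4:7, 3:10] <- TRUE           # anterior blob 2, same size
  m[8:12, 4:7, 15:22] <- TRUE           # posterior blob
  seeds <- seed_lines(x1 = c(14, 14, 14), y1 = rep(5, 3),
                      z1 = c(1, 12.5, 24),
                      x2 = c(16, 16, 16), y2 = rep(5, 3),
                      z2 = c(1, 12.5, 24))
  expect_error(separate_vertebrae(m, seeds), "seed 1")
})

test_that("manual cuts sever bridges and are idempotent", {
  m <- bridged_cubes()
  expect_equal(max(label_components(m)), 1L)
  cut1 <- apply_cut(m, c(10, 12, 13), c(14, 12, 14))
  expect_equal(max(label_components(cut1)), 2L)
  expect_identical(apply_cut(cut1, c(10, 12, 13), c(14, 12, 14)), cut1)
  # a cut through background only changes nothing
  empty_cut <- apply_cut(m, c(1, 1, 1), c(2, 2, 1))
  expect_identical(empty_cut, m)
  expect_error(apply_cut(m, c(0, 1, 1), c(2, 2, 1)), "inside")
})

test_that("component reassignment moves exactly the named fragment", {
  run <- segmented_phantom()
  vm <- run$vmap
  # add a floating fragment near vertebra 2 and label it 2
  labels <- vm$labels
  frag <- array(FALSE, dim(labels))
  frag[2:3, 2:3, 40:41] <- TRUE
  labels[frag] <- 2L
  vm2 <- vertebrome:::new_vertebra_map(labels, vm$n_vertebrae, vm$seeds,
                                       vm$extents)
  comp <- label_components(vm2$labels > 0)
  frag_id <- comp[2, 2, 40]
  n2_before <- sum(vm2$labels == 2)
  vm3 <- assign_components(vm2,
                           data.frame(component = frag_id, vertebra = 1))
  expect_equal(sum(vm3$labels == 2), n2_before - sum(frag))
  expect_equal(sum(vm3$labels == 1), sum(vm2$labels == 1) + sum(frag))
  # empty reassignment is the identity
  expect_identical(assign_components(vm2, data.frame()), vm2)
  expect_error(assign_components(vm2, data.frame(component = 10000,
                                                 vertebra = 1)),
               "does not exist")
})

test_that("element masks partition each vertebra exactly", {
  run <- segmented_phantom()
  vm <- run$vmap
  for (v in seq_len(vm$n_vertebrae)) {
    vert <- vm$labels == v
    el <- segment_elements(vert, vm$seeds[v, ], vm$seeds[v + 1, ])
    expect_false(any(el$neur & el$cent))
    expect_false(any(el$neur & el$haem))
    expect_false(any(el$cent & el$haem))
    expect_identical(el$neur | el$cent | el$haem, vert)
  }
})

test_that("limiting geometry puts everything in the neural arch", {
  vert <- array(FALSE, c(30, 10, 30))
  vert[2:6, 4:6, 8:22] <- TRUE           # all voxels dorsal of the line
  ant <- list(x1 = 20, y1 = 5, z1 = 5, x2 = 25, y2 = 5, z2 = 5)
  post <- list(x1 = 20, y1 = 5, z1 = 25, x2 = 25, y2 = 5, z2 = 25)
  el <- segment_elements(vert, ant, post, buffer = 2)
  expect_identical(el$neur, vert)
  expect_equal(sum(el$cent), 0)
  expect_equal(sum(el$haem), 0)
  # collinear endpoints are rejected
  bad_post <- list(x1 = 20, y1 = 5, z1 = 5, x2 = 25, y2 = 5, z2 = 5)
  expect_error(segment_elements(vert, ant, bad_post, buffer = 2),
               "degenerate")
})

test_that("the centrum grows and the haemal mask shrinks with the buffer", {
  run <- segmented_phantom()
  vm <- run$vmap
  vert <- vm$labels == 2
  el0 <- segment_elements(vert, vm$seeds[2, ], vm$seeds[3, ], buffer = 0)
  el5 <- segment_elements(vert, vm$seeds[2, ], vm$seeds[3, ], buffer = 5)
  expect_true(all(el5$cent[el0$cent]))   # cent(0) subset of cent(5)
  expect_true(all(el0$haem[el5$haem]))   # haem(5) subset of haem(0)
})

test_that("no 26-connected component carries two vertebra labels", {
  run <- segmented_phantom()
  labels <- run$vmap$labels
  comp <- label_components(labels > 0)
  fg <- which(labels > 0)
  per_comp <- tapply(labels[fg], comp[fg], function(v) length(unique(v)))
  expect_true(all(per_comp == 1))
})

test_that("dice coefficient follows its definition and symmetry", {
  a <- array(FALSE, c(5, 5, 5)); a[1:4, 1:5, 1:5] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- array(FALSE, c(5, 5, 5)); b[5, , ] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  # |A| = |B| = 100, overlap 50 -> 0.5
  a2 <- array(FALSE, c(10, 10, 2)); a2[, , 1] <- TRUE
  b2 <- array(FALSE, c(10, 10, 2)); b2[1:5, , 1] <- TRUE; b2[1:5, , 2] <- TRUE
  expect_equal(dice_coefficient(a2, b2), 0.5)
  expect_equal(dice_coefficient(b2, a2), 0.5)
  empty <- array(FALSE, c(5, 5, 5))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_error(dice_coefficient(a, array(FALSE, c(4, 5, 5))), "shapes")
})
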