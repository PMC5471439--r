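test_that("segmenting an all-zero stack yields no cells", {
  arr <- array(0L, dim = c(30, 30, 10))
  expect_identical(nrow(segment_stack(arr, 0.5, 10)), 0L)
})

test_that("a single rendered ellipsoid is measured to within 5%", {
  vol <- imaging_volume(60, 60, 40, 1)
  cells <- data.frame(x = 30.3, y = 29.6, z = 20.2, a = 11, b = 11, c = 8.8,
                      true_class = "neuron")
  stk <- render_stack(cells, vol)
  rec <- segment_stack(stk, 0.5, min_voxels = 50)
  expect_identical(nrow(rec), 1L)
  expect_lt(abs(rec$soma_area_um2 - pi * 121) / (pi * 121), 0.05)
  expect_lt(abs(rec$x - 30.3), 1)
  expect_lt(abs(rec$z - 20.2), 1)
})

test_that("segmentation recovers every placed cell, blurred or crisp", {
  vol <- imaging_volume(150, 150, 60, 1)
  cells <- place_cells(12, 12, vol, seed = 21)
  for (bs in c(0, 1)) {
    stk <- render_stack(cells, vol, blur_sigma = bs)
    rec <- segment_stack(stk, 0.5, min_voxels = 50)
    expect_identical(nrow(rec), nrow(cells))
  }
})

test_that("classification partitions records at the 200 um^2 threshold", {
  rec <- data.frame(soma_area_um2 = c(389, 300, 88, 200, 200.001))
  out <- classify_cells(rec, classification_rule(200))
  expect_identical(out$assigned_class,
                   c("neuron", "neuron", "glia", "glia", "neuron"))
  cnt <- count_cells(out)
  expect_identical(unname(cnt["neuron_count"] + cnt["glia_count"]),
                   nrow(rec))
  expect_identical(unname(cnt), c(3L, 2L))
})

test_that("counting requires classified records and handles empty input", {
  expect_identical(unname(count_cells(data.frame())), c(0L, 0L))
  rec <- data.frame(soma_area_um2 = 100, assigned_class = "unassigned")
  expect_error(count_cells(rec), "classified")
  expect_error(classify_cells(data.frame(soma_area_um2 = NA_real_)),
               "soma_area")
})

test_that("classification + counting is a deterministic partition (property)", {
  for (s in 1:20) {
    areas <- generate_soma_areas(sample(0:30, 1), sample(0:30, 1),
                                 seed = 500 + s)
    rec <- classify_cells(data.frame(soma_area_um2 = areas$area_um2))
    cnt <- count_cells(rec)
    expect_identical(unname(cnt["neuron_count"] + cnt["glia_count"]),
                     nrow(rec))
    # truncation gap straddles the threshold: zero misclassification
    expect_identical(rec$assigned_class, areas$true_class)
  }
})

test_that("bimodal break falls inside the empty truncation gap", {
  a <- generate_soma_areas(500, 500, seed = 13)
  brk <- find_bimodal_break(a$area_um2, 18)
  expect_gte(brk, 160)
  expect_lte(brk, 210)
})

test_that("unimodal inputs give an explicit no-break result", {
  expect_true(is.na(find_bimodal_break(rep(100, 50), 18)))
  unimodal <- withr::with_seed(31, rnorm(500, 100, 10))
  expect_true(is.na(find_bimodal_break(unimodal, 18)))
})

test_that("break detection is invariant to input permutation", {
  a <- generate_soma_areas(300, 400, seed = 17)$area_um2
  b1 <- find_bimodal_break(a, 18)
  b2 <- find_bimodal_break(rev(a), 18)
  b3 <- find_bimodal_break(sample(a), 18)
  expect_identical(b1, b2)
  expect_identical(b1, b3)
})

test_that("break detection validates its inputs", {
  expect_error(find_bimodal_break(c(100), 18), "2 finite")
  expect_error(find_bimodal_break(c(100, 200), 0), "bin_size")
})

test_that("segmentation threshold and min_voxels are validated", {
  arr <- array(1L, dim = c(5, 5, 5))
  expect_error(segment_stack(arr, 1.5, 10), "between 0 and 1")
  expect_error(segment_stack(array(integer(0), c(0, 0, 0))), "empty")
})
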