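test_that("soma-area generator respects truncation bounds and class separation", {
  m <- area_model()
  a <- generate_soma_areas(2000, 2000, m, seed = 42)
  neu <- a$area_um2[a$true_class == "neuron"]
  gli <- a$area_um2[a$true_class == "glia"]
  expect_true(all(neu >= m$neuron_floor))
  expect_true(all(gli <= m$glia_ceiling))
  expect_true(all(gli >= m$glia_floor))
  expect_lt(max(gli), min(neu))

  expect_identical(nrow(generate_soma_areas(0, 0, m, seed = 1)), 0L)
  expect_error(generate_soma_areas(-1, 5, m), "n_neurons")
})

test_that("soma-area generator recovers the nominal class means", {
  a <- generate_soma_areas(10000, 10000, seed = 7)
  neu <- a$area_um2[a$true_class == "neuron"]
  gli <- a$area_um2[a$true_class == "glia"]
  expect_lt(abs(mean(neu) - 389) / 389, 0.02)
  expect_lt(abs(mean(gli) - 88) / 88, 0.02)
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(generate_soma_areas(50, 50, seed = 3),
                   generate_soma_areas(50, 50, seed = 3))
  d <- prebotc_cohort_design()
  expect_identical(generate_cohort(d, seed = 3), generate_cohort(d, seed = 3))
  vol <- imaging_volume(60, 60, 30, 1)
  c1 <- place_cells(3, 3, vol, seed = 9)
  expect_identical(c1, place_cells(3, 3, vol, seed = 9))
  s1 <- render_stack(c1, vol, blur_sigma = 1, noise_scale = 20, seed = 4)
  s2 <- render_stack(c1, vol, blur_sigma = 1, noise_scale = 20, seed = 4)
  expect_identical(s1$intensities, s2$intensities)
})

test_that("area model rejects overlapping or invalid truncation bounds", {
  expect_error(area_model(glia_ceiling = 250), "overlap")
  expect_error(area_model(neuron_floor = -5), "neuron_floor")
  expect_error(area_model(glia_floor = 170), "glia_floor")
})

test_that("cohort counts equal rounded means when all SDs are zero", {
  co <- generate_cohort(sd_zero_design(), seed = 1)
  expect_true(all(co$neuron_count[co$tamoxifen_day == "E9.5"] == 63))
  expect_true(all(co$neuron_count[co$genotype == "constitutive"] == 70))
  expect_true(all(co$glia_count[co$tamoxifen_day == "E11.5"] == 34))
})

test_that("cohort counts are non-negative integers even when mean - 3sd < 0", {
  d <- cohort_design(data.frame(
    genotype = "inducible", tamoxifen_day = "E11.5",
    neuron_mean = 1, neuron_sd = 5, glia_mean = 0.5, glia_sd = 4),
    n_animals = 200)
  co <- generate_cohort(d, seed = 2)
  expect_true(all(co$neuron_count >= 0))
  expect_true(all(co$glia_count >= 0))
  expect_true(is.integer(co$neuron_count))
})

test_that("per-condition sample means stay within 3 SE of design means", {
  # rate over (seed x condition x class) pairs of |mean - design| <= 3 sd/sqrt(3)
  d <- prebotc_cohort_design()
  cond <- d$conditions
  n_seeds <- 500
  hits <- 0L; total <- 0L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(d, seed = 20000 + s)
    sm <- aggregate(cbind(neuron_count, glia_count) ~ tamoxifen_day, co, mean)
    sm <- sm[match(cond$tamoxifen_day, sm$tamoxifen_day), ]
    for (cl in c("neuron", "glia")) {
      dm <- cond[[paste0(cl, "_mean")]]
      ds <- cond[[paste0(cl, "_sd")]]
      ok <- abs(sm[[paste0(cl, "_count")]] - dm) <= 3 * ds / sqrt(3)
      hits <- hits + sum(ok); total <- total + length(ok)
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("large-cohort summaries recover the design means (closure)", {
  d <- prebotc_cohort_design(n_animals = 300)
  co <- generate_cohort(d, seed = 11)
  sm <- summarize_cohort(co)
  cond <- d$conditions
  for (i in seq_len(nrow(cond))) {
    for (cl in c("neuron", "glia")) {
      got <- sm$mean_count[sm$tamoxifen_day == cond$tamoxifen_day[i] &
                             sm$cell_class == cl]
      want <- cond[[paste0(cl, "_mean")]][i]
      tol <- max(0.01 * want, 4 * cond[[paste0(cl, "_sd")]][i] / sqrt(300))
      expect_lt(abs(got - want), tol + 1e-9)
    }
  }
})

test_that("cohort CSV round-trips", {
  co <- generate_cohort(small_design(), seed = 8)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, p)
  expect_equal(read_cohort_csv(p), co)
})

test_that("rendering an empty scene gives an all-zero grid", {
  vol <- imaging_volume(20, 20, 10, 1)
  cells <- place_cells(0, 0, vol, seed = 1)
  stk <- render_stack(cells, vol, blur_sigma = 0, noise_scale = 0)
  expect_true(all(stk$intensities == 0))
  expect_identical(dim(stk$intensities), vol$dim)
})

test_that("ground-truth soma area is the analytic ellipse area", {
  vol <- imaging_volume(60, 60, 40, 1)
  cells <- data.frame(x = 30, y = 30, z = 20, a = 11, b = 11, c = 8,
                      true_class = "neuron")
  stk <- render_stack(cells, vol)
  expect_equal(stk$ground_truth$true_area_um2, pi * 121, tolerance = 1e-12)
})

test_that("rendering rejects centroids outside the volume and bad radii", {
  vol <- imaging_volume(20, 20, 10, 1)
  bad <- data.frame(x = 25, y = 10, z = 5, a = 3, b = 3, c = 2,
                    true_class = "glia")
  expect_error(render_stack(bad, vol), "outside")
  bad2 <- data.frame(x = 10, y = 10, z = 5, a = -1, b = 3, c = 2,
                     true_class = "glia")
  expect_error(render_stack(bad2, vol), "radii")
})
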