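test_that("voxel allocation is deterministic largest-remainder, not multinomial", {
  p <- roi_preset("custom", n_voxels = 1000L,
                  mixture = c(number = 0.5, avg_item_area = 0,
                              total_field_area = 0, total_surface_area = 0,
                              density = 0.5, none = 0))
  pop <- make_population(p, seed = 1)
  expect_equal(sum(pop$dimension == "number"), 500)
  expect_equal(sum(pop$dimension == "density"), 500)

  p2 <- roi_preset("custom", n_voxels = 100L,
                   mixture = c(number = 1, avg_item_area = 0,
                               total_field_area = 0, total_surface_area = 0,
                               density = 0, none = 0))
  pop2 <- make_population(p2, seed = 1)
  expect_equal(nrow(pop2), 100)
  expect_true(all(pop2$dimension == "number"))

  expect_identical(make_population(p, seed = 4), make_population(p, seed = 4))
  expect_error(roi_preset("custom", mixture = c(number = 0.6, none = 0.6)),
               "sum to 1")
})

test_that("number voxels prefer log numerosities spanning the extended range", {
  set <- condition_grid()
  p <- roi_preset("higher", n_voxels = 2000L)
  pop <- make_population(p, seed = 3, stimulus_set = set)
  pref <- pop$preferred_log_value[pop$dimension == "number"]
  w <- p$number_tuning_width
  expect_true(all(pref >= log(6) - w & pref <= log(17) + w))
  expect_gt(max(pref), log(17) - 0.05)  # the extension is actually used
  expect_lt(min(pref), log(6) + 0.05)
})

test_that("simulation is deterministic and task-symmetric when gains are equal", {
  set <- condition_grid()
  p <- roi_preset("early", n_voxels = 100L, noise_sd = 0)
  pop <- make_population(p, seed = 5)
  ds <- simulate_betas(pop, set, n_subjects = 2, n_runs = 3, seed = 6)
  # gains all 1 and no noise: the two tasks' patterns are identical
  expect_equal(ds$values[, "number", , , ], ds$values[, "size", , , ])

  p2 <- roi_preset("early", n_voxels = 100L)
  pop2 <- make_population(p2, seed = 5)
  a <- simulate_betas(pop2, set, n_subjects = 2, n_runs = 3, seed = 6)
  b <- simulate_betas(pop2, set, n_subjects = 2, n_runs = 3, seed = 6)
  expect_identical(a$values, b$values)
})

test_that("extending the cohort does not disturb earlier subjects", {
  set <- condition_grid()
  pop <- make_population(roi_preset("early", n_voxels = 50L), seed = 2)
  small <- simulate_betas(pop, set, n_subjects = 2, n_runs = 2, seed = 9)
  large <- simulate_betas(pop, set, n_subjects = 4, n_runs = 2, seed = 9)
  expect_identical(small$values[1:2, , , , ], large$values[1:2, , , , ])
})

test_that("a number-tuned voxel peaks at its preferred numerosity", {
  set <- condition_grid()
  p <- roi_preset("custom", n_voxels = 50L, noise_sd = 0,
                  mixture = c(number = 1, avg_item_area = 0,
                              total_field_area = 0, total_surface_area = 0,
                              density = 0, none = 0))
  pop <- make_population(p, seed = 8, stimulus_set = set)
  ds <- simulate_betas(pop, set, tasks = "number", n_subjects = 1,
                       n_runs = 1, seed = 1)
  # pick a voxel whose preferred value is nearest log(10)
  v <- which.min(abs(pop$preferred_log_value - log(10)))
  resp <- ds$values[1, 1, 1, , v]
  by_num <- tapply(resp, set$number, mean)
  expect_gt(by_num[["10"]], by_num[["6"]])
  expect_gt(by_num[["10"]], by_num[["17"]])
})

test_that("presets express the early-to-higher hierarchy", {
  early <- roi_preset("early")
  higher <- roi_preset("higher")
  inter <- roi_preset("intermediate")
  expect_equal(early$attention_gain["number", "number"], 1.0)
  expect_gt(higher$mixture[["number"]], early$mixture[["number"]])
  expect_gt(higher$attention_gain["number", "number"],
            higher$attention_gain["size", "number"])
  expect_true(inter$attention_gain["number", "number"] >
                early$attention_gain["number", "number"] &&
              inter$attention_gain["number", "number"] <
                higher$attention_gain["number", "number"])
  expect_error(roi_preset("parietal"), "arg")
})

test_that("beta datasets survive the directory round-trip", {
  set <- condition_grid()
  pop <- make_population(roi_preset("early", n_voxels = 20L), seed = 2)
  ds <- simulate_betas(pop, set, n_subjects = 2, n_runs = 2, seed = 3)
  dir <- tempfile()
  write_beta_dataset(ds, dir)
  back <- read_beta_dataset(dir)
  expect_equal(back$values, ds$values, tolerance = 1e-12)
  expect_equal(back$tasks, ds$tasks)
  expect_equal(back$subject_seeds, ds$subject_seeds)
  unlink(dir, recursive = TRUE)
})

test_that("decoding accuracy does not decrease with number-population weight", {
  set <- condition_grid()
  accs <- vapply(c(0.3, 1, 3), function(w) {
    p <- roi_preset("higher", n_voxels = 300L,
                    weights = c(number = w, avg_item_area = 1,
                                total_field_area = 1,
                                total_surface_area = 1, density = 1))
    pop <- make_population(p, seed = 11, stimulus_set = set)
    ds <- simulate_betas(pop, set, tasks = "number", n_subjects = 2,
                         n_runs = 6, seed = 12)
    mean(pairwise_number_decoding(ds, "number", k = 250)$mean_accuracy)
  }, 0)
  expect_true(all(diff(accs) >= -0.03))  # Monte-Carlo tolerance
  expect_gt(accs[3], accs[1])
})
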