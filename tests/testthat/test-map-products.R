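test_that("probability cubes enforce the percent-sum contract", {
  g <- grid_spec(2, 2, lon_min = 0, lat_min = 0, cell_size = 1)
  good <- array(50, c(2, 2, 2))
  expect_s3_class(prob_cube(g, c("A", "B"), good), "prob_cube")
  bad <- array(49, c(2, 2, 2))
  expect_error(prob_cube(g, c("A", "B"), bad), "sum to 100")
  g1 <- grid_spec(1, 1, cell_size = 1)
  neg <- array(c(150, -50), c(1, 1, 2))  # sums to 100 but leaves [0, 100]
  expect_error(prob_cube(g1, c("A", "B"), neg), "0, 100")
})

test_that("margin of victory spans its printed bounds and handles masks", {
  g <- grid_spec(1, 3, lon_min = 0, lat_min = 0, cell_size = 1)
  vals <- array(NA_real_, c(1, 3, 3))
  vals[1, 1, ] <- c(100, 0, 0)      # one-hot
  vals[1, 2, ] <- c(100 / 3, 100 / 3, 100 / 3)  # uniform
  vals[1, 3, ] <- c(50, 30, 20)
  cube <- prob_cube(g, c("A", "B", "C"), vals)
  mov <- margin_of_victory(cube)
  expect_equal(mov[1, 1], 100)
  expect_equal(mov[1, 2], 0)
  expect_equal(mov[1, 3], 20)

  msk <- matrix(c(FALSE, FALSE, TRUE), 1, 3)
  vals_m <- vals; vals_m[1, 3, ] <- NA
  cube_m <- prob_cube(g, c("A", "B", "C"), vals_m, mask = msk)
  expect_true(is.na(margin_of_victory(cube_m)[1, 3]))

  one_class <- prob_cube(grid_spec(1, 1, cell_size = 1), "A",
                         array(100, c(1, 1, 1)))
  expect_error(margin_of_victory(one_class), "at least 2")
})

test_that("hard classification takes the argmax with legend-order tie-break", {
  g <- grid_spec(1, 3, lon_min = 0, lat_min = 0, cell_size = 1)
  vals <- array(NA_real_, c(1, 3, 3))
  vals[1, 1, ] <- c(50, 30, 20)
  vals[1, 2, ] <- c(50, 50, 0)    # tie -> first class in the legend
  vals[1, 3, ] <- c(0, 10, 90)
  msk <- matrix(c(FALSE, FALSE, FALSE), 1, 3)
  cube <- prob_cube(g, c("A", "B", "C"), vals, msk)
  hard <- hard_classify(cube)
  expect_identical(as.integer(hard[1, ]), c(1L, 1L, 3L))

  vals[1, 2, ] <- NA
  cube2 <- prob_cube(g, c("A", "B", "C"), vals,
                     mask = matrix(c(FALSE, TRUE, FALSE), 1, 3))
  expect_true(is.na(hard_classify(cube2)[1, 2]))
})

test_that("the biome-to-IUCN scheme is total onto the six targets", {
  scheme <- biome_iucn_scheme()
  expect_length(scheme, 20)
  expect_identical(sort(unique(unname(scheme))), paste0("T", 1:6))
  expect_identical(unname(scheme[["Tropical savanna"]]), "T4")
  expect_identical(as.integer(table(scheme)[paste0("T", 1:6)]),
                   c(3L, 7L, 3L, 1L, 2L, 4L))
})

test_that("legend aggregation conserves mass and collapses 20 classes to 6", {
  scheme <- biome_iucn_scheme()
  src <- names(scheme)
  g <- grid_spec(2, 2, lon_min = 0, lat_min = 0, cell_size = 1)

  # all mass on "Tropical savanna" lands entirely on T4
  vals <- array(0, c(2, 2, 20))
  vals[, , which(src == "Tropical savanna")] <- 100
  cube <- prob_cube(g, src, vals)
  out <- translate_probabilities(cube, scheme)
  expect_identical(out$classes, paste0("T", 1:6))
  expect_true(all(out$values[, , "T4"] == 100))
  expect_true(all(out$values[, , setdiff(out$classes, "T4")] == 0))

  # uniform 5% over 20 source classes: row counts of the scheme x 5
  uni <- prob_cube(g, src, array(5, c(2, 2, 20)))
  agg <- translate_probabilities(uni, scheme)
  expect_equal(unname(agg$values[1, 1, ]), c(15, 35, 15, 5, 10, 20))

  # exact conservation and non-decreasing per-pixel maximum
  set.seed(9)
  r <- array(rexp(2 * 2 * 20), c(2, 2, 20))
  r <- 100 * sweep(r, c(1, 2), apply(r, c(1, 2), sum), "/")
  rc <- prob_cube(g, src, r)
  ragg <- translate_probabilities(rc, scheme)
  expect_equal(apply(ragg$values, c(1, 2), sum),
               apply(rc$values, c(1, 2), sum))
  expect_true(all(apply(ragg$values, c(1, 2), max) >=
                    apply(rc$values, c(1, 2), max)))

  # margin of victory is recomputable on the aggregated cube
  expect_no_error(margin_of_victory(ragg))

  expect_error(translate_probabilities(prob_cube(g, c("Nonexistent biome"),
                                                 array(100, c(2, 2, 1))),
                                       scheme),
               "Nonexistent biome")
})

test_that("map products round-trip through ASCII grids with a legend file", {
  d <- small_study()
  m <- small_model()
  pred <- predict_probabilities(m, d$stack)
  dir <- withr::local_tempdir()
  paths <- write_map_products(pred$cube, dir, prefix = "t")
  expect_true(all(file.exists(paths)))
  back <- read_asc(file.path(dir, "t_prob_01.asc"))
  expect_equal(back$values, pred$cube$values[, , 1], tolerance = 1e-6)
  expect_true(same_grid <- isTRUE(all.equal(back$grid$cell_size,
                                            d$grid$cell_size)))
  leg <- jsonlite::read_json(file.path(dir, "t_legend.json"))
  expect_identical(names(leg$classes), m$classes)
})
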