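fx <- mqimp_fixture()
ev <- evaluate_from_first_level(fx$scores)

test_that("surface matrix is the row-major 3x3 arrangement of dimension scores", {
  s <- surface_matrix(ev, policy = "P11")
  expect_equal(round_half_up(unclass(s), 2),
               matrix(c(0.67, 1.00, 1.00,
                        0.67, 1.00, 0.67,
                        1.00, 1.00, 1.00), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  # pure rearrangement: same multiset of values as the scorecard
  card <- dplyr::filter(tidy(ev), policy_id == "P11")
  expect_equal(sort(as.vector(unclass(s))),
               sort(as.numeric(card[1, paste0("X", 1:9)])))
  expect_equal(unclass(surface_matrix(rep(0, 9))), matrix(0, 3, 3),
               ignore_attr = TRUE)
})

test_that("average surface matches the published corpus averages", {
  s <- average_surface(ev)
  expect_equal(round_half_up(unclass(s), 2),
               matrix(c(0.76, 0.76, 0.80,
                        0.53, 0.65, 0.45,
                        0.85, 0.59, 0.89), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  # two complementary policies average to a constant 0.5 surface
  both <- dplyr::bind_rows(tibble::as_tibble(constant_matrix(1, 1)),
                           dplyr::mutate(tibble::as_tibble(constant_matrix(1, 0)),
                                         policy_id = "Q2"))
  ev2 <- evaluate_corpus(as_coding_matrix(both))
  expect_true(all(unclass(average_surface(ev2)) == 0.5))
})

test_that("interpolated grid hits nodes exactly and stays within range", {
  s <- average_surface(ev)
  g <- surface_grid(s, resolution = 31)
  expect_equal(nrow(g), 31 * 31)
  expect_gte(min(g$value), min(unclass(s)) - 1e-9)
  expect_lte(max(g$value), max(unclass(s)) + 1e-9)
  # corner nodes are control values
  corner <- g$value[g$row == 1 & g$col == 1]
  expect_equal(corner, unclass(s)[1, 1])
  # resolution 3 returns the control grid itself
  g3 <- surface_grid(s, resolution = 3)
  expect_equal(matrix(g3$value, 3, 3), unclass(s), ignore_attr = TRUE)
  # constant surface interpolates to a constant field
  gc <- surface_grid(surface_matrix(rep(0.4, 9)), resolution = 12)
  expect_true(all(abs(gc$value - 0.4) < 1e-12))
  expect_error(surface_grid(s, resolution = 2), class = "pmcindex_input_error")
})

test_that("tile mode repeats control values without smoothing", {
  s <- average_surface(ev)
  g <- surface_grid(s, resolution = 9, mode = "tile")
  expect_true(all(g$value %in% as.vector(unclass(s))))
})

test_that("radar data flags the published weak dimensions and honours thresholds", {
  rd <- radar_data(ev)
  expect_equal(rd$dimension[rd$flagged], c("X4", "X6", "X8"))
  expect_equal(rd$display, c(0.76, 0.76, 0.80, 0.53, 0.65, 0.45, 0.85, 0.59, 0.89))
  rd7 <- radar_data(ev, threshold = 0.7)
  expect_equal(rd7$dimension[rd7$flagged], c("X4", "X5", "X6", "X8"))
  ev_ones <- evaluate_corpus(constant_matrix(2, 1))
  expect_false(any(radar_data(ev_ones)$flagged))
})

test_that("surface export writes a readable grid file", {
  f <- withr::local_tempfile(fileext = ".csv")
  g <- export_surface_grid(average_surface(ev), f, resolution = 10)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(back), 100)
  expect_equal(back$value, g$value)
})
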