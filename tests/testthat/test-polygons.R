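test_that("midpoint splitting partitions the box exactly", {
  box <- tibble::tibble(box_id = "b", x0 = 0L, x1 = 30L, y0 = 0L, y1 = 4L)
  cen <- tibble::tibble(col = c(5L, 15L, 25L), row = c(2L, 2L, 2L))
  out <- split_row_polygon(box, cen, axis = "x")
  expect_equal(out$x0, c(0, 10, 20))
  expect_equal(out$x1, c(10, 20, 30))
  expect_equal(out$y0, rep(0, 3))
  expect_equal(out$y1, rep(4, 3))
  # single centre gets the whole box
  one <- split_row_polygon(box, cen[2, ], axis = "x")
  expect_equal(c(one$x0, one$x1), c(0, 30))
})

test_that("32 equally spaced centres give 32 equal polygons containing them", {
  box <- tibble::tibble(box_id = "b", x0 = 0L, x1 = 10L, y0 = 0L, y1 = 416L)
  cen <- tibble::tibble(col = rep(5L, 32), row = seq(6L, by = 13L,
                                                     length.out = 32))
  out <- split_row_polygon(box, cen)
  expect_equal(nrow(out), 32)
  expect_true(all(out$y1 - out$y0 == 13))
  expect_true(all(out$row >= out$y0 & out$row < out$y1))
})

test_that("partition conservation holds for random boxes and centres", {
  set.seed(55)
  for (i in 1:50) {
    box <- tibble::tibble(box_id = "b", x0 = 0L, x1 = sample(5:20, 1),
                          y0 = 0L, y1 = sample(30:200, 1))
    k <- sample(1:20, 1)
    cen <- tibble::tibble(col = sample(0:(box$x1 - 1), k, replace = TRUE),
                          row = sort(sample(0:(box$y1 - 1), k)))
    out <- split_row_polygon(box, cen)
    # areas sum exactly to the box area
    expect_equal(sum((out$x1 - out$x0) * (out$y1 - out$y0)),
                 (box$x1 - box$x0) * (box$y1 - box$y0))
    # contiguous, ordered, each polygon contains its centre
    expect_equal(out$y0[-1], out$y1[-nrow(out)])
    expect_true(all(out$row >= out$y0 & out$row < out$y1))
  }
})

test_that("centres outside all boxes are discarded and edits are applied", {
  boxes <- tibble::tibble(box_id = c("A", "B"), block = 1L,
                          row_in_block = 1:2,
                          x0 = c(0L, 20L), x1 = c(10L, 30L),
                          y0 = 0L, y1 = 50L)
  cands <- tibble::tibble(col = c(5L, 15L, 25L), row = c(10L, 10L, 10L),
                          score = c(0.9, 0.8, 0.7))
  kept <- suppressMessages(filter_and_qc(cands, boxes, image_dim = c(60, 40)))
  expect_equal(nrow(kept), 2)       # alley candidate dropped
  expect_setequal(kept$box_id, c("A", "B"))
  # add a manual centre; remove a matched one
  edits <- tibble::tibble(action = c("add", "remove"),
                          col = c(7L, 25L), row = c(30L, 11L))
  kept2 <- suppressMessages(filter_and_qc(cands, boxes, edits = edits,
                                          image_dim = c(60, 40)))
  expect_equal(nrow(kept2), 2)
  expect_true(any(kept2$provenance == "manual-add"))
  expect_false(any(kept2$col == 25))
  # edit outside the image errors mentioning the offending row
  bad <- tibble::tibble(action = "add", col = 999L, row = 1L)
  expect_error(filter_and_qc(cands, boxes, edits = bad,
                             image_dim = c(60, 40)), "outside the image")
  # remove with no match warns
  nm <- tibble::tibble(action = "remove", col = 0L, row = 49L)
  expect_warning(suppressMessages(filter_and_qc(cands, boxes, edits = nm,
                                                image_dim = c(60, 40))),
                 "matches no detection")
})

test_that("plant IDs encode block, plot, row and position; empty boxes flag", {
  fx <- tiny_fix()
  lay <- fx$layout
  polys <- fx$polys
  expect_equal(nrow(polys),
               lay$n_entries * lay$n_reps * lay$rows_per_plot *
                 lay$plants_per_row)
  expect_true(all(table(polys$box_id) == lay$plants_per_row))
  expect_true(all(grepl("^B\\d{2}-P\\d{2}-R\\d-N\\d{2}$", polys$plant_id)))
  expect_false(anyDuplicated(polys$plant_id) > 0)
  # detected IDs coincide with ground-truth IDs (same naming convention)
  expect_setequal(polys$plant_id, fx$truth$plants$plant_id)
  # a box with no centres yields no polygons and is flagged
  boxes <- fx$boxes[1:2, ]
  cen <- fx$kept[fx$kept$box_id == boxes$box_id[1], ]
  out <- suppressMessages(split_row_polygons(boxes, cen, 3))
  expect_equal(attr(out, "empty_boxes"), boxes$box_id[2])
})
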