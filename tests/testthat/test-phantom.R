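test_that("identical specs render bit-identical phantoms", {
  s <- phantom_spec(rng_seed = 5)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
})

test_that("unrotated noise-free phantom has an axis-aligned exposed field", {
  ph <- generate_phantom(phantom_spec(box_angle = 0, noise_sigma = 0,
                                      blur_sigma = 0, texture_sigma = 0,
                                      rng_seed = 1))
  cropped <- crop_to_content(ph$image)
  off <- attr(cropped, "offset")
  expect_identical(off[["row"]] + 1L, ph$truth$box_rows[1])
  expect_identical(off[["col"]] + 1L, ph$truth$box_cols[1])
  expect_identical(nrow(cropped), diff(ph$truth$box_rows) + 1L)
  # every boundary row/column of the crop carries exposure
  expect_true(all(cropped[1, ] > 0) && all(cropped[nrow(cropped), ] > 0))
})

test_that("PCA recovers the generated box angle", {
  for (ang in c(-30, 15)) {
    ph <- generate_phantom(phantom_spec(box_angle = ang, rng_seed = 2))
    ori <- align_image(ph$image)$orientation
    expect_lt(abs(ori$rotation - (-ang)), 2)
  }
})

test_that("ground-truth edges form 4 lines long enough for the path filter", {
  ph <- generate_phantom(phantom_spec(rng_seed = 3))
  ed <- ph$truth$edges
  expect_setequal(unique(ed$line), 1:4)
  # the ROI never exceeds the exposed field, so spanning over 60% of the
  # field height guarantees passing the 60% path-length filter
  field_h <- diff(ph$truth$box_rows) + 1L
  for (i in 1:4) {
    g <- ed[ed$line == i, ]
    expect_gt(diff(range(g$row)), 0.6 * field_h)
    expect_identical(g$row, seq(min(g$row), max(g$row)))
  }
})

test_that("fracture-free edges deviate < 3 px from their own cubic fit", {
  ph <- generate_phantom(phantom_spec(rng_seed = 4))
  for (i in 1:4) {
    g <- ph$truth$edges[ph$truth$edges$line == i, ]
    fit <- lm(col ~ row + I(row^2) + I(row^3), data = g)
    expect_lt(max(abs(residuals(fit))), 3)
  }
})

test_that("fracture kinds perturb the stated bone only, below the stated row", {
  base <- generate_phantom(phantom_spec(rng_seed = 6))
  step <- generate_phantom(phantom_spec(
    rng_seed = 6, fracture = fracture_truth(1, "step", 8, 0.55)))
  gb <- base$truth$edges
  gs <- step$truth$edges
  frow <- step$truth$fracture$row
  expect_equal(gs[gs$bone == 0, ], gb[gb$bone == 0, ], ignore_attr = TRUE)
  moved <- merge(gs[gs$bone == 1, ], gb[gb$bone == 1, ],
                 by = c("row", "line", "bone"))
  expect_true(all(moved$col.x[moved$row < frow] == moved$col.y[moved$row < frow]))
  expect_true(all(abs(abs(moved$col.x[moved$row > frow] -
                            moved$col.y[moved$row > frow]) - 8) < 1e-9))

  gap <- generate_phantom(phantom_spec(
    rng_seed = 6, fracture = fracture_truth(0, "gap", 6, 0.5)))
  gg <- gap$truth$edges
  expect_lt(nrow(gg[gg$bone == 0, ]), nrow(gb[gb$bone == 0, ]))
  expect_equal(gg[gg$bone == 1, ], gb[gb$bone == 1, ], ignore_attr = TRUE)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(bone_intensity = 90, tissue_intensity = 100),
               "bone > tissue > box")
  expect_error(phantom_spec(tissue_half_width = 80),
               "inside the tissue/box region")
  expect_error(phantom_spec(fracture = fracture_truth(1, "step", 20)),
               "magnitude too large")
  expect_error(fracture_truth(1, "step", 6, row_frac = 0.1), "top 20%")
  expect_error(fracture_truth(2, "step"), "bone_index")
})

test_that("batch generation is reproducible and writes sidecars", {
  out <- withr::local_tempdir()
  a <- generate_phantom_batch(3, seed = 9, fracture_rate = 0.5, out_dir = out)
  b <- generate_phantom_batch(3, seed = 9, fracture_rate = 0.5)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  expect_length(list.files(out, "\\.png$"), 3L)
  js <- jsonlite::read_json(file.path(out, "phantom_001.json"))
  expect_true(is.numeric(js$bone_end_row) || is.integer(js$bone_end_row))
})
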