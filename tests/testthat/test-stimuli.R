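# glyph rendering and stimulus-set construction

test_that("glyph rendering is deterministic, bounded and style-sensitive", {
  a1 <- render_glyph("A", "hf1", "normal")
  a2 <- render_glyph("A", "hf1", "normal")
  expect_identical(a1$pixels, a2$pixels)

  expect_true(all(a1$pixels >= 0 & a1$pixels <= 1))
  expect_length(a1$vector, 900L)
  expect_identical(a1$vector, as.vector(t(a1$pixels)))  # row-major flattening
  expect_gt(sum(a1$pixels), 0)
  expect_equal(dim(a1$pixels), c(30L, 30L))

  bold <- render_glyph("A", "hf1", "bold")
  italic <- render_glyph("A", "hf1", "italic")
  expect_false(identical(a1$pixels, bold$pixels))
  expect_false(identical(a1$pixels, italic$pixels))
  # fonts are distinct typefaces, not reparameterisations of one bitmap
  expect_false(identical(a1$pixels, render_glyph("A", "hf2")$pixels))

  expect_error(render_glyph("A", "nosuchfont"), "nosuchfont")
  expect_error(render_glyph("a", "hf1"), "A-Z")
})

test_that("the font registry provides 9 + 2 + 4 disjoint roles", {
  reg <- font_registry()
  expect_equal(sum(reg$role == "train_he"), 9L)
  expect_equal(sum(reg$role == "train_le"), 2L)
  expect_equal(sum(reg$role == "test"), 4L)
  expect_false(any(duplicated(reg$font_id)))
})

test_that("TC-HE holds 27 versions of each letter, 702 images", {
  he <- build_training_set("TC-HE")
  expect_equal(nrow(he$x), 702L)
  expect_equal(as.integer(table(he$meta$letter)), rep(27L, 26L))
  expect_equal(length(unique(he$meta$font_id)), 9L)
  expect_setequal(unique(he$meta$style), c("normal", "italic", "bold"))
})

test_that("TC-LE has 52 unique images and cycles up to the TC-HE size", {
  le_u <- build_training_set("TC-LE", replicate_le = FALSE)
  expect_equal(nrow(le_u$x), 52L)
  expect_equal(as.integer(table(le_u$meta$letter)), rep(2L, 26L))
  expect_true(all(le_u$meta$style == "normal"))

  le <- build_training_set("TC-LE")
  expect_equal(nrow(le$x), 702L)
  # cyclic fill: 13 full passes over the 52 uniques, then the first 26 again
  expect_identical(le$x[677:702, ], le$x[1:26, ])
  expect_identical(le$meta[53:104, ], le$meta[1:52, ], ignore_attr = TRUE)
  expect_equal(nrow(unique(le$meta)), 52L)
})

test_that("the test set is 312 contrast-halved images from held-out fonts", {
  test <- build_test_set()
  expect_equal(nrow(test$x), 312L)
  expect_equal(as.integer(table(test$meta$letter)), rep(12L, 26L))
  expect_lte(max(test$x), 0.5)
  expect_false(any(test$meta$font_id %in%
                     build_training_set("TC-HE")$meta$font_id))
  # halving is exactly pixelwise: rebuild one glyph at full contrast
  full <- render_glyph(test$meta$letter[1], test$meta$font_id[1],
                       test$meta$style[1])
  expect_equal(test$x[1, ], full$vector / 2)
})

test_that("reduce_contrast divides pixels and composes multiplicatively", {
  ones <- make_image(blank30(1))
  expect_equal(reduce_contrast(ones, 2)$pixels, blank30(0.5))
  zero <- make_image(blank30(0))
  expect_equal(reduce_contrast(zero, 7)$pixels, blank30(0))
  img <- render_glyph("Q", "hf1")
  expect_equal(reduce_contrast(img, 1)$pixels, img$pixels)
  twice_sqrt2 <- reduce_contrast(reduce_contrast(img, sqrt(2)), sqrt(2))
  expect_equal(twice_sqrt2$pixels, reduce_contrast(img, 2)$pixels,
               tolerance = 1e-12)
  expect_equal(twice_sqrt2$vector, reduce_contrast(img, 2)$vector,
               tolerance = 1e-12)
  expect_error(reduce_contrast(img, 0), "positive")
  expect_error(reduce_contrast(img, -1), "positive")
})

test_that("active_pixel_count counts luminosities above threshold", {
  expect_equal(active_pixel_count(make_image(blank30(0))), 0L)
  one <- blank30(0); one[15, 15] <- 1
  expect_equal(active_pixel_count(make_image(one)), 1L)
  blk <- blank30(0); blk[10:12, 20:22] <- 1
  expect_equal(active_pixel_count(make_image(blk)), 9L)
  # faint anti-aliasing at 0.5 or below is not active
  faint <- blank30(0.5)
  expect_equal(active_pixel_count(make_image(faint)), 0L)
})

test_that("perimetric complexity equals area over exposed-edge perimeter", {
  one <- blank30(0); one[4, 7] <- 1
  expect_equal(perimetric_complexity(make_image(one)), 1 / 4)

  sq <- blank30(0); sq[11:20, 11:20] <- 1
  expect_equal(perimetric_complexity(make_image(sq)), 100 / 40)
  expect_equal(perimetric_complexity(make_image(sq), pelli = TRUE),
               40^2 / 100)

  expect_error(perimetric_complexity(make_image(blank30(0))), "empty")

  # random masks against the brute-force edge counter
  set.seed(71)
  for (i in 1:5) {
    m <- matrix(stats::runif(900) < 0.3, 30, 30)
    if (!any(m)) next
    expect_equal(perimetric_complexity(make_image(m * 1)),
                 sum(m) / brute_perimeter(m))
  }
})

test_that("entropy profile matches the covariance eigendecomposition", {
  set.seed(5)
  imgs <- lapply(1:3, function(i) make_image(matrix(stats::runif(900), 30)))
  set <- harmonium:::.new_stimulus_set("TEST", imgs)
  prof <- entropy_profile(set)
  ev <- eigen(stats::cov(set$x), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(prof$explained[seq_along(ev)], ev / sum(ev), tolerance = 1e-8)
  expect_true(all(diff(prof$cumulative) >= -1e-12))
  expect_equal(prof$cumulative[length(prof$cumulative)], 1, tolerance = 1e-9)
})

test_that("identical images give a degenerate single-component profile", {
  imgs <- rep(list(render_glyph("B", "hf1")), 4)
  set <- harmonium:::.new_stimulus_set("TEST", imgs)
  expect_warning(prof <- entropy_profile(set), "identical")
  expect_equal(prof$explained, 1)
})

test_that("the high-entropy set needs more components than the low-entropy set", {
  k_he <- components_to_reach(entropy_profile(build_training_set("TC-HE")))
  k_le <- components_to_reach(entropy_profile(build_training_set("TC-LE")))
  expect_gte(k_he, k_le)
})
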