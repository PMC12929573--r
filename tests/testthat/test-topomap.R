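test_that("montage projection is symmetric, in-disk and validated", {
  lay <- project_montage()
  expect_equal(nrow(lay), 16)
  expect_true(all(lay$x^2 + lay$y^2 < 1))
  expect_equal(nrow(unique(lay[, c("x", "y")])), 16)
  pairs <- list(c("FP1", "FP2"), c("F3", "F4"), c("C3", "C4"),
                c("P3", "P4"), c("O1", "O2"), c("F7", "F8"),
                c("T3", "T4"), c("T5", "T6"))
  for (p in pairs) {
    l <- lay[lay$label == p[1], ]; r <- lay[lay$label == p[2], ]
    expect_identical(l$y, r$y)
    expect_identical(l$x, -r$x)
  }
  expect_error(project_montage(c("FP1", "XX")), "unknown")
})

test_that("rendering is exact at electrodes and pure", {
  # uniform frame -> constant color inside the disk
  uni <- structure(stats::setNames(rep(0.7, 16), doc_montage()),
                   class = "apen_frame")
  img <- render_topomap(uni)
  inside <- img[, , 1] != 1 | img[, , 2] != 1 | img[, , 3] != 1
  for (ch in 1:3)
    expect_equal(length(unique(img[, , ch][inside])), 1)

  # decoded electrode pixels match input values within one colormap step
  q <- 1.2 / 255
  for (s in 1:20) {
    f <- random_frame(s)
    im <- render_topomap(f)
    for (ch in c("FP1", "C3", "O2", "T6"))
      expect_lt(abs(decode_electrode_value(im, ch) - f[[ch]]), q)
  }

  # purity: identical frame and config give bit-identical rasters
  f <- random_frame(99)
  expect_identical(render_topomap(f), render_topomap(f))

  # out-of-scale values clip with a warning
  hotf <- structure(stats::setNames(c(5, rep(0.5, 15)), doc_montage()),
                    class = "apen_frame")
  expect_warning(render_topomap(hotf), "clipped")
})

test_that("a single hot electrode decays monotonically along a ray (IDW)", {
  f <- structure(stats::setNames(c(rep(0.2, 4), 1.0, rep(0.2, 11)),
                                 doc_montage()), class = "apen_frame")
  # hot electrode is C3 at (-0.5, 0); walk toward the left disk edge
  lay <- project_montage()
  op_size <- c(256, 256)
  img <- render_topomap(f, size = op_size, method = "idw",
                        scale = c(0, 1.2))
  h <- op_size[1]; w <- op_size[2]
  R <- min(h, w) / 2 - 1; cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- seq(-0.5, -0.98, length.out = 24)
  vals <- vapply(xs, function(x) {
    r <- round(cy); c_ <- round(x * R + cx)
    idx <- which.min(colSums((t(apen_colormap()) - img[r, c_, ])^2))
    idx
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_equal(which.max(vals), 1L)
})

test_that("tiling builds the 4 x 5 grid on a 512-pixel canvas", {
  f <- random_frame(3)
  map <- render_topomap(f)
  tiled <- tile_images(rep(list(map), 20))
  expect_equal(dim(tiled), c(512L, 512L, 3L))
  # cell (2, 3): rows 129..256, cols 1 + 2*102 + (1:102)
  expect_identical(tiled[129:256, (1 + 204 + 1):(1 + 204 + 102), ], map)
  expect_error(tile_images(rep(list(map), 19)), "exactly 20")
})

test_that("center crop and block downscale behave exactly", {
  arr <- array(withr::with_seed(4, runif(512 * 512 * 3)), c(512, 512, 3))
  cr <- crop_center(arr, 256)
  expect_identical(cr, arr[129:384, 129:384, , drop = FALSE])
  small <- array(runif(256 * 256 * 3), c(256, 256, 3))
  expect_identical(crop_center(small, 256), small)
  red <- array(rep(c(1, 0, 0), each = 300 * 300), c(300, 300, 3))
  cred <- crop_center(red, 256)
  expect_true(all(cred[, , 1] == 1) && all(cred[, , 2] == 0))
  expect_error(crop_center(small, 300), "dimension")

  ds <- downscale_image(cr, 4)
  expect_equal(dim(ds), c(64L, 64L, 3L))
  expect_equal(ds[1, 1, 2], mean(cr[1:4, 1:4, 2]))
})

test_that("patients get 6 images from 120 topographies, with padding rules", {
  mk_frames <- function(n, cond) lapply(seq_len(n), function(i)
    random_frame(i, patient_id = "P9", condition = cond, epoch = i))
  imgs <- images_per_patient(list(resting = mk_frames(60, "resting"),
                                  music = mk_frames(60, "music")))
  expect_length(imgs, 6)
  expect_equal(sum(lengths(lapply(imgs, `[[`, "epochs"))), 120)
  expect_true(all(vapply(imgs, function(im)
    identical(dim(im$raster), c(256L, 256L, 3L)), logical(1))))
  expect_equal(table(vapply(imgs, `[[`, "", "condition")),
               table(rep(c("music", "resting"), each = 3)))

  # one condition only
  solo <- images_per_patient(list(music = mk_frames(60, "music")))
  expect_length(solo, 3)
  expect_true(all(vapply(solo, `[[`, "", "condition") == "music"))

  # 59 frames: pad by repeating the last frame, recorded in provenance
  expect_message(
    padded <- images_per_patient(list(resting = mk_frames(59, "resting"))),
    "padding")
  last_epochs <- padded[[3]]$epochs
  expect_equal(last_epochs[20], 59L)
  expect_equal(last_epochs[19], 59L)  # the repeated frame
  expect_true(padded[[3]]$padded)

  expect_error(images_per_patient(list(resting = mk_frames(19, "resting"))),
               "insufficiency")
})
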