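test_that("rasterize sets exactly the pixels whose centers fall inside", {
  fr <- image_frame("f1", 1024, 1024, 0.1058, "FFPE", "panel2")
  sq <- square_cell("sq", "CD4T", 0, 0, side = 10)
  m <- rasterize(sq, fr)
  expect_identical(dim(m), c(1024L, 1024L))
  expect_equal(sum(m), 100)
  expect_true(all(m[1:10, 1:10]))

  full <- cell_instance("full", "CD4T", rect_outline(0, 0, 16, 16))
  fr16 <- test_frame(side = 16)
  expect_true(all(rasterize(full, fr16)))

  degen <- structure(list(id = "d", cell_class = "CD4T",
                          outline = cbind(c(0, 5), c(0, 5)),
                          confidence = 1, source = "manual"),
                     class = "cell_instance")
  expect_error(rasterize(degen, fr16), "degenerate")
})

test_that("rasterization agrees with an independent point-in-polygon test", {
  skip_if_not_installed("pracma")
  set.seed(71)
  fr <- test_frame(side = 48)
  for (k in 1:25) {
    o <- star_outline(runif(1, 14, 34), runif(1, 14, 34), 3, 12,
                      nv = sample(5:20, 1))
    inst <- cell_instance("s", "CD4T", o)
    m <- rasterize(inst, fr)
    jj <- rep(0:47, each = 48); ii <- rep(0:47, times = 48)
    ref <- pracma::inpolygon(jj + 0.5, ii + 0.5, o[, 1], o[, 2],
                             boundary = FALSE)
    got <- m[cbind(ii + 1, jj + 1)]
    expect_equal(got, as.logical(ref))
  }
})

test_that("iou matches hand-counted examples and flags misuse", {
  fr <- test_frame(side = 16)
  a <- rasterize(square_cell("a", "CD4T", 2, 2, 4), fr)
  expect_equal(iou(a, a), 1)
  b <- rasterize(square_cell("b", "CD4T", 10, 10, 4), fr)
  expect_equal(iou(a, b), 0)
  # two 2x2 squares overlapping on a 2x1 strip: 2 / (4 + 4 - 2)
  p <- rasterize(square_cell("p", "CD4T", 0, 0, 2), fr)
  q <- rasterize(square_cell("q", "CD4T", 1, 0, 2), fr)
  expect_equal(iou(p, q), 2 / 6)
  expect_error(iou(a, matrix(FALSE, 8, 8)), "16x16.*8x8")
  expect_warning(v <- iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), "empty")
  expect_equal(v, 0)
})

test_that("iou is symmetric, bounded, and translation invariant", {
  set.seed(5)
  fr <- test_frame(side = 64)
  for (k in 1:20) {
    o1 <- star_outline(runif(1, 18, 30), runif(1, 18, 30), 4, 10)
    o2 <- star_outline(runif(1, 18, 30), runif(1, 18, 30), 4, 10)
    m1 <- rasterize(cell_instance("a", "CD4T", o1), fr)
    m2 <- rasterize(cell_instance("b", "CD4T", o2), fr)
    v <- iou(m1, m2)
    expect_identical(v, iou(m2, m1))
    expect_gte(v, 0); expect_lte(v, 1)
    # frame-wide translation of both masks by the same integer offset
    t1 <- rasterize(cell_instance("a", "CD4T", sweep(o1, 2, c(17, 12), "+")), fr)
    t2 <- rasterize(cell_instance("b", "CD4T", sweep(o2, 2, c(17, 12), "+")), fr)
    expect_equal(iou(t1, t2), v)
  }
  m <- rasterize(cell_instance("a", "CD4T", star_outline(30, 30, 4, 10)), fr)
  expect_equal(iou(m, m), 1)
})

test_that("label-map export round-trips disjoint frames", {
  fr <- test_frame(list(
    square_cell("a", "CD4T", 2, 2, 6),
    square_cell("b", "mDC", 20, 2, 8),
    square_cell("c", "pDC", 40, 30, 5, confidence = 0.8, source = "predicted")
  ), side = 64)
  lm <- to_label_map(fr)
  expect_setequal(unique(as.vector(lm$labels)), c(0L, 1L, 2L, 3L))
  expect_equal(sum(lm$labels == 1L), 36)
  expect_equal(sum(lm$labels == 2L), 64)
  expect_equal(sum(lm$labels == 3L), 25)
  expect_equal(lm$sidecar$cell_class, c("CD4T", "mDC", "pDC"))

  back <- polygonize(lm$labels, lm$sidecar, "rt", 1, "FFPE", "panel2")
  expect_length(back$instances, 3)
  for (k in 1:3) {
    orig <- sort(immunoseg:::instance_pixels(fr$instances[[k]], fr))
    got <- sort(immunoseg:::instance_pixels(back$instances[[k]], back))
    expect_identical(got, orig)
    expect_identical(back$instances[[k]]$cell_class,
                     fr$instances[[k]]$cell_class)
    expect_identical(back$instances[[k]]$confidence,
                     fr$instances[[k]]$confidence)
  }

  empty <- to_label_map(test_frame())
  expect_true(all(empty$labels == 0L))
  expect_equal(nrow(empty$sidecar), 0)
})

test_that("overlap handling: strict errors, precedence favours confidence", {
  fr <- test_frame(list(
    square_cell("low", "CD4T", 2, 2, 6, confidence = 0.5, source = "predicted"),
    square_cell("high", "CD4T", 5, 2, 6, confidence = 0.9, source = "predicted")
  ), side = 32)
  expect_error(to_label_map(fr, mode = "strict"), "low|high")
  lm <- to_label_map(fr, mode = "precedence")
  # contested 3x6 strip belongs to the higher-confidence instance (label 2)
  expect_equal(sum(lm$labels == 2L), 36)
  expect_equal(sum(lm$labels == 1L), 18)
})

test_that("polygonize validates inputs", {
  z <- matrix(0L, 8, 8)
  empty <- polygonize(z, data.frame(label = integer(0),
                                    cell_class = character(0),
                                    confidence = numeric(0)),
                      "e", 1, "FFPE", "panel2")
  expect_length(empty$instances, 0)

  z[3:5, 3:5] <- 5L
  expect_error(
    polygonize(z, data.frame(label = 1L, cell_class = "CD4T",
                             confidence = 1), "m", 1, "FFPE", "panel2"),
    "5")
  fr <- polygonize(z, data.frame(label = 5L, cell_class = "CD4T",
                                 confidence = 1), "ok", 1, "FFPE", "panel2")
  expect_length(fr$instances, 1)
  expect_equal(length(immunoseg:::instance_pixels(fr$instances[[1]], fr)), 9)

  # a label split into two disconnected islands has no single outline
  z2 <- matrix(0L, 8, 8)
  z2[2:3, 2:3] <- 1L; z2[6:7, 6:7] <- 1L
  expect_error(
    polygonize(z2, data.frame(label = 1L, cell_class = "CD4T",
                              confidence = 1), "d", 1, "FFPE", "panel2"),
    "connected")

  # diagonally pinched labels remain one weakly simple outline
  z3 <- matrix(0L, 8, 8)
  z3[2:3, 2:3] <- 1L; z3[4:5, 4:5] <- 1L
  fr3 <- polygonize(z3, data.frame(label = 1L, cell_class = "CD4T",
                                   confidence = 1), "p", 1, "FFPE", "panel2")
  expect_identical(sort(immunoseg:::instance_pixels(fr3$instances[[1]], fr3)),
                   sort(which(z3 == 1L)))
})

test_that("polygonize/rasterize round-trip reproduces pixel sets exactly", {
  set.seed(99)
  for (trial in 1:15) {
    # non-overlapping by construction: one star per 24x24 tile
    insts <- list()
    for (gx in 0:1) for (gy in 0:1) {
      # smooth blob: evenly spaced angles, mild radial variation, so the
      # raster is connected and round-trippable as a single outline
      th <- seq(0, 2 * pi, length.out = 21)[-21]
      r <- runif(20, 6.5, 9)
      insts[[length(insts) + 1L]] <- cell_instance(
        sprintf("g%d%d", gx, gy), sample(cell_classes(), 1),
        cbind(x = 24 * gx + 12 + r * cos(th), y = 24 * gy + 12 + r * sin(th)),
        confidence = round(runif(1, 0.4, 1), 3), source = "predicted")
    }
    fr <- test_frame(insts, side = 48)
    lm <- to_label_map(fr, mode = "strict")
    back <- polygonize(lm$labels, lm$sidecar, fr$frame_id, 1, fr$fixation,
                       fr$panel)
    expect_length(back$instances, length(insts))
    for (k in seq_along(insts)) {
      expect_identical(
        sort(immunoseg:::instance_pixels(back$instances[[k]], back)),
        sort(which(lm$labels == k)))
      expect_identical(back$instances[[k]]$confidence, insts[[k]]$confidence)
    }
    # idempotence at the raster level: a second round-trip is a fixed point
    lm2 <- to_label_map(back, mode = "strict")
    expect_identical(lm2$labels, lm$labels)
  }
})

test_that("validation enforces the instance and cohort invariants", {
  fr <- test_frame(list(square_cell("a", "CD4T", 2, 2, 5)))
  expect_true(validate_frame(fr))

  bad <- fr
  bad$instances[[1]]$outline <- rect_outline(-3, 2, 5, 9)
  expect_error(validate_frame(bad), "bounds")

  bowtie <- cell_instance("x", "CD4T",
                          cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)))
  expect_error(validate_instance(bowtie), "self-intersecting")

  manual_low <- structure(list(id = "m", cell_class = "CD4T",
                               outline = rect_outline(1, 1, 4, 4),
                               confidence = 0.5, source = "manual"),
                          class = "cell_instance")
  expect_error(validate_instance(manual_low), "confidence 1")

  mixed <- cohort_dataset("mix", list(
    test_frame(frame_id = "a", ps = 1),
    test_frame(frame_id = "b", ps = 2)), role = "truth")
  expect_error(validate_cohort(mixed), "pixel size")
})
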