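test_that("confidence filtering is strictly greater-than the threshold", {
  fr <- test_frame(list(
    square_cell("a", "CD4T", 2, 2, 5, confidence = 0.29, source = "predicted"),
    square_cell("b", "CD4T", 12, 2, 5, confidence = 0.30, source = "predicted"),
    square_cell("c", "CD4T", 22, 2, 5, confidence = 0.31, source = "predicted")
  ))
  kept <- filter_confidence(fr, 0.3)
  expect_length(kept$instances, 1)
  expect_identical(kept$instances[[1]]$id, "c")

  expect_length(filter_confidence(test_frame(), 0.3)$instances, 0)

  manual <- test_frame(list(square_cell("m", "CD4T", 2, 2, 5)))
  expect_identical(filter_confidence(manual, 0.3), manual)

  expect_error(filter_confidence(fr, 1.5), "\\[0, 1\\]")
})

test_that("matching honours the IOU threshold and class agreement", {
  t10 <- function(id, cls, x0) square_cell(id, cls, x0, 0, 10)
  p10 <- function(id, cls, x0) square_cell(id, cls, x0, 0, 10,
                                           confidence = 0.9,
                                           source = "predicted")
  # identical squares: one pair, no errors
  ms <- match_instances(test_frame(list(t10("t", "CD4T", 0))),
                        test_frame(list(p10("p", "CD4T", 0))))
  expect_equal(nrow(ms$pairs), 1)
  expect_equal(ms$pairs$iou, 1)
  expect_equal(nrow(ms$unmatched_truth), 0)
  expect_equal(nrow(ms$unmatched_pred), 0)

  # overlap exactly at threshold 40/160 = 0.25 -> matched ("at least")
  ms <- match_instances(test_frame(list(t10("t", "CD4T", 0))),
                        test_frame(list(p10("p", "CD4T", 6))))
  expect_equal(ms$pairs$iou, 0.25)

  # below threshold: 30/170 < 0.25 -> one FN plus one FP
  ms <- match_instances(test_frame(list(t10("t", "CD4T", 0))),
                        test_frame(list(p10("p", "CD4T", 7))))
  expect_equal(nrow(ms$pairs), 0)
  expect_equal(nrow(ms$unmatched_truth), 1)
  expect_equal(nrow(ms$unmatched_pred), 1)

  # high overlap but different class never pairs
  ms <- match_instances(test_frame(list(t10("t", "mDC", 0))),
                        test_frame(list(p10("p", "CD4T", 1))))
  expect_equal(nrow(ms$pairs), 0)

  # two predictions over one truth: the higher IOU wins, the other is FP
  ms <- match_instances(
    test_frame(list(t10("t", "CD4T", 0))),
    test_frame(list(p10("pA", "CD4T", 2), p10("pB", "CD4T", 4))))
  expect_equal(nrow(ms$pairs), 1)
  expect_identical(ms$pairs$pred_id, "pA")
  expect_identical(ms$unmatched_pred$id, "pB")

  # assignment is globally optimal, not greedy: pairing the best-IOU edge
  # first would strand a prediction
  truth <- test_frame(list(t10("t1", "CD4T", 0), t10("t2", "CD4T", 6)))
  pred <- test_frame(list(p10("p1", "CD4T", 3), p10("p2", "CD4T", 1)))
  ms <- match_instances(truth, pred)
  expect_equal(nrow(ms$pairs), 2)

  expect_error(
    match_instances(test_frame(side = 64), test_frame(side = 32)),
    "dimension mismatch")
})

test_that("matched pair count equals brute-force enumeration", {
  set.seed(301)
  for (trial in 1:120) {
    fp <- random_frame_pair()
    ms <- match_instances(fp$truth, fp$pred, theta = 0.25)
    oracle <- brute_force_match(frame_iou_matrix(fp$truth, fp$pred), 0.25)
    expect_identical(nrow(ms$pairs), oracle$count)
    if (oracle$count > 0) {
      expect_equal(sum(ms$pairs$iou), oracle$total, tolerance = 1e-9)
    }
  }
})

test_that("class metrics pool counts before forming ratios", {
  mk_ms <- function(pairs, fn_cls = character(0), fp_cls = character(0)) {
    lab <- function(p, cls) {
      if (length(cls)) paste0(p, seq_along(cls)) else character(0)
    }
    structure(list(
      frame_id = "f", pairs = pairs,
      unmatched_truth = data.frame(id = lab("fn", fn_cls),
                                   cell_class = fn_cls,
                                   stringsAsFactors = FALSE),
      unmatched_pred = data.frame(id = lab("fp", fp_cls),
                                  cell_class = fp_cls,
                                  stringsAsFactors = FALSE),
      theta = 0.25), class = "match_set")
  }
  pairs9 <- data.frame(truth_id = paste0("t", 1:9), pred_id = paste0("p", 1:9),
                       cell_class = "CD4T", iou = seq(0.5, 0.9, length.out = 9),
                       stringsAsFactors = FALSE)
  cm <- class_metrics(list(mk_ms(pairs9, fp_cls = "CD4T")))
  expect_equal(cm$tp, 9); expect_equal(cm$fp, 1)
  expect_equal(cm$specificity, 0.9)
  expect_equal(cm$sensitivity, 1)

  # perfect class: every truth matched, no false positives
  cm <- class_metrics(list(mk_ms(pairs9)))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)

  # no predictions at all for a class with truth cells
  cm <- class_metrics(list(mk_ms(pairs9[0, ], fn_cls = rep("mDC", 10))))
  expect_equal(cm$sensitivity, 0)
  expect_equal(cm$fp, 0)
  expect_true(is.na(cm$specificity))  # no predictions to be right about

  # class absent everywhere is flagged, not silently zero
  cm <- class_metrics(list(mk_ms(pairs9)), classes = c("CD4T", "Bcell"))
  expect_false(cm$defined[cm$cell_class == "Bcell"])
  expect_true(is.na(cm$sensitivity[cm$cell_class == "Bcell"]))
})

test_that("overall metrics weight by cell counts and report class means", {
  pc <- data.frame(
    cell_class = c("CD4T", "mDC"),
    n_truth = c(10, 90), n_pred = c(10, 90),
    tp = c(10, 72), fp = c(0, 18), fn = c(0, 18),
    sensitivity = c(1.0, 0.8), specificity = c(1.0, 0.8),
    iou_mean = c(0.9, 0.7), iou_sd = c(0.1, 0.1),
    defined = TRUE, stringsAsFactors = FALSE)
  class(pc) <- c("class_metrics", "data.frame")
  ov <- overall_metrics(pc)
  expect_equal(ov$overall$sensitivity[ov$overall$averaging == "cell_weighted"],
               0.82)
  expect_equal(ov$overall$sensitivity[ov$overall$averaging == "class_mean"],
               0.90)

  # equal class sizes: the two conventions coincide
  pc$n_truth <- pc$n_pred <- c(50, 50); pc$tp <- c(50, 40)
  ov <- overall_metrics(pc)
  expect_equal(ov$overall$sensitivity[1], ov$overall$sensitivity[2])

  # single class: overall equals that class
  ov1 <- overall_metrics(pc[1, ])
  expect_true(all(ov1$overall$sensitivity == pc$sensitivity[1]))

  pc$defined <- FALSE
  expect_error(overall_metrics(pc), "no class")
})

test_that("counts are conserved and thresholds act monotonically", {
  set.seed(77)
  for (trial in 1:15) {
    fp <- random_frame_pair(max_cells = 6)
    thetas <- c(0.1, 0.25, 0.5, 0.8)
    last_tp <- Inf
    for (th in thetas) {
      ms <- match_instances(fp$truth, fp$pred, theta = th)
      cm <- class_metrics(list(ms))
      expect_equal(cm$tp + cm$fn, cm$n_truth)
      expect_equal(cm$tp + cm$fp, cm$n_pred)
      expect_equal(sum(cm$n_truth), length(fp$truth$instances))
      expect_equal(sum(cm$n_pred), length(fp$pred$instances))
      expect_lte(nrow(ms$pairs), last_tp)
      last_tp <- nrow(ms$pairs)
    }
  }
  # raising tau never increases the retained prediction count
  fr <- test_frame(lapply(1:8, function(k) {
    square_cell(paste0("p", k), "CD4T", 5 * k, 2, 4,
                confidence = k / 10, source = "predicted")
  }))
  n_prev <- Inf
  for (tau in c(0.1, 0.3, 0.5, 0.9)) {
    n <- length(filter_confidence(fr, tau)$instances)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("cross_evaluate runs the full protocol and checks alignment", {
  truth <- generate_truth(small_tissue_config(n_frames = 3, seed = 31))
  pred <- degrade(truth, degradation_config(
    panel_classes("panel2"), detect_prob = 1, fp_rate = 0, jitter = 0,
    confidence_correct = c(50, 1), seed = 2))
  ev <- cross_evaluate(truth, pred)
  expect_s3_class(ev, "eval_summary")
  expect_equal(ev$overall$sensitivity[1], 1)
  expect_equal(ev$overall$specificity[1], 1)
  expect_equal(ev$overall$iou_mean[1], 1)
  expect_equal(ev$tau, 0.3)
  expect_equal(ev$theta, 0.25)
  expect_match(ev$specificity_definition, "positive predictive value")

  other <- pred
  other$frames[[1]]$frame_id <- "elsewhere"
  expect_error(cross_evaluate(truth, other), "frame ids do not align")
})
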