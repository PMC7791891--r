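# Cell-level evaluation: confidence filtering, one-to-one class-matched
# assignment at an IOU threshold, and sensitivity/specificity/IOU metrics.
#
# "Specificity" note: true negatives are undefined for an instance
# detection task, so per-class specificity is operationalized as the
# positive predictive value tp / (tp + fp) over that class's predictions.
# Every metrics object records this definition in its metadata.

#' Filter predicted instances by network confidence
#'
#' Retains instances whose confidence is strictly greater than `tau`
#' (a cell is kept when the confidence is *above* the threshold). Order is
#' preserved. Manual instances carry confidence 1 and always pass.
#'
#' @param frame an [image_frame()]
#' @param tau confidence threshold in \[0, 1\]; default 0.3
#' @return the frame with only retained instances
#' @export
filter_confidence <- function(frame, tau = 0.3) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    stop("confidence threshold tau must lie in [0, 1]", call. = FALSE)
  }
  keep <- vapply(frame$instances, function(z) z$confidence > tau, logical(1))
  frame$instances <- frame$instances[keep]
  frame
}

#' Match predicted to ground-truth instances at an IOU threshold
#'
#' A prediction is admissible for a truth cell only if both have the same
#' class and their raster IOU is at least `theta`. Among all one-to-one
#' assignments over admissible pairs, the maximum-cardinality matching is
#' chosen, with ties broken by maximizing total IOU (solved as a
#' maximum-weight bipartite matching), so the result is order-independent
#' and reproducible. Unmatched truth cells are false negatives; unmatched
#' predictions are false positives.
#'
#' @param truth,pred [image_frame()] objects of identical dimensions;
#'   `pred` should already be confidence-filtered
#' @param theta IOU threshold; default 0.25
#' @return an object of class `match_set`: `pairs` (data.frame truth_id,
#'   pred_id, cell_class, iou), `unmatched_truth`, `unmatched_pred`
#'   (data.frames id, cell_class), `frame_id`, `theta`
#' @export
match_instances <- function(truth, pred, theta = 0.25) {
  if (truth$width_px != pred$width_px || truth$height_px != pred$height_px) {
    stop(sprintf("frame dimension mismatch: %dx%d vs %dx%d",
                 truth$width_px, truth$height_px,
                 pred$width_px, pred$height_px), call. = FALSE)
  }
  t_inst <- truth$instances
  p_inst <- pred$instances
  nt <- length(t_inst); np <- length(p_inst)
  t_class <- vapply(t_inst, function(z) z$cell_class, character(1))
  p_class <- vapply(p_inst, function(z) z$cell_class, character(1))
  t_id <- vapply(t_inst, function(z) as.character(z$id), character(1))
  p_id <- vapply(p_inst, function(z) as.character(z$id), character(1))

  bbox <- function(z) c(range(z$outline[, 1]), range(z$outline[, 2]))
  t_bb <- lapply(t_inst, bbox)
  p_bb <- lapply(p_inst, bbox)
  t_pix <- vector("list", nt)
  p_pix <- vector("list", np)

  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      if (t_class[i] != p_class[j]) next
      a <- t_bb[[i]]; b <- p_bb[[j]]
      if (a[2] < b[1] || b[2] < a[1] || a[4] < b[3] || b[4] < a[3]) next
      if (is.null(t_pix[[i]])) t_pix[[i]] <- instance_pixels(t_inst[[i]], truth)
      if (is.null(p_pix[[j]])) p_pix[[j]] <- instance_pixels(p_inst[[j]], pred)
      v <- iou_sets(t_pix[[i]], p_pix[[j]])
      if (v >= theta) {
        ei <- c(ei, i); ej <- c(ej, j); ew <- c(ew, v)
      }
    }
  }

  pairs <- data.frame(truth_id = character(0), pred_id = character(0),
                      cell_class = character(0), iou = numeric(0),
                      stringsAsFactors = FALSE)
  matched_t <- integer(0); matched_p <- integer(0)
  if (length(ei)) {
    # cardinality dominates: any extra pair outweighs all IOU tie-break mass
    Wbig <- min(nt, np) + 1
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("t", ei), to = paste0("p", ej)),
      directed = FALSE
    )
    igraph::V(g)$type <- grepl("^p", igraph::V(g)$name)
    m <- igraph::max_bipartite_match(g, weights = ew + Wbig)
    mm <- m$matching
    t_names <- paste0("t", ei)
    sel <- !is.na(mm[unique(t_names)])
    tv <- unique(t_names)[sel]
    if (length(tv)) {
      ti <- as.integer(sub("^t", "", tv))
      pj <- as.integer(sub("^p", "", mm[tv]))
      key <- match(paste(ti, pj), paste(ei, ej))
      ord <- order(ti)
      ti <- ti[ord]; pj <- pj[ord]; key <- key[ord]
      pairs <- data.frame(truth_id = t_id[ti], pred_id = p_id[pj],
                          cell_class = t_class[ti], iou = ew[key],
                          stringsAsFactors = FALSE)
      matched_t <- ti; matched_p <- pj
    }
  }
  un_t <- setdiff(seq_len(nt), matched_t)
  un_p <- setdiff(seq_len(np), matched_p)
  structure(
    list(frame_id = truth$frame_id,
         pairs = pairs,
         unmatched_truth = data.frame(id = t_id[un_t],
                                      cell_class = t_class[un_t],
                                      stringsAsFactors = FALSE),
         unmatched_pred = data.frame(id = p_id[un_p],
                                     cell_class = p_class[un_p],
                                     stringsAsFactors = FALSE),
         theta = theta),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set %s> pairs=%d fn=%d fp=%d (theta=%.2f)\n",
              x$frame_id, nrow(x$pairs), nrow(x$unmatched_truth),
              nrow(x$unmatched_pred), x$theta))
  invisible(x)
}

#' Pooled per-class detection metrics from a set of matched frames
#'
#' Counts are pooled over frames before ratios are formed
#' (micro-averaging): sensitivity = tp / (tp + fn), specificity (positive
#' predictive value) = tp / (tp + fp), and per-cell IOU mean and SD over
#' all matched pairs of the class. Classes with no truth or predicted
#' cells report `NA` ratios and are flagged via the `defined` column
#' rather than silently reported as zero.
#'
#' @param matchsets list of [match_instances()] results from disjoint frames
#' @param classes classes to report; defaults to all classes present
#' @return data.frame of class `class_metrics` with one row per class:
#'   cell_class, n_truth, n_pred, tp, fp, fn, sensitivity, specificity,
#'   iou_mean, iou_sd, defined
#' @export
class_metrics <- function(matchsets, classes = NULL) {
  pairs <- do.call(rbind, lapply(matchsets, `[[`, "pairs"))
  fns <- do.call(rbind, lapply(matchsets, `[[`, "unmatched_truth"))
  fps <- do.call(rbind, lapply(matchsets, `[[`, "unmatched_pred"))
  if (is.null(classes)) {
    classes <- intersect(cell_classes(),
                         unique(c(pairs$cell_class, fns$cell_class,
                                  fps$cell_class)))
  }
  rows <- lapply(classes, function(cl) {
    p <- pairs[pairs$cell_class == cl, , drop = FALSE]
    tp <- nrow(p)
    fn <- sum(fns$cell_class == cl)
    fp <- sum(fps$cell_class == cl)
    n_truth <- tp + fn
    n_pred <- tp + fp
    data.frame(
      cell_class = cl, n_truth = n_truth, n_pred = n_pred,
      tp = tp, fp = fp, fn = fn,
      sensitivity = if (n_truth > 0) tp / n_truth else NA_real_,
      specificity = if (n_pred > 0) tp / n_pred else NA_real_,
      iou_mean = if (tp > 0) mean(p$iou) else NA_real_,
      iou_sd = if (tp > 1) stats::sd(p$iou) else NA_real_,
      defined = n_truth > 0 || n_pred > 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("class_metrics", "data.frame")
  out
}

#' Overall performance summary across cell classes
#'
#' Reports cell-weighted averages (sensitivity weighted by truth-cell
#' count, specificity by prediction count, IOU by matched-pair count -
#' equivalent to pooling all cells) alongside unweighted means over the
#' defined classes, since printed "average" columns in the literature are
#' ambiguous between the two conventions.
#'
#' @param per_class a [class_metrics()] data.frame
#' @param tau,theta thresholds recorded in the summary metadata
#' @return an object of class `eval_summary`: `per_class`, `overall`
#'   (rows `cell_weighted` and `class_mean`), thresholds, and the
#'   specificity definition used
#' @export
overall_metrics <- function(per_class, tau = NA_real_, theta = NA_real_) {
  pc <- per_class[per_class$defined, , drop = FALSE]
  if (nrow(pc) == 0) {
    stop("no class has any truth or predicted cells", call. = FALSE)
  }
  wmean <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  overall <- data.frame(
    averaging = c("cell_weighted", "class_mean"),
    sensitivity = c(wmean(pc$sensitivity, pc$n_truth),
                    mean(pc$sensitivity, na.rm = TRUE)),
    specificity = c(wmean(pc$specificity, pc$n_pred),
                    mean(pc$specificity, na.rm = TRUE)),
    iou_mean = c(wmean(pc$iou_mean, pc$tp),
                 mean(pc$iou_mean, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  structure(
    list(per_class = per_class, overall = overall, tau = tau, theta = theta,
         specificity_definition = "tp / (tp + fp), positive predictive value"),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary> tau=%s theta=%s\n", format(x$tau),
              format(x$theta)))
  cat("specificity := ", x$specificity_definition, "\n", sep = "")
  print.data.frame(x$per_class, row.names = FALSE, digits = 4)
  print.data.frame(x$overall, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a predicted cohort against a ground-truth cohort
#'
#' Runs the full evaluation protocol over all frames: confidence filtering
#' at `tau`, one-to-one class-matched assignment at IOU >= `theta`, and
#' pooled per-class plus overall metrics. Frames are aligned by
#' `frame_id`; the cohorts may come from different sources (e.g. a model
#' trained on one fixation evaluated against another cohort's truth).
#'
#' @param truth_cohort,pred_cohort [cohort_dataset()] objects whose frame
#'   ids align
#' @param theta IOU threshold (default 0.25)
#' @param tau confidence threshold (default 0.3)
#' @param classes classes to report (default: the union of panel classes
#'   present in the truth cohort)
#' @return an `eval_summary`; the per-frame `match_set`s are attached as
#'   attribute `"matchsets"`
#' @export
cross_evaluate <- function(truth_cohort, pred_cohort, theta = 0.25,
                           tau = 0.3, classes = NULL) {
  t_ids <- vapply(truth_cohort$frames, function(f) as.character(f$frame_id),
                  character(1))
  p_ids <- vapply(pred_cohort$frames, function(f) as.character(f$frame_id),
                  character(1))
  missing_p <- setdiff(t_ids, p_ids)
  missing_t <- setdiff(p_ids, t_ids)
  if (length(missing_p) || length(missing_t)) {
    stop("frame ids do not align; missing from predictions: ",
         paste(missing_p, collapse = ", "), "; missing from truth: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- intersect(
      cell_classes(),
      unique(unlist(lapply(truth_cohort$frames,
                           function(f) panel_classes(f$panel))))
    )
  }
  matchsets <- lapply(seq_along(t_ids), function(k) {
    tf <- truth_cohort$frames[[k]]
    pf <- pred_cohort$frames[[match(t_ids[k], p_ids)]]
    match_instances(tf, filter_confidence(pf, tau), theta)
  })
  pc <- class_metrics(matchsets, classes = classes)
  out <- overall_metrics(pc, tau = tau, theta = theta)
  attr(out, "matchsets") <- matchsets
  out
}
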