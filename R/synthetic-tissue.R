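# Synthetic tissue simulator: ground-truth cohorts and a controllable
# detection-degradation model that turns them into "predicted" cohorts.

# Run expr with a private RNG state so simulation never perturbs the
# caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Independent per-frame streams derived from one master seed, so changing
# the frame count never reshuffles earlier frames. Kept within 32-bit range.
derive_seed <- function(seed, stream, index) {
  ((seed %% 2147483647) * 48271 + stream * 69621 + index * 16807) %% 2147483647
}

default_area_params <- function() {
  list(
    CD4T    = list(median = 48, gsd = 1.35),
    CD4negT = list(median = 48, gsd = 1.35),
    mDC     = list(median = 95, gsd = 1.50),
    pDC     = list(median = 72, gsd = 1.45),
    Bcell   = list(median = 45, gsd = 1.35)
  )
}

default_irregularity <- function() {
  c(CD4T = 0.08, CD4negT = 0.08, mDC = 0.30, pDC = 0.20, Bcell = 0.08)
}

#' Configuration for the synthetic tissue generator
#'
#' Defines one simulated imaging condition: frame geometry, cell density,
#' class mixture, per-class cell-size distributions, shape irregularity,
#' spatial aggregation and a fixation-shrinkage factor.
#'
#' Cells are placed by a cluster-then-scatter process (immune infiltrates
#' aggregate rather than tile the tissue uniformly): `aggregation$n_clusters`
#' cluster centers per frame, cells displaced from their cluster center by
#' isotropic Gaussian noise with standard deviation `aggregation$spread_um`.
#' Cell areas are log-normal per class, parameterised by the median (um^2)
#' and geometric standard deviation. `shrinkage_s` is a linear scale factor
#' in (0, 1] applied to every cell's linear size and to within-cluster
#' displacements, emulating the tissue contraction caused by formalin
#' fixation; `shrinkage_s = 1` under the same seed reproduces the unshrunk
#' cohort draw for draw.
#'
#' @param panel one of [panel_tags()]
#' @param pixel_size_um micrometres per pixel
#' @param fixation one of [fixation_tags()]
#' @param n_frames number of frames to generate
#' @param cells_per_frame Poisson mean cell count per frame
#' @param class_mixture probability vector over `panel_classes(panel)`
#'   (named or in panel order); must sum to 1
#' @param area_um2 per-class list of `list(median, gsd)` (um^2)
#' @param shape_irregularity boundary perturbation amplitude in \[0, 1),
#'   scalar or named per class
#' @param aggregation `list(n_clusters, spread_um)`; an optional
#'   `min_separation_um` (default `3 * spread_um`) keeps cluster centers
#'   apart so that aggregates are spatially distinct
#' @param shrinkage_s linear shrinkage factor in (0, 1\]
#' @param frame_size_px frame side length in pixels
#' @param seed master seed for the cohort
#' @return an object of class `tissue_config`
#' @export
tissue_config <- function(panel, pixel_size_um, fixation, n_frames,
                          cells_per_frame, class_mixture = NULL,
                          area_um2 = default_area_params(),
                          shape_irregularity = default_irregularity(),
                          aggregation = list(n_clusters = 3, spread_um = 12),
                          shrinkage_s = 1, frame_size_px = 1024, seed = 1) {
  classes <- panel_classes(panel)
  if (is.null(class_mixture)) {
    class_mixture <- stats::setNames(rep(1 / length(classes), length(classes)),
                                     classes)
  }
  if (length(class_mixture) != length(classes)) {
    stop("class_mixture has ", length(class_mixture), " entries; panel '",
         panel, "' has ", length(classes), " classes", call. = FALSE)
  }
  if (is.null(names(class_mixture))) names(class_mixture) <- classes
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture must sum to 1", call. = FALSE)
  }
  if (shrinkage_s <= 0 || shrinkage_s > 1) {
    stop("shrinkage_s must lie in (0, 1]", call. = FALSE)
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  irr <- shape_irregularity
  if (length(irr) == 1 && is.null(names(irr))) {
    irr <- stats::setNames(rep(irr, length(classes)), classes)
  }
  structure(
    list(panel = panel, pixel_size_um = pixel_size_um, fixation = fixation,
         n_frames = as.integer(n_frames), cells_per_frame = cells_per_frame,
         class_mixture = class_mixture[classes], area_um2 = area_um2,
         shape_irregularity = irr, aggregation = aggregation,
         shrinkage_s = shrinkage_s, frame_size_px = as.integer(frame_size_px),
         seed = as.integer(seed)),
    class = "tissue_config"
  )
}

#' Rescale a tissue configuration by a fixation-shrinkage factor
#'
#' Multiplies `shrinkage_s` by `s`. Because shrinkage acts linearly on cell
#' size and intercellular spacing, the expected mean cell area scales by
#' s^2 while expected perimeter and nearest-neighbour distances scale by s;
#' the percent reduction in mean area is therefore 100 (1 - s^2).
#'
#' @param config a [tissue_config()]
#' @param s linear scale factor in (0, 1\]
#' @return the rescaled config
#' @export
apply_fixation_shrinkage <- function(config, s) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0 || s > 1) {
    stop("shrinkage factor s must be a scalar in (0, 1]", call. = FALSE)
  }
  config$shrinkage_s <- config$shrinkage_s * s
  config
}

# One shape-perturbed ellipse polygon, centered at (cx, cy) px.
# area_px2: target expected raster area. Radii are corrected for the
# inscribed-polygon and harmonic-modulation area factors so that the
# expected pixel-count area matches area_px2.
make_cell_outline <- function(cx, cy, area_px2, irregularity, n_vertices = 32) {
  q <- stats::runif(1, 0.6, 1)                # minor/major axis ratio
  phi <- stats::runif(1, 0, 2 * pi)           # orientation
  k <- sample(2:5, 1)                         # harmonic order
  psi <- stats::runif(1, 0, 2 * pi)
  a_mod <- irregularity * stats::runif(1, 0.5, 1)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  h <- 2 * pi / n_vertices
  sinc_corr <- sqrt(h / sin(h))               # inscribed-polygon area loss
  harm_corr <- 1 / sqrt(1 + a_mod^2 / 2)      # harmonic modulation area gain
  A <- sqrt(area_px2 / (pi * q)) * sinc_corr * harm_corr
  B <- A * q
  mod <- 1 + a_mod * cos(k * t + psi)
  ex <- A * cos(t) * mod
  ey <- B * sin(t) * mod
  x <- cx + ex * cos(phi) - ey * sin(phi)
  y <- cy + ex * sin(phi) + ey * cos(phi)
  cbind(x = x, y = y)
}

generate_frame <- function(config, frame_index) {
  ps <- config$pixel_size_um
  W <- config$frame_size_px
  s <- config$shrinkage_s
  classes <- names(config$class_mixture)
  with_seed(derive_seed(config$seed, 1L, frame_index), {
    n_cells <- stats::rpois(1, config$cells_per_frame)
    # margin keeps shapes in bounds without distorting the spatial process
    max_med <- max(vapply(config$area_um2[classes],
                          function(p) p$median, numeric(1)))
    rmax_px <- 2.5 * sqrt(max_med * exp(2 * log(1.6)) / pi) / ps
    spread_px <- config$aggregation$spread_um / ps
    margin <- min(W / 3, rmax_px + 3.5 * spread_px)
    # displacements are truncated before shrinkage scaling, so cell
    # positions depend on shrinkage_s only through the linear factor and
    # the in-bounds clamp below almost never engages
    disp_max <- max(margin - rmax_px, 0)
    nc <- max(1L, as.integer(config$aggregation$n_clusters))
    # aggregates are distinct infiltrates: keep cluster centers apart
    # (rejection sampling up to 60 draws, else the most separated draw)
    min_sep_um <- config$aggregation$min_separation_um
    if (is.null(min_sep_um)) min_sep_um <- 3 * config$aggregation$spread_um
    min_sep_px <- min_sep_um / ps
    best_sep <- -Inf
    cl_x <- cl_y <- numeric(nc)
    for (try_k in 1:60) {
      px <- stats::runif(nc, margin, W - margin)
      py <- stats::runif(nc, margin, W - margin)
      sep <- if (nc > 1) min(stats::dist(cbind(px, py))) else Inf
      if (sep > best_sep) {
        best_sep <- sep; cl_x <- px; cl_y <- py
      }
      if (best_sep >= min_sep_px) break
    }
    insts <- vector("list", n_cells)
    for (c_i in seq_len(n_cells)) {
      cl <- sample.int(nc, 1)
      disp <- pmin(pmax(stats::rnorm(2, 0, spread_px), -disp_max),
                   disp_max) * s
      cls <- sample(classes, 1, prob = config$class_mixture)
      ap <- config$area_um2[[cls]]
      area_um2 <- stats::rlnorm(1, log(ap$median), log(ap$gsd)) * s^2
      area_px2 <- area_um2 / ps^2
      irr <- config$shape_irregularity[[cls]]
      r_out <- 1.6 * sqrt(area_px2 / (pi * 0.6))  # bound on outline radius
      cx <- min(max(cl_x[cl] + disp[1], r_out), W - r_out)
      cy <- min(max(cl_y[cl] + disp[2], r_out), W - r_out)
      insts[[c_i]] <- cell_instance(
        id = sprintf("f%d_c%d", frame_index, c_i),
        cell_class = cls,
        outline = make_cell_outline(cx, cy, area_px2, irr),
        confidence = 1, source = "manual"
      )
    }
    image_frame(frame_id = sprintf("frame_%04d", frame_index),
                width_px = W, height_px = W, pixel_size_um = ps,
                fixation = config$fixation, panel = config$panel,
                instances = insts)
  })
}

#' Generate a ground-truth cohort from a tissue configuration
#'
#' Deterministic given `config$seed`: per-frame random streams are derived
#' from the master seed, so frame k is identical whether 10 or 1000 frames
#' are requested.
#'
#' @param config a [tissue_config()]
#' @param name cohort name
#' @return a [cohort_dataset()] with role `"truth"`
#' @export
generate_truth <- function(config, name = "synthetic-truth") {
  frames <- lapply(seq_len(config$n_frames), function(k) {
    generate_frame(config, k)
  })
  cohort_dataset(name = name, frames = frames, role = "truth")
}

#' Configuration for the detection-degradation model
#'
#' Describes the error structure of an instance-segmentation predictor:
#' per-class detection probabilities, per-class expected false positives
#' per frame, a row-stochastic class-confusion matrix applied to detected
#' cells, a boundary-jitter amplitude (as a fraction of the cell's
#' equivalent radius) that controls the IOU of matched pairs, and Beta
#' confidence distributions - one for correct detections and one for false
#' positives and misclassifications.
#'
#' @param classes character vector of classes the model acts on
#' @param detect_prob per-class detection probability (scalar or named)
#' @param fp_rate per-class expected false positives per frame
#' @param confusion row-stochastic matrix over `classes`; default identity
#' @param jitter boundary displacement amplitude >= 0 (fraction of
#'   equivalent radius); 0 reproduces truth outlines exactly
#' @param confidence_correct,confidence_error `c(shape1, shape2)` of the
#'   Beta confidence distributions
#' @param seed master seed
#' @return an object of class `degradation_config`
#' @export
degradation_config <- function(classes, detect_prob = 0.9, fp_rate = 0.5,
                               confusion = NULL, jitter = 0.1,
                               confidence_correct = c(20, 2),
                               confidence_error = c(2, 4), seed = 1) {
  expand <- function(x, what) {
    if (length(x) == 1) x <- stats::setNames(rep(x, length(classes)), classes)
    if (is.null(names(x))) names(x) <- classes
    if (!all(classes %in% names(x))) {
      stop(what, " must be named for every class", call. = FALSE)
    }
    x[classes]
  }
  detect_prob <- expand(detect_prob, "detect_prob")
  fp_rate <- expand(fp_rate, "fp_rate")
  if (any(detect_prob < 0 | detect_prob > 1)) {
    stop("detect_prob values must lie in [0, 1]", call. = FALSE)
  }
  if (any(fp_rate < 0)) stop("fp_rate values must be >= 0", call. = FALSE)
  if (is.null(confusion)) {
    confusion <- diag(length(classes))
    dimnames(confusion) <- list(classes, classes)
  }
  if (!all(dim(confusion) == length(classes)) ||
      any(abs(rowSums(confusion) - 1) > 1e-9) || any(confusion < 0)) {
    stop("confusion must be a row-stochastic matrix over the classes",
         call. = FALSE)
  }
  if (is.null(dimnames(confusion))) {
    dimnames(confusion) <- list(classes, classes)
  }
  structure(
    list(classes = classes, detect_prob = detect_prob, fp_rate = fp_rate,
         confusion = confusion[classes, classes], jitter = jitter,
         confidence_correct = confidence_correct,
         confidence_error = confidence_error, seed = as.integer(seed)),
    class = "degradation_config"
  )
}

# Smoothly perturb and shift an outline; amplitude scales with the cell's
# equivalent radius so the induced IOU loss is size-independent.
jitter_outline <- function(outline, jitter, W, H) {
  if (jitter <= 0) return(outline)
  ctr <- colMeans(outline)
  r_eq <- sqrt(abs(polygon_area(outline)) / pi)
  k <- sample(2:4, 1)
  psi <- stats::runif(1, 0, 2 * pi)
  amp <- jitter * stats::runif(1, 0.3, 1)
  th <- atan2(outline[, 2] - ctr[2], outline[, 1] - ctr[1])
  scale <- 1 + amp * cos(k * th + psi)
  ang <- stats::runif(1, 0, 2 * pi)
  shift_len <- jitter * r_eq * stats::runif(1, 0, 0.8)
  out <- cbind(ctr[1] + scale * (outline[, 1] - ctr[1]) + shift_len * cos(ang),
               ctr[2] + scale * (outline[, 2] - ctr[2]) + shift_len * sin(ang))
  # keep vertices inside the frame by translating back, then clamping
  dx <- max(0, -min(out[, 1])) - max(0, max(out[, 1]) - W)
  dy <- max(0, -min(out[, 2])) - max(0, max(out[, 2]) - H)
  out[, 1] <- pmin(pmax(out[, 1] + dx, 0), W)
  out[, 2] <- pmin(pmax(out[, 2] + dy, 0), H)
  colnames(out) <- c("x", "y")
  out
}

#' Degrade a truth cohort into a simulated predicted cohort
#'
#' Each truth cell is independently detected with its class's
#' `detect_prob`; detected cells receive a confusion-sampled class, a
#' jittered boundary and a confidence drawn from the correct-detection
#' Beta distribution (misclassified cells draw from the error
#' distribution). Poisson(`fp_rate`) spurious cells per frame and class
#' are placed uniformly at random, with shapes resampled from the cohort's
#' own cells of that class and confidences from the error distribution.
#' Deterministic given `config$seed`.
#'
#' @param truth a [cohort_dataset()] with role `"truth"`
#' @param config a [degradation_config()]
#' @return a [cohort_dataset()] with role `"predicted"`
#' @export
degrade <- function(truth, config) {
  classes <- config$classes
  # shape templates per class for false positives
  templates <- stats::setNames(vector("list", length(classes)), classes)
  for (f in truth$frames) {
    for (inst in f$instances) {
      cl <- inst$cell_class
      if (cl %in% classes && length(templates[[cl]]) < 200) {
        templates[[cl]] <- c(templates[[cl]], list(inst$outline))
      }
    }
  }
  all_templates <- do.call(c, templates[lengths(templates) > 0])
  frames <- vector("list", length(truth$frames))
  for (fi in seq_along(truth$frames)) {
    f <- truth$frames[[fi]]
    W <- f$width_px; H <- f$height_px
    frames[[fi]] <- with_seed(derive_seed(config$seed, 2L, fi), {
      preds <- list()
      np <- 0L
      for (inst in f$instances) {
        cl <- inst$cell_class
        if (!cl %in% classes) next
        if (stats::runif(1) > config$detect_prob[[cl]]) next
        new_cl <- sample(classes, 1, prob = config$confusion[cl, ])
        out <- jitter_outline(inst$outline, config$jitter, W, H)
        par <- if (new_cl == cl) config$confidence_correct
               else config$confidence_error
        conf <- stats::rbeta(1, par[1], par[2])
        np <- np + 1L
        preds[[np]] <- cell_instance(
          id = sprintf("%s_p%d", f$frame_id, np), cell_class = new_cl,
          outline = out, confidence = conf, source = "predicted"
        )
      }
      for (cl in classes) {
        n_fp <- stats::rpois(1, config$fp_rate[[cl]])
        for (k in seq_len(n_fp)) {
          tpl <- if (length(templates[[cl]])) {
            templates[[cl]][[sample.int(length(templates[[cl]]), 1)]]
          } else if (length(all_templates)) {
            all_templates[[sample.int(length(all_templates), 1)]]
          } else next
          ctr <- colMeans(tpl)
          r_out <- max(sqrt((tpl[, 1] - ctr[1])^2 + (tpl[, 2] - ctr[2])^2))
          cx <- stats::runif(1, r_out, W - r_out)
          cy <- stats::runif(1, r_out, H - r_out)
          out <- cbind(x = tpl[, 1] - ctr[1] + cx, y = tpl[, 2] - ctr[2] + cy)
          np <- np + 1L
          preds[[np]] <- cell_instance(
            id = sprintf("%s_p%d", f$frame_id, np), cell_class = cl,
            outline = out,
            confidence = stats::rbeta(1, config$confidence_error[1],
                                      config$confidence_error[2]),
            source = "predicted"
          )
        }
      }
      image_frame(frame_id = f$frame_id, width_px = W, height_px = H,
                  pixel_size_um = f$pixel_size_um, fixation = f$fixation,
                  panel = f$panel, instances = preds)
    })
  }
  cohort_dataset(name = paste0(truth$name, "-predicted"), frames = frames,
                 role = "predicted")
}
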