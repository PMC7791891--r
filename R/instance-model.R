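#' @keywords internal
"_PACKAGE"

# Controlled vocabularies ------------------------------------------------

#' Cell classes, panels and fixation tags
#'
#' The package models five immune-cell classes: two T-lymphocyte subsets
#' (`CD4T` = CD3+CD4+, `CD4negT` = CD3+CD4-) and three antigen-presenting
#' cell populations (myeloid dendritic cells `mDC`, plasmacytoid dendritic
#' cells `pDC`, and B cells `Bcell`). A double-stain image (panel 1) carries
#' the two T subsets plus a single DC type, so panel tags distinguish
#' `panel1-mDC` and `panel1-pDC` frames; a single-stain image (panel 2)
#' carries all five classes.
#'
#' @return `cell_classes()` returns the five class labels; `panel_classes()`
#'   the classes present on a frame of the given panel; `fixation_tags()` the
#'   recognised fixation labels.
#' @export
cell_classes <- function() c("CD4T", "CD4negT", "mDC", "pDC", "Bcell")

#' @rdname cell_classes
#' @export
panel_tags <- function() c("panel1-mDC", "panel1-pDC", "panel2")

#' @rdname cell_classes
#' @export
fixation_tags <- function() c("fresh_frozen", "FFPE")

#' @rdname cell_classes
#' @param panel one of `panel_tags()`
#' @export
panel_classes <- function(panel) {
  switch(panel,
    "panel1-mDC" = c("CD4T", "CD4negT", "mDC"),
    "panel1-pDC" = c("CD4T", "CD4negT", "pDC"),
    "panel2"     = cell_classes(),
    stop("unknown panel tag: ", panel, call. = FALSE)
  )
}

#' @rdname cell_classes
#' @export
t_cell_classes <- function() c("CD4T", "CD4negT")

#' @rdname cell_classes
#' @export
dc_classes <- function() c("mDC", "pDC")

# Core containers --------------------------------------------------------

#' Construct a cell instance
#'
#' A cell instance is one segmented cell: a simple polygon outline in
#' continuous pixel coordinates (x right, y down; pixel (i,j) occupies the
#' half-open square \[j, j+1) x \[i, i+1)), a class label, a confidence in
#' \[0,1\] and a provenance tag. Manually segmented cells always carry
#' confidence 1 so that a single confidence-filtering path serves both
#' manual and predicted cohorts.
#'
#' @param id instance identifier, unique within its frame
#' @param cell_class one of [cell_classes()]
#' @param outline numeric matrix with two columns (x, y) in pixel units
#' @param confidence numeric in \[0,1\]; forced to 1 for `source = "manual"`
#' @param source `"manual"` or `"predicted"`
#' @return an object of class `cell_instance`
#' @export
cell_instance <- function(id, cell_class, outline, confidence = 1,
                          source = c("manual", "predicted")) {
  source <- match.arg(source)
  outline <- as.matrix(outline)
  if (ncol(outline) != 2) stop("outline must be a two-column (x, y) matrix")
  colnames(outline) <- c("x", "y")
  if (source == "manual") confidence <- 1
  structure(
    list(id = id, cell_class = cell_class, outline = outline,
         confidence = as.numeric(confidence), source = source),
    class = "cell_instance"
  )
}

#' Construct an image frame
#'
#' One 2-D field of view with its segmented cell instances. Physical units
#' enter through `pixel_size_um` (micrometres per pixel).
#'
#' @param frame_id frame identifier, unique within a cohort
#' @param width_px,height_px frame dimensions in pixels
#' @param pixel_size_um micrometres per pixel (> 0)
#' @param fixation one of [fixation_tags()]
#' @param panel one of [panel_tags()]
#' @param instances list of [cell_instance()] objects
#' @return an object of class `image_frame`
#' @export
image_frame <- function(frame_id, width_px = 1024, height_px = 1024,
                        pixel_size_um, fixation, panel, instances = list()) {
  structure(
    list(frame_id = frame_id, width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         pixel_size_um = as.numeric(pixel_size_um),
         fixation = fixation, panel = panel, instances = instances),
    class = "image_frame"
  )
}

#' Construct a cohort dataset
#'
#' A named collection of frames playing either the ground-truth or the
#' predicted role. All frames of a cohort share fixation and pixel size;
#' double-stain cohorts may mix `panel1-mDC` and `panel1-pDC` frames.
#'
#' @param name cohort name
#' @param frames list of [image_frame()] objects
#' @param role `"truth"` or `"predicted"`
#' @return an object of class `cohort_dataset`
#' @export
cohort_dataset <- function(name, frames, role = c("truth", "predicted")) {
  role <- match.arg(role)
  structure(list(name = name, frames = frames, role = role),
            class = "cohort_dataset")
}

#' @export
print.cell_instance <- function(x, ...) {
  cat(sprintf("<cell_instance %s> class=%s conf=%.3f source=%s vertices=%d\n",
              x$id, x$cell_class, x$confidence, x$source, nrow(x$outline)))
  invisible(x)
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %s> %dx%d px @ %.4f um/px, %s, %s, %d instances\n",
              x$frame_id, x$width_px, x$height_px, x$pixel_size_um,
              x$fixation, x$panel, length(x$instances)))
  invisible(x)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n_cells <- sum(vapply(x$frames, function(f) length(f$instances), integer(1)))
  cat(sprintf("<cohort_dataset '%s'> role=%s frames=%d cells=%d\n",
              x$name, x$role, length(x$frames), n_cells))
  invisible(x)
}

# Geometry helpers -------------------------------------------------------

#' Signed polygon area by the shoelace formula (pixel^2 units)
#' @param outline two-column vertex matrix
#' @return signed area; absolute value is the geometric area
#' @export
polygon_area <- function(outline) {
  x <- outline[, 1]; y <- outline[, 2]
  n <- length(x)
  if (n < 3) return(0)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Proper-crossing test between segment sets; shared endpoints are allowed
# (outlines traced from label maps may touch themselves at a corner).
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test whether a polygon outline is (weakly) simple
#'
#' Checks that no two edges properly cross. Edges sharing an endpoint or
#' touching at a vertex are permitted, so outlines traced from pixel label
#' maps (which may pinch at a corner) pass.
#'
#' @param outline two-column vertex matrix
#' @return logical
#' @export
is_simple_polygon <- function(outline) {
  n <- nrow(outline)
  if (n < 3) return(FALSE)
  v <- rbind(outline, outline[1, , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      if (segments_cross(v[i, ], v[i + 1, ], v[j, ], v[j + 1, ])) return(FALSE)
    }
  }
  TRUE
}

# Validation -------------------------------------------------------------

#' Validate instance, frame and cohort invariants
#'
#' `validate_instance()` checks the polygon is a simple polygon with at
#' least three vertices and positive area, confidence lies in \[0,1\] and
#' manual instances carry confidence 1. `validate_frame()` additionally
#' checks all vertices fall inside \[0, width\] x \[0, height\] and instance
#' ids are unique. `validate_cohort()` checks frame-id uniqueness and that
#' all frames share fixation and pixel size.
#'
#' @param instance,frame,cohort objects to validate
#' @param check_simple run the O(n^2) proper-crossing test (default TRUE)
#' @return invisibly `TRUE`; stops with an informative error otherwise
#' @export
validate_instance <- function(instance, check_simple = TRUE) {
  o <- instance$outline
  if (nrow(o) < 3) {
    stop("instance ", instance$id, ": degenerate polygon (", nrow(o),
         " vertices)", call. = FALSE)
  }
  if (check_simple && !is_simple_polygon(o)) {
    stop("instance ", instance$id, ": polygon is self-intersecting",
         call. = FALSE)
  }
  if (abs(polygon_area(o)) <= 0) {
    stop("instance ", instance$id, ": polygon has zero area", call. = FALSE)
  }
  if (is.na(instance$confidence) || instance$confidence < 0 ||
      instance$confidence > 1) {
    stop("instance ", instance$id, ": confidence outside [0, 1]",
         call. = FALSE)
  }
  if (instance$source == "manual" && instance$confidence != 1) {
    stop("instance ", instance$id, ": manual instances must have confidence 1",
         call. = FALSE)
  }
  if (!instance$cell_class %in% cell_classes()) {
    stop("instance ", instance$id, ": unknown cell class '",
         instance$cell_class, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname validate_instance
#' @export
validate_frame <- function(frame, check_simple = TRUE) {
  if (frame$pixel_size_um <= 0) {
    stop("frame ", frame$frame_id, ": pixel_size_um must be > 0",
         call. = FALSE)
  }
  if (!frame$panel %in% panel_tags()) {
    stop("frame ", frame$frame_id, ": unknown panel '", frame$panel, "'",
         call. = FALSE)
  }
  if (!frame$fixation %in% fixation_tags()) {
    stop("frame ", frame$frame_id, ": unknown fixation '", frame$fixation,
         "'", call. = FALSE)
  }
  ids <- vapply(frame$instances, function(z) as.character(z$id), character(1))
  if (anyDuplicated(ids)) {
    stop("frame ", frame$frame_id, ": duplicated instance ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  allowed <- panel_classes(frame$panel)
  for (inst in frame$instances) {
    validate_instance(inst, check_simple = check_simple)
    o <- inst$outline
    if (any(o[, 1] < 0 | o[, 1] > frame$width_px |
            o[, 2] < 0 | o[, 2] > frame$height_px)) {
      stop("frame ", frame$frame_id, ", instance ", inst$id,
           ": vertices outside frame bounds", call. = FALSE)
    }
    if (!inst$cell_class %in% allowed) {
      stop("frame ", frame$frame_id, ", instance ", inst$id, ": class '",
           inst$cell_class, "' not in panel '", frame$panel, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @rdname validate_instance
#' @export
validate_cohort <- function(cohort, check_simple = TRUE) {
  ids <- vapply(cohort$frames, function(f) as.character(f$frame_id),
                character(1))
  if (anyDuplicated(ids)) {
    stop("cohort ", cohort$name, ": duplicated frame ids", call. = FALSE)
  }
  if (length(cohort$frames)) {
    fx <- unique(vapply(cohort$frames, function(f) f$fixation, character(1)))
    ps <- unique(vapply(cohort$frames, function(f) f$pixel_size_um, numeric(1)))
    if (length(fx) > 1) {
      stop("cohort ", cohort$name, ": mixed fixation tags: ",
           paste(fx, collapse = ", "), call. = FALSE)
    }
    if (length(ps) > 1) {
      stop("cohort ", cohort$name, ": mixed pixel sizes", call. = FALSE)
    }
  }
  for (f in cohort$frames) validate_frame(f, check_simple = check_simple)
  invisible(TRUE)
}
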