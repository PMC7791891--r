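# Rasterization, IOU, and label-map conversion.
#
# Convention: 0-based pixel (i, j) (row i = y, column j = x) occupies the
# half-open square [j, j+1) x [i, i+1); its center is (j + 0.5, i + 0.5).
# Raster masks are H x W logical matrices indexed mask[i + 1, j + 1].

# Even-odd (crossing-number) point-in-polygon, vectorized over points.
# Points exactly on a boundary are resolved by the same rule; pixel centers
# at half-integers never coincide with integer-coordinate edges.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside <- xor(inside, crosses & (px < xint))  # FALSE & NaN is FALSE
    }
    j <- i
  }
  inside
}

# Linear (1-based, column-major) indices of the set pixels of an instance
# within its frame. Even-odd scanline fill over the polygon's bounding
# box; a pixel center (j + 0.5, i + 0.5) is set iff the number of edge
# crossings strictly to its right along the scanline is odd - the same
# parity rule as points_in_polygon(), but O(rows x edges) instead of
# O(pixels x edges).
instance_pixels <- function(instance, frame) {
  o <- instance$outline
  if (nrow(o) < 3) {
    stop("instance ", instance$id, ": degenerate polygon (", nrow(o),
         " vertices)", call. = FALSE)
  }
  H <- frame$height_px; W <- frame$width_px
  vx <- o[, 1]; vy <- o[, 2]
  vx2 <- c(vx[-1], vx[1]); vy2 <- c(vy[-1], vy[1])
  j0 <- max(0L, as.integer(floor(min(vx))))
  j1 <- min(W - 1L, as.integer(ceiling(max(vx))))
  i0 <- max(0L, as.integer(floor(min(vy))))
  i1 <- min(H - 1L, as.integer(ceiling(max(vy))))
  if (j1 < j0 || i1 < i0) {
    stop("instance ", instance$id, ": polygon lies outside the frame",
         call. = FALSE)
  }
  out <- vector("list", i1 - i0 + 1L)
  for (i in i0:i1) {
    py <- i + 0.5
    cr <- (vy > py) != (vy2 > py)
    if (!any(cr)) next
    xint <- vx[cr] + (py - vy[cr]) * (vx2[cr] - vx[cr]) / (vy2[cr] - vy[cr])
    xint <- if (length(xint) == 2L) {
      if (xint[1L] > xint[2L]) xint[2:1] else xint
    } else sort.int(xint, method = "quick")
    n2 <- length(xint) %/% 2L
    for (m in seq_len(n2)) {
      ja <- max(j0, as.integer(ceiling(xint[2L * m - 1L] - 0.5)))
      jb <- min(j1, as.integer(ceiling(xint[2L * m] - 0.5)) - 1L)
      if (jb >= ja) {
        out[[i - i0 + 1L]] <- c(out[[i - i0 + 1L]],
                                (ja:jb) * H + i + 1L)
      }
    }
  }
  idx <- unlist(out, use.names = FALSE)
  if (!length(idx)) {
    stop("instance ", instance$id, ": rasterizes to an empty mask",
         call. = FALSE)
  }
  as.integer(idx)
}

#' Rasterize a cell instance onto its frame grid
#'
#' A pixel is set iff its center lies inside the instance polygon, with
#' boundary cases resolved by the even-odd rule.
#'
#' @param instance a [cell_instance()]
#' @param frame the [image_frame()] supplying the grid dimensions
#' @return logical matrix of dimension `height_px` x `width_px`
#' @export
rasterize <- function(instance, frame) {
  mask <- matrix(FALSE, frame$height_px, frame$width_px)
  mask[instance_pixels(instance, frame)] <- TRUE
  mask
}

#' Intersection over union (Jaccard index) of two raster masks
#'
#' @param mask_a,mask_b logical matrices of identical dimensions
#' @return |A intersect B| / |A union B| in \[0,1\]. When both masks are
#'   empty the union is empty and 0 is returned with a warning.
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop(sprintf("mask dimension mismatch: %s vs %s",
                 paste(dim(mask_a), collapse = "x"),
                 paste(dim(mask_b), collapse = "x")), call. = FALSE)
  }
  inter <- sum(mask_a & mask_b)
  uni <- sum(mask_a | mask_b)
  if (uni == 0) {
    warning("both masks empty; IOU reported as 0 by convention")
    return(0)
  }
  inter / uni
}

# IOU on pixel-index sets (each a vector of unique linear indices).
iou_sets <- function(a, b) {
  inter <- sum(a %in% b)
  inter / (length(a) + length(b) - inter)
}

#' Export a frame as an integer label map with a class/confidence sidecar
#'
#' Background pixels are 0 and the pixels of the k-th instance are labeled
#' k. Because a flat label image cannot encode overlapping cells, two modes
#' are offered: `"strict"` fails when any two instances share a pixel;
#' `"precedence"` resolves contested pixels in favour of the
#' higher-confidence instance (ties broken by instance order).
#'
#' @param frame an [image_frame()]
#' @param mode `"strict"` or `"precedence"`
#' @return list with `labels` (integer H x W matrix) and `sidecar`
#'   (data.frame: label, cell_class, confidence, source, id)
#' @export
to_label_map <- function(frame, mode = c("strict", "precedence")) {
  mode <- match.arg(mode)
  labels <- matrix(0L, frame$height_px, frame$width_px)
  insts <- frame$instances
  n <- length(insts)
  sidecar <- data.frame(
    label = seq_len(n),
    cell_class = vapply(insts, function(z) z$cell_class, character(1)),
    confidence = vapply(insts, function(z) z$confidence, numeric(1)),
    source = vapply(insts, function(z) z$source, character(1)),
    id = vapply(insts, function(z) as.character(z$id), character(1)),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(list(labels = labels, sidecar = sidecar))
  pix <- lapply(insts, instance_pixels, frame = frame)
  order_k <- seq_len(n)
  if (mode == "precedence") {
    # paint low-confidence first so higher confidence overwrites
    order_k <- order(sidecar$confidence, -seq_len(n))
  }
  for (k in order_k) {
    taken <- labels[pix[[k]]] != 0L
    if (mode == "strict" && any(taken)) {
      other <- unique(labels[pix[[k]]][taken])
      stop("overlapping instances in strict mode: ",
           paste(sidecar$id[other], collapse = ", "), " overlap ",
           sidecar$id[k], call. = FALSE)
    }
    labels[pix[[k]]] <- k
  }
  list(labels = labels, sidecar = sidecar)
}

# Trace the boundary of a pixel set (linear indices into an H x W grid) as
# a closed polygon with vertices at integer pixel-corner coordinates.
# Directed boundary edges keep the region on the right; at corner-contact
# vertices (degree 4) the walk turns left, threading through the pinch so
# that diagonally-touching parts stay on a single (weakly simple) loop
# whose even-odd interior is exactly the pixel set. A label whose pixels
# form several disconnected regions cannot be described by one outline and
# is rejected.
trace_pixel_boundary <- function(idx, H, W) {
  i <- (idx - 1L) %% H          # 0-based row (y)
  j <- (idx - 1L) %/% H         # 0-based col (x)
  set <- logical(H * W); set[idx] <- TRUE
  has <- function(ii, jj) {
    ok <- ii >= 0L & ii < H & jj >= 0L & jj < W
    out <- logical(length(ii))
    out[ok] <- set[jj[ok] * H + ii[ok] + 1L]
    out
  }
  # directed edges (x1,y1) -> (x2,y2), region on the right (y grows down)
  ex1 <- integer(0); ey1 <- integer(0); ex2 <- integer(0); ey2 <- integer(0)
  add <- function(sel, x1, y1, x2, y2) {
    ex1 <<- c(ex1, x1[sel]); ey1 <<- c(ey1, y1[sel])
    ex2 <<- c(ex2, x2[sel]); ey2 <<- c(ey2, y2[sel])
  }
  add(!has(i - 1L, j), j,      i,      j + 1L, i)       # top: +x
  add(!has(i, j + 1L), j + 1L, i,      j + 1L, i + 1L)  # right: +y
  add(!has(i + 1L, j), j + 1L, i + 1L, j,      i + 1L)  # bottom: -x
  add(!has(i, j - 1L), j,      i + 1L, j,      i)       # left: -y
  m <- length(ex1)
  vkey <- function(x, y) x * (H + 1L) + y
  start_key <- vkey(ex1, ey1)
  # directions: 1=+x, 2=+y, 3=-x, 4=-y (clockwise order on screen)
  dirs <- ifelse(ex2 > ex1, 1L, ifelse(ey2 > ey1, 2L, ifelse(ex2 < ex1, 3L, 4L)))
  by_start <- split(seq_len(m), start_key)
  used <- logical(m)
  loops <- list()
  while (any(!used)) {
    e <- which(!used)[1]
    lx <- ex1[e]; ly <- ey1[e]
    first <- e
    repeat {
      used[e] <- TRUE
      lx <- c(lx, ex2[e]); ly <- c(ly, ey2[e])
      cand <- by_start[[as.character(vkey(ex2[e], ey2[e]))]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1) {
        # 1 = right turn, 3 = left; prefer left to cross the pinch
        turn <- (dirs[cand] - dirs[e]) %% 4L
        cand <- cand[which.max(turn)]
      }
      e <- cand
    }
    loops[[length(loops) + 1L]] <- cbind(x = lx[-length(lx)], y = ly[-length(ly)])
  }
  if (length(loops) != 1) {
    stop("pixel set is not a single hole-free connected region (",
         length(loops), " boundary loops)", call. = FALSE)
  }
  loops[[1]]
}

#' Reconstruct an image frame from a label map and sidecar table
#'
#' Inverse of [to_label_map()] for non-overlapping frames: each nonzero
#' label becomes one instance whose outline, traced along pixel edges,
#' rasterizes back to exactly the label's pixel set.
#'
#' @param labels integer H x W matrix (0 = background)
#' @param sidecar data.frame with columns `label`, `cell_class`,
#'   `confidence`, and optionally `source` and `id`
#' @param frame_id,pixel_size_um,fixation,panel frame metadata
#' @return an [image_frame()]
#' @export
polygonize <- function(labels, sidecar, frame_id, pixel_size_um,
                       fixation, panel) {
  if (any(labels < 0) || any(labels != floor(labels))) {
    stop("label image must contain nonnegative integers", call. = FALSE)
  }
  H <- nrow(labels); W <- ncol(labels)
  present <- sort(unique(labels[labels > 0]))
  missing <- setdiff(present, sidecar$label)
  if (length(missing)) {
    stop("labels missing from sidecar: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  insts <- vector("list", length(present))
  for (k in seq_along(present)) {
    lab <- present[k]
    row <- sidecar[sidecar$label == lab, , drop = FALSE][1, ]
    outline <- trace_pixel_boundary(which(labels == lab), H, W)
    insts[[k]] <- cell_instance(
      id = if (!is.null(row$id) && !is.na(row$id)) row$id else lab,
      cell_class = row$cell_class,
      outline = outline,
      confidence = row$confidence,
      source = if (!is.null(row$source) && !is.na(row$source)) row$source
               else "manual"
    )
  }
  image_frame(frame_id = frame_id, width_px = W, height_px = H,
              pixel_size_um = pixel_size_um, fixation = fixation,
              panel = panel, instances = insts)
}
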