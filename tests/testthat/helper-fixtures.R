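# Shared fixtures and independent oracles, built in code at test time.

# Axis-aligned rectangle outline [x0,x1] x [y0,y1]
rect_outline <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

square_cell <- function(id, cls, x0, y0, side = 10, confidence = 1,
                        source = "manual") {
  cell_instance(id, cls, rect_outline(x0, y0, x0 + side, y0 + side),
                confidence = confidence, source = source)
}

test_frame <- function(instances = list(), side = 64, ps = 1,
                       panel = "panel2", fixation = "FFPE",
                       frame_id = "tf") {
  image_frame(frame_id, side, side, ps, fixation, panel,
              instances = instances)
}

# Random star-shaped polygon (guaranteed simple)
star_outline <- function(cx, cy, rmin, rmax, nv = 12) {
  th <- sort(stats::runif(nv, 0, 2 * pi))
  r <- stats::runif(nv, rmin, rmax)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Brute-force oracle for one-to-one same-class matching: enumerates all
# assignments, maximizing pair count then total IOU. iou_mat rows = truth,
# cols = pred; inadmissible entries (class mismatch) must be -1.
brute_force_match <- function(iou_mat, theta) {
  nt <- nrow(iou_mat); np <- ncol(iou_mat)
  best_count <- 0L; best_total <- 0
  used <- logical(np)
  rec <- function(i, count, total) {
    if (i > nt) {
      if (count > best_count ||
          (count == best_count && total > best_total + 1e-12)) {
        best_count <<- count; best_total <<- total
      }
      return(invisible())
    }
    rec(i + 1L, count, total)
    for (j in seq_len(np)) {
      if (!used[j] && iou_mat[i, j] >= theta) {
        used[j] <<- TRUE
        rec(i + 1L, count + 1L, total + iou_mat[i, j])
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0L, 0)
  list(count = best_count, total = best_total)
}

# Admissible IOU matrix between two frames via the public raster API
frame_iou_matrix <- function(truth, pred) {
  nt <- length(truth$instances); np <- length(pred$instances)
  m <- matrix(-1, nt, np)
  tm <- lapply(truth$instances, rasterize, frame = truth)
  pm <- lapply(pred$instances, rasterize, frame = pred)
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      if (truth$instances[[i]]$cell_class == pred$instances[[j]]$cell_class) {
        m[i, j] <- iou(tm[[i]], pm[[j]])
      }
    }
  }
  m
}

# A random frame pair with <= max_cells cells each, crowded enough that
# matchings are ambiguous
random_frame_pair <- function(max_cells = 6, side = 64,
                              classes = c("CD4T", "mDC")) {
  mk <- function(n, src) {
    insts <- lapply(seq_len(n), function(k) {
      cell_instance(paste0(src, k), sample(classes, 1),
                    star_outline(stats::runif(1, 15, side - 15),
                                 stats::runif(1, 15, side - 15),
                                 4, 11),
                    confidence = 1,
                    source = if (src == "t") "manual" else "predicted")
    })
    insts
  }
  nt <- sample.int(max_cells, 1); np <- sample.int(max_cells, 1)
  panel <- "panel1-mDC"
  list(truth = test_frame(mk(nt, "t"), side, panel = panel),
       pred = test_frame(mk(np, "p"), side, panel = panel))
}

# Brute-force two-sample KS statistic: sup of |ECDF difference| over all
# observed values
ks_D_bruteforce <- function(x, y) {
  g <- c(x, y)
  Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
  max(abs(Fx(g) - Fy(g)))
}

# Small simulation configs reused across tests
small_tissue_config <- function(n_frames = 4, seed = 11,
                                cells_per_frame = 20, ...) {
  tissue_config(panel = "panel2", pixel_size_um = 0.1058, fixation = "FFPE",
                n_frames = n_frames, cells_per_frame = cells_per_frame,
                class_mixture = c(CD4T = 0.35, CD4negT = 0.27, mDC = 0.07,
                                  pDC = 0.08, Bcell = 0.23),
                seed = seed, ...)
}

# Counts printed in the cell-census fixture shipped with the package
table6_counts <- function() {
  utils::read.csv(system.file("extdata", "table6_counts.csv",
                              package = "immunoseg"),
                  stringsAsFactors = FALSE)
}

row_counts <- function(tbl, ds, src) {
  r <- tbl[tbl$dataset == ds & tbl$source == src, ]
  cn <- c("CD4T", "CD4negT", "mDC", "pDC", "Bcell")
  counts <- unlist(r[cn])
  counts <- counts[!is.na(counts)]
  list(counts = counts, images = r$total_images)
}
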