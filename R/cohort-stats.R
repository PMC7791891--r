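# Comparative statistics between cohorts: two-sample Kolmogorov-Smirnov
# tests, percent change of means, population tables, and reproducible
# train/validation/test splits.

#' Round half away from zero at a given number of decimals
#'
#' Population tables are printed with round-half-up at the displayed
#' precision (1 decimal for cells/image, 2 for percentages), unlike base
#' R's round-half-even.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over t of |ECDF_x(t) - ECDF_y(t)|. By default the
#' p-value comes from the asymptotic Kolmogorov distribution with
#' effective sample size n_x n_y / (n_x + n_y), which is the appropriate
#' regime for the cohort-scale samples the package compares; `exact = TRUE`
#' requests the exact small-sample distribution.
#'
#' @param x,y numeric samples (each nonempty)
#' @param exact use the exact p-value computation
#' @return list with `D`, `p_value`, `n_x`, `n_y`
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Percent change of means between a reference and a comparison sample
#'
#' 100 (mean(reference) - mean(comparison)) / mean(reference); positive
#' values are reductions relative to the reference (e.g. the shrinkage of
#' FFPE cells relative to fresh-frozen).
#'
#' @param reference,comparison numeric samples
#' @return percent change (positive = reduction)
#' @export
percent_change_of_means <- function(reference, comparison) {
  m_a <- mean(reference, na.rm = TRUE)
  if (!is.finite(m_a) || m_a == 0) {
    stop("reference sample mean is zero or undefined", call. = FALSE)
  }
  100 * (m_a - mean(comparison, na.rm = TRUE)) / m_a
}

#' Population table: counts, percentages and cells per image
#'
#' Summarises a cohort (or a named count vector) in the layout of a cell
#' census table: total cells, total images, average cells per image
#' (printed at 1 decimal) and per-class counts with percentage of total
#' (printed at 2 decimals), both rounded half-up.
#'
#' @param x a [cohort_dataset()], or a named integer vector of per-class
#'   counts
#' @param total_images number of images (required when `x` is a count
#'   vector)
#' @param name dataset label
#' @return an object of class `population_table`: data.frame (cell_class,
#'   count, percent, percent_printed) with attributes `total_cells`,
#'   `total_images`, `avg_cells_per_image`, `avg_cells_per_image_printed`,
#'   `name`
#' @export
population_table <- function(x, total_images = NULL, name = NULL) {
  if (inherits(x, "cohort_dataset")) {
    if (is.null(total_images)) total_images <- length(x$frames)
    if (is.null(name)) name <- x$name
    cls <- unlist(lapply(x$frames, function(f) {
      vapply(f$instances, function(z) z$cell_class, character(1))
    }))
    classes <- intersect(cell_classes(),
                         unique(unlist(lapply(x$frames,
                                              function(f) panel_classes(f$panel)))))
    counts <- vapply(classes, function(cl) sum(cls == cl), numeric(1))
  } else {
    counts <- x
    if (is.null(names(counts))) {
      stop("count vector must be named by cell class", call. = FALSE)
    }
  }
  if (is.null(total_images) || total_images < 1) {
    stop("total_images must be >= 1", call. = FALSE)
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_, length(counts))
  if (total == 0) warning("cohort contains no cells; percentages undefined")
  out <- data.frame(
    cell_class = names(counts),
    count = as.numeric(counts),
    percent = as.numeric(pct),
    percent_printed = round_half_up(as.numeric(pct), 2),
    stringsAsFactors = FALSE
  )
  attr(out, "total_cells") <- total
  attr(out, "total_images") <- total_images
  attr(out, "avg_cells_per_image") <- total / total_images
  attr(out, "avg_cells_per_image_printed") <-
    round_half_up(total / total_images, 1)
  attr(out, "name") <- name
  class(out) <- c("population_table", "data.frame")
  out
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table%s> %g cells / %g images = %.1f cells/image\n",
              if (!is.null(attr(x, "name"))) paste0(" ", attr(x, "name")) else "",
              attr(x, "total_cells"), attr(x, "total_images"),
              attr(x, "avg_cells_per_image_printed")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Reproducible train/validation/test split of frames
#'
#' Frames are shuffled by `seed` and apportioned by largest-remainder
#' allocation of `ratios` x n, so each partition size differs from its
#' exact share by less than one frame. Splits operate at the image level:
#' frames from one biopsy may land in different partitions, which keeps
#' patient composition comparable across partitions at the cost of
#' non-independence between them.
#'
#' @param frame_ids character vector of frame identifiers
#' @param ratios positive ratios for (train, validation, test); must sum
#'   to 1
#' @param seed integer seed
#' @return data.frame (frame_id, partition) of class `split_assignment`
#'   with attributes `ratios` and `seed`
#' @export
split_dataset <- function(frame_ids,
                          ratios = c(train = 0.9, validation = 0.05,
                                     test = 0.05),
                          seed = 1) {
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be positive and sum to 1", call. = FALSE)
  }
  if (is.null(names(ratios))) names(ratios) <- c("train", "validation", "test")
  n <- length(frame_ids)
  exact <- ratios * n
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  partition <- rep(names(ratios), times = sizes)
  out <- data.frame(frame_id = frame_ids[perm], partition = partition,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$frame_id, frame_ids)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  attr(out, "seed") <- seed
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Compare feature distributions between two cohorts
#'
#' For each morphometric feature (area, perimeter, equivalent diameter)
#' within each cell class, plus the nearest-DC distance of T cells and the
#' prediction confidence of all cells, computes sample sizes, means,
#' percent change of means (cohort A as reference; positive = reduction)
#' and a two-sample Kolmogorov-Smirnov test. Comparisons where either
#' sample has fewer than 10 observations are flagged `small_sample`; no
#' multiple-testing correction is applied and the number of tests is
#' recorded in the `n_tests` attribute.
#'
#' @param features_a,features_b outputs of [cohort_features()]
#' @param label_a,label_b group labels for the report
#' @param features which morphometry columns to compare
#' @return data.frame of class `comparison_result` with one row per
#'   feature x class
#' @export
compare_fixations <- function(features_a, features_b,
                              label_a = "A", label_b = "B",
                              features = c("area_um2", "perimeter_um",
                                           "equivalent_diameter_um")) {
  ma <- features_a$morphometry; mb <- features_b$morphometry
  for (f in features) {
    if (!f %in% names(ma) || !f %in% names(mb)) {
      stop("feature column missing from morphometry tables: ", f,
           call. = FALSE)
    }
  }
  one <- function(feature, cls, xa, xb) {
    if (!length(xa) || !length(xb)) return(NULL)
    kt <- ks_two_sample(xa, xb)
    data.frame(
      feature = feature, cell_class = cls,
      group_a = label_a, group_b = label_b,
      n_a = length(xa), n_b = length(xb),
      mean_a = mean(xa), mean_b = mean(xb),
      percent_change = percent_change_of_means(xa, xb),
      ks_D = kt$D, p_value = kt$p_value,
      small_sample = length(xa) < 10 || length(xb) < 10,
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  classes <- intersect(cell_classes(),
                       union(ma$cell_class, mb$cell_class))
  for (f in features) {
    for (cl in classes) {
      rows[[length(rows) + 1L]] <-
        one(f, cl, ma[[f]][ma$cell_class == cl], mb[[f]][mb$cell_class == cl])
    }
  }
  pa <- features_a$proximity; pb <- features_b$proximity
  rows[[length(rows) + 1L]] <-
    one("min_distance_to_dc_um", "Tcells", pa$distance_um, pb$distance_um)
  rows[[length(rows) + 1L]] <-
    one("confidence", "all", ma$confidence, mb$confidence)
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("comparison_result", "data.frame")
  out
}
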