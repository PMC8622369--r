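#' Labeled image dataset
#'
#' The container every stage of the pipeline consumes and produces: a batch
#' of RGB images with intensities in \[0, 1\] plus one class label per image.
#' Images are held as an `H x W x 3 x M` array (`M` = number of samples);
#' labels are integers in `1..N` indexing `class_names`.
#'
#' @param images numeric array of dimension `H x W x 3 x M`, values in
#'   \[0, 1\].
#' @param labels integer vector of length `M` with values in `1..N`.
#' @param class_names character vector of the `N` class names.
#' @return An object of class `image_dataset` with elements `images`,
#'   `labels` and `class_names`.
#' @export
image_dataset <- function(images, labels, class_names) {
  d <- dim(images)
  if (length(d) != 4L || d[3L] != 3L)
    stop("`images` must be an H x W x 3 x M array", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != d[4L])
    stop("length(labels) must equal the number of images", call. = FALSE)
  if (any(labels < 1L) || any(labels > length(class_names)))
    stop("every label must index `class_names`", call. = FALSE)
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names)),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_dataset> %d images, %dx%dx%d, %d classes (%s)\n",
              d[4L], d[1L], d[2L], d[3L], length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

n_images <- function(ds) dim(ds$images)[4L]
img_height <- function(ds) dim(ds$images)[1L]
img_width <- function(ds) dim(ds$images)[2L]

subset_dataset <- function(ds, idx) {
  image_dataset(ds$images[, , , idx, drop = FALSE], ds$labels[idx],
                ds$class_names)
}

#' Load a class-folder tree of images
#'
#' Reads `root/<class>/<file>.png` (or `.jpg`/`.jpeg` when a JPEG reader is
#' installed) into an [image_dataset]. Class labels follow the lexicographic
#' order of the subfolder names so the assignment does not depend on
#' filesystem enumeration order; 8-bit intensities are scaled to \[0, 1\]
#' (value / 255). Grayscale images are expanded to RGB; alpha channels are
#' dropped. All images must share one size.
#'
#' @param root path to a directory whose subdirectories are the classes.
#' @return An [image_dataset].
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE))
  if (length(classes) == 0L)
    stop("no class subfolders under ", root, call. = FALSE)
  files <- list(); labels <- integer()
  for (i in seq_along(classes)) {
    f <- sort(list.files(file.path(root, classes[i]),
                         pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                         full.names = TRUE))
    files <- c(files, as.list(f))
    labels <- c(labels, rep.int(i, length(f)))
  }
  if (length(files) == 0L)
    stop("no decodable PNG/JPEG images under ", root, call. = FALSE)
  imgs <- lapply(files, read_rgb_image)
  hw <- vapply(imgs, function(im) dim(im)[1:2], integer(2L))
  if (any(hw[1L, ] != hw[1L, 1L]) || any(hw[2L, ] != hw[2L, 1L]))
    stop("images of differing sizes found; all images must share one HxW",
         call. = FALSE)
  arr <- array(0, c(hw[1L, 1L], hw[2L, 1L], 3L, length(imgs)))
  for (k in seq_along(imgs)) arr[, , , k] <- imgs[[k]]
  image_dataset(arr, labels, classes)
}

read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    im <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package: ", path, call. = FALSE)
    eb <- EBImage::readImage(path)
    im <- aperm(as.array(eb), if (length(dim(eb)) == 3L) c(2L, 1L, 3L)
                else c(2L, 1L))
  }
  if (length(dim(im)) == 2L) im <- array(im, c(dim(im), 1L))
  if (dim(im)[3L] == 1L) im <- im[, , c(1L, 1L, 1L), drop = FALSE]
  im[, , 1:3, drop = FALSE]
}

#' Stratified train/validation split
#'
#' Randomly holds out `round(fraction * class size)` samples per class
#' (at least one) for validation; the split is stratified so every class is
#' represented even under heavy imbalance, and reproducible from `seed`.
#'
#' @param ds an [image_dataset].
#' @param fraction validation fraction in (0, 1); default `0.1`.
#' @param seed integer seed controlling the permutation.
#' @return A list with elements `train`, `validation` (both
#'   [image_dataset]s) and `fraction_validation`.
#' @export
split_train_validation <- function(ds, fraction = 0.1, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  counts <- tabulate(ds$labels, nbins = length(ds$class_names))
  present <- which(counts > 0L)
  if (any(counts[present] < 2L))
    stop("every class needs at least 2 samples to split", call. = FALSE)
  val_idx <- with_seed(seed, {
    unlist(lapply(present, function(cl) {
      idx <- which(ds$labels == cl)
      n_val <- max(1L, round(fraction * length(idx)))
      sample(idx, n_val)
    }), use.names = FALSE)
  })
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_len(n_images(ds)), val_idx)
  structure(list(train = subset_dataset(ds, train_idx),
                 validation = subset_dataset(ds, val_idx),
                 fraction_validation = fraction),
            class = "split_datasets")
}

#' Metric tables (blocks x treatments)
#'
#' A complete `n x k` matrix of one performance metric, rows indexed by
#' experimental blocks (here: dataset x classifier pairs) and columns by
#' treatments (preprocessing approaches). This is the input format of the
#' aligned-ranks comparison in [aligned_ranks()].
#'
#' @param values numeric `n x k` matrix without missing entries.
#' @param block_labels,treatment_labels row / column labels.
#' @param metric_name name of the metric the cells hold.
#' @param higher_is_better logical; `TRUE` when larger values are better.
#' @return An object of class `metric_table`.
#' @export
metric_table <- function(values, block_labels = rownames(values),
                         treatment_labels = colnames(values),
                         metric_name = "metric", higher_is_better = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a metric table needs at least one block and one treatment",
         call. = FALSE)
  if (anyNA(values) || !is.numeric(values))
    stop("metric table cells must all be numeric and non-missing",
         call. = FALSE)
  if (is.null(block_labels)) block_labels <- paste0("block", seq_len(nrow(values)))
  if (is.null(treatment_labels))
    treatment_labels <- paste0("treatment", seq_len(ncol(values)))
  dimnames(values) <- list(block_labels, treatment_labels)
  structure(list(values = values, block_labels = block_labels,
                 treatment_labels = treatment_labels,
                 metric_name = metric_name,
                 higher_is_better = isTRUE(higher_is_better)),
            class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> %s (%s is better), %d blocks x %d treatments\n",
              x$metric_name, if (x$higher_is_better) "higher" else "lower",
              nrow(x$values), ncol(x$values)))
  print(x$values)
  invisible(x)
}

#' Read / write a metric table as CSV
#'
#' The CSV carries the treatment labels in the header, block labels in the
#' first column, and one numeric cell per (block, treatment); values round
#' trip at full printed precision. A ragged or non-numeric cell aborts with
#' the offending row named.
#'
#' @param path CSV file path.
#' @param metric_name,higher_is_better metadata attached on read.
#' @return [read_metric_table()] returns a [metric_table];
#'   [write_metric_table()] invisibly returns `path`.
#' @export
read_metric_table <- function(path, metric_name = "metric",
                              higher_is_better = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("metric table CSV needs a header and >= 1 row",
                               call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- length(cells[[1L]])
  treatments <- trimws(cells[[1L]][-1L])
  vals <- matrix(NA_real_, length(lines) - 1L, ncols - 1L)
  blocks <- character(length(lines) - 1L)
  for (i in seq_len(length(lines) - 1L)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncols)
      stop(sprintf("row %d of %s has %d fields, expected %d",
                   i + 1L, path, length(row), ncols), call. = FALSE)
    blocks[i] <- trimws(row[1L])
    v <- suppressWarnings(as.numeric(trimws(row[-1L])))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric or missing cell at row %d, column '%s' of %s",
                   i + 1L, treatments[bad], path), call. = FALSE)
    }
    vals[i, ] <- v
  }
  metric_table(vals, blocks, treatments, metric_name, higher_is_better)
}

#' @rdname read_metric_table
#' @param table a [metric_table] to serialise.
#' @export
write_metric_table <- function(table, path) {
  stopifnot(inherits(table, "metric_table"))
  header <- paste(c("block", table$treatment_labels), collapse = ",")
  rows <- vapply(seq_len(nrow(table$values)), function(i) {
    paste(c(table$block_labels[i],
            format(table$values[i, ], digits = 15, trim = TRUE,
                   scientific = FALSE)),
          collapse = ",")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Combine per-dataset metric tables into one blocked table
#'
#' Stacks tables that share the same treatments, prefixing block labels with
#' the table names, e.g. blocks `plant/VGG`, `skin/VGG`, ... This produces
#' the `n = datasets x classifiers` block structure consumed by the
#' aligned-ranks comparison.
#'
#' @param tables named list of [metric_table]s with identical treatment
#'   labels.
#' @return A single [metric_table].
#' @export
combine_metric_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  tl <- tables[[1L]]$treatment_labels
  for (t in tables)
    if (!identical(t$treatment_labels, tl))
      stop("all tables must share the same treatment labels", call. = FALSE)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("table", seq_along(tables))
  vals <- do.call(rbind, lapply(tables, function(t) t$values))
  blocks <- unlist(lapply(seq_along(tables), function(i)
    paste(nm[i], tables[[i]]$block_labels, sep = "/")), use.names = FALSE)
  metric_table(vals, blocks, tl, tables[[1L]]$metric_name,
               tables[[1L]]$higher_is_better)
}

#' Bundled benchmark metric tables
#'
#' The package ships the published benchmark results it was validated
#' against: accuracy, geometric-mean and AUC tables for three image
#' classification case studies (plant disease, skin cancer, deepfake face
#' detection), each evaluated with four CNN backbones (VGG, ResNet,
#' DenseNet, MobileNet) under the three preprocessing approaches
#' (Traditional, MD, CAE). `benchmark_table()` returns the combined
#' 12-block table for one metric.
#'
#' @param metric one of `"accuracy"`, `"gm"`, `"auc"`.
#' @return A [metric_table] with 12 blocks and 3 treatments.
#' @export
benchmark_table <- function(metric = c("accuracy", "gm", "auc")) {
  metric <- match.arg(metric)
  datasets <- c("plant", "skin", "deepfake")
  tabs <- lapply(datasets, function(d) {
    path <- system.file("extdata", sprintf("%s_%s.csv", d, metric),
                        package = "caecnn", mustWork = TRUE)
    read_metric_table(path, metric_name = metric, higher_is_better = TRUE)
  })
  names(tabs) <- datasets
  combine_metric_tables(tabs)
}
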