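# Occupancy featurization: tag binning, [0,1] normalization, model-facing
# flattening, and a seekable binary tensor container.

#' Bin tag positions over a window
#'
#' Counts tags falling in consecutive `bin_width` bp bins of a half-open
#' window: entry `k` counts tags with position in
#' `[start + (k-1)*bw, start + k*bw)`. With the 1 kb / 10 bp defaults this is
#' the length-100 occupancy vector used throughout.
#'
#' @param tag_positions Integer vector of tag bp positions on the window's
#'   chromosome (e.g. read 5' ends), any order.
#' @param window One-row interval data.frame (`chrom`, `start`, `end`).
#' @param bin_width Bin width in bp (default 10); must divide the window
#'   width.
#' @return Integer count vector of length `width / bin_width`.
#' @export
bin_occupancy <- function(tag_positions, window, bin_width = 10L) {
  w <- window$end[1] - window$start[1]
  if (w %% bin_width != 0) {
    stop("window width ", w, " not divisible by bin_width ", bin_width,
         call. = FALSE)
  }
  n_bins <- w %/% bin_width
  inside <- tag_positions >= window$start[1] & tag_positions < window$end[1]
  if (!any(inside)) return(integer(n_bins))
  idx <- (tag_positions[inside] - window$start[1]) %/% bin_width + 1L
  as.integer(tabulate(idx, nbins = n_bins))
}

#' Read tag positions from a text file
#'
#' Accepts either BED3 (point or short intervals; the start coordinate is
#' taken as the tag position, e.g. a read 5' end) or a two-column
#' chrom/position table.
#'
#' @param path Tab-separated file path.
#' @return Named list mapping chromosome to a sorted integer vector of
#'   positions, the per-target format consumed by [occupancy_tensor()].
#' @export
read_tag_positions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("tag file needs at least 2 columns: ", path, call. = FALSE)
  pos <- as.integer(df[[2]])
  if (any(pos < 0)) stop("negative tag position in ", path, call. = FALSE)
  lapply(split(pos, as.character(df[[1]])), sort)
}

#' Build a raw count tensor for a set of windows
#'
#' @param tags Named list (one element per target) of per-chromosome sorted
#'   position lists, i.e. `tags[[target]][[chrom]]` is an integer vector of
#'   tag positions.
#' @param windows Interval data.frame of equal-width windows.
#' @param bin_width Bin width in bp (default 10).
#' @return Array of counts, samples x targets x bins.
#' @export
occupancy_tensor <- function(tags, windows, bin_width = 10L) {
  n <- nrow(windows)
  n_t <- length(tags)
  w <- windows$end[1] - windows$start[1]
  n_b <- w %/% bin_width
  out <- array(0, dim = c(n, n_t, n_b))
  for (t in seq_len(n_t)) {
    for (i in seq_len(n)) {
      pos <- tags[[t]][[windows$chrom[i]]]
      if (is.null(pos)) next
      out[i, t, ] <- bin_occupancy(pos, windows[i, , drop = FALSE], bin_width)
    }
  }
  dimnames(out) <- list(NULL, names(tags), NULL)
  out
}

#' Normalize a count tensor to [0,1] per target
#'
#' Divides each target's values by that target's global maximum over all
#' samples and bins (targets that are all zero stay zero), bounding the
#' tensor to `[0,1]`. The per-target scale factors are recorded so the map
#' is invertible.
#'
#' @param raw Numeric array, samples x targets x bins, non-negative.
#' @return An `occupancy_tensor` object: list with `values` (normalized
#'   array), `scales` (per-target max), plus optional metadata fields
#'   (`windows`, `target_names`, `bin_width`) carried by callers.
#' @export
normalize_tensor <- function(raw) {
  if (any(raw < 0)) stop("raw counts must be non-negative", call. = FALSE)
  n_t <- dim(raw)[2]
  scales <- vapply(seq_len(n_t), function(t) max(raw[, t, ]), numeric(1))
  values <- raw
  for (t in seq_len(n_t)) {
    if (scales[t] > 0) values[, t, ] <- raw[, t, ] / scales[t]
  }
  structure(list(values = values, scales = scales), class = "occupancy_tensor")
}

#' Invert per-target max normalization
#'
#' @param tensor An `occupancy_tensor` from [normalize_tensor()].
#' @return The original raw array.
#' @export
denormalize_tensor <- function(tensor) {
  raw <- tensor$values
  for (t in seq_along(tensor$scales)) {
    if (tensor$scales[t] > 0) raw[, t, ] <- raw[, t, ] * tensor$scales[t]
  }
  raw
}

#' Flatten one sample to the model-facing vector layout
#'
#' Target-major concatenation: all bins of target 1, then target 2, etc.
#' Length is `targets * bins`. The same layout is used by the swarm attack
#' and the attribution methods, so any flat feature index maps back to a
#' unique (target, bin) pair.
#'
#' @param tensor Array samples x targets x bins (or an `occupancy_tensor`).
#' @param sample_index Which sample to flatten.
#' @return Numeric vector of length `targets * bins`.
#' @export
flatten_for_model <- function(tensor, sample_index) {
  values <- if (inherits(tensor, "occupancy_tensor")) tensor$values else tensor
  m <- values[sample_index, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(values)[2])
  as.vector(t(m))
}

#' Flatten all samples to a model input matrix
#'
#' @inheritParams flatten_for_model
#' @return Matrix samples x (targets * bins), target-major columns.
#' @export
flatten_all <- function(tensor) {
  values <- if (inherits(tensor, "occupancy_tensor")) tensor$values else tensor
  d <- dim(values)
  # (n, T, B) -> columns ordered (t-1)*B + b
  m <- aperm(values, c(1, 3, 2))       # n x B x T
  dim(m) <- c(d[1], d[2] * d[3])       # columns: b fastest within t
  m
}

#' Invert [flatten_for_model()] / [flatten_all()]
#'
#' @param x Flat vector (length `n_targets * n_bins`) or matrix
#'   (samples x that length).
#' @param n_targets,n_bins Tensor shape.
#' @return Array samples x targets x bins (a 1-sample array for a vector).
#' @export
unflatten <- function(x, n_targets, n_bins) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == n_targets * n_bins)
  a <- x
  dim(a) <- c(nrow(x), n_bins, n_targets)
  aperm(a, c(1, 3, 2))
}

# ---- tensor container -------------------------------------------------------
# Binary layout: magic line, JSON header line (shape, targets, bin width,
# scales, labels, window table, endianness), then samples * targets * bins
# doubles in sample-major order. The header carries the byte offset of the
# payload so single samples can be read by seeking.

.CONTAINER_MAGIC <- "chromswarm-tensor-v1"

#' Save an occupancy tensor container
#'
#' Losslessly persists values, labels, window coordinates, target names, and
#' normalization scales in a single binary file with per-sample random
#' access.
#'
#' @param tensor Array samples x targets x bins, or `occupancy_tensor`.
#' @param path Output path.
#' @param labels Optional 0/1 label vector (length = samples).
#' @param windows Optional window data.frame.
#' @param target_names Optional character vector.
#' @param scales Optional per-target normalization factors.
#' @param bin_width Bin width in bp (default 10).
#' @return `path`, invisibly.
#' @export
save_container <- function(tensor, path, labels = NULL, windows = NULL,
                           target_names = NULL, scales = NULL,
                           bin_width = 10L) {
  if (inherits(tensor, "occupancy_tensor")) {
    if (is.null(scales)) scales <- tensor$scales
    tensor <- tensor$values
  }
  d <- dim(tensor)
  if (length(d) != 3) stop("tensor must be samples x targets x bins", call. = FALSE)
  if (is.null(target_names)) target_names <- paste0("target", seq_len(d[2]))
  header <- list(
    magic = .CONTAINER_MAGIC,
    shape = as.integer(d),
    target_names = target_names,
    bin_width = as.integer(bin_width),
    scales = scales,
    labels = labels,
    windows = windows,
    endian = "little"
  )
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(.CONTAINER_MAGIC, as.character(hjson)), con)
  # sample-major, target-major within sample: sample i occupies a contiguous
  # run of targets*bins doubles in flatten_for_model() order
  flat <- flatten_all(tensor)
  writeBin(as.vector(t(flat)), con, size = 8, endian = "little")
  invisible(path)
}

.read_container_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(magic, .CONTAINER_MAGIC)) {
    stop("not a chromswarm tensor container (bad magic)", call. = FALSE)
  }
  header <- jsonlite::fromJSON(readLines(con, n = 1), simplifyVector = TRUE)
  header$offset <- seek(con)
  header
}

#' Load an occupancy tensor container
#'
#' @param path Container path.
#' @param samples Optional integer vector of sample indices; when given, only
#'   those samples are read (by seeking), not the full tensor.
#' @return List with `values` (samples x targets x bins), `labels`,
#'   `windows`, `target_names`, `scales`, `bin_width`.
#' @export
load_container <- function(path, samples = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_container_header(con)
  d <- h$shape
  per <- d[2] * d[3]
  if (is.null(samples)) {
    vals <- readBin(con, "double", n = d[1] * per, size = 8, endian = "little")
    if (length(vals) < d[1] * per) stop("truncated container: ", path, call. = FALSE)
    flat <- matrix(vals, nrow = d[1], byrow = TRUE)
    idx <- seq_len(d[1])
  } else {
    samples <- as.integer(samples)
    if (any(samples < 1 | samples > d[1])) stop("sample index out of range", call. = FALSE)
    flat <- matrix(0, nrow = length(samples), ncol = per)
    for (i in seq_along(samples)) {
      seek(con, where = h$offset + 8 * per * (samples[i] - 1L), origin = "start")
      v <- readBin(con, "double", n = per, size = 8, endian = "little")
      if (length(v) < per) stop("truncated container: ", path, call. = FALSE)
      flat[i, ] <- v
    }
    idx <- samples
  }
  windows <- h$windows
  if (!is.null(windows)) {
    windows <- as.data.frame(windows, stringsAsFactors = FALSE)[idx, , drop = FALSE]
    rownames(windows) <- NULL
  }
  list(
    values = unflatten(flat, d[2], d[3]),
    labels = if (!is.null(h$labels)) h$labels[idx] else NULL,
    windows = windows,
    target_names = h$target_names,
    scales = h$scales,
    bin_width = h$bin_width
  )
}
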