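# File I/O: multi-page 16-bit TIFF stacks, JSON ground truth/configs, CSV
# tables. Stacks are numeric arrays [height, width, frame] in counts;
# on disk they are 16-bit grayscale with a recorded max-count scale.

#' Write a time-lapse stack as a multi-page 16-bit TIFF
#'
#' @param stack numeric array `[h, w, n_frames]`, counts.
#' @param path output file.
#' @param max_count full-scale count mapped to 65535; defaults to the stack
#'   maximum.
#' @return Invisibly, `max_count` (needed to restore counts on reading).
#' @export
write_stack_tiff <- function(stack, path, max_count = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (is.null(max_count)) max_count <- max(stack)
  if (max_count <= 0) max_count <- 1
  pages <- lapply(seq_len(dim(stack)[3]), function(i) {
    pmin(pmax(stack[, , i] / max_count, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(max_count)
}

#' Read a multi-page TIFF stack back into a count array
#'
#' @param path TIFF file.
#' @param max_count the scale used when writing (counts at full scale).
#' @return Numeric array `[h, w, n_frames]`.
#' @export
read_stack_tiff <- function(path, max_count = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra channels
    p * max_count
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Serialize scene/pore ground truth to JSON
#'
#' @param truth a `scene_truth` or `pore_truth` object.
#' @param path output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  cls <- class(truth)[1]
  obj <- unclass(truth)
  if (!is.null(obj$params)) {
    obj$params <- lapply(obj$params, unclass)
  }
  jsonlite::write_json(list(type = cls, data = obj), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
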