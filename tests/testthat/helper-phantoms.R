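# Shared phantom builders: binary disks/rectangles with known geometry,
# used by the shape-extraction, photometry and morphometry tests.

make_disk <- function(r, bg = 50, value = 200, n = 2 * r + 41, cx = NULL,
                      cy = NULL) {
  if (is.null(cx)) cx <- (n - 1) / 2
  if (is.null(cy)) cy <- (n - 1) / 2
  M <- matrix(bg, n, n)
  for (i in seq_len(n)) {
    dx2 <- ((seq_len(n) - 1) - cx)^2
    M[i, dx2 + ((i - 1) - cy)^2 <= r^2] <- value
  }
  list(img = M, center = c(cx, cy), r = r)
}

make_rect <- function(w, h, bg = 50, value = 200, n = max(w, h) + 41) {
  M <- matrix(bg, n, n)
  r0 <- floor((n - h) / 2); c0 <- floor((n - w) / 2)
  M[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- value
  list(img = M, center = c(c0 + w / 2 - 0.5, r0 + h / 2 - 0.5), w = w, h = h)
}

# binary pore mask with disks at given centers (0-based) and radius
make_pore_mask <- function(centers, r, height, width) {
  M <- matrix(FALSE, height, width)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    for (i in seq_len(height)) {
      dx2 <- ((seq_len(width) - 1) - cx)^2
      M[i, dx2 + ((i - 1) - cy)^2 <= r^2] <- TRUE
    }
  }
  M
}
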