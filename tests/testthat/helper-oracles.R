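# Independent brute-force oracles used across the test files. These are kept
# deliberately naive (explicit loops, direct definitions) and share no code
# with the implementation they check.

# pair-enumeration GLCM: walk every position, test bounds, count
naive_glcm <- function(img, offset, L, symmetric = FALSE, normalize = FALSE) {
  d <- dim(img)
  raw <- matrix(0, L, L)
  if (length(d) == 2L) {
    for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= d[1] && c2 >= 1 && c2 <= d[2]) {
        a <- img[r, c]; b <- img[r2, c2]
        raw[a + 1, b + 1] <- raw[a + 1, b + 1] + 1
      }
    }
  } else {
    for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
      s2 <- s + offset[1]; r2 <- r + offset[2]; c2 <- c + offset[3]
      if (s2 >= 1 && s2 <= d[1] && r2 >= 1 && r2 <= d[2] &&
          c2 >= 1 && c2 <= d[3]) {
        a <- img[s, r, c]; b <- img[s2, r2, c2]
        raw[a + 1, b + 1] <- raw[a + 1, b + 1] + 1
      }
    }
  }
  if (symmetric) raw <- raw + t(raw)
  if (normalize && sum(raw) > 0) raw <- raw / sum(raw)
  raw
}

# per-pixel sort-and-pick median filter with symmetric (edge-included) padding
naive_median_slice <- function(img, w) {
  p <- (w - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- function(n) c(rev(seq_len(p)), seq_len(n), n + 1L - seq_len(p))
  padded <- img[pad(nr), pad(nc)]
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- padded[r:(r + 2L * p), c:(c + 2L * p)]
    out[r, c] <- sort(as.vector(win))[(w * w + 1L) %/% 2L]
  }
  out
}

# AUC by exhaustive pair counting (ties count 1/2)
pair_count_auc <- function(is_pos, scores) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random quantized test image
rand_img <- function(dims, L) {
  array(sample(0:(L - 1L), prod(dims), replace = TRUE), dim = dims)
}

# three-mode intensity histogram at L = 64: the standard multi-level
# segmentation test condition (three tissue-like intensity populations)
three_mode_histogram <- function(seed = 99, L = 64L) {
  vals <- glcmfusion:::with_seed(seed, {
    v <- c(round(stats::rnorm(3000, 12, 4)),
           round(stats::rnorm(3000, 32, 5)),
           round(stats::rnorm(3000, 52, 4)))
    as.integer(pmin(pmax(v, 0), L - 1L))
  })
  gray_histogram(vals, L = L)
}
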