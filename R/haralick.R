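#' Haralick texture descriptors of a normalized GLCM
#'
#' Sixteen scalar texture summaries of a normalized co-occurrence matrix
#' `p(i, j)` (gray levels 0-based), in this fixed order:
#'
#'  1. `energy` — angular second moment, `sum p^2`
#'  2. `contrast` — `sum (i - j)^2 p`
#'  3. `correlation` — `(sum i j p - mu_x mu_y) / (sd_x sd_y)` (0 when a
#'     marginal sd is 0)
#'  4. `variance` — sum of squares, `sum (i - mu_x)^2 p`
#'  5. `idm` — inverse difference moment, `sum p / (1 + (i - j)^2)`
#'  6. `sum_average` — mean of the `i + j` distribution
#'  7. `sum_variance` — variance of the `i + j` distribution about
#'     `sum_average`
#'  8. `sum_entropy` — entropy (bits) of the `i + j` distribution
#'  9. `entropy` — `-sum p log2 p` (bits)
#' 10. `diff_variance` — variance of the `|i - j|` distribution
#' 11. `diff_entropy` — entropy (bits) of the `|i - j|` distribution
#' 12. `imc1` — information measure of correlation 1,
#'     `(HXY - HXY1) / max(HX, HY)` (natural logs; 0 when degenerate)
#' 13. `imc2` — information measure of correlation 2,
#'     `sqrt(1 - exp(-2 (HXY2 - HXY)))` (natural logs)
#' 14. `mcc` — maximal correlation coefficient, the square root of the
#'     second-largest eigenvalue of `Q(i, j) = sum_k p(i,k) p(j,k) /
#'     (p_x(i) p_y(k))`; defined as 0 when the support has fewer than two
#'     levels
#' 15. `max_prob` — `max p`
#' 16. `dissimilarity` — `sum |i - j| p`
#'
#' Entropies use the convention `0 log 0 = 0`.
#'
#' @param p a normalized `L x L` GLCM (entries sum to 1).
#' @return named numeric vector of length 16.
#' @export
haralick_descriptors <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) stop_param("`p` must be a square matrix")
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop_param("`p` must be a normalized GLCM (non-negative, summing to 1)")
  }
  L <- nrow(p)
  i <- matrix(0:(L - 1L), L, L)           # row index value
  j <- t(i)                               # col index value
  px <- rowSums(p); py <- colSums(p)
  lev <- 0:(L - 1L)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))

  # distributions of i + j (0 .. 2L-2) and |i - j| (0 .. L-1)
  psum <- vapply(0:(2L * L - 2L), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1L), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 0:(2L * L - 2L); kd <- 0:(L - 1L)

  ent2 <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  entn <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }

  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  variance <- sum((i - mu_x)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- ent2(psum)
  entropy <- ent2(p)
  diff_mean <- sum(kd * pdiff)
  diff_variance <- sum((kd - diff_mean)^2 * pdiff)
  diff_entropy <- ent2(pdiff)

  hxy <- entn(p)
  hx <- entn(px); hy <- entn(py)
  pxy_outer <- outer(px, py)
  nz <- p > 0 & pxy_outer > 0
  hxy1 <- -sum(p[nz] * log(pxy_outer[nz]))
  nz2 <- pxy_outer > 0
  hxy2 <- -sum(pxy_outer[nz2] * log(pxy_outer[nz2]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  sup_x <- which(px > 0); sup_y <- which(py > 0)
  mcc <- if (length(sup_x) < 2L || length(sup_y) < 2L) 0 else {
    ps <- p[sup_x, sup_y, drop = FALSE]
    q <- (ps / px[sup_x]) %*% t(ps / matrix(py[sup_y], nrow = length(sup_x),
                                            ncol = length(sup_y), byrow = TRUE))
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }

  max_prob <- max(p)
  dissimilarity <- sum(abs(i - j) * p)

  c(energy = energy, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy, entropy = entropy,
    diff_variance = diff_variance, diff_entropy = diff_entropy,
    imc1 = imc1, imc2 = imc2, mcc = mcc, max_prob = max_prob,
    dissimilarity = dissimilarity)
}
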