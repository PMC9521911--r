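#' Water strider position updates
#'
#' The water strider algorithm (WSA) evolves a population of candidate
#' threshold vectors. Positions are real-valued internally and decoded to
#' valid integer threshold vectors (see [decode_position]) whenever the Otsu
#' objective is evaluated. The update steps are pure functions of the
#' position and the supplied uniform draw, which keeps them directly
#' testable:
#'
#' * `mating_step`: with mating, `X + R * rand`; without, `X + R * (1 + rand)`
#'   where `R = female - X` is the signed displacement toward the territory's
#'   female (its norm is the male-female distance). The no-mating branch
#'   overshoots past the female.
#' * `foraging_step`: `X + 2 * rand * (X_BL - X)` toward the territory-best
#'   position `X_BL`; `rand = 0.5` lands exactly on `X_BL`.
#'
#' @param position numeric position vector (length `m`).
#' @param female,x_bl positions of the territory female / territory best.
#' @param mating logical: take the mating branch?
#' @param rand uniform \[0, 1\] draw(s): a scalar, or a length-`m` vector for
#'   per-coordinate updates (the optimizer draws one uniform per coordinate,
#'   which lets moves explore the full box between a strider and its target
#'   rather than only the connecting line segment).
#' @return the updated (real-valued) position.
#' @export
mating_step <- function(position, female, mating, rand) {
  if (length(position) != length(female)) {
    stop_param("position and female must have the same dimension")
  }
  R <- female - position
  if (isTRUE(mating)) position + R * rand else position + R * (1 + rand)
}

#' @rdname mating_step
#' @export
foraging_step <- function(position, x_bl, rand) {
  if (length(position) != length(x_bl)) {
    stop_param("position and x_bl must have the same dimension")
  }
  position + 2 * rand * (x_bl - position)
}

#' Larva replacement
#'
#' A failing water strider is replaced by a fresh larva sampled uniformly
#' inside the coordinate-wise min/max box spanned by its territory's members.
#' A single-member territory has a degenerate box, so the larva coincides
#' with that member.
#'
#' @param territory_positions numeric matrix, one row per territory member,
#'   `m` columns. Uses the session RNG (seed it for reproducibility).
#' @return a new position vector of length `m`.
#' @export
larva_replacement <- function(territory_positions) {
  tp <- as.matrix(territory_positions)
  if (nrow(tp) < 1L) stop_param("territory must have at least one member")
  lo <- apply(tp, 2L, min)
  hi <- apply(tp, 2L, max)
  lo + stats::runif(ncol(tp)) * (hi - lo)
}

#' Allocate striders to territories by fitness rank
#'
#' The population is ranked by fitness (best first, ties by index) and dealt
#' round-robin into `territories` groups, so each territory receives a spread
#' of solution qualities: with 6 striders and 3 territories, ranks 1 and 4 go
#' to territory 1, ranks 2 and 5 to territory 2, and so on.
#'
#' @param fitness numeric fitness values, one per strider.
#' @param territories number of territories (>= 1).
#' @return integer vector of territory indices, one per strider.
#' @export
allocate_territories <- function(fitness, territories) {
  territories <- as_count(territories, "territories")
  terr_of <- integer(length(fitness))
  rank_order <- order(fitness, decreasing = TRUE)  # ties: lowest index first
  terr_of[rank_order] <- rep_len(seq_len(territories), length(fitness))
  terr_of
}

#' Decode a real-valued position to a valid threshold vector
#'
#' Clips to \[1, L−1\], rounds, sorts ascending, and resolves duplicates by
#' incrementing collided coordinates upward; coordinates pushed past `L − 1`
#' are resampled uniformly among free levels (never wrapped). The result is
#' always a strictly increasing integer vector, defined whenever
#' `m <= L - 1`.
#'
#' @param position real-valued position of length `m`.
#' @param L gray-level count.
#' @return integer threshold vector of length `m`.
#' @export
decode_position <- function(position, L) {
  m <- length(position)
  if (m > L - 1L) stop_param("position longer than L - 1")
  r <- sort(pmin(pmax(round_half_away(position), 1), L - 1L))
  if (m > 1L) {
    for (j in 2:m) if (r[j] <= r[j - 1L]) r[j] <- r[j - 1L] + 1
  }
  over <- which(r > L - 1L)
  if (length(over) > 0L) {
    free <- setdiff(seq_len(L - 1L), r[-over])
    pick <- if (length(free) == length(over)) free else
      sample(free, length(over))
    r[over] <- pick
    r <- sort(r)
  }
  as.integer(r)
}

#' WSA-Otsu multi-level threshold segmentation
#'
#' Hybrid of multi-level Otsu thresholding and the water strider algorithm:
#' a population of candidate threshold vectors is evolved by territory
#' allocation, mating, foraging toward the territory best, and larva
#' replacement, scoring every candidate with [between_class_variance]. The
#' returned thresholds maximize the between-class variance found within the
#' iteration budget; on modest level counts the optimum matches
#' [exhaustive_otsu] while scaling to threshold counts where enumeration is
#' infeasible.
#'
#' One iteration, per water strider: (1) a mating move toward (or past) the
#' territory female, kept only if it strictly improves the objective;
#' (2) otherwise a foraging move toward the territory best, always taken;
#' (3) if the objective is still below the territory median, replacement by
#' a random larva inside the territory's bounding box. Territories are
#' re-allocated each iteration by dealing the fitness-ranked population
#' round-robin into `territories` groups; the best member of each territory
#' is its female. The best-so-far fitness trace is monotone non-decreasing
#' by construction.
#'
#' @param img a [ct_volume]/array in a quantized or gray8 domain, or a
#'   `gray_histogram`.
#' @param m threshold count, `1 <= m <= L - 1`.
#' @param pop_size population size (default 20).
#' @param territories number of territories `NT` (default 5).
#' @param max_iter iteration budget (default 100).
#' @param mating_prob probability of the mating branch (default 0.5).
#' @param seed optional integer seed; the session RNG state is restored
#'   afterwards. Identical seeds give identical runs.
#' @param best_of `"territory"` (default) steers foraging toward the
#'   territory best; `"global"` toward the global best.
#' @param L gray-level count when `img` carries none.
#' @return an object of class `wsa_otsu`: list with `thresholds`, `fitness`,
#'   `trace` (best fitness per iteration), `mask` (a [label_mask] when `img`
#'   was an image; `NULL` for bare histograms), `params`, and `histogram`.
#' @seealso [exhaustive_otsu], [apply_thresholds]
#' @export
wsa_otsu <- function(img, m, pop_size = 20L, territories = 5L, max_iter = 100L,
                     mating_prob = 0.5, seed = NULL,
                     best_of = c("territory", "global"), L = NULL) {
  best_of <- match.arg(best_of)
  h <- as_gray_histogram(img, L)
  m <- as_count(m, "m", min = 1L)
  if (m >= h$L) stop_param("m must be < L")
  pop_size <- as_count(pop_size, "pop_size")
  territories <- as_count(territories, "territories")
  max_iter <- as_count(max_iter, "max_iter")
  if (pop_size < territories) stop_param("pop_size must be >= territories")
  if (mating_prob < 0 || mating_prob > 1) stop_param("mating_prob must be in [0, 1]")

  runner <- function() {
    fit_of <- function(pos) between_class_variance(h, decode_position(pos, h$L))
    pos <- matrix(stats::runif(pop_size * m, 1, h$L - 1L), nrow = pop_size)
    fits <- apply(pos, 1L, fit_of)
    best_f <- max(fits)
    best_x <- pos[which.max(fits), , drop = TRUE]
    trace <- numeric(max_iter)
    for (it in seq_len(max_iter)) {
      terr_of <- allocate_territories(fits, territories)
      for (tr in seq_len(territories)) {
        members <- which(terr_of == tr)
        if (length(members) == 0L) next
        tfits <- fits[members]
        female_idx <- members[which.max(tfits)]
        female <- pos[female_idx, , drop = TRUE]
        xbl <- if (best_of == "global") best_x else female
        tmed <- stats::median(tfits)
        box <- pos[members, , drop = FALSE]
        for (i in members) {
          cand <- mating_step(pos[i, ], female,
                              mating = stats::runif(1) < mating_prob,
                              rand = stats::runif(m))
          f_cand <- fit_of(cand)
          if (f_cand > fits[i]) {            # strict improvement keeps the move
            pos[i, ] <- cand
            fits[i] <- f_cand
          } else {
            old_dec <- decode_position(pos[i, ], h$L)
            pos[i, ] <- foraging_step(pos[i, ], xbl, stats::runif(m))
            fits[i] <- fit_of(pos[i, ])
            if (fits[i] < tmed) {            # still low: replace by a larva
              larva <- larva_replacement(box)
              # a larva indistinguishable from the stagnant position means the
              # territory has collapsed; relocate the strider to a fresh
              # territory (uniform in the domain) for more foraging
              if (identical(decode_position(larva, h$L), old_dec)) {
                larva <- stats::runif(m, 1, h$L - 1L)
              }
              pos[i, ] <- larva
              fits[i] <- fit_of(pos[i, ])
            }
          }
          if (fits[i] > best_f) {
            best_f <- fits[i]
            best_x <- pos[i, , drop = TRUE]
          }
        }
      }
      trace[it] <- best_f
    }
    list(thresholds = decode_position(best_x, h$L), fitness = best_f,
         trace = trace)
  }
  res <- if (is.null(seed)) runner() else with_seed(seed, runner())

  mask <- NULL
  if (!inherits(img, "gray_histogram")) {
    mask <- apply_thresholds(img, res$thresholds, L = h$L)
  }
  structure(list(thresholds = res$thresholds, fitness = res$fitness,
                 trace = res$trace, mask = mask, histogram = h,
                 params = list(m = m, L = h$L, pop_size = pop_size,
                               territories = territories, max_iter = max_iter,
                               mating_prob = mating_prob, seed = seed,
                               best_of = best_of)),
            class = "wsa_otsu")
}

#' @export
print.wsa_otsu <- function(x, ...) {
  p <- x$params
  cat("WSA-Otsu multi-level threshold segmentation\n")
  cat(sprintf("  m = %d thresholds over L = %d levels\n", p$m, p$L))
  cat(sprintf("  population %d in %d territories, %d iterations\n",
              p$pop_size, p$territories, p$max_iter))
  cat(sprintf("  thresholds: %s\n", paste(x$thresholds, collapse = ", ")))
  cat(sprintf("  between-class variance: %.6g\n", x$fitness))
  invisible(x)
}

#' @export
coef.wsa_otsu <- function(object, ...) object$thresholds

#' @export
plot.wsa_otsu <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "s",
       xlab = "iteration", ylab = "best between-class variance",
       main = "WSA-Otsu convergence", ...)
  invisible(x)
}

#' @export
summary.wsa_otsu <- function(object, ...) {
  cs <- class_stats(object$histogram, object$thresholds)
  out <- list(thresholds = object$thresholds, fitness = object$fitness,
              class_mass = cs$w, class_mean = cs$mu, global_mean = cs$mu_T,
              iterations = length(object$trace))
  class(out) <- "summary.wsa_otsu"
  out
}

#' @export
print.summary.wsa_otsu <- function(x, ...) {
  cat("WSA-Otsu segmentation summary\n")
  cat(sprintf("  thresholds: %s (fitness %.6g, %d iterations)\n",
              paste(x$thresholds, collapse = ", "), x$fitness, x$iterations))
  df <- data.frame(class = seq_along(x$class_mass) - 1L,
                   mass = x$class_mass, mean = x$class_mean)
  print(df, row.names = FALSE)
  cat(sprintf("  global mean: %.4f\n", x$global_mean))
  invisible(x)
}

# run code under a temporary seed, restoring the RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
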