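# Shared fixtures, built in code at test time.

# The published 12-rank comparison table, frozen from the printed source:
# geometric (trendline-smoothed) column, Zipf 1/r, meta-law exp(-r/3).
printed_geometric <- c(0.67, 0.50, 0.37, 0.27, 0.20, 0.15,
                       0.11, 0.09, 0.07, 0.06, 0.05, 0.04)
printed_zipf <- c(1.00, 0.50, 0.33, 0.25, 0.20, 0.17,
                  0.14, 0.13, 0.11, 0.10, 0.09, 0.08)
printed_metalaw <- c(0.72, 0.51, 0.37, 0.26, 0.19, 0.14,
                     0.10, 0.07, 0.05, 0.04, 0.03, 0.02)

# Two hand-wired microgenera: genus g1 = ancestor A1 with descendants X1, X2;
# genus g2 = ancestor A2 (derived from A1 by 4 traits) with Y1, Y2. Every
# novon is a disjoint 4-trait block, so all expected counts are exact.
two_genus_matrix <- function() {
  traits <- sprintf("t%03d", 1:24)
  sp <- c("OG", "A1", "X1", "X2", "A2", "Y1", "Y2")
  m <- matrix(0L, length(sp), length(traits), dimnames = list(sp, traits))
  m["A1", 1:4] <- 1L
  m["X1", ] <- m["A1", ]; m["X1", 5:8] <- 1L
  m["X2", ] <- m["A1", ]; m["X2", 9:12] <- 1L
  m["A2", ] <- m["A1", ]; m["A2", 13:16] <- 1L
  m["Y1", ] <- m["A2", ]; m["Y1", 17:20] <- 1L
  m["Y2", ] <- m["A2", ]; m["Y2", 21:24] <- 1L
  trait_matrix(m, "OG", group_assignments = c(
    A1 = "g1", X1 = "g1", X2 = "g1", A2 = "g2", Y1 = "g2", Y2 = "g2"))
}

two_genus_caulogram <- function() {
  assemble_caulogram(two_genus_matrix())
}

# Independent Monte-Carlo oracle for the median-bracketing probability:
# n uniform draws bracket the population median (1/2) iff min < 1/2 < max.
mc_bracketing_probability <- function(n, trials, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- matrix(runif(n * trials), nrow = n)
  mins <- draws[1L, ]
  maxs <- draws[1L, ]
  if (n > 1L) {
    for (i in 2:n) {
      mins <- pmin(mins, draws[i, ])
      maxs <- pmax(maxs, draws[i, ])
    }
  }
  mean(mins < 0.5 & maxs > 0.5)
}

# Brute-force point-in-circle / point-in-polygon fraction on a lattice grid,
# used as a slow independent check of the closed-form area fraction.
grid_outside_fraction <- function(n, grid = 2001L) {
  xs <- seq(-1, 1, length.out = grid)
  pts <- expand.grid(x = xs, y = xs)
  r <- sqrt(pts$x^2 + pts$y^2)
  in_circle <- r <= 1
  theta <- atan2(pts$y, pts$x) %% (2 * pi)
  phi <- (theta %% (2 * pi / n)) - pi / n
  in_poly <- r <= cos(pi / n) / cos(phi)
  sum(in_circle & !in_poly) / sum(in_circle)
}

test_tempfile <- function(ext) tempfile(fileext = ext)
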