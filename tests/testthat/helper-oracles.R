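# Independent oracles used across the suite.

# Exact two-sided Mann-Whitney p by full enumeration of all rank assignments
# (min-tail doubling, capped at 1). Independent of stats::wilcox.test.
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Second, independent RGB -> Lab implementation (scalar, written against the
# published XYZ/Lab formulas; cross-checked externally against scikit-image).
oracle_lab <- function(rgb, gamma = "linear", white = "D65") {
  v <- rgb / 255
  if (gamma == "srgb")
    v <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- rbind(c(0.4124564, 0.3575761, 0.1804375),
             c(0.2126729, 0.7151522, 0.0721750),
             c(0.0193339, 0.1191920, 0.9503041))
  xyz <- as.numeric(M %*% v)
  wp <- if (white == "D65") rowSums(M) else c(0.96422, 1, 0.82521)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# 1x1 image from an RGB triple
pixel_image <- function(rgb) array(rgb, c(1, 1, 3))

# uniform RGB image
uniform_image <- function(rgb, h = 8, w = 8) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}
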