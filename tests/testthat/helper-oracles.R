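# Independent brute-force oracles, kept free of the package's own code
# paths.

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
enum_mw_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  mean(abs(all_u - mu) >= abs(u_obs - mu))
}

enum_mw_u <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(u1, n1 * n2 - u1)
}

# brute-force pit segmentation on a noiseless trace with known level:
# maximal runs of height < level, boundaries at exact linear crossings
brute_force_extents <- function(pos, h, level = 0) {
  below <- h < level - 1e-12
  if (!any(below)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- NULL
  for (j in which(r$values)) {
    i1 <- starts[j]
    i2 <- ends[j]
    s <- if (i1 > 1) {
      pos[i1 - 1] + (level - h[i1 - 1]) / (h[i1] - h[i1 - 1]) *
        (pos[i1] - pos[i1 - 1])
    } else {
      pos[1]
    }
    e <- if (i2 < length(pos)) {
      pos[i2] + (level - h[i2]) / (h[i2 + 1] - h[i2]) *
        (pos[i2 + 1] - pos[i2])
    } else {
      pos[length(pos)]
    }
    out <- rbind(out, data.frame(start = s, end = e))
  }
  out
}

# count internal local maxima of a sampled profile that rise to at least
# level - tol, by exhaustive scan
brute_force_dents <- function(h, level, tol) {
  n <- length(h)
  ridges <- 0
  for (i in 2:(n - 1)) {
    if (h[i] > h[i - 1] && h[i] >= h[i + 1] && h[i] >= level - tol) {
      ridges <- ridges + 1
    }
  }
  ridges + 1
}

# 2x2 chi-square closed form N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chisq_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- sum(m)
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}
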