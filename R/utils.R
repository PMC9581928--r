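# Internal helpers: seeded evaluation, truncated normals, and patch-based
# rendering of Gaussian nuclei and marker disks.

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds (< 2^31) derived from a master seed.
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated normal on [0, 1] via inverse-CDF; sd = 0 collapses to center.
.truncNorm01 <- function(n, center, sd) {
  if (sd <= 0) return(rep(pmin(pmax(center, 0), 1), n))
  lo <- pnorm((0 - center) / sd)
  hi <- pnorm((1 - center) / sd)
  qnorm(lo + runif(n) * (hi - lo)) * sd + center
}

# Add an isotropic Gaussian of given sigma (pixels) and peak amplitude.
.addGaussian <- function(img, cx, cy, sigmaPx, amplitude = 1) {
  r <- ceiling(3 * sigmaPx)
  rows <- max(1L, round(cy) - r):min(nrow(img), round(cy) + r)
  cols <- max(1L, round(cx) - r):min(ncol(img), round(cx) + r)
  g <- amplitude * exp(-(outer((rows - cy)^2, (cols - cx)^2, `+`)) /
                         (2 * sigmaPx^2))
  img[rows, cols] <- img[rows, cols] + g
  img
}

# Paint a (half-)disk of given radius (pixels) with max(value, existing).
# halves: "full", or "apical" (rows <= cy only).
.addDisk <- function(img, cx, cy, radiusPx, value = 1, half = "full") {
  r <- ceiling(radiusPx)
  rows <- max(1L, round(cy) - r):min(nrow(img), round(cy) + r)
  cols <- max(1L, round(cx) - r):min(ncol(img), round(cx) + r)
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  inside <- d2 <= radiusPx^2
  if (half == "apical") inside <- inside & (rows <= cy)
  patch <- img[rows, cols]
  patch[inside] <- pmax(patch[inside], value)
  img[rows, cols] <- patch
  img
}

# Hard-core sequential placement: returns accepted (x, y) given candidate
# generator function candFun(k) -> c(x, y); stops after maxRetry failures.
.placeHardCore <- function(n, candFun, minDistPx, maxRetry = 3000,
                           what = "cell") {
  x <- numeric(n); y <- numeric(n)
  minD2 <- minDistPx^2
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(maxRetry)) {
      p <- candFun(k)
      if (is.null(p)) next
      if (k == 1L ||
          min((x[seq_len(k - 1L)] - p[1])^2 +
              (y[seq_len(k - 1L)] - p[2])^2) >= minD2) {
        x[k] <- p[1]; y[k] <- p[2]; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %s %d of %d after %d retries: ROI too small for the requested count at min spacing %.2f px",
        what, k, n, maxRetry, minDistPx))
  }
  cbind(x = x, y = y)
}

# Centered moving average with replicated ends; k odd.
.movingAvg <- function(v, k) {
  h <- (k - 1L) %/% 2L
  padded <- c(rep(v[1], h), v, rep(v[length(v)], h))
  as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))[h + seq_along(v)]
}

.clamp0 <- function(m) {
  m[m < 0] <- 0
  m
}
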