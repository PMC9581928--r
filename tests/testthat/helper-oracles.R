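# Independent brute-force oracles used across the suite.  Each is written
# from the definition, not from the package implementation.

# 4-connected component labelling by breadth-first flood fill.
oracleLabel4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Exhaustive local-maxima detection with greedy distance suppression,
# re-implementing the documented rule by explicit loops.
oracleMaxima <- function(img, minIntensity, minSepPx) {
  nr <- nrow(img); nc <- ncol(img)
  cand <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- img[i, j]
    if (v < minIntensity) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      r <- i + di; c <- j + dj
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && img[r, c] > v)
        ok <- FALSE
    }
    if (ok) cand <- rbind(cand, c(x = j, y = i, v = v))
  }
  if (is.null(cand)) return(cand)
  cand <- cand[order(-cand[, "v"], cand[, "y"], cand[, "x"]), ,
               drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (sum((cand[i, 1:2] - cand[j, 1:2])^2) < minSepPx^2) ok <- FALSE
    }
    keep[i] <- ok
  }
  cand[keep, , drop = FALSE]
}

# Pearson correlation from the textbook covariance / (sd sd) formula.
oracleCor <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# First PC of a genes x samples matrix via eigen-decomposition of the
# sample covariance computed longhand.
oracleEigengene <- function(m) {
  mc <- m - rowMeans(m)                 # centre genes
  X <- t(mc)                            # samples x genes
  S <- matrix(0, ncol(X), ncol(X))
  for (a in seq_len(ncol(X))) for (b in seq_len(ncol(X)))
    S[a, b] <- sum(X[, a] * X[, b]) / (nrow(X) - 1)
  e <- eigen(S, symmetric = TRUE)
  scores <- as.numeric(X %*% e$vectors[, 1])
  list(scores = scores,
       varExplained = 100 * e$values[1] / sum(e$values))
}

# One-way ANOVA F and p from the sums-of-squares formulas, plus Tukey
# pairwise adjusted p values from the studentized range distribution.
oracleAnova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  ni <- tapply(values, groups, length)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- k - 1; dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  p <- pf(f, dfb, dfw, lower.tail = FALSE)
  mse <- ssw / dfw
  pairs <- combn(levels(groups), 2)
  tukey <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    q <- abs(gm[pr[1]] - gm[pr[2]]) / se
    ptukey(q, k, dfw, lower.tail = FALSE)
  })
  names(tukey) <- apply(pairs, 2, paste, collapse = "-")
  list(f = f, p = p, tukey = tukey)
}

# A tiny synthetic measurement table builder.
makeTable <- function(values, group = "CTRL", metric = "m") {
  # values: list per organoid of ROI values
  do.call(rbind, lapply(seq_along(values), function(o) {
    data.frame(organoid_id = o, roi_id = seq_along(values[[o]]),
               group = group, metric = metric, value = values[[o]])
  }))
}

# Render one Gaussian blob (for detection tests).
blobImage <- function(nr, nc, cx, cy, sigma, amp = 1) {
  outer(seq_len(nr), seq_len(nc), function(i, j)
    amp * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)))
}

# Flat tissue slab stack: tissue (value 0.8) from row `top` downward.
slabStack <- function(nr = 100, nc = 120, top = 50, pixelSize = 0.5,
                      extra = NULL) {
  glia <- matrix(0, nr, nc)
  glia[top:nr, ] <- 0.8
  if (!is.null(extra)) glia <- pmax(glia, extra)
  dapi <- matrix(0, nr, nc)
  dapi[(top + 5):(nr - 5), ] <- 0.5
  ImageStack(list(dapi = dapi, glia = glia), pixelSize = pixelSize)
}

flatBoundary <- function(width, y, pixelSize = 0.5) {
  new("BoundaryCurve", x = as.numeric(seq_len(width)),
      y = rep(as.numeric(y), width), pixelSize = pixelSize)
}
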