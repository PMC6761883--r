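# Independent brute-force oracles used to cross-check the image pipeline.

# Euclidean distance transform by direct search: for every foreground
# pixel, the minimum distance to any background pixel or to the virtual
# background frame outside the image.  O(n_fg * n_bg); keep fixtures small.
bruteEDT <- function(mask) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  frameR <- c(rep(0L, d[2] + 2), rep(d[1] + 1L, d[2] + 2),
              seq_len(d[1]), seq_len(d[1]))
  frameC <- c(seq(0L, d[2] + 1L), seq(0L, d[2] + 1L),
              rep(0L, d[1]), rep(d[2] + 1L, d[1]))
  bgAll <- rbind(bg, cbind(row = frameR, col = frameC))
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(fg))) {
    dr <- bgAll[, 1] - fg[i, 1]
    dc <- bgAll[, 2] - fg[i, 2]
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(dr * dr + dc * dc))
  }
  out
}

# Count distance-transform regional maxima, merging maxima closer than
# minSep (single linkage): the brute-force stand-in for watershed marker
# counting on well-separated blob fixtures.
bruteMaximaCount <- function(mask, minSep = 2) {
  if (!any(mask)) return(0L)
  dm <- bruteEDT(mask)
  d <- dim(dm)
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- dm
  isMax <- dm > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(d[1] + 1) + dr, 2:(d[2] + 1) + dc]
    isMax <- isMax & dm >= nb
  }
  pts <- which(isMax, arr.ind = TRUE)
  if (nrow(pts) <= 1L) return(nrow(pts))
  hc <- stats::hclust(stats::dist(pts), method = "single")
  length(unique(stats::cutree(hc, h = minSep)))
}

# Draw a disk into a logical mask (pixel centres within radius).
addDisk <- function(mask, r0, c0, radius) {
  d <- dim(mask)
  ri <- max(1, floor(r0 - radius)):min(d[1], ceiling(r0 + radius))
  ci <- max(1, floor(c0 - radius)):min(d[2], ceiling(c0 + radius))
  patch <- outer((ri - r0)^2, (ci - c0)^2, "+") <= radius^2
  mask[ri, ci] <- mask[ri, ci] | patch
  mask
}

# Two-sided permutation test for a difference in group means.
permutationTest <- function(a, b, nPerm = 10000, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  nA <- length(a)
  set.seed(seed)
  stat <- replicate(nPerm, {
    idx <- sample.int(length(pooled), nA)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  (1 + sum(stat >= obs - 1e-12)) / (nPerm + 1)
}
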