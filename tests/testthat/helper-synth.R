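# shared fixtures: small scenes, tiny networks, independent oracles

smallScene <- function(seed = 1L, n = 5L, h = 128L, w = 128L, r = 11) {
  SceneSpec(imageHeight = h, imageWidth = w, dropletRadius = r,
            radiusJitter = 0.08, dropletsPerFrame = n, crystalSizePx = 3L,
            backgroundContrast = 0.5, noiseSd = 5, rngSeed = seed)
}

mixedPhases <- function(seed, n = 5L) {
  set.seed(seed + 500L)
  sample(c("acc", "vaterite", "calcite"), n, TRUE, c(0.4, 0.3, 0.3))
}

mkScene <- function(seed, n = 5L) {
  generateScene(smallScene(seed, n), mixedPhases(seed, n), seed = seed)
}

# render an exact digital disk mask
diskMask <- function(h, w, row, col, radius) {
  d2 <- outer((seq_len(h) - row)^2, (seq_len(w) - col)^2, "+")
  m <- matrix(0L, h, w)
  m[d2 <= radius^2] <- 255L
  m
}

# independent recursive flood-fill component counter (pure R, queue-based)
floodFillCount <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 8L)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (mask[rr, cc] == 0 || seen[rr, cc]) next
    count <- count + 1L
    queue <- list(c(rr, cc)); seen[rr, cc] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] != 0 && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  count
}

maskIoU <- function(a, b) sum(a != 0 & b != 0) / sum(a != 0 | b != 0)

tinyUnetSpec <- function(nEpochs = 10L, seed = 0L, nEncoders = 2L,
                         baseFilters = 4L, lr = 2e-3, batch = 2L) {
  UNetSpec(nEncoders, baseFilters, lr, batch, nEpochs, seed = seed)
}
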