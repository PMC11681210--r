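# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: plain per-pixel loops and direct
# arithmetic, so agreement is meaningful.

# Per-pixel confusion counting loop.
brute_confusion <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      t <- truth[i, j]
      p <- pred[i, j]
      if (t == 1 && p == 1) tp <- tp + 1L
      else if (t == 0 && p == 0) tn <- tn + 1L
      else if (t == 0 && p == 1) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Sliding-window median with replicate edge padding.
brute_median <- function(x, k) {
  r <- (k - 1) / 2
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- pmin(pmax((i - r):(i + r), 1), h)
      jj <- pmin(pmax((j - r):(j + r), 1), w)
      out[i, j] <- median(x[ii, jj])
    }
  }
  out
}

# 3x3 stride-1 max pooling over in-bounds neighbours (same padding).
brute_maxpool3 <- function(x) {
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- max(1, i - 1):min(h, i + 1)
      jj <- max(1, j - 1):min(w, j + 1)
      out[i, j] <- max(x[ii, jj])
    }
  }
  out
}

# Direct same-padded 2-D convolution (single channel in/out) with dilation.
brute_conv2d <- function(x, kern, dil = 1) {
  k <- nrow(kern)
  r <- (k - 1) / 2
  h <- nrow(x)
  w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      s <- 0
      for (ki in seq_len(k)) {
        for (kj in seq_len(k)) {
          ii <- i + (ki - 1 - r) * dil
          jj <- j + (kj - 1 - r) * dil
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
            s <- s + x[ii, jj] * kern[ki, kj]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Random binary mask pair with a blob-ish truth, for metric properties.
random_mask_pair <- function(h, w) {
  truth <- matrix(rbinom(h * w, 1, runif(1, 0.05, 0.6)), h, w)
  flip <- matrix(rbinom(h * w, 1, runif(1, 0, 0.3)), h, w)
  pred <- abs(truth - flip)
  list(truth = truth, pred = pred)
}

# Small preprocessed phantom set shared by training tests.
tiny_training_set <- function(n, size = 32L, seed = 11L) {
  spec <- phantomSpec(imageSize = size, nVessels = 1L,
                      vesselRadiusRange = c(4, 8), clotFraction = 0.6,
                      noiseSigma = 0.02, backgroundLevel = 0.2, seed = seed)
  samples <- generateDataset(spec, n, seed = seed)
  pre <- preprocessConfig(targetSize = size)
  suppressMessages(lapply(samples, preprocessSample, cfg = pre))
}

# Independent per-layer parameter hand count for the assembled network,
# from the architecture description alone (channel bookkeeping done by
# hand, not by querying the model).
hand_count_parameters <- function(depth, base, growth = 2) {
  conv <- function(k, cin, f) k * k * cin * f + f
  bn <- function(f) 2 * f
  inception <- function(cin, f)
    conv(1, cin, f) + conv(3, cin, f) + conv(5, cin, f)
  residual <- function(cin, f) {
    n <- conv(3, cin, f) + bn(f) + conv(3, f, f) + bn(f)
    if (cin != f) n <- n + conv(1, cin, f)
    n
  }
  fl <- function(l) max(1, round(base * growth^(l - 1)))
  total <- 0
  cin <- 1
  for (l in seq_len(depth)) {
    f <- fl(l)
    total <- total + inception(cin, f) + residual(3 * f + cin, f) + bn(f)
    cin <- f
  }
  fb <- fl(depth + 1)
  inc_out <- 3 * fb + cin
  total <- total + inception(cin, fb) +  # bottleneck inception
    conv(1, inc_out, cin) +              # gating projection
    conv(1, cin, 1) +                    # attention mask conv
    conv(3, cin, fb) +                   # dilated conv
    conv(1, fb, fb)                      # spp 1x1 conv
  ccur <- 3 * fb                         # spp output channels (2C + F)
  for (l in rev(seq_len(depth))) {
    f <- fl(l)
    total <- total + (2 * 2 * ccur * f + f) +    # transpose conv
      inception(2 * f, f) + residual(3 * f + 2 * f, f)
    ccur <- f
  }
  total + conv(1, fl(1), 1)              # sigmoid head
}
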