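# shared fixtures and independent brute-force oracles

.fixture_env <- new.env(parent = emptyenv())

# one pixel classifier trained on three standard synthetic images; cached
# across test files
get_test_model <- function() {
  if (is.null(.fixture_env$model)) {
    imgs <- lapply(1:3, function(s) generate_worm_image(worm_image_config(seed = s)))
    .fixture_env$model <- train_pixel_classifier(
      lapply(imgs, function(w) to_grayscale(w$pixels)),
      lapply(imgs, function(w) w$worm_mask),
      seed = 42)
  }
  .fixture_env$model
}

# --- oracles -----------------------------------------------------------------

# flood-fill connected-component labeling, deliberately naive
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs$dr[k]; c <- p[2] + offs$dc[k]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# per-window histogram entropy, exhaustive per pixel
oracle_entropy <- function(img, radius, nbins = 32L) {
  bins <- pmin(floor(img / 256 * nbins), nbins - 1L)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di * di + dj * dj <= radius * radius) {
        r <- i + di; c <- j + dj
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) vals <- c(vals, bins[r, c])
      }
    }
    p <- table(vals) / length(vals)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# every integer threshold t that is a fixed point of the intermeans rule
# t = floor((mean(v <= t) + mean(v > t)) / 2), scanned over all 256 candidates
oracle_isodata_fixed_points <- function(v) {
  cands <- c()
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    if (t == floor((mean(lo) + mean(hi)) / 2)) cands <- c(cands, t)
  }
  cands
}

# random blob mask for component tests
random_mask <- function(nr = 24, nc = 24, p = 0.35) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
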