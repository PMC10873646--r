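## Independent oracles and tiny fixture builders used across the suite.
## These deliberately use naive algorithms (BFS, double loops, exhaustive
## enumeration) so they stay independent of the package's vectorized paths.

## Brute-force BFS connected-component labeling (8/26-connectivity),
## relabeled in order of smallest linear index to match the package.
bfs_label <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- cc + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1]
        mult <- 1L
        for (j in seq_along(d)[-1]) {
          mult <- mult * d[j - 1]
          li <- li + (nb[j] - 1L) * mult
        }
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

## Naive two-segment piecewise-constant changepoint by double loop.
naive_changepoint <- function(y) {
  n <- length(y)
  best <- Inf
  best_k <- 1L
  for (k in 1:(n - 1)) {
    r <- sum((y[1:k] - mean(y[1:k]))^2) +
      sum((y[(k + 1):n] - mean(y[(k + 1):n]))^2)
    if (r < best) {
      best <- r
      best_k <- k
    }
  }
  best_k
}

## Exhaustive hypergeometric over-representation p: enumerate every
## n-subset of a universe of size N and count those with overlap >= k.
exhaustive_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  inset <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% inset) >= k)
  mean(hits)
}

## A 10x10 toy cell: uniform interior with one bright 2x2 block on a zero
## background frame, for hand-computable SPARK values.
toy_cell <- function() {
  img <- matrix(0, 10, 10)
  img[2:9, 2:9] <- 25                       # 64 px dilute
  img[4:5, 4:5] <- 125                      # 4 px condensate
  mask <- matrix(FALSE, 10, 10)
  mask[2:9, 2:9] <- TRUE
  list(img = image_stack(img, 1), mask = mask)
}

## Noiseless imaging ground truth (tiny Poisson gain, zero read noise).
quiet_gt <- function(...) {
  imaging_ground_truth(gain = 1e-4, read_noise_sd = 0, offset = 0, ...)
}
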