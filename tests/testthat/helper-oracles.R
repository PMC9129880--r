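# Brute-force frame-by-frame overtaking oracle, independent of the
# run-length implementation in detect_overtakings(): scans every window of
# min_frames consecutive frames for a sustained lead.
brute_force_overtakers <- function(y, delta, min_frames) {
  n <- ncol(y)
  front <- which.max(y[1, ])
  hits <- integer(0)
  for (j in seq_len(n)) {
    if (j == front) next
    lead <- y[, j] > y[, front] + delta
    found <- FALSE
    if (nrow(y) >= min_frames) {
      for (s in seq_len(nrow(y) - min_frames + 1)) {
        if (all(lead[s:(s + min_frames - 1)])) found <- TRUE
      }
    }
    if (found) hits <- c(hits, j)
  }
  list(front = front, overtakers = hits,
       category = if (length(hits) == 0) "0"
         else if (length(hits) == 1) "1" else ">1")
}

# Random multi-cell y-trajectory fixture for oracle comparisons.
random_y_trajectory <- function(n_cells, n_frames) {
  y0 <- sort(runif(n_cells, 0, 40), decreasing = TRUE)
  y <- matrix(0, n_frames, n_cells)
  y[1, ] <- y0
  for (f in 2:n_frames)
    y[f, ] <- y[f - 1, ] + rnorm(n_cells, 0.2, 1.5)
  y
}

trajectory_from_y <- function(y, identities = NULL) {
  n <- ncol(y)
  if (is.null(identities))
    identities <- c("leader", rep("follower", n - 1))
  pos <- array(0, dim = c(nrow(y), n, 2))
  pos[, , 1] <- 8
  pos[, , 2] <- y
  trajectory(pos, identities = identities)
}
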