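# Brute-force oracles and small fixture builders shared across tests.

# O(N * w^2) windowed mean: the naive double loop the fast path must match.
oracle_local_mean <- function(m, w) {
  r <- (w - 1) %/% 2
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- mean(m[max(1, i - r):min(nrow(m), i + r),
                          max(1, j - r):min(ncol(m), j + r)])
    }
  }
  out
}

oracle_window_sd <- function(m, w) {
  r <- (w - 1) %/% 2
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- sd(m[max(1, i - r):min(nrow(m), i + r),
                        max(1, j - r):min(ncol(m), j + r)])
    }
  }
  out
}

make_disk <- function(nr, nc, cr, cc, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= radius^2
}

# Per-true-object best IoU against a predicted label matrix.
match_iou <- function(truth, pred) {
  truth <- qicyte:::.as_labels(truth)
  pred <- qicyte:::.as_labels(pred)
  vapply(sort(unique(truth[truth > 0L])), function(i) {
    ti <- truth == i
    ov <- table(pred[ti])
    ov <- ov[names(ov) != "0"]
    if (length(ov) == 0) return(0)
    j <- as.integer(names(ov)[which.max(ov)])
    sum(ti & pred == j) / sum(ti | pred == j)
  }, numeric(1))
}

# A tiny two-timepoint synthetic plate for pipeline tests.
make_small_plate <- function(seed = 77, n_cells = 20L, size = 300L) {
  lapply(1:2, function(t) {
    generate_field(
      synthetic_field_spec(n_cells = n_cells, field_size_px = size,
                           seed = seed + t),
      well_id = sprintf("A%02d", t), time_min = (t - 1) * 10,
      treatment = "NGF", field_index = 1L)
  })
}
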