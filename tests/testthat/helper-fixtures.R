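# Shared fixtures and independent oracles used across the test files.

# small, fast scene for pipeline tests
tiny_scene_config <- function(seed, n_bolls = 10L, ...) {
  scene_config(height = 120L, width = 160L, n_bolls = n_bolls,
               boll_radius_range = c(2, 4), min_separation = 12,
               seed = seed, ...)
}

# uniform-color image helper
flat_image <- function(r, g, b, h = 4L, w = 5L, plot_id = "flat") {
  px <- array(0, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  plot_image(px, plot_id = plot_id)
}

# independent connected-components oracle: BFS flood fill, 8- or 4-way
flood_fill_count <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8)
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  count <- 0L
  for (start in which(mask == 1L)) {
    r <- (start - 1L) %% H + 1L; c <- (start - 1L) %/% H + 1L
    if (seen[r, c]) next
    count <- count + 1L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nr <- cur[1] + offs[k, 1]; nc <- cur[2] + offs[k, 2]
        if (nr >= 1 && nr <= H && nc >= 1 && nc <= W &&
            mask[nr, nc] == 1L && !seen[nr, nc]) {
          seen[nr, nc] <- TRUE
          queue <- c(queue, list(c(nr, nc)))
        }
      }
    }
  }
  count
}

# brute-force metric computation: row-by-row counting, no confusion matrix
brute_force_metrics <- function(predicted, truth) {
  n <- length(predicted)
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(n)) {
    if (predicted[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (predicted[i] == 0 && truth[i] == 0) tn <- tn + 1L
    if (predicted[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (predicted[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = 100 * (tp + tn) / n)
}

# run cmd_evaluate with its console reports swallowed
capture_eval <- function(counts_csv, truth_csv, out_dir) {
  res <- NULL
  capture.output(res <- cmd_evaluate(counts_csv, truth_csv, out_dir))
  res
}

# ground-truth CSV fixture writer: 45 plots, counts spanning 14..362
write_gt_fixture <- function(path, n = 45L) {
  set.seed(99)
  counts <- c(14L, 362L, sample(20:350, n - 2L))
  df <- data.frame(plot_id = sprintf("plot%03d", seq_len(n)),
                   genotype = rep(c("A", "B", "C", "D", "E"), length.out = n),
                   boll_count = counts)
  write.csv(df, path, row.names = FALSE)
  df
}
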