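# Brute-force reference implementations used to cross-check the fast paths.

# per-pixel circular-neighbourhood mean by explicit double loop
oracle_focal_mean <- function(m, px, radius_m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  k <- floor(radius_m / px)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j])) next
    acc <- 0; n <- 0
    for (di in -k:k) for (dj in -k:k) {
      if ((di^2 + dj^2) * px^2 > radius_m^2) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (is.na(m[ii, jj])) next
      acc <- acc + m[ii, jj]; n <- n + 1
    }
    if (n > 0) out[i, j] <- acc / n
  }
  out
}

# pooled per-pixel temporal stats by explicit concatenation
oracle_envisat <- function(hh_stack, vv_stack, min_obs = 2) {
  nr <- nrow(hh_stack[[1]]); nc <- ncol(hh_stack[[1]])
  mean_m <- matrix(NA_real_, nr, nc); sd_m <- mean_m; min_m <- mean_m
  gap <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- c(vapply(hh_stack, function(s) s[i, j], numeric(1)),
           vapply(vv_stack, function(s) s[i, j], numeric(1)))
    v <- v[!is.na(v)]
    if (length(v) >= min_obs) {
      gap[i, j] <- FALSE
      mean_m[i, j] <- mean(v); sd_m[i, j] <- sd(v); min_m[i, j] <- min(v)
    }
  }
  list(mean = mean_m, std = sd_m, min = min_m, gap = gap)
}

# cloud-mask-then-reduce optical composite per pixel
oracle_composite <- function(band_stacks, qa_stack) {
  nr <- nrow(qa_stack[[1]]); nc <- ncol(qa_stack[[1]])
  nd_max <- matrix(NA_real_, nr, nc); nd_min <- nd_max
  means <- lapply(band_stacks, function(x) matrix(NA_real_, nr, nc))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    clear <- !vapply(qa_stack, function(q) q[i, j] != 0, logical(1))
    if (!any(clear)) next
    for (nm in names(band_stacks)) {
      v <- vapply(band_stacks[[nm]], function(s) s[i, j], numeric(1))[clear]
      means[[nm]][i, j] <- mean(v)
    }
    nir <- vapply(band_stacks$nir, function(s) s[i, j], numeric(1))[clear]
    red <- vapply(band_stacks$red, function(s) s[i, j], numeric(1))[clear]
    nd <- (nir - red) / (nir + red)
    nd_max[i, j] <- max(nd); nd_min[i, j] <- min(nd)
  }
  list(means = means, ndvi_max = nd_max, ndvi_min = nd_min,
       ndvi_diff = nd_max - nd_min)
}

# spatial binning of footprints into square cells, by hand
oracle_cell_counts <- function(x, y, cell_size, min_count = 2) {
  key <- paste(floor(x / cell_size), floor(y / cell_size))
  tab <- table(key)
  sum(tab >= min_count)
}

oracle_metrics <- function(pred, obs) {
  list(r2 = (sum((pred - mean(pred)) * (obs - mean(obs))) /
               sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2)))^2,
       rmse = sqrt(sum((pred - obs)^2) / length(obs)))
}

oracle_hist <- function(v, bw = 10) {
  v <- v[is.finite(v)]
  ups <- sort(unique(pmax(1, ceiling(v / bw)) * bw))
  counts <- vapply(ups, function(u) sum(v > u - bw & v <= u | (u == bw & v == 0)),
                   numeric(1))
  list(bin_upper = ups, freq = counts / length(v))
}

# raster pixel values as a bare matrix (grid attributes dropped)
vals <- function(r) r[, , drop = FALSE]

rand_raster <- function(nr, nc, seed, px = 50, na_frac = 0) {
  set.seed(seed)
  m <- matrix(runif(nr * nc, 0, 100), nr, nc)
  if (na_frac > 0) m[sample.int(nr * nc, round(na_frac * nr * nc))] <- NA
  grid_raster(m, pixel_size = px)
}

# cached default pipeline run shared across test files
.run_cache <- new.env(parent = emptyenv())
default_run <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_agb_pipeline(seed = seed)
  }
  .run_cache[[key]]
}
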