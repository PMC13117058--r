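# Independent brute-force oracles. Each is written as a plain loop (or an
# external-library route) sharing no code with the package implementation it
# checks.

# BFS flood-fill 4-connected labeling
flood_fill_label <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!bin[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r, c), 1)
    lab[r, c] <- cur
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nr <- p[1] + d[1]; nc <- p[2] + d[2]
        if (nr >= 1L && nr <= H && nc >= 1L && nc <= W &&
            bin[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- cur
          queue <- rbind(queue, c(nr, nc))
        }
      }
    }
  }
  lab
}

# exhaustive optimal one-to-one matching (maximum cardinality over pairs with
# IoU >= threshold) via bipartite maximum matching
optimal_match_counts <- function(gt, pred, thr) {
  gids <- sort(unique(gt[gt > 0L])); pids <- sort(unique(pred[pred > 0L]))
  edges <- NULL
  for (g in gids) for (p in pids) {
    inter <- sum(gt == g & pred == p)
    if (inter == 0L) next
    iou <- inter / sum(gt == g | pred == p)
    if (iou >= thr) edges <- rbind(edges, c(g, p))
  }
  if (is.null(edges))
    return(list(tp = 0L, fp = length(pids), fn = length(gids)))
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(gids)), rep(TRUE, length(pids))),
    edges = as.vector(t(cbind(match(edges[, 1], gids),
                              length(gids) + match(edges[, 2], pids)))))
  tp <- igraph::max_bipartite_match(g)$matching_size
  list(tp = tp, fp = length(pids) - tp, fn = length(gids) - tp)
}

# Haralick statistics by explicit pair enumeration: builds the symmetric
# co-occurrence counts with a double loop, then evaluates the 13 statistics
# with scalar loops.
haralick_oracle <- function(channel, bin, levels, offset,
                            directions = c("0", "45", "90", "135")) {
  v <- channel[bin]
  rng <- range(v)
  H <- nrow(bin); W <- ncol(bin)
  q <- matrix(0L, H, W)
  if (diff(rng) > 0)
    for (r in seq_len(H)) for (c in seq_len(W))
      q[r, c] <- min(max(floor((channel[r, c] - rng[1]) / diff(rng) * levels),
                         0), levels - 1L)
  dirvec <- list("0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(1L, 0L),
                 "135" = c(1L, 1L))
  per_dir <- list()
  for (dn in directions) {
    d <- dirvec[[dn]] * offset
    cnt <- matrix(0, levels, levels)
    npairs <- 0L
    for (r in seq_len(H)) for (c in seq_len(W)) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1L || r2 > H || c2 < 1L || c2 > W) next
      if (!bin[r, c] || !bin[r2, c2]) next
      i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
      npairs <- npairs + 1L
    }
    if (npairs == 0L) next
    per_dir[[dn]] <- haralick_stats_oracle(cnt / sum(cnt))
  }
  if (!length(per_dir)) return(numeric(13))
  Reduce(`+`, per_dir) / length(per_dir)
}

haralick_stats_oracle <- function(p) {
  L <- nrow(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- py <- numeric(L)
  for (i in 1:L) for (j in 1:L) { px[i] <- px[i] + p[i, j]; py[j] <- py[j] + p[i, j] }
  mux <- muy <- 0
  for (i in 1:L) { mux <- mux + (i - 1) * px[i]; muy <- muy + (i - 1) * py[i] }
  sdx <- sdy <- 0
  for (i in 1:L) { sdx <- sdx + (i - 1 - mux)^2 * px[i]; sdy <- sdy + (i - 1 - muy)^2 * py[i] }
  sdx <- sqrt(sdx); sdy <- sqrt(sdy)
  asm <- contrast <- idm <- ent <- corr_num <- varr <- 0
  psum <- numeric(2 * L - 1); pdif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    asm <- asm + pij^2
    contrast <- contrast + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    ent <- ent - pij * lg(pij)
    corr_num <- corr_num + (i - 1) * (j - 1) * pij
    varr <- varr + (i - 1 - mux)^2 * pij
    psum[i + j - 1] <- psum[i + j - 1] + pij
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + pij
  }
  corr <- if (sdx > 0 && sdy > 0) (corr_num - mux * muy) / (sdx * sdy) else 0
  sum_avg <- sum_ent <- 0
  for (k in seq_along(psum)) {
    sum_avg <- sum_avg + (k - 1) * psum[k]
    sum_ent <- sum_ent - psum[k] * lg(psum[k])
  }
  sum_var <- 0
  for (k in seq_along(psum)) sum_var <- sum_var + (k - 1 - sum_avg)^2 * psum[k]
  dmu <- dvar <- dent <- 0
  for (k in seq_along(pdif)) dmu <- dmu + (k - 1) * pdif[k]
  for (k in seq_along(pdif)) {
    dvar <- dvar + (k - 1 - dmu)^2 * pdif[k]
    dent <- dent - pdif[k] * lg(pdif[k])
  }
  hx <- hy <- hxy1 <- hxy2 <- 0
  for (i in 1:L) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  for (i in 1:L) for (j in 1:L) {
    hxy1 <- hxy1 - p[i, j] * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  im1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  im2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  c(asm, contrast, corr, varr, idm, sum_avg, sum_var, sum_ent, ent,
    dvar, dent, im1, im2)
}

# Zernike moment magnitudes by direct numerical integration over the
# rasterized object: explicit complex accumulation with an independently
# coded radial polynomial
zernike_oracle <- function(bin, degree) {
  idx <- which(bin)
  H <- nrow(bin)
  rows <- (idx - 1L) %% H; cols <- (idx - 1L) %/% H
  cr <- mean(rows); cc <- mean(cols)
  R <- sqrt(max((rows - cr)^2 + (cols - cc)^2))
  if (R == 0) R <- 1
  N <- length(idx)
  out <- c()
  for (n in 0:degree) for (m in seq(n %% 2, n, by = 2)) {
    acc <- 0 + 0i
    for (k in seq_len(N)) {
      dr <- rows[k] - cr; dc <- cols[k] - cc
      rho <- sqrt(dr^2 + dc^2) / R
      th <- atan2(dr, dc)
      fact <- function(k) prod(seq_len(k))   # empty product = 1 for k = 0
      rad <- 0
      for (s in 0:((n - m) / 2))
        rad <- rad + (-1)^s * fact(n - s) /
          (fact(s) * fact((n + m) / 2 - s) * fact((n - m) / 2 - s)) *
          rho^(n - 2 * s)
      acc <- acc + rad * exp(-1i * m * th)
    }
    out <- c(out, (n + 1) / pi * Mod(acc) / N)
  }
  out
}
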