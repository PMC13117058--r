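# Fixture builders shared across the suite. All fixtures are generated in
# code; coordinates follow the package convention (matrix [row, col],
# 0-based reporting).

# filled disk mask of radius r centred in an n x n matrix
disk_mask <- function(r, n = 2L * r + 11L, cr = (n + 1) / 2, cc = (n + 1) / 2) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i, j] <- TRUE
  m
}

# closed 1-px rectangle outline (border value 255) on a zero background
rect_outline <- function(H, W, r1, r2, c1, c2) {
  o <- matrix(0L, H, W)
  o[r1:r2, c(c1, c2)] <- 255L
  o[c(r1, r2), c1:c2] <- 255L
  o
}

# label mask of k disjoint axis-aligned squares of side s, in raster order
squares_mask <- function(H, W, tops, lefts, s) {
  m <- matrix(0L, H, W)
  for (k in seq_along(tops))
    m[tops[k]:(tops[k] + s - 1L), lefts[k]:(lefts[k] + s - 1L)] <- k
  m
}

# random disjoint-rectangle label pair for matching tests: later rectangles
# overwrite earlier ones, so labels stay internally disjoint
random_mask <- function(n_obj, H = 48L, W = 48L) {
  m <- matrix(0L, H, W)
  for (k in seq_len(n_obj)) {
    h <- sample(4:10, 1); w <- sample(4:10, 1)
    r <- sample(seq_len(H - h), 1); c <- sample(seq_len(W - w), 1)
    m[r:(r + h - 1L), c:(c + w - 1L)] <- k
  }
  # relabel to drop fully-overwritten objects
  u <- sort(unique(m[m > 0L]))
  m[m > 0L] <- match(m[m > 0L], u)
  m
}

small_scene <- function(seed, n_cells = 6L, size = 192L, ...) {
  generate_scene(scene_params(size = size, n_cells = n_cells,
                              noise = "none", ...), seed = seed)
}
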