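## Windowed sums via integral images (exact, O(1) per pixel), plus small
## fixed-stencil gradients.  All mask-aware operations share one idiom:
## sum(values * mask) / sum(mask) over the window, so that invalid or vessel
## pixels contribute nothing rather than a sentinel value.

## integral image with a leading zero row/column
integral_image <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(apply(m, 2, cumsum), nr, nc)
  rs <- t(matrix(apply(cs, 1, cumsum), nc, nr))
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- rs
  ii
}

## sum over the window [y - hy, y + hy] x [x - hx, x + hx], clipped at the
## borders; hx/hy may be matrices (per-pixel window half-sizes)
box_sum <- function(m, hx, hy = hx) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- integral_image(m)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  x1 <- pmax(xs - hx, 1); x2 <- pmin(xs + hx, nc)
  y1 <- pmax(ys - hy, 1); y2 <- pmin(ys + hy, nr)
  lin <- function(r, c) r + (c - 1) * (nr + 1)
  out <- ii[lin(y2 + 1, x2 + 1)] - ii[lin(y1, x2 + 1)] -
    ii[lin(y2 + 1, x1)] + ii[lin(y1, x1)]
  matrix(out, nr, nc)
}

## mask-aware window mean: NA where the window holds no valid pixel
box_mean_masked <- function(values, mask, hx, hy = hx) {
  v <- values; v[!mask | is.na(v)] <- 0
  mk <- matrix(0, nrow(values), ncol(values)); mk[mask & !is.na(values)] <- 1
  s <- box_sum(v, hx, hy)
  n <- box_sum(mk, hx, hy)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

## shift a matrix by (dy, dx), zero-filling; helper for fixed stencils
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

## 3x3 Sobel gradients in physical units (per micrometer); pixels whose
## stencil touches an invalid pixel are themselves invalid
sobel_gradients <- function(values, mask, spacing_x, spacing_y) {
  v <- values; v[!mask] <- 0
  ## x gradient: smooth in y, difference in x (divide by 8 -> central diff/px)
  sy <- shift_mat(v, -1, 0) + 2 * v + shift_mat(v, 1, 0)
  gx <- (shift_mat(sy, 0, 1) - shift_mat(sy, 0, -1)) / 8
  sx <- shift_mat(v, 0, -1) + 2 * v + shift_mat(v, 0, 1)
  gy <- (shift_mat(sx, 1, 0) - shift_mat(sx, -1, 0)) / 8
  ok <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & shift_mat_logical(mask, dy, dx)
  }
  list(gx = gx / spacing_x, gy = gy / spacing_y, valid = ok)
}

shift_mat_logical <- function(m, dy, dx) {
  out <- shift_mat(matrix(as.numeric(m), nrow(m), ncol(m)), dy, dx)
  out > 0.5
}

## iterative doubled-component diffusion fill: propagates orientation from
## valid pixels into invalid ones (3x3 neighborhood means) until dense
diffuse_fill_axial <- function(m, max_iter = 500) {
  s <- sin(2 * m$values); s[!m$valid] <- 0
  c <- cos(2 * m$values); c[!m$valid] <- 0
  w <- matrix(0, nrow(s), ncol(s)); w[m$valid] <- 1
  fixed <- m$valid
  for (i in seq_len(max_iter)) {
    if (all(w > 0)) break
    s2 <- box_sum(s, 1, 1); c2 <- box_sum(c, 1, 1); w2 <- box_sum(w, 1, 1)
    upd <- !fixed & w2 > 0
    if (!any(upd)) break
    s[upd] <- s2[upd] / w2[upd]
    c[upd] <- c2[upd] / w2[upd]
    w[upd] <- 1
  }
  vals <- axial_from_components(s, c)
  vals[!(w > 0)] <- NA_real_
  axial_map(matrix(vals, nrow(s), ncol(s)), w > 0, m$spacing_x, m$spacing_y)
}
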