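# internal helpers: error classes, rounding, image shifts, blur, median filter

stop_invalid <- function(msg, class = "evlfm_invalid_argument") {
  abort(msg, class = c(class, "evlfm_error"))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

# round-half-up to integer (bit-exact golden tests depend on this, not IEC 60559
# round-half-even)
round_half_up <- function(x) floor(x + 0.5)

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# integer-pixel shift with zero padding: content moves by +dx columns (right)
# and +dy rows (down)
int_shift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  if (abs(dx) >= nc || abs(dy) >= nr) return(out)
  if (dy >= 0) { dst_r <- (1 + dy):nr; src_r <- 1:(nr - dy) }
  else         { dst_r <- 1:(nr + dy); src_r <- (1 - dy):nr }
  if (dx >= 0) { dst_c <- (1 + dx):nc; src_c <- 1:(nc - dx) }
  else         { dst_c <- 1:(nc + dx); src_c <- (1 - dx):nc }
  out[dst_r, dst_c] <- img[src_r, src_c]
  out
}

# subpixel shift, bilinear interpolation over the four neighbouring integer
# shifts, zero padding outside the support
shift_image <- function(img, dx, dy, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (interp == "nearest") {
    return(int_shift(img, round_half_up(dx), round_half_up(dy)))
  }
  ix <- floor(dx); iy <- floor(dy)
  fx <- dx - ix;   fy <- dy - iy
  if (fx == 0 && fy == 0) return(int_shift(img, ix, iy))
  out <- (1 - fx) * (1 - fy) * int_shift(img, ix, iy)
  if (fx > 0) out <- out + fx * (1 - fy) * int_shift(img, ix + 1L, iy)
  if (fy > 0) out <- out + (1 - fx) * fy * int_shift(img, ix, iy + 1L)
  if (fx > 0 && fy > 0) out <- out + fx * fy * int_shift(img, ix + 1L, iy + 1L)
  out
}

gauss_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(1)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur as a weighted sum of shifted copies; kernels are
# normalized so interior energy is preserved (zero boundary)
blur_gauss <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  taps <- (-r):r
  h <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(taps)) h <- h + k[i] * int_shift(img, taps[i], 0L)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(taps)) out <- out + k[i] * int_shift(h, 0L, taps[i])
  out
}

# pad a matrix by replicating its edges
pad_replicate <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(seq_len(nr + 2 * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * r) - r, 1L), nc)
  img[ri, ci, drop = FALSE]
}

# vectorized 3x3 median via the classic 19-exchange sorting network
median3x3 <- function(img) {
  p <- pad_replicate(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  v <- vector("list", 9L)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    v[[k]] <- as.vector(p[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)])
  }
  sw <- function(a, b) {
    lo <- pmin(v[[a]], v[[b]]); hi <- pmax(v[[a]], v[[b]])
    v[[a]] <<- lo; v[[b]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  matrix(v[[5]], nr, nc)
}

median_filter <- function(img, kernel) {
  if (kernel == 1L) return(img)
  if (kernel == 3L) return(median3x3(img))
  r <- (kernel - 1L) %/% 2L
  p <- pad_replicate(img, r)
  nr <- nrow(img); nc <- ncol(img)
  cols <- vector("list", kernel^2)
  k <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    k <- k + 1L
    cols[[k]] <- as.vector(p[(r + 1 + dy):(nr + r + dy),
                             (r + 1 + dx):(nc + r + dx)])
  }
  m <- do.call(cbind, cols)
  matrix(apply(m, 1L, median), nr, nc)
}

# cosine similarity between two equally shaped arrays
cosine_sim <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
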