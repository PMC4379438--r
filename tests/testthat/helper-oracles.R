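# Independent oracles, kept deliberately naive and separate from the package
# code paths they check.

# scalar single-axis rotation applied sequentially (axis-1, then 2, then 3)
oracle_rotate <- function(v, rot1, rot2, rot3) {
  r1 <- function(p, a) c(p[1], cos(a) * p[2] - sin(a) * p[3],
                         sin(a) * p[2] + cos(a) * p[3])
  r2 <- function(p, a) c(cos(a) * p[1] + sin(a) * p[3], p[2],
                         -sin(a) * p[1] + cos(a) * p[3])
  r3 <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                         sin(a) * p[1] + cos(a) * p[2], p[3])
  r3(r2(r1(v, rot1), rot2), rot3)
}

# scalar 2-theta at a subpixel point, written independently of point_angles
oracle_tth <- function(geom, y, x) {
  p1 <- (y - 0.5) * geom$detector$pixel1
  p2 <- (x - 0.5) * geom$detector$pixel2
  v <- oracle_rotate(c(p1 - geom$poni1, p2 - geom$poni2, geom$dist),
                     geom$rot1, geom$rot2, geom$rot3)
  atan2(sqrt(v[1]^2 + v[2]^2), v[3])
}

# dense rasterization oracle for box/grid overlap fractions
oracle_box_fractions <- function(umin, umax, amin, amax, ue, ae, nsub = 700) {
  us <- umin + (seq_len(nsub) - 0.5) / nsub * (umax - umin)
  as_ <- amin + (seq_len(nsub) - 0.5) / nsub * (amax - amin)
  iu <- findInterval(us, ue, rightmost.closed = TRUE)
  ia <- findInterval(as_, ae, rightmost.closed = TRUE)
  tab <- table(factor(rep(iu, times = nsub), levels = seq_len(length(ue) - 1)),
               factor(rep(ia, each = nsub), levels = seq_len(length(ae) - 1)))
  tab / (nsub * nsub)
}

# Monte-Carlo point-in-polygon fractions for a quad against a grid
oracle_mc_quad <- function(qu, qa, ue, ae, n = 1e5) {
  px <- runif(n, min(qu), max(qu))
  py <- runif(n, min(qa), max(qa))
  nv <- 4
  ins <- rep(FALSE, n)
  j <- nv
  for (i in 1:nv) {
    cross <- (qa[i] > py) != (qa[j] > py)
    xint <- (qu[j] - qu[i]) * (py - qa[i]) / (qa[j] - qa[i]) + qu[i]
    ins <- xor(ins, cross & (px < xint))
    j <- i
  }
  iu <- findInterval(px, ue, rightmost.closed = TRUE)
  ia <- findInterval(py, ae, rightmost.closed = TRUE)
  list(inside = ins, iu = iu, ia = ia, n_in = sum(ins))
}

# brute-force DoG scale sweep at a blob center: the scale maximizing
# B(sigma) - B(sigma * sqrt(2)) sampled on a dense ladder
oracle_dog_optimum <- function(img, y, x, sigmas = 2^seq(0, 3, by = 0.1)) {
  resp <- vapply(sigmas, function(s) {
    b1 <- gaussian_blur(img, s)
    b2 <- gaussian_blur(img, s * sqrt(2))
    b1[round(y), round(x)] - b2[round(y), round(x)]
  }, 0)
  # report the geometric-mean scale like the detector does
  sigmas[which.max(resp)] * 2^0.25
}
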