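# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately use naive per-pixel / enumerative
# algorithms, not the package's code paths.

# per-pixel median with edge replication (nested loops, no shared code)
oracle_median <- function(m, w = 3) {
  h <- w %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax(i + (-h:h), 1), nr)
      ci <- pmin(pmax(j + (-h:h), 1), nc)
      out[i, j] <- median(m[ri, ci])
    }
  }
  out
}

# grayscale opening with a spherical-cap ball element, edge replication;
# computed by looping structuring-element offsets over shifted index grids
oracle_open_ball <- function(m, radius) {
  R <- floor(radius)
  offs <- expand.grid(di = -R:R, dj = -R:R)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  hgt <- sqrt(radius^2 - offs$di^2 - offs$dj^2) - radius
  nr <- nrow(m); nc <- ncol(m)
  stage <- function(x, erode) {
    out <- matrix(if (erode) Inf else -Inf, nr, nc)
    for (k in seq_len(nrow(offs))) {
      ri <- pmin(pmax(seq_len(nr) + offs$di[k], 1), nr)
      ci <- pmin(pmax(seq_len(nc) + offs$dj[k], 1), nc)
      shifted <- x[ri, ci, drop = FALSE]
      out <- if (erode) pmin(out, shifted - hgt[k]) else pmax(out, shifted + hgt[k])
    }
    out
  }
  stage(stage(m, TRUE), FALSE)
}

# exact maximum-cardinality matching under a cutoff, by enumeration of all
# injective assignments of the smaller marker set (feasible for n <= 6)
oracle_match_count <- function(a, b, cutoff) {
  if (nrow(a) > nrow(b)) return(oracle_match_count(b, a, cutoff))
  na <- nrow(a); nb <- nrow(b)
  if (na == 0) return(0L)
  D <- sqrt(outer(a$x_um, b$x_um, `-`)^2 + outer(a$y_um, b$y_um, `-`)^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- 0L
  for (sub in utils::combn(nb, na, simplify = FALSE)) {
    for (p in perms(sub)) {
      cnt <- sum(D[cbind(seq_len(na), p)] <= cutoff)
      best <- max(best, cnt)
    }
  }
  best
}

# single-layer annulus mask (label 1 between the radii, in um)
make_annulus_mask <- function(inner_um, outer_um, resolution,
                              margin_um = 5, name = "band") {
  side <- 2L * ceiling((outer_um + margin_um) * resolution) + 1L
  cen <- (side + 1) / 2
  d <- sqrt(outer((seq_len(side) - cen)^2, (seq_len(side) - cen)^2, `+`))
  labs <- matrix(0L, side, side)
  labs[d > inner_um * resolution & d <= outer_um * resolution] <- 1L
  layer_mask(labs, resolution, stats::setNames(1L, name))
}

# small flat single-layer field mask
make_field_mask <- function(side_px, resolution = 7) {
  layer_mask(matrix(1L, side_px, side_px), resolution, c(field = 1L))
}
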