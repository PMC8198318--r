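# Independent oracles and fixture builders, implemented with different
# algorithms than the package code paths they check.

# -- geometric fixtures (0-based center coords to match package convention) --

disc_mask <- function(nr, nc, r0, c0, radius) {
  d2 <- outer((seq_len(nr) - 1 - r0)^2, (seq_len(nc) - 1 - c0)^2, "+")
  d2 <= radius^2
}

ellipse_mask <- function(nr, nc, r0, c0, a, b, theta = 0) {
  dr <- outer(seq_len(nr) - 1 - r0, rep(1, nc))
  dc <- outer(rep(1, nr), seq_len(nc) - 1 - c0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

rect_mask <- function(nr, nc, r0, c0, h, w) {
  rr <- outer(abs(seq_len(nr) - 1 - r0), rep(1, nc))
  cc <- outer(rep(1, nr), abs(seq_len(nc) - 1 - c0))
  rr <= (h - 1) / 2 & cc <= (w - 1) / 2
}

# union of random discs: a connected-ish random blob mask for oracle tests
random_blob_mask <- function(seed, nr = 64, nc = 64) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, nr, nc)
    n_discs <- sample(3:6, 1)
    r0 <- runif(1, 20, nr - 21); c0 <- runif(1, 20, nc - 21)
    for (i in seq_len(n_discs)) {
      rad <- runif(1, 4, 10)
      m <- m | disc_mask(nr, nc, r0, c0, rad)
      ang <- runif(1, 0, 2 * pi); step <- runif(1, 4, 12)
      r0 <- min(max(r0 + step * sin(ang), 8), nr - 9)
      c0 <- min(max(c0 + step * cos(ang), 8), nc - 9)
    }
    m
  })
}

sample_seeds_on_mask <- function(mask, n, seed) {
  withr::with_seed(seed, {
    fg <- which(mask, arr.ind = TRUE)
    pick <- fg[sample(nrow(fg), n), , drop = FALSE]
    data.frame(nucleus_id = seq_len(n), row = pick[, 1] - 1L,
               col = pick[, 2] - 1L)
  })
}

# -- brute-force seeded flood fill: per-seed geodesic distance by iterative
#    relaxation over 8-neighbour shifts (not BFS), argmin label with ties to
#    the lowest nucleus_id --

shift_inf <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(Inf, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

oracle_flood_fill <- function(mask, seeds) {
  ord <- order(seeds$nucleus_id)
  best <- matrix(Inf, nrow(mask), ncol(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_along(ord)) {
    s <- ord[k]
    d <- matrix(Inf, nrow(mask), ncol(mask))
    d[seeds$row[s] + 1L, seeds$col[s] + 1L] <- 0
    repeat {
      d2 <- d
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        d2 <- pmin(d2, shift_inf(d, dr, dc) + 1)
      }
      d2[!mask] <- Inf
      d2[seeds$row[s] + 1L, seeds$col[s] + 1L] <- 0
      if (identical(d2, d)) break
      d <- d2
    }
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- k
  }
  lab
}

# -- grid-search oracle for LL4 least squares: dense (b, e) grid with the
#    linear parameters (c, d) profiled out in closed form --

oracle_ll4_grid <- function(x, y, b_grid, e_grid) {
  best <- list(rss = Inf)
  for (b in b_grid) for (e in e_grid) {
    s <- 1 / (1 + exp(b * (log(x) - log(e))))
    X <- cbind(1, s)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                     error = function(err) NULL)
    if (is.null(beta)) next
    rss <- sum((y - X %*% beta)^2)
    if (rss < best$rss)
      best <- list(rss = rss, b = b, e = e, c = beta[1],
                   d = beta[1] + beta[2])
  }
  best
}

# doses used throughout the dose-response tests: 8 geometric steps
geom_doses <- function(lo = 0.02, hi = 10, n = 8) {
  exp(seq(log(lo), log(hi), length.out = n))
}
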