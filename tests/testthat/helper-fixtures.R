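# shared fixture builders (everything generated in code at test time)

bct_cell <- function() unit_cell(27.9, 27.9, 33, centering = "body_centered")

triclinic_cell <- function()
  unit_cell(28.4, 26.5, 24.2, alpha = 78, beta = 66, gamma = 61)

bct_points <- function(box = c(170, 170, 170))
  build_lattice_points(bct_cell(), box = box)

# FCC as explicit conventional-cell points (corners + face centres)
fcc_points <- function(a = 30, box = c(160, 160, 160)) {
  base <- build_lattice_points(unit_cell(a), box = box)
  offs <- list(c(.5, .5, 0) * a, c(.5, 0, .5) * a, c(0, .5, .5) * a)
  pts <- rbind(base, do.call(rbind, lapply(offs, function(o)
    sweep(base, 2, -o))))
  pts[pts[, 1] < box[1] & pts[, 2] < box[2] & pts[, 3] < box[3], ,
      drop = FALSE]
}

# ABAB close-packed stack (not a Bravais lattice)
hcp_points <- function(a = 27, nlayer = 8, half = 60) {
  h <- a * sqrt(2 / 3)
  u <- c(a, 0, 0); v <- c(a / 2, a * sqrt(3) / 2, 0)
  off <- (u + v) / 3
  g <- expand.grid(L = 0:(nlayer - 1), i = -4:4, j = -4:4)
  p <- t(apply(g, 1, function(r)
    r["i"] * u + r["j"] * v + c(0, 0, r["L"] * h) +
      if (r["L"] %% 2 == 1) off else c(0, 0, 0)))
  p[abs(p[, 1]) < half & abs(p[, 2]) < half, , drop = FALSE]
}

# brute-force enumeration of lattice translation classes with length <= cut:
# integer combinations of the (possibly centered) cell, one per antipodal pair
lattice_translations <- function(cell, cut, hmax = 3) {
  B <- cell_basis(cell)
  g <- as.matrix(expand.grid(-hmax:hmax, -hmax:hmax, -hmax:hmax))
  if (cell$centering == "body_centered")
    g <- rbind(g, sweep(g, 2, -c(.5, .5, .5)))
  g <- g[rowSums(abs(g)) > 0, ]
  v <- g %*% t(B)
  len <- sqrt(rowSums(v^2))
  v <- v[len <= cut & len > 1e-9, , drop = FALSE]
  # deduplicate antipodes
  key <- apply(round(v, 6), 1, function(r) {
    s <- if (r[1] < 0 || (r[1] == 0 && r[2] < 0) ||
             (r[1] == 0 && r[2] == 0 && r[3] < 0)) -1 else 1
    paste(s * r, collapse = ",")
  })
  v[!duplicated(key), , drop = FALSE]
}

coef_cell <- function(cl)
  c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)

# soft-sphere image used by linker-angle tests
disc_image <- function(n = 45, radius = 10, softness = 1.5) {
  ctr <- (n + 1) / 2
  out <- matrix(0, n, n)
  for (x in 1:n) for (y in 1:n)
    out[x, y] <- pnorm((radius - sqrt((x - ctr)^2 + (y - ctr)^2)) / softness)
  out
}

ridge_image <- function(angle_deg, n = 45, radius = 10) {
  img <- disc_image(n, radius)
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  for (x in 1:n) for (y in 1:n) {
    dx <- x - ctr; dy <- y - ctr
    r <- sqrt(dx^2 + dy^2)
    along <- dx * cos(th) + dy * sin(th)
    perp <- abs(-dx * sin(th) + dy * cos(th))
    if (along > 0 && r < 2 * radius)
      img[x, y] <- max(img[x, y], 0.5 * pnorm((2.2 - perp) / 1.2))
  }
  img
}
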