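# Shared fixture builders. Everything is generated in code; no data files.

square_mask <- function(side = 1000, origin = c(0, 0)) {
  nuclear_mask(rbind(origin,
                     origin + c(side, 0),
                     origin + c(side, side),
                     origin + c(0, side)))
}

ellipse_mask <- function(a = 1000, b = 700, n = 64, exclusions = list()) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nuclear_mask(cbind(a * cos(th), b * sin(th)), exclusions)
}

uniform_locs <- function(n, mask, z = NULL) {
  bb <- clutchscope:::.mask_bbox(mask)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    x <- runif(2 * n, bb[1], bb[2]); y <- runif(2 * n, bb[3], bb[4])
    t <- clip_to_mask(loc_table(x, y), mask)
    out <- if (is.null(out)) t else rbind(out, t)
  }
  out <- out[seq_len(n), ]
  if (!is.null(z)) out$z <- runif(n, z[1], z[2])
  clutchscope:::.as_loc(out)
}

# tight point clusters at given centers: each becomes one clutch under
# small-eps segmentation, letting tests construct exact clutch sets
clutch_points <- function(centers, spread = 1, n_each = 5) {
  x <- c(); y <- c()
  for (i in seq_len(nrow(centers))) {
    x <- c(x, centers[i, 1] + seq(0, spread, length.out = n_each))
    y <- c(y, centers[i, 2] + rep(0, n_each))
  }
  loc_table(x, y)
}

# brute-force single-linkage oracle: union-find over the full distance matrix
brute_components <- function(x, y, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  d <- as.matrix(dist(cbind(x, y)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (d[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  # canonical labels
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
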