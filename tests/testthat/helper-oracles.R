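# Brute-force oracles, kept independent of the package's internal code
# paths: boundary extraction by whole-image neighbour comparison, cluster
# recovery by all-pairs distances + graph components, p values by
# exhaustive permutation.

# (row, col, label) of all boundary pixels of all objects, via padded
# whole-image shifts (8-connectivity).
bf_all_boundaries <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- labels
  differs <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    differs <- differs | (nb != labels)
  }
  idx <- which(differs & labels > 0L, arr.ind = TRUE)
  cbind(idx, label = labels[idx])
}

# All-pairs minimal border-to-border distances (um) between objects.
bf_gap_matrix <- function(mask) {
  bd <- bf_all_boundaries(mask$labels)
  labs <- sort(unique(bd[, "label"]))
  pts <- lapply(labs, function(l)
    bd[bd[, "label"] == l, c("row", "col"), drop = FALSE] * mask$pixel_size)
  n <- length(labs)
  g <- matrix(Inf, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    d2 <- outer(pts[[i]][, 1L], pts[[j]][, 1L], "-")^2 +
      outer(pts[[i]][, 2L], pts[[j]][, 2L], "-")^2
    g[i, j] <- g[j, i] <- sqrt(min(d2))
  }
  diag(g) <- 0
  g
}

# Brute-force single-linkage components: adjacency from the all-pairs gap
# matrix, components via igraph.
bf_cluster_components <- function(mask, max_gap = 3) {
  g <- bf_gap_matrix(mask)
  adj <- (g < max_gap)
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  igraph::components(gr)$membership
}

# Same-partition check for two integer labellings.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(seq_along(a), a, function(i) length(unique(b[i])) == 1L)) &&
    length(unique(a)) == length(unique(b))
}

# Exhaustive-permutation two-sided rank-sum p value.
bf_perm_wilcox_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (N + 1) / 2)
  combs <- utils::combn(N, n1)
  stat <- abs(colSums(matrix(r[combs], nrow = n1)) - n1 * (N + 1) / 2)
  mean(stat >= obs - 1e-9)
}

# Rectangle blob painter: a mask whose objects have exactly the requested
# pixel counts (rectangles of height 1..n), for exact-area fixtures.
make_rect_mask <- function(pixel_counts, pixel_size = 1) {
  n <- length(pixel_counts)
  wmax <- max(pixel_counts)
  m <- matrix(0L, 3L * n + 2L, wmax + 4L)
  for (i in seq_len(n))
    m[3L * i, 2L + seq_len(pixel_counts[i])] <- i
  labeled_mask(m, pixel_size)
}

# A disk/ellipse painter on a fresh mask (wraps the generator's rasterizer
# only through public mask arithmetic: painted per-pixel here).
paint_ellipse <- function(m, label, cr, cc, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  for (r in seq_len(nrow(m))) for (cl in seq_len(ncol(m))) {
    dx <- cl - cc; dy <- -(r - cr)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    if ((u / a)^2 + (v / b)^2 <= 1) m[r, cl] <- label
  }
  m
}
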