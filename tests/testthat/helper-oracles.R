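# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition by direct enumeration/looping, sharing no code with the
# package implementation.

# distance of every pixel to the nearest TRUE pixel, minimum over all mask
# pixels, in um
brute_distance_map <- function(mask, pixel_size_um = 1) {
  idx <- which(mask, arr.ind = TRUE)
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W))
    out[r, cc] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - cc)^2)) * pixel_size_um
  out
}

# exhaustive two-sided rank-sum p over all C(n1+n2, n1) group assignments of
# the pooled observations (midranks, so tie-aware)
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# ssGSEA by materialising both ECDF vectors position by position
brute_ssgsea <- function(expr, genes_in_set, alpha) {
  ord <- order(-expr, names(expr))
  g <- names(expr)[ord]
  rk <- rank(expr)[ord]
  n <- length(g)
  inset <- g %in% genes_in_set
  w <- abs(rk)^alpha
  p_in <- numeric(n); p_out <- numeric(n)
  for (i in seq_len(n)) {
    p_in[i] <- sum(w[seq_len(i)][inset[seq_len(i)]]) / sum(w[inset])
    p_out[i] <- sum(!inset[seq_len(i)]) / sum(!inset)
  }
  sum(p_in - p_out)
}

# running-sum ES by explicit walk
brute_running_es <- function(stats, genes_in_set, weight_exponent) {
  ord <- order(-stats, names(stats))
  g <- names(stats)[ord]; v <- stats[ord]
  n <- length(g)
  inset <- g %in% genes_in_set
  w <- if (weight_exponent == 0) rep(1, n) else abs(v)^weight_exponent
  run <- 0; best <- 0; curve <- numeric(n)
  for (i in seq_len(n)) {
    run <- run + if (inset[i]) unname(w[i]) / sum(w[inset]) else -1 / sum(!inset)
    curve[i] <- run
    if (abs(run) > abs(best)) best <- run
  }
  list(es = best, curve = curve)
}

# midrank Spearman via Pearson on ranks, p from the t approximation
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  rho <- sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  rho
}

# match detected cells to truth centroids within a radius; returns per-cell
# matched truth index (NA when unmatched)
match_cells <- function(cells, truth, radius_um = 10, pixel_size_um = 1) {
  D <- outer(cells$row_px, truth$row_px, "-")^2 +
    outer(cells$col_px, truth$col_px, "-")^2
  j <- apply(D, 1, which.min)
  d <- sqrt(D[cbind(seq_len(nrow(cells)), j)]) * pixel_size_um
  ifelse(d <= radius_um, j, NA_integer_)
}

# small raw-count expression object for unit tests
toy_sce <- function(counts, ...) {
  expression_matrix(counts, data.frame(..., row.names = colnames(counts)))
}
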