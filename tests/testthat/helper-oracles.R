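# Independent oracle implementations used to validate the package. These are
# deliberately naive/brute-force and share no code with the implementation.

# sort-based percentile via direct closest-rank interpolation arithmetic
oracle_psmd <- function(x) {
  s <- sort(x)
  n <- length(s)
  pick <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  pick(0.95) - pick(0.05)
}

# naive TFCE: independent per-threshold connected-component labelling
# (components via igraph), summed over the threshold ladder
oracle_tfce <- function(stat, mask, H = 2, E = 0.5, dh = NULL,
                        connectivity = 26) {
  d <- dim(mask)
  one_sign <- function(v) {
    out <- array(0, dim = d)
    mx <- max(v[mask], 0)
    if (mx <= 0) return(out)
    step <- if (is.null(dh)) mx / 100 else dh
    nsteps <- floor(mx / step + 1e-9)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
    if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
    for (s in seq_len(nsteps)) {
      h <- s * step
      sup <- which(mask & v >= h - 1e-12)
      if (!length(sup)) next
      k <- length(sup)
      id <- array(0L, dim = d)
      id[sup] <- seq_len(k)
      co <- arrayInd(sup, d)
      edges <- NULL
      for (r in seq_len(nrow(offs))) {
        nb <- sweep(co, 2, offs[r, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        nbl <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) +
          d[1] * d[2] * (nb[ok, 3] - 1)
        hit <- id[nbl] > 0
        if (any(hit))
          edges <- rbind(edges, cbind(which(ok)[hit], id[nbl][hit]))
      }
      g <- igraph::graph_from_edgelist(
        rbind(cbind(seq_len(k), seq_len(k)),
              if (!is.null(edges)) edges),
        directed = FALSE)
      comp <- igraph::components(g)
      sizes <- comp$csize[comp$membership]
      out[sup] <- out[sup] + sizes^E * h^H * step
    }
    out
  }
  one_sign(stat) - one_sign(-stat)
}

# textbook OLS t for a contrast, via lm()
oracle_ols_t <- function(y, X, contrast) {
  fit <- lm(y ~ X - 1)
  b <- coef(fit)
  V <- vcov(fit)
  drop(crossprod(contrast, b)) / sqrt(drop(t(contrast) %*% V %*% contrast))
}

# entry voxel of a ray into an axis-aligned slab (0-based voxel coords)
oracle_slab_entry <- function(origin, direction, axis, slab_from) {
  if (direction[axis] <= 0) return(NULL)
  tmin <- (slab_from - 0.5 - origin[axis]) / direction[axis]  # voxel boundary
  p <- origin + max(tmin, 0) * direction
  entry <- floor(p + 0.5)   # half-up voxelization, centres at integers
  entry[axis] <- max(entry[axis], slab_from)
  entry
}

# Benjamini-Hochberg step-up, written out directly
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
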