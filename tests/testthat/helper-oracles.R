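# Independent oracles used by the tests. These re-derive expected results by
# brute force or enumeration and deliberately share no code with the package
# internals they check.

# Exhaustive Euclidean-distance ring assignment: for every pixel of the image
# and every fiber, the squared distance to the fiber's outline is computed
# directly; pixels within the radius are assigned to the nearest outline
# (ties to the lower fiber id). Returns the ring ownership matrix.
brute_force_rings <- function(labels, radius) {
  h <- nrow(labels); w <- ncol(labels)
  K <- max(labels)
  outlines <- lapply(seq_len(K), function(k) {
    idx <- which(labels == k)
    ys <- (idx - 1L) %% h + 1L
    xs <- (idx - 1L) %/% h + 1L
    on_edge <- logical(length(idx))
    for (i in seq_along(idx)) {
      y <- ys[i]; x <- xs[i]
      nb <- rbind(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))
      out <- nb[, 1] < 1 | nb[, 1] > h | nb[, 2] < 1 | nb[, 2] > w
      vals <- rep(FALSE, 4)
      vals[!out] <- labels[nb[!out, , drop = FALSE]] != k
      on_edge[i] <- any(out) || any(vals)
    }
    cbind(ys[on_edge], xs[on_edge])
  })
  owner <- matrix(0L, h, w)
  bestd2 <- matrix(Inf, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    for (k in seq_len(K)) {
      ol <- outlines[[k]]
      if (nrow(ol) == 0) next
      d2 <- min((ol[, 1] - y)^2 + (ol[, 2] - x)^2)
      if (d2 <= radius^2 && d2 < bestd2[y, x]) {
        bestd2[y, x] <- d2
        owner[y, x] <- k
      }
    }
  }
  owner
}

# 4-connected flood fill from a seed over a predicate mask
flood_fill_region <- function(mask, seed_y, seed_x) {
  h <- nrow(mask); w <- ncol(mask)
  visited <- matrix(FALSE, h, w)
  stack_idx <- (seed_x - 1L) * h + seed_y
  while (length(stack_idx)) {
    i <- stack_idx[length(stack_idx)]
    stack_idx <- stack_idx[-length(stack_idx)]
    if (visited[i] || !mask[i]) next
    visited[i] <- TRUE
    y <- (i - 1L) %% h + 1L; x <- (i - 1L) %/% h + 1L
    if (y > 1) stack_idx <- c(stack_idx, i - 1L)
    if (y < h) stack_idx <- c(stack_idx, i + 1L)
    if (x > 1) stack_idx <- c(stack_idx, i - h)
    if (x < w) stack_idx <- c(stack_idx, i + h)
  }
  visited
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  ranks <- rank(pooled)
  u_stat <- function(idx) sum(ranks[idx]) - n * (n + 1) / 2
  obs <- u_stat(seq_len(n))
  m <- length(pooled)
  combs <- utils::combn(m, n)
  us <- apply(combs, 2, u_stat)
  center <- n * (length(b)) / 2
  mean(abs(us - center) >= abs(obs - center))
}

# Kruskal-Wallis H with tie correction, straight from the rank formula
hand_kruskal_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# small biopsy spec used across fiber tests
tiny_biopsy <- function(n_fibers = 4, seed = 1, noise_sd = 0, intensity_cv = 0,
                        group_effect = 1, ...) {
  biopsy_spec(n_fibers = n_fibers, seed = seed, noise_sd = noise_sd,
              intensity_cv = intensity_cv, group_effect = group_effect,
              area_lognormal = c(log(600), 0.2), ...)
}
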