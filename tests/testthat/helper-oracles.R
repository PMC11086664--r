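# Independent straight-line oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# fixed-point iteration of the fuzzy c-means update equations
oracle_fcm <- function(x, k, m = 2, tol = 1e-10, max_iter = 2000) {
  v <- seq(min(x), max(x), length.out = k)
  for (it in seq_len(max_iter)) {
    u <- matrix(0, length(x), k)
    for (i in seq_along(x)) {
      d2 <- (x[i] - v)^2
      if (any(d2 == 0)) {
        u[i, ] <- as.numeric(d2 == 0) / sum(d2 == 0)
      } else {
        inv <- d2^(-1 / (m - 1))
        u[i, ] <- inv / sum(inv)
      }
    }
    v_new <- numeric(k)
    for (j in seq_len(k)) v_new[j] <- sum(u[, j]^m * x) / sum(u[, j]^m)
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  list(centers = v, membership = u)
}

# per-pixel loop projections
oracle_project <- function(a, type) {
  out <- matrix(NA_real_, dim(a)[2], dim(a)[3])
  for (r in seq_len(dim(a)[2])) for (cc in seq_len(dim(a)[3])) {
    out[r, cc] <- if (type == "MIP") max(a[, r, cc]) else mean(a[, r, cc])
  }
  out
}

# explicit loop masked mean
oracle_masked_mean <- function(img, mask) {
  s <- 0; n <- 0
  for (i in seq_along(img)) if (mask[i]) { s <- s + img[i]; n <- n + 1 }
  s / n
}

# exhaustive pair counting AUC (ties 0.5)
oracle_auc <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  tot <- 0
  for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(ys))
}

# exhaustive pair enumeration Kendall tau-b
oracle_tau_b <- function(x, y) {
  n <- length(x)
  P <- 0; Q <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) next
    if (dx == 0) { tx <- tx + 1 }
    else if (dy == 0) { ty <- ty + 1 }
    else if (sign(dx) == sign(dy)) P <- P + 1 else Q <- Q + 1
  }
  nb <- n * (n - 1) / 2
  tt <- table(x); uu <- table(y)
  n1 <- sum(tt * (tt - 1) / 2); n2 <- sum(uu * (uu - 1) / 2)
  (P - Q) / sqrt((nb - n1) * (nb - n2))
}

# brute-force border ring mean for a 2D slice lesion mask (8-connectivity,
# configurable ring width) by explicit pixel enumeration
oracle_ring_mean <- function(slice, mask, width = 1) {
  vals <- c()
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (mask[r, cc]) next
    near <- FALSE
    for (dr in -width:width) for (dc in -width:width) {
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) && mask[rr, c2]) near <- TRUE
    }
    if (near) vals <- c(vals, slice[r, cc])
  }
  mean(vals)
}

# recursive-free flood fill labeling with full (8/26) connectivity
oracle_label <- function(mask) {
  dm <- dim(mask); if (length(dm) == 2) dm <- c(dm, 1)
  m <- array(as.logical(mask), dm)
  lab <- array(0L, dm)
  nxt <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[cur] != 0L) next
      lab[cur] <- nxt
      pos <- arrayInd(cur, dm)
      for (d1 in -1:1) for (d2 in -1:1) for (d3 in -1:1) {
        p <- pos + c(d1, d2, d3)
        if (all(p >= 1) && all(p <= dm)) {
          li <- p[1] + (p[2] - 1) * dm[1] + (p[3] - 1) * dm[1] * dm[2]
          if (m[li] && lab[li] == 0L) stack <- c(stack, li)
        }
      }
    }
  }
  array(lab, dim(mask))
}
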