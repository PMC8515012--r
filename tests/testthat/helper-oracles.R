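# Independent oracles: deliberately naive implementations used only to
# freeze expected values. They never share code paths with the package.

# least squares by the normal equations, one column at a time
oracle_normal_equations <- function(X, Y) {
  XtXinv <- solve(t(X) %*% X)
  apply(as.matrix(Y), 2L, function(y) XtXinv %*% t(X) %*% y)
}

# ridge by the literal closed form with an explicit inverse
oracle_ridge <- function(X, y, lambda_vec) {
  solve(t(X) %*% X + diag(lambda_vec, ncol(X)), t(X) %*% y)
}

# singular values via eigendecomposition of the Gram matrix
oracle_singular_values <- function(E) {
  ev <- eigen(t(E) %*% E, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

# tau-b by explicit O(n^2) pair enumeration
oracle_kendall <- function(a, b) {
  n <- length(a)
  conc <- disc <- ta <- tb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- a[i] - a[j]; db <- b[i] - b[j]
    if (da == 0 && db == 0) { ta <- ta + 1; tb <- tb + 1 }
    else if (da == 0) ta <- ta + 1
    else if (db == 0) tb <- tb + 1
    else if (sign(da) == sign(db)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - ta) * (n0 - tb))
}

# MI by direct summation over the contingency table, plus Miller-Madow terms
oracle_mi_mm <- function(x, y) {
  n <- length(x)
  tab <- table(x, y)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  corr <- ((sum(px > 0) - 1) + (sum(py > 0) - 1) - (sum(p > 0) - 1)) /
    (2 * n * log(2))
  unname(mi + corr)
}

# exhaustive pointwise-term redundancy oracle on small alphabets; its own
# straightforward IPF loop, triple loops over every joint state
oracle_iccs <- function(s1, s2, t) {
  n <- length(t)
  a1 <- sort(unique(s1)); a2 <- sort(unique(s2)); at <- sort(unique(t))
  p <- array(0, c(length(a1), length(a2), length(at)))
  for (r in 1:n) {
    i <- which(a1 == s1[r]); j <- which(a2 == s2[r]); k <- which(at == t[r])
    p[i, j, k] <- p[i, j, k] + 1 / n
  }
  m13 <- apply(p, c(1, 3), sum); m23 <- apply(p, c(2, 3), sum)
  m12 <- apply(p, c(1, 2), sum)
  # same stopping rule as the package definition (part of the construction)
  q <- array(1 / length(p), dim(p))
  for (iter in 1:5000) {
    cur <- apply(q, c(1, 3), sum)
    for (i in seq_along(a1)) for (k in seq_along(at))
      q[i, , k] <- q[i, , k] * (if (cur[i, k] > 0) m13[i, k] / cur[i, k] else 0)
    cur <- apply(q, c(2, 3), sum)
    for (j in seq_along(a2)) for (k in seq_along(at))
      q[, j, k] <- q[, j, k] * (if (cur[j, k] > 0) m23[j, k] / cur[j, k] else 0)
    cur <- apply(q, c(1, 2), sum)
    for (i in seq_along(a1)) for (j in seq_along(a2))
      q[i, j, ] <- q[i, j, ] * (if (cur[i, j] > 0) m12[i, j] / cur[i, j] else 0)
    err <- max(abs(apply(q, c(1, 3), sum) - m13),
               abs(apply(q, c(2, 3), sum) - m23),
               abs(apply(q, c(1, 2), sum) - m12))
    if (err < 1e-10) break
  }
  p1 <- apply(q, 1, sum); p2 <- apply(q, 2, sum); pt <- apply(q, 3, sum)
  q13 <- apply(q, c(1, 3), sum); q23 <- apply(q, c(2, 3), sum)
  q12 <- apply(q, c(1, 2), sum)
  red <- 0
  for (i in seq_along(a1)) for (j in seq_along(a2)) for (k in seq_along(at)) {
    if (q[i, j, k] <= 0) next
    if (q13[i, k] <= 0 || q23[j, k] <= 0 || q12[i, j] <= 0) next
    i1 <- log2(q13[i, k] / (p1[i] * pt[k]))
    i2 <- log2(q23[j, k] / (p2[j] * pt[k]))
    i12 <- log2(q[i, j, k] / (q12[i, j] * pt[k]))
    cc <- i1 + i2 - i12
    if (i1 > 0 && i2 > 0 && cc > 0) red <- red + q[i, j, k] * cc
  }
  mi_plug <- function(x, y) {
    pxy <- table(x, y) / n
    s <- 0
    px <- rowSums(pxy); py <- colSums(pxy)
    for (i in seq_along(px)) for (j in seq_along(py))
      if (pxy[i, j] > 0) s <- s + pxy[i, j] * log2(pxy[i, j] / (px[i] * py[j]))
    s
  }
  min(max(red, 0), mi_plug(s1, t), mi_plug(s2, t))
}
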