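# Internal numeric helpers shared across modules.

# wrap displacements into [-L/2, L/2)
.wrapHalf <- function(d, L) d - L * floor(d / L + 0.5)

# wrap absolute coordinates into [0, L)
.wrapBox <- function(x, L) x - L * floor(x / L)

# row-wise cross product of two n x 3 matrices
.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rowNorm <- function(a) sqrt(rowSums(a * a))

.unitRows <- function(a) a / .rowNorm(a)

# row-wise minimum of a matrix (single C pass via max.col)
.rowMins <- function(m) {
  if (ncol(m) == 1L) return(m[, 1L])
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# IUPAC-signed dihedral angle (degrees) for rows of four n x 3 matrices
.dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- .unitRows(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - rowSums(b0 * b1) * b1
  w <- b2 - rowSums(b2 * b1) * b1
  x <- rowSums(v * w)
  y <- rowSums(.rowCross(b1, v) * w)
  atan2(y, x) * 180 / pi
}

# NeRF extension: place D given bond C-D = r (Angstrom), angle B-C-D = theta
# (degrees) and torsion A-B-C-D = chi (degrees)
.nerf <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  C + bc * d[1] + m * d[2] + n * d[3]
}

# rotation matrix sending unit vector 'from' onto unit vector 'to'
.rotationBetween <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (abs(c_ + 1) < 1e-12) { # antiparallel: rotate 180 deg about any orthogonal
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# rotation matrix about axis (unit 3-vector) by angle in radians
.rotationAbout <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  matrix(c(
    ca + ux^2 * (1 - ca), ux * uy * (1 - ca) + uz * sa, ux * uz * (1 - ca) - uy * sa,
    ux * uy * (1 - ca) - uz * sa, ca + uy^2 * (1 - ca), uy * uz * (1 - ca) + ux * sa,
    ux * uz * (1 - ca) + uy * sa, uy * uz * (1 - ca) - ux * sa, ca + uz^2 * (1 - ca)
  ), 3, 3)
}

# Kabsch superposition: rotation + translation mapping P onto Q (n x 3 each),
# proper rotation only (no reflection).
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  Pr <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Q0)^2)))
  list(R = R, center = cp, shift = cq, rmsd = rmsd)
}

.applyTransform <- function(X, fit) {
  sweep(sweep(X, 2, fit$center) %*% t(fit$R), 2, fit$shift, `+`)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# derived sub-seed, kept below 2^31
.subSeed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + j * 15485863) %% 2147483629)
}
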