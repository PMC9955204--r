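# Internal numeric helpers shared across modules.

# round() in R rounds half to even; compositions are reported with
# conventional half-up rounding (31.75 -> 31.8).
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-12) / p
}

# Draw n samples from N(0, Sigma) for symmetric PSD Sigma (possibly
# singular), via eigendecomposition.
rmvnormPSD <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(vals), length(vals))
  Z <- matrix(rnorm(n * length(vals)), n)
  Z %*% t(L)
}

isPSD <- function(Sigma, tol = 1e-8) {
  if (max(abs(Sigma - t(Sigma))) > tol * max(1, max(abs(Sigma)))) return(FALSE)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(1, max(abs(ev)))
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vectorized signed dihedral over rows of n x 3 matrices, degrees in
# (-180, 180], IUPAC sign convention (cis = 0).
dihedralRows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cr(n1, n2) * b2) / b2n
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

# Place atom D from reference atoms A-B-C given bond |CD|, angle B-C-D
# (degrees) and torsion A-B-C-D (degrees); the standard internal-coordinate
# (NeRF) construction.
placeAtom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- crossProd3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate reference geometry for atom placement")
  n <- n / nn
  m <- crossProd3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + C)
}

# Deterministic child seed derived from a base seed and a stage tag,
# kept below 2^31.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103 + h * 12289 + 49297) %% 2147483647)
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
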