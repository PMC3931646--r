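# Independent brute-force oracles used to cross-check the package's
# implementations. These are written from the definitions, not by
# calling the code paths they verify.

# all-pairs / all-frames mean distance between acidic and basic charge
# atoms, by explicit loops over frames and pairs
oracleMeanDistances <- function(ensemble, sites, frames) {
  neg <- sites[sites$sign < 0, , drop = FALSE]
  pos <- sites[sites$sign > 0, , drop = FALSE]
  out <- matrix(0, nrow(neg), ncol = nrow(pos))
  for (a in seq_len(nrow(neg))) {
    for (b in seq_len(nrow(pos))) {
      d <- 0
      for (f in frames) {
        pa <- ensemble@xyz[f, 3 * (neg$atom[a] - 1) + 1:3]
        pb <- ensemble@xyz[f, 3 * (pos$atom[b] - 1) + 1:3]
        d <- d + sqrt(sum((pa - pb)^2))
      }
      out[a, b] <- d / length(frames)
    }
  }
  rownames(out) <- paste0(neg$resid, neg$resno)
  colnames(out) <- paste0(pos$resid, pos$resno)
  out
}

# union-find connected components over site keys
oracleComponents <- function(keys, edges) {
  parent <- stats::setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(match(edges[k, 1], keys))
      rb <- find(match(edges[k, 2], keys))
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(keys), find, numeric(1))
  match(roots, unique(roots))
}

# brute-force Tri-Asp scan: explicit character tests at every offset
oracleTriAsp <- function(seq, allowE = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- integer()
  flank <- if (allowE) c("D", "E") else "D"
  for (i in seq_len(max(0, n - 10))) {
    if (ch[i] %in% flank && ch[i + 4] == "D" && ch[i + 10] %in% flank)
      hits <- c(hits, i)
  }
  hits
}

# grid search for the Hill fit: Imax solved conditionally by linear
# least squares at each (K, N) grid node
oracleHillGrid <- function(conc, current,
                           kGrid = exp(seq(log(0.5), log(1000),
                                           length.out = 120)),
                           nGrid = seq(0.5, 5, length.out = 80)) {
  best <- list(rss = Inf)
  for (K in kGrid) {
    for (N in nGrid) {
      m <- conc^N / (conc^N + K^N)
      imax <- sum(current * m) / sum(m^2)
      rss <- sum((current - imax * m)^2)
      if (rss < best$rss)
        best <- list(imax = imax, k05 = K, nh = N, rss = rss)
    }
  }
  best
}

# independent constant-field current sum (no small-u series, evaluated
# away from E = 0) and reversal by plain bisection
oracleGHKCurrent <- function(E, aNaIn, aNaOut, aCaIn, aCaOut, r, kT) {
  u <- E / kT
  iNa <- E * (aNaIn - aNaOut * exp(-u)) / (1 - exp(-u))
  iCa <- 4 * E * (aCaIn - aCaOut * exp(-2 * u)) / (1 - exp(-2 * u))
  iNa + r * iCa
}

oracleBisectErev <- function(aNaIn, aNaOut, aCaIn, aCaOut, r, kT,
                             lo = -150, hi = 150, tol = 1e-9) {
  f <- function(E) oracleGHKCurrent(E, aNaIn, aNaOut, aCaIn, aCaOut, r, kT)
  if (sign(f(lo)) == sign(f(hi))) stop("oracle: no bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mid == 0) mid <- mid + tol / 10
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# rigid rotation matrix from an axis-angle
oracleRotation <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

applyRigid <- function(ensemble, R, shift) {
  xyz <- ensemble@xyz
  for (f in seq_len(nrow(xyz))) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    co <- t(R %*% t(co)) + matrix(shift, nrow(co), 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(co))
  }
  methods::new("StructureEnsemble", atoms = ensemble@atoms, xyz = xyz,
               midplaneZ = ensemble@midplaneZ)
}
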