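# shared fixtures and independent oracles

# reversible chain with prescribed stationary vector (Metropolis construction:
# uniform proposal over the other states, move probability `a`)
metropolis_chain <- function(pi, a = 0.2) {
  n <- length(pi)
  T <- matrix(0, n, n, dimnames = list(names(pi), names(pi)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) T[i, j] <- a / (n - 1) * min(1, pi[j] / pi[i])
  }
  diag(T) <- 1 - rowSums(T)
  T
}

# independent rigid-superposition oracle: Horn's quaternion method
quaternion_superpose <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  # rotation acting as A %*% R (row-vector convention used by the package)
  R <- t(R)
  rmsd <- sqrt(mean(rowSums((A %*% R - B)^2)))
  list(rotation = R, rmsd = rmsd)
}

# build a state_shift_set from residues x states shift matrices
make_set <- function(H, N, lw_H = 0.02, lw_N = 0.15,
                     state_names = paste0("s", seq_len(ncol(H)))) {
  tables <- lapply(seq_len(ncol(H)), function(s) {
    data.frame(residue = seq_len(nrow(H)), code = NA_character_,
               N = N[, s], H = H[, s],
               lw_N = rep_len(lw_N, nrow(H)), lw_H = rep_len(lw_H, nrow(H)))
  })
  names(tables) <- state_names
  state_shift_set(tables)
}

# wrap a raw correlation matrix as the chesca_matrix the scoring ops consume
as_chesca <- function(R, residues = seq_len(nrow(R))) {
  dimnames(R) <- list(residues, residues)
  structure(list(residues = residues, R = R), class = "chesca_matrix")
}
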