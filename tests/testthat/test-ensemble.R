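test_that("Kabsch superposition: identity, known rotation, quaternion oracle", {
  set.seed(1)
  ref <- matrix(rnorm(15), 5, 3)
  same <- kabsch_superpose(ref, ref)
  expect_equal(same$rotation, diag(3), tolerance = 1e-12)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)

  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))   # 90 deg about z
  mob <- ref %*% t(Rz)
  fit <- kabsch_superpose(mob, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$transform(mob), ref, tolerance = 1e-10)

  # perturbed copy: rmsd must match an independent quaternion solution
  mob2 <- sweep(ref %*% t(Rz), 2, c(3, -1, 2), `+`) +
    matrix(rnorm(15, 0, 0.1), 5, 3)
  k <- kabsch_superpose(mob2, ref)
  q <- quaternion_superpose(mob2, ref)
  expect_equal(k$rmsd, q$rmsd, tolerance = 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-12)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 0.1), "collinear")
})

test_that("featurization removes rigid-body motion and flags displacements", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  key <- 8:10; align <- 1:7
  ident <- featurize(list(ref, ref), key, align, reference = ref)
  expect_equal(max(abs(ident$features)), 0, tolerance = 1e-12)

  moved <- sweep(ref, 2, c(5, -2, 1), `+`)            # pure translation
  rot <- ref %*% t(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1)))
  ft <- featurize(list(moved, rot), key, align, reference = ref)
  expect_lt(max(abs(ft$features)), 1e-8)

  disp <- ref; disp[9, ] <- disp[9, ] + c(1, 0, 0)    # one atom, 1 A in x
  f1 <- featurize(list(disp), key, align, reference = ref)
  v <- drop(f1$features)
  expect_equal(unname(v[names(v) == "atom9_x"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(v[names(v) != "atom9_x"])), 1e-10)

  short <- ref[1:5, ]
  expect_error(featurize(list(short), key, align, reference = ref),
               "model 1")
})

test_that("tICA: AR(1) eigenvalue, white-noise null, and a 2x2 oracle", {
  set.seed(3)
  n <- 20000
  x <- numeric(n)
  for (i in 2:n) x[i] <- 0.9 * x[i - 1] + rnorm(1)
  t1 <- tica(matrix(x, ncol = 1), lag = 1)
  expect_equal(t1$eigenvalues[1], 0.9, tolerance = 0.02)

  wn <- matrix(rnorm(4000), 2000, 2)
  t2 <- tica(wn, lag = 1)
  expect_lt(max(abs(t2$eigenvalues)), 0.1)
  expect_true(all(t2$eigenvalues >= -1 - 1e-6 & t2$eigenvalues <= 1 + 1e-6))

  # independent generalized-eigen solution on the same 2x2 covariances
  set.seed(4)
  X <- matrix(rnorm(600), 300, 2) %*% rbind(c(1, 0.6), c(0, 1))
  X[, 1] <- X[, 1] + 0.5 * c(0, X[-300, 1])
  tf <- tica(X, lag = 2, n_components = 2)
  Xc <- sweep(X, 2, colMeans(X))
  m <- nrow(X) - 2
  X0 <- Xc[1:m, ]; Xt <- Xc[3:nrow(X), ]
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * m)
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * m)
  ge <- eigen(solve(C0) %*% Ct)      # non-symmetric route, same problem
  ord <- order(Re(ge$values), decreasing = TRUE)
  expect_equal(tf$eigenvalues, Re(ge$values)[ord], tolerance = 1e-10)
  for (j in 1:2) {
    v <- Re(ge$vectors[, ord[j]])
    v <- v / sqrt(sum((Xc %*% v)^2))   # match unit-variance normalization
    ratio <- tf$components[, j] / v
    expect_equal(abs(ratio / ratio[1]), c(1, 1), tolerance = 1e-6)
  }

  expect_message(tica(cbind(x[1:100], x[1:100]), lag = 1), "regularized")
})

test_that("k-means microstates: separation, k=1 mean, exhaustive SSE oracle", {
  set.seed(5)
  blob1 <- matrix(rnorm(60, 0, 0.2), 30, 2)
  blob2 <- matrix(rnorm(60, 10, 0.2), 30, 2)
  km <- kmeans_microstates(rbind(blob1, blob2), k = 2, seed = 1)
  expect_equal(length(unique(km$labels[1:30])), 1L)
  expect_equal(length(unique(km$labels[31:60])), 1L)
  expect_false(km$labels[1] == km$labels[31])

  one <- kmeans_microstates(blob1, k = 1, seed = 1)
  expect_equal(drop(one$centers), colMeans(blob1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # 6 points, k = 2: compare with exhaustive enumeration of 2-partitions
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5, 5, 6), 6, 2, byrow = TRUE)
  km6 <- kmeans_microstates(pts, k = 2, seed = 3)
  best_sse <- Inf
  for (mask in 1:(2^5)) {        # point 1 fixed in group A
    grp <- c(1L, as.integer(intToBits(mask))[1:5] + 1L)
    if (length(unique(grp)) < 2L) next
    sse <- sum(vapply(1:2, function(g) {
      p <- pts[grp == g, , drop = FALSE]
      sum(sweep(p, 2, colMeans(p))^2)
    }, numeric(1)))
    best_sse <- min(best_sse, sse)
  }
  expect_equal(km6$sse, best_sse, tolerance = 1e-10)
})

test_that("MSM estimation: exact small cases and detailed balance", {
  alt <- rep(c(0L, 1L), 50)
  m <- estimate_msm(alt, lag = 1, mode = "naive")
  expect_equal(unname(m$T), rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(m$pi), c(0.5, 0.5))

  single <- estimate_msm(rep(1L, 10), lag = 1)
  expect_equal(unname(single$T), matrix(1, 1, 1))
  expect_equal(unname(single$pi), 1)

  set.seed(6)
  labs <- sample(1:3, 5000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  rev <- estimate_msm(labs, lag = 1, mode = "reversible")
  expect_lt(max(abs(rev$pi * rev$T - t(rev$pi * rev$T))), 1e-10)
  expect_lt(max(abs(rowSums(rev$T) - 1)), 1e-12)
  expect_lt(max(abs(drop(rev$pi %*% rev$T) - rev$pi)), 1e-10)
})

test_that("MSM recovers a known transition matrix within binomial error", {
  T <- rbind(c(0.90, 0.08, 0.02),
             c(0.30, 0.60, 0.10),
             c(0.10, 0.30, 0.60))
  set.seed(7)
  s <- allokin:::sample_chain(T, 1e5)
  m <- estimate_msm(s, lag = 1, mode = "naive")
  visits <- table(s[-length(s)])
  for (i in 1:3) for (j in 1:3) {
    sd_ij <- sqrt(T[i, j] * (1 - T[i, j]) / visits[[i]])
    expect_lt(abs(m$T[i, j] - T[i, j]), max(3 * sd_ij, 1e-9))
  }
})

test_that("disconnected microstates are dropped to the largest strong component", {
  labs <- c(rep(c(1L, 2L), 30), rep(3L, 5))   # 3 reachable but never left
  expect_message(m <- estimate_msm(labs, lag = 1, mode = "naive"), "dropped")
  expect_setequal(m$states, c("1", "2"))
  expect_true(all(is.na(m$dtraj[61:65])))
})

test_that("macrostate populations: analytic stationary vectors and coverage", {
  T <- rbind(c(0.9, 0.1), c(0.5, 0.5))    # pi = (5/6, 1/6)
  tm <- transition_model(T)
  pops <- macrostate_population(tm, list(GS = "1", ES = "2"), n_boot = 0)
  expect_equal(pops$population, c(5 / 6, 1 / 6), tolerance = 1e-12)
  all_one <- macrostate_population(tm, list(all = c("1", "2")), n_boot = 0)
  expect_equal(all_one$population, 1)
  expect_message(
    un <- macrostate_population(tm, list(GS = "1"), n_boot = 0),
    "unassigned")
  expect_equal(un$population[un$macro == "unassigned"], 1 / 6,
               tolerance = 1e-12)
})

test_that("bootstrap CIs cover the generating macrostate population", {
  pi_t <- c(GS = 0.82, ES1 = 0.12, ES2 = 0.06)
  T <- metropolis_chain(pi_t)
  hits <- 0; reps <- 10
  for (r in seq_len(reps)) {
    km <- kmc_sample(T, 20000, seed = 100 + r)
    m <- estimate_msm(km$states, lag = 1)
    pops <- macrostate_population(m, list(GS = "GS", ES1 = "ES1", ES2 = "ES2"),
                                  n_boot = 50, seed = r)
    row <- pops[pops$macro == "ES2", ]
    if (row$lower <= 0.06 && 0.06 <= row$upper) hits <- hits + 1
  }
  expect_gte(hits, reps * 0.7)
})

test_that("kinetic Monte Carlo: determinism, absorbing chain, stationarity", {
  T <- metropolis_chain(c(GS = 0.82, ES1 = 0.12, ES2 = 0.06))
  a <- kmc_sample(T, 5000, seed = 11)
  b <- kmc_sample(T, 5000, seed = 11)
  expect_identical(a$states, b$states)

  ident <- kmc_sample(diag(2), 100, seed = 1, init = "2")
  expect_true(all(ident$states == "2"))

  long <- kmc_sample(T, 60000, seed = 11)
  freq <- table(factor(long$states, levels = names(T[1, ]))) / 60000
  expect_lt(max(abs(as.numeric(freq) - c(0.82, 0.12, 0.06))), 0.02)

  em <- list(GS = matrix(0, 2, 1), ES1 = matrix(1, 2, 1),
             ES2 = matrix(2, 2, 1))
  ks <- kmc_sample(T, 500, seed = 2, emissions = em)
  expect_equal(nrow(ks$series), 500)
  expect_equal(drop(ks$series),
               c(GS = 0, ES1 = 1, ES2 = 2)[ks$states],
               ignore_attr = TRUE)
})

test_that("principal modes match hand-computed covariance eigenpairs", {
  line <- cbind(1:10, 2 * (1:10))               # rank-1 data
  pm <- principal_modes(line, n_modes = 2)
  expect_equal(pm$values[2], 0, tolerance = 1e-10)
  expect_equal(abs(pm$vectors[, 1]), c(1, 2) / sqrt(5), tolerance = 1e-10)

  tri <- rbind(c(0, 0), c(2, 0), c(1, 2))       # 3-point planar fixture
  pm3 <- principal_modes(tri, n_modes = 2)
  ev <- eigen(stats::cov(scale(tri, scale = FALSE)))
  expect_equal(pm3$values, ev$values, tolerance = 1e-12)
  expect_equal(abs(pm3$vectors), abs(ev$vectors), tolerance = 1e-12)

  set.seed(8)
  iso <- matrix(rnorm(4000), 2000, 2)
  pmi <- principal_modes(iso)
  expect_lt(pmi$values[1] / pmi$values[2], 1.2)
})

test_that("group RMSD isolates per-group displacements", {
  set.seed(9)
  ref <- matrix(rnorm(36), 12, 3)
  groups <- list(cspine = 1:4, shell = 5:8, rspine = 9:12)
  zero <- group_rmsd(list(ref, ref), ref, groups, align = 1:8)
  expect_equal(max(abs(zero$per_frame)), 0, tolerance = 1e-12)

  disp <- ref; disp[9:12, 1] <- disp[9:12, 1] + 1      # move rspine 1 A in x
  g <- group_rmsd(list(disp), ref, groups, align = 1:8)
  expect_equal(unname(g$per_frame[1, "rspine"]), 1, tolerance = 1e-10)
  expect_lt(max(g$per_frame[1, c("cspine", "shell")]), 1e-10)

  one <- ref; one[5, ] <- one[5, ] + c(0.3, 0.4, 0)
  g1 <- group_rmsd(list(one), ref, list(solo = 5), align = c(1:4, 6:12))
  expect_equal(unname(g1$per_frame[1, "solo"]), 0.5, tolerance = 1e-10)
  expect_error(group_rmsd(list(ref), ref, list(a = integer(0))), "empty")
})

test_that("rotamer mutual information reproduces closed forms", {
  set.seed(10)
  x <- sample(c(60, 180, 300), 3000, replace = TRUE)    # 3 equiprobable bins
  mi <- suppressWarnings(rotamer_mi(cbind(a = x, b = x)))
  expect_equal(mi["a", "b"], log2(3), tolerance = 0.01)
  expect_equal(mi["a", "a"], log2(3), tolerance = 0.01) # marginal entropy
  expect_true(isSymmetric(mi))

  # joint counts [[40,10],[10,40]] over two half-circle bins: 0.278 bits
  a <- c(rep(90, 50), rep(270, 50))
  b <- c(rep(90, 40), rep(270, 10), rep(90, 10), rep(270, 40))
  mi2 <- suppressWarnings(rotamer_mi(cbind(a, b), breaks = c(0, 180, 360)))
  expect_equal(mi2["a", "b"], 0.2780719, tolerance = 1e-6)

  y <- sample(c(60, 180, 300), 3000, replace = TRUE)    # independent
  mi3 <- suppressWarnings(rotamer_mi(cbind(x = x, y = y)))
  expect_lt(mi3["x", "y"], 0.05)
  expect_gte(mi3["x", "y"], 0)

  const <- suppressWarnings(rotamer_mi(cbind(c = rep(10, 500), x = x[1:500])))
  expect_equal(const["c", "c"], 0)
  expect_equal(const["c", "x"], 0)
})

test_that("delta omega pipeline: exact means, bootstrap sd, missing states", {
  means <- rbind(GS = c(V104 = 2.0), ES2 = c(V104 = 1.0))
  exact <- delta_omega(gen_snapshot_shifts(means, sd = 0, n_per_state = 10))
  expect_equal(exact$delta_omega, 1.0, tolerance = 1e-12)

  same <- gen_snapshot_shifts(rbind(GS = c(s = 5), ES2 = c(s = 5)), sd = 0.1,
                              n_per_state = 200, seed = 3)
  d0 <- delta_omega(same)
  expect_lt(d0$delta_omega, 3 * 0.1 * sqrt(2 / 200))
  expect_gt(d0$boot_sd, 0)

  partial <- gen_snapshot_shifts(rbind(GS = c(a = 1, b = 2),
                                       ES2 = c(a = 2, b = 3)),
                                 sd = 0.1, n_per_state = 50, seed = 4)
  partial <- partial[!(partial$site == "b" & partial$state == "ES2"), ]
  expect_message(dp <- delta_omega(partial), "skipped")
  expect_equal(dp$site, "a")
})

test_that("predicted-vs-experimental comparison matches normal equations", {
  x <- c(0.3, 0.9, 1.1, 0.6)
  expect_equal(compare_delta_omega(x, x)$slope, 1, tolerance = 1e-12)
  expect_equal(compare_delta_omega(x, x)$r_squared, 1, tolerance = 1e-12)
  half <- compare_delta_omega(0.5 * x, x)
  expect_equal(half$slope, 0.5, tolerance = 1e-12)
  expect_equal(half$r_squared, 1, tolerance = 1e-12)

  y <- c(0.35, 0.80, 1.00, 0.70)
  fit <- compare_delta_omega(y, x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)       # normal-equations oracle
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  ss_res <- sum((y - X %*% beta)^2)
  expect_equal(fit$r_squared, 1 - ss_res / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_error(compare_delta_omega(x[1:2], x[1:2]), "paired sites")
})

test_that("kMC round trip recovers the generating transition matrix", {
  T <- metropolis_chain(c(GS = 0.7, ES1 = 0.2, ES2 = 0.1), a = 0.3)
  for (seed in c(21, 22, 23)) {
    km <- kmc_sample(T, 30000, seed = seed)
    m <- estimate_msm(km$states, lag = 1, mode = "naive")
    visits <- table(factor(km$states[-30000], levels = rownames(T)))
    for (i in rownames(T)) for (j in colnames(T)) {
      sd_ij <- sqrt(T[i, j] * (1 - T[i, j]) / visits[[i]])
      expect_lt(abs(m$T[i, j] - T[i, j]), max(3.5 * sd_ij, 1e-9))
    }
  }
})
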