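test_that("correlation matrix reproduces hand Pearson values", {
  # encode per-state response directly in H (N held flat so combined = H)
  H <- rbind(c(0, 1, 2, 3),
             c(0, 1, 2, 3),
             c(3, 2, 1, 0),
             c(0, 1, 2, 10))
  N <- matrix(120, 4, 4)
  suppressWarnings(cm <- correlation_matrix(make_set(H, N)))
  expect_equal(cm$R[1, 2], 1)
  expect_equal(cm$R[1, 3], -1)
  expect_equal(cm$R[1, 4], 0.875064, tolerance = 1e-6)   # frozen from cor()
  expect_true(isSymmetric(cm$R, tol = 1e-12))
  expect_equal(unname(diag(cm$R)), rep(1, 4))
})

test_that("zero-variance residues are excluded with a warning", {
  H <- rbind(c(0, 1, 2, 3), c(8, 8, 8, 8), c(1, 0, 2, 5))
  set <- make_set(H, matrix(120, 3, 4))
  expect_warning(cm <- correlation_matrix(set), "zero")
  expect_equal(cm$residues, c(1L, 3L))
})

test_that("correlations are invariant to affine rescaling of responses", {
  set.seed(42)
  H <- matrix(rnorm(20, 8, 0.1), 5, 4)
  N <- matrix(rnorm(20, 120, 1), 5, 4)
  base <- correlation_matrix(make_set(H, N))
  # per-residue affine map of the response vector: r -> a*r + b
  resp <- H + 0.154 * N
  a <- c(2, -3, 0.5, 10, 1); b <- c(1, 0, -5, 2, 7)
  H2 <- resp * a + b           # fold affine map into H, zero out N
  scaled <- correlation_matrix(make_set(H2, matrix(0, 5, 4)))
  expect_equal(abs(scaled$R), abs(base$R), tolerance = 1e-10)
})

test_that("corr_score counts pairs above the cutoff with a strict inequality", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.99
  R[1, 3] <- R[3, 1] <- 0.50
  R[2, 3] <- R[3, 2] <- 0.10
  cm <- as_chesca(R)
  expect_equal(corr_score(cm, cutoff = 0.98, subset = 1), 0.5)  # 1 of 2
  expect_equal(corr_score(cm, cutoff = 0.98), 1 / 3)
  # strict '>' at cutoff 1 excludes exact duplicates with R = 1
  dup <- as_chesca(matrix(1, 2, 2))
  expect_equal(corr_score(dup, cutoff = 1), 0)
  expect_equal(corr_score(dup, cutoff = 0.98), 1)
})

test_that("corr_score is monotone in the cutoff and matches brute force", {
  set.seed(7)
  X <- matrix(rnorm(24), 6, 4)
  R <- cor(t(X))
  cm <- as_chesca(R)
  cuts <- seq(0, 1, 0.05)
  scores <- vapply(cuts, function(ct) corr_score(cm, cutoff = ct), numeric(1))
  expect_true(all(diff(scores) <= 0))
  expect_true(all(scores >= 0 & scores <= 1))
  # brute-force pair counting oracle
  for (ct in c(0.3, 0.7, 0.98)) {
    cnt <- 0; tot <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      tot <- tot + 1
      if (abs(R[i, j]) > ct) cnt <- cnt + 1
    }
    expect_equal(corr_score(cm, cutoff = ct), cnt / tot)
  }
})

test_that("whole-protein corr_score reflects the coordinated fraction", {
  sp <- shift_gen_spec(n_residues = 40, coordinated_fraction = 0.5,
                       noise_sd_H = 0.001, noise_sd_N = 0.005, seed = 19)
  set <- gen_shift_states(sp)
  cm <- correlation_matrix(set)
  truth <- attr(set, "truth")
  # brute-force expectation: only coordinated-coordinated pairs correlate
  coord <- truth$residue[truth$coordinated]
  n_pairs <- choose(length(cm$residues), 2)
  expected <- choose(length(intersect(coord, cm$residues)), 2) / n_pairs
  # random (noise-only) pairs clear 0.98 only rarely, inflating the score
  # by at most a few percent over the pure coordinated-pair count
  expect_lt(abs(corr_score(cm, cutoff = 0.98) - expected), 0.05)
})

test_that("agglomerative clustering recovers exact blocks and handles edge cases", {
  R <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  cl <- cluster_residues(as_chesca(R), n_clusters = 2)
  expect_equal(unname(cl[1]), unname(cl[2]))
  expect_equal(unname(cl[3]), unname(cl[4]))
  expect_false(cl[[1]] == cl[[3]])
  single <- as_chesca(matrix(1, 1, 1))
  expect_equal(unname(cluster_residues(single)), 1L)
})

test_that("complete-linkage merges match a brute-force implementation", {
  set.seed(3)
  X <- matrix(rnorm(16), 4, 4)
  R <- cor(t(X))
  D <- 1 - abs(R)
  # brute-force complete linkage on 4 items
  clusters <- as.list(1:4)
  heights <- c()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a < b) {
        d <- max(D[clusters[[a]], clusters[[b]]])
        if (d < bd) { bd <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    if (length(clusters) == 2L) brute_k2 <- clusters
  }
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  expect_equal(hc$height, heights, tolerance = 1e-12)
  cl <- cluster_residues(as_chesca(R), n_clusters = 2)
  grp1 <- which(cl == cl[[brute_k2[[1]][1]]])
  expect_setequal(grp1, brute_k2[[1]])
})

test_that("community scores count cross pairs over nA*nB", {
  R <- diag(4)
  R[1, 3] <- R[3, 1] <- 0.9
  R[1, 4] <- R[4, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- 0.9
  R[2, 4] <- R[4, 2] <- 0.5    # 3 of 4 cross pairs above 0.8
  cm <- as_chesca(R)
  S <- community_scores(cm, list(A = 1:2, B = 3:4), cutoff = 0.8)
  expect_equal(S["A", "B"], 0.75)
  expect_equal(S["B", "A"], 0.75)
  all_hi <- as_chesca(matrix(0.95, 4, 4) + diag(4) * 0.05)
  expect_equal(community_scores(all_hi, list(A = 1:2, B = 3:4))["A", "B"], 1)
  none <- as_chesca(diag(4))
  expect_equal(community_scores(none, list(A = 1:2, B = 3:4))["A", "B"], 0)
})

test_that("cross-community score equals brute-force restricted pair counting", {
  set.seed(9)
  X <- matrix(rnorm(24), 6, 4)
  R <- cor(t(X))
  cm <- as_chesca(R)
  A <- 1:3; B <- 4:6; ct <- 0.5
  S <- community_scores(cm, list(A = A, B = B), cutoff = ct)
  cnt <- 0
  for (i in A) for (j in B) if (abs(R[i, j]) > ct) cnt <- cnt + 1
  expect_equal(S["A", "B"], cnt / (length(A) * length(B)))
  # diagonal block over ordered off-diagonal pairs
  cntA <- 0
  for (i in A) for (j in A) if (i != j && abs(R[i, j]) > ct) cntA <- cntA + 1
  expect_equal(S["A", "A"], cntA / (length(A) * (length(A) - 1)))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("community map handling: missing residues and empty communities", {
  R <- diag(3)
  cm <- as_chesca(R)
  expect_warning(S <- community_scores(cm, list(A = 1:2, B = c(99L))),
                 "dropped")
  expect_equal(dim(S), c(1L, 1L))
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"ComA": [1, 2], "ComB": [3]}', f)
  m <- read_community_map(f)
  expect_equal(m$ComA, c(1L, 2L))
  writeLines('{"ComA": []}', f)
  expect_error(read_community_map(f), "no residues")
})
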