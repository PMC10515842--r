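#' Construct a feature trajectory
#'
#' Time-ordered feature matrix extracted from superposed conformational
#' ensembles (or generated synthetically), the substrate of [tica()],
#' [kmeans_microstates()] and [principal_modes()].
#'
#' @param features frames x dimensions numeric matrix.
#' @param times frame times in lag units (default 0, 1, ...).
#' @param labels optional per-frame state labels (sidecar for synthetic
#'   data).
#' @param feature_labels optional column labels.
#' @return object of class `feature_trajectory`.
#' @export
feature_trajectory <- function(features, times = NULL, labels = NULL,
                               feature_labels = NULL) {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop("need >= 1 feature dimension", call. = FALSE)
  if (anyNA(features)) stop("missing frames/features not allowed", call. = FALSE)
  if (is.null(times)) times <- seq_len(nrow(features)) - 1
  if (!is.null(feature_labels)) colnames(features) <- feature_labels
  structure(list(features = features, times = times, labels = labels),
            class = "feature_trajectory")
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_trajectory")) x$features else as.matrix(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (reflections excluded) and translation that
#' superpose `mobile` onto `reference` over an alignment index set, in the
#' least-squares sense.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param align indices of the atoms used for the superposition (default:
#'   all); needs >= 3 non-collinear points.
#' @return list: `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` over the alignment set, and `transform(x)` applying the fit to
#'   any n x 3 matrix as `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, align = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(align)) align <- seq_len(nrow(mobile))
  if (length(align) < 3L) stop("need >= 3 alignment atoms", call. = FALSE)
  A <- mobile[align, , drop = FALSE]
  B <- reference[align, , drop = FALSE]
  if (anyNA(A) || anyNA(B)) stop("missing coordinates in alignment set", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2L) {
    stop("degenerate (collinear) alignment set", call. = FALSE)
  }
  H <- crossprod(Ac, Bc)           # minimizes ||Ac %*% R - Bc||
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- cb - drop(ca %*% R)
  moved <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((moved - Bc)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% R, 2, tr, `+`))
}

coerce_models <- function(models) {
  if (is.array(models) && length(dim(models)) == 3L) {
    lapply(seq_len(dim(models)[1]), function(i) models[i, , ])
  } else if (is.list(models)) {
    lapply(models, as.matrix)
  } else {
    list(as.matrix(models))
  }
}

#' Featurize a conformational ensemble as Cartesian deviations
#'
#' Each model is superposed on the reference over the alignment set (e.g.
#' the rigid helices of the C-lobe), then represented by the flattened
#' deviation of the key atoms' Cartesian coordinates from the reference.
#' Rigid-body motion of the input therefore produces all-zero features.
#'
#' @param models list of n x 3 coordinate matrices, or a frames x atoms x 3
#'   array.
#' @param key indices of the reporter atoms (e.g. side-chain atoms of the
#'   regulatory-spine and shell residues).
#' @param align indices used for the superposition.
#' @param reference n x 3 reference coordinates (default: first model).
#' @return a [feature_trajectory()] with 3 x `length(key)` dimensions,
#'   columns labelled `atom<k>_<x|y|z>`.
#' @export
featurize <- function(models, key, align, reference = NULL) {
  models <- coerce_models(models)
  if (is.null(reference)) reference <- models[[1]]
  reference <- as.matrix(reference)
  nat <- nrow(reference)
  for (i in seq_along(models)) {
    m <- models[[i]]
    bad <- unique(c(key, align))[unique(c(key, align)) > nrow(m)]
    if (length(bad) || anyNA(m[unique(c(key, align)), ])) {
      stop(sprintf("model %d: missing key/alignment atom(s)%s", i,
                   if (length(bad)) paste0(" ", paste(bad, collapse = ","))
                   else ""), call. = FALSE)
    }
  }
  feats <- t(vapply(models, function(m) {
    fit <- kabsch_superpose(m, reference, align)
    moved <- fit$transform(m)
    as.vector(t(moved[key, , drop = FALSE] - reference[key, , drop = FALSE]))
  }, numeric(3L * length(key))))
  labs <- as.vector(t(outer(key, c("x", "y", "z"),
                            function(k, a) sprintf("atom%d_%s", k, a))))
  feature_trajectory(feats, feature_labels = labs)
}

#' Read a multi-model PDB ensemble as a coordinate list
#'
#' Thin wrapper over `bio3d::read.pdb(multi = TRUE)` returning the format
#' [featurize()] consumes.
#'
#' @param path PDB file with MODEL records.
#' @return list of n_atoms x 3 coordinate matrices, one per model.
#' @export
read_ensemble_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB ensembles requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
}

#' Time-lagged independent component analysis
#'
#' Solves the generalized eigenproblem \eqn{C(\tau) v = \lambda C(0) v}
#' using the symmetrized lagged-covariance estimator; the slowest
#' decorrelating linear combinations of the features come first. Sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param X a [feature_trajectory()] or frames x d matrix.
#' @param lag lag time in frames (frames must exceed the lag).
#' @param n_components number of components to return (default
#'   `min(10, d)`).
#' @return list of class `tica_fit`: `eigenvalues`, `components` (d x k
#'   loadings), `projections` (frames x k), `lag`, `epsilon`
#'   (regularization added to a singular covariance, 0 when none).
#' @export
tica <- function(X, lag = 1, n_components = NULL) {
  X <- as_feature_matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= lag) stop("need more frames than the lag", call. = FALSE)
  if (is.null(n_components)) n_components <- min(10L, d)
  n_components <- min(n_components, d)
  Xc <- sweep(X, 2, colMeans(X))
  X0 <- Xc[seq_len(n - lag), , drop = FALSE]
  Xt <- Xc[seq_len(n - lag) + lag, , drop = FALSE]
  m <- n - lag
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * m)
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * m)
  e0 <- eigen(C0, symmetric = TRUE)
  eps <- 0
  tol <- max(e0$values[1], 0) * 1e-10
  if (any(e0$values < tol) || e0$values[1] <= 0) {
    eps <- max(e0$values[1] * 1e-8, 1e-12)
    message("singular instantaneous covariance: regularized with epsilon = ",
            format(eps))
    e0$values <- e0$values + eps
  }
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), d) %*% t(e0$vectors)
  M <- W %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)[seq_len(n_components)]
  comp <- W %*% em$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(comp))) {
    if (comp[which.max(abs(comp[, j])), j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(eigenvalues = em$values[ord], components = comp,
                 projections = Xc %*% comp, lag = lag, epsilon = eps),
            class = "tica_fit")
}

#' Seeded k-means microstate clustering
#'
#' Deterministic given the seed; an empty-cluster failure is retried with a
#' derived seed (logged via message).
#'
#' @param Y frames x d matrix or [feature_trajectory()] (typically tICA
#'   projections).
#' @param k number of microstates (<= frames).
#' @param seed integer RNG seed.
#' @param nstart random restarts per attempt.
#' @return list: `labels` (per frame), `centers` (k x d), `sse` (total
#'   within-cluster sum of squares).
#' @export
kmeans_microstates <- function(Y, k, seed = 1, nstart = 10) {
  Y <- as_feature_matrix(Y)
  if (k > nrow(Y)) stop("k exceeds number of frames", call. = FALSE)
  for (attempt in 0:4) {
    km <- try(with_seed(seed + attempt * 1000L,
                        stats::kmeans(Y, centers = k, nstart = nstart,
                                      iter.max = 100)),
              silent = TRUE)
    if (!inherits(km, "try-error")) {
      if (attempt > 0) message("k-means re-seeded ", attempt, " time(s)")
      return(list(labels = km$cluster, centers = km$centers,
                  sse = km$tot.withinss))
    }
  }
  stop("k-means failed after re-seeding: ", attr(km, "condition")$message,
       call. = FALSE)
}

#' Estimate a Markov state model from a discrete trajectory
#'
#' Counts transitions with a sliding window at the given lag, restricts to
#' the largest strongly connected set of microstates (dropped states are
#' reported), and row-normalizes. In `reversible` mode the count matrix is
#' symmetrized, \eqn{(C + C^T)/2}, before normalization, which enforces
#' detailed balance exactly with stationary vector proportional to the
#' symmetrized row sums; in `naive` mode the stationary vector is the
#' leading left eigenvector.
#'
#' @param labels integer (or factor) microstate sequence.
#' @param lag lag in frames.
#' @param mode `"reversible"` (default) or `"naive"`.
#' @return object of class `transition_model`: `states`, `counts`, `T`
#'   (row-stochastic), `pi` (stationary), `lag`, `mode`, `dtraj` (the input
#'   restricted to retained states, `NA` elsewhere), `dropped`.
#' @export
estimate_msm <- function(labels, lag = 1, mode = c("reversible", "naive")) {
  mode <- match.arg(mode)
  f <- as.factor(labels)
  raw <- levels(f)
  labels <- as.integer(f)
  n <- length(labels)
  if (n <= lag) stop("trajectory shorter than the lag", call. = FALSE)
  ns <- length(raw)
  from <- labels[seq_len(n - lag)]
  to <- labels[seq_len(n - lag) + lag]
  C <- matrix(tabulate((to - 1L) * ns + from, ns * ns), ns, ns,
              dimnames = list(raw, raw))
  # largest strongly connected component of the transition graph
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  keep_id <- which.max(sizes)
  keep <- which(comp$membership == keep_id)
  dropped <- raw[-keep]
  if (length(dropped)) {
    message("disconnected microstate(s) dropped: ",
            paste(dropped, collapse = ", "))
  }
  C <- C[keep, keep, drop = FALSE]
  if (mode == "reversible") {
    S <- (C + t(C)) / 2
    T <- S / rowSums(S)
    pi <- rowSums(S) / sum(S)
  } else {
    T <- C / rowSums(C)
    ev <- eigen(t(T))
    i1 <- which.min(abs(ev$values - 1))
    pi <- abs(Re(ev$vectors[, i1]))
    pi <- pi / sum(pi)
  }
  names(pi) <- rownames(T)
  dtraj <- raw[labels]
  dtraj[!dtraj %in% rownames(T)] <- NA
  structure(list(states = rownames(T), counts = C, T = T, pi = pi,
                 lag = lag, mode = mode, dtraj = dtraj, dropped = dropped),
            class = "transition_model")
}

#' Build a transition model directly from a known matrix
#'
#' Convenience constructor for kinetic Monte Carlo sampling from a
#' prescribed transition matrix (e.g. a synthetic ground truth).
#'
#' @param T row-stochastic matrix; row/column names become state labels.
#' @param lag lag in time units (default 1).
#' @return a `transition_model` with analytically computed stationary
#'   vector.
#' @export
transition_model <- function(T, lag = 1) {
  T <- as.matrix(T)
  if (any(abs(rowSums(T) - 1) > 1e-12) || any(T < 0)) {
    stop("T must be row-stochastic", call. = FALSE)
  }
  if (is.null(rownames(T))) {
    dimnames(T) <- list(seq_len(nrow(T)), seq_len(nrow(T)))
  }
  ev <- eigen(t(T))
  i1 <- which.min(abs(ev$values - 1))
  pi <- abs(Re(ev$vectors[, i1])); pi <- pi / sum(pi)
  names(pi) <- rownames(T)
  structure(list(states = rownames(T), counts = NULL, T = T, pi = pi,
                 lag = lag, mode = "prescribed", dtraj = NULL,
                 dropped = character()),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("transition_model:", length(x$states), "states, lag", x$lag,
      paste0("(", x$mode, ")\n"))
  cat("stationary:", paste(sprintf("%s=%.3g", names(x$pi), x$pi),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Macrostate populations with block-bootstrap confidence intervals
#'
#' Sums the stationary vector over the microstates of each macrostate.
#' When the model carries its source trajectory, uncertainty is estimated
#' by a block bootstrap: the trajectory is cut into contiguous blocks,
#' blocks are resampled with replacement, the MSM is re-estimated and the
#' macrostate populations recomputed.
#'
#' @param model a `transition_model`.
#' @param macro named list mapping macrostate label -> microstate labels
#'   (character, matching `model$states`). Microstates not covered are
#'   pooled into `"unassigned"` and reported.
#' @param n_boot bootstrap replicates (default 200; 0 disables the CI).
#' @param seed integer RNG seed for the bootstrap.
#' @param n_blocks number of contiguous blocks (default 20).
#' @return data.frame: `macro`, `population`, `lower`, `upper` (95%
#'   percentile interval, `NA` without a trajectory or with `n_boot = 0`).
#' @export
macrostate_population <- function(model, macro, n_boot = 200, seed = 1,
                                  n_blocks = 20) {
  micro <- model$states
  covered <- unlist(macro, use.names = FALSE)
  un <- setdiff(micro, covered)
  if (length(un)) {
    message("microstate(s) not covered by the macro map -> 'unassigned': ",
            paste(un, collapse = ", "))
    macro <- c(macro, list(unassigned = un))
  }
  pops <- vapply(macro, function(m) sum(model$pi[intersect(m, micro)]),
                 numeric(1))
  lower <- upper <- rep(NA_real_, length(pops))
  if (n_boot > 0 && !is.null(model$dtraj)) {
    traj <- model$dtraj[!is.na(model$dtraj)]
    cuts <- floor(seq(0, length(traj), length.out = n_blocks + 1))
    blocks <- lapply(seq_len(n_blocks),
                     function(b) traj[(cuts[b] + 1):cuts[b + 1]])
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(r) {
        bt <- unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)])
        bm <- suppressMessages(estimate_msm(bt, lag = model$lag,
                                            mode = model$mode))
        vapply(macro, function(m) sum(bm$pi[intersect(m, bm$states)]),
               numeric(1))
      }, numeric(length(macro)))
    })
    if (is.null(dim(boot))) boot <- matrix(boot, nrow = 1)
    lower <- apply(boot, 1, stats::quantile, 0.025)
    upper <- apply(boot, 1, stats::quantile, 0.975)
  }
  data.frame(macro = names(macro), population = unname(pops),
             lower = unname(lower), upper = unname(upper))
}

#' Kinetic Monte Carlo sampling from a transition model
#'
#' Samples discrete jumps from the transition probability matrix, one per
#' lag step. Optionally emits, per visited state, a randomly chosen row of
#' a per-state table of stored snapshots or order parameters.
#'
#' @param model a `transition_model` (or row-stochastic matrix).
#' @param n_steps trajectory length.
#' @param seed integer RNG seed.
#' @param init initial state label (default: drawn from the stationary
#'   vector).
#' @param emissions optional named list (per state) of matrices/vectors;
#'   each step emits one randomly selected row of the visited state's
#'   table.
#' @return list: `states` (character sequence), `series` (emitted rows,
#'   frames x d matrix, `NULL` without emissions).
#' @export
kmc_sample <- function(model, n_steps, seed = 1, init = NULL,
                       emissions = NULL) {
  if (!inherits(model, "transition_model")) model <- transition_model(model)
  with_seed(seed, {
    i0 <- if (is.null(init)) sample.int(length(model$pi), 1, prob = model$pi)
          else match(as.character(init), model$states)
    if (is.na(i0)) stop("unknown initial state", call. = FALSE)
    s <- sample_chain(model$T, n_steps, init = i0)
    states <- model$states[s]
    series <- NULL
    if (!is.null(emissions)) {
      emissions <- lapply(emissions, function(e) {
        if (is.null(dim(e))) matrix(e, ncol = 1) else as.matrix(e)
      })
      pick <- vapply(states, function(st)
        sample.int(nrow(emissions[[st]]), 1), integer(1))
      series <- do.call(rbind, lapply(seq_len(n_steps), function(i)
        emissions[[states[i]]][pick[i], , drop = FALSE]))
      rownames(series) <- NULL
    }
    list(states = states, series = series)
  })
}

#' Principal modes of a feature trajectory
#'
#' Eigendecomposition of the covariance of the centered features; for
#' kinase ensembles the first two modes typically separate the lobe
#' breathing and shearing motions. Sign convention: largest-magnitude
#' loading positive.
#'
#' @param X a [feature_trajectory()] or frames x d matrix.
#' @param n_modes number of modes (default 2).
#' @return list: `values` (eigenvalues), `vectors` (d x k), `projections`
#'   (frames x k, for 2D density comparison between conditions).
#' @export
principal_modes <- function(X, n_modes = 2) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 frames", call. = FALSE)
  n_modes <- min(n_modes, ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  V <- ev$vectors[, seq_len(n_modes), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  list(values = ev$values[seq_len(n_modes)], vectors = V,
       projections = Xc %*% V)
}

#' Per-group RMSD of an ensemble after global superposition
#'
#' Each frame is superposed on the reference over the alignment set, then
#' the RMSD is computed separately for each named atom group (e.g. C-spine,
#' R-spine, shell residues).
#'
#' @param models list of n x 3 matrices or frames x atoms x 3 array.
#' @param reference n x 3 reference coordinates.
#' @param groups named list of atom index vectors (all non-empty).
#' @param align indices for the global superposition (default: all atoms).
#' @return list: `per_frame` (frames x groups matrix of RMSDs),
#'   `summary` (data.frame: group, mean, sd).
#' @export
group_rmsd <- function(models, reference, groups, align = NULL) {
  models <- coerce_models(models)
  reference <- as.matrix(reference)
  if (any(lengths(groups) == 0L)) {
    stop("empty group: ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(align)) align <- seq_len(nrow(reference))
  per <- vapply(models, function(m) {
    moved <- kabsch_superpose(m, reference, align)$transform(m)
    vapply(groups, function(g) {
      sqrt(mean(rowSums((moved[g, , drop = FALSE] -
                           reference[g, , drop = FALSE])^2)))
    }, numeric(1))
  }, numeric(length(groups)))
  per <- if (is.null(dim(per))) matrix(per, ncol = 1) else t(per)
  colnames(per) <- names(groups)
  list(per_frame = per,
       summary = data.frame(group = names(groups),
                            mean = colMeans(per),
                            sd = apply(per, 2, stats::sd),
                            row.names = NULL))
}

#' Mutual information of side-chain rotamer states
#'
#' Discretizes each residue's dihedral time series into rotamer bins
#' (default the three chi1 wells g+/t/g- as thirds of the circle after
#' shifting to [0, 360)) and computes the plug-in mutual information, in
#' bits, from the joint histogram of every residue pair. The diagonal holds
#' the marginal entropies; constant series have zero entropy and zero MI
#' with all partners.
#'
#' @param dihedrals frames x residues matrix of angles in degrees.
#' @param breaks bin edges on [0, 360] (default `c(0, 120, 240, 360)`).
#' @param min_frames sample-size warning threshold (default 100).
#' @return symmetric residues x residues matrix of MI values in bits
#'   (diagonal: entropies).
#' @export
rotamer_mi <- function(dihedrals, breaks = c(0, 120, 240, 360),
                       min_frames = 100) {
  D <- as.matrix(dihedrals)
  n <- nrow(D); p <- ncol(D)
  if (n < min_frames) {
    warning("fewer than ", min_frames,
            " frames: plug-in MI estimates carry noticeable positive bias",
            call. = FALSE)
  }
  bins <- apply(D %% 360, 2, function(x) {
    cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE,
        labels = FALSE)
  })
  nb <- length(breaks) - 1L
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  MI <- matrix(0, p, p, dimnames = list(colnames(D), colnames(D)))
  marg <- lapply(seq_len(p), function(j) tabulate(bins[, j], nb) / n)
  for (i in seq_len(p)) {
    MI[i, i] <- ent(marg[[i]])
    if (i < p) for (j in (i + 1L):p) {
      joint <- tabulate((bins[, i] - 1L) * nb + bins[, j], nb * nb) / n
      mi <- ent(marg[[i]]) + ent(marg[[j]]) - ent(joint)
      MI[i, j] <- MI[j, i] <- max(mi, 0)
    }
  }
  MI
}

#' Ground-/excited-state chemical shift differences from snapshot ensembles
#'
#' For each site, \eqn{\Delta\omega} is the absolute difference of the mean
#' predicted shift over the two state ensembles; its uncertainty is a
#' bootstrap sd over snapshots.
#'
#' @param snapshots a `snapshot_shift_table` (long data.frame: `site`,
#'   `state`, `shift`).
#' @param state_a,state_b state labels (defaults `GS`, `ES2`).
#' @param n_boot bootstrap replicates (default 200).
#' @param seed integer RNG seed.
#' @return data.frame of class `delta_omega_record`: `site`, `mean_a`,
#'   `mean_b`, `delta_omega`, `boot_sd`, `n_a`, `n_b`. Sites present in
#'   only one state are skipped and reported.
#' @export
delta_omega <- function(snapshots, state_a = "GS", state_b = "ES2",
                        n_boot = 200, seed = 1) {
  sites <- unique(snapshots$site)
  rows <- lapply(sites, function(si) {
    a <- snapshots$shift[snapshots$site == si & snapshots$state == state_a]
    b <- snapshots$shift[snapshots$site == si & snapshots$state == state_b]
    if (length(a) < 2L || length(b) < 2L) {
      message("site skipped (needs >= 2 snapshots in both states): ", si)
      return(NULL)
    }
    bsd <- with_seed(seed, {
      stats::sd(vapply(seq_len(n_boot), function(r) {
        abs(mean(sample(b, replace = TRUE)) - mean(sample(a, replace = TRUE)))
      }, numeric(1)))
    })
    data.frame(site = si, mean_a = mean(a), mean_b = mean(b),
               delta_omega = abs(mean(b) - mean(a)), boot_sd = bsd,
               n_a = length(a), n_b = length(b))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delta_omega_record", "data.frame")
  out
}

#' Compare predicted and experimental chemical shift differences
#'
#' Ordinary least squares of predicted on experimental \eqn{\Delta\omega}
#' over paired sites.
#'
#' @param predicted,experimental numeric vectors (>= 3 paired sites).
#' @return list: `slope`, `intercept`, `r_squared`, `fit` (the `lm`
#'   object).
#' @export
compare_delta_omega <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || length(predicted) < 3L) {
    stop("need >= 3 paired sites", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ experimental)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot,
       fit = fit)
}
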