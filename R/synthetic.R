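#' Specification for a synthetic multi-state amide shift set
#'
#' Defines the statistical structure of a generated [state_shift_set()]:
#' a fraction of residues respond *coordinately*, i.e. their (\eqn{\delta_H},
#' \eqn{\delta_N}) peaks move along residue-specific straight lines
#' parameterized by a common reaction coordinate (the per-state positions on
#' the open-to-closed axis), while the remaining residues show only
#' independent per-state scatter. The default four states and positions
#' mimic a nucleotide/pseudosubstrate titration of a kinase:
#' apo (0) -> ADP (0.4) -> ATP-analogue (0.6) -> ternary complex (1.0).
#'
#' Defaults for amplitudes, noise and linewidths are chosen at magnitudes
#' typical of amide titrations on a 600 MHz instrument (response up to a few
#' tenths of a ppm in H, about 1 ppm in N; peak-position noise a few
#' thousandths of a ppm in H).
#'
#' @param n_residues number of residues.
#' @param state_names ordered state labels (>= 3).
#' @param state_positions per-state scalar in [0, 1] along the reaction
#'   coordinate, monotone non-decreasing in the given order.
#' @param coordinated_fraction fraction of residues responding linearly.
#' @param response_amplitude_H,response_amplitude_N full-scale response, ppm.
#' @param noise_sd_H,noise_sd_N Gaussian peak-position noise, ppm.
#' @param linewidth_H,linewidth_N linewidths attached to every peak, ppm.
#' @param seed integer RNG seed.
#' @return validated list of class `shift_gen_spec`.
#' @export
shift_gen_spec <- function(n_residues = 100,
                           state_names = c("apo", "ADP", "ATPgN", "ATPgN_PKI"),
                           state_positions = c(0, 0.4, 0.6, 1.0),
                           coordinated_fraction = 0.7,
                           response_amplitude_H = 0.15,
                           response_amplitude_N = 1.0,
                           noise_sd_H = 0.003, noise_sd_N = 0.02,
                           linewidth_H = 0.02, linewidth_N = 0.15,
                           seed = 1) {
  if (length(state_names) < 3L) {
    stop("validation error: need >= 3 states", call. = FALSE)
  }
  if (length(state_positions) != length(state_names)) {
    stop("validation error: one position per state required", call. = FALSE)
  }
  if (is.unsorted(state_positions)) {
    stop("validation error: state_positions must be monotone non-decreasing",
         call. = FALSE)
  }
  if (coordinated_fraction < 0 || coordinated_fraction > 1) {
    stop("validation error: coordinated_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  for (s in c(noise_sd_H, noise_sd_N, linewidth_H, linewidth_N)) {
    if (s < 0) stop("validation error: sds and linewidths must be >= 0",
                    call. = FALSE)
  }
  structure(as.list(environment()), class = "shift_gen_spec")
}

#' Generate a synthetic multi-state amide shift set
#'
#' Pure function of its spec (seed included): regeneration with the same
#' spec is bit-identical. Coordinated residues move along residue-specific
#' straight lines in the (\eqn{\delta_H}, \eqn{\delta_N}) plane,
#' parameterized by the spec's state positions, plus Gaussian noise;
#' uncoordinated residues receive independent per-state noise only.
#'
#' @param spec a [shift_gen_spec()].
#' @return a [state_shift_set()] with a `truth` attribute: data.frame of
#'   per-residue ground truth (`coordinated` flag, base position, response
#'   amplitudes) sufficient for parameter-recovery tests.
#' @export
gen_shift_states <- function(spec) {
  if (!inherits(spec, "shift_gen_spec")) {
    stop("validation error: `spec` must be a shift_gen_spec", call. = FALSE)
  }
  n <- spec$n_residues
  k <- length(spec$state_names)
  with_seed(spec$seed, {
    n_coord <- round(spec$coordinated_fraction * n)
    coord <- rep(FALSE, n)
    coord[sample.int(n, n_coord)] <- TRUE
    H0 <- stats::runif(n, 7.0, 9.5)
    N0 <- stats::runif(n, 105, 130)
    # residue-specific response line: random magnitude scatter and sign
    amp_H <- spec$response_amplitude_H * stats::runif(n, 0.5, 1.5) *
      sample(c(-1, 1), n, replace = TRUE)
    amp_N <- spec$response_amplitude_N * stats::runif(n, 0.5, 1.5) *
      sample(c(-1, 1), n, replace = TRUE)
    amp_H[!coord] <- 0
    amp_N[!coord] <- 0
    tables <- lapply(seq_len(k), function(s) {
      pos <- spec$state_positions[s]
      data.frame(residue = seq_len(n), code = NA_character_,
                 N = N0 + amp_N * pos + stats::rnorm(n, 0, spec$noise_sd_N),
                 H = H0 + amp_H * pos + stats::rnorm(n, 0, spec$noise_sd_H),
                 lw_N = rep(spec$linewidth_N, n),
                 lw_H = rep(spec$linewidth_H, n))
    })
    names(tables) <- spec$state_names
    set <- state_shift_set(tables)
    attr(set, "truth") <- data.frame(residue = seq_len(n), coordinated = coord,
                                     H0 = H0, N0 = N0,
                                     amp_H = amp_H, amp_N = amp_N)
    attr(set, "gen_spec") <- spec
    set
  })
}

#' Generate a synthetic single-site ITC titration
#'
#' Heats follow the exact 1:1 binding model with displaced-volume
#' concentration bookkeeping (each injection displaces cell content), plus a
#' constant molar dilution heat, plus Gaussian noise scaled to the
#' first-injection (maximal) heat.
#'
#' @param true_Kd dissociation constant, uM.
#' @param dH binding enthalpy, kcal/mol.
#' @param n_sites stoichiometry (default 1).
#' @param cell_vol active cell volume, uL.
#' @param cell_conc initial macromolecule concentration in the cell, uM.
#' @param syringe_conc titrant concentration, uM.
#' @param n_injections number of injections (>= 5).
#' @param inj_vol per-injection volume, uL.
#' @param dilution_heat constant heat of dilution, kcal per mol of
#'   injectant.
#' @param noise_sd Gaussian heat noise, expressed as a fraction of the
#'   magnitude of the first (noiseless) injection heat.
#' @param temperature K.
#' @param seed integer RNG seed.
#' @return an [itc_titration()] with a `truth` attribute (generating
#'   parameters and the noiseless heats).
#' @export
gen_itc <- function(true_Kd, dH, n_sites = 1, cell_vol = 300,
                    cell_conc = 100, syringe_conc = 2000,
                    n_injections = 25, inj_vol = 2, dilution_heat = 0,
                    noise_sd = 0.02, temperature = 300, seed = 1) {
  stopifnot_scalar(true_Kd, "true_Kd", positive = TRUE)
  stopifnot_scalar(cell_conc, "cell_conc", positive = TRUE)
  stopifnot_scalar(syringe_conc, "syringe_conc", positive = TRUE)
  if (n_injections < 5L) stop("need >= 5 injections", call. = FALSE)
  inj_vols <- rep(inj_vol, n_injections)
  tot_inj_umol <- syringe_conc * sum(inj_vols) * 1e-6
  cell_umol <- n_sites * cell_conc * cell_vol * 1e-6
  if (tot_inj_umol < cell_umol) {
    warning("syringe load below cell site content: titration cannot saturate",
            call. = FALSE)
  }
  base <- predict_itc_heats(true_Kd, dH, n_sites, cell_conc, syringe_conc,
                            cell_vol, inj_vols, dilution_heat)
  with_seed(seed, {
    q <- base$q_ucal + stats::rnorm(n_injections, 0, noise_sd * abs(base$q_ucal[1]))
    t <- itc_titration(inj_vols, q, cell_vol, cell_conc, syringe_conc,
                       temperature)
    attr(t, "truth") <- list(Kd = true_Kd, dH = dH, n_sites = n_sites,
                             dilution_heat = dilution_heat,
                             noise_sd = noise_sd, seed = seed,
                             noiseless_q_ucal = base$q_ucal)
    t
  })
}

#' Generate synthetic Michaelis-Menten initial velocities
#'
#' \eqn{v = k_{cat} E_0 S / (K_M + S)} with multiplicative Gaussian noise.
#'
#' @param kcat turnover number, 1/s.
#' @param KM Michaelis constant, uM.
#' @param E0 enzyme concentration, uM.
#' @param S_grid substrate concentrations, uM; should span below and above
#'   `KM` (warned otherwise).
#' @param noise_frac multiplicative noise sd as a fraction of each velocity.
#' @param seed integer RNG seed.
#' @return a [velocity_table()] with a `truth` attribute.
#' @export
gen_mm_velocities <- function(kcat, KM, E0, S_grid, noise_frac = 0.02,
                              seed = 1) {
  if (length(S_grid) == 0L) stop("S_grid is empty", call. = FALSE)
  stopifnot_scalar(kcat, "kcat", positive = TRUE)
  stopifnot_scalar(KM, "KM", positive = TRUE)
  if (min(S_grid) > KM || max(S_grid) < KM) {
    warning("S_grid does not span KM: fit identifiability is reduced",
            call. = FALSE)
  }
  v0 <- kcat * E0 * S_grid / (KM + S_grid)
  with_seed(seed, {
    v <- v0 * (1 + stats::rnorm(length(S_grid), 0, noise_frac))
    t <- velocity_table(S_grid, v, E0)
    attr(t, "truth") <- list(kcat = kcat, KM = KM, E0 = E0,
                             kcat_over_KM = kcat / KM,
                             noise_frac = noise_frac, seed = seed,
                             noiseless_v = v0)
    t
  })
}

#' Specification for a synthetic metastable-state trajectory
#'
#' Defines a hidden Markov chain over conformational macrostates (default
#' GS/ES1/ES2: ground state and two sparsely populated excited states) with
#' Gaussian emission in feature space.
#'
#' @param transition_matrix row-stochastic matrix at the stated lag (row
#'   sums within 1e-12 of 1).
#' @param emission_centers states x dimensions matrix of feature-space
#'   centers.
#' @param emission_sd per-dimension emission spread (> 0; recycled).
#' @param n_steps trajectory length (>= 1).
#' @param lag_time time units per step (default 1, i.e. one lag per frame).
#' @param state_names labels, default `GS`, `ES1`, `ES2` truncated/extended
#'   to the matrix size.
#' @param seed integer RNG seed.
#' @return validated list of class `markov_gen_spec`.
#' @export
markov_gen_spec <- function(transition_matrix, emission_centers,
                            emission_sd = 0.2, n_steps = 1000,
                            lag_time = 1, state_names = NULL, seed = 1) {
  transition_matrix <- as.matrix(transition_matrix)
  ns <- nrow(transition_matrix)
  if (ncol(transition_matrix) != ns) {
    stop("validation error: transition_matrix must be square", call. = FALSE)
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12) ||
      any(transition_matrix < 0)) {
    stop("validation error: transition_matrix must be row-stochastic ",
         "(rows sum to 1 within 1e-12)", call. = FALSE)
  }
  emission_centers <- as.matrix(emission_centers)
  if (nrow(emission_centers) != ns) {
    stop("validation error: one emission center row per state", call. = FALSE)
  }
  if (any(emission_sd <= 0)) {
    stop("validation error: emission_sd must be > 0", call. = FALSE)
  }
  if (n_steps < 1L) stop("validation error: n_steps >= 1", call. = FALSE)
  if (is.null(state_names)) {
    state_names <- c("GS", "ES1", "ES2",
                     paste0("ES", seq_len(max(ns - 3, 0)) + 2))[seq_len(ns)]
  }
  emission_sd <- rep_len(emission_sd, ncol(emission_centers))
  structure(list(transition_matrix = transition_matrix,
                 emission_centers = emission_centers,
                 emission_sd = emission_sd, n_steps = n_steps,
                 lag_time = lag_time, state_names = state_names, seed = seed),
            class = "markov_gen_spec")
}

# sample a discrete Markov chain from row-stochastic T (uses current RNG)
sample_chain <- function(T, n_steps, init = 1L) {
  cum <- t(apply(T, 1, cumsum))
  u <- stats::runif(n_steps - 1L)
  s <- integer(n_steps)
  s[1] <- init
  for (i in seq_len(n_steps - 1L)) {
    s[i + 1L] <- findInterval(u[i], cum[s[i], ]) + 1L
  }
  s
}

#' Generate a synthetic feature trajectory from a hidden Markov chain
#'
#' Samples the hidden state sequence from the spec's transition matrix
#' (starting in the first state) and emits, per frame, the state's feature
#' center plus Gaussian noise. The true label sequence is retained as a
#' sidecar for recovery tests.
#'
#' @param spec a [markov_gen_spec()].
#' @return a [feature_trajectory()] whose `labels` field holds the true
#'   state sequence (integer, with `state_names` attribute) and with a
#'   `gen_spec` attribute.
#' @export
gen_markov_ensemble <- function(spec) {
  if (!inherits(spec, "markov_gen_spec")) {
    stop("validation error: `spec` must be a markov_gen_spec", call. = FALSE)
  }
  d <- ncol(spec$emission_centers)
  with_seed(spec$seed, {
    s <- sample_chain(spec$transition_matrix, spec$n_steps)
    noise <- matrix(stats::rnorm(spec$n_steps * d), spec$n_steps, d)
    noise <- sweep(noise, 2, spec$emission_sd, `*`)
    X <- spec$emission_centers[s, , drop = FALSE] + noise
    ft <- feature_trajectory(X, times = (seq_len(spec$n_steps) - 1) * spec$lag_time,
                             labels = s)
    attr(ft$labels, "state_names") <- spec$state_names
    attr(ft, "gen_spec") <- spec
    ft
  })
}

#' Generate synthetic per-snapshot predicted chemical shifts
#'
#' Emulates predicted shift distributions over representative-structure
#' ensembles of conformational states: per state and site, shifts are drawn
#' from Normal(mean, sd).
#'
#' @param state_means states x sites numeric matrix of mean shifts (ppm),
#'   with state row names and site column names (defaults supplied when
#'   absent).
#' @param sd emission sd, ppm.
#' @param n_per_state snapshots per state (>= 2).
#' @param seed integer RNG seed.
#' @return long data.frame of class `snapshot_shift_table`: `site`, `state`,
#'   `shift`; `truth` attribute holds the generating means.
#' @export
gen_snapshot_shifts <- function(state_means, sd = 0.15, n_per_state = 500,
                                seed = 1) {
  state_means <- as.matrix(state_means)
  if (nrow(state_means) < 2L) stop("need >= 2 states", call. = FALSE)
  if (n_per_state < 2L) stop("n_per_state must be >= 2", call. = FALSE)
  if (is.null(rownames(state_means))) {
    rownames(state_means) <- c("GS", "ES2",
                               paste0("S", seq_len(max(nrow(state_means) - 2, 0))))[
                                 seq_len(nrow(state_means))]
  }
  if (is.null(colnames(state_means))) {
    colnames(state_means) <- paste0("site", seq_len(ncol(state_means)))
  }
  with_seed(seed, {
    rows <- expand.grid(snapshot = seq_len(n_per_state),
                        state = rownames(state_means),
                        site = colnames(state_means),
                        stringsAsFactors = FALSE)
    mu <- state_means[cbind(rows$state, rows$site)]
    out <- data.frame(site = rows$site, state = rows$state,
                      shift = mu + stats::rnorm(nrow(rows), 0, sd))
    attr(out, "truth") <- list(state_means = state_means, sd = sd,
                               n_per_state = n_per_state, seed = seed)
    class(out) <- c("snapshot_shift_table", "data.frame")
    out
  })
}

#' Write a shift set as per-state Sparky lists plus a truth sidecar
#'
#' @param set a [state_shift_set()] (typically from [gen_shift_states()]).
#' @param dir output directory (created if needed); writes one
#'   `<state>.list` per state and, when ground truth is attached,
#'   `truth.json`.
#' @return the directory path, invisibly.
#' @export
write_state_shift_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in attr(set, "state_names")) {
    sub <- set[set$state == s, c("residue", "code", "N", "H", "lw_N", "lw_H")]
    write_peaklist(sub, file.path(dir, paste0(s, ".list")))
  }
  truth <- attr(set, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
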