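#' Per-residue principal-component fits of chemical shift trajectories
#'
#' CONCISE (COordiNated ChemIcal Shift bEhavior) screens each residue for a
#' linear chemical-shift trajectory across ligation states. For every
#' residue observed in all states the k state points are laid out in the
#' scaled plane (\eqn{\delta_H}, `scale_N`\eqn{\cdot\delta_N}), centered, and
#' decomposed by SVD. The leading singular direction is the residue's
#' response axis; the singular-value ratio \eqn{\sigma_1/\sigma_2} measures
#' how collinear the response is (infinite for exactly collinear points).
#'
#' @param set a [state_shift_set()] with at least 3 states.
#' @param scale_N nitrogen scaling applied before the PCA (default 0.154);
#'   set to 1 to fit in raw ppm units.
#' @return list of class `concise_fits`: per residue, `pc1` (unit vector),
#'   `linearity_ratio`, `projections` (per-state scalar along pc1, state
#'   order preserved); plus `state_names`.
#' @export
fit_residue_trajectories <- function(set, scale_N = 0.154) {
  sn <- attr(set, "state_names")
  if (length(sn) < 3L) stop("need at least 3 states", call. = FALSE)
  res <- complete_residues(set)
  fits <- lapply(res, function(r) {
    pts <- residue_track(set, r)
    pts[, "N"] <- pts[, "N"] * scale_N
    ctr <- scale(pts, scale = FALSE)
    sv <- svd(ctr)
    s1 <- sv$d[1]; s2 <- sv$d[2]
    if (s1 < 1e-12) {           # degenerate: all states identical
      return(list(residue = r, pc1 = c(1, 0),
                  linearity_ratio = Inf,
                  projections = stats::setNames(rep(0, length(sn)), sn)))
    }
    pc1 <- sv$v[, 1]
    # deterministic sign: largest-magnitude loading positive
    if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
    list(residue = r, pc1 = pc1,
         linearity_ratio = if (s2 < 1e-12 * s1) Inf else s1 / s2,
         projections = stats::setNames(drop(ctr %*% pc1), sn))
  })
  structure(list(fits = fits, state_names = sn), class = "concise_fits")
}

#' Per-state equilibrium positions from coordinated residues
#'
#' Retains residues whose trajectories are sufficiently linear
#' (`linearity_ratio >= linearity_threshold`), normalizes each residue's
#' projections affinely so the first-listed state maps to 0 and the
#' last-listed state to 1 (the open-to-closed axis), and summarizes the
#' across-residue position distribution of every state by a normal fit.
#'
#' @param fits a `concise_fits` object from [fit_residue_trajectories()].
#' @param linearity_threshold minimum \eqn{\sigma_1/\sigma_2} (default 3).
#' @param residues optional residue subset to consider (typically the
#'   responders from [response_filter()]); screening out non-responding
#'   residues first is recommended, since a residue that is "linear" by
#'   chance but barely moves gets an ill-conditioned normalization.
#' @param orientation_rule `"first_last"`: the anchors are the first and
#'   last states in declared order; residues whose two anchors coincide are
#'   dropped as uninformative.
#' @return list of class `concise_result`: `positions` (residues x states
#'   matrix of normalized positions), `summary` (data.frame: state, mean,
#'   sd), `included_residues`.
#' @export
concise_positions <- function(fits, linearity_threshold = 3,
                              residues = NULL,
                              orientation_rule = "first_last") {
  orientation_rule <- match.arg(orientation_rule, "first_last")
  sn <- fits$state_names
  pool <- fits$fits
  if (!is.null(residues)) {
    pool <- Filter(function(f) f$residue %in% residues, pool)
  }
  keep <- Filter(function(f) f$linearity_ratio >= linearity_threshold, pool)
  pos <- lapply(keep, function(f) {
    p <- f$projections
    span <- p[[length(p)]] - p[[1L]]
    if (abs(span) < 1e-12) return(NULL)
    (p - p[[1L]]) / span
  })
  ok <- !vapply(pos, is.null, logical(1))
  pos <- pos[ok]; keep <- keep[ok]
  if (length(pos) < 2L) {
    stop("fewer than 2 residues pass the linearity threshold; lower it",
         call. = FALSE)
  }
  m <- do.call(rbind, pos)
  rownames(m) <- vapply(keep, function(f) as.character(f$residue), character(1))
  colnames(m) <- sn
  summ <- data.frame(state = sn,
                     mean = colMeans(m),
                     sd = apply(m, 2, stats::sd),
                     row.names = NULL)
  structure(list(positions = m, summary = summ,
                 included_residues = as.integer(rownames(m))),
            class = "concise_result")
}

#' @export
print.concise_result <- function(x, ...) {
  cat("CONCISE positions over", length(x$included_residues), "residues\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Normal probability-density curves for CONCISE state positions
#'
#' @param result a `concise_result`.
#' @param grid positions at which to evaluate the densities.
#' @return data.frame: `position`, one density column per state.
#' @export
concise_density <- function(result, grid = seq(-0.3, 1.3, length.out = 201)) {
  out <- data.frame(position = grid)
  for (i in seq_len(nrow(result$summary))) {
    s <- result$summary[i, ]
    out[[s$state]] <- stats::dnorm(grid, s$mean, max(s$sd, 1e-12))
  }
  out
}
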