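#' Combined chemical shift perturbation between two ligation states
#'
#' Computes the combined amide CSP
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2}}
#' per residue, where 0.154 is the conventional nitrogen scaling factor.
#' Residues missing from either state are kept in the output with `NA`
#' perturbation and flagged, never silently dropped.
#'
#' @param set a [state_shift_set()].
#' @param state_a,state_b state names to compare.
#' @param scale_N nitrogen scaling factor (default 0.154).
#' @return data.frame with columns `residue`, `d_H`, `d_N`, `csp`, `missing`;
#'   attributes `mean` and `sd` hold the across-residue mean and standard
#'   deviation of the CSP (the usual significance threshold line).
#' @export
csp <- function(set, state_a, state_b, scale_N = 0.154) {
  sn <- attr(set, "state_names")
  for (s in c(state_a, state_b)) {
    if (!s %in% sn) stop("unknown state: ", s, call. = FALSE)
  }
  a <- set[set$state == state_a, , drop = FALSE]
  b <- set[set$state == state_b, , drop = FALSE]
  res <- sort(unique(set$residue))
  ia <- match(res, a$residue)
  ib <- match(res, b$residue)
  d_H <- b$H[ib] - a$H[ia]
  d_N <- b$N[ib] - a$N[ia]
  val <- sqrt(d_H^2 + (scale_N * d_N)^2)
  out <- data.frame(residue = res, d_H = d_H, d_N = d_N, csp = val,
                    missing = is.na(ia) | is.na(ib))
  attr(out, "mean") <- mean(val, na.rm = TRUE)
  attr(out, "sd") <- stats::sd(val, na.rm = TRUE)
  out
}

#' Linewidth-based residue inclusion filter for covariance analysis
#'
#' A residue is considered a genuine responder, and retained for CHESCA-type
#' analysis, when in at least one dimension (\eqn{^1}H or \eqn{^{15}}N) its
#' chemical-shift excursion across states exceeds the mean linewidth of the
#' two states realizing that excursion:
#' \eqn{|\Delta\delta| > \frac{1}{2}(\Delta\nu_A + \Delta\nu_B)}.
#'
#' @param set a [state_shift_set()] carrying linewidths.
#' @param rule `"max_pair"` (default): the test pair (A, B) is the pair
#'   realizing the maximum excursion in that dimension; `"any_pair"`: any
#'   state pair whose shift difference beats its own linewidth average
#'   qualifies.
#' @return data.frame with one row per residue observed in all states:
#'   `residue`, `included`, `dim` (qualifying dimension, `NA` if excluded),
#'   `pair` (qualifying state pair as "A|B"), `max_dH`, `max_dN`.
#' @export
response_filter <- function(set, rule = c("max_pair", "any_pair")) {
  rule <- match.arg(rule)
  if (all(is.na(set$lw_H)) && all(is.na(set$lw_N))) {
    stop("no linewidths in the shift set; supply linewidths or skip the filter",
         call. = FALSE)
  }
  sn <- attr(set, "state_names")
  pairs <- utils::combn(length(sn), 2L)
  res <- complete_residues(set)
  one <- function(r) {
    sub <- set[set$residue == r, , drop = FALSE]
    sub <- sub[match(sn, sub$state), , drop = FALSE]
    qual_dim <- NA_character_; qual_pair <- NA_character_
    mx <- c(H = 0, N = 0)
    for (dim in c("H", "N")) {
      dd <- abs(sub[[dim]][pairs[1, ]] - sub[[dim]][pairs[2, ]])
      lw <- sub[[paste0("lw_", dim)]]
      half <- 0.5 * (lw[pairs[1, ]] + lw[pairs[2, ]])
      mx[dim] <- max(dd)
      ok <- if (rule == "max_pair") {
        j <- which.max(dd)
        is.finite(half[j]) && dd[j] > half[j]
      } else {
        any(is.finite(half) & dd > half)
      }
      if (ok && is.na(qual_dim)) {
        j <- if (rule == "max_pair") which.max(dd) else which(is.finite(half) & dd > half)[1]
        qual_dim <- dim
        qual_pair <- paste(sn[pairs[1, j]], sn[pairs[2, j]], sep = "|")
      }
    }
    data.frame(residue = r, included = !is.na(qual_dim),
               dim = qual_dim, pair = qual_pair,
               max_dH = mx[["H"]], max_dN = mx[["N"]])
  }
  out <- do.call(rbind, lapply(res, one))
  rownames(out) <- NULL
  out
}

#' Replica-averaged chemical-shift restraint energy
#'
#' Harmonic penalty used to restrain simulation replicas to experimental
#' chemical shifts:
#' \deqn{E = \alpha \sum_k \sum_l \left(\delta^{exp}_{kl} -
#'   \tfrac{1}{M}\sum_m \delta^{calc}_{klm}\right)^2}
#' over residues \eqn{k}, backbone atom kinds \eqn{l} and replicas \eqn{m}.
#' The energy is zero exactly when the replica mean matches experiment on
#' every restrained atom, and is linear in the force constant.
#'
#' @param exp_shifts numeric matrix, residues x atom kinds (columns named
#'   from `N`, `CA`, `CO`, `CB`, `HN`), experimental shifts in ppm.
#' @param calc_shifts list of matrices (one per replica) with the same
#'   dimensions and column names as `exp_shifts`.
#' @param alpha force constant, kcal/(mol ppm^2).
#' @param atom_kinds atom kinds to restrain; kinds absent from the
#'   experimental set are skipped with a warning.
#' @return energy in kcal/mol (single number).
#' @export
cs_restraint_energy <- function(exp_shifts, calc_shifts, alpha = 20,
                                atom_kinds = colnames(exp_shifts)) {
  stopifnot_scalar(alpha, "alpha", nonneg = TRUE)
  if (!is.list(calc_shifts)) calc_shifts <- list(calc_shifts)
  keep <- atom_kinds %in% colnames(exp_shifts)
  if (any(!keep)) {
    warning("atom kind(s) absent from experimental set, skipped: ",
            paste(atom_kinds[!keep], collapse = ", "), call. = FALSE)
    atom_kinds <- atom_kinds[keep]
  }
  M <- length(calc_shifts)
  mean_calc <- Reduce(`+`, lapply(calc_shifts, function(m) m[, atom_kinds, drop = FALSE])) / M
  dev <- exp_shifts[, atom_kinds, drop = FALSE] - mean_calc
  alpha * sum(dev^2, na.rm = TRUE)
}
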