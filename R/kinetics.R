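#' Construct an initial-velocity table
#'
#' @param S substrate concentrations, uM.
#' @param v initial velocities, uM/s.
#' @param E0 total enzyme concentration, uM.
#' @return object of class `velocity_table`.
#' @export
velocity_table <- function(S, v, E0) {
  stopifnot(length(S) == length(v), all(S > 0), all(is.finite(v)))
  if (length(S) < 5L) stop("need at least 5 substrate points", call. = FALSE)
  stopifnot_scalar(E0, "E0", positive = TRUE)
  structure(list(S = S, v = v, E0 = E0), class = "velocity_table")
}

#' Read an initial-velocity table from CSV
#'
#' Expects columns `S` (uM) and `v` (uM/s); `E0` is taken from an `E0`
#' column (constant per file) or the argument.
#'
#' @param path CSV file.
#' @param E0 enzyme concentration, uM (overrides any file column).
#' @return a [velocity_table()].
#' @export
read_velocity_csv <- function(path, E0 = NULL) {
  d <- utils::read.csv(path)
  if (is.null(E0)) {
    if (!"E0" %in% names(d)) stop("supply `E0` or an E0 column", call. = FALSE)
    E0 <- d$E0[1]
  }
  velocity_table(d$S, d$v, E0)
}

#' Michaelis-Menten fit of steady-state initial velocities
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_M + S)}, reporting
#' \eqn{V_{max}}, \eqn{K_M}, \eqn{k_{cat} = V_{max}/E_0} and the catalytic
#' efficiency \eqn{k_{cat}/K_M} with standard errors; the efficiency error
#' uses first-order propagation with the full parameter covariance. A
#' warning is issued when the substrate range does not bracket the fitted
#' \eqn{K_M} (the efficiency remains identifiable from the linear regime;
#' \eqn{V_{max}} and \eqn{K_M} individually are not).
#'
#' @param t a [velocity_table()].
#' @return object of class `mm_fit`: `Vmax` (uM/s), `KM` (uM), `kcat`
#'   (1/s), `kcat_over_KM` ((uM s)^-1), `se` (named vector), `fitted`,
#'   `converged`.
#' @export
fit_mm <- function(t) {
  S <- t$S; v <- t$v
  # start values: Vmax from the top of the curve, KM from half-saturation
  start <- c(Vmax = max(v) * 1.1, KM = stats::median(S))
  resid_fun <- function(par) {
    par["Vmax"] * S / (par["KM"] + S) - v
  }
  ft <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(Vmax = 0, KM = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!ft$info %in% 1:4) {
    stop("Michaelis-Menten fit did not converge (residual ",
         format(ft$deviance), ")", call. = FALSE)
  }
  Vmax <- ft$par[["Vmax"]]; KM <- ft$par[["KM"]]
  dof <- max(length(v) - 2L, 1L)
  s2 <- ft$deviance / dof
  cov <- try(s2 * solve(ft$hessian / 2), silent = TRUE)
  if (inherits(cov, "try-error") || any(diag(cov) < 0)) {
    cov <- matrix(NA_real_, 2, 2)
  }
  se_Vmax <- sqrt(cov[1, 1]); se_KM <- sqrt(cov[2, 2])
  kcat <- Vmax / t$E0
  eff <- kcat / KM
  # gradient of Vmax/(E0*KM) in (Vmax, KM)
  g <- c(1 / (t$E0 * KM), -Vmax / (t$E0 * KM^2))
  se_eff <- if (anyNA(cov)) NA_real_ else sqrt(drop(g %*% cov %*% g))
  if (KM < min(S) || KM > max(S)) {
    warning("substrate range does not bracket the fitted KM; Vmax and KM ",
            "are weakly identifiable (kcat/KM remains constrained)",
            call. = FALSE)
  }
  structure(list(Vmax = Vmax, KM = KM, kcat = kcat, kcat_over_KM = eff,
                 se = c(Vmax = se_Vmax, KM = se_KM,
                        kcat = se_Vmax / t$E0, kcat_over_KM = se_eff),
                 fitted = Vmax * S / (KM + S),
                 converged = TRUE),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g uM/s, KM = %.4g uM\n",
              x$Vmax, x$KM))
  cat(sprintf("  kcat = %.4g 1/s, kcat/KM = %.4g (uM s)^-1 (se %.2g)\n",
              x$kcat, x$kcat_over_KM, x$se[["kcat_over_KM"]]))
  invisible(x)
}
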