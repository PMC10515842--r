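#' Wiseman differential heat for single-site binding
#'
#' Closed-form derivative of the total binding heat with respect to total
#' titrant, for a 1:1 binding isotherm:
#' \deqn{\frac{dQ}{dX_{tot}} = \Delta H V_0 \left[\frac{1}{2} +
#'  \frac{1 - (1+r)/2 - R_m/2}{\sqrt{R_m^2 - 2R_m(1-r) + (1+r)^2}}\right]}
#' with \eqn{r = K_d/[M]_{tot}} and \eqn{R_m = [X]_{tot}/[M]_{tot}}.
#' In the tight-binding limit (\eqn{r \to 0}) this is a step function:
#' \eqn{\Delta H V_0} until molar ratio 1, then 0; the removable singularity
#' at \eqn{r = 0, R_m = 1} takes its limit value \eqn{\Delta H V_0 / 2}.
#'
#' @param r ratio of Kd to total cell (macromolecule) concentration.
#' @param Rm molar ratio, total titrant over total macromolecule
#'   (vectorized).
#' @param dH binding enthalpy (default 1, i.e. return the dimensionless
#'   bracket scaled by `V0`).
#' @param V0 cell volume (default 1).
#' @return differential heat per mole of injectant, same length as `Rm`.
#' @export
wiseman_heat <- function(r, Rm, dH = 1, V0 = 1) {
  stopifnot_scalar(r, "r", nonneg = TRUE)
  disc <- Rm^2 - 2 * Rm * (1 - r) + (1 + r)^2
  disc <- pmax(disc, 0)
  num <- 1 - (1 + r) / 2 - Rm / 2
  out <- ifelse(disc < 1e-300,
                0.5,                              # r = 0, Rm = 1 limit
                0.5 + num / sqrt(disc))
  dH * V0 * out
}

# Exact per-injection heats for a 1:1 isotherm with displaced-volume
# bookkeeping: each injection of volume v displaces a fraction v/V0 of the
# cell content before the new titrant mixes in. All concentrations in uM,
# volumes in uL, dH and dilution_heat in kcal/mol.  Returns per-injection
# heats in ucal plus normalized heats in kcal per mol of injectant.
predict_itc_heats <- function(Kd, dH, n_sites, cell_conc, syringe_conc,
                              cell_vol, inj_vols, dilution_heat = 0) {
  k <- length(inj_vols)
  Mt <- Xt <- MX <- q <- numeric(k)
  m_prev <- cell_conc; x_prev <- 0; mx_prev <- 0
  V0_L <- cell_vol * 1e-6
  for (i in seq_len(k)) {
    f <- inj_vols[i] / cell_vol
    m <- m_prev * (1 - f)
    x <- x_prev * (1 - f) + syringe_conc * f
    sites <- n_sites * m
    b <- sites + x + Kd
    mx <- (b - sqrt(b^2 - 4 * sites * x)) / 2
    # ucal: dH (kcal/mol) * delta-moles (uM * L = umol) * 1000
    q[i] <- dH * V0_L * (mx - mx_prev * (1 - f)) * 1000 +
      dilution_heat * (syringe_conc * inj_vols[i] * 1e-6) * 1000
    Mt[i] <- m; Xt[i] <- x; MX[i] <- mx
    m_prev <- m; x_prev <- x; mx_prev <- mx
  }
  inj_umol <- syringe_conc * inj_vols * 1e-6
  list(q_ucal = q, ndh = (q / 1000) / inj_umol,
       Mt = Mt, Xt = Xt, MX = MX, Rm = Xt / Mt)
}

#' Construct an ITC titration object
#'
#' @param inj_vols injection volumes, uL (recycled to `n` if scalar with
#'   `n` given via length of `heats`).
#' @param heats observed per-injection heats, ucal.
#' @param cell_vol active cell volume, uL.
#' @param cell_conc initial cell (macromolecule) concentration, uM.
#' @param syringe_conc titrant concentration in the syringe, uM.
#' @param temperature measurement temperature, K (default 300).
#' @return object of class `itc_titration`.
#' @export
itc_titration <- function(inj_vols, heats, cell_vol, cell_conc,
                          syringe_conc, temperature = 300) {
  if (length(inj_vols) == 1L) inj_vols <- rep(inj_vols, length(heats))
  stopifnot(length(inj_vols) == length(heats), all(inj_vols > 0),
            all(is.finite(heats)))
  stopifnot_scalar(cell_vol, "cell_vol", positive = TRUE)
  stopifnot_scalar(cell_conc, "cell_conc", positive = TRUE)
  stopifnot_scalar(syringe_conc, "syringe_conc", positive = TRUE)
  structure(list(inj_vols = inj_vols, heats = heats, cell_vol = cell_vol,
                 cell_conc = cell_conc, syringe_conc = syringe_conc,
                 temperature = temperature),
            class = "itc_titration")
}

#' Read an ITC titration from CSV
#'
#' Expects one row per injection with columns `inj_vol` (uL) and `heat`
#' (ucal); cell volume and concentrations are passed as arguments or read
#' from identically named columns (constant per file).
#'
#' @param path CSV file.
#' @param ... passed to [itc_titration()] (`cell_vol`, `cell_conc`,
#'   `syringe_conc`, `temperature`).
#' @return an `itc_titration`.
#' @export
read_itc_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  extra <- list(...)
  for (f in c("cell_vol", "cell_conc", "syringe_conc", "temperature")) {
    if (is.null(extra[[f]]) && f %in% names(d)) extra[[f]] <- d[[f]][1]
  }
  do.call(itc_titration, c(list(inj_vols = d$inj_vol, heats = d$heat), extra))
}

#' Fit a single-site binding isotherm to an ITC titration
#'
#' Weighted least squares over (Kd, \eqn{\Delta H}, stoichiometry n, constant
#' dilution offset) on heats normalized per mole of injectant, with
#' displaced-volume concentration bookkeeping per injection. Kd is fit on a
#' log scale for positivity. The dilution heat can be fit as a constant
#' offset (`dilution = "fitted"`), subtracted from a blank-titration heat
#' vector (`dilution = <numeric>` in ucal), or ignored (`"none"`).
#'
#' @param t an [itc_titration()].
#' @param model only `"single-site"`.
#' @param fix named list of parameters to hold fixed, e.g.
#'   `list(n_sites = 1)`.
#' @param dilution `"fitted"`, `"none"`, or a numeric blank-heat vector.
#' @return object of class `binding_fit` with elements `Kd` (uM), `dH`
#'   (kcal/mol), `n_sites`, `q_dil` (kcal/mol injectant), `dG`, `TdS`
#'   (kcal/mol), standard errors (`se`), `c_value`, `fitted_ndh`,
#'   `converged`.
#' @export
fit_titration <- function(t, model = "single-site", fix = list(),
                          dilution = "fitted") {
  model <- match.arg(model, "single-site")
  if (length(t$heats) < 5L) stop("need at least 5 injections", call. = FALSE)
  heats <- t$heats
  if (is.numeric(dilution)) {
    heats <- heats - dilution
    dilution <- "none"
  }
  inj_umol <- t$syringe_conc * t$inj_vols * 1e-6
  ndh_obs <- (heats / 1000) / inj_umol
  if (stats::sd(ndh_obs) < 1e-12 && all(abs(ndh_obs) < 1e-9)) {
    warning("all heats ~0: dH -> 0 and Kd is unidentifiable", call. = FALSE)
  }
  fit_dil <- identical(dilution, "fitted")

  free <- c(logKd = TRUE, dH = TRUE, n_sites = !("n_sites" %in% names(fix)),
            q_dil = fit_dil)
  if ("Kd" %in% names(fix)) free["logKd"] <- FALSE
  if ("dH" %in% names(fix)) free["dH"] <- FALSE
  base <- c(logKd = log(t$cell_conc / 2),
            dH = ndh_obs[1],
            n_sites = if ("n_sites" %in% names(fix)) fix$n_sites else 1,
            q_dil = 0)
  if ("Kd" %in% names(fix)) base["logKd"] <- log(fix$Kd)
  if ("dH" %in% names(fix)) base["dH"] <- fix$dH

  resid_fun <- function(par) {
    p <- base; p[names(par)] <- par
    pred <- predict_itc_heats(exp(p[["logKd"]]), p[["dH"]], p[["n_sites"]],
                              t$cell_conc, t$syringe_conc, t$cell_vol,
                              t$inj_vols)$ndh + p[["q_dil"]]
    pred - ndh_obs
  }

  starts_Kd <- t$cell_conc * c(0.05, 0.5, 2, 10)
  best <- NULL
  for (k0 in starts_Kd) {
    st <- base[free]
    if ("logKd" %in% names(st)) st["logKd"] <- log(k0)
    ft <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(ft, "try-error")) next
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  if (is.null(best)) {
    stop("titration fit failed to converge from all start points", call. = FALSE)
  }
  p <- base; p[names(best$par)] <- best$par
  Kd <- exp(p[["logKd"]])

  npar <- length(best$par)
  dof <- max(length(ndh_obs) - npar, 1L)
  s2 <- best$deviance / dof
  cov <- try(s2 * solve(best$hessian / 2), silent = TRUE)
  se <- stats::setNames(rep(NA_real_, 4), names(base))
  if (!inherits(cov, "try-error") && all(diag(cov) >= 0)) {
    se[names(best$par)] <- sqrt(diag(cov))
  }
  se_Kd <- Kd * se[["logKd"]]  # delta method on log scale

  td <- thermodynamics(Kd, p[["dH"]], t$temperature)
  c_value <- p[["n_sites"]] * t$cell_conc / Kd
  if (is.finite(c_value) && (c_value < 1 || c_value > 1000)) {
    warning(sprintf("c-value %.3g outside [1, 1000]: Kd weakly identifiable",
                    c_value), call. = FALSE)
  }
  structure(list(Kd = Kd, dH = p[["dH"]], n_sites = p[["n_sites"]],
                 q_dil = p[["q_dil"]], dG = td$dG, TdS = td$TdS,
                 se = c(Kd = se_Kd, dH = se[["dH"]],
                        n_sites = se[["n_sites"]], q_dil = se[["q_dil"]]),
                 c_value = c_value,
                 fitted_ndh = ndh_obs - resid_fun(best$par),
                 residual_ss = best$deviance,
                 converged = best$info %in% 1:4),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("single-site fit: Kd = %.3g uM (se %.2g), dH = %.3g kcal/mol, n = %.3g\n",
              x$Kd, x$se[["Kd"]], x$dH, x$n_sites))
  cat(sprintf("  dG = %.3g, TdS = %.3g kcal/mol; c = %.3g\n",
              x$dG, x$TdS, x$c_value))
  invisible(x)
}

#' Binding free energy and entropic term from Kd and dH
#'
#' \eqn{\Delta G = RT\ln K_d} (Kd expressed in molar, standard state 1 M,
#' R = 1.9872e-3 kcal/(mol K)) and \eqn{T\Delta S = \Delta H - \Delta G}.
#'
#' @param Kd dissociation constant, uM.
#' @param dH binding enthalpy, kcal/mol.
#' @param temperature K (default 300).
#' @return list with `dG` and `TdS` in kcal/mol.
#' @export
thermodynamics <- function(Kd, dH, temperature = 300) {
  stopifnot_scalar(Kd, "Kd", positive = TRUE)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  dG <- .R_KCAL * temperature * log(Kd * 1e-6)
  list(dG = dG, TdS = dH - dG)
}

#' Nucleotide/substrate binding cooperativity coefficient
#'
#' \eqn{\sigma = K_d^{apo} / K_d^{nucleotide}}: the ratio of the substrate
#' (pseudosubstrate) dissociation constant for the apo enzyme over that for
#' the nucleotide-saturated enzyme. \eqn{\sigma > 1} indicates positive
#' cooperativity (nucleotide binding enhances substrate affinity),
#' \eqn{\sigma < 1} negative cooperativity. Uncertainty, when input sds are
#' given, is propagated first-order in quadrature on the relative errors.
#'
#' @param Kd_apo,Kd_nucleotide dissociation constants (same units).
#' @param sd_apo,sd_nucleotide optional standard deviations.
#' @return list: `sigma`, `sd` (NA without input sds), `cooperativity`
#'   (`"positive"`, `"negative"` or `"none"`).
#' @export
cooperativity <- function(Kd_apo, Kd_nucleotide,
                          sd_apo = NA, sd_nucleotide = NA) {
  stopifnot_scalar(Kd_apo, "Kd_apo", positive = TRUE)
  stopifnot_scalar(Kd_nucleotide, "Kd_nucleotide", positive = TRUE)
  sigma <- Kd_apo / Kd_nucleotide
  sd <- if (is.finite(sd_apo) && is.finite(sd_nucleotide)) {
    sigma * sqrt((sd_apo / Kd_apo)^2 + (sd_nucleotide / Kd_nucleotide)^2)
  } else NA_real_
  list(sigma = sigma, sd = sd,
       cooperativity = if (sigma > 1) "positive"
                       else if (sigma < 1) "negative" else "none")
}
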