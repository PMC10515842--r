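#' Read a Sparky-style amide peak list
#'
#' Parses whitespace-separated `.list` exports with an assignment column of
#' the form `G17N-H` followed by the \eqn{^{15}}N and \eqn{^1}H chemical
#' shifts in ppm and, optionally, the two linewidths (same order). A header
#' line beginning with `Assignment` is skipped.
#'
#' @param path path to the peak list file.
#' @param dialect only `"sparky"` is supported: columns are
#'   `assignment  w1(15N)  w2(1H)  [lw1  lw2]`.
#' @return a data.frame with columns `residue` (integer), `code` (one-letter
#'   amino acid code, `NA` when absent), `N`, `H` (ppm) and `lw_N`, `lw_H`
#'   (ppm, `NA` when the file carries no linewidths).
#' @export
read_peaklist <- function(path, dialect = "sparky") {
  dialect <- match.arg(dialect, "sparky")
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^Assignment", lines, ignore.case = TRUE)]
  if (length(lines) == 0L) {
    warning("empty peak list: ", path, call. = FALSE)
    return(data.frame(residue = integer(), code = character(),
                      N = numeric(), H = numeric(),
                      lw_N = numeric(), lw_H = numeric()))
  }
  parse_line <- function(i) {
    tok <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    m <- regmatches(tok[1], regexec("^([A-Za-z]?)([0-9]+)N-H$", tok[1]))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed assignment '%s' on line %d of %s",
                   tok[1], i, path), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop(sprintf("expected numeric shifts on line %d of %s", i, path),
           call. = FALSE)
    }
    data.frame(residue = as.integer(m[3]),
               code = if (nzchar(m[2])) toupper(m[2]) else NA_character_,
               N = vals[1], H = vals[2],
               lw_N = if (length(vals) >= 4L) vals[3] else NA_real_,
               lw_H = if (length(vals) >= 4L) vals[4] else NA_real_)
  }
  out <- do.call(rbind, lapply(seq_along(lines), parse_line))
  if (anyDuplicated(out$residue)) {
    stop("duplicate residue(s) in ", path, ": ",
         paste(unique(out$residue[duplicated(out$residue)]), collapse = ", "),
         call. = FALSE)
  }
  out[order(out$residue), , drop = FALSE]
}

#' Write a Sparky-style amide peak list
#'
#' Inverse of [read_peaklist()]; linewidth columns are written only when
#' present (non-`NA`) for every row.
#'
#' @param x data.frame as returned by [read_peaklist()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  code <- ifelse(is.na(x$code), "", x$code)
  assig <- sprintf("%s%dN-H", code, x$residue)
  has_lw <- all(!is.na(x$lw_N)) && all(!is.na(x$lw_H))
  body <- if (has_lw) {
    sprintf("%-12s %10.4f %10.4f %10.4f %10.4f", assig, x$N, x$H, x$lw_N, x$lw_H)
  } else {
    sprintf("%-12s %10.4f %10.4f", assig, x$N, x$H)
  }
  writeLines(c("Assignment         w1         w2", body), path)
  invisible(path)
}

#' Assemble a multi-state amide shift set
#'
#' Combines per-state peak tables (one per ligation state, e.g. apo, ADP,
#' ATP-analogue, ternary) into the container consumed by [csp()],
#' [response_filter()], [fit_residue_trajectories()] and
#' [correlation_matrix()]. State order is meaningful: it encodes the
#' open-to-closed direction of the conformational equilibrium.
#'
#' @param tables named list of per-state data.frames (columns as produced by
#'   [read_peaklist()]); names give the state order.
#' @param freq_H spectrometer \eqn{^1}H Larmor frequency in MHz, used for
#'   Hz-to-ppm linewidth conversion when requested.
#' @return an object of class `state_shift_set`: a long data.frame with
#'   columns `residue`, `code`, `state`, `H`, `N`, `lw_H`, `lw_N` and
#'   attributes `state_names` and `freq_H`.
#' @export
state_shift_set <- function(tables, freq_H = 600) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("`tables` must be a named list (one entry per state)", call. = FALSE)
  }
  long <- do.call(rbind, lapply(names(tables), function(s) {
    t <- tables[[s]]
    data.frame(residue = t$residue, code = t$code, state = s,
               H = t$H, N = t$N, lw_H = t$lw_H, lw_N = t$lw_N)
  }))
  rownames(long) <- NULL
  structure(long,
            state_names = names(tables),
            freq_H = freq_H,
            class = c("state_shift_set", "data.frame"))
}

#' @export
print.state_shift_set <- function(x, ...) {
  sn <- attr(x, "state_names")
  cat("state_shift_set:", length(unique(x$residue)), "residues x",
      length(sn), "states (", paste(sn, collapse = " -> "), ")\n")
  invisible(x)
}

# residues observed in every state, in residue order
complete_residues <- function(set) {
  sn <- attr(set, "state_names")
  tab <- table(set$residue)
  sort(as.integer(names(tab)[tab == length(sn)]))
}

# k x 2 matrix of (H, N) for one residue across states (state order preserved)
residue_track <- function(set, res) {
  sn <- attr(set, "state_names")
  sub <- set[set$residue == res, , drop = FALSE]
  sub <- sub[match(sn, sub$state), , drop = FALSE]
  cbind(H = sub$H, N = sub$N)
}
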