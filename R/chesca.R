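#' Inter-residue chemical-shift correlation matrix (CHESCA)
#'
#' CHESCA maps allosteric networks by correlating, across ligation states,
#' the chemical-shift responses of residue pairs. Each residue is reduced to
#' one response value per state and the matrix holds the Pearson correlation
#' of those per-state vectors.
#'
#' @param set a [state_shift_set()] with at least 3 states (4 recommended;
#'   a warning notes the reduced power below 4).
#' @param included residues to correlate (e.g. the `included` set from
#'   [response_filter()]); default: all residues present in every state.
#' @param mode `"combined"` (default): response value
#'   \eqn{\delta_H + 0.154\,\delta_N} per state; `"max"`: per pair, the
#'   larger in magnitude of the H-only and N-only correlations.
#' @param scale_N nitrogen scaling for `mode = "combined"`.
#' @return object of class `chesca_matrix`: list with `residues` and `R`
#'   (symmetric correlation matrix, unit diagonal). Residues with zero
#'   variance across states are excluded with a warning.
#' @export
correlation_matrix <- function(set, included = NULL,
                               mode = c("combined", "max"), scale_N = 0.154) {
  mode <- match.arg(mode)
  sn <- attr(set, "state_names")
  if (length(sn) < 3L) stop("need at least 3 states", call. = FALSE)
  if (length(sn) == 3L) {
    warning("only 3 states: correlations have reduced discriminating power",
            call. = FALSE)
  }
  res <- complete_residues(set)
  if (!is.null(included)) res <- res[res %in% included]
  tracks <- lapply(res, residue_track, set = set)
  H <- do.call(rbind, lapply(tracks, function(t) t[, "H"]))
  N <- do.call(rbind, lapply(tracks, function(t) t[, "N"]))
  drop_zero <- function(X, Y) {
    vH <- apply(X, 1, stats::var); vN <- apply(Y, 1, stats::var)
    if (mode == "combined") apply(X + scale_N * Y, 1, stats::var) > 1e-24
    else vH > 1e-24 | vN > 1e-24
  }
  ok <- drop_zero(H, N)
  if (any(!ok)) {
    warning("residue(s) with zero shift variance excluded: ",
            paste(res[!ok], collapse = ", "), call. = FALSE)
    res <- res[ok]; H <- H[ok, , drop = FALSE]; N <- N[ok, , drop = FALSE]
  }
  if (mode == "combined") {
    R <- stats::cor(t(H + scale_N * N))
  } else {
    RH <- suppressWarnings(stats::cor(t(H)))
    RN <- suppressWarnings(stats::cor(t(N)))
    RH[is.na(RH)] <- 0; RN[is.na(RN)] <- 0
    R <- ifelse(abs(RH) >= abs(RN), RH, RN)
    diag(R) <- 1
  }
  dimnames(R) <- list(res, res)
  structure(list(residues = res, R = R), class = "chesca_matrix")
}

#' CHESCA correlation score
#'
#' Fraction of admissible residue pairs whose correlation beats a cutoff:
#' for a single residue, its pairs with all other residues; for the whole
#' set, all unordered off-diagonal pairs.
#'
#' @param cm a `chesca_matrix` from [correlation_matrix()].
#' @param cutoff correlation cutoff (strict `>`; default 0.98).
#' @param subset single residue id, vector of ids, or `NULL` for the whole
#'   matrix.
#' @param use_abs compare `|R_ij|` (default, CHESCA convention) or signed
#'   `R_ij` against the cutoff.
#' @return score in [0, 1].
#' @export
corr_score <- function(cm, cutoff = 0.98, subset = NULL, use_abs = TRUE) {
  R <- cm$R
  v <- if (use_abs) abs(R) else R
  if (is.null(subset)) {
    up <- v[upper.tri(v)]
    if (length(up) == 0L) stop("need at least 2 residues", call. = FALSE)
    mean(up > cutoff)
  } else {
    idx <- match(subset, cm$residues)
    if (anyNA(idx)) stop("subset residue(s) not in matrix", call. = FALSE)
    if (length(idx) == 1L) {
      mean(v[idx, -idx] > cutoff)
    } else {
      sub <- v[idx, idx]
      mean(sub[upper.tri(sub)] > cutoff)
    }
  }
}

#' Agglomerative clustering of the CHESCA correlation matrix
#'
#' Clusters residues on the distance `1 - |R|` with deterministic,
#' residue-id-ordered tie handling (the order in which `hclust` receives
#' observations is fixed by residue id).
#'
#' @param cm a `chesca_matrix`.
#' @param linkage linkage criterion for [stats::hclust()] (default
#'   `"complete"`).
#' @param n_clusters number of clusters to cut into; alternatively give
#'   `height` to cut at a distance threshold.
#' @param height optional distance threshold.
#' @return integer vector of cluster labels named by residue id.
#' @export
cluster_residues <- function(cm, linkage = "complete", n_clusters = NULL,
                             height = NULL) {
  d <- 1 - abs(cm$R)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (length(cm$residues) == 1L) {
    return(stats::setNames(1L, cm$residues))
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  if (is.null(n_clusters) && is.null(height)) n_clusters <- 2L
  labels <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters)
            else stats::cutree(hc, h = height)
  stats::setNames(as.integer(labels), cm$residues)
}

#' Read a community-membership map from JSON
#'
#' Communities are functional residue groups (e.g. ComA..ComH of the kinase
#' community decomposition); the JSON holds `{"ComA": [resid, ...], ...}`.
#'
#' @param path JSON file path.
#' @return named list of integer residue vectors, class `community_map`.
#' @export
read_community_map <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lapply(m, as.integer)
  if (any(lengths(m) == 0L)) {
    stop("community with no residues: ",
         paste(names(m)[lengths(m) == 0L], collapse = ", "), call. = FALSE)
  }
  all_res <- unlist(m, use.names = FALSE)
  if (anyDuplicated(all_res)) {
    warning("residue(s) shared between communities: ",
            paste(unique(all_res[duplicated(all_res)]), collapse = ", "),
            call. = FALSE)
  }
  structure(m, class = "community_map")
}

#' Community-level CHESCA correlation scores
#'
#' For communities A and B the score is the fraction of cross pairs whose
#' correlation beats the cutoff:
#' \deqn{R_{A,B} = \#\{|R_{ij}| > R_{cutoff}: i \in A, j \in B\} / (n_A n_B)}
#' The diagonal entry \eqn{R_{A,A}} is computed over the \eqn{n_A(n_A-1)}
#' ordered off-diagonal pairs within the community.
#'
#' @param cm a `chesca_matrix`.
#' @param map named list of residue vectors (a `community_map` or plain
#'   list). Residues missing from the matrix are dropped per community and
#'   reported; communities left empty are dropped with a warning.
#' @param cutoff correlation cutoff (default 0.8, the community-level
#'   convention).
#' @param use_abs compare absolute correlations (default).
#' @return matrix of scores in [0, 1], labels x labels.
#' @export
community_scores <- function(cm, map, cutoff = 0.8, use_abs = TRUE) {
  v <- if (use_abs) abs(cm$R) else cm$R
  mapped <- lapply(map, function(r) {
    miss <- setdiff(r, cm$residues)
    if (length(miss)) {
      message("community residues absent from matrix dropped: ",
              paste(miss, collapse = ", "))
    }
    match(intersect(r, cm$residues), cm$residues)
  })
  empty <- lengths(mapped) == 0L
  if (any(empty)) {
    warning("community with 0 mapped residues dropped: ",
            paste(names(map)[empty], collapse = ", "), call. = FALSE)
    mapped <- mapped[!empty]
  }
  nm <- names(mapped)
  S <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in seq_along(mapped)) {
    for (b in seq_along(mapped)) {
      ia <- mapped[[a]]; ib <- mapped[[b]]
      block <- v[ia, ib, drop = FALSE]
      if (a == b) {
        n <- length(ia)
        if (n < 2L) { S[a, b] <- NA_real_; next }
        off <- block[row(block) != col(block)]
        S[a, b] <- sum(off > cutoff) / (n * (n - 1L))
      } else {
        S[a, b] <- sum(block > cutoff) / (length(ia) * length(ib))
      }
    }
  }
  S
}
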