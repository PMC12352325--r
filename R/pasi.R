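#' Build the fuzzy decision matrix from respondent-level microdata
#'
#' Converts the nine ordinal item codes of each respondent into triangular
#' fuzzy numbers via the registered scale mappings, producing the
#' respondents-by-indicators fuzzy decision matrix that the TOPSIS stage
#' ranks. Because every cell is a TFN on the shared \[0, 100\] universe of
#' discourse, no further normalization of the decision matrix is needed.
#'
#' Respondents with a missing or out-of-range code on any item are dropped
#' (complete-case policy); the count of dropped rows is reported with a
#' message and kept in the result.
#'
#' @param data data.frame with one row per respondent: an id column
#'   (`respondent_id`, created if absent), integer item columns named as in
#'   `items$item_id`, and any number of categorical covariate columns.
#' @param items item definition table, by default [pasi_items()].
#' @return An object of class `"fuzzy_decision_matrix"`: list with
#'   `respondent_id`, `items`, TFN component matrices `L`, `M`, `U`
#'   (n x 9), the centroid-defuzzified matrix `crisp`, the covariate
#'   data.frame `covariates`, and `n_dropped`.
#' @export
build_decision_matrix <- function(data, items = pasi_items()) {
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("no respondents: input must be a non-empty data.frame", call. = FALSE)
  missing_items <- setdiff(items$item_id, names(data))
  if (length(missing_items))
    stop("missing item columns: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  if (!"respondent_id" %in% names(data))
    data$respondent_id <- seq_len(nrow(data))

  codes <- as.matrix(data[items$item_id])
  storage.mode(codes) <- "integer"
  npts <- vapply(items$scale_id, function(s) get_scale(s)$n_points, integer(1))
  in_range <- !is.na(codes) &
    codes >= 1L & codes <= matrix(npts, nrow(codes), ncol(codes), byrow = TRUE)
  keep <- rowSums(in_range) == ncol(codes)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("dropped ", n_dropped,
            " respondent(s) with missing or out-of-range item codes")
  if (!any(keep)) stop("no respondents left after complete-case filtering",
                       call. = FALSE)
  data <- data[keep, , drop = FALSE]
  codes <- codes[keep, , drop = FALSE]

  n <- nrow(codes); p <- nrow(items)
  L <- M <- U <- matrix(NA_real_, n, p, dimnames = list(NULL, items$item_id))
  for (j in seq_len(p)) {
    t_j <- to_tfn(items$scale_id[j], codes[, j])
    L[, j] <- t_j[, "lower"]; M[, j] <- t_j[, "mode"]; U[, j] <- t_j[, "upper"]
  }
  cov_cols <- setdiff(names(data), c("respondent_id", items$item_id))
  structure(list(respondent_id = data$respondent_id,
                 items = items,
                 L = L, M = M, U = U,
                 crisp = (L + M + U) / 3,
                 covariates = data[cov_cols],
                 n_dropped = n_dropped),
            class = "fuzzy_decision_matrix")
}

#' @export
print.fuzzy_decision_matrix <- function(x, ...) {
  cat("<fuzzy_decision_matrix> ", nrow(x$crisp), " respondents x ",
      ncol(x$crisp), " indicators (", x$n_dropped, " dropped)\n", sep = "")
  cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate one population segment of the fuzzy decision matrix
#'
#' A segment profile is the component-wise arithmetic mean of the member
#' TFNs on each indicator, together with its centroid defuzzification -- the
#' crisp value used for ideal-solution selection and distance computation.
#'
#' @param fdm a `"fuzzy_decision_matrix"`.
#' @param members logical vector over respondents (or an index vector).
#' @param label segment label.
#' @return A `"segment_profile"`: list with `label`, `n`, `mean_tfns`
#'   (a 9-row `"tfn"`), and `defuzzified` (numeric 9-vector of centroids).
#' @export
aggregate_segment <- function(fdm, members, label = "segment") {
  stopifnot(inherits(fdm, "fuzzy_decision_matrix"))
  idx <- if (is.logical(members)) which(members) else as.integer(members)
  if (length(idx) == 0L) stop("empty segment: ", label, call. = FALSE)
  L <- colMeans(fdm$L[idx, , drop = FALSE])
  M <- colMeans(fdm$M[idx, , drop = FALSE])
  U <- colMeans(fdm$U[idx, , drop = FALSE])
  mt <- tfn(L, M, U)
  rownames(mt) <- names(L)
  structure(list(label = label, n = length(idx),
                 mean_tfns = mt,
                 defuzzified = (L + M + U) / 3),
            class = "segment_profile")
}

#' Segment profiles for every category of the chosen covariates
#'
#' @param fdm a `"fuzzy_decision_matrix"`.
#' @param covariates character vector of covariate column names; default all.
#' @return A list of `"segment_profile"` objects, labelled
#'   `"<covariate>: <category>"`, in covariate order then category order of
#'   first appearance.
#' @export
segment_profiles <- function(fdm, covariates = names(fdm$covariates)) {
  stopifnot(inherits(fdm, "fuzzy_decision_matrix"))
  bad <- setdiff(covariates, names(fdm$covariates))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- list()
  for (cv in covariates) {
    vals <- as.character(fdm$covariates[[cv]])
    for (cat in unique(vals)) {
      lab <- paste0(cv, ": ", cat)
      out[[lab]] <- aggregate_segment(fdm, vals == cat, label = lab)
    }
  }
  out
}

#' Positive and negative ideal solutions
#'
#' For each indicator the positive ideal A+ is the largest defuzzified value
#' attained by any reference unit (segment profile, or individual row of the
#' decision matrix) and the negative ideal A- the smallest; the attaining
#' unit is recorded as the "representative". Ties are broken by first
#' occurrence in input order and reported with a message.
#'
#' @param x either a list of `"segment_profile"` objects (segment mode,
#'   the default reference set mirroring published ideal-solution tables) or
#'   a `"fuzzy_decision_matrix"` (individual mode: the most and least active
#'   respondents in the sample anchor the index).
#' @return An `"ideal_solutions"` data.frame with columns `item_id`,
#'   `a_plus`, `rep_plus`, `a_minus`, `rep_minus`; attributes `mode` and the
#'   fuzzy ideal TFNs `tfn_plus`, `tfn_minus` of the attaining units (used
#'   by the fully fuzzy distance mode).
#' @export
ideal_solutions <- function(x) {
  if (inherits(x, "fuzzy_decision_matrix")) {
    crisp <- x$crisp
    labels <- as.character(x$respondent_id)
    Ls <- x$L; Ms <- x$M; Us <- x$U
    mode <- "individual"
    item_ids <- colnames(crisp)
  } else {
    if (!is.list(x) || length(x) < 2L ||
        !all(vapply(x, inherits, logical(1), "segment_profile")))
      stop("degenerate reference set: need >= 2 segment profiles",
           call. = FALSE)
    crisp <- do.call(rbind, lapply(x, `[[`, "defuzzified"))
    labels <- vapply(x, `[[`, character(1), "label")
    Ls <- do.call(rbind, lapply(x, function(p) p$mean_tfns[, "lower"]))
    Ms <- do.call(rbind, lapply(x, function(p) p$mean_tfns[, "mode"]))
    Us <- do.call(rbind, lapply(x, function(p) p$mean_tfns[, "upper"]))
    mode <- "segment"
    item_ids <- rownames(x[[1L]]$mean_tfns)
    if (is.null(item_ids)) item_ids <- paste0("QB", seq_len(ncol(crisp)))
  }
  if (nrow(crisp) < 2L)
    stop("degenerate reference set: need >= 2 reference units", call. = FALSE)

  i_plus <- apply(crisp, 2L, which.max)
  i_minus <- apply(crisp, 2L, which.min)
  for (j in seq_along(i_plus)) {
    n_tied <- sum(crisp[, j] == crisp[i_plus[j], j]) +
      sum(crisp[, j] == crisp[i_minus[j], j]) - 2L
    if (n_tied > 0L)
      message("ideal-solution tie on ", item_ids[j],
              "; kept first unit in input order")
  }
  jj <- seq_along(i_plus)
  out <- data.frame(
    item_id = item_ids,
    a_plus = crisp[cbind(i_plus, jj)],
    rep_plus = labels[i_plus],
    a_minus = crisp[cbind(i_minus, jj)],
    rep_minus = labels[i_minus],
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- mode
  attr(out, "tfn_plus") <- tfn(Ls[cbind(i_plus, jj)], Ms[cbind(i_plus, jj)],
                               Us[cbind(i_plus, jj)])
  attr(out, "tfn_minus") <- tfn(Ls[cbind(i_minus, jj)], Ms[cbind(i_minus, jj)],
                                Us[cbind(i_minus, jj)])
  class(out) <- c("ideal_solutions", "data.frame")
  out
}

#' TOPSIS closeness coefficient
#'
#' The ratio `d_minus / (d_plus + d_minus)`: the share of a unit's total
#' ideal-distance attributable to its remoteness from the least-active
#' reference. Equals 1 at the positive ideal and 0 at the negative ideal.
#' In the degenerate case where both distances are zero (all reference
#' values equal) the unit is equidistant by convention and 0.5 is returned
#' with a warning.
#'
#' @param d_plus,d_minus non-negative distances to the positive and negative
#'   ideal solutions (vectorized).
#' @return Numeric vector of closeness coefficients in \[0, 1\].
#' @export
closeness <- function(d_plus, d_minus) {
  if (any(d_plus < 0) || any(d_minus < 0))
    stop("distances must be non-negative", call. = FALSE)
  tot <- d_plus + d_minus
  out <- ifelse(tot > 0, d_minus / tot, 0.5)
  if (any(tot == 0))
    warning("degenerate unit equidistant from both ideals; closeness set to 0.5",
            call. = FALSE)
  out
}

# distances of a crisp matrix (units x indicators) to the two ideal vectors
.ideal_distances <- function(crisp, ideals, distance, L = NULL, M = NULL,
                             U = NULL) {
  if (!identical(colnames(crisp), ideals$item_id))
    stop("indicator mismatch between decision matrix and ideal solutions",
         call. = FALSE)
  if (distance == "crisp") {
    d_plus <- sqrt(rowSums(sweep(crisp, 2L, ideals$a_plus)^2))
    d_minus <- sqrt(rowSums(sweep(crisp, 2L, ideals$a_minus)^2))
  } else {
    tp <- unclass(attr(ideals, "tfn_plus"))
    tm <- unclass(attr(ideals, "tfn_minus"))
    dp2 <- dm2 <- 0
    for (j in seq_len(ncol(crisp))) {
      dp2 <- dp2 + ((L[, j] - tp[j, 1])^2 + (M[, j] - tp[j, 2])^2 +
                      (U[, j] - tp[j, 3])^2) / 3
      dm2 <- dm2 + ((L[, j] - tm[j, 1])^2 + (M[, j] - tm[j, 2])^2 +
                      (U[, j] - tm[j, 3])^2) / 3
    }
    d_plus <- sqrt(dp2); d_minus <- sqrt(dm2)
  }
  list(d_plus = d_plus, d_minus = d_minus)
}

#' Individual-level PASI scores
#'
#' Scores every respondent by TOPSIS closeness to the ideal solutions. In
#' the default crisp mode the distance is the unweighted Euclidean distance
#' across the nine centroid-defuzzified indicators; in fuzzy mode it is the
#' Euclidean aggregate of per-indicator vertex distances to the fuzzy ideals
#' (a sensitivity-analysis variant).
#'
#' @param fdm a `"fuzzy_decision_matrix"`.
#' @param ideals an `"ideal_solutions"` object on the same indicator set.
#' @param distance `"crisp"` (default) or `"fuzzy"`.
#' @return data.frame with `respondent_id`, `d_plus`, `d_minus`, `pasi`.
#' @export
pasi_individual <- function(fdm, ideals, distance = c("crisp", "fuzzy")) {
  stopifnot(inherits(fdm, "fuzzy_decision_matrix"),
            inherits(ideals, "ideal_solutions"))
  distance <- match.arg(distance)
  d <- .ideal_distances(fdm$crisp, ideals, distance, fdm$L, fdm$M, fdm$U)
  data.frame(respondent_id = fdm$respondent_id,
             d_plus = d$d_plus, d_minus = d$d_minus,
             pasi = closeness(d$d_plus, d$d_minus))
}

#' Segment-level PASI scores
#'
#' @param profiles list of `"segment_profile"` objects.
#' @param ideals an `"ideal_solutions"` object on the same indicator set.
#' @param distance `"crisp"` (default) or `"fuzzy"`.
#' @return data.frame with `segment`, `n`, `d_plus`, `d_minus`, `pasi`.
#' @export
pasi_segment <- function(profiles, ideals, distance = c("crisp", "fuzzy")) {
  stopifnot(inherits(ideals, "ideal_solutions"))
  distance <- match.arg(distance)
  crisp <- do.call(rbind, lapply(profiles, `[[`, "defuzzified"))
  colnames(crisp) <- ideals$item_id
  L <- do.call(rbind, lapply(profiles, function(p) p$mean_tfns[, "lower"]))
  M <- do.call(rbind, lapply(profiles, function(p) p$mean_tfns[, "mode"]))
  U <- do.call(rbind, lapply(profiles, function(p) p$mean_tfns[, "upper"]))
  d <- .ideal_distances(crisp, ideals, distance, L, M, U)
  data.frame(segment = vapply(profiles, `[[`, character(1), "label"),
             n = vapply(profiles, `[[`, integer(1), "n"),
             d_plus = d$d_plus, d_minus = d$d_minus,
             pasi = closeness(d$d_plus, d$d_minus),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage variation between the ideal solutions
#'
#' `100 * (a_plus - a_minus) / a_minus`, the heterogeneity measure reported
#' alongside each indicator's ideal solutions: large values flag indicators
#' on which the sample is most polarized.
#'
#' @param a_plus,a_minus positive and negative ideal values (`a_minus > 0`).
#' @return Percentage variation (vectorized); display convention is one
#'   decimal.
#' @examples
#' pct_variation(57.04, 14.96)  # 281.3 after rounding to one decimal
#' @export
pct_variation <- function(a_plus, a_minus) {
  if (any(a_minus <= 0))
    stop("undefined variation: a_minus must be > 0", call. = FALSE)
  100 * (a_plus - a_minus) / a_minus
}

#' Quintile assignment of PASI scores
#'
#' Rank-based split into five groups: quintile 1 holds the lowest scores
#' (the most sedentary fifth), quintile 5 the highest. Group sizes are
#' n/5 rounded, any remainder going to the lower quintiles, so sizes differ
#' by at most one. Ties are broken by stable input order; a warning is
#' emitted when tied values straddle a quintile boundary.
#'
#' @param pasi_values numeric vector, length >= 5.
#' @return Integer vector of quintiles 1..5, aligned with the input.
#' @export
quintile_assign <- function(pasi_values) {
  n <- length(pasi_values)
  if (n < 5L) stop("need at least 5 values to form quintiles", call. = FALSE)
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(pasi_values)  # stable for ties
  q <- integer(n)
  q[ord] <- rep.int(1:5, sizes)
  bounds <- cumsum(sizes)[1:4]
  sorted <- pasi_values[ord]
  if (any(sorted[bounds] == sorted[bounds + 1L]))
    warning("tied PASI values straddle a quintile boundary; stable input order used",
            call. = FALSE)
  q
}
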