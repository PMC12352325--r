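#' Daly normalization of categorical covariates
#'
#' In choice and ordinal models categorical regressors need an
#' identification constraint. The usual dummy coding fixes one category's
#' coefficient to zero, so every coefficient is a contrast against that
#' (arbitrary) base. The Daly normalization instead constrains the
#' share-weighted sum of a covariate's coefficients to zero,
#' `sum_k w_k beta_k = 0`, with `w_k` the sample share of category k. Every
#' coefficient then reads directly as a deviation from the average citizen,
#' which is the interpretation used throughout the sedentarism model.
#'
#' `daly_spec()` derives categories and shares from data; `daly_encode()`
#' produces the design matrix. A covariate with K categories yields K-1
#' columns: an observation in category k < K scores 1 on column k; an
#' observation in the last (reference) category scores `-w_k / w_K` on every
#' column k. The implied reference coefficient is recovered by
#' [implied_coefficients()].
#'
#' @param data data.frame of categorical covariate columns.
#' @param covariates character vector of column names to include.
#' @return For `daly_spec()`: a `"daly_spec"` object, a named list with one
#'   entry per covariate holding `categories` (order of first appearance;
#'   the last is the encoding reference) and `shares`.
#' @export
daly_spec <- function(data, covariates = names(data)) {
  stopifnot(is.data.frame(data))
  bad <- setdiff(covariates, names(data))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  spec <- lapply(covariates, function(cv) {
    vals <- as.character(data[[cv]])
    cats <- unique(vals)
    if (length(cats) < 2L)
      stop("covariate '", cv, "' needs >= 2 categories", call. = FALSE)
    shares <- as.numeric(table(factor(vals, levels = cats))) / length(vals)
    list(categories = cats, shares = shares)
  })
  names(spec) <- covariates
  structure(spec, class = "daly_spec")
}

#' @rdname daly_spec
#' @param spec a `"daly_spec"` object (or a compatible named list of
#'   `categories`/`shares` entries with shares summing to one).
#' @return For `daly_encode()`: a `"daly_design"` object: list with the
#'   design matrix `X` (n x total(K-1) columns, named `covariate.category`),
#'   a `map` data.frame (column, covariate, category, share) and the `spec`.
#' @export
daly_encode <- function(data, spec) {
  stopifnot(is.data.frame(data))
  blocks <- list(); map <- list()
  for (cv in names(spec)) {
    cats <- spec[[cv]]$categories
    w <- spec[[cv]]$shares
    K <- length(cats)
    if (abs(sum(w) - 1) > 1e-9)
      stop("shares for '", cv, "' must sum to 1", call. = FALSE)
    if (w[K] <= 0)
      stop("zero-share reference category for '", cv, "'", call. = FALSE)
    vals <- as.character(data[[cv]])
    unseen <- setdiff(unique(vals), cats)
    if (length(unseen))
      stop("category not in spec for '", cv, "': ",
           paste(unseen, collapse = ", "), call. = FALSE)
    k <- match(vals, cats)
    B <- matrix(0, length(vals), K - 1L,
                dimnames = list(NULL, paste(cv, cats[-K], sep = ".")))
    for (j in seq_len(K - 1L)) B[k == j, j] <- 1
    ref <- k == K
    if (any(ref)) B[ref, ] <- matrix(-w[-K] / w[K], sum(ref), K - 1L,
                                     byrow = TRUE)
    blocks[[cv]] <- B
    map[[cv]] <- data.frame(covariate = cv, category = cats[-K],
                            share = w[-K], stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, blocks)
  map <- do.call(rbind, map)
  map$column <- colnames(X)
  rownames(map) <- NULL
  structure(list(X = X, map = map, spec = spec), class = "daly_design")
}

# the Daly encoding row (length K-1) for a named category of a covariate
.daly_row <- function(spec, covariate, category) {
  cats <- spec[[covariate]]$categories
  w <- spec[[covariate]]$shares
  K <- length(cats)
  k <- match(category, cats)
  if (is.na(k)) stop("unknown category '", category, "' for covariate '",
                     covariate, "'", call. = FALSE)
  if (k == K) return(-w[-K] / w[K])
  out <- numeric(K - 1L); out[k] <- 1
  out
}

#' Implied full coefficient set under the Daly constraint
#'
#' Expands the K-1 estimated coefficients of each covariate with the
#' implied reference coefficient `-sum_{k<K} (w_k / w_K) beta_k`, so that
#' the share-weighted coefficients sum to zero exactly. Standard errors for
#' the reference coefficient follow from the delta method (it is linear in
#' beta).
#'
#' @param fit an `"ordered_probit_fit"` estimated on a `"daly_design"`.
#' @return data.frame with `covariate`, `category`, `share`, `coef`, `se`.
#' @export
implied_coefficients <- function(fit) {
  stopifnot(inherits(fit, "ordered_probit_fit"))
  if (is.null(fit$design)) stop("fit carries no Daly design", call. = FALSE)
  spec <- fit$design$spec
  map <- fit$design$map
  Vb <- fit$vcov[seq_along(fit$beta), seq_along(fit$beta), drop = FALSE]
  out <- list()
  for (cv in names(spec)) {
    cats <- spec[[cv]]$categories
    w <- spec[[cv]]$shares
    K <- length(cats)
    idx <- which(map$covariate == cv)
    b <- fit$beta[idx]
    se <- sqrt(diag(Vb)[idx])
    a <- -w[-K] / w[K]                       # reference coef = a' beta_cv
    b_ref <- sum(a * b)
    se_ref <- sqrt(drop(t(a) %*% Vb[idx, idx, drop = FALSE] %*% a))
    out[[cv]] <- data.frame(covariate = cv, category = cats,
                            share = w, coef = c(b, b_ref), se = c(se, se_ref),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ordered probit outcome probabilities
#'
#' The latent model is `y* = x'beta + eps`, `eps ~ N(0, 1)`; the observed
#' outcome is `y = j` when `eta_{j-1} < y* <= eta_j` with ordered thresholds
#' (`eta_0 = -Inf`, `eta_J = +Inf`). Hence
#' `P(y = j | x) = Phi(eta_j - x'beta) - Phi(eta_{j-1} - x'beta)`.
#' There is no intercept: it is absorbed into the thresholds.
#'
#' @param beta coefficient vector (length = ncol(X)).
#' @param eta strictly increasing threshold vector (length J-1; J = 5 for
#'   PASI quintiles).
#' @param X design matrix.
#' @return n x J matrix of probabilities; rows sum to 1.
#' @export
predict_probs <- function(beta, eta, X) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop("beta/X dimension mismatch", call. = FALSE)
  if (is.unsorted(eta, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  xb <- drop(X %*% beta)
  cum <- cbind(0, stats::pnorm(outer(-xb, eta, `+`)), 1)
  P <- cum[, -1L, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  colnames(P) <- paste0("P", seq_len(ncol(P)))
  P
}

#' Ordered probit log-likelihood
#'
#' `sum_i log P(y_i | x_i)` under the threshold model of [predict_probs()].
#' Probabilities are floored at 1e-300 so the log never returns -Inf.
#'
#' @inheritParams predict_probs
#' @param y integer outcomes in 1..J.
#' @return Scalar log-likelihood (<= 0).
#' @export
ordered_probit_loglik <- function(beta, eta, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("y/X dimension mismatch", call. = FALSE)
  J <- length(eta) + 1L
  if (any(y < 1L | y > J)) stop("outcomes must lie in 1..", J, call. = FALSE)
  P <- predict_probs(beta, eta, X)
  sum(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
}

# analytic score in the original (beta, eta) parameterization
.op_score <- function(beta, eta, X, y) {
  xb <- drop(X %*% beta)
  J <- length(eta) + 1L
  z_hi <- ifelse(y == J, Inf, eta[pmin(y, J - 1L)] - xb)
  z_lo <- ifelse(y == 1L, -Inf, eta[pmax(y - 1L, 1L)] - xb)
  P <- pmax(stats::pnorm(z_hi) - stats::pnorm(z_lo), 1e-300)
  phi_hi <- ifelse(is.finite(z_hi), stats::dnorm(z_hi), 0)
  phi_lo <- ifelse(is.finite(z_lo), stats::dnorm(z_lo), 0)
  g_beta <- drop(crossprod(X, (phi_lo - phi_hi) / P))
  g_eta <- numeric(J - 1L)
  for (j in seq_len(J - 1L)) {
    g_eta[j] <- sum(phi_hi[y == j] / P[y == j]) -
      sum(phi_lo[y == j + 1L] / P[y == j + 1L])
  }
  c(g_beta, g_eta)
}

# eta <-> unconstrained a: eta1 = a1, eta_j = eta_{j-1} + exp(a_j)
.eta_to_a <- function(eta) c(eta[1L], log(diff(eta)))
.a_to_eta <- function(a) cumsum(c(a[1L], exp(a[-1L])))

#' Fit the ordered probit by maximum likelihood
#'
#' Hand-coded estimation: quasi-Newton (BFGS) with the analytic score on a
#' reparameterized threshold vector (first threshold free, subsequent
#' increments as exponentials, so `eta_1 < ... < eta_{J-1}` holds at every
#' iterate), followed by Newton polishing until the score norm falls below
#' 1e-8. Standard errors come from the inverse observed Hessian (central
#' finite differences of the analytic score) in the original
#' parameterization. Non-convergence is flagged, not thrown.
#'
#' @param design a `"daly_design"` from [daly_encode()], or a plain design
#'   matrix.
#' @param y integer outcomes 1..J (all J categories must be present).
#' @param n_outcomes number of outcome categories J (default 5, the PASI
#'   quintiles); every category 1..J must appear in `y`.
#' @param init optional list with starting `beta` and `eta`; defaults to
#'   `beta = 0` and thresholds at the normal quantiles of the cumulative
#'   outcome shares (the exact MLE when beta = 0).
#' @return An `"ordered_probit_fit"`: list with `beta`, `eta`, `se_beta`,
#'   `se_eta`, `vcov` (over `c(beta, eta)`), `loglik`, `converged`,
#'   `score_norm`, `n`, and the `design` when one was supplied.
#' @export
fit_ordered_probit <- function(design, y, init = NULL, n_outcomes = 5L) {
  daly <- inherits(design, "daly_design")
  X <- if (daly) design$X else as.matrix(design)
  y <- as.integer(y)
  J <- as.integer(n_outcomes)
  if (!all(seq_len(J) %in% y))
    stop("every outcome category 1..", J, " must be present", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + J - 1L) stop("more parameters than observations", call. = FALSE)

  bi <- seq_len(p)                 # beta indices (may be empty)
  ei <- p + seq_len(J - 1L)        # threshold indices
  if (is.null(init)) {
    shares <- cumsum(tabulate(y, J) / n)[seq_len(J - 1L)]
    init <- list(beta = numeric(p), eta = stats::qnorm(shares))
  }
  theta0 <- c(init$beta, .eta_to_a(init$eta))
  split_theta <- function(th) list(beta = th[bi], eta = .a_to_eta(th[ei]))
  # exp() underflow can collapse a threshold increment during line search;
  # penalize instead of erroring so BFGS backs off
  nll <- function(th) {
    pr <- split_theta(th)
    if (is.unsorted(pr$eta, strictly = TRUE)) return(.Machine$double.xmax / 2)
    -ordered_probit_loglik(pr$beta, pr$eta, X, y)
  }
  ngr <- function(th) {
    pr <- split_theta(th)
    if (is.unsorted(pr$eta, strictly = TRUE)) return(numeric(length(th)))
    g <- .op_score(pr$beta, pr$eta, X, y)     # wrt (beta, eta)
    a <- th[ei]
    g_eta <- g[ei]
    # chain rule: d eta_j / d a_m = 1 (m = 1), exp(a_m) * [m <= j] (m > 1)
    g_a <- c(sum(g_eta),
             if (J > 2L) exp(a[-1L]) * rev(cumsum(rev(g_eta)))[-1L])
    -c(g[bi], g_a)
  }
  opt <- stats::optim(theta0, nll, ngr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  theta <- opt$par

  # Newton polish in the original parameterization to score norm < 1e-8
  pr <- split_theta(theta)
  par <- c(pr$beta, pr$eta)
  score_orig <- function(par) .op_score(par[bi], par[ei], X, y)
  num_hessian <- function(par) {
    k <- length(par)
    H <- matrix(0, k, k)
    h <- 1e-6 * (1 + abs(par))
    for (m in seq_len(k)) {
      up <- par; up[m] <- up[m] + h[m]
      dn <- par; dn[m] <- dn[m] - h[m]
      H[, m] <- (score_orig(up) - score_orig(dn)) / (2 * h[m])
    }
    (H + t(H)) / 2
  }
  ll_of <- function(par) ordered_probit_loglik(par[bi], par[ei], X, y)
  g <- score_orig(par)
  iter <- 0L
  while (sqrt(sum(g^2)) > 1e-8 && iter < 30L) {
    H <- num_hessian(par)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - step
    sc <- 1
    while ((is.unsorted(cand[ei], strictly = TRUE) ||
            ll_of(cand) < ll_of(par) - 1e-12) && sc > 1e-4) {
      sc <- sc / 2
      cand <- par - sc * step
    }
    if (is.unsorted(cand[ei], strictly = TRUE)) break
    par <- cand
    g <- score_orig(par)
    iter <- iter + 1L
  }
  score_norm <- sqrt(sum(g^2))
  converged <- score_norm < 1e-8

  H <- num_hessian(par)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, length(par),
                                                      length(par)))
  beta <- par[bi]
  eta <- par[ei]
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(V), 0))
  fit <- structure(list(beta = beta, eta = eta,
                        se_beta = stats::setNames(se[bi], colnames(X)),
                        se_eta = se[ei],
                        vcov = V,
                        loglik = ll_of(par),
                        converged = converged,
                        score_norm = score_norm,
                        n = n,
                        design = if (daly) design else NULL),
                   class = "ordered_probit_fit")
  if (!converged)
    warning("ordered probit did not reach score norm 1e-8 (got ",
            format(score_norm, digits = 3), ")", call. = FALSE)
  fit
}

#' @export
print.ordered_probit_fit <- function(x, ...) {
  cat("<ordered_probit_fit> n =", x$n, " logLik =",
      format(x$loglik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  coefs <- data.frame(estimate = c(x$beta, x$eta),
                      se = c(x$se_beta, x$se_eta),
                      row.names = c(names(x$beta),
                                    paste0("eta", seq_along(x$eta))))
  print(round(coefs, 4))
  invisible(x)
}

#' Significance stars
#'
#' Conventional significance flags: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `.` p < 0.1, empty otherwise.
#'
#' @param p p-values in \[0, 1\].
#' @return Character vector of flags.
#' @export
stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cut_lab <- c("***", "**", "*", ".", "")
  cut_lab[findInterval(p, c(-1, 0.001, 0.01, 0.05, 0.1)) ]
}

#' Marginal effect of a covariate category on one outcome
#'
#' Average discrete-change marginal effect: over the estimation sample, the
#' covariate's encoded columns are switched from the Daly average (all
#' zeros, the "average citizen") to the named category's encoding, and the
#' change in `P(y = outcome)` is averaged and reported in percentage points.
#' Standard errors by the delta method over `c(beta, eta)`; two-sided
#' z-test p-values.
#'
#' @param fit an `"ordered_probit_fit"` estimated on a `"daly_design"`.
#' @param covariate,category the switch to evaluate.
#' @param outcome outcome index (1 = most sedentary quintile, the default).
#' @return One-row data.frame: `covariate`, `category`, `effect_pp`, `se_pp`,
#'   `p_value`, `stars`.
#' @export
marginal_effect_outcome1 <- function(fit, covariate, category, outcome = 1L) {
  stopifnot(inherits(fit, "ordered_probit_fit"))
  if (is.null(fit$design)) stop("fit carries no Daly design", call. = FALSE)
  X <- fit$design$X
  map <- fit$design$map
  cols <- which(map$covariate == covariate)
  if (!length(cols)) stop("unknown covariate '", covariate, "'", call. = FALSE)
  enc <- .daly_row(fit$design$spec, covariate, category)

  Xc <- X; Xc[, cols] <- matrix(enc, nrow(X), length(cols), byrow = TRUE)
  X0 <- X; X0[, cols] <- 0
  beta <- fit$beta; eta <- fit$eta
  J <- length(eta) + 1L
  j <- as.integer(outcome)
  stopifnot(j >= 1L, j <= J)

  zb_c <- drop(Xc %*% beta); zb_0 <- drop(X0 %*% beta)
  hi <- function(zb) if (j == J) rep(Inf, length(zb)) else eta[j] - zb
  lo <- function(zb) if (j == 1L) rep(-Inf, length(zb)) else eta[j - 1L] - zb
  Pj <- function(zb) stats::pnorm(hi(zb)) - stats::pnorm(lo(zb))
  eff <- mean(Pj(zb_c) - Pj(zb_0))

  # delta-method gradient wrt c(beta, eta)
  dphi <- function(z) ifelse(is.finite(z), stats::dnorm(z), 0)
  phi_hi_c <- dphi(hi(zb_c)); phi_lo_c <- dphi(lo(zb_c))
  phi_hi_0 <- dphi(hi(zb_0)); phi_lo_0 <- dphi(lo(zb_0))
  # d/dbeta_m: -(phi_hi - phi_lo) * x_m, averaged, difference c minus 0
  w_c <- phi_hi_c - phi_lo_c
  w_0 <- phi_hi_0 - phi_lo_0
  g_beta <- (colMeans(-w_c * Xc) - colMeans(-w_0 * X0))
  g_eta <- numeric(J - 1L)
  if (j <= J - 1L) g_eta[j] <- mean(phi_hi_c - phi_hi_0)
  if (j >= 2L) g_eta[j - 1L] <- g_eta[j - 1L] - mean(phi_lo_c - phi_lo_0)
  grad <- c(g_beta, g_eta)
  se <- sqrt(pmax(drop(t(grad) %*% fit$vcov %*% grad), 0))
  z <- if (se > 0) eff / se else 0
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(covariate = covariate, category = category,
             effect_pp = 100 * eff, se_pp = 100 * se,
             p_value = p, stars = stars(p),
             stringsAsFactors = FALSE)
}

#' Marginal-effects table for the most-sedentary outcome
#'
#' Evaluates [marginal_effect_outcome1()] for every category of every
#' covariate in the fitted Daly design and labels each row a driver
#' (positive effect on the probability of the most-sedentary quintile) or a
#' barrier (negative effect), sorted by magnitude.
#'
#' @param fit an `"ordered_probit_fit"` estimated on a `"daly_design"`.
#' @param outcome outcome index, default 1.
#' @return data.frame with one row per (covariate, category) plus a `role`
#'   column (`"driver"`/`"barrier"`).
#' @export
marginal_effects_table <- function(fit, outcome = 1L) {
  stopifnot(inherits(fit, "ordered_probit_fit"))
  spec <- fit$design$spec
  rows <- list()
  for (cv in names(spec)) {
    for (cat in spec[[cv]]$categories) {
      rows[[paste(cv, cat)]] <- marginal_effect_outcome1(fit, cv, cat,
                                                         outcome = outcome)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$role <- ifelse(out$effect_pp >= 0, "driver", "barrier")
  out[order(-abs(out$effect_pp)), ]
}
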