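# Independent brute-force oracles, written with plain loops against the
# shipped lookup table only -- no shared code with the package internals.

oracle_tfn_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab))
      tab <<- read.csv(system.file("extdata", "tfn_scales.csv",
                                   package = "pasindex"))
    tab
  }
})

# defuzzified (centroid) value of one ordinal code on one scale
oracle_defuzz <- function(scale_id, point) {
  tab <- oracle_tfn_lookup()
  r <- tab[tab$scale_id == scale_id & tab$point == point, ]
  (r$lower + r$mode + r$upper) / 3
}

# brute-force individual PASI for a code matrix (rows = respondents,
# columns = the nine items in standard order), individual-mode ideals
oracle_pasi <- function(codes) {
  scales <- c("monthly6", "monthly6", "weekly8", "daily6", "weekly8",
              "daily6", "weekly8", "daily6", "sitting10")
  n <- nrow(codes); p <- ncol(codes)
  V <- matrix(0, n, p)
  for (i in seq_len(n))
    for (j in seq_len(p))
      V[i, j] <- oracle_defuzz(scales[j], codes[i, j])
  a_plus <- apply(V, 2, max)
  a_minus <- apply(V, 2, min)
  pasi <- numeric(n)
  for (i in seq_len(n)) {
    dp <- 0; dm <- 0
    for (j in seq_len(p)) {
      dp <- dp + (V[i, j] - a_plus[j])^2
      dm <- dm + (V[i, j] - a_minus[j])^2
    }
    dp <- sqrt(dp); dm <- sqrt(dm)
    pasi[i] <- if (dp + dm > 0) dm / (dp + dm) else 0.5
  }
  pasi
}

# finite recomputation of the discrete-change marginal effect on P(y = 1):
# plain pnorm arithmetic over the rows, independent of the package routine
oracle_marginal_effect1 <- function(beta, eta1, X, cols, enc) {
  Xc <- X; Xc[, cols] <- matrix(enc, nrow(X), length(cols), byrow = TRUE)
  X0 <- X; X0[, cols] <- 0
  eff <- 0
  for (i in seq_len(nrow(X))) {
    eff <- eff + pnorm(eta1 - sum(Xc[i, ] * beta)) -
      pnorm(eta1 - sum(X0[i, ] * beta))
  }
  100 * eff / nrow(X)
}

# random code matrix over the nine items (all codes within scale ranges)
random_codes <- function(n) {
  npts <- c(6, 6, 8, 6, 8, 6, 8, 6, 10)
  vapply(npts, function(k) sample.int(k, n, replace = TRUE),
         integer(n))
}

# respondent data.frame from a code matrix, plus a throwaway covariate
codes_to_records <- function(codes) {
  df <- as.data.frame(codes)
  names(df) <- paste0("QB", 1:9)
  df$respondent_id <- seq_len(nrow(df))
  df$group <- rep_len(c("g1", "g2"), nrow(df))
  df
}

# 20-respondent fixture for the monotonicity suite: contains an all-minimum
# and an all-maximum respondent, so individual-mode ideals sit at the scale
# endpoints and every raised code stays inside [A-, A+]
monotonicity_fixture <- function(seed = 424) {
  set.seed(seed)
  npts <- c(6, 6, 8, 6, 8, 6, 8, 6, 10)
  codes <- random_codes(18)
  codes <- rbind(rep(1L, 9), npts, codes)
  storage.mode(codes) <- "integer"
  codes
}
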