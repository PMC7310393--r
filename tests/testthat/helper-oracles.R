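# Shared test oracles and fixture builders. Everything here is independent
# of the code paths it checks: the likelihood works record-wise on a dense
# phenotypic covariance matrix, and pedigrees are generated directly.

# random pedigree with n animals over a few generations; parents always
# have lower index, some unknown
random_test_pedigree <- function(n, p_known = 0.8, seed = 1) {
  set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  ids <- paste0("a", seq_len(n))
  n_founder <- max(3, round(n * 0.2))
  for (i in (n_founder + 1):n) {
    if (runif(1) < p_known) sire[i] <- ids[sample.int(i - 1, 1)]
    if (runif(1) < p_known) {
      d <- sample.int(i - 1, 1)
      if (ids[d] != sire[i] %||% "") dam[i] <- ids[d]
    }
  }
  as_pedigree(tibble::tibble(animal = ids, sire = sire, dam = dam))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# dense restricted log-likelihood of the maternal-effects model, built
# record-wise from the tabular relationship matrix
reml_loglik_oracle <- function(phen, ped, design, vc) {
  A <- relationship_matrix(ped)
  P <- design$P
  a_i <- match(phen$animal, ped$animal)
  dam <- if ("dam" %in% names(phen)) as.character(phen$dam) else ped$dam[a_i]
  d_i <- match(dam, ped$animal)
  p_i <- match(phen$population, design$populations)
  Aaug <- rbind(cbind(A, 0), 0)
  miss <- nrow(Aaug)
  d_i2 <- ifelse(is.na(d_i), miss, d_i)
  G <- vc$genetic
  Gum <- G[p_i, P + p_i, drop = FALSE]
  V <- Aaug[a_i, a_i] * G[p_i, p_i, drop = FALSE] +
    Aaug[a_i, d_i2] * Gum +
    Aaug[d_i2, a_i] * t(Gum) +
    Aaug[d_i2, d_i2] * G[P + p_i, P + p_i, drop = FALSE]
  pe_v <- vc$pe[design$populations][p_i]
  pe_v[is.na(pe_v) | is.na(d_i)] <- 0
  same_dam <- outer(d_i2, d_i2, "==") & outer(p_i, p_i, "==")
  V <- V + same_dam * outer(sqrt(pe_v), sqrt(pe_v))
  if (any(!is.na(vc$extra))) {
    for (p in names(design$extra_levels)) {
      col <- design$specs[[p]]$extra_random
      lev <- as.character(phen[[col]])
      samr <- outer(lev, lev, "==") & outer(phen$population == p,
                                            phen$population == p, "&")
      V <- V + samr * vc$extra[p]
    }
  }
  diag(V) <- diag(V) + vc$resid[design$populations][p_i]
  em <- design$effect_map
  X <- as.matrix(design$W[, em$column[em$type == "fixed"], drop = FALSE])
  cV <- chol(V)
  logdetV <- 2 * sum(log(diag(cV)))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), design$y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  cX <- chol(XtViX)
  logdetX <- 2 * sum(log(diag(cX)))
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Vi_y)))
  yPy <- sum(design$y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  -0.5 * (logdetV + logdetX + yPy)
}

# small multi-population dataset for model-level tests
small_dataset <- function(n_records = 150, populations = c("A", "B"),
                          shares = NULL, herds = NULL, f = 0.5, seed = 1,
                          n_years = 4, dam_career = 4, n_intl = 10,
                          vc = NULL) {
  P <- length(populations)
  if (is.null(shares)) shares <- rep(1 / P, P)
  if (is.null(herds)) herds <- rep(3, P)
  pops <- tibble::tibble(name = populations, share = shares, n_herds = herds,
                         has_pe = TRUE, mean = seq(250, by = -10,
                                                   length.out = P))
  if (is.null(vc)) {
    vc <- vc_from_correlations(populations, 120, 60, 0.8, 0.7, -0.2, 0,
                               pe = 40, resid = 350)
  }
  cfg <- simulation_config(pops, n_records = n_records, vc_true = vc,
                           n_years = n_years, international_sire_fraction = f,
                           n_international_sires = n_intl,
                           dam_career = dam_career)
  dat <- simulate_dataset(cfg, seed = seed)
  dat$vc_true <- vc
  dat$cfg <- cfg
  dat
}

# flatten helpers reused across tests
vc_get <- function(vc, a, b) vc$genetic[a, b]
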