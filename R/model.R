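#' National model specification for one population
#'
#' The international model fits, for each population, the effects of that
#' population's national evaluation: fixed effects (always including an
#' overall mean), an optional extra random environmental effect, and an
#' optional maternal permanent environmental effect.
#'
#' @param population Population identifier.
#' @param fixed Character vector of fixed-effect factor columns in the
#'   phenotype table (the intercept is always added; identifiability by
#'   reference-level constraints).
#' @param extra_random Column name of an extra random environmental effect
#'   (e.g. herd-year), or `NULL`.
#' @param has_pe Whether a maternal permanent environmental effect is
#'   fitted (attached to the record's dam).
#' @return A `national_model_spec` list.
#' @export
national_model_spec <- function(population, fixed = "contemporary_group",
                                extra_random = NULL, has_pe = TRUE) {
  structure(
    list(population = population, fixed = fixed,
         extra_random = extra_random, has_pe = has_pe),
    class = "national_model_spec"
  )
}

#' Default model specifications for a set of populations
#'
#' @param populations Character vector of populations.
#' @param fixed Fixed-effect columns used for every population.
#' @param pe_populations Populations with a maternal permanent
#'   environmental effect (default: all).
#' @param extra_random Named character vector mapping population to an
#'   extra random-effect column (populations not named get none).
#' @return A named list of [national_model_spec()] objects.
#' @export
default_model_specs <- function(populations, fixed = "contemporary_group",
                                pe_populations = populations,
                                extra_random = NULL) {
  specs <- lapply(populations, function(p) {
    national_model_spec(
      p, fixed = fixed,
      extra_random = if (!is.null(extra_random) && p %in% names(extra_random))
        extra_random[[p]] else NULL,
      has_pe = p %in% pe_populations
    )
  })
  setNames(specs, populations)
}

#' Variance components of the multi-trait maternal-effects model
#'
#' The genetic block is a `2 * n_pop` square covariance matrix over the
#' direct effects of every population followed by the maternal effects of
#' every population; its Kronecker product with the numerator relationship
#' matrix is the genetic covariance of the model. Maternal permanent
#' environmental and extra random environmental effects are uncorrelated
#' across populations, and residuals are population specific.
#'
#' @param genetic Symmetric `2P x 2P` matrix, ordered
#'   `(direct_1..direct_P, maternal_1..maternal_P)`.
#' @param pe Named per-population maternal permanent environmental
#'   variances (`NA` for populations without the effect).
#' @param resid Named per-population residual variances.
#' @param populations Character vector of populations (row order of the
#'   genetic blocks).
#' @param extra Named per-population extra random environmental variances
#'   (`NA` for populations without the effect).
#' @return A `variance_components` object.
#' @export
variance_components <- function(genetic, pe, resid, populations,
                                extra = NULL) {
  P <- length(populations)
  stopifnot(nrow(genetic) == 2 * P, ncol(genetic) == 2 * P)
  if (max(abs(genetic - t(genetic))) > 1e-8 * max(1, max(abs(genetic)))) {
    abort("genetic matrix must be symmetric")
  }
  genetic <- (genetic + t(genetic)) / 2
  labs <- c(paste0("direct_", populations), paste0("maternal_", populations))
  dimnames(genetic) <- list(labs, labs)
  pe <- .named_over(pe, populations)
  resid <- .named_over(resid, populations)
  if (any(is.na(resid)) || any(resid <= 0)) abort("residual variances must be positive")
  if (is.null(extra)) extra <- setNames(rep(NA_real_, P), populations)
  extra <- .named_over(extra, populations)
  structure(
    list(genetic = genetic, pe = pe, extra = extra, resid = resid,
         populations = populations),
    class = "variance_components"
  )
}

.named_over <- function(x, populations) {
  if (is.null(names(x))) {
    stopifnot(length(x) %in% c(1, length(populations)))
    x <- setNames(rep_len(as.numeric(x), length(populations)), populations)
  }
  missing <- setdiff(populations, names(x))
  if (length(missing) > 0) {
    x <- c(x, setNames(rep(NA_real_, length(missing)), missing))
  }
  x[populations]
}

#' Build a variance-components object from correlations
#'
#' Convenience constructor: per-population direct and maternal variances
#' plus constant across-country correlations for each block.
#'
#' @param populations Character vector of populations.
#' @param direct_var,maternal_var Per-population genetic variances
#'   (recycled).
#' @param rg_direct,rg_maternal Across-country correlation of direct
#'   (resp. maternal) effects.
#' @param r_dm_within,r_dm_between Direct-maternal correlation within and
#'   between countries.
#' @param pe,resid,extra As in [variance_components()].
#' @export
vc_from_correlations <- function(populations, direct_var, maternal_var,
                                 rg_direct = 0.8, rg_maternal = 0.7,
                                 r_dm_within = -0.2, r_dm_between = 0,
                                 pe = NA_real_, resid = 1, extra = NULL) {
  P <- length(populations)
  sdu <- sqrt(rep_len(direct_var, P))
  sdm <- sqrt(rep_len(maternal_var, P))
  R <- matrix(0, 2 * P, 2 * P)
  R[1:P, 1:P] <- rg_direct
  R[P + 1:P, P + 1:P] <- rg_maternal
  R[1:P, P + 1:P] <- r_dm_between
  R[P + 1:P, 1:P] <- r_dm_between
  for (i in seq_len(P)) R[i, P + i] <- R[P + i, i] <- r_dm_within
  diag(R) <- 1
  s <- c(sdu, sdm)
  G <- R * tcrossprod(s)
  variance_components(G, pe = pe, resid = resid, populations = populations,
                      extra = extra)
}

#' @export
print.variance_components <- function(x, ...) {
  P <- length(x$populations)
  cat("Variance components for", P, "populations\n")
  cat(" direct variances:  ",
      paste(signif(diag(x$genetic)[1:P], 4), collapse = " "), "\n")
  cat(" maternal variances:",
      paste(signif(diag(x$genetic)[P + 1:P], 4), collapse = " "), "\n")
  cat(" residual variances:", paste(signif(x$resid, 4), collapse = " "), "\n")
  invisible(x)
}

#' Build design structures for the multi-trait animal model
#'
#' Constructs the sparse incidence of every effect: per-population fixed
#' effects (reference-level constrained factors), extra random and
#' maternal permanent environmental effects, and the genetic effects.
#' Direct and maternal genetic effects span the whole pedigree for every
#' population, so covariances propagate through relatives; equations are
#' ordered fixed, extra, pe, then genetic effects animal-major with the
#' `2P` within-animal block contiguous.
#'
#' @param phen Phenotype tibble (`animal`, `population`, `value`, the
#'   fixed-effect columns, `dam` for maternal/pe incidence).
#' @param ped Pedigree containing every phenotyped animal and every
#'   recorded dam.
#' @param specs List of [national_model_spec()], one per population.
#' @return An `amaci_design` object.
#' @export
build_design <- function(phen, ped, specs) {
  .check_phen_in_ped(phen, ped)
  populations <- names(specs)
  if (is.null(populations)) populations <- vapply(specs, `[[`, "", "population")
  unknown <- setdiff(unique(phen$population), populations)
  if (length(unknown) > 0) {
    abort(paste0("no model spec for populations: ", paste(unknown, collapse = ", ")))
  }
  P <- length(populations)
  n_rec <- nrow(phen)
  n_anim <- nrow(ped)
  dam <- if ("dam" %in% names(phen)) as.character(phen$dam) else
    ped$dam[match(phen$animal, ped$animal)]
  dam[!is.na(dam) & (dam == "" | dam == "0")] <- NA_character_
  bad_dam <- setdiff(unique(dam[!is.na(dam)]), ped$animal)
  if (length(bad_dam) > 0) {
    abort(paste0("record dams absent from pedigree: ",
                 paste(head(bad_dam, 10), collapse = ", ")))
  }

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  map <- list()
  offset <- 0L

  # fixed effects, one block per population
  for (p in populations) {
    rows <- which(phen$population == p)
    sub <- phen[rows, , drop = FALSE]
    fx <- specs[[p]]$fixed
    # drop factors with a single observed level (no contrast estimable)
    fx <- fx[vapply(fx, function(cc) {
      cc %in% names(sub) && dplyr::n_distinct(sub[[cc]]) > 1
    }, logical(1))]
    form <- if (length(fx) == 0) ~1 else
      stats::reformulate(paste0("factor(", fx, ")"))
    X <- Matrix::sparse.model.matrix(form, data = sub)
    Xt <- as(X, "TsparseMatrix")
    trip_i <- c(trip_i, list(rows[Xt@i + 1L]))
    trip_j <- c(trip_j, list(offset + Xt@j + 1L))
    trip_x <- c(trip_x, list(Xt@x))
    map[[length(map) + 1]] <- tibble(
      column = offset + seq_len(ncol(X)), type = "fixed",
      population = p, level = colnames(X)
    )
    offset <- offset + ncol(X)
  }

  # extra random environmental effects
  extra_levels <- list()
  for (p in populations) {
    col <- specs[[p]]$extra_random
    if (is.null(col)) next
    if (!col %in% names(phen)) {
      abort(paste0("extra random column '", col, "' missing for ", p))
    }
    rows <- which(phen$population == p & !is.na(phen[[col]]))
    lev <- sort(unique(as.character(phen[[col]][rows])))
    if (length(lev) == 0) next
    extra_levels[[p]] <- lev
    j <- match(as.character(phen[[col]][rows]), lev)
    trip_i <- c(trip_i, list(rows))
    trip_j <- c(trip_j, list(offset + j))
    trip_x <- c(trip_x, list(rep(1, length(rows))))
    map[[length(map) + 1]] <- tibble(
      column = offset + seq_along(lev), type = "extra", population = p,
      level = lev
    )
    offset <- offset + length(lev)
  }

  # maternal permanent environmental effects (dams with records, per pop)
  pe_levels <- list()
  for (p in populations) {
    if (!isTRUE(specs[[p]]$has_pe)) next
    rows <- which(phen$population == p & !is.na(dam))
    if (length(rows) == 0) next
    lev <- sort(unique(dam[rows]))
    pe_levels[[p]] <- lev
    j <- match(dam[rows], lev)
    trip_i <- c(trip_i, list(rows))
    trip_j <- c(trip_j, list(offset + j))
    trip_x <- c(trip_x, list(rep(1, length(rows))))
    map[[length(map) + 1]] <- tibble(
      column = offset + seq_along(lev), type = "pe", population = p,
      level = lev
    )
    offset <- offset + length(lev)
  }

  # genetic effects: animal-major, within-animal order (u_1..u_P, m_1..m_P)
  g0 <- offset
  anim_idx <- match(phen$animal, ped$animal)
  pop_idx <- match(phen$population, populations)
  u_col <- g0 + (anim_idx - 1L) * 2L * P + pop_idx
  trip_i <- c(trip_i, list(seq_len(n_rec)))
  trip_j <- c(trip_j, list(u_col))
  trip_x <- c(trip_x, list(rep(1, n_rec)))
  has_dam <- !is.na(dam)
  dam_idx <- match(dam[has_dam], ped$animal)
  m_col <- g0 + (dam_idx - 1L) * 2L * P + P + pop_idx[has_dam]
  trip_i <- c(trip_i, list(which(has_dam)))
  trip_j <- c(trip_j, list(m_col))
  trip_x <- c(trip_x, list(rep(1, sum(has_dam))))
  n_eff <- g0 + 2L * P * n_anim

  W <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n_rec, n_eff)
  )
  effect_map <- bind_rows(map)

  structure(
    list(
      W = W, y = as.numeric(phen$value), n_records = n_rec,
      rec_pop = pop_idx, populations = populations, P = P,
      n_animals = n_anim, animal_ids = ped$animal,
      genetic_offset = g0, n_equations = n_eff,
      effect_map = effect_map,
      pe_levels = pe_levels, extra_levels = extra_levels,
      specs = specs
    ),
    class = "amaci_design"
  )
}

#' @export
print.amaci_design <- function(x, ...) {
  cat("Multi-trait animal model design:", x$n_records, "records,",
      x$P, "populations,", x$n_animals, "pedigree animals,",
      x$n_equations, "equations\n")
  invisible(x)
}

# per-effect-column diagonal prior additions and record weights
.mme_parts <- function(design, vc) {
  w <- 1 / vc$resid[design$populations[design$rec_pop]]
  diag_add <- numeric(design$genetic_offset)
  em <- design$effect_map
  for (p in names(design$extra_levels)) {
    v <- vc$extra[p]
    if (is.na(v) || v <= 0) abort(paste0("missing extra random variance for ", p))
    diag_add[em$column[em$type == "extra" & em$population == p]] <- 1 / v
  }
  for (p in names(design$pe_levels)) {
    v <- vc$pe[p]
    if (is.na(v) || v <= 0) abort(paste0("missing pe variance for ", p))
    diag_add[em$column[em$type == "pe" & em$population == p]] <- 1 / v
  }
  list(w = unname(w), diag_add = diag_add)
}

#' Assemble the mixed-model equations
#'
#' Standard mixed-model equations with records weighted by the inverse of
#' their population's residual variance, diagonal prior additions for the
#' permanent environmental and extra random effects, and the Kronecker
#' product of the inverse genetic covariance with the inverse relationship
#' matrix added to the genetic block.
#'
#' @param design An [build_design()] object.
#' @param A_inv A [a_inverse()] object over the same pedigree.
#' @param vc A [variance_components()] object.
#' @param explicit If `TRUE`, the Kronecker genetic block is materialized
#'   and the full sparse coefficient matrix is stored in `lhs` (needed
#'   for dense reference computations). By default the genetic block is
#'   kept in factored form and applied on the fly during iteration, which
#'   is faster and lighter.
#' @return An `mme_system` list with `rhs`, the data part `Adata`, the
#'   factored genetic block (`Ainv`, `Ginv`), the preconditioner, and
#'   (when `explicit = TRUE`) the full `lhs`.
#' @export
assemble_mme <- function(design, A_inv, vc, explicit = FALSE) {
  stopifnot(inherits(design, "amaci_design"),
            inherits(A_inv, "relationship_inverse"),
            inherits(vc, "variance_components"))
  if (length(A_inv$ids) != design$n_animals) {
    abort("relationship inverse does not match the design's pedigree")
  }
  Ginv <- tryCatch(chol2inv(chol(vc$genetic)), error = function(e) {
    abort(paste0("genetic covariance matrix is singular or not positive ",
                 "definite; add a small ridge or restart from different values"))
  })
  Ginv <- (Ginv + t(Ginv)) / 2
  parts <- .mme_parts(design, vc)
  Wsc <- design$W * sqrt(parts$w)
  Adata <- Matrix::crossprod(Wsc)
  rhs <- as.numeric(Matrix::crossprod(design$W, parts$w * design$y))

  n_eff <- design$n_equations
  if (any(parts$diag_add > 0)) {
    Adata <- Adata + Matrix::Diagonal(
      n_eff, c(parts$diag_add, numeric(n_eff - length(parts$diag_add)))
    )
  }
  Adata <- as(as(Matrix::forceSymmetric(Adata), "generalMatrix"),
              "CsparseMatrix")
  g0 <- design$genetic_offset

  # per-animal block preconditioner: the within-animal 2P x 2P diagonal
  # block is Ainv[a,a] * Ginv plus data contributions on its diagonal
  bs <- 2L * design$P
  n_anim <- design$n_animals
  ad <- Matrix::diag(A_inv$matrix)
  data_diag <- Matrix::diag(Adata)
  full_gen_diag <- data_diag[(g0 + 1):n_eff] + as.vector(diag(Ginv) %o% ad)
  blocks <- as.vector(Ginv) %o% ad
  dpos <- (seq_len(bs) - 1L) * bs + seq_len(bs)
  blocks[dpos, ] <- matrix(full_gen_diag, nrow = bs)
  binv <- matrix(0, bs * bs, n_anim)
  for (a in seq_len(n_anim)) {
    binv[, a] <- as.vector(solve(matrix(blocks[, a], bs, bs)))
  }
  d0 <- data_diag[seq_len(g0)]
  diag_pre <- ifelse(d0 > 0, 1 / d0, 1)

  lhs <- NULL
  if (explicit) {
    kron <- Matrix::kronecker(A_inv$matrix, Ginv)
    kt <- as(kron, "TsparseMatrix")
    gad <- Matrix::sparseMatrix(i = kt@i + 1L + g0, j = kt@j + 1L + g0,
                                x = kt@x, dims = c(n_eff, n_eff))
    lhs <- as(as(Matrix::forceSymmetric(Adata + gad), "generalMatrix"),
              "CsparseMatrix")
  }
  structure(
    list(lhs = lhs, rhs = rhs, n_equations = n_eff,
         genetic_offset = g0, P = design$P,
         Adata = Adata, Ainv = A_inv$matrix, Ginv = Ginv,
         precond = list(g0 = g0, bs = bs, binv = binv,
                        diag_pre = diag_pre)),
    class = "mme_system"
  )
}

#' Solve mixed-model equations by preconditioned conjugate gradient
#'
#' Conjugate gradient with a block-Jacobi preconditioner: the dense
#' within-animal genetic block for the genetic equations, the plain
#' diagonal elsewhere. The convergence criterion is
#' the square root of the relative difference between the solutions of
#' consecutive iterations; iteration stops when it drops below `tol` or
#' at `max_iter` (flagged as unconverged).
#'
#' @param sys An [assemble_mme()] system (or any list with sparse `lhs`
#'   and numeric `rhs`).
#' @param tol Convergence criterion threshold (default `1e-5`).
#' @param max_iter Iteration cap (default 1000).
#' @param x0 Optional starting solution (warm start).
#' @return A list with `solution`, `iterations`, `criterion`, `converged`.
#' @export
solve_pcg <- function(sys, tol = 1e-5, max_iter = 1000, x0 = NULL) {
  rhs <- sys$rhs
  if (is.null(x0)) x0 <- numeric(length(rhs))
  res <- if (!is.null(sys$Adata)) {
    pcg_kron_cpp(sys$Adata, sys$Ainv, sys$Ginv, sys$precond$g0, rhs, x0,
                 tol, as.integer(max_iter), sys$precond$diag_pre,
                 sys$precond$binv)
  } else if (!is.null(sys$precond)) {
    pcg_block_cpp(sys$lhs, rhs, x0, tol, as.integer(max_iter),
                  sys$precond$g0, sys$precond$bs, sys$precond$binv)
  } else {
    pcg_cpp(sys$lhs, rhs, x0, tol, as.integer(max_iter))
  }
  if (!isTRUE(res$finite)) {
    abort(paste0("non-finite values in PCG at iteration ", res$iterations,
                 "; the system may be singular or badly scaled"))
  }
  res$solution <- as.numeric(res$solution)
  res[c("solution", "iterations", "criterion", "converged")]
}

# eigen-based factor of a PSD matrix (tolerates zero eigenvalues)
.psd_factor <- function(G, tol = 1e-8) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1)) {
    abort("genetic covariance matrix is not positive semi-definite")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(G))
}

#' Simulate phenotypes under the fitted model
#'
#' Draws genetic effects with covariance `G (x) A` by pedigree recursion
#' (parent average plus Mendelian sampling with inbreeding-adjusted
#' variance; the within-animal `2P`-dimensional covariance is factorized
#' once), permanent environmental, extra random and residual effects
#' independently, and assembles simulated records over the same design.
#' Fixed effects are zero by default — BLUP solutions of simulated data
#' are invariant to them, which is the Monte Carlo convention used in
#' the EM algorithm.
#'
#' @param design An [build_design()] object.
#' @param ped The pedigree the design was built on.
#' @param vc True [variance_components()] (genetic block must be positive
#'   semi-definite).
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @param fixed_values Optional coefficients for the fixed-effect columns
#'   (default all zero).
#' @return A list with the simulated record vector `y`, the full true
#'   effect vector `effects`, and the true genetic effect matrix
#'   `genetic` (animals by `2P` effects).
#' @export
simulate_from_model <- function(design, ped, vc, seed = NULL,
                                fixed_values = NULL) {
  run <- function() {
    P <- design$P
    n <- design$n_animals
    L <- .psd_factor(vc$genetic)
    dmf <- .ped_inbreeding(ped)$d
    z <- matrix(rnorm(n * 2 * P), n, 2 * P) %*% t(L)
    g <- matrix(0, n, 2 * P)
    sidx <- ped$sire_idx; didx <- ped$dam_idx
    sqd <- sqrt(dmf)
    for (i in seq_len(n)) {
      pa <- 0
      if (!is.na(sidx[i])) pa <- pa + 0.5 * g[sidx[i], ]
      if (!is.na(didx[i])) pa <- pa + 0.5 * g[didx[i], ]
      g[i, ] <- pa + sqd[i] * z[i, ]
    }
    theta <- numeric(design$n_equations)
    em <- design$effect_map
    if (!is.null(fixed_values)) {
      fcol <- em$column[em$type == "fixed"]
      stopifnot(length(fixed_values) == length(fcol))
      theta[fcol] <- fixed_values
    }
    for (p in names(design$extra_levels)) {
      cols <- em$column[em$type == "extra" & em$population == p]
      theta[cols] <- rnorm(length(cols), 0, sqrt(vc$extra[p]))
    }
    for (p in names(design$pe_levels)) {
      cols <- em$column[em$type == "pe" & em$population == p]
      theta[cols] <- rnorm(length(cols), 0, sqrt(vc$pe[p]))
    }
    theta[(design$genetic_offset + 1):design$n_equations] <- as.vector(t(g))
    e <- rnorm(design$n_records, 0,
               sqrt(vc$resid[design$populations[design$rec_pop]]))
    y <- as.numeric(design$W %*% theta) + e
    list(y = y, effects = theta, genetic = g, residual = e)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
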