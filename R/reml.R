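#' Settings for Monte Carlo EM REML
#'
#' Defaults follow routine international-evaluation practice: at most 1000
#' PCG iterations per solve at a convergence criterion of `1e-5`, one
#' simulated dataset per REML round, and a variance-component convergence
#' criterion of `1e-9` on the standardized regression slope of the
#' estimates over the last `slope_window` rounds. The standard-error round
#' uses `se_n_sim` simulated datasets with no practical PCG iteration
#' limit.
#'
#' @param pcg_max_iter,pcg_tol PCG iteration cap and convergence
#'   criterion.
#' @param n_sim_per_round Simulated datasets per REML round.
#' @param vce_slope_tol Convergence threshold for the standardized slope.
#' @param slope_window Number of trailing rounds in the convergence
#'   regression (at least 2).
#' @param max_rounds Cap on REML rounds.
#' @param se_n_sim Simulated datasets in the standard-error round.
#' @param seed Master seed; every round and replicate draws from a named
#'   substream derived from it, so runs are fully reproducible.
#' @return A `reml_settings` list.
#' @export
reml_settings <- function(pcg_max_iter = 1000, pcg_tol = 1e-5,
                          n_sim_per_round = 1, vce_slope_tol = 1e-9,
                          slope_window = 100, max_rounds = 500,
                          se_n_sim = 500, seed = 1) {
  stopifnot(pcg_max_iter > 0, pcg_tol > 0, n_sim_per_round > 0,
            vce_slope_tol > 0, slope_window >= 2, max_rounds >= 0,
            se_n_sim > 0)
  structure(
    list(pcg_max_iter = pcg_max_iter, pcg_tol = pcg_tol,
         n_sim_per_round = n_sim_per_round, vce_slope_tol = vce_slope_tol,
         slope_window = slope_window, max_rounds = max_rounds,
         se_n_sim = se_n_sim, seed = seed),
    class = "reml_settings"
  )
}

# flatten a variance_components object to a named vector (trajectory rows)
.vc_flatten <- function(vc) {
  labs <- rownames(vc$genetic)
  out <- c()
  for (k in seq_along(labs)) {
    for (l in k:length(labs)) {
      out[paste0("g_", labs[k], ":", labs[l])] <- vc$genetic[k, l]
    }
  }
  for (p in names(vc$pe)) if (!is.na(vc$pe[p])) out[paste0("pe_", p)] <- vc$pe[p]
  for (p in names(vc$extra)) if (!is.na(vc$extra[p])) out[paste0("extra_", p)] <- vc$extra[p]
  for (p in names(vc$resid)) out[paste0("resid_", p)] <- vc$resid[p]
  out
}

# rebuild a variance_components object from a flattened named vector,
# using `template` for structure (populations, NA patterns)
.vc_unflatten <- function(vals, template) {
  labs <- rownames(template$genetic)
  G <- template$genetic
  for (k in seq_along(labs)) {
    for (l in k:length(labs)) {
      G[k, l] <- G[l, k] <- vals[paste0("g_", labs[k], ":", labs[l])]
    }
  }
  pe <- template$pe
  for (p in names(pe)) {
    if (!is.na(pe[p])) pe[p] <- vals[paste0("pe_", p)]
  }
  extra <- template$extra
  for (p in names(extra)) {
    if (!is.na(extra[p])) extra[p] <- vals[paste0("extra_", p)]
  }
  resid <- template$resid
  for (p in names(resid)) resid[p] <- vals[paste0("resid_", p)]
  variance_components(G, pe = pe, resid = resid,
                      populations = template$populations, extra = extra)
}

# genetic-effect matrix (animals x 2P) from a solution vector
.genetic_matrix <- function(solution, design) {
  g <- solution[(design$genetic_offset + 1):design$n_equations]
  matrix(g, nrow = design$n_animals, ncol = 2 * design$P, byrow = TRUE)
}

# per-population residual sums of squares of y - W theta
.resid_ss <- function(y, solution, design) {
  e <- y - as.numeric(design$W %*% solution)
  vapply(seq_len(design$P),
         function(p) sum(e[design$rec_pop == p]^2), numeric(1))
}

#' One Monte Carlo EM update of the variance components
#'
#' Each REML round solves the mixed-model equations for the real data and
#' for `n_sim_per_round` datasets simulated under the current values. The
#' update combines the real-data sums of squares of estimated effects
#' with the Monte Carlo prediction-error correction: for genetic block
#' entry (k, l), `(u_k' Ainv u_l (real BLUP) + mean_s(true*' Ainv true* -
#' blup*' Ainv blup*)) / q` with `q` the pedigree size; permanent
#' environmental and extra random variances analogously with the identity
#' metric and their level counts; residual variances from the real
#' residual sum of squares plus the simulated-residual correction over
#' the record count.
#'
#' @param real_solution Solution vector for the real data.
#' @param sim_batches List of simulated batches, each a list with `y`
#'   (simulated records), `effects` (true simulated effect vector) and
#'   `blup` (solution of the simulated system).
#' @param A_inv The [a_inverse()] object.
#' @param design The [build_design()] object.
#' @param vc Current [variance_components()] (carries structure/labels).
#' @return An updated, symmetric `variance_components` object (not yet
#'   projected to positive semi-definiteness).
#' @export
em_update <- function(real_solution, sim_batches, A_inv, design, vc) {
  if (length(real_solution) != design$n_equations) {
    abort("solution length does not match the design")
  }
  if (length(sim_batches) < 1) abort("need at least one simulated batch")
  q <- design$n_animals
  Ai <- A_inv$matrix
  quad <- function(sol) {
    U <- .genetic_matrix(sol, design)
    as.matrix(Matrix::crossprod(U, Ai %*% U))
  }
  S <- quad(real_solution)
  corr <- matrix(0, 2 * design$P, 2 * design$P)
  for (b in sim_batches) corr <- corr + quad(b$effects) - quad(b$blup)
  corr <- corr / length(sim_batches)
  G_new <- (S + corr) / q
  G_new <- (G_new + t(G_new)) / 2

  em <- design$effect_map
  upd_scalar <- function(type, p) {
    cols <- em$column[em$type == type & em$population == p]
    ss <- sum(real_solution[cols]^2)
    cc <- mean(vapply(sim_batches, function(b) {
      sum(b$effects[cols]^2) - sum(b$blup[cols]^2)
    }, numeric(1)))
    (ss + cc) / length(cols)
  }
  pe_new <- vc$pe
  for (p in names(design$pe_levels)) pe_new[p] <- upd_scalar("pe", p)
  extra_new <- vc$extra
  for (p in names(design$extra_levels)) extra_new[p] <- upd_scalar("extra", p)

  n_per_pop <- tabulate(design$rec_pop, design$P)
  ss_real <- .resid_ss(design$y, real_solution, design)
  ss_corr <- rowMeans(matrix(vapply(sim_batches, function(b) {
    sum_true <- vapply(seq_len(design$P), function(p) {
      sum(b$residual[design$rec_pop == p]^2)
    }, numeric(1))
    sum_true - .resid_ss(b$y, b$blup, design)
  }, numeric(design$P)), nrow = design$P))
  resid_new <- setNames((ss_real + ss_corr) / n_per_pop, design$populations)

  # guard: single-replicate Monte Carlo noise can push a scalar variance
  # below zero; floor at a negligible fraction of the phenotypic variance
  floor_v <- 1e-6 * max(stats::var(design$y), 1e-12, na.rm = TRUE)
  pe_new <- ifelse(is.na(pe_new), pe_new, pmax(pe_new, floor_v))
  extra_new <- ifelse(is.na(extra_new), extra_new, pmax(extra_new, floor_v))
  resid_new <- pmax(resid_new, floor_v)

  variance_components(G_new, pe = pe_new, resid = resid_new,
                      populations = design$populations, extra = extra_new)
}

#' Exact EM update (dense prediction-error trace)
#'
#' The analytic counterpart of [em_update()]: the Monte Carlo correction
#' is replaced by traces of prediction-error (co)variance blocks taken
#' from the dense inverse of the mixed-model coefficient matrix. Only
#' feasible for small systems; used as the oracle for the Monte Carlo
#' update and for likelihood-ascent checks.
#'
#' @param real_solution Solution vector for the real data.
#' @param sys The assembled [assemble_mme()] system.
#' @param A_inv,design,vc As in [em_update()].
#' @return An updated `variance_components` object.
#' @export
em_update_exact <- function(real_solution, sys, A_inv, design, vc) {
  C <- solve(as.matrix(sys$lhs))
  q <- design$n_animals
  P2 <- 2 * design$P
  Ai <- as.matrix(A_inv$matrix)
  g0 <- design$genetic_offset
  gcols <- function(k) g0 + (seq_len(design$n_animals) - 1L) * P2 + k
  U <- .genetic_matrix(real_solution, design)
  S <- crossprod(U, Ai %*% U)
  Tm <- matrix(0, P2, P2)
  for (k in seq_len(P2)) {
    for (l in k:P2) {
      Tm[k, l] <- Tm[l, k] <- sum(Ai * C[gcols(k), gcols(l)])
    }
  }
  G_new <- (S + Tm) / q
  em <- design$effect_map
  pe_new <- vc$pe
  for (p in names(design$pe_levels)) {
    cols <- em$column[em$type == "pe" & em$population == p]
    pe_new[p] <- (sum(real_solution[cols]^2) +
                    sum(diag(C)[cols])) / length(cols)
  }
  extra_new <- vc$extra
  for (p in names(design$extra_levels)) {
    cols <- em$column[em$type == "extra" & em$population == p]
    extra_new[p] <- (sum(real_solution[cols]^2) +
                       sum(diag(C)[cols])) / length(cols)
  }
  W <- as.matrix(design$W)
  tr_rec <- rowSums((W %*% C) * W)
  ss_real <- .resid_ss(design$y, real_solution, design)
  n_per_pop <- tabulate(design$rec_pop, design$P)
  resid_new <- setNames(vapply(seq_len(design$P), function(p) {
    (ss_real[p] + sum(tr_rec[design$rec_pop == p])) / n_per_pop[p]
  }, numeric(1)), design$populations)
  variance_components(as.matrix((G_new + t(G_new)) / 2), pe = pe_new,
                      resid = resid_new, populations = design$populations,
                      extra = extra_new)
}

# eigenvalue clipping to the nearest PSD matrix (guard inside iterations)
.project_psd <- function(G, rel_tol = 1e-8) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  floor_val <- rel_tol * max(abs(e$values), 1e-12)
  if (min(e$values) >= floor_val) return(list(G = G, projected = FALSE))
  vals <- pmax(e$values, floor_val)
  list(G = e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors),
       projected = TRUE)
}

#' Convergence check for variance-component estimation
#'
#' Fits, for every variance component, a least-squares regression of the
#' estimates on the round number over the last `slope_window` rounds, and
#' standardizes each slope by the component's window mean. Convergence is
#' declared when the largest absolute standardized slope is below
#' `vce_slope_tol`.
#'
#' @param trajectory A long tibble with columns `round`, `component`,
#'   `value` (as stored in a fit's `$trajectory`).
#' @param settings A [reml_settings()] object.
#' @return A list with `converged`, `worst_slope`, `enough_rounds` and a
#'   `slopes` tibble. A trajectory shorter than the window yields
#'   `enough_rounds = FALSE` rather than an error.
#' @export
check_vce_convergence <- function(trajectory, settings) {
  rounds <- sort(unique(trajectory$round))
  if (length(rounds) < settings$slope_window) {
    return(list(converged = FALSE, worst_slope = NA_real_,
                enough_rounds = FALSE, slopes = NULL))
  }
  win <- tail(rounds, settings$slope_window)
  slopes <- trajectory %>%
    filter(.data$round %in% win) %>%
    group_by(.data$component) %>%
    summarise(
      slope = {
        x <- .data$round - mean(.data$round)
        sum(x * .data$value) / sum(x^2)
      },
      window_mean = mean(.data$value),
      .groups = "drop"
    ) %>%
    mutate(std_slope = ifelse(abs(.data$window_mean) > 1e-12,
                              .data$slope / abs(.data$window_mean),
                              .data$slope))
  worst <- max(abs(slopes$std_slope))
  list(converged = worst < settings$vce_slope_tol, worst_slope = worst,
       enough_rounds = TRUE, slopes = slopes)
}

#' Estimate variance components by Monte Carlo EM REML
#'
#' Iterates REML rounds: solve the mixed-model equations for the real
#' data by PCG, simulate `n_sim_per_round` datasets under the current
#' variance components and solve them against the same coefficient
#' matrix, then apply the EM update combining real-data sums of squares
#' with the Monte Carlo prediction-error correction. Rounds continue
#' until the regression-slope convergence criterion or `max_rounds`. A
#' non-positive-semi-definite intermediate genetic matrix is projected to
#' the nearest PSD matrix by eigenvalue clipping (with a warning); the
#' final reported matrix is never bent.
#'
#' @param phen Phenotype tibble.
#' @param ped Pedigree.
#' @param specs List of [national_model_spec()] per population.
#' @param start_vc Starting [variance_components()].
#' @param settings A [reml_settings()] object.
#' @param method `"mc"` (Monte Carlo correction) or `"exact"` (dense
#'   prediction-error traces; small systems only).
#' @param report_window Number of trailing rounds averaged to form the
#'   reported estimates (default 1, i.e. the last round). With one
#'   simulated dataset per round the chain fluctuates around the EM path,
#'   and a trailing mean is a lower-noise read-out of where it has
#'   settled; the averaged matrix is checked for positive definiteness
#'   but never bent.
#' @param verbose Print per-round progress.
#' @return An `mcem_reml_fit` object: final `vc`, long `trajectory`
#'   tibble, PCG `diagnostics`, `converged` flag, `rounds_run`, the
#'   per-round seeds, and the design/relationship objects needed by
#'   [approximate_se()].
#' @export
run_mcem_reml <- function(phen, ped, specs, start_vc, settings = reml_settings(),
                          method = c("mc", "exact"), report_window = 1,
                          verbose = FALSE) {
  method <- match.arg(method)
  design <- build_design(phen, ped, specs)
  A_inv <- a_inverse(ped)
  vc <- start_vc
  traj <- list()
  diags <- list()
  n_sim <- settings$n_sim_per_round
  round_seeds <- .with_seed(settings$seed, {
    matrix(sample.int(.Machine$integer.max - 1, max(settings$max_rounds, 1) * max(n_sim, 1)),
           nrow = max(settings$max_rounds, 1))
  })
  x_real <- NULL
  x_sim <- NULL
  converged <- FALSE
  rounds_run <- 0
  projected_any <- FALSE

  if (settings$max_rounds > 0) {
    for (r in seq_len(settings$max_rounds)) {
      sys <- assemble_mme(design, A_inv, vc, explicit = (method == "exact"))
      sol <- solve_pcg(sys, tol = settings$pcg_tol,
                       max_iter = settings$pcg_max_iter, x0 = x_real)
      x_real <- sol$solution
      diags[[length(diags) + 1]] <- tibble(
        round = r, system = "real", iterations = sol$iterations,
        criterion = sol$criterion, converged = sol$converged
      )
      if (method == "exact") {
        vc_new <- em_update_exact(x_real, sys, A_inv, design, vc)
      } else {
        parts <- .mme_parts(design, vc)
        batches <- vector("list", n_sim)
        for (s in seq_len(n_sim)) {
          sim <- simulate_from_model(design, ped, vc, seed = round_seeds[r, s])
          sys_s <- sys
          sys_s$rhs <- as.numeric(Matrix::crossprod(design$W, parts$w * sim$y))
          bs <- solve_pcg(sys_s, tol = settings$pcg_tol,
                          max_iter = settings$pcg_max_iter, x0 = x_sim)
          x_sim <- bs$solution
          diags[[length(diags) + 1]] <- tibble(
            round = r, system = paste0("sim", s), iterations = bs$iterations,
            criterion = bs$criterion, converged = bs$converged
          )
          batches[[s]] <- list(y = sim$y, effects = sim$effects,
                               residual = sim$residual, blup = bs$solution)
        }
        vc_new <- em_update(x_real, batches, A_inv, design, vc)
      }
      pr <- .project_psd(vc_new$genetic)
      if (pr$projected) {
        projected_any <- TRUE
        vc_new <- variance_components(pr$G, pe = vc_new$pe,
                                      resid = vc_new$resid,
                                      populations = vc_new$populations,
                                      extra = vc_new$extra)
      }
      vc <- vc_new
      flat <- .vc_flatten(vc)
      traj[[r]] <- tibble(round = r, component = names(flat),
                          value = unname(flat))
      rounds_run <- r
      if (verbose) {
        message("round ", r, ": first components ",
                paste(signif(head(flat, 3), 4), collapse = " "))
      }
      if (r >= settings$slope_window) {
        chk <- check_vce_convergence(bind_rows(traj), settings)
        if (isTRUE(chk$converged)) { converged <- TRUE; break }
      }
    }
  }
  if (projected_any) {
    warn("an intermediate genetic matrix was projected to the nearest PSD matrix")
  }
  trajectory <- if (length(traj) > 0) bind_rows(traj) else
    tibble(round = integer(), component = character(), value = numeric())
  if (report_window > 1 && rounds_run > 0) {
    win <- max(1, rounds_run - report_window + 1):rounds_run
    avg <- trajectory %>%
      filter(.data$round %in% win) %>%
      group_by(.data$component) %>%
      summarise(value = mean(.data$value), .groups = "drop")
    vals <- setNames(avg$value, avg$component)
    vc <- .vc_unflatten(vals, vc)
  }
  structure(
    list(
      vc = vc, start_vc = start_vc,
      trajectory = trajectory,
      diagnostics = if (length(diags) > 0) bind_rows(diags) else NULL,
      converged = converged, rounds_run = rounds_run,
      settings = settings, method = method,
      design = design, A_inv = A_inv, pedigree = ped,
      populations = design$populations,
      round_seeds = round_seeds[seq_len(max(rounds_run, 1)), , drop = FALSE],
      real_solution = x_real
    ),
    class = "mcem_reml_fit"
  )
}

#' @export
print.mcem_reml_fit <- function(x, ...) {
  cat("Monte Carlo EM REML fit:", x$rounds_run, "rounds,",
      if (x$converged) "converged" else "round cap reached", "\n")
  print(x$vc)
  invisible(x)
}

# labelled parameter vector of a variance_components object (SE ordering)
.vc_param_info <- function(vc) {
  labs <- rownames(vc$genetic)
  P2 <- length(labs)
  rows <- list()
  for (k in seq_len(P2)) {
    for (l in k:P2) {
      rows[[length(rows) + 1]] <- tibble(
        param = paste0("g_", labs[k], ":", labs[l]),
        type = "genetic", k = k, l = l, population = NA_character_
      )
    }
  }
  for (p in names(vc$pe)) {
    if (!is.na(vc$pe[p])) {
      rows[[length(rows) + 1]] <- tibble(param = paste0("pe_", p), type = "pe",
                                         k = NA, l = NA, population = p)
    }
  }
  for (p in names(vc$extra)) {
    if (!is.na(vc$extra[p])) {
      rows[[length(rows) + 1]] <- tibble(param = paste0("extra_", p),
                                         type = "extra", k = NA, l = NA,
                                         population = p)
    }
  }
  for (p in names(vc$resid)) {
    rows[[length(rows) + 1]] <- tibble(param = paste0("resid_", p),
                                       type = "resid", k = NA, l = NA,
                                       population = p)
  }
  bind_rows(rows)
}

#' Monte Carlo approximate standard errors
#'
#' Runs one additional round at the final estimates with `se_n_sim`
#' simulated datasets (and an effectively unlimited PCG iteration count).
#' The restricted-likelihood information matrix is approximated by the
#' empirical covariance, over replicates, of the complete-data score
#' evaluated at the final estimates — the score is linear in each
#' replicate's conditional-expected sufficient statistics (BLUP quadratic
#' forms), whose shared prediction-error constant cancels in the
#' covariance. Its inverse is the sampling covariance of the variance
#' components; correlation standard errors follow by the delta method.
#'
#' @param fit A converged [run_mcem_reml()] fit.
#' @param se_n_sim Number of simulated replicates (default from the fit's
#'   settings).
#' @param seed Seed for the SE round (default: derived from the fit's
#'   master seed).
#' @return An `mcem_se` object: named `vc_se`, full `vc_cov`, the
#'   parameter `info` matrix, and the `rg_se` matrix of correlation
#'   standard errors.
#' @export
approximate_se <- function(fit, se_n_sim = NULL, seed = NULL) {
  stopifnot(inherits(fit, "mcem_reml_fit"))
  design <- fit$design
  A_inv <- fit$A_inv
  vc <- fit$vc
  settings <- fit$settings
  if (is.null(se_n_sim)) se_n_sim <- settings$se_n_sim
  if (is.null(seed)) seed <- settings$seed + 1000003L
  sys <- assemble_mme(design, A_inv, vc)
  parts <- .mme_parts(design, vc)
  Ginv <- chol2inv(chol(vc$genetic))
  q <- design$n_animals
  info_tab <- .vc_param_info(vc)
  n_par <- nrow(info_tab)
  P2 <- 2 * design$P
  em <- design$effect_map
  rep_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1, se_n_sim))

  scores <- matrix(NA_real_, se_n_sim, n_par,
                   dimnames = list(NULL, info_tab$param))
  x_warm <- NULL
  Ai <- A_inv$matrix
  for (s in seq_len(se_n_sim)) {
    sim <- simulate_from_model(design, fit$pedigree, vc, seed = rep_seeds[s])
    sys_s <- sys
    sys_s$rhs <- as.numeric(Matrix::crossprod(design$W, parts$w * sim$y))
    bs <- solve_pcg(sys_s, tol = settings$pcg_tol,
                    max_iter = 100000, x0 = x_warm)
    x_warm <- bs$solution
    U <- .genetic_matrix(bs$solution, design)
    S <- as.matrix(Matrix::crossprod(U, Ai %*% U))
    M <- Ginv %*% S %*% Ginv
    sc <- numeric(n_par)
    gi <- which(info_tab$type == "genetic")
    sc[gi] <- vapply(gi, function(j) {
      k <- info_tab$k[j]; l <- info_tab$l[j]
      if (k == l) 0.5 * M[k, k] else M[k, l]
    }, numeric(1))
    for (j in which(info_tab$type %in% c("pe", "extra"))) {
      p <- info_tab$population[j]
      cols <- em$column[em$type == info_tab$type[j] & em$population == p]
      v <- if (info_tab$type[j] == "pe") vc$pe[p] else vc$extra[p]
      sc[j] <- sum(bs$solution[cols]^2) / (2 * v^2)
    }
    ss <- .resid_ss(sim$y, bs$solution, design)
    for (j in which(info_tab$type == "resid")) {
      p <- info_tab$population[j]
      pi <- match(p, design$populations)
      sc[j] <- ss[pi] / (2 * vc$resid[p]^2)
    }
    scores[s, ] <- sc
  }
  info <- cov(scores)
  vc_cov <- tryCatch(solve(info), error = function(e) {
    warn("singular information matrix; using a pseudo-inverse")
    sv <- svd(info)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  vc_se <- setNames(sqrt(pmax(diag(vc_cov), 0)), info_tab$param)

  # delta-method SEs of the genetic correlations
  labs <- rownames(vc$genetic)
  gpar <- function(k, l) {
    kk <- min(k, l); ll <- max(k, l)
    which(info_tab$type == "genetic" & info_tab$k == kk & info_tab$l == ll)
  }
  rg_se <- matrix(0, P2, P2, dimnames = list(labs, labs))
  for (k in seq_len(P2)) {
    for (l in seq_len(P2)) {
      if (k == l) next
      ik <- gpar(k, k); il <- gpar(l, l); ikl <- gpar(k, l)
      skk <- vc$genetic[k, k]; sll <- vc$genetic[l, l]
      skl <- vc$genetic[k, l]
      r <- skl / sqrt(skk * sll)
      grad <- c(1 / sqrt(skk * sll), -r / (2 * skk), -r / (2 * sll))
      V3 <- vc_cov[c(ikl, ik, il), c(ikl, ik, il)]
      rg_se[k, l] <- sqrt(max(drop(t(grad) %*% V3 %*% grad), 0))
    }
  }
  structure(
    list(vc_se = vc_se, vc_cov = vc_cov, info = info, rg_se = rg_se,
         params = info_tab, n_sim = se_n_sim),
    class = "mcem_se"
  )
}

#' @export
print.mcem_se <- function(x, ...) {
  cat("Monte Carlo approximate standard errors from", x$n_sim,
      "simulated replicates;", nrow(x$params), "parameters\n")
  invisible(x)
}
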