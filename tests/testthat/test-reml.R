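test_that("the EM update follows the stated combination rule", {
  # one founder with one record: the direct-effect entry reduces to
  # (u_hat^2 + (true*^2 - blup*^2)) / 1
  ped <- as_pedigree(tibble::tibble(animal = "a", sire = NA_character_,
                                    dam = NA_character_))
  phen <- tibble::tibble(animal = "a", population = "A", sex = "F",
                         herd = "h", contemporary_group = "c",
                         dam = NA_character_, value = 1)
  specs <- default_model_specs("A", fixed = character(0),
                               pe_populations = character(0))
  des <- build_design(phen, ped, specs)
  Ai <- a_inverse(ped)
  vc <- variance_components(diag(c(1, 1)), pe = NA_real_, resid = 1,
                            populations = "A")
  g0 <- des$genetic_offset
  real <- numeric(des$n_equations); real[g0 + 1] <- 0.5
  tru <- numeric(des$n_equations); tru[g0 + 1] <- 1.0
  blup <- numeric(des$n_equations); blup[g0 + 1] <- 0.6
  batch <- list(y = 0.6, effects = tru, residual = 0, blup = blup)
  up <- em_update(real, list(batch), Ai, des, vc)
  expect_equal(up$genetic[1, 1], (0.25 + (1.0 - 0.36)) / 1)

  # no-shrinkage limit: if simulated BLUPs equal the truth the correction
  # vanishes and the update is u'Ainv u / q
  batch0 <- list(y = 1.0, effects = tru, residual = 0, blup = tru)
  up0 <- em_update(real, list(batch0), Ai, des, vc)
  expect_equal(up0$genetic[1, 1], 0.25)
})

test_that("Monte Carlo and exact EM updates agree in expectation", {
  dat <- small_dataset(n_records = 120, populations = c("A", "B"),
                       seed = 11, n_years = 4)
  des <- build_design(dat$phenotypes, dat$pedigree, dat$specs)
  Ai <- a_inverse(dat$pedigree)
  cur <- vc_from_correlations(c("A", "B"), 100, 50, 0.5, 0.4, 0, 0,
                              pe = 30, resid = 380)
  sys <- assemble_mme(des, Ai, cur, explicit = TRUE)
  sol <- solve_pcg(sys, tol = 1e-9, max_iter = 20000)
  ex <- em_update_exact(sol$solution, sys, Ai, des, cur)
  parts <- rgacross:::.mme_parts(des, cur)
  batches <- lapply(1:150, function(s) {
    sim <- simulate_from_model(des, dat$pedigree, cur, seed = 4000 + s)
    ss <- sys
    ss$rhs <- as.numeric(Matrix::crossprod(des$W, parts$w * sim$y))
    bs <- solve_pcg(ss, tol = 1e-8, max_iter = 20000)
    list(y = sim$y, effects = sim$effects, residual = sim$residual,
         blup = bs$solution)
  })
  mc <- em_update(sol$solution, batches, Ai, des, cur)
  scale <- mean(diag(ex$genetic))
  expect_lt(max(abs(mc$genetic - ex$genetic)) / scale, 0.05)
  expect_lt(max(abs(mc$resid - ex$resid) / ex$resid), 0.05)
  expect_lt(max(abs(mc$pe - ex$pe) / ex$pe), 0.15)
})

test_that("exact EM ascends the restricted likelihood", {
  dat <- small_dataset(n_records = 100, populations = c("A", "B"),
                       seed = 11, n_years = 4)
  start <- vc_from_correlations(c("A", "B"), 100, 50, 0.5, 0.4, 0, 0,
                                pe = 30, resid = 380)
  st <- reml_settings(max_rounds = 6, seed = 5)
  fit <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, start, st,
                       method = "exact")
  des <- fit$design
  lls <- reml_loglik_oracle(dat$phenotypes, dat$pedigree, des, start)
  for (r in seq_len(fit$rounds_run)) {
    flat <- fit$trajectory %>% dplyr::filter(round == r)
    vals <- setNames(flat$value, flat$component)
    vcr <- rgacross:::.vc_unflatten(vals, start)
    lls <- c(lls, reml_loglik_oracle(dat$phenotypes, dat$pedigree, des, vcr))
  }
  expect_true(all(diff(lls) > -1e-6))
})

test_that("the convergence check regresses the trailing window", {
  mk <- function(values) {
    tibble::tibble(round = seq_along(values), component = "x",
                   value = values)
  }
  st <- reml_settings(slope_window = 10, vce_slope_tol = 1e-9, seed = 1)
  # constant trajectory: slope exactly zero, converged
  chk <- check_vce_convergence(mk(rep(5, 20)), st)
  expect_true(chk$converged)
  expect_equal(chk$worst_slope, 0)
  # linear drift 0.1 per round: raw slope recovered
  chk2 <- check_vce_convergence(mk(0.1 * (1:20)), st)
  expect_false(chk2$converged)
  expect_equal(chk2$slopes$slope, 0.1, tolerance = 1e-10)
  # alternating around a constant: slope shrinks with the window
  alt <- 5 + 0.01 * rep(c(-1, 1), 50)
  s_small <- check_vce_convergence(mk(alt), reml_settings(slope_window = 10,
                                                          seed = 1))
  s_big <- check_vce_convergence(mk(alt), reml_settings(slope_window = 100,
                                                        seed = 1))
  expect_lt(abs(s_big$worst_slope), abs(s_small$worst_slope) + 1e-12)
  # shorter trajectory than the window signals rather than errors
  chk3 <- check_vce_convergence(mk(1:3), st)
  expect_false(chk3$converged)
  expect_false(chk3$enough_rounds)
})

test_that("REML runs are reproducible and respect the round cap", {
  dat <- small_dataset(n_records = 90, populations = c("A", "B"),
                       seed = 3, n_years = 4)
  start <- dat$vc_true
  # zero rounds returns the start values untouched
  fit0 <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, start,
                        reml_settings(max_rounds = 0, seed = 9))
  expect_equal(fit0$vc$genetic, start$genetic)
  expect_equal(fit0$rounds_run, 0)
  # identical seeds, identical trajectories
  fit1 <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, start,
                        reml_settings(max_rounds = 4, seed = 9))
  fit2 <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, start,
                        reml_settings(max_rounds = 4, seed = 9))
  expect_identical(fit1$trajectory, fit2$trajectory)
  fit3 <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, start,
                        reml_settings(max_rounds = 4, seed = 10))
  expect_false(identical(fit3$trajectory$value, fit1$trajectory$value))
})

test_that("estimates started at the truth stay near it", {
  dat <- small_dataset(n_records = 450, populations = c("A", "B"),
                       herds = c(5, 4), f = 0.5, seed = 42, n_years = 6)
  fit <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, dat$vc_true,
                       reml_settings(max_rounds = 25, seed = 7),
                       report_window = 10)
  R <- genetic_correlations(fit$vc)
  Rt <- genetic_correlations(dat$vc_true)
  expect_lt(abs(R[2, 1] - Rt[2, 1]), 0.25)
  expect_lt(max(abs(diag(fit$vc$genetic) / diag(dat$vc_true$genetic) - 1)),
            0.6)
  expect_lt(max(abs(fit$vc$resid / dat$vc_true$resid - 1)), 0.3)
})

test_that("genetic correlations scale covariances and flag definiteness", {
  vc <- variance_components(diag(2), pe = NA_real_, resid = 1,
                            populations = "A")
  R <- genetic_correlations(vc)
  expect_equal(R[1, 2], 0)
  expect_true(attr(R, "positive_definite"))
  expect_equal(genetic_correlations(matrix(c(1, 0.8, 0.8, 1), 2, 2,
               dimnames = list(c("a","b"), c("a","b"))))[2, 1], 0.8)
  m <- matrix(c(2, 1.6, 1.6, 4), 2, 2, dimnames = list(c("a","b"), c("a","b")))
  expect_equal(genetic_correlations(m)[2, 1], 1.6 / sqrt(8))
  bad <- vc
  bad$genetic[1, 1] <- -1
  expect_error(genetic_correlations(bad), "nonpositive")
})

test_that("block summaries compute the four across-country statistics", {
  # constant correlation matrix: every block mean equals the constant
  P <- 3
  labs <- c(paste0("direct_", c("A","B","C")), paste0("maternal_", c("A","B","C")))
  cm <- matrix(0.5, 2 * P, 2 * P, dimnames = list(labs, labs))
  diag(cm) <- 1
  s <- summarize_rg(cm)
  expect_equal(s$mean, rep(0.5, 4))
  expect_equal(s$n, c(3, 3, 3, 6))
  # deviation from a reference is a plain subtraction
  dev <- rg_summary_deviation(s, s)
  expect_equal(dev$mean, rep(0, 4))
})

test_that("correlation standard errors follow the delta method", {
  # with a diagonal genetic matrix the delta method reduces to
  # SE(cov) / sqrt(var_k var_l)
  dat <- small_dataset(n_records = 150, populations = c("A", "B"),
                       seed = 19, n_years = 4)
  vc0 <- vc_from_correlations(c("A", "B"), 120, 60, 0, 0, 0, 0,
                              pe = 40, resid = 350)
  des <- build_design(dat$phenotypes, dat$pedigree, dat$specs)
  fit <- structure(list(vc = vc0, design = des,
                        A_inv = a_inverse(dat$pedigree),
                        pedigree = dat$pedigree,
                        settings = reml_settings(seed = 2)),
                   class = "mcem_reml_fit")
  se <- approximate_se(fit, se_n_sim = 40)
  info <- se$params
  for (pair in list(c(1, 2), c(1, 3), c(3, 4))) {
    k <- pair[1]; l <- pair[2]
    j <- which(info$type == "genetic" & info$k == k & info$l == l)
    expected <- sqrt(se$vc_cov[j, j]) /
      sqrt(vc0$genetic[k, k] * vc0$genetic[l, l])
    expect_equal(se$rg_se[k, l], expected, tolerance = 1e-10)
  }
  expect_true(all(se$vc_se >= 0))
  expect_equal(unname(diag(se$rg_se)), rep(0, 4))
})

test_that("tidy, glance and autoplot expose the fit", {
  dat <- small_dataset(n_records = 90, populations = c("A", "B"),
                       seed = 3, n_years = 4)
  fit <- run_mcem_reml(dat$phenotypes, dat$pedigree, dat$specs, dat$vc_true,
                       reml_settings(max_rounds = 3, seed = 9))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(td), length(rgacross:::.vc_flatten(fit$vc)))
  tc <- tidy(fit, what = "correlation")
  expect_true(all(abs(tc$estimate) <= 1 + 1e-8))
  gl <- glance(fit)
  expect_equal(gl$rounds, 3)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_rg_matrix(genetic_correlations(fit$vc)), "ggplot")
})

test_that("heritability reporting exposes the denominator composition", {
  vc <- vc_from_correlations("A", 120, 60, 0.8, 0.7, -0.2, 0,
                             pe = 40, resid = 350)
  h_full <- heritabilities(vc)
  denom <- 120 + 60 + vc$genetic[1, 2] + 40 + 350
  expect_equal(h_full$h2_direct, 120 / denom)
  expect_equal(h_full$h2_maternal, 60 / denom)
  h_noc <- heritabilities(vc, include_dm_covariance = FALSE,
                          include_pe = FALSE)
  expect_equal(h_noc$h2_direct, 120 / (120 + 60 + 350))
})
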