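test_that("design dimensions follow the model contract", {
  ped <- as_pedigree(tibble::tibble(animal = c("s", "d", "o1", "o2", "o3"),
                                    sire = c(NA, NA, "s", "s", NA),
                                    dam = c(NA, NA, "d", NA, NA)))
  phen <- tibble::tibble(
    animal = c("o1", "o2", "o3"),
    population = c("A", "A", "B"),
    sex = c("F", "M", "F"), herd = "h",
    contemporary_group = c("c1", "c1", "c2"),
    dam = c("d", NA, NA), value = c(1, 2, 3)
  )
  specs <- default_model_specs(c("A", "B"), fixed = character(0))
  des <- build_design(phen, ped, specs)
  # genetic effects: 2 populations x (direct + maternal) x 5 animals
  expect_equal(des$n_equations - des$genetic_offset, 2 * 2 * 5)
  expect_equal(des$n_records, 3)
  # record with unknown dam has no maternal or pe incidence
  W <- as.matrix(des$W)
  m_cols <- des$genetic_offset +
    as.vector(vapply(seq_len(5), function(a) (a - 1) * 4 + 3:4, numeric(2)))
  expect_equal(sum(W[2, m_cols]), 0)
  expect_equal(sum(W[1, m_cols]), 1)   # o1 links its dam's maternal effect
  # a record citing a dam missing from the pedigree is an error
  bad <- phen; bad$dam[1] <- "ghost"
  expect_error(build_design(bad, ped, specs), "dams absent")
})

test_that("assembled equations are symmetric and block-separate without covariance", {
  dat <- small_dataset(n_records = 80, populations = c("A", "B"), seed = 4)
  des <- build_design(dat$phenotypes, dat$pedigree, dat$specs)
  Ai <- a_inverse(dat$pedigree)
  vc0 <- vc_from_correlations(c("A", "B"), 120, 60, 0, 0, 0, 0,
                              pe = 40, resid = 350)
  sys <- assemble_mme(des, Ai, vc0, explicit = TRUE)
  L <- as.matrix(sys$lhs)
  expect_equal(L, t(L))
  # zero across-population covariance: no equations couple A and B effects
  g0 <- des$genetic_offset
  for (a in utils::head(seq_len(des$n_animals), 10)) {
    blk <- L[g0 + (a - 1) * 4 + 1:4, g0 + (a - 1) * 4 + 1:4]
    expect_equal(blk[1, 2], 0)   # direct A x direct B
    expect_equal(blk[3, 4], 0)   # maternal A x maternal B
  }
  # singular genetic matrix is rejected with advice
  vc_bad <- vc0
  vc_bad$genetic[1, ] <- vc_bad$genetic[, 1] <- 0
  expect_error(assemble_mme(des, Ai, vc_bad), "ridge|restart")
})

test_that("mixed-model solutions match the hand-solved example", {
  ped <- as_pedigree(tibble::tibble(animal = c("a1", "a2"),
                                    sire = NA_character_,
                                    dam = NA_character_))
  phen <- tibble::tibble(animal = c("a1", "a2"), population = "A",
                         sex = "F", herd = "h", contemporary_group = "c",
                         dam = NA_character_, value = c(1, 3))
  specs <- default_model_specs("A", fixed = character(0),
                               pe_populations = character(0))
  vc <- variance_components(diag(c(1, 1)), pe = NA_real_, resid = 1,
                            populations = "A")
  des <- build_design(phen, ped, specs)
  sys <- assemble_mme(des, a_inverse(ped), vc)
  sol <- solve_pcg(sys, tol = 1e-9, max_iter = 100)
  # mean 2, direct effects -0.5 and +0.5, maternal effects 0
  expect_equal(sol$solution, c(2, -0.5, 0, 0.5, 0), tolerance = 1e-6)
})

test_that("PCG solves known systems and matches dense solutions", {
  # identity system converges immediately to the right-hand side
  I5 <- Matrix::Diagonal(5)
  r <- c(3, 1, 4, 1, 5)
  s <- solve_pcg(list(lhs = as(I5, "CsparseMatrix"), rhs = r), tol = 1e-8)
  expect_equal(s$solution, r, tolerance = 1e-10)
  expect_equal(s$iterations, 1)
  # closed-form 2x2
  A2 <- as(Matrix::Matrix(c(4, 1, 1, 3), 2, 2, sparse = TRUE), "CsparseMatrix")
  s2 <- solve_pcg(list(lhs = A2, rhs = c(1, 2)), tol = 1e-10, max_iter = 50)
  expect_equal(s2$solution, c(1 / 11, 7 / 11), tolerance = 1e-8)
  # full mixed-model system against a dense solve
  dat <- small_dataset(n_records = 100, populations = c("A", "B"), seed = 6)
  des <- build_design(dat$phenotypes, dat$pedigree, dat$specs)
  sys <- assemble_mme(des, a_inverse(dat$pedigree), dat$vc_true,
                      explicit = TRUE)
  dense <- solve(as.matrix(sys$lhs), sys$rhs)
  fast <- solve_pcg(sys, tol = 1e-8, max_iter = 5000)
  expect_lt(sqrt(sum((fast$solution - dense)^2) / sum(dense^2)), 1e-6)
})

test_that("model simulation reproduces the specified moments", {
  # residual-only variance at Monte Carlo scale
  ped <- as_pedigree(tibble::tibble(animal = paste0("f", 1:2000),
                                    sire = NA_character_,
                                    dam = NA_character_))
  phen <- tibble::tibble(animal = ped$animal, population = "A", sex = "F",
                         herd = "h", contemporary_group = "c",
                         dam = NA_character_, value = 0)
  specs <- default_model_specs("A", fixed = character(0),
                               pe_populations = character(0))
  des <- build_design(phen, ped, specs)
  vc0 <- variance_components(diag(c(1e-8, 1e-8)), pe = NA_real_, resid = 25,
                             populations = "A")
  sim <- simulate_from_model(des, ped, vc0, seed = 1)
  expect_lt(abs(var(sim$y) - 25), 3 * 25 * sqrt(2 / 1999))
  expect_lt(abs(mean(sim$y)), 3 * 5 / sqrt(2000))  # E[y] = Xb = 0

  # founder effects carry the specified within-animal covariance
  vc1 <- vc_from_correlations("A", 120, 60, r_dm_within = -0.2,
                              pe = NA_real_, resid = 1)
  vc1$pe[] <- NA
  sim2 <- simulate_from_model(des, ped, vc1, seed = 2)
  emp <- cov(sim2$genetic)
  se_cov <- sqrt((120 * 60 + vc1$genetic[1, 2]^2) / 1999)
  expect_lt(abs(emp[1, 2] - vc1$genetic[1, 2]), 3 * se_cov)
  expect_lt(abs(emp[1, 1] - 120), 3 * 120 * sqrt(2 / 1999))

  # identical seeds give identical data
  sim3 <- simulate_from_model(des, ped, vc0, seed = 1)
  expect_identical(sim$y, sim3$y)
})

test_that("offspring inherit half the parental genetic effect on average", {
  dat <- small_dataset(n_records = 1500, populations = "A", herds = 5,
                       f = 0, seed = 31, n_years = 5)
  g <- dat$truth$genetic[, 1]   # direct effects, only population
  ped <- dat$pedigree
  has_s <- !is.na(ped$sire_idx)
  fitco <- coef(lm(g[has_s] ~ g[ped$sire_idx[has_s]]))[2]
  expect_lt(abs(fitco - 0.5), 0.1)
})

test_that("BLUP solutions are invariant to the true fixed effects", {
  dat <- small_dataset(n_records = 100, populations = c("A", "B"), seed = 17)
  des <- build_design(dat$phenotypes, dat$pedigree, dat$specs)
  Ai <- a_inverse(dat$pedigree)
  sys <- assemble_mme(des, Ai, dat$vc_true)
  em <- des$effect_map
  nfix <- sum(em$type == "fixed")
  sim0 <- simulate_from_model(des, dat$pedigree, dat$vc_true, seed = 5)
  simb <- simulate_from_model(des, dat$pedigree, dat$vc_true, seed = 5,
                              fixed_values = seq_len(nfix) * 10)
  parts <- rgacross:::.mme_parts(des, dat$vc_true)
  solve_y <- function(y) {
    s <- sys
    s$rhs <- as.numeric(Matrix::crossprod(des$W, parts$w * y))
    solve_pcg(s, tol = 1e-9, max_iter = 20000)$solution
  }
  s0 <- solve_y(sim0$y)
  sb <- solve_y(simb$y)
  rand <- (max(em$column[em$type == "fixed"]) + 1):des$n_equations
  expect_lt(max(abs(sb[rand] - s0[rand])), 1e-4)
})
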