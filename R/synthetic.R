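#' Configuration for the multi-country data generator
#'
#' Describes a multi-population beef-cattle recording scheme with one or
#' more populations of very different sizes, herd and contemporary-group
#' structure, overlapping generations, and international sires shared
#' across populations (the source of common bulls and, through their
#' daughters kept as dams, of common maternal grand-sires).
#'
#' @param populations A tibble with columns `name`, `share` (fractions of
#'   records, summing to 1), `n_herds`, `has_pe` (whether the national
#'   model fits a maternal permanent environmental effect), `mean`
#'   (population phenotypic mean, kg).
#' @param n_records Total number of phenotype records to generate.
#' @param vc_true True [variance_components()] (its `pe` entries must be
#'   `NA` exactly for populations with `has_pe = FALSE`).
#' @param n_years Number of birth-year cohorts with recording.
#' @param international_sire_fraction Mean probability that a mating uses
#'   an international-pool sire rather than a national one; drives common
#'   bull counts and genetic similarity.
#' @param herd_usage_concentration Beta-distribution concentration of the
#'   herd-specific international-usage probabilities around the mean
#'   (small values give strongly heterogeneous herds).
#' @param n_international_sires Size of the shared sire pool.
#' @param dam_career Years a dam stays in production (one calf per year);
#'   replacements are recruited from the herd's own reared females when
#'   available, which creates maternal grand-sire links.
#' @param cg_sd Standard deviation (kg) of the fixed contemporary-group
#'   effects (contemporary group = herd x birth year).
#' @param sex_effect Fixed male-female difference (kg).
#' @param min_cg_size Named per-population minimum contemporary-group
#'   sizes for the editing step (carried along for convenience).
#' @param first_year Calendar year of the first recorded cohort.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(populations, n_records, vc_true,
                              n_years = 6, international_sire_fraction = 0.1,
                              herd_usage_concentration = 2,
                              n_international_sires = 30, dam_career = 4,
                              cg_sd = 10, sex_effect = 15,
                              min_cg_size = NULL, first_year = 2000) {
  stopifnot(is.data.frame(populations),
            all(c("name", "share", "n_herds", "has_pe", "mean") %in%
                  names(populations)))
  if (abs(sum(populations$share) - 1) > 1e-6) abort("shares must sum to 1")
  stopifnot(international_sire_fraction >= 0,
            international_sire_fraction <= 1, n_records >= 1, n_years >= 1)
  ev <- eigen(vc_true$genetic, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("true genetic matrix must be positive semi-definite")
  }
  pe_ok <- is.na(vc_true$pe[populations$name]) == !populations$has_pe
  if (!all(pe_ok)) {
    abort("vc_true$pe must be NA exactly for populations without pe")
  }
  if (is.null(min_cg_size)) {
    min_cg_size <- setNames(rep(1L, nrow(populations)), populations$name)
  }
  structure(
    list(populations = populations, n_records = n_records,
         vc_true = vc_true, n_years = n_years,
         international_sire_fraction = international_sire_fraction,
         herd_usage_concentration = herd_usage_concentration,
         n_international_sires = n_international_sires,
         dam_career = dam_career, cg_sd = cg_sd, sex_effect = sex_effect,
         min_cg_size = min_cg_size, first_year = first_year),
    class = "simulation_config"
  )
}

#' Generate pedigree and herd structure
#'
#' Builds an overlapping-generation pedigree: founder national sires,
#' founder dams per herd, and a shared international sire pool; every
#' year each active dam produces one recorded calf whose sire is drawn
#' from the international pool with the herd's usage probability and from
#' the national pool otherwise. Retiring dams are replaced by the herd's
#' own reared females when old enough, otherwise by new founder dams.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (byte-identical structure for equal seeds).
#' @return A list with `pedigree` (a [as_pedigree()] object covering all
#'   animals) and `animals` (a tibble of the recorded animals with
#'   `population`, `herd`, `sex`, `birth_year`, `sire`, `dam`).
#' @export
generate_structure <- function(cfg, seed = 1) {
  .with_seed(seed, .generate_structure_impl(cfg))
}

.generate_structure_impl <- function(cfg) {
  pops <- cfg$populations
  y0 <- cfg$first_year
  f <- cfg$international_sire_fraction
  conc <- cfg$herd_usage_concentration

  cap <- 3L * cfg$n_records + 10000L
  id <- character(cap); sire <- rep(NA_character_, cap)
  dam <- rep(NA_character_, cap)
  year <- integer(cap); origin <- character(cap)
  n_anim <- 0L
  add_animal <- function(a, s, d, y, o) {
    n_anim <<- n_anim + 1L
    id[n_anim] <<- a; sire[n_anim] <<- s; dam[n_anim] <<- d
    year[n_anim] <<- y; origin[n_anim] <<- o
  }

  # shared international sire pool; origin country sampled by record share
  intl <- paste0("INT_s", seq_len(cfg$n_international_sires))
  intl_origin <- sample(pops$name, cfg$n_international_sires, replace = TRUE,
                        prob = pops$share)
  for (k in seq_along(intl)) {
    add_animal(intl[k], NA, NA, y0 - 6L, intl_origin[k])
  }

  rcap <- cfg$n_records + 10000L
  r_animal <- character(rcap); r_pop <- character(rcap)
  r_herd <- character(rcap); r_sex <- character(rcap)
  r_year <- integer(rcap); r_sire <- character(rcap); r_dam <- character(rcap)
  n_rec <- 0L
  founder_ct <- 0L
  calf_ct <- 0L
  for (pi in seq_len(nrow(pops))) {
    p <- pops$name[pi]
    n_target <- round(pops$share[pi] * cfg$n_records)
    if (n_target < 1) next
    n_herds <- max(1L, pops$n_herds[pi])
    per_year <- max(1, round(n_target / cfg$n_years))
    dams_per_herd <- max(1L, round(per_year / n_herds))
    n_nat <- max(2L, ceiling(per_year / 15))
    nat <- paste0(p, "_s", seq_len(n_nat))
    for (s in nat) add_animal(s, NA, NA, y0 - 5L, p)
    herd_f <- if (f <= 0) rep(0, n_herds) else if (f >= 1) rep(1, n_herds) else
      stats::rbeta(n_herds, conc * f, conc * (1 - f))

    for (h in seq_len(n_herds)) {
      herd_id <- paste0(p, "_h", h)
      # active dams: parallel vectors of id and first year of production
      dam_ids <- character(dams_per_herd)
      dam_start <- integer(dams_per_herd)
      for (k in seq_len(dams_per_herd)) {
        founder_ct <- founder_ct + 1L
        dam_ids[k] <- paste0(p, "_fd", founder_ct)
        add_animal(dam_ids[k], NA, NA, y0 - 3L, p)
        # stagger founder dam entry so replacements do not all coincide
        dam_start[k] <- 1L - sample.int(cfg$dam_career, 1) + 1L
      }
      reared <- character(0)   # herd-born females old enough to breed
      reared_year <- integer(0)
      for (t in seq_len(cfg$n_years)) {
        for (k in seq_len(dams_per_herd)) {
          if (t - dam_start[k] >= cfg$dam_career) {
            ok <- reared_year <= t - 2L
            if (any(ok)) {
              pick <- which(ok)[1]
              dam_ids[k] <- reared[pick]
              reared <- reared[-pick]; reared_year <- reared_year[-pick]
            } else {
              founder_ct <- founder_ct + 1L
              dam_ids[k] <- paste0(p, "_fd", founder_ct)
              add_animal(dam_ids[k], NA, NA, y0 + t - 3L, p)
            }
            dam_start[k] <- t
          }
          use_intl <- stats::runif(1) < herd_f[h]
          s_id <- if (use_intl) intl[sample.int(length(intl), 1)] else
            nat[sample.int(n_nat, 1)]
          calf_ct <- calf_ct + 1L
          a_id <- paste0(p, "_a", calf_ct)
          sx <- if (stats::runif(1) < 0.5) "F" else "M"
          add_animal(a_id, s_id, dam_ids[k], y0 + t, p)
          n_rec <- n_rec + 1L
          r_animal[n_rec] <- a_id; r_pop[n_rec] <- p
          r_herd[n_rec] <- herd_id; r_sex[n_rec] <- sx
          r_year[n_rec] <- y0 + t; r_sire[n_rec] <- s_id
          r_dam[n_rec] <- dam_ids[k]
          if (sx == "F") {
            reared <- c(reared, a_id)
            reared_year <- c(reared_year, t)
          }
        }
      }
    }
  }
  animals <- tibble(
    animal = r_animal[seq_len(n_rec)], population = r_pop[seq_len(n_rec)],
    herd = r_herd[seq_len(n_rec)], sex = r_sex[seq_len(n_rec)],
    birth_year = r_year[seq_len(n_rec)], sire = r_sire[seq_len(n_rec)],
    dam = r_dam[seq_len(n_rec)]
  )
  keep <- seq_len(n_anim)
  ped <- as_pedigree(tibble(animal = id[keep], sire = sire[keep],
                            dam = dam[keep], birth_year = year[keep],
                            origin_country = origin[keep]))
  list(pedigree = ped, animals = animals)
}

#' Generate phenotypes under the multi-trait maternal model
#'
#' Simulates records over a generated structure with the analysis model
#' itself as the generative model: population mean + fixed contemporary
#' group (herd x year) and sex effects + direct genetic + maternal
#' genetic (dam) + maternal permanent environmental (dam) + residual,
#' with genetic effects drawn by pedigree recursion under the true
#' `2P x 2P` covariance matrix.
#'
#' @param structure Output of [generate_structure()].
#' @param cfg The same [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `phenotypes` (records tibble with `value`),
#'   `pedigree`, `specs` (the matching [national_model_spec()] list), and
#'   `truth` (true effect vector, effect map, genetic effect matrix,
#'   fixed-effect values and the true variance components).
#' @export
generate_phenotypes <- function(structure, cfg, seed = 1) {
  pops <- cfg$populations
  phen <- structure$animals %>%
    mutate(contemporary_group = paste0(.data$herd, "_", .data$birth_year),
           value = 0)
  specs <- default_model_specs(
    pops$name, fixed = c("contemporary_group", "sex"),
    pe_populations = pops$name[pops$has_pe]
  )
  design <- build_design(phen, structure$pedigree, specs)
  em <- design$effect_map
  fixed_rows <- em %>% filter(.data$type == "fixed")
  fixed_values <- .with_seed(seed, {
    v <- numeric(nrow(fixed_rows))
    for (r in seq_len(nrow(fixed_rows))) {
      lev <- fixed_rows$level[r]
      v[r] <- if (lev == "(Intercept)") {
        pops$mean[match(fixed_rows$population[r], pops$name)]
      } else if (grepl("^factor\\(sex\\)", lev)) {
        if (grepl("M$", lev)) cfg$sex_effect else -cfg$sex_effect
      } else {
        rnorm(1, 0, cfg$cg_sd)
      }
    }
    v
  })
  sim <- simulate_from_model(design, structure$pedigree, cfg$vc_true,
                             seed = seed + 1L, fixed_values = fixed_values)
  phen$value <- sim$y
  list(
    phenotypes = phen,
    pedigree = structure$pedigree,
    specs = specs,
    truth = list(
      effects = sim$effects, effect_map = em, genetic = sim$genetic,
      residual = sim$residual,
      fixed = fixed_rows %>% mutate(value = fixed_values),
      vc_true = cfg$vc_true
    )
  )
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_structure()] and [generate_phenotypes()] under a single
#' seed.
#'
#' @inheritParams generate_structure
#' @return See [generate_phenotypes()].
#' @export
simulate_dataset <- function(cfg, seed = 1) {
  structure <- generate_structure(cfg, seed = seed)
  generate_phenotypes(structure, cfg, seed = seed + 1L)
}

#' Preset emulating the international Limousin weaning-weight structure
#'
#' Eight populations whose record shares match the routine international
#' evaluation (one dominant population with 87.1% of records), herd
#' counts scaled proportionally, the national minimum contemporary-group
#' sizes, one population (the DEU analogue) without a maternal permanent
#' environmental effect, and a default true parameter set with
#' across-country direct correlations of about 0.8 and maternal
#' correlations of about 0.7.
#'
#' @param scale Total number of records to generate (at least 1000).
#' @return A [simulation_config()].
#' @export
preset_interbeef_like <- function(scale) {
  if (scale < 1000) abort("scale must be at least 1000 records")
  name <- c("FRA", "GBR", "DFS", "DEU", "ESP", "CHE", "IRL", "CZE")
  share <- c(0.871, 0.041, 0.029, 0.028, 0.011, 0.010, 0.007, 0.003)
  herds_full <- c(6677, 745, 190, 881, 188, 224, 1304, 121)
  n_herds <- pmax(2L, round(herds_full * scale / 3115598))
  has_pe <- name != "DEU"
  means <- c(FRA = 260, GBR = 250, DFS = 240, DEU = 255, ESP = 230,
             CHE = 245, IRL = 235, CZE = 240)
  pops <- tibble(name = name, share = share / sum(share), n_herds = n_herds,
                 has_pe = has_pe, mean = unname(means[name]))
  vc <- vc_from_correlations(
    name, direct_var = 120, maternal_var = 60,
    rg_direct = 0.8, rg_maternal = 0.7,
    r_dm_within = -0.2, r_dm_between = -0.05,
    pe = setNames(ifelse(has_pe, 40, NA_real_), name),
    resid = 350
  )
  min_cg <- c(FRA = 2L, GBR = 5L, DFS = 1L, DEU = 3L, ESP = 5L, CHE = 5L,
              IRL = 3L, CZE = 1L)
  simulation_config(pops, n_records = scale, vc_true = vc,
                    min_cg_size = min_cg)
}
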