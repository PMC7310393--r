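#' Tally phenotyped offspring per sire, population and herd
#'
#' Offspring means phenotyped offspring in the supplied (edited) phenotype
#' table; pedigree offspring without records do not count. Records whose
#' sire is unknown contribute to no sire.
#'
#' @param phen Phenotype tibble with at least `animal`, `population`,
#'   `herd`.
#' @param ped A [as_pedigree()] pedigree containing every phenotyped animal.
#' @return A tibble with columns `sire`, `population`, `herd`, `n`.
#' @export
tally_sire_offspring <- function(phen, ped) {
  .check_phen_in_ped(phen, ped)
  idx <- match(phen$animal, ped$animal)
  sire <- ped$sire[idx]
  phen %>%
    mutate(sire = sire) %>%
    filter(!is.na(.data$sire)) %>%
    count(.data$sire, .data$population, .data$herd, name = "n")
}

#' Tally phenotyped grand-offspring per maternal grand-sire
#'
#' The counted ancestor is the sire of the record's dam. Records with an
#' unknown dam, or whose dam has an unknown sire, contribute to no
#' maternal grand-sire.
#'
#' @inheritParams tally_sire_offspring
#' @return A tibble with columns `sire` (the maternal grand-sire),
#'   `population`, `herd`, `n`.
#' @export
tally_mgs_grandoffspring <- function(phen, ped) {
  .check_phen_in_ped(phen, ped)
  dam <- if ("dam" %in% names(phen)) phen$dam else ped$dam[match(phen$animal, ped$animal)]
  mgs <- ped$sire[match(dam, ped$animal)]
  phen %>%
    mutate(sire = mgs) %>%
    filter(!is.na(.data$sire)) %>%
    count(.data$sire, .data$population, .data$herd, name = "n")
}

.check_phen_in_ped <- function(phen, ped) {
  stopifnot(is.data.frame(phen), inherits(ped, "pedigree"))
  need <- c("animal", "population", "herd")
  if (!all(need %in% names(phen))) {
    abort(paste0("phenotypes need columns ", paste(need, collapse = ", ")))
  }
  missing <- setdiff(unique(phen$animal), ped$animal)
  if (length(missing) > 0) {
    abort(paste0("phenotyped animals absent from pedigree: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  invisible(TRUE)
}

# collapse a (sire, population, herd, n) tally to (sire, population, n)
.pop_counts <- function(counts) {
  if (!"herd" %in% names(counts)) return(counts)
  counts %>%
    group_by(.data$sire, .data$population) %>%
    summarise(n = sum(.data$n), .groups = "drop")
}

#' Coefficient of genetic similarity between two populations
#'
#' The proportion of sired offspring in populations `pop_a` and `pop_b`
#' that originate from common bulls (sires with offspring in both). Ranges
#' from 0 (no common bulls) to 1 (every bull common). An undefined ratio
#' (no sired offspring in either population) is reported as `NA`, not 0.
#'
#' @param counts A tally from [tally_sire_offspring()] (or
#'   [tally_mgs_grandoffspring()] for the grand-sire analogue).
#' @param pop_a,pop_b Population identifiers.
#' @return A single numeric GS coefficient.
#' @export
genetic_similarity <- function(counts, pop_a, pop_b) {
  pc <- .pop_counts(counts) %>% filter(.data$population %in% c(pop_a, pop_b))
  if (nrow(pc) == 0) return(NA_real_)
  wide <- pc %>%
    group_by(.data$sire) %>%
    summarise(
      n_a = sum(.data$n[.data$population == pop_a]),
      n_b = sum(.data$n[.data$population == pop_b]),
      .groups = "drop"
    )
  den <- sum(wide$n_a + wide$n_b)
  if (den == 0) return(NA_real_)
  common <- wide$n_a > 0 & wide$n_b > 0
  sum(wide$n_a[common] + wide$n_b[common]) / den
}

#' All pairwise genetic similarity coefficients
#'
#' @inheritParams genetic_similarity
#' @param populations Optional character vector fixing the population set
#'   (defaults to the populations present in `counts`).
#' @return A tibble with one row per unordered population pair: common
#'   bull count `cb`, total bull count `tb`, and `gs`.
#' @export
gs_pairwise <- function(counts, populations = NULL) {
  pc <- .pop_counts(counts)
  if (is.null(populations)) populations <- sort(unique(pc$population))
  pairs <- utils::combn(populations, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sub <- pc %>% filter(.data$population %in% c(a, b))
    wide <- sub %>%
      group_by(.data$sire) %>%
      summarise(
        n_a = sum(.data$n[.data$population == a]),
        n_b = sum(.data$n[.data$population == b]),
        .groups = "drop"
      )
    den <- sum(wide$n_a + wide$n_b)
    common <- wide$n_a > 0 & wide$n_b > 0
    tibble(
      pop_a = a, pop_b = b,
      cb = sum(common), tb = nrow(wide),
      gs = if (den == 0) NA_real_ else
        sum(wide$n_a[common] + wide$n_b[common]) / den
    )
  })
}

#' Herd-level genetic similarity versus every other population
#'
#' Treats each herd of `target_population` as one unit of the genetic
#' similarity ratio, compared against each population other than the
#' herd's own.
#'
#' @inheritParams tally_sire_offspring
#' @param target_population The population whose herds are scored.
#' @param ancestor Count connections through sires (`"cb"`, common bulls)
#'   or through maternal grand-sires (`"cmgs"`).
#' @return A tibble with columns `herd`, `population`, `cb`, `gs`
#'   (`NA` when the ratio is undefined).
#' @export
herd_gs <- function(phen, ped, target_population, ancestor = c("cb", "cmgs")) {
  ancestor <- match.arg(ancestor)
  tally <- if (ancestor == "cb") tally_sire_offspring(phen, ped) else
    tally_mgs_grandoffspring(phen, ped)
  herds <- phen %>%
    filter(.data$population == target_population) %>%
    distinct(.data$herd)
  counts_h <- tally %>%
    filter(.data$population == target_population) %>%
    group_by(.data$sire, .data$herd) %>%
    summarise(n_h = sum(.data$n), .groups = "drop")
  counts_b <- tally %>%
    filter(.data$population != target_population) %>%
    group_by(.data$sire, .data$population) %>%
    summarise(n_b = sum(.data$n), .groups = "drop")
  pops <- sort(unique(counts_b$population))
  all_pops <- sort(setdiff(unique(phen$population), target_population))
  tot_h <- counts_h %>% group_by(.data$herd) %>%
    summarise(tot_h = sum(.data$n_h), .groups = "drop")
  tot_b <- counts_b %>% group_by(.data$population) %>%
    summarise(tot_b = sum(.data$n_b), .groups = "drop")
  common <- inner_join(counts_h, counts_b, by = "sire",
                       relationship = "many-to-many") %>%
    group_by(.data$herd, .data$population) %>%
    summarise(cb = n(), num = sum(.data$n_h + .data$n_b),
              hm = sum(2 / (1 / .data$n_h + 1 / .data$n_b)),
              .groups = "drop")
  grid <- tidyr::expand_grid(herd = herds$herd, population = all_pops) %>%
    left_join(tot_h, by = "herd") %>%
    left_join(tot_b, by = "population") %>%
    left_join(common, by = c("herd", "population")) %>%
    mutate(
      tot_h = ifelse(is.na(.data$tot_h), 0, .data$tot_h),
      tot_b = ifelse(is.na(.data$tot_b), 0, .data$tot_b),
      cb = ifelse(is.na(.data$cb), 0L, .data$cb),
      num = ifelse(is.na(.data$num), 0, .data$num),
      hm = ifelse(is.na(.data$hm), 0, .data$hm),
      den = .data$tot_h + .data$tot_b,
      gs = ifelse(.data$den == 0, NA_real_, .data$num / .data$den)
    )
  grid %>% select("herd", "population", "cb", "gs", "hm")
}

#' Balanced offspring distribution coefficient of a sire
#'
#' `1 - sum(|n_j - mean|) / (2 * sum(n_j))`, with the sum running over all
#' populations of the evaluation (zero counts included). Ranges from
#' `1/n_populations` (all offspring in one population) to 1 (perfectly
#' balanced).
#'
#' @param n Numeric vector of per-population offspring counts for one
#'   sire; shorter vectors are padded with zeros up to `n_populations`.
#' @param n_populations Number of populations in the evaluation.
#' @return The BOD coefficient.
#' @examples
#' bod(c(10, 10), 8) # 0.25
#' @export
bod <- function(n, n_populations) {
  stopifnot(length(n) <= n_populations, all(n >= 0))
  total <- sum(n)
  if (total <= 0) abort("sire has no offspring; BOD undefined")
  n <- c(n, rep(0, n_populations - length(n)))
  nbar <- total / n_populations
  1 - sum(abs(n - nbar)) / (2 * total)
}

#' Adjusted number of populations
#'
#' Rescales a [bod()] coefficient to the population count scale:
#' `n_populations * bod`.
#'
#' @param bod_value A BOD coefficient in \[0, 1\].
#' @param n_populations Number of populations.
#' @export
an_pop <- function(bod_value, n_populations) {
  stopifnot(all(bod_value >= 0 & bod_value <= 1))
  n_populations * bod_value
}

#' Harmonic mean of a sire's progeny sizes in two units
#'
#' @param n1,n2 Positive progeny sizes (vectors recycle).
#' @return `2 / (1/n1 + 1/n2)`.
#' @export
harmonic_mean_progeny <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) {
    abort("progeny sizes must be positive (a common bull has offspring on both sides)")
  }
  2 / (1 / n1 + 1 / n2)
}

#' Herd-level harmonic mean coefficients
#'
#' For each herd of the target population, sums over the other populations
#' and over the common bulls between the herd and that population the
#' harmonic mean of the bull's progeny sizes in the two units. Herds with
#' no common bulls score 0.
#'
#' @inheritParams herd_gs
#' @return A tibble with columns `herd`, `hm`.
#' @export
herd_harmonic_means <- function(phen, ped, target_population) {
  herd_gs(phen, ped, target_population, ancestor = "cb") %>%
    group_by(.data$herd) %>%
    summarise(hm = sum(.data$hm), .groups = "drop")
}

#' Full connectedness report
#'
#' Computes all pairwise, per-sire and (optionally) per-herd connectedness
#' coefficients for a phenotype table: common bull (CB) and common
#' maternal grand-sire (CMGS) counts, genetic similarity, balanced
#' offspring distribution and adjusted number of populations per sire,
#' the distribution of CB by number of connected populations and by birth
#' year and origin country, and the CMGS-also-CB cross-tabulation.
#'
#' @inheritParams tally_sire_offspring
#' @param populations Optional fixed population set.
#' @param herd_population If non-`NULL`, herd-level coefficients are
#'   computed for the herds of this population.
#' @return An object of class `connectedness_report` (a list of tibbles).
#' @export
connectedness_report <- function(phen, ped, populations = NULL,
                                 herd_population = NULL) {
  tally <- tally_sire_offspring(phen, ped)
  mgs_tally <- tally_mgs_grandoffspring(phen, ped)
  if (is.null(populations)) populations <- sort(unique(phen$population))
  n_pop <- length(populations)
  pc <- .pop_counts(tally)

  pairwise <- gs_pairwise(tally, populations)
  bulls_per_pop <- pc %>% group_by(.data$population) %>%
    summarise(bulls = dplyr::n_distinct(.data$sire), .groups = "drop")

  sires <- pc %>%
    group_by(.data$sire) %>%
    summarise(
      total = sum(.data$n),
      n_pops = dplyr::n_distinct(.data$population),
      dev = {
        nbar <- sum(.data$n) / n_pop
        sum(abs(.data$n - nbar)) + (n_pop - dplyr::n_distinct(.data$population)) * nbar
      },
      .groups = "drop"
    ) %>%
    mutate(
      bod = 1 - .data$dev / (2 * .data$total),
      an_pop = n_pop * .data$bod,
      is_cb = .data$n_pops >= 2
    ) %>%
    select(-"dev")

  cb_ids <- sires$sire[sires$is_cb]
  cb_by_npops <- sires %>% filter(.data$is_cb) %>% count(.data$n_pops)
  cb_year_origin <- ped %>%
    filter(.data$animal %in% cb_ids) %>%
    count(.data$birth_year, .data$origin_country)

  # pairwise harmonic means for common bulls
  cb_pair_hm <- pc %>%
    filter(.data$sire %in% cb_ids) %>%
    inner_join(pc %>% filter(.data$sire %in% cb_ids),
               by = "sire", relationship = "many-to-many",
               suffix = c("_a", "_b")) %>%
    filter(.data$population_a < .data$population_b) %>%
    mutate(hm = 2 / (1 / .data$n_a + 1 / .data$n_b)) %>%
    select(sire = "sire", pop_a = "population_a", pop_b = "population_b",
           n_a = "n_a", n_b = "n_b", hm = "hm")

  mgs_pc <- .pop_counts(mgs_tally)
  cmgs <- mgs_pc %>%
    group_by(.data$sire) %>%
    summarise(n_pops = dplyr::n_distinct(.data$population), .groups = "drop") %>%
    filter(.data$n_pops >= 2) %>%
    mutate(also_cb = .data$sire %in% cb_ids)
  cmgs_pairwise <- gs_pairwise(mgs_tally, populations)

  herd <- NULL
  if (!is.null(herd_population)) {
    g_cb <- herd_gs(phen, ped, herd_population, "cb")
    g_cm <- herd_gs(phen, ped, herd_population, "cmgs")
    herd_sizes <- phen %>%
      filter(.data$population == herd_population) %>%
      count(.data$herd, name = "records")
    herd <- g_cb %>%
      rename(gs_cb = "gs") %>%
      left_join(g_cm %>% select("herd", "population", gs_cmgs = "gs"),
                by = c("herd", "population")) %>%
      mutate(gs_tot = (.data$gs_cb + .data$gs_cmgs) / 2) %>%
      group_by(.data$herd) %>%
      summarise(
        gs_cb = mean(.data$gs_cb, na.rm = TRUE),
        gs_tot = mean(.data$gs_tot, na.rm = TRUE),
        hm = sum(.data$hm),
        .groups = "drop"
      ) %>%
      mutate(
        gs_cb = ifelse(is.nan(.data$gs_cb), NA_real_, .data$gs_cb),
        gs_tot = ifelse(is.nan(.data$gs_tot), NA_real_, .data$gs_tot)
      ) %>%
      left_join(herd_sizes, by = "herd")
  }

  structure(
    list(
      populations = populations,
      n_populations = n_pop,
      pairwise = pairwise,
      bulls_per_population = bulls_per_pop,
      sires = sires,
      unique_cb = length(cb_ids),
      cb_by_npops = cb_by_npops,
      cb_by_year_origin = cb_year_origin,
      cb_pair_hm = cb_pair_hm,
      cmgs = cmgs,
      cmgs_pairwise = cmgs_pairwise,
      unique_cmgs = nrow(cmgs),
      herd = herd
    ),
    class = "connectedness_report"
  )
}

#' @export
print.connectedness_report <- function(x, ...) {
  cat("Connectedness report:", x$n_populations, "populations;",
      x$unique_cb, "unique common bulls;", x$unique_cmgs,
      "unique common maternal grand-sires\n")
  cat("Mean pairwise genetic similarity:",
      signif(mean(x$pairwise$gs, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @describeIn connectedness_report Pairwise table in tidy form.
#' @param x A `connectedness_report`.
#' @param ... Unused.
#' @export
tidy.connectedness_report <- function(x, ...) {
  x$pairwise
}

#' @describeIn connectedness_report Heatmap of pairwise genetic similarity.
#' @param object A `connectedness_report`.
#' @export
autoplot.connectedness_report <- function(object, ...) {
  df <- object$pairwise
  df2 <- bind_rows(df, df %>% rename(pop_a = "pop_b", pop_b = "pop_a"))
  ggplot2::ggplot(df2, ggplot2::aes(.data$pop_a, .data$pop_b, fill = .data$gs)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$gs, 2)), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "GS",
                  title = "Pairwise genetic similarity")
}

#' Pairwise connectedness in the standard reporting layout
#'
#' Formats the pairwise table of a [connectedness_report()] as a square
#' matrix with the total number of bulls used within each population on
#' the diagonal, common-bull counts above the diagonal and genetic
#' similarity coefficients below it.
#'
#' @param report A `connectedness_report`.
#' @return A tibble with a `population` label column followed by one
#'   column per population.
#' @export
format_gs_table <- function(report) {
  stopifnot(inherits(report, "connectedness_report"))
  pops <- report$populations
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  bl <- report$bulls_per_population
  diag(m) <- bl$bulls[match(pops, bl$population)]
  for (r in seq_len(nrow(report$pairwise))) {
    a <- report$pairwise$pop_a[r]; b <- report$pairwise$pop_b[r]
    m[a, b] <- report$pairwise$cb[r]
    m[b, a] <- report$pairwise$gs[r]
  }
  as_tibble(as.data.frame(m), rownames = "population")
}
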