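#' Random herd subsets ranked by genetic similarity
#'
#' Partitions the herds of the target population uniformly at random into
#' `n_subsets` groups. For each group, the mean pairwise genetic
#' similarity between the target population (restricted to the group's
#' herds) and every other population is computed, and the groups are
#' ranked on it.
#'
#' @inheritParams herd_gs
#' @param n_subsets Number of random groups (default 20).
#' @param top_k How many top-ranked subsets to flag as selected (default 3).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A tibble with one row per subset: `subset`, `herds`
#'   (list-column), `n_herds`, `records`, `mean_gs`, `rank`, `selected`.
#' @export
subset_random <- function(phen, ped, target_population, n_subsets = 20,
                          top_k = 3, seed = 1) {
  herds <- sort(unique(phen$herd[phen$population == target_population]))
  if (length(herds) < n_subsets) {
    abort("fewer target-population herds than requested subsets")
  }
  assignment <- .with_seed(seed, {
    sample(rep_len(seq_len(n_subsets), length(herds)))
  })
  groups <- split(herds, assignment)
  other <- phen %>% filter(.data$population != target_population)
  res <- purrr::map_dfr(seq_len(n_subsets), function(k) {
    hk <- groups[[k]]
    sub <- bind_rows(
      other,
      phen %>% filter(.data$population == target_population,
                      .data$herd %in% hk)
    )
    gs <- gs_pairwise(tally_sire_offspring(sub, ped),
                      sort(unique(phen$population))) %>%
      filter(.data$pop_a == target_population | .data$pop_b == target_population)
    tibble(
      subset = k,
      herds = list(hk),
      n_herds = length(hk),
      records = sum(phen$population == target_population & phen$herd %in% hk),
      mean_gs = mean(gs$gs, na.rm = TRUE)
    )
  })
  res %>%
    mutate(rank = rank(-.data$mean_gs, ties.method = "first"),
           selected = .data$rank <= top_k) %>%
    arrange(.data$rank)
}

# rank herds on a score and accumulate records until the target is first
# reached; ties broken by record count (descending) then herd id.
.select_herds <- function(scored, target_records = NULL, top_fraction = NULL) {
  ranked <- scored %>%
    mutate(score = ifelse(is.na(.data$score), -Inf, .data$score)) %>%
    arrange(dplyr::desc(.data$score), dplyr::desc(.data$records), .data$herd) %>%
    mutate(cum_records = cumsum(.data$records))
  if (!is.null(top_fraction)) {
    k <- max(1L, ceiling(top_fraction * nrow(ranked)))
    ranked$selected <- seq_len(nrow(ranked)) <= k
  } else {
    if (is.null(target_records)) abort("give target_records or top_fraction")
    if (target_records > sum(ranked$records)) {
      abort("target_records exceeds the target population's record count")
    }
    first_hit <- which(ranked$cum_records >= target_records)[1]
    ranked$selected <- seq_len(nrow(ranked)) <= first_hit
  }
  disconnected <- ranked$herd[ranked$selected &
                                (!is.finite(ranked$score) |
                                   ranked$score < 0.001)]
  if (length(disconnected) > 0) {
    warn(paste0(length(disconnected),
                " selected herd(s) are disconnected",
                " (genetic similarity below 0.001)"))
  }
  ranked
}

#' Select target-population herds by herd-level genetic similarity
#'
#' Herds are ranked on their average herd-level genetic similarity with
#' the other populations (missing pairs ignored): either the common-bull
#' coefficient alone (`ancestor = "cb"`) or the mean of the common-bull
#' and common-maternal-grand-sire coefficients (`ancestor = "tot"`).
#' Herds are then selected in rank order until the cumulative record count
#' first reaches `target_records`, or down to a `top_fraction` of herds.
#'
#' @inheritParams herd_gs
#' @param target_records Record count at which selection stops.
#' @param top_fraction Alternative stopping rule: select this fraction of
#'   the target population's herds (e.g. 0.01 for the top 1%).
#' @param ancestor `"cb"` or `"tot"`.
#' @return A tibble of all target herds with `score`, `records`,
#'   `cum_records` and logical `selected`, in rank order.
#' @export
subset_by_gs <- function(phen, ped, target_population, target_records = NULL,
                         top_fraction = NULL, ancestor = c("cb", "tot")) {
  ancestor <- match.arg(ancestor)
  g_cb <- herd_gs(phen, ped, target_population, "cb")
  if (ancestor == "tot") {
    g_cm <- herd_gs(phen, ped, target_population, "cmgs")
    g <- g_cb %>%
      left_join(g_cm %>% select("herd", "population", gs_cmgs = "gs"),
                by = c("herd", "population")) %>%
      mutate(gs = (.data$gs + .data$gs_cmgs) / 2)
  } else {
    g <- g_cb
  }
  scored <- g %>%
    group_by(.data$herd) %>%
    summarise(score = mean(.data$gs, na.rm = TRUE), .groups = "drop") %>%
    mutate(score = ifelse(is.nan(.data$score), NA_real_, .data$score)) %>%
    left_join(
      phen %>% filter(.data$population == target_population) %>%
        count(.data$herd, name = "records"),
      by = "herd"
    )
  .select_herds(scored, target_records, top_fraction)
}

#' Select target-population herds by herd-level harmonic mean
#'
#' As [subset_by_gs()] but ranking herds on their harmonic-mean
#' coefficient (sum over populations and common bulls of the harmonic
#' mean of progeny sizes).
#'
#' @inheritParams subset_by_gs
#' @export
subset_by_hm <- function(phen, ped, target_population, target_records = NULL,
                         top_fraction = NULL) {
  scored <- herd_harmonic_means(phen, ped, target_population) %>%
    rename(score = "hm") %>%
    left_join(
      phen %>% filter(.data$population == target_population) %>%
        count(.data$herd, name = "records"),
      by = "herd"
    )
  .select_herds(scored, target_records, top_fraction)
}

#' Finalize a data subset and re-prune the pedigree
#'
#' Keeps non-target populations whole, restricts the target population to
#' the selected herds (if any), optionally drops a whole population or
#' all records of animals born before a threshold year, and re-prunes the
#' pedigree to the phenotyped animals and all their ancestors.
#'
#' @inheritParams herd_gs
#' @param selected_herds Character vector of retained target-population
#'   herds, or `NULL` to keep the target population whole.
#' @param drop_population Population to exclude entirely, or `NULL`.
#' @param min_birth_year Drop records of animals born before this year, or
#'   `NULL`.
#' @return A list with the restricted `phenotypes` and re-pruned
#'   `pedigree`.
#' @export
finalize_subset <- function(phen, ped, target_population = NULL,
                            selected_herds = NULL, drop_population = NULL,
                            min_birth_year = NULL) {
  out <- phen
  if (!is.null(selected_herds) && !is.null(target_population)) {
    out <- out %>%
      filter(.data$population != target_population |
               .data$herd %in% selected_herds)
  }
  if (!is.null(drop_population)) {
    out <- out %>% filter(.data$population != drop_population)
  }
  if (!is.null(min_birth_year)) {
    by <- ped$birth_year[match(out$animal, ped$animal)]
    out <- out[is.na(by) | by >= min_birth_year, ]
  }
  list(
    phenotypes = out,
    pedigree = prune_pedigree(ped, unique(out$animal))
  )
}
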