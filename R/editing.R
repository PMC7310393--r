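#' Apply national data edits to a phenotype table
#'
#' Sequentially (1) drops records in contemporary groups smaller than the
#' population's national minimum size, (2) drops embryo-transfer flagged
#' records, and (3) drops records further than `outlier_sd` phenotypic
#' standard deviations from the phenotypic mean of their population-sex
#' combination, computed on the survivors of the first two filters.
#'
#' @param phen Phenotype tibble with columns `animal`, `population`,
#'   `sex`, `herd`, `contemporary_group`, `value` (and optionally an
#'   embryo-transfer flag column).
#' @param min_cg_size Named integer vector mapping population to its
#'   minimum contemporary-group size, or a single unnamed value applied to
#'   every population.
#' @param et_column Name of a logical embryo-transfer flag column, or
#'   `NULL` (no ET filter; ET status is rarely shareable).
#' @param outlier_sd Standard-deviation multiplier for the outlier filter
#'   (default 3). Population-sex cells with fewer than 3 survivors skip
#'   the filter (the standard deviation is not estimable).
#' @return A list with `data` (the edited tibble) and `log` (a tibble of
#'   per-filter removal counts).
#' @export
apply_data_edits <- function(phen, min_cg_size, et_column = NULL,
                             outlier_sd = 3) {
  stopifnot(is.data.frame(phen), outlier_sd > 0)
  pops <- unique(phen$population)
  if (!is.null(names(min_cg_size))) {
    unknown <- setdiff(pops, names(min_cg_size))
    if (length(unknown) > 0) {
      abort(paste0("populations without a minimum CG size: ",
                   paste(unknown, collapse = ", ")))
    }
    mins <- min_cg_size[phen$population]
  } else {
    stopifnot(length(min_cg_size) == 1)
    mins <- rep(min_cg_size, nrow(phen))
  }

  n0 <- nrow(phen)
  d1 <- phen %>%
    mutate(.min_cg = as.numeric(mins)) %>%
    group_by(.data$population, .data$contemporary_group) %>%
    filter(n() >= .data$.min_cg[1]) %>%
    ungroup() %>%
    select(-".min_cg")
  n1 <- nrow(d1)

  if (!is.null(et_column) && et_column %in% names(d1)) {
    d2 <- d1 %>% filter(!(.data[[et_column]] %in% TRUE))
  } else {
    d2 <- d1
  }
  n2 <- nrow(d2)

  d3 <- d2 %>%
    group_by(.data$population, .data$sex) %>%
    filter({
      if (n() < 3) rep(TRUE, n()) else {
        m <- mean(.data$value); s <- sd(.data$value)
        if (!is.finite(s) || s == 0) rep(TRUE, n()) else
          abs(.data$value - m) <= .env$outlier_sd * s
      }
    }) %>%
    ungroup()
  n3 <- nrow(d3)

  list(
    data = d3,
    log = tibble(
      filter = c("cg", "et", "outlier"),
      removed = c(n0 - n1, n1 - n2, n2 - n3)
    )
  )
}

# run code with a local RNG seed, restoring global RNG state afterwards
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
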