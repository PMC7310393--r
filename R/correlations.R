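#' Genetic correlation matrix from variance components
#'
#' Scales the genetic covariance block to correlations,
#' `r_kl = s_kl / sqrt(s_kk * s_ll)`, and reports whether the covariance
#' matrix is positive definite (it is checked, never bent).
#'
#' @param vc A [variance_components()] object, or a labelled symmetric
#'   covariance matrix.
#' @return A correlation matrix with attributes `positive_definite` and
#'   `populations` (when available).
#' @export
genetic_correlations <- function(vc) {
  G <- if (inherits(vc, "variance_components")) vc$genetic else as.matrix(vc)
  if (any(diag(G) <= 0)) abort("nonpositive genetic variance on the diagonal")
  R <- stats::cov2cor(G)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  attr(R, "positive_definite") <- min(ev) > 0
  if (inherits(vc, "variance_components")) {
    attr(R, "populations") <- vc$populations
  }
  R
}

# long form of the four across-country blocks of a 2P x 2P matrix whose
# labels are direct_<pop> then maternal_<pop>
.rg_blocks <- function(m, populations = NULL) {
  labs <- rownames(m)
  if (is.null(labs)) abort("matrix must carry direct_/maternal_ labels")
  if (is.null(populations)) {
    populations <- sub("^direct_", "", grep("^direct_", labs, value = TRUE))
  }
  P <- length(populations)
  stopifnot(nrow(m) == 2 * P)
  di <- match(paste0("direct_", populations), labs)
  mi <- match(paste0("maternal_", populations), labs)
  rows <- list()
  for (a in seq_len(P - 1)) {
    for (b in (a + 1):P) {
      rows[[length(rows) + 1]] <- tibble(
        block = "direct", pop_a = populations[a], pop_b = populations[b],
        value = m[di[a], di[b]]
      )
      rows[[length(rows) + 1]] <- tibble(
        block = "maternal", pop_a = populations[a], pop_b = populations[b],
        value = m[mi[a], mi[b]]
      )
    }
  }
  for (a in seq_len(P)) {
    for (b in seq_len(P)) {
      rows[[length(rows) + 1]] <- tibble(
        block = if (a == b) "direct_maternal_within" else
          "direct_maternal_between",
        pop_a = populations[a], pop_b = populations[b],
        value = m[di[a], mi[b]]
      )
    }
  }
  bind_rows(rows)
}

#' Block summary statistics of across-country genetic correlations
#'
#' Summarizes a labelled `2P x 2P` correlation matrix into the four
#' standard blocks: direct-direct off-diagonal (`P(P-1)/2` values),
#' maternal-maternal off-diagonal, direct-maternal within-country (`P`
#' values) and direct-maternal between-country (`P(P-1)` values, the two
#' directions counted separately). Standard errors, if supplied, are
#' summarized the same way.
#'
#' @param rg Labelled correlation matrix (labels `direct_<pop>`,
#'   `maternal_<pop>`), e.g. from [genetic_correlations()].
#' @param se Optional matching matrix of standard errors.
#' @param populations Optional explicit population order.
#' @return A tibble with columns `quantity` (`"rg"` and optionally
#'   `"se"`), `block`, `mean`, `min`, `max`, `n`.
#' @export
summarize_rg <- function(rg, se = NULL, populations = NULL) {
  one <- function(m, what) {
    .rg_blocks(m, populations) %>%
      group_by(.data$block) %>%
      summarise(mean = mean(.data$value), min = min(.data$value),
                max = max(.data$value), n = n(), .groups = "drop") %>%
      mutate(quantity = what, .before = 1)
  }
  out <- one(rg, "rg")
  if (!is.null(se)) out <- bind_rows(out, one(se, "se"))
  out %>%
    mutate(block = factor(.data$block,
                          levels = c("direct", "maternal",
                                     "direct_maternal_within",
                                     "direct_maternal_between"))) %>%
    arrange(.data$quantity, .data$block)
}

#' Deviation of one correlation summary from a reference
#'
#' Expresses a scenario's block statistics as deviations from a reference
#' summary (typically the full-data analysis), subtracting the reference
#' values.
#'
#' @param summary,reference Tibbles from [summarize_rg()].
#' @return A tibble of the same shape with differenced `mean`, `min`,
#'   `max`.
#' @export
rg_summary_deviation <- function(summary, reference) {
  inner_join(summary, reference, by = c("quantity", "block"),
             suffix = c("", "_ref")) %>%
    mutate(mean = .data$mean - .data$mean_ref,
           min = .data$min - .data$min_ref,
           max = .data$max - .data$max_ref) %>%
    select("quantity", "block", "mean", "min", "max", "n")
}

#' Read a printed-style correlation table
#'
#' Parses the standard reporting layout for a multi-population maternal
#' model: a square table with heritabilities on the diagonal, estimated
#' genetic correlations below the diagonal and their standard errors
#' above it, rows/columns ordered direct effects then maternal effects.
#'
#' @param path CSV file whose first column holds the row labels
#'   (`direct_<pop>` / `maternal_<pop>`).
#' @return A list with symmetric `rg` (unit diagonal), symmetric `se`
#'   (`NA` diagonal), the `h2` diagonal vector, and `populations`.
#' @export
read_rg_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), .default = readr::col_double()
  ))
  labs <- df$label
  m <- as.matrix(df[, -1])
  rownames(m) <- labs
  stopifnot(identical(colnames(m), labs))
  n <- nrow(m)
  rg <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  se <- rg
  lower <- lower.tri(m)
  rg[lower] <- m[lower]
  rg[upper.tri(rg)] <- t(rg)[upper.tri(rg)]
  diag(rg) <- 1
  se[upper.tri(se)] <- m[upper.tri(m)]
  se[lower.tri(se)] <- t(se)[lower.tri(se)]
  list(rg = rg, se = se, h2 = setNames(diag(m), labs),
       populations = sub("^direct_", "", grep("^direct_", labs, value = TRUE)))
}

#' Reference across-country correlation estimates for Limousin weaning weight
#'
#' The published full-data estimates for the eight European Limousin
#' populations of the international age-adjusted weaning-weight
#' evaluation: heritabilities, across-country genetic correlations for
#' direct and maternal effects, and their approximate standard errors.
#' Bundled as a worked example for [summarize_rg()].
#'
#' @return See [read_rg_table()].
#' @export
limousin_rg_reference <- function() {
  read_rg_table(system.file("extdata", "limousin_rg_full_data.csv",
                            package = "rgacross", mustWork = TRUE))
}

#' Format correlations, standard errors and heritabilities as one table
#'
#' The inverse of [read_rg_table()]: correlations below the diagonal,
#' standard errors above, heritabilities (or any supplied diagonal) on
#' the diagonal.
#'
#' @param rg Correlation matrix.
#' @param se Matching standard-error matrix (optional).
#' @param h2 Diagonal values (optional; defaults to `NA`).
#' @return A tibble with a `label` column followed by one column per
#'   effect-population combination.
#' @export
format_rg_table <- function(rg, se = NULL, h2 = NULL) {
  labs <- rownames(rg)
  m <- rg
  diag(m) <- if (is.null(h2)) NA_real_ else h2
  if (!is.null(se)) m[upper.tri(m)] <- se[upper.tri(se)]
  as_tibble(as.data.frame(m), rownames = "label")
}

#' Heritabilities from the variance components
#'
#' The phenotypic-variance denominator of a maternal-effects model is a
#' reporting convention rather than a single formula, so its composition
#' is explicit: direct and maternal genetic variances always enter;
#' the direct-maternal covariance, the maternal permanent environmental
#' variance and the extra random environmental variance are included or
#' excluded by flags.
#'
#' @param vc A [variance_components()] object.
#' @param include_dm_covariance Add the within-country direct-maternal
#'   covariance to the denominator (default `TRUE`).
#' @param include_pe Add the maternal permanent environmental variance
#'   where fitted (default `TRUE`).
#' @param include_extra Add the extra random environmental variance
#'   where fitted (default `FALSE`).
#' @return A tibble with columns `population`, `phenotypic_var`,
#'   `h2_direct`, `h2_maternal`.
#' @export
heritabilities <- function(vc, include_dm_covariance = TRUE,
                           include_pe = TRUE, include_extra = FALSE) {
  stopifnot(inherits(vc, "variance_components"))
  P <- length(vc$populations)
  out <- purrr::map_dfr(seq_len(P), function(i) {
    su <- vc$genetic[i, i]
    sm <- vc$genetic[P + i, P + i]
    sum_ <- su + sm + unname(vc$resid[i])
    if (include_dm_covariance) sum_ <- sum_ + vc$genetic[i, P + i]
    if (include_pe && !is.na(vc$pe[i])) sum_ <- sum_ + unname(vc$pe[i])
    if (include_extra && !is.na(vc$extra[i])) sum_ <- sum_ + unname(vc$extra[i])
    tibble(population = vc$populations[i], phenotypic_var = sum_,
           h2_direct = su / sum_, h2_maternal = sm / sum_)
  })
  out
}
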