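#' Run the full estimation pipeline
#'
#' Chains the analysis stages end to end: simulate (or accept) data,
#' apply the national edits, build the connectedness report, select a
#' data subset for the dominant population, estimate variance components
#' by Monte Carlo EM REML, optionally run the standard-error round, and
#' summarize the across-country genetic correlations. Artifacts are
#' written as CSV files when `out_dir` is given.
#'
#' @param phen,ped Phenotypes and pedigree (e.g. from
#'   [simulate_dataset()]).
#' @param specs National model specifications.
#' @param start_vc Starting [variance_components()].
#' @param settings [reml_settings()].
#' @param min_cg_size Passed to [apply_data_edits()].
#' @param strategy One of `"all"`, `"rnd"`, `"gscb"`, `"gstot"`, `"hm"`,
#'   `"drop_pop"`, `"min_year"`.
#' @param target_population Dominant population for sub-setting.
#' @param target_records Record target for the sub-setting strategies.
#' @param min_birth_year Threshold for `strategy = "min_year"`.
#' @param run_se Whether to run the standard-error round.
#' @param out_dir Output directory for CSV artifacts, or `NULL`.
#' @return A list with the edited data, the connectedness report, the
#'   subset, the fit, the SE object (or `NULL`), the correlation matrix
#'   and its block summary.
#' @export
run_pipeline <- function(phen, ped, specs, start_vc,
                         settings = reml_settings(),
                         min_cg_size = 1L,
                         strategy = c("all", "rnd", "gscb", "gstot", "hm",
                                      "drop_pop", "min_year"),
                         target_population = NULL, target_records = NULL,
                         min_birth_year = NULL, run_se = FALSE,
                         out_dir = NULL) {
  strategy <- match.arg(strategy)
  edited <- apply_data_edits(phen, min_cg_size)
  dat <- edited$data
  report <- connectedness_report(dat, ped,
                                 herd_population = target_population)

  sel <- NULL
  if (strategy %in% c("rnd", "gscb", "gstot", "hm") &&
      is.null(target_population)) {
    abort("sub-setting strategies need a target_population")
  }
  sub <- switch(
    strategy,
    all = list(phenotypes = dat, pedigree = prune_pedigree(ped, unique(dat$animal))),
    rnd = {
      rs <- subset_random(dat, ped, target_population, seed = settings$seed)
      sel <- unlist(rs$herds[rs$rank == 1])
      finalize_subset(dat, ped, target_population, sel)
    },
    gscb = {
      rs <- subset_by_gs(dat, ped, target_population,
                         target_records = target_records, ancestor = "cb")
      sel <- rs$herd[rs$selected]
      finalize_subset(dat, ped, target_population, sel)
    },
    gstot = {
      rs <- subset_by_gs(dat, ped, target_population,
                         target_records = target_records, ancestor = "tot")
      sel <- rs$herd[rs$selected]
      finalize_subset(dat, ped, target_population, sel)
    },
    hm = {
      rs <- subset_by_hm(dat, ped, target_population,
                         target_records = target_records)
      sel <- rs$herd[rs$selected]
      finalize_subset(dat, ped, target_population, sel)
    },
    drop_pop = finalize_subset(dat, ped, drop_population = target_population),
    min_year = finalize_subset(dat, ped, min_birth_year = min_birth_year)
  )

  fit <- run_mcem_reml(sub$phenotypes, sub$pedigree, specs, start_vc,
                       settings)
  se <- if (run_se) approximate_se(fit) else NULL
  rg <- genetic_correlations(fit$vc)
  summary <- summarize_rg(rg, se = if (is.null(se)) NULL else se$rg_se)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(edited$log, file.path(out_dir, "edit_log.csv"))
    readr::write_csv(report$pairwise, file.path(out_dir, "gs_pairwise.csv"))
    readr::write_csv(report$sires, file.path(out_dir, "sire_coefficients.csv"))
    readr::write_csv(fit$trajectory, file.path(out_dir, "reml_trajectory.csv"))
    readr::write_csv(tidy(fit), file.path(out_dir, "variance_components.csv"))
    readr::write_csv(
      format_rg_table(rg, se = if (is.null(se)) NULL else se$rg_se),
      file.path(out_dir, "rg_matrix.csv")
    )
    readr::write_csv(summary, file.path(out_dir, "rg_summary.csv"))
  }

  list(edited = edited, report = report, subset = sub,
       selected_herds = sel, fit = fit, se = se, rg = rg,
       summary = summary)
}
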