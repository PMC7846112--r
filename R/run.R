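#' Run the full family-study analysis end to end
#'
#' Orchestrates the whole pipeline in the order of the discovery strategy:
#' simulate (or load) a study, select sequencing subjects by kinship
#' (the most distant affected members as cases, the unaffected members
#' closest to them as controls), run the five-stage filtering cascade on the
#' sequenced subset, check co-segregation of the final candidates in the
#' fully genotyped pedigree, screen a simulated external replication cohort
#' for additional carriers of the top candidate, aggregate reference-panel
#' allele counts, and compare the plasma phenotypes between cases and
#' controls.
#'
#' @param config a \code{\link{sim_config}} describing the synthetic study;
#'   alternatively pass \code{study} directly.
#' @param study optional pre-built \code{famvar_study} (overrides
#'   \code{config}).
#' @param filter a \code{\link{filter_config}}.
#' @param n_cases,n_controls sequencing design (capped at the available
#'   affected/unaffected counts).
#' @param cohort_cases,cohort_controls external replication cohort sizes.
#' @param panel_table data frame of reference-panel counts for
#'   \code{\link{aggregate_panels}}; default is the panel table shipped with
#'   the package (a synthetic split whose totals match the published
#'   aggregate: 2 alternate alleles among 345,939 individuals).
#' @param out_dir optional directory; when given, the study files and a JSON
#'   report are written there.
#' @param verbose emit per-stage log messages.
#' @return object of class \code{"famvar_report"}: a list with the study,
#'   selected subjects, \code{cascade} (a \code{cascade_report}),
#'   \code{segregation} (ranked \code{segregation_result}),
#'   \code{cohort_screen}, \code{panel_aggregate}, \code{phenotype}
#'   (a \code{group_comparison}) and \code{provenance}.
#' @export
run_full_study <- function(config = sim_config(), study = NULL,
                           filter = filter_config(),
                           n_cases = 4L, n_controls = 2L,
                           cohort_cases = 6790L, cohort_controls = 5970L,
                           panel_table = NULL, out_dir = NULL,
                           verbose = FALSE) {
  if (is.null(study)) study <- simulate_study(config)
  ped <- study$pedigree
  n_aff <- sum(ped$status == "affected")
  n_unaff <- sum(ped$status == "unaffected")
  cases <- select_cases_for_sequencing(ped, min(n_cases, n_aff))
  controls <- select_controls_for_sequencing(ped, cases,
                                             min(n_controls, n_unaff))
  if (verbose) {
    message("WES cases: ", paste(cases, collapse = ", "),
            "; controls: ", paste(controls, collapse = ", "))
  }
  cascade <- run_cascade(study$variants, cases, controls, filter,
                         verbose = verbose)
  seg <- if (length(cascade$final_candidates)) {
    rank_candidates(check_cosegregation(study$variants, ped,
                                        cascade$final_candidates))
  } else {
    check_cosegregation(study$variants, ped, character(0))
  }

  # external replication cohort: carriers of the top candidate at its true
  # population frequency (the planted allele is essentially private)
  af_cohort <- study$config$causal_spec$panel_afs[[1]]
  n_cohort <- cohort_cases + cohort_controls
  cohort_geno <- stats::setNames(stats::rbinom(n_cohort, 2L, af_cohort),
                                 paste0("ext", seq_len(n_cohort)))
  cohort_status <- stats::setNames(rep(c("case", "control"),
                                       c(cohort_cases, cohort_controls)),
                                   names(cohort_geno))
  screen <- screen_cohort(cohort_geno, cohort_status, "replication")

  if (is.null(panel_table)) {
    panel_table <- read_panel_table(system.file("extdata",
                                                "synthetic_reference_panels.tsv",
                                                package = "famvar"))
  }
  agg <- aggregate_panels(panel_table)
  pheno <- compare_all(study$plasma)

  report <- structure(list(
    study = study, cases = cases, controls = controls, cascade = cascade,
    segregation = seg, cohort_screen = screen, panel_aggregate = agg,
    phenotype = pheno,
    provenance = list(seed = study$config$seed,
                      package_version = as.character(utils::packageVersion("famvar")),
                      r_version = R.version.string,
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "famvar_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_study(study, out_dir)
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a report to JSON
#'
#' @param report a \code{famvar_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(
    provenance = report$provenance,
    design = list(cases = report$cases, controls = report$controls),
    cascade = list(stages = report$cascade$stages,
                   final_candidates = report$cascade$final_candidates),
    segregation = as.data.frame(report$segregation),
    cohort_screen = unclass(report$cohort_screen),
    panel_aggregate = list(
      total_individuals = report$panel_aggregate$total_individuals,
      total_alt_alleles = report$panel_aggregate$total_alt_alleles,
      allele_frequency = report$panel_aggregate$allele_frequency),
    phenotype = as.data.frame(report$phenotype)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.famvar_report <- function(x, ...) {
  cat("Family rare-variant study report (seed ", x$provenance$seed, ")\n",
      sep = "")
  cat("WES design: cases ", paste(x$cases, collapse = ", "), "; controls ",
      paste(x$controls, collapse = ", "), "\n", sep = "")
  print(x$cascade)
  print(x$segregation)
  print(x$cohort_screen)
  print(x$panel_aggregate)
  print(x$phenotype)
  invisible(x)
}

#' Build a run configuration from a YAML file
#'
#' The YAML may contain \code{simulation}, \code{filter} and \code{run}
#' blocks whose keys override the corresponding argument defaults of
#' \code{\link{sim_config}}, \code{\link{filter_config}} and
#' \code{\link{run_full_study}}.
#'
#' @param path YAML file path.
#' @return list with elements \code{simulation} (\code{sim_config}),
#'   \code{filter} (\code{filter_config}) and \code{run} (named list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$simulation %||% list())
  flt <- do.call(filter_config, raw$filter %||% list())
  list(simulation = sim, filter = flt, run = raw$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
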