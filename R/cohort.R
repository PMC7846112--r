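#' Screen a candidate variant in an external cohort
#'
#' Counts carriers (alt-allele count >= 1) among cases and controls of a
#' genotyped replication cohort. Individuals with missing genotypes are
#' excluded from the denominators and reported.
#'
#' @param genotypes named integer vector of alt-allele counts (\code{NA} =
#'   missing), one per individual.
#' @param status named character vector (\code{"case"} / \code{"control"})
#'   over the same ids.
#' @param name cohort label.
#' @return object of class \code{"cohort_screen"}: \code{cohort_name,
#'   n_cases, n_controls, case_carriers, control_carriers, missing}.
#' @export
screen_cohort <- function(genotypes, status, name = "cohort") {
  if (!length(genotypes)) {
    warning("screen_cohort: empty cohort '", name, "'")
    return(structure(list(cohort_name = name, n_cases = 0L, n_controls = 0L,
                          case_carriers = 0L, control_carriers = 0L,
                          missing = 0L), class = "cohort_screen"))
  }
  status <- status[names(genotypes)]
  ok <- !is.na(genotypes)
  g <- genotypes[ok]; s <- status[ok]
  structure(list(cohort_name = name,
                 n_cases = sum(s == "case"),
                 n_controls = sum(s == "control"),
                 case_carriers = sum(g >= 1L & s == "case"),
                 control_carriers = sum(g >= 1L & s == "control"),
                 missing = sum(!ok)),
            class = "cohort_screen")
}

#' @export
print.cohort_screen <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d/%d case carriers, %d/%d control carriers (%d missing)\n",
              x$cohort_name, x$case_carriers, x$n_cases, x$control_carriers,
              x$n_controls, x$missing))
  invisible(x)
}

#' Aggregate allele counts across reference panels
#'
#' Sums individuals and alternate-allele counts over panels and reports the
#' aggregate allele frequency with a diploid denominator: frequency =
#' total alt alleles / (2 x total individuals).
#'
#' @param panels data frame with columns \code{name}, \code{n_individuals},
#'   \code{alt_allele_count}.
#' @return object of class \code{"panel_aggregate"}: the panel table plus
#'   \code{total_individuals}, \code{total_alt_alleles},
#'   \code{allele_frequency}.
#' @export
aggregate_panels <- function(panels) {
  stopifnot(all(c("name", "n_individuals", "alt_allele_count")
                %in% names(panels)))
  if (any(panels$n_individuals < 0) || any(panels$alt_allele_count < 0)) {
    stop("aggregate_panels: counts must be non-negative")
  }
  if (any(panels$alt_allele_count > 2 * panels$n_individuals)) {
    stop("aggregate_panels: alt allele count exceeds 2 x individuals")
  }
  ti <- sum(panels$n_individuals)
  ta <- sum(panels$alt_allele_count)
  structure(list(panels = panels, total_individuals = ti,
                 total_alt_alleles = ta,
                 allele_frequency = if (ti > 0) ta / (2 * ti) else NA_real_),
            class = "panel_aggregate")
}

#' Read a reference-panel count table
#'
#' TSV with header columns \code{name}, \code{n_individuals},
#' \code{alt_allele_count}.
#'
#' @param path path to the TSV.
#' @return data frame suitable for \code{\link{aggregate_panels}}.
#' @export
read_panel_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @export
print.panel_aggregate <- function(x, ...) {
  cat("Reference-panel aggregate: ", x$total_alt_alleles,
      " alt allele(s) in ", x$total_individuals,
      " individuals (2N = ", 2 * x$total_individuals, ")\n", sep = "")
  cat("  allele frequency = ", format(x$allele_frequency, digits = 6),
      " (diploid denominator)\n", sep = "")
  invisible(x)
}
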