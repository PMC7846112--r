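#' Filtering-cascade configuration
#'
#' Defaults reproduce the dominant-model exome strategy: keep likely
#' functional classes (stop gain/loss, frameshift indel, nonsynonymous,
#' splicing), require every reported reference-panel frequency below 1
#' per mille, and require deleteriousness by all three in-silico tools
#' (SIFT deleterious, PolyPhen probably damaging, CADD PHRED >= 20).
#'
#' @param functional_classes functional classes retained.
#' @param max_panel_af rarity threshold applied to the maximum frequency
#'   across panels reporting the variant.
#' @param require_sift_deleterious,require_polyphen_damaging,min_cadd
#'   deleteriousness criteria; each may be disabled (\code{FALSE} /
#'   \code{-Inf}).
#' @param unknown_prediction_policy \code{"keep"}: an unknown prediction does
#'   not fail its criterion; \code{"drop"}: it does.
#' @param missing_genotype_policy \code{"strict"}: a missing case genotype
#'   cannot confirm sharing, so the variant is dropped; \code{"permissive"}:
#'   missing case genotypes are ignored. A missing control genotype never
#'   excludes (it cannot confirm carriage).
#' @return object of class \code{"filter_config"}.
#' @export
filter_config <- function(functional_classes = c("stop_gain", "stop_loss",
                                                 "frameshift_indel",
                                                 "nonsynonymous", "splicing"),
                          max_panel_af = 0.001,
                          require_sift_deleterious = TRUE,
                          require_polyphen_damaging = TRUE,
                          min_cadd = 20,
                          unknown_prediction_policy = c("keep", "drop"),
                          missing_genotype_policy = c("strict", "permissive")) {
  if (max_panel_af < 0 || max_panel_af > 1) {
    stop("filter_config: max_panel_af must lie in [0, 1]")
  }
  structure(list(functional_classes = functional_classes,
                 max_panel_af = max_panel_af,
                 require_sift_deleterious = require_sift_deleterious,
                 require_polyphen_damaging = require_polyphen_damaging,
                 min_cadd = min_cadd,
                 unknown_prediction_policy = match.arg(unknown_prediction_policy),
                 missing_genotype_policy = match.arg(missing_genotype_policy)),
            class = "filter_config")
}

check_sample_ids <- function(x, ids, what) {
  miss <- setdiff(ids, colnames(x$geno))
  if (length(miss)) {
    stop(what, " id(s) absent from genotype map: ",
         paste(miss, collapse = ", "))
  }
  if (!length(ids)) stop(what, " ids must be non-empty")
}

#' Keep variants carried by every case
#'
#' A case is a carrier when its alt-allele count is >= 1 (dominant model).
#' Under \code{policy = "strict"} a missing case genotype excludes the
#' variant (sharing cannot be confirmed); under \code{"permissive"} that
#' case is ignored.
#'
#' @param x an \code{annotated_variants} object.
#' @param cases case sample ids.
#' @param policy missing-genotype policy.
#' @return the surviving subset.
#' @export
filter_shared_by_cases <- function(x, cases, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  check_sample_ids(x, cases, "case")
  g <- x$geno[, cases, drop = FALSE]
  carrier <- g >= 1L
  if (policy == "strict") carrier[is.na(carrier)] <- FALSE
  else carrier[is.na(carrier)] <- TRUE
  x[rowSums(carrier) == length(cases)]
}

#' Drop variants carried by any control
#'
#' A missing control genotype never excludes a variant: carriage cannot be
#' confirmed, so the control is treated as a non-carrier under both
#' policies.
#'
#' @inheritParams filter_shared_by_cases
#' @param controls control sample ids.
#' @return the surviving subset.
#' @export
filter_absent_in_controls <- function(x, controls,
                                      policy = c("strict", "permissive")) {
  match.arg(policy)
  check_sample_ids(x, controls, "control")
  g <- x$geno[, controls, drop = FALSE]
  carrier <- g >= 1L
  carrier[is.na(carrier)] <- FALSE
  x[rowSums(carrier) == 0L]
}

#' Keep likely functional variants
#'
#' @param x an \code{annotated_variants} object.
#' @param config a \code{\link{filter_config}}.
#' @return the surviving subset.
#' @export
filter_functional <- function(x, config = filter_config()) {
  x[x$ann$functional_class %in% config$functional_classes]
}

#' Keep reference-panel-rare variants
#'
#' A variant survives when its maximum allele frequency across the panels
#' that report it is below \code{max_panel_af}. A variant absent from every
#' panel is kept: absence of evidence of commonness must not exclude a
#' candidate (the typical causal variant is precisely the one the panels
#' have never seen).
#'
#' @inheritParams filter_functional
#' @return the surviving subset.
#' @export
filter_rare <- function(x, config = filter_config()) {
  if (ncol(x$panel_af) == 0L) return(x)
  max_af <- apply(x$panel_af, 1L, function(a) {
    if (all(is.na(a))) -Inf else max(a, na.rm = TRUE)
  })
  x[max_af < config$max_panel_af]
}

#' Keep variants predicted deleterious
#'
#' All enabled criteria must hold (SIFT deleterious; PolyPhen probably
#' damaging; CADD PHRED >= \code{min_cadd}). An unknown prediction passes
#' its criterion under \code{unknown_prediction_policy = "keep"} and fails
#' it under \code{"drop"}.
#'
#' @inheritParams filter_functional
#' @return the surviving subset.
#' @export
filter_deleterious <- function(x, config = filter_config()) {
  keep_unknown <- config$unknown_prediction_policy == "keep"
  ok <- rep(TRUE, n_variants(x))
  if (isTRUE(config$require_sift_deleterious)) {
    s <- x$ann$sift
    ok <- ok & ifelse(s == "unknown", keep_unknown, s == "deleterious")
  }
  if (isTRUE(config$require_polyphen_damaging)) {
    p <- x$ann$polyphen
    ok <- ok & ifelse(p == "unknown", keep_unknown, p == "probably_damaging")
  }
  if (is.finite(config$min_cadd)) {
    cd <- x$ann$cadd_phred
    ok <- ok & ifelse(is.na(cd), keep_unknown, cd >= config$min_cadd)
  }
  x[ok]
}

#' Run the five-stage dominant-model filtering cascade
#'
#' Applies, in order: shared-by-all-cases, absent-in-all-controls,
#' functional class, reference-panel rarity, in-silico deleteriousness.
#' The order is the narrative order of the strategy being reproduced; the
#' last three filters are pure per-variant predicates and commute.
#'
#' @param x an \code{annotated_variants} object (non-empty).
#' @param cases,controls sample ids of the sequenced cases and controls.
#' @param config a \code{\link{filter_config}}.
#' @param verbose emit one message per stage with input/output counts.
#' @return object of class \code{"cascade_report"}: \code{stages} (data
#'   frame of name/input_count/output_count), \code{survivors} (list of id
#'   vectors per stage), \code{final_candidates} (id vector) and
#'   \code{final} (the surviving \code{annotated_variants}).
#' @export
run_cascade <- function(x, cases, controls, config = filter_config(),
                        verbose = FALSE) {
  if (n_variants(x) == 0L) stop("run_cascade: empty variant set")
  stages <- list(
    shared_by_cases = function(v) filter_shared_by_cases(
      v, cases, config$missing_genotype_policy),
    absent_in_controls = function(v) filter_absent_in_controls(
      v, controls, config$missing_genotype_policy),
    functional = function(v) filter_functional(v, config),
    rare = function(v) filter_rare(v, config),
    deleterious = function(v) filter_deleterious(v, config)
  )
  cur <- x
  rows <- list(); survivors <- list()
  for (nm in names(stages)) {
    n_in <- n_variants(cur)
    cur <- stages[[nm]](cur)
    rows[[nm]] <- data.frame(name = nm, input_count = n_in,
                             output_count = n_variants(cur),
                             stringsAsFactors = FALSE)
    survivors[[nm]] <- variant_ids(cur)
    if (verbose) {
      message("cascade stage ", nm, ": ", n_in, " -> ", n_variants(cur))
    }
  }
  structure(list(stages = do.call(rbind, c(rows, make.row.names = FALSE)),
                 survivors = survivors,
                 final_candidates = variant_ids(cur),
                 final = cur),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Filtering cascade:\n")
  for (r in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-20s %7d -> %7d\n", x$stages$name[r],
                x$stages$input_count[r], x$stages$output_count[r]))
  }
  cat("final candidates (", length(x$final_candidates), "): ",
      paste(utils::head(x$final_candidates, 10), collapse = ", "),
      if (length(x$final_candidates) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}
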