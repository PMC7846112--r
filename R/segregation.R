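#' Check co-segregation of variants with affection status
#'
#' For each variant, counts carriers (alt-allele count >= 1; heterozygous
#' and homozygous alike, dominant model) among affected and unaffected
#' pedigree members. Members with unknown status or a missing genotype are
#' excluded from the totals and reported. A variant co-segregates perfectly
#' when every counted case is a carrier and no counted control is.
#'
#' @param x an \code{annotated_variants} object.
#' @param ped a \code{fam_pedigree}; members absent from the genotype map
#'   are counted as missing.
#' @param ids variant ids to check (default: all).
#' @return data frame of class \code{"segregation_result"}, one row per
#'   variant: \code{variant_id, case_carriers, case_total, control_carriers,
#'   control_total, missing_cases, missing_controls, cosegregates,
#'   discordant_ids} (comma-separated non-carrier cases and carrier
#'   controls).
#' @export
check_cosegregation <- function(x, ped, ids = variant_ids(x)) {
  cases <- ped$id[ped$status == "affected"]
  controls <- ped$id[ped$status == "unaffected"]
  out <- lapply(ids, function(id) {
    g <- x$geno[match(id, x$sites$id), ]
    gc <- g[intersect(cases, names(g))]
    gu <- g[intersect(controls, names(g))]
    missing_cases <- union(setdiff(cases, names(g)), names(gc)[is.na(gc)])
    missing_controls <- union(setdiff(controls, names(g)),
                              names(gu)[is.na(gu)])
    gc <- gc[!is.na(gc)]
    gu <- gu[!is.na(gu)]
    if (length(gc) + length(gu) == 0L) {
      warning("variant ", id, ": no genotyped member with known status")
    }
    case_car <- sum(gc >= 1L)
    ctrl_car <- sum(gu >= 1L)
    coseg <- length(gc) > 0L && case_car == length(gc) && ctrl_car == 0L
    disc <- sort(c(names(gc)[gc == 0L], names(gu)[gu >= 1L]))
    data.frame(variant_id = id,
               case_carriers = case_car, case_total = length(gc),
               control_carriers = ctrl_car, control_total = length(gu),
               missing_cases = length(missing_cases),
               missing_controls = length(missing_controls),
               cosegregates = coseg,
               discordant_ids = paste(disc, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("segregation_result", "data.frame")
  res
}

#' Rank candidate variants by segregation evidence
#'
#' Perfectly co-segregating variants first; within each group, descending
#' difference between the case carrier rate and the control carrier rate
#' (rates are 0 when the corresponding total is 0); ties broken by variant
#' id.
#'
#' @param results a \code{segregation_result} data frame.
#' @return the same rows, reordered.
#' @export
rank_candidates <- function(results) {
  if (nrow(results) == 0L) return(results)
  case_rate <- ifelse(results$case_total > 0,
                      results$case_carriers / results$case_total, 0)
  ctrl_rate <- ifelse(results$control_total > 0,
                      results$control_carriers / results$control_total, 0)
  res <- results[order(-results$cosegregates, -(case_rate - ctrl_rate),
                       results$variant_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("Co-segregation over the genotyped pedigree:\n")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("  %s: cases %d/%d, controls %d/%d -> %s%s\n",
                x$variant_id[r], x$case_carriers[r], x$case_total[r],
                x$control_carriers[r], x$control_total[r],
                if (x$cosegregates[r]) "co-segregates" else "discordant",
                if (nzchar(x$discordant_ids[r]))
                  paste0(" (", x$discordant_ids[r], ")") else ""))
  }
  invisible(x)
}
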