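#' Summary statistics for one group
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error of
#' the mean (sd / sqrt(n)). With a single observation the SD and SEM are
#' undefined and reported as \code{NA}.
#'
#' @param values numeric vector (n >= 1, finite).
#' @return list with \code{n, mean, sd, sem}.
#' @export
summarize_group <- function(values) {
  if (!length(values)) stop("summarize_group: empty group")
  if (any(!is.finite(values))) stop("summarize_group: non-finite values")
  n <- length(values)
  s <- if (n > 1L) stats::sd(values) else NA_real_
  list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

#' Exact Mann-Whitney U test
#'
#' U is computed from mid-rank sums of the pooled sample. When
#' \code{choose(n1 + n2, n1)} does not exceed \code{max_enumeration}, the
#' two-sided p-value is computed by exhaustive enumeration of all
#' assignments of the pooled observed values into groups of sizes n1 and n2
#' (tie-correct by construction): p = P(|U - n1 n2 / 2| >= observed
#' deviation) under the permutation null. Because the permutation
#' distribution of U is symmetric about n1 n2 / 2 under label swap, this
#' equals symmetric tail doubling capped at 1. Larger problems fall back to
#' the normal approximation with tie-corrected variance and continuity
#' correction, flagged in \code{method}.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param max_enumeration largest number of assignments enumerated exactly.
#' @return list with \code{U} (statistic for \code{x}), \code{p_two_sided}
#'   and \code{method} (\code{"exact_enumeration"} or
#'   \code{"normal_approx"}).
#' @export
mann_whitney_exact <- function(x, y, max_enumeration = 1e6) {
  if (!length(x) || !length(y)) {
    stop("mann_whitney_exact: both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  d_obs <- abs(U_obs - mu)
  if (choose(n, n1) <= max_enumeration) {
    idx <- utils::combn(n, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    U_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(U_all - mu) >= d_obs - 1e-9)
    list(U = U_obs, p_two_sided = p, method = "exact_enumeration")
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(list(U = U_obs, p_two_sided = 1, method = "normal_approx"))
    }
    z <- max(d_obs - 0.5, 0) / sqrt(sigma2)
    list(U = U_obs, p_two_sided = min(1, 2 * stats::pnorm(-z)),
         method = "normal_approx")
  }
}

#' Compare every plasma parameter between cases and controls
#'
#' For each parameter in a long-format plasma panel (\code{subject_id,
#' status, parameter, value, units}), computes per-group n / mean / SD / SEM
#' and the exact Mann-Whitney two-sided p-value. Parameters with fewer than
#' 2 subjects in either group are flagged untestable (summaries are still
#' reported; U and p are \code{NA}).
#'
#' @param panel long-format plasma data frame.
#' @return data frame of class \code{"group_comparison"}, one row per
#'   parameter.
#' @export
compare_all <- function(panel) {
  cols <- c("subject_id", "status", "parameter", "value")
  stopifnot(all(cols %in% names(panel)))
  if (anyDuplicated(panel[, c("subject_id", "parameter")])) {
    stop("compare_all: duplicated (subject, parameter) measurement")
  }
  params <- unique(panel$parameter)
  if (!length(params)) {
    res <- data.frame(parameter = character(0), units = character(0),
                      case_n = integer(0), case_mean = numeric(0),
                      case_sd = numeric(0), case_sem = numeric(0),
                      control_n = integer(0), control_mean = numeric(0),
                      control_sd = numeric(0), control_sem = numeric(0),
                      U = numeric(0), p_two_sided = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
    class(res) <- c("group_comparison", "data.frame")
    return(res)
  }
  rows <- lapply(params, function(p) {
    sub <- panel[panel$parameter == p, ]
    xs <- sub$value[sub$status == "case"]
    ys <- sub$value[sub$status == "control"]
    sx <- if (length(xs)) summarize_group(xs) else list(n = 0L, mean = NA,
                                                        sd = NA, sem = NA)
    sy <- if (length(ys)) summarize_group(ys) else list(n = 0L, mean = NA,
                                                        sd = NA, sem = NA)
    testable <- length(xs) >= 2L && length(ys) >= 2L
    mw <- if (testable) mann_whitney_exact(xs, ys) else
      list(U = NA_real_, p_two_sided = NA_real_, method = "untestable")
    data.frame(parameter = p,
               units = if ("units" %in% names(sub)) sub$units[1] else NA,
               case_n = sx$n, case_mean = sx$mean, case_sd = sx$sd,
               case_sem = sx$sem,
               control_n = sy$n, control_mean = sy$mean, control_sd = sy$sd,
               control_sem = sy$sem,
               U = mw$U, p_two_sided = mw$p_two_sided, method = mw$method,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' @export
print.group_comparison <- function(x, digits = 1, ...) {
  cat("Case/control plasma comparison (mean +/- SEM, exact Mann-Whitney):\n")
  for (r in seq_len(nrow(x))) {
    cat(sprintf("  %-16s cases %s +/- %s (n=%d) vs controls %s +/- %s (n=%d)%s\n",
                x$parameter[r],
                round(x$case_mean[r], digits), round(x$case_sem[r], digits),
                x$case_n[r],
                round(x$control_mean[r], digits),
                round(x$control_sem[r], digits), x$control_n[r],
                if (x$method[r] == "untestable") " [untestable]"
                else sprintf(", p = %.4g", x$p_two_sided[r])))
  }
  invisible(x)
}

#' Strip plot of plasma values by group
#'
#' One panel per parameter, cases and controls side by side, in the style of
#' the usual per-parameter family plots.
#'
#' @param x a long-format plasma panel (as in \code{\link{compare_all}}).
#' @param parameters parameters to plot (default: all).
#' @param ... passed to \code{stripchart}.
#' @return invisibly, \code{x}.
#' @export
plot_plasma <- function(x, parameters = unique(x$parameter), ...) {
  old <- graphics::par(mfrow = c(1, length(parameters)))
  on.exit(graphics::par(old))
  for (p in parameters) {
    sub <- x[x$parameter == p, ]
    graphics::stripchart(value ~ factor(status, c("case", "control")),
                         data = sub, vertical = TRUE, method = "jitter",
                         pch = 19, main = p,
                         ylab = if ("units" %in% names(sub)) sub$units[1]
                                else "value", ...)
  }
  invisible(x)
}

#' Measured plasma coagulation panel of the study family
#'
#' The coagulation and fibrinolysis parameters measured in the 10 family
#' members with citrated plasma available (3 VTE cases, all on
#' vitamin K antagonists at sampling, and 7 unaffected controls):
#' prothrombin time, INR, aPTT, fibrinogen, factors II/V/X, free TFPI and
#' PAI-1 activity. Long format, one row per (subject, parameter).
#'
#' @return data frame with columns \code{subject_id, status, parameter,
#'   value, units}.
#' @export
family_plasma <- function() {
  subjects <- c("305000", "305001", "305002", "305004", "305006", "305007",
                "305010", "305013", "305014", "305015")
  status <- c("case", "case", "case", rep("control", 7))
  wide <- list(
    "PT"         = list(c(30, 26, 33, 98, 93, 100, 114, 104, 98, 106), "%"),
    "INR"        = list(c(2.55, 2.88, 2.29, 1.01, 1.04, 1, 0.93, 0.98, 1.01,
                          0.97), "ratio"),
    "aPTT"       = list(c(49.5, 46.7, 40.1, 32.4, 39, 35.4, 34.3, 35.1, 33.9,
                          37.8), "sec"),
    "Fibrinogen" = list(c(4.16, 4.3, 3.87, 4.93, 1.97, 2.62, 3.17, 3.13, 2.66,
                          3.26), "g/L"),
    "FII"        = list(c(27, 18, 29, 99, 82, 107, 103, 97, 102, 95), "%"),
    "FV"         = list(c(64, 76, 96, 86, 91, 75, 117, 95, 102, 91), "%"),
    "FX"         = list(c(13, 9, 14, 105, 96, 122, 102, 90, 98, 95), "%"),
    "f-TFPI"     = list(c(7.4, 2.9, 9.5, 17.2, 17.7, 15.1, 17.1, 21.9, 20.7,
                          12.3), "ng/mL"),
    "PAI-1"      = list(c(15, 16, 34, 1, 4, 1, 2, 4, 5, 6), "IU/mL")
  )
  do.call(rbind, lapply(names(wide), function(p) {
    data.frame(subject_id = subjects, status = status, parameter = p,
               value = wide[[p]][[1]], units = wide[[p]][[2]],
               stringsAsFactors = FALSE)
  }))
}
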