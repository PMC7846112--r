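# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (scalar loops, explicit enumeration, Monte Carlo) kept free
# of the package's own code paths.

# Monte-Carlo kinship by gene-dropping uniquely labelled founder alleles:
# phi(i, j) is estimated as the probability that one allele drawn from i and
# one from j carry the same founder label. Returns the estimate matrix and
# its per-pair standard errors.
mc_kinship <- function(ped, n_drops = 200000L) {
  ord <- famvar:::pedigree_order(ped)
  n <- nrow(ped)
  a1 <- a2 <- matrix(0L, n_drops, n, dimnames = list(NULL, ped$id))
  lab <- 0L
  for (i in ord) {
    id <- ped$id[i]
    if (is.na(ped$father[i])) {
      a1[, id] <- lab + 1L
      a2[, id] <- lab + 2L
      lab <- lab + 2L
    } else {
      f <- ped$father[i]; m <- ped$mother[i]
      pf <- stats::runif(n_drops) < 0.5
      pm <- stats::runif(n_drops) < 0.5
      a1[, id] <- ifelse(pf, a1[, f], a2[, f])
      a2[, id] <- ifelse(pm, a1[, m], a2[, m])
    }
  }
  est <- se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
                (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
      est[i, j] <- est[j, i] <- mean(share)
      se[i, j] <- se[j, i] <- stats::sd(share) / sqrt(n_drops)
    }
  }
  list(est = est, se = se)
}

# Exhaustive subset selection scored by an arbitrary function; first optimum
# in lexicographic order of the sorted ids.
enumerate_best <- function(ids, k, score, minimize = TRUE) {
  subsets <- utils::combn(sort(ids), k, simplify = FALSE)
  vals <- vapply(subsets, score, numeric(1))
  subsets[[if (minimize) which.min(vals) else which.max(vals)]]
}

# Single-pass brute-force evaluation of the full cascade predicate for one
# variant, written directly from the filter definitions.
brute_force_survivors <- function(x, cases, controls, config) {
  keep <- logical(famvar::n_variants(x))
  for (r in seq_along(keep)) {
    g <- x$geno[r, ]
    shared <- TRUE
    for (cs in cases) {
      gc <- g[[cs]]
      if (is.na(gc)) {
        if (config$missing_genotype_policy == "strict") shared <- FALSE
      } else if (gc < 1) shared <- FALSE
    }
    carried <- FALSE
    for (ct in controls) {
      gc <- g[[ct]]
      if (!is.na(gc) && gc >= 1) carried <- TRUE
    }
    functional <- x$ann$functional_class[r] %in% config$functional_classes
    afs <- x$panel_af[r, ]
    rare <- if (length(afs) == 0 || all(is.na(afs))) TRUE
            else max(afs, na.rm = TRUE) < config$max_panel_af
    unk_ok <- config$unknown_prediction_policy == "keep"
    del <- TRUE
    if (isTRUE(config$require_sift_deleterious)) {
      del <- del && (if (x$ann$sift[r] == "unknown") unk_ok
                     else x$ann$sift[r] == "deleterious")
    }
    if (isTRUE(config$require_polyphen_damaging)) {
      del <- del && (if (x$ann$polyphen[r] == "unknown") unk_ok
                     else x$ann$polyphen[r] == "probably_damaging")
    }
    if (is.finite(config$min_cadd)) {
      del <- del && (if (is.na(x$ann$cadd_phred[r])) unk_ok
                     else x$ann$cadd_phred[r] >= config$min_cadd)
    }
    keep[r] <- shared && !carried && functional && rare && del
  }
  famvar::variant_ids(x)[keep]
}

# Random annotated variant fixture with missing genotypes, unknown
# predictions and panel dropouts.
random_variants <- function(n, samples, panels = c("p1", "p2"),
                            na_rate = 0.05) {
  geno <- matrix(sample(c(0L, 0L, 0L, 1L, 1L, 2L, NA),
                        n * length(samples), replace = TRUE),
                 n, length(samples), dimnames = list(NULL, samples))
  af <- matrix(stats::runif(n * length(panels), 0, 0.02), n, length(panels),
               dimnames = list(NULL, panels))
  af[stats::runif(length(af)) < 0.3] <- NA
  sites <- data.frame(id = sprintf("v%04d", seq_len(n)),
                      chrom = sample(as.character(1:5), n, replace = TRUE),
                      pos = sample.int(1e6, n), ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  ann <- data.frame(
    functional_class = sample(famvar:::FUNCTIONAL_CLASSES, n, replace = TRUE),
    sift = sample(famvar:::SIFT_LEVELS, n, replace = TRUE),
    polyphen = sample(famvar:::POLYPHEN_LEVELS, n, replace = TRUE),
    cadd_phred = ifelse(stats::runif(n) < 0.15, NA, stats::runif(n, 0, 40)),
    stringsAsFactors = FALSE)
  famvar::annotated_variants(sites, geno, ann, af)
}

# Write a PED file for a pedigree-like data frame of raw PED fields.
write_ped_lines <- function(lines) {
  path <- tempfile(fileext = ".ped")
  writeLines(lines, path)
  path
}

# Small nuclear pedigree: two founder parents, two children.
nuclear_pedigree <- function() {
  famvar::pedigree(
    id = c("f", "m", "c1", "c2"),
    father = c(NA, NA, "f", "f"),
    mother = c(NA, NA, "m", "m"),
    sex = c("male", "female", "female", "male"),
    status = c("unaffected", "affected", "affected", "unaffected"),
    name = "nuclear")
}
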