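#' Default plasma phenotype model
#'
#' Per-parameter case/control means and SDs used to simulate plasma values.
#' f-TFPI and PAI-1 moments are the sample moments of the measured
#' 10-subject family panel (3 cases, 7 controls); ECLT moments come from the
#' reported group summaries (mean +/- SEM, converted to SDs with n = 3 and
#' n = 7); uPA and thrombomodulin showed no case/control difference, so both
#' groups share one plausible mean/SD.
#'
#' @return data frame with columns \code{parameter, units, case_mean,
#'   case_sd, control_mean, control_sd}.
#' @export
default_plasma_model <- function() {
  data.frame(
    parameter = c("f-TFPI", "PAI-1", "ECLT", "uPA", "thrombomodulin"),
    units = c("ng/mL", "IU/mL", "min", "ng/mL", "ng/mL"),
    case_mean = c(6.6, 65 / 3, 1200, 1.0, 4.0),
    case_sd = c(3.3727, 10.6927, 300 * sqrt(3), 0.3, 1.0),
    control_mean = c(122 / 7, 23 / 7, 458, 1.0, 4.0),
    control_sd = c(3.2228, 1.9760, 90 * sqrt(7), 0.3, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic-study generator. Defaults are calibrated to
#' the study being emulated: a 15-member, 3-generation pedigree; roughly one
#' in ten candidate variants functional (the observed 108/1,153); 2\% of
#' functional variants predicted deleterious by all three in-silico tools;
#' a Beta(0.2, 2) population allele-frequency spectrum truncated to
#' [1e-5, 0.5], giving the rare-skewed spectrum typical of exome variation;
#' and a fully penetrant dominant causal variant (nonsynonymous, SIFT
#' deleterious, PolyPhen probably damaging, CADD 30, essentially absent from
#' reference panels).
#'
#' @param seed integer RNG seed; every random draw in the simulation derives
#'   from it.
#' @param n_background_variants number of gene-dropped background variants.
#' @param af_beta shape parameters (a, b) of the Beta allele-frequency
#'   spectrum.
#' @param af_bounds truncation bounds for the spectrum.
#' @param functional_fraction probability a background variant is in a
#'   functional class.
#' @param rare_fraction_of_functional probability a functional variant is
#'   predicted deleterious by all enabled tools.
#' @param penetrance probability a causal-allele carrier is affected.
#' @param phenocopy_rate probability a non-carrier is affected.
#' @param panel_af_sigma log-normal sigma of the multiplicative noise
#'   applied to true allele frequencies when reporting panel frequencies.
#' @param panels reference panel names simulated.
#' @param causal_spec named list giving the planted variant's annotation.
#' @param plasma_model data frame as \code{\link{default_plasma_model}}.
#' @return object of class \code{"sim_config"} (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_background_variants = 20000L,
                       af_beta = c(0.2, 2.0),
                       af_bounds = c(1e-5, 0.5),
                       functional_fraction = 0.094,
                       rare_fraction_of_functional = 0.02,
                       penetrance = 1.0,
                       phenocopy_rate = 0.0,
                       panel_af_sigma = 0.2,
                       panels = c("gnomAD", "G100K"),
                       causal_spec = list(functional_class = "nonsynonymous",
                                          sift = "deleterious",
                                          polyphen = "probably_damaging",
                                          cadd_phred = 30,
                                          panel_afs = c(gnomAD = 2.9e-06)),
                       plasma_model = default_plasma_model()) {
  cfg <- list(seed = as.integer(seed),
              n_background_variants = as.integer(n_background_variants),
              af_beta = af_beta, af_bounds = af_bounds,
              functional_fraction = functional_fraction,
              rare_fraction_of_functional = rare_fraction_of_functional,
              penetrance = penetrance, phenocopy_rate = phenocopy_rate,
              panel_af_sigma = panel_af_sigma, panels = panels,
              causal_spec = causal_spec, plasma_model = plasma_model)
  probs <- c(functional_fraction = cfg$functional_fraction,
             rare_fraction_of_functional = cfg$rare_fraction_of_functional,
             penetrance = cfg$penetrance,
             phenocopy_rate = cfg$phenocopy_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("sim_config: probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (cfg$n_background_variants < 1L) {
    stop("sim_config: n_background_variants must be >= 1")
  }
  if (any(cfg$plasma_model$case_sd <= 0) ||
      any(cfg$plasma_model$control_sd <= 0)) {
    stop("sim_config: plasma SDs must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' The template study pedigree
#'
#' A deterministic 15-member, 3-generation pedigree with 5 affected members
#' mirroring the study family: an affected index case, her affected mother,
#' affected maternal uncle and aunt, and an affected first cousin in the
#' index's generation. Founders are the maternal grandparents and three
#' married-in spouses.
#'
#' @return a validated \code{fam_pedigree}.
#' @export
template_pedigree <- function() {
  pedigree(
    id      = c("305008", "305009",            # grandparents
                "305001", "305002", "305003", "305013",  # their children
                "305010", "305011", "305004",  # married-in spouses
                "305000", "305006",            # children of 305001 x 305010
                "305012", "305007",            # children of 305002 x 305011
                "305005", "305015"),           # children of 305003 x 305004
    father  = c(NA, NA,
                "305008", "305008", "305008", "305008",
                NA, NA, NA,
                "305010", "305010",
                "305002", "305002",
                "305004", "305004"),
    mother  = c(NA, NA,
                "305009", "305009", "305009", "305009",
                NA, NA, NA,
                "305001", "305001",
                "305011", "305011",
                "305003", "305003"),
    sex     = c("male", "female",
                "female", "male", "female", "female",
                "male", "female", "male",
                "female", "male",
                "female", "male",
                "male", "female"),
    status  = c("unaffected", "unaffected",
                "affected", "affected", "affected", "unaffected",
                "unaffected", "unaffected", "unaffected",
                "affected", "unaffected",
                "affected", "unaffected",
                "unaffected", "unaffected"),
    name = "FAM305"
  )
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders are drawn from Hardy-Weinberg proportions at the given allele
#' frequency; every non-founder inherits one allele chosen uniformly at
#' random from each parent's two alleles. Vectorized over variants:
#' \code{af} may be a vector, giving one independent drop per frequency.
#'
#' @param ped a \code{fam_pedigree}.
#' @param af allele frequency (scalar or vector, each in [0, 1]).
#' @return integer matrix of alt-allele counts, \code{length(af)} rows
#'   (variants) by pedigree members (columns named by id).
#' @export
gene_drop <- function(ped, af) {
  if (any(af < 0 | af > 1)) stop("gene_drop: af must lie in [0, 1]")
  n <- length(af)
  ord <- pedigree_order(ped)
  a1 <- a2 <- matrix(0L, n, nrow(ped), dimnames = list(NULL, ped$id))
  for (i in ord) {
    id <- ped$id[i]
    if (is.na(ped$father[i])) {
      a1[, id] <- stats::rbinom(n, 1L, af)
      a2[, id] <- stats::rbinom(n, 1L, af)
    } else {
      f <- ped$father[i]; m <- ped$mother[i]
      pick_f <- stats::rbinom(n, 1L, 0.5)
      pick_m <- stats::rbinom(n, 1L, 0.5)
      a1[, id] <- ifelse(pick_f == 1L, a1[, f], a2[, f])
      a2[, id] <- ifelse(pick_m == 1L, a1[, m], a2[, m])
    }
  }
  g <- a1 + a2
  storage.mode(g) <- "integer"
  g
}

# Founders that are ancestors of (or equal to) every affected member,
# earliest generation first, lexicographic within a generation.
shared_affected_founders <- function(ped) {
  aff <- ped$id[ped$status == "affected"]
  parents <- function(id) {
    r <- ped[ped$id == id, ]
    c(r$father, r$mother)[!is.na(c(r$father, r$mother))]
  }
  ancestors <- function(id) {
    out <- character(0); queue <- parents(id)
    while (length(queue)) {
      out <- union(out, queue)
      queue <- unique(unlist(lapply(queue, parents)))
      queue <- setdiff(queue, out)
    }
    out
  }
  anc_or_self <- lapply(aff, function(a) c(a, ancestors(a)))
  shared <- Reduce(intersect, anc_or_self)
  founders <- ped$id[is.na(ped$father)]
  shared <- intersect(shared, founders)
  depth <- pedigree_depth(ped)
  shared[order(depth[shared], shared)]
}

#' Plant a dominant causal allele and assign affection status
#'
#' One copy of the causal allele is introduced in a single founder and
#' gene-dropped down the pedigree, re-drawing until at least 3 members carry
#' it across at least 2 generations (so a dominant segregation pattern is
#' visible). Each carrier is then affected with probability
#' \code{penetrance} and each non-carrier with probability
#' \code{phenocopy_rate}; at the defaults (1, 0) carriers and affected
#' coincide exactly.
#'
#' @param ped a \code{fam_pedigree}.
#' @param penetrance probability a carrier is affected.
#' @param phenocopy_rate probability a non-carrier is affected.
#' @param founder_id founder receiving the allele; default is the
#'   earliest-generation founder ancestral to all members the pedigree marks
#'   affected (falling back to the first founder).
#' @param max_tries bound on re-draws before erroring.
#' @return list with \code{genotypes} (named integer vector of alt counts)
#'   and \code{status} (named character vector).
#' @export
plant_causal_and_assign_status <- function(ped, penetrance = 1.0,
                                           phenocopy_rate = 0.0,
                                           founder_id = NULL,
                                           max_tries = 10000L) {
  if (is.null(founder_id)) {
    cand <- shared_affected_founders(ped)
    founder_id <- if (length(cand)) cand[1L] else ped$id[is.na(ped$father)][1L]
  }
  if (!founder_id %in% ped$id[is.na(ped$father)]) {
    stop("founder_id must be a founder of the pedigree")
  }
  ord <- pedigree_order(ped)
  depth <- pedigree_depth(ped)
  for (try in seq_len(max_tries)) {
    a1 <- a2 <- stats::setNames(integer(nrow(ped)), ped$id)
    a1[founder_id] <- 1L
    for (i in ord) {
      if (!is.na(ped$father[i])) {
        f <- ped$father[i]; m <- ped$mother[i]
        a1[ped$id[i]] <- if (stats::runif(1) < 0.5) a1[f] else a2[f]
        a2[ped$id[i]] <- if (stats::runif(1) < 0.5) a1[m] else a2[m]
      }
    }
    g <- a1 + a2
    carriers <- names(g)[g >= 1L]
    if (length(carriers) >= 3L && length(unique(depth[carriers])) >= 2L) {
      p_aff <- ifelse(g >= 1L, penetrance, phenocopy_rate)
      status <- ifelse(stats::runif(length(g)) < p_aff, "affected",
                       "unaffected")
      return(list(genotypes = g, status = stats::setNames(status, names(g))))
    }
  }
  stop("plant_causal_and_assign_status: no admissible drop in ", max_tries,
       " attempts")
}

sample_functional_class <- function(n, functional) {
  if (functional) {
    sample(c("nonsynonymous", "splicing", "frameshift_indel", "stop_gain",
             "stop_loss"), n, replace = TRUE,
           prob = c(0.80, 0.08, 0.06, 0.04, 0.02))
  } else {
    sample(c("synonymous", "nonframeshift_indel", "other"), n, replace = TRUE,
           prob = c(0.70, 0.05, 0.25))
  }
}

#' Simulate a complete synthetic family study
#'
#' Generates, from one seed: the template pedigree with affection status
#' re-assigned by a planted fully penetrant dominant causal variant;
#' \code{n_background_variants} independently gene-dropped background
#' variants with annotations (functional class with probability
#' \code{functional_fraction}; panel allele frequencies equal to the true
#' frequency under multiplicative log-normal noise; in-silico predictions
#' such that a fraction \code{rare_fraction_of_functional} of functional
#' variants is predicted deleterious by every tool); the causal variant
#' itself (satisfying every cascade criterion by construction, essentially
#' absent from reference panels); and per-member plasma values drawn
#' Normal(group mean, group SD) per parameter.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{"famvar_study"}: a list with
#'   \code{pedigree}, \code{variants} (an \code{annotated_variants}),
#'   \code{plasma} (long-format data frame), \code{causal_id} and
#'   \code{config}.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- template_pedigree()
  planted <- plant_causal_and_assign_status(ped, config$penetrance,
                                            config$phenocopy_rate)
  ped$status <- unname(planted$status[ped$id])

  n <- config$n_background_variants
  af <- stats::rbeta(n, config$af_beta[1], config$af_beta[2])
  af <- pmin(pmax(af, config$af_bounds[1]), config$af_bounds[2])
  geno <- gene_drop(ped, af)

  is_func <- stats::runif(n) < config$functional_fraction
  func_class <- character(n)
  func_class[is_func] <- sample_functional_class(sum(is_func), TRUE)
  func_class[!is_func] <- sample_functional_class(sum(!is_func), FALSE)

  # predictions: a `rare_fraction_of_functional` slice of functional variants
  # passes all three tools; everything else fails PolyPhen (and mostly the
  # others), so the deleteriousness filter retains exactly that slice of the
  # background.
  combo <- is_func & stats::runif(n) < config$rare_fraction_of_functional
  sift <- sample(c("tolerated", "deleterious", "unknown"), n, replace = TRUE,
                 prob = c(0.75, 0.15, 0.10))
  polyphen <- sample(c("benign", "possibly_damaging", "unknown"), n,
                     replace = TRUE, prob = c(0.65, 0.25, 0.10))
  cadd <- stats::runif(n, 0, 25)
  sift[combo] <- "deleterious"
  polyphen[combo] <- "probably_damaging"
  cadd[combo] <- stats::runif(sum(combo), 20, 35)

  noise <- matrix(exp(stats::rnorm(n * length(config$panels), 0,
                                   config$panel_af_sigma)),
                  n, length(config$panels))
  panel_af <- pmin(af * noise, 1)
  colnames(panel_af) <- config$panels

  chrom <- sample(as.character(1:22), n, replace = TRUE)
  pos <- sample.int(2.4e8, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  sites <- data.frame(id = paste0("var", seq_len(n), ":", chrom, ":", pos),
                      chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  ann <- data.frame(functional_class = func_class, sift = sift,
                    polyphen = polyphen, cadd_phred = cadd,
                    stringsAsFactors = FALSE)

  # planted causal variant: every cascade criterion satisfied by construction
  cs <- config$causal_spec
  causal_id <- "causal:1:46361844"
  causal_af <- matrix(NA_real_, 1, length(config$panels),
                      dimnames = list(causal_id, config$panels))
  for (p in names(cs$panel_afs)) {
    if (p %in% config$panels) causal_af[1, p] <- cs$panel_afs[[p]]
  }
  sites <- rbind(data.frame(id = causal_id, chrom = "1", pos = 46361844L,
                            ref = "G", alt = "A", stringsAsFactors = FALSE),
                 sites)
  geno <- rbind(matrix(planted$genotypes[ped$id], 1,
                       dimnames = list(causal_id, ped$id)), geno)
  ann <- rbind(data.frame(functional_class = cs$functional_class,
                          sift = cs$sift, polyphen = cs$polyphen,
                          cadd_phred = cs$cadd_phred,
                          stringsAsFactors = FALSE), ann)
  panel_af <- rbind(causal_af, panel_af)
  variants <- annotated_variants(sites, geno, ann, panel_af)

  pm <- config$plasma_model
  plasma <- do.call(rbind, lapply(seq_len(nrow(pm)), function(r) {
    is_case <- ped$status == "affected"
    mu <- ifelse(is_case, pm$case_mean[r], pm$control_mean[r])
    sd <- ifelse(is_case, pm$case_sd[r], pm$control_sd[r])
    data.frame(subject_id = ped$id,
               status = ifelse(is_case, "case", "control"),
               parameter = pm$parameter[r],
               value = stats::rnorm(nrow(ped), mu, sd),
               units = pm$units[r], stringsAsFactors = FALSE)
  }))

  structure(list(pedigree = ped, variants = variants, plasma = plasma,
                 causal_id = causal_id, config = config),
            class = "famvar_study")
}

#' @export
print.famvar_study <- function(x, ...) {
  cat("Synthetic family study (seed ", x$config$seed, ")\n", sep = "")
  cat("  pedigree: ", nrow(x$pedigree), " members, ",
      sum(x$pedigree$status == "affected"), " affected\n", sep = "")
  cat("  variants: ", n_variants(x$variants), " (causal: ", x$causal_id,
      ")\n", sep = "")
  cat("  plasma: ", nrow(x$plasma), " measurements, ",
      length(unique(x$plasma$parameter)), " parameters\n", sep = "")
  invisible(x)
}

#' Write a simulated study bundle to disk
#'
#' Writes \code{study.ped}, \code{study.vcf}, \code{annotations.tsv} and
#' \code{plasma.csv} into \code{dir}. All outputs are plain text and
#' byte-deterministic given the study object.
#'
#' @param study a \code{famvar_study}.
#' @param dir output directory (created if absent).
#' @return named character vector of paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "study.ped"),
             vcf = file.path(dir, "study.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             plasma = file.path(dir, "plasma.csv"))
  write_ped(study$pedigree, paths["ped"])
  write_annotated_vcf(study$variants, study$pedigree$id, paths["vcf"])
  write_annotation_tsv(study$variants, paths["annotations"])
  utils::write.csv(study$plasma, paths["plasma"], row.names = FALSE,
                   quote = FALSE)
  message("wrote ", paste(paths, collapse = ", "))
  invisible(paths)
}
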