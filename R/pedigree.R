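#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' \code{id}, \code{father}, \code{mother} (\code{NA} for founders),
#' \code{sex} (\code{"male"}, \code{"female"} or \code{"unknown"}) and
#' \code{status} (\code{"affected"}, \code{"unaffected"} or
#' \code{"unknown"}). Construction validates the structure: ids must be
#' unique and non-empty, an individual has either both parents or neither,
#' every named parent must be present, fathers must be male and mothers
#' female where sex is known, and the parent relation must be acyclic.
#'
#' @param id character vector of individual ids.
#' @param father,mother character vectors of parent ids; \code{NA} marks a
#'   founder.
#' @param sex character vector, \code{"male"}, \code{"female"} or
#'   \code{"unknown"}.
#' @param status character vector, \code{"affected"}, \code{"unaffected"} or
#'   \code{"unknown"}.
#' @param name single string naming the family.
#' @return An object of class \code{"fam_pedigree"} (a data frame).
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", status = "unknown", name = "family") {
  ped <- data.frame(
    id = as.character(id),
    father = as.character(rep_len(father, length(id))),
    mother = as.character(rep_len(mother, length(id))),
    sex = as.character(rep_len(sex, length(id))),
    status = as.character(rep_len(status, length(id))),
    stringsAsFactors = FALSE
  )
  attr(ped, "name") <- name
  class(ped) <- c("fam_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' @param ped a \code{fam_pedigree}.
#' @return \code{ped}, invisibly; stops with an informative error when an
#'   invariant is violated. Parents of unknown sex produce a warning only.
#' @export
validate_pedigree <- function(ped) {
  if (nrow(ped) == 0L) stop("pedigree validation: no individuals")
  if (any(!nzchar(ped$id)) || anyNA(ped$id)) {
    stop("pedigree validation: empty individual id")
  }
  if (anyDuplicated(ped$id)) {
    stop("pedigree validation: duplicated ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("male", "female", "unknown"))) {
    stop("pedigree validation: sex must be male/female/unknown")
  }
  if (!all(ped$status %in% c("affected", "unaffected", "unknown"))) {
    stop("pedigree validation: status must be affected/unaffected/unknown")
  }
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half)) {
    stop("pedigree validation: individuals with exactly one parent: ",
         paste(ped$id[half], collapse = ", "))
  }
  parents <- c(ped$father, ped$mother)
  dangling <- setdiff(parents[!is.na(parents)], ped$id)
  if (length(dangling)) {
    stop("pedigree validation: parent ids not in pedigree: ",
         paste(sort(unique(dangling)), collapse = ", "))
  }
  sex_of <- stats::setNames(ped$sex, ped$id)
  f <- ped$father[!is.na(ped$father)]
  m <- ped$mother[!is.na(ped$mother)]
  if (any(sex_of[f] == "female")) {
    stop("pedigree validation: female individual named as father: ",
         paste(unique(f[sex_of[f] == "female"]), collapse = ", "))
  }
  if (any(sex_of[m] == "male")) {
    stop("pedigree validation: male individual named as mother: ",
         paste(unique(m[sex_of[m] == "male"]), collapse = ", "))
  }
  if (any(sex_of[unique(c(f, m))] == "unknown")) {
    warning("pedigree: parent(s) of unknown sex: ",
            paste(unique(c(f, m))[sex_of[unique(c(f, m))] == "unknown"],
                  collapse = ", "))
  }
  if (is.null(pedigree_order(ped))) {
    stop("pedigree validation: parent relation contains a cycle involving: ",
         paste(cycle_members(ped), collapse = ", "))
  }
  invisible(ped)
}

# Topological order (parents before children), or NULL if cyclic.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(ped$father) | placed[idx[ped$father]]) &
      (is.na(ped$mother) | placed[idx[ped$mother]])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) NULL else ord
}

cycle_members <- function(ped) {
  ord <- integer(0)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  placed <- rep(FALSE, n)
  repeat {
    ready <- !placed &
      (is.na(ped$father) | placed[idx[ped$father]]) &
      (is.na(ped$mother) | placed[idx[ped$mother]])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    placed[ready] <- TRUE
  }
  sort(ped$id[!placed])
}

#' Generation depth of each pedigree member
#'
#' Founders have depth 0; a child's depth is one more than the maximum of
#' its parents' depths.
#'
#' @param ped a \code{fam_pedigree}.
#' @return named integer vector of depths.
#' @export
pedigree_depth <- function(ped) {
  ord <- pedigree_order(ped)
  depth <- stats::setNames(integer(nrow(ped)), ped$id)
  for (i in ord) {
    if (!is.na(ped$father[i])) {
      depth[ped$id[i]] <- max(depth[ped$father[i]], depth[ped$mother[i]]) + 1L
    }
  }
  depth
}

#' Read a PLINK-style 6-column PED file
#'
#' Whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex, phenotype. Codes follow the PED convention: parent
#' \code{0} means missing (founder); sex \code{1} = male, \code{2} = female,
#' anything else unknown; phenotype \code{1} = unaffected, \code{2} =
#' affected, \code{0} or \code{-9} (or anything else) unknown.
#'
#' @param path path to the PED file.
#' @return a validated \code{fam_pedigree} named after the first family id.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("pedigree validation: no individuals in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) < 6L)
  if (length(bad)) {
    stop("PED parse error: line ", bad[1L], " has fewer than 6 fields")
  }
  tab <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  sex <- unname(c("1" = "male", "2" = "female")[tab[, 5L]])
  status <- unname(c("1" = "unaffected", "2" = "affected")[tab[, 6L]])
  pedigree(
    id = tab[, 2L],
    father = ifelse(tab[, 3L] == "0", NA_character_, tab[, 3L]),
    mother = ifelse(tab[, 4L] == "0", NA_character_, tab[, 4L]),
    sex = ifelse(is.na(sex), "unknown", sex),
    status = ifelse(is.na(status), "unknown", status),
    name = tab[1L, 1L]
  )
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped a \code{fam_pedigree}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ped <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  status <- c(unaffected = "1", affected = "2", unknown = "0")[ped$status]
  lines <- paste(attr(ped, "name"), ped$id,
                 ifelse(is.na(ped$father), "0", ped$father),
                 ifelse(is.na(ped$mother), "0", ped$mother),
                 sex, status, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Kinship coefficients for a pedigree
#'
#' Wright's kinship coefficient phi(i, j): the probability that one allele
#' drawn at random from i and one from j are identical by descent. Computed
#' by the standard recursion with founders assumed unrelated and
#' non-inbred relative to one another: phi(i, i) = (1 + phi(father_i,
#' mother_i)) / 2, and for i != j, processing individuals parents-first,
#' phi(i, j) = (phi(i, father_j) + phi(i, mother_j)) / 2 where j is the
#' later-born of the pair. Inbred pedigrees are handled by the same
#' recursion.
#'
#' @param ped a \code{fam_pedigree}.
#' @return symmetric numeric matrix with ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  ord <- pedigree_order(ped)
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- stats::setNames(seq_len(n), ped$id)
  done <- integer(0)
  for (i in ord) {
    fi <- ped$father[i]; mi <- ped$mother[i]
    if (is.na(fi)) {
      K[i, i] <- 0.5
      if (length(done)) K[i, done] <- K[done, i] <- 0
    } else {
      K[i, i] <- 0.5 * (1 + K[pos[fi], pos[mi]])
      if (length(done)) {
        v <- 0.5 * (K[done, pos[fi]] + K[done, pos[mi]])
        K[i, done] <- v
        K[done, i] <- v
      }
    }
    done <- c(done, i)
  }
  K
}

#' @rdname kinship_matrix
#' @param i,j individual ids.
#' @return \code{kinship()} returns the single coefficient phi(i, j).
#' @export
kinship <- function(ped, i, j) {
  miss <- setdiff(c(i, j), ped$id)
  if (length(miss)) stop("kinship: unknown id(s): ", paste(miss, collapse = ", "))
  kinship_matrix(ped)[i, j]
}

# Enumerate k-subsets of ids (sorted, hence lexicographic order) and score
# each with `score`; return the first subset attaining the optimum.
best_subset <- function(ids, k, score, minimize = TRUE) {
  ids <- sort(ids)
  subsets <- utils::combn(ids, k, simplify = FALSE)
  vals <- vapply(subsets, score, numeric(1))
  pick <- if (minimize) which.min(vals) else which.max(vals)
  subsets[[pick]]
}

#' Select affected individuals for sequencing
#'
#' Picks the k affected members minimizing the sum of pairwise kinship
#' coefficients — the "most genealogically distant" affected relatives, the
#' design that maximizes the expected filtering power of requiring a shared
#' dominant variant. Exhaustive search over all subsets; ties are broken by
#' lexicographic order of the sorted member ids.
#'
#' @param ped a \code{fam_pedigree}.
#' @param k number of cases to select.
#' @return character vector of k ids, sorted.
#' @export
select_cases_for_sequencing <- function(ped, k) {
  aff <- ped$id[ped$status == "affected"]
  if (k > length(aff)) {
    stop("select_cases_for_sequencing: k = ", k, " exceeds affected count ",
         length(aff))
  }
  K <- kinship_matrix(ped)
  best_subset(aff, k, function(s) sum(K[s, s][upper.tri(diag(length(s)))]),
              minimize = TRUE)
}

#' Select unaffected controls for sequencing
#'
#' Picks the m unaffected members maximizing the summed kinship to the
#' chosen cases ("as genetically close as possible" to the cases, so that
#' shared background variation is excluded efficiently). Exhaustive search;
#' lexicographic tie-break.
#'
#' @param ped a \code{fam_pedigree}.
#' @param cases character vector of case ids.
#' @param m number of controls to select.
#' @return character vector of m ids, sorted.
#' @export
select_controls_for_sequencing <- function(ped, cases, m) {
  unaff <- ped$id[ped$status == "unaffected"]
  if (m > length(unaff)) {
    stop("select_controls_for_sequencing: m = ", m,
         " exceeds unaffected count ", length(unaff))
  }
  miss <- setdiff(cases, ped$id)
  if (length(miss)) stop("unknown case id(s): ", paste(miss, collapse = ", "))
  K <- kinship_matrix(ped)
  best_subset(unaff, m, function(s) sum(K[s, cases, drop = FALSE]),
              minimize = FALSE)
}

#' @export
print.fam_pedigree <- function(x, ...) {
  cat("Pedigree '", attr(x, "name"), "': ", nrow(x), " members, ",
      sum(x$status == "affected"), " affected, ",
      sum(is.na(x$father)), " founders, ",
      max(pedigree_depth(x)) + 1L, " generations\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
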