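FUNCTIONAL_CLASSES <- c("stop_gain", "stop_loss", "frameshift_indel",
                        "nonframeshift_indel", "nonsynonymous", "splicing",
                        "synonymous", "other")
SIFT_LEVELS <- c("deleterious", "tolerated", "unknown")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign",
                     "unknown")

#' Annotated multi-sample variant set
#'
#' The unit of work for the filtering cascade: a set of bi-allelic sites
#' (multi-allelic records are decomposed upstream), a genotype matrix of
#' alternate-allele counts (0/1/2, \code{NA} = missing call) and per-variant
#' annotations: functional class, SIFT and PolyPhen categories, CADD PHRED
#' score (\code{NA} = unknown) and per-reference-panel allele frequencies
#' (\code{NA} = variant absent from that panel).
#'
#' @param sites data frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}.
#' @param geno integer matrix, one row per variant, one column per sample,
#'   entries in \code{0:2} or \code{NA}.
#' @param ann data frame with columns \code{functional_class}, \code{sift},
#'   \code{polyphen}, \code{cadd_phred}.
#' @param panel_af numeric matrix, one row per variant, one column per
#'   reference panel; \code{NA} marks absence from the panel. May have zero
#'   columns.
#' @return object of class \code{"annotated_variants"}.
#' @export
annotated_variants <- function(sites, geno, ann, panel_af = NULL) {
  n <- nrow(sites)
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(sites)))
  if (any(sites$pos < 1L)) stop("variant pos must be >= 1")
  if (any(!nzchar(sites$ref)) || any(!nzchar(sites$alt))) {
    stop("ref and alt alleles must be non-empty")
  }
  if (any(sites$ref == sites$alt)) stop("ref must differ from alt")
  geno <- as.matrix(geno)
  if (nrow(geno) != n) stop("genotype matrix rows must match sites")
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be alt-allele counts in 0:2 or NA")
  }
  storage.mode(geno) <- "integer"
  rownames(geno) <- sites$id
  if (is.null(panel_af)) {
    panel_af <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  panel_af <- as.matrix(panel_af)
  if (nrow(panel_af) != n) stop("panel_af rows must match sites")
  ok_af <- is.na(panel_af) | (panel_af >= 0 & panel_af <= 1)
  if (!all(ok_af)) stop("panel allele frequencies must lie in [0, 1]")
  rownames(panel_af) <- sites$id
  stopifnot(all(c("functional_class", "sift", "polyphen", "cadd_phred")
                %in% names(ann)), nrow(ann) == n)
  if (!all(ann$functional_class %in% FUNCTIONAL_CLASSES)) {
    stop("unknown functional_class value")
  }
  if (!all(ann$sift %in% SIFT_LEVELS)) stop("unknown sift value")
  if (!all(ann$polyphen %in% POLYPHEN_LEVELS)) stop("unknown polyphen value")
  if (any(ann$cadd_phred < 0, na.rm = TRUE)) stop("cadd_phred must be >= 0")
  structure(list(sites = sites, geno = geno,
                 ann = as.data.frame(ann, stringsAsFactors = FALSE),
                 panel_af = panel_af),
            class = "annotated_variants")
}

#' @export
print.annotated_variants <- function(x, ...) {
  cat("annotated_variants: ", n_variants(x), " variants x ",
      ncol(x$geno), " samples; panels: ",
      if (ncol(x$panel_af)) paste(colnames(x$panel_af), collapse = ", ")
      else "(none)", "\n", sep = "")
  cl <- table(factor(x$ann$functional_class, levels = FUNCTIONAL_CLASSES))
  cat("functional classes:",
      paste(names(cl)[cl > 0], cl[cl > 0], sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of variants in a set
#' @param x an \code{annotated_variants} object.
#' @export
n_variants <- function(x) nrow(x$sites)

#' Subset an annotated variant set by row
#' @param x an \code{annotated_variants} object.
#' @param i row indices (integer, logical or variant ids).
#' @param ... ignored.
#' @export
`[.annotated_variants` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sites$id)
  structure(list(sites = x$sites[i, , drop = FALSE],
                 geno = x$geno[i, , drop = FALSE],
                 ann = x$ann[i, , drop = FALSE],
                 panel_af = x$panel_af[i, , drop = FALSE]),
            class = "annotated_variants")
}

#' Variant ids of a set
#' @param x an \code{annotated_variants} object.
#' @export
variant_ids <- function(x) x$sites$id

# Split "0/1", "0|1", "./." into alt-allele counts per decomposed allele.
# alleles: integer codes of the record's GT; k: which alternate (1-based).
gt_alt_count <- function(gt, k) {
  if (is.na(gt) || gt == "" || gt == ".") return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(as.integer(alleles) == k)
}

default_info_keys <- function() {
  list(functional_class = "FUNC", sift = "SIFT", polyphen = "POLYPHEN",
       cadd_phred = "CADD", panel_af_prefix = "AF_")
}

#' Read a multi-sample VCF with annotations
#'
#' Reads a VCF v4.2 (plain or gzip) via \pkg{vcfR}, decomposes multi-allelic
#' records into one bi-allelic variant per alternate allele (genotypes are
#' recoded to the count of that allele; a genotype containing any missing
#' allele becomes a missing call; phase is dropped), and attaches
#' annotations. Annotations are taken from INFO keys (\code{FUNC},
#' \code{SIFT}, \code{POLYPHEN}, \code{CADD} and \code{AF_<panel>} by
#' default) and, when \code{annotation_path} is given, from a sidecar TSV
#' keyed by \code{chrom, pos, ref, alt}; TSV values override INFO.
#'
#' @param vcf_path path to the VCF file.
#' @param annotation_path optional path to the annotation TSV; columns
#'   \code{chrom, pos, ref, alt, functional_class, sift, polyphen,
#'   cadd_phred} plus any number of \code{af_<panel>} columns.
#' @param info_keys named list overriding the INFO key names.
#' @return an \code{annotated_variants} object.
#' @export
read_annotated_vcf <- function(vcf_path, annotation_path = NULL,
                               info_keys = default_info_keys()) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix  # CHROM POS ID REF ALT QUAL FILTER INFO
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(vcf@gt) == 0L || !("FORMAT" %in% colnames(vcf@gt))) {
    stop("VCF format error: no FORMAT/genotype columns in ", vcf_path)
  }
  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("VCF format error: FORMAT lacks GT field in ", vcf_path)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  samples <- colnames(gt)
  info_raw <- fix[, "INFO"]

  # discover AF_<panel> INFO keys from the header
  meta <- vcf@meta
  ids <- regmatches(meta, regexpr("ID=[A-Za-z0-9_.]+", meta))
  ids <- sub("^ID=", "", ids)
  panel_keys <- ids[startsWith(ids, info_keys$panel_af_prefix)]
  panels <- substring(panel_keys, nchar(info_keys$panel_af_prefix) + 1L)

  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    info <- info_raw[r]
    func <- info_get(info, info_keys$functional_class)
    sift <- info_get(info, info_keys$sift)
    poly <- info_get(info, info_keys$polyphen)
    cadd <- suppressWarnings(as.numeric(info_get(info, info_keys$cadd_phred)))
    paf <- vapply(panel_keys, function(k)
      suppressWarnings(as.numeric(info_get(info, k))), numeric(1))
    sub_rows <- lapply(seq_along(alts), function(k) {
      id <- fix[r, "ID"]
      if (is.na(id) || id == "." || length(alts) > 1L) {
        id <- paste(fix[r, "CHROM"], fix[r, "POS"], fix[r, "REF"], alts[k],
                    sep = ":")
      }
      counts <- vapply(gt[r, ], gt_alt_count, integer(1), k = k)
      list(site = data.frame(id = id, chrom = fix[r, "CHROM"],
                             pos = as.integer(fix[r, "POS"]),
                             ref = fix[r, "REF"], alt = alts[k],
                             stringsAsFactors = FALSE),
           geno = counts,
           ann = data.frame(
             functional_class = if (is.na(func)) "other" else func,
             sift = if (is.na(sift)) "unknown" else sift,
             polyphen = if (is.na(poly)) "unknown" else poly,
             cadd_phred = cadd, stringsAsFactors = FALSE),
           paf = paf)
    })
    rows[[r]] <- sub_rows
  }
  rows <- unlist(rows, recursive = FALSE)
  sites <- do.call(rbind, lapply(rows, `[[`, "site"))
  geno <- do.call(rbind, lapply(rows, `[[`, "geno"))
  colnames(geno) <- samples
  ann <- do.call(rbind, lapply(rows, `[[`, "ann"))
  panel_af <- do.call(rbind, lapply(rows, `[[`, "paf"))
  if (length(panels)) colnames(panel_af) <- panels
  else panel_af <- matrix(numeric(0), nrow = nrow(sites), ncol = 0)
  x <- annotated_variants(sites, geno, ann, panel_af)
  if (!is.null(annotation_path)) x <- join_annotations(x, annotation_path)
  x
}

#' Join a sidecar annotation table onto a variant set
#'
#' The TSV is keyed by \code{chrom, pos, ref, alt}; matching rows override
#' any annotation already present (explicit sidecar beats embedded INFO).
#' Rows matching no variant produce one warning with the count.
#'
#' @param x an \code{annotated_variants} object.
#' @param path path to the annotation TSV (header line required).
#' @return the annotated set.
#' @export
join_annotations <- function(x, path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  key_x <- paste(x$sites$chrom, x$sites$pos, x$sites$ref, x$sites$alt,
                 sep = ":")
  key_t <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  hit <- match(key_x, key_t)
  unmatched <- sum(!(key_t %in% key_x))
  if (unmatched > 0) {
    warning(unmatched, " annotation row(s) matched no variant")
  }
  got <- which(!is.na(hit))
  for (col in c("functional_class", "sift", "polyphen")) {
    if (col %in% names(tab)) x$ann[[col]][got] <- tab[[col]][hit[got]]
  }
  if ("cadd_phred" %in% names(tab)) {
    x$ann$cadd_phred[got] <- suppressWarnings(as.numeric(tab$cadd_phred[hit[got]]))
  }
  af_cols <- grep("^af_", names(tab), value = TRUE)
  if (length(af_cols)) {
    panels <- sub("^af_", "", af_cols)
    add <- setdiff(panels, colnames(x$panel_af))
    if (length(add)) {
      x$panel_af <- cbind(x$panel_af,
                          matrix(NA_real_, nrow(x$sites), length(add),
                                 dimnames = list(x$sites$id, add)))
    }
    for (k in seq_along(panels)) {
      x$panel_af[got, panels[k]] <-
        suppressWarnings(as.numeric(tab[[af_cols[k]]][hit[got]]))
    }
  }
  annotated_variants(x$sites, x$geno, x$ann, x$panel_af)
}

fmt_af <- function(a) sub("e-0", "e-", sprintf("%.6g", a))

#' Write an annotated variant set as VCF v4.2
#'
#' Annotations are serialized to INFO keys \code{FUNC}, \code{SIFT},
#' \code{POLYPHEN}, \code{CADD} and \code{AF_<panel>}; genotypes are written
#' unphased (\code{0/0}, \code{0/1}, \code{1/1}, \code{./.}). Reading the
#' file back yields the identical data model (allele frequencies to 6
#' significant digits).
#'
#' @param x an \code{annotated_variants} object.
#' @param samples sample ids to write, in column order.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotated_vcf <- function(x, samples, path) {
  miss <- setdiff(samples, colnames(x$geno))
  if (length(miss)) {
    stop("sample(s) ", paste(miss, collapse = ", "),
         " missing from variant set (first site: ", x$sites$id[1], ")")
  }
  panels <- colnames(x$panel_af)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=famvar",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=SIFT,Number=1,Type=String,Description=\"SIFT category\">",
    "##INFO=<ID=POLYPHEN,Number=1,Type=String,Description=\"PolyPhen category\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD PHRED score\">",
    vapply(panels, function(p) paste0(
      "##INFO=<ID=AF_", p, ",Number=1,Type=Float,Description=\"",
      p, " allele frequency\">"), character(1)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  recs <- vapply(seq_len(n_variants(x)), function(r) {
    info <- c(paste0("FUNC=", x$ann$functional_class[r]),
              paste0("SIFT=", x$ann$sift[r]),
              paste0("POLYPHEN=", x$ann$polyphen[r]),
              if (!is.na(x$ann$cadd_phred[r]))
                paste0("CADD=", fmt_af(x$ann$cadd_phred[r])))
    for (p in panels) {
      if (!is.na(x$panel_af[r, p])) {
        info <- c(info, paste0("AF_", p, "=", fmt_af(x$panel_af[r, p])))
      }
    }
    g <- x$geno[r, samples]
    gts <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(x$sites$chrom[r], x$sites$pos[r], x$sites$id[r], x$sites$ref[r],
            x$sites$alt[r], ".", "PASS", paste(info, collapse = ";"), "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write the annotation sidecar TSV for a variant set
#'
#' @param x an \code{annotated_variants} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_tsv <- function(x, path) {
  tab <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    ref = x$sites$ref, alt = x$sites$alt,
                    functional_class = x$ann$functional_class,
                    sift = x$ann$sift, polyphen = x$ann$polyphen,
                    cadd_phred = x$ann$cadd_phred,
                    stringsAsFactors = FALSE)
  for (p in colnames(x$panel_af)) {
    tab[[paste0("af_", p)]] <- x$panel_af[, p]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
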