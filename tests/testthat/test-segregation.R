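# Pedigree of 15 with 5 affected, plus genotypes replaying the replication
# genotyping: one perfectly co-segregating candidate and one with a
# non-carrying case (305012), mirroring the elimination of the second
# candidate.
replay_fixture <- function() {
  ped <- template_pedigree()
  carriers <- ped$id[ped$status == "affected"]
  g_coseg <- ifelse(ped$id %in% carriers, 1L, 0L)
  g_discord <- g_coseg
  g_discord[ped$id == "305012"] <- 0L          # the case that did not carry
  g_discord[ped$id == "305013"] <- 0L
  geno <- rbind(g_coseg, g_discord)
  colnames(geno) <- ped$id
  sites <- data.frame(id = c("MAST2_R89Q", "ADAMTS10_like"),
                      chrom = c("1", "19"), pos = c(46361844L, 8578000L),
                      ref = "G", alt = "A", stringsAsFactors = FALSE)
  ann <- data.frame(functional_class = "nonsynonymous",
                    sift = c("deleterious", "tolerated"),
                    polyphen = c("probably_damaging", "benign"),
                    cadd_phred = c(30, 8), stringsAsFactors = FALSE)
  list(ped = ped, x = annotated_variants(sites, geno, ann))
}

test_that("a perfectly co-segregating variant is recognized", {
  f <- replay_fixture()
  res <- check_cosegregation(f$x, f$ped, "MAST2_R89Q")
  expect_true(res$cosegregates)
  expect_equal(res$case_carriers, 5L)
  expect_equal(res$case_total, 5L)
  expect_equal(res$control_carriers, 0L)
  expect_equal(res$control_total, 10L)
  expect_equal(res$discordant_ids, "")
})

test_that("a non-carrying case breaks co-segregation and is named", {
  f <- replay_fixture()
  res <- check_cosegregation(f$x, f$ped, "ADAMTS10_like")
  expect_false(res$cosegregates)
  expect_equal(res$case_carriers, 4L)
  expect_equal(res$discordant_ids, "305012")
})

test_that("carrier controls are discordant too, and 1/1 counts as carrier", {
  f <- replay_fixture()
  g <- f$x$geno
  g["MAST2_R89Q", "305013"] <- 2L   # homozygous control carrier
  y <- annotated_variants(f$x$sites, g, f$x$ann)
  res <- check_cosegregation(y, f$ped, "MAST2_R89Q")
  expect_false(res$cosegregates)
  expect_equal(res$control_carriers, 1L)
  expect_equal(res$discordant_ids, "305013")
})

test_that("missing genotypes and unknown status are excluded and counted", {
  f <- replay_fixture()
  g <- f$x$geno
  g["MAST2_R89Q", "305000"] <- NA
  ped <- f$ped
  ped$status[ped$id == "305013"] <- "unknown"
  y <- annotated_variants(f$x$sites, g, f$x$ann)
  res <- check_cosegregation(y, ped, "MAST2_R89Q")
  expect_equal(res$case_total, 4L)
  expect_equal(res$missing_cases, 1L)
  expect_equal(res$control_total, 9L)   # unknown status not a control
  expect_true(res$cosegregates)
  # counts conserve: carriers + non-carriers + missing = affected members
  expect_equal(res$case_carriers + 0L + res$missing_cases,
               sum(ped$status == "affected"))
})

test_that("an all-missing variant yields 0/0 totals and a warning", {
  f <- replay_fixture()
  g <- f$x$geno
  g["MAST2_R89Q", ] <- NA
  y <- annotated_variants(f$x$sites, g, f$x$ann)
  expect_warning(res <- check_cosegregation(y, f$ped, "MAST2_R89Q"),
                 "no genotyped member")
  expect_equal(res$case_total, 0L)
  expect_equal(res$control_total, 0L)
  expect_false(res$cosegregates)
})

test_that("rank_candidates puts co-segregating variants first", {
  f <- replay_fixture()
  res <- check_cosegregation(f$x, f$ped)
  ranked <- rank_candidates(res[order(res$variant_id), ])
  expect_equal(ranked$variant_id[1], "MAST2_R89Q")
  expect_equal(rank_candidates(res[0, ])$variant_id, character(0))
})

test_that("ranking agrees with a brute-force comparator sort", {
  set.seed(41)
  n <- 40
  res <- data.frame(
    variant_id = sprintf("v%02d", sample.int(99, n)),
    case_carriers = sample(0:5, n, TRUE), case_total = 5L,
    control_carriers = sample(0:10, n, TRUE), control_total = 10L,
    missing_cases = 0L, missing_controls = 0L, stringsAsFactors = FALSE)
  res$cosegregates <- res$case_carriers == 5L & res$control_carriers == 0L
  res$discordant_ids <- ""
  class(res) <- c("segregation_result", "data.frame")
  ranked <- rank_candidates(res)
  # pairwise comparator: coseg first, then score, then id
  score <- function(r) r$case_carriers / r$case_total -
    r$control_carriers / r$control_total
  for (k in seq_len(nrow(ranked) - 1)) {
    a <- ranked[k, ]; b <- ranked[k + 1, ]
    ok <- (a$cosegregates > b$cosegregates) ||
      (a$cosegregates == b$cosegregates && score(a) > score(b)) ||
      (a$cosegregates == b$cosegregates && score(a) == score(b) &&
         a$variant_id <= b$variant_id)
    expect_true(ok)
  }
})

test_that("a cascade survivor on the WES subset can fail full-pedigree segregation", {
  f <- replay_fixture()
  ped <- f$ped
  # WES used the index, mother, uncle and aunt; 305012 entered only at the
  # replication-genotyping step
  cases <- c("305000", "305001", "305002", "305003")
  controls <- select_controls_for_sequencing(ped, cases, 2)
  # make the discordant candidate pass the WES cascade: carried by the 4 WES
  # cases, absent in the 2 WES controls, annotated functional/rare/deleterious
  g <- f$x$geno
  g["ADAMTS10_like", cases] <- 1L
  g["ADAMTS10_like", controls] <- 0L
  g["ADAMTS10_like", "305012"] <- 0L
  ann <- f$x$ann
  ann[2, ] <- list("nonsynonymous", "deleterious", "probably_damaging", 28)
  y <- annotated_variants(f$x$sites, g, ann)
  rep <- run_cascade(y, cases, controls)
  expect_true("ADAMTS10_like" %in% rep$final_candidates)
  seg <- check_cosegregation(y, ped, "ADAMTS10_like")
  expect_false(seg$cosegregates)
  expect_true("305012" %in% strsplit(seg$discordant_ids, ",")[[1]])
})
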