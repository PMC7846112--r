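test_that("read_ped maps PED codes and validates structure", {
  path <- write_ped_lines(c(
    "FAM 305008 0 0 1 1",
    "FAM 305009 0 0 2 1",
    "FAM 305001 305008 305009 2 2",
    "FAM 305000 0 0 2 -9"
  ))
  ped <- read_ped(path)
  expect_s3_class(ped, "fam_pedigree")
  expect_equal(nrow(ped), 4L)
  expect_true(is.na(ped$father[ped$id == "305008"]))
  expect_equal(ped$sex[ped$id == "305001"], "female")
  expect_equal(ped$status[ped$id == "305001"], "affected")
  expect_equal(ped$status[ped$id == "305000"], "unknown")
  expect_equal(attr(ped, "name"), "FAM")
})

test_that("a 15-line PED mirroring the study family parses to 5 affected", {
  tp <- template_pedigree()
  path <- tempfile(fileext = ".ped")
  write_ped(tp, path)
  ped <- read_ped(path)
  expect_equal(nrow(ped), 15L)
  expect_equal(sum(ped$status == "affected"), 5L)
  expect_equal(sum(ped$status == "unaffected"), 10L)
  expect_identical(ped$father, tp$father)
  expect_identical(ped$mother, tp$mother)
})

test_that("malformed and degenerate PED inputs raise informative errors", {
  expect_error(read_ped(write_ped_lines(character(0))), "no individuals")
  expect_error(read_ped(write_ped_lines("FAM only three fields")),
               "line 1")
  # an individual that is its own father: cycle
  expect_error(read_ped(write_ped_lines(c("F a a b 1 1", "F b 0 0 2 1"))),
               "cycle")
  # dangling parent id
  expect_error(read_ped(write_ped_lines("F a ghost ghost2 1 1")),
               "ghost")
  # exactly one parent
  expect_error(
    pedigree(id = c("a", "b"), father = c("b", NA),
             mother = c(NA, NA), sex = c("male", "male")),
    "one parent")
  # female father
  expect_error(
    pedigree(id = c("a", "b", "c"), father = c(NA, NA, "a"),
             mother = c(NA, NA, "b"), sex = c("female", "female", "male")),
    "father")
})

test_that("parents of unknown sex warn but do not error", {
  expect_warning(
    pedigree(id = c("a", "b", "c"), father = c(NA, NA, "a"),
             mother = c(NA, NA, "b"),
             sex = c("unknown", "female", "male")),
    "unknown sex")
})

test_that("kinship matches the closed forms forced by the recursion", {
  ped <- template_pedigree()
  K <- kinship_matrix(ped)
  expect_equal(K["305008", "305008"], 0.5)          # non-inbred founder
  expect_equal(K["305008", "305009"], 0)            # two founders
  expect_equal(K["305000", "305001"], 0.25)         # parent-offspring
  expect_equal(K["305001", "305002"], 0.25)         # full siblings
  expect_equal(K["305000", "305012"], 0.0625)       # first cousins
  expect_equal(K["305000", "305002"], 0.125)        # avuncular
  expect_equal(kinship(ped, "305000", "305012"), 0.0625)
  expect_error(kinship(ped, "305000", "nobody"), "unknown id")
})

test_that("kinship handles inbreeding through the same recursion", {
  # offspring of a father-daughter mating: phi(child, child) = 0.5 * (1 + 0.25)
  ped <- pedigree(id = c("f", "m", "d", "x"),
                  father = c(NA, NA, "f", "f"),
                  mother = c(NA, NA, "m", "d"),
                  sex = c("male", "female", "female", "male"))
  K <- kinship_matrix(ped)
  expect_equal(K["x", "x"], 0.625)
})

test_that("kinship is symmetric and bounded by self-kinship", {
  ped <- template_pedigree()
  K <- kinship_matrix(ped)
  expect_equal(K, t(K))
  selfmax <- max(diag(K))
  expect_true(all(K <= selfmax + 1e-12))
})

test_that("recursive kinship agrees with Monte-Carlo gene dropping", {
  set.seed(42)
  ped <- template_pedigree()
  K <- kinship_matrix(ped)
  mc <- mc_kinship(ped, n_drops = 200000L)
  for (i in ped$id) {
    for (j in ped$id) {
      if (mc$se[i, j] == 0) {
        expect_equal(mc$est[i, j], K[i, j], tolerance = 1e-12)
      } else {
        expect_lt(abs(mc$est[i, j] - K[i, j]), 3 * mc$se[i, j])
      }
    }
  }
})

test_that("case selection minimizes summed kinship, with exhaustive oracle", {
  ped <- template_pedigree()
  K <- kinship_matrix(ped)
  aff <- ped$id[ped$status == "affected"]
  # unique subset when k equals the affected count
  expect_equal(select_cases_for_sequencing(ped, 5), sort(aff))
  # k = 4 against enumeration of all C(5, 4) subsets
  oracle <- enumerate_best(aff, 4, function(s)
    sum(K[s, s][upper.tri(diag(4))]), minimize = TRUE)
  expect_equal(select_cases_for_sequencing(ped, 4), oracle)
  expect_error(select_cases_for_sequencing(ped, 6), "exceeds affected")
})

test_that("control selection maximizes kinship to cases, oracle-checked", {
  ped <- template_pedigree()
  K <- kinship_matrix(ped)
  cases <- select_cases_for_sequencing(ped, 4)
  unaff <- ped$id[ped$status == "unaffected"]
  oracle <- enumerate_best(unaff, 2, function(s)
    sum(K[s, cases]), minimize = FALSE)
  expect_equal(select_controls_for_sequencing(ped, cases, 2), oracle)
  expect_equal(sort(select_controls_for_sequencing(ped, cases, 10)),
               sort(unaff))
  expect_error(select_controls_for_sequencing(ped, cases, 11),
               "exceeds unaffected")
})

test_that("a married-in unrelated control is never preferred to a sibling", {
  ped <- template_pedigree()
  cases <- c("305000", "305001", "305002", "305003")
  picked <- select_controls_for_sequencing(ped, cases, 2)
  married_in <- c("305010", "305011", "305004")
  K <- kinship_matrix(ped)
  # every selected control has higher summed kinship than any married-in
  for (m in married_in) {
    for (p in picked) {
      expect_gt(sum(K[p, cases]), sum(K[m, cases]))
    }
  }
  expect_false(any(picked %in% married_in))
})

test_that("tied optimal subsets resolve to the lexicographically first", {
  # two founder couples, each with one affected child: the two k=1 subsets
  # are exchangeable, and any k=2 choice across families ties as well
  ped <- pedigree(id = c("a1", "a2", "b1", "b2", "ca", "cb"),
                  father = c(NA, NA, NA, NA, "a1", "b1"),
                  mother = c(NA, NA, NA, NA, "a2", "b2"),
                  sex = c("male", "female", "male", "female", "male", "male"),
                  status = c(rep("unaffected", 4), "affected", "affected"))
  expect_equal(select_cases_for_sequencing(ped, 1), "ca")
})
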