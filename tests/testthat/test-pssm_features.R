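# PSI-BLAST ASCII PSSM parsing and the three evolutionary descriptors.

make_pssm_file <- function(scores_psiblast_order, residues, path) {
  # Hand-built ASCII layout, independent of write_ascii_pssm().
  hdr <- c("", "Last position-specific scoring matrix computed ...",
           paste0("         ", paste(golgiCSP::AA_PSIBLAST, collapse = "  "),
                  "   ", paste(golgiCSP::AA_PSIBLAST, collapse = "  ")))
  rows <- vapply(seq_len(nrow(scores_psiblast_order)), function(i) {
    paste(c(i, substr(residues, i, i), scores_psiblast_order[i, ],
            rep(0, 20), "0.36", "0.07"), collapse = "  ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

test_that("parser reads scores, reorders columns and keeps residues", {
  f <- withr::local_tempfile(fileext = ".pssm")
  make_pssm_file(matrix(0, 3, 20), "MKL", f)
  p <- read_ascii_pssm(f)
  expect_s3_class(p, "pssm")
  expect_identical(dim(p$scores), c(3L, 20L))
  expect_true(all(p$scores == 0))
  expect_identical(p$residues, "MKL")

  # row with scores 1..20 in PSI-BLAST order: A is 1st, C is 5th
  make_pssm_file(matrix(rep(1:20, each = 3), 3, 20), "AAA", f)
  p <- read_ascii_pssm(f)
  expect_equal(unname(p$scores[1, "A"]), 1)
  expect_equal(unname(p$scores[1, "C"]), 5)
  expect_equal(unname(p$scores[1, "V"]), 20)
  # column reorder is the exact permutation between the two alphabets
  expect_identical(colnames(p$scores), golgiCSP::AA_ALPHABETICAL)
})

test_that("parser reports truncated and non-numeric rows with line numbers", {
  f <- withr::local_tempfile(fileext = ".pssm")
  make_pssm_file(matrix(1, 4, 20), "ACDE", f)
  lines <- readLines(f)
  lines[5] <- "2 C  1 2 3"                       # truncated row (line 5)
  writeLines(lines, f)
  expect_error(read_ascii_pssm(f), "line 5")

  make_pssm_file(matrix(1, 4, 20), "ACDE", f)
  lines <- readLines(f)
  lines[6] <- sub(" 1 ", " xx ", lines[6])        # non-numeric cell (line 6)
  writeLines(lines, f)
  expect_error(read_ascii_pssm(f), "line 6")

  make_pssm_file(matrix(1, 2, 20), "AC", f)       # L < 3
  expect_error(read_ascii_pssm(f), "fewer than 3")
})

test_that("writer/reader round-trip is the identity on integer profiles", {
  set.seed(52)
  for (rep_i in 1:10) {
    p <- rand_pssm(L = sample(3:12, 1), id = sprintf("rt%d", rep_i))
    f <- withr::local_tempfile(fileext = ".pssm")
    write_ascii_pssm(p, f)
    p2 <- read_ascii_pssm(f, id = p$id)
    expect_identical(unname(p2$scores), unname(p$scores))
    expect_identical(p2$residues, p$residues)
  }
})

test_that("pssm_dc groups rows by query residue and divides by L", {
  p0 <- golgiCSP::pssm("z", matrix(0, 4, 20), "ACDE")
  expect_true(all(pssm_dc(p0) == 0))

  E <- matrix(0, 2, 20)
  E[1, which(AA20 == "D")] <- 1    # row 1 (residue A): unit at D
  E[2, which(AA20 == "A")] <- 1    # row 2 (residue C): unit at A
  M <- pssm_dc(golgiCSP::pssm("u", E, "AC"))
  expect_equal(unname(M["A", "D"]), 1 / 2)
  expect_equal(unname(M["C", "A"]), 1 / 2)
  expect_equal(sum(M != 0), 2)

  expect_length(flatten_evo(M), 400)
})

test_that("bigram_pssm collapses to an outer product at L = 2", {
  set.seed(62)
  E <- matrix(rnorm(40), 2, 20)
  B <- bigram_pssm(golgiCSP::pssm("b", E, "AC"))
  expect_equal(unclass(B), outer(E[1, ], E[2, ]),
               ignore_attr = TRUE)
})

test_that("ed_pssm vanishes on constant profiles and collapses at L = 3", {
  pc <- golgiCSP::pssm("c", matrix(3, 6, 20), "ACDEFG")
  expect_true(all(ed_pssm(pc) == 0))

  set.seed(63)
  E <- matrix(sample(-5:5, 60, TRUE), 3, 20)
  M <- ed_pssm(golgiCSP::pssm("e", E, "ACD"))
  expect_equal(unclass(M), outer(E[1, ], E[3, ], function(a, b) (a - b)^2),
               ignore_attr = TRUE)
  expect_true(all(M >= 0))
})

test_that("descriptors match brute-force oracles on random profiles", {
  set.seed(64)
  for (rep_i in 1:15) {
    p <- rand_pssm(L = sample(3:8, 1))
    expect_equal(unclass(pssm_dc(p)), oracle_pssm_dc(p), ignore_attr = TRUE)
    expect_equal(unclass(bigram_pssm(p)), oracle_bigram(p),
                 ignore_attr = TRUE)
    expect_equal(unclass(ed_pssm(p)), oracle_ed(p), ignore_attr = TRUE)
  }
})

test_that("pssm_dc is linear and bigram quadratic under score scaling", {
  set.seed(65)
  p <- rand_pssm(L = 7)
  p3 <- p; p3$scores <- 3 * p$scores
  expect_equal(unclass(pssm_dc(p3)), 3 * unclass(pssm_dc(p)))
  expect_equal(unclass(bigram_pssm(p3)), 9 * unclass(bigram_pssm(p)))
})

test_that("length preconditions are enforced", {
  p1 <- golgiCSP::pssm("one", matrix(1, 1, 20), "A")
  expect_error(bigram_pssm(p1), "L >= 2")
  p2 <- golgiCSP::pssm("two", matrix(1, 2, 20), "AC")
  expect_error(ed_pssm(p2), "L >= 3")
})

test_that("sigmoid rescaling maps scores through 1/(1+exp(-x))", {
  p <- golgiCSP::pssm("s", matrix(c(0, 2, -2), 3, 20), "ACD")
  ps <- scale_pssm(p, "sigmoid")
  expect_equal(unname(ps$scores[1, 1]), 0.5)
  expect_equal(ps$scores, 1 / (1 + exp(-p$scores)))
  expect_identical(scale_pssm(p, "raw")$scores, p$scores)
})
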