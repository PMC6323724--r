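# Jensen-Shannon conservation scoring, reference mapping and motif
# overlap counting.

test_that("column distributions count residues and gaps", {
  aln <- c(s1 = "GA-", s2 = "GV-", s3 = "GA-", s4 = "GVG",
           s5 = "GAG", s6 = "GVG", s7 = "GAG", s8 = "GVG",
           s9 = "GA-", s10 = "GVG")
  cd <- column_distribution(aln, 1)
  expect_equal(unname(cd$freq["G"]), 1)
  expect_equal(cd$gap_fraction, 0)
  cd2 <- column_distribution(aln, 2)
  expect_equal(unname(cd2$freq[c("A", "V")]), c(0.5, 0.5))
  cd3 <- column_distribution(aln, 3)
  expect_equal(cd3$gap_fraction, 0.4)
  expect_error(column_distribution(aln, 9),
               class = "septinevo_invalid_input")
})

test_that("js_divergence has the defining properties", {
  u <- rep(1 / 20, 20)
  expect_equal(js_divergence(u, u), 0)
  delta <- c(1, rep(0, 19))
  # direct formula evaluation: 0.5*KL(d||m) + 0.5*KL(u||m)
  m <- 0.5 * delta + 0.5 * u
  want <- 0.5 * log2(1 / m[1]) +
    0.5 * sum(u * log2(u / m))
  got <- js_divergence(delta, u)
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(got, 0.5)
  expect_lte(got, 1)
  # symmetry at lambda = 0.5
  set.seed(2)
  for (i in 1:5) {
    p <- runif(20); p <- p / sum(p)
    q <- runif(20); q <- q / sum(q)
    expect_equal(js_divergence(p, q), js_divergence(q, p),
                 tolerance = 1e-12)
  }
  expect_error(js_divergence(rep(0.1, 20), u),
               class = "septinevo_invalid_input")
  expect_error(js_divergence(u, u, lambda = 1),
               class = "septinevo_invalid_parameter")
})

test_that("background-equal columns score zero, invariant columns high", {
  # 20 sequences, each column a permutation of all 20 residues:
  # column distribution is exactly uniform
  set.seed(5)
  cols <- replicate(10, sample(septinevo:::AA20))
  aln_bg <- setNames(apply(cols, 1, paste, collapse = ""),
                     paste0("s", 1:20))
  prof <- conservation_profile(aln_bg, background = "uniform",
                               pseudocount = 0)
  expect_equal(as.numeric(prof), rep(0, 10), tolerance = 1e-12)

  # invariant ungapped column: composition with js_divergence
  aln <- c(a = "GGAC", b = "GGVC", c = "GGAC")
  prof2 <- conservation_profile(aln, background = "blosum62",
                                pseudocount = 0)
  delta <- setNames(as.numeric(septinevo:::AA20 == "G"),
                    septinevo:::AA20)
  expect_equal(prof2[1], js_divergence(delta, aa_background("blosum62")))
  expect_true(all(prof2 >= 0 & prof2 <= 1))
  # invariant columns outscore the mixed column
  expect_gt(min(prof2[c(1, 2, 4)]), prof2[3])
})

test_that("all-gap columns score zero and gaps down-weight", {
  aln <- c(a = "G-A", b = "G-A", c = "G--")
  prof <- conservation_profile(aln, background = "uniform",
                               pseudocount = 0)
  expect_equal(prof[2], 0)
  expect_equal(prof[3], (2 / 3) * prof[1], tolerance = 1e-12)
})

test_that("window smoothing is the identity on flat profiles", {
  aln <- c(a = "GGGG", b = "GGGG", c = "GGGG")
  p0 <- conservation_profile(aln, window = 0)
  p1 <- conservation_profile(aln, window = 1)
  expect_equal(as.numeric(p0), as.numeric(p1), tolerance = 1e-12)
  expect_error(conservation_profile(aln, window = 10),
               class = "septinevo_invalid_parameter")
})

test_that("excluding sequences changes the scored set", {
  aln <- c(a = "GG", b = "GG", grp5 = "AA")
  full <- conservation_profile(aln, background = "uniform",
                               pseudocount = 0)
  part <- conservation_profile(aln, background = "uniform",
                               exclude_ids = "grp5", pseudocount = 0)
  expect_gt(part[1], full[1])   # removing the divergent row sharpens
})

test_that("reference mapping is a bijection over mapped columns", {
  aln <- c(ref = "A-CD", other = "AGCD")
  rm <- map_to_reference(aln, "ref")
  expect_equal(rm$col_to_res, c("1" = 1L, "3" = 2L, "4" = 3L))
  expect_false("2" %in% names(rm$col_to_res))
  # round trip
  for (col in names(rm$col_to_res)) {
    expect_equal(unname(rm$res_to_col[as.character(rm$col_to_res[col])]),
                 as.integer(col))
  }
  # ungapped reference: identity
  rm2 <- map_to_reference(c(ref = "ACD", x = "A-D"), "ref")
  expect_equal(unname(rm2$col_to_res), 1:3)
  expect_error(map_to_reference(aln, "nope"),
               class = "septinevo_invalid_input")
})

test_that("motif_overlap partitions positions by region membership", {
  regions <- data.frame(name = c("G1", "SUE"),
                        start = c(1L, 40L), end = c(10L, 60L))
  ov <- motif_overlap(c(5L, 50L), regions)
  expect_equal(ov$inside, 1L + 1L)
  expect_equal(ov$outside, 0L)
  ov2 <- motif_overlap(c(5L, 30L), regions)
  expect_equal(ov2$inside, 1L)
  expect_equal(ov2$outside, 1L)
  # empty positions and inclusive boundaries
  expect_equal(motif_overlap(integer(0), regions)$inside, 0L)
  expect_equal(motif_overlap(10L, regions)$inside, 1L)
  expect_equal(motif_overlap(11L, regions)$inside, 0L)
  expect_error(motif_overlap(1L, data.frame(name = "x", start = 5L,
                                            end = 2L)),
               class = "septinevo_invalid_input")
})
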