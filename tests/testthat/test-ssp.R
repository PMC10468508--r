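test_that("hydrogen-bond assigner labels ideal geometries correctly", {
  # ideal alpha-helix: interior residues helical, termini coil
  helix <- isolated_trimer(build_peptide(rep(-57, 16), rep(-47, 16)))
  ss_h <- assign_secondary_structure(helix)
  lab1 <- ss_h$ss[ss_h$peptide == 1]
  expect_true(all(lab1[3:14] == "H"))
  expect_identical(lab1[1], "C")
  expect_identical(lab1[16], "C")
  # isolated fully extended chain: no hydrogen-bond partners, all coil
  ext <- isolated_trimer(build_peptide(rep(-139, 16), rep(135, 16)))
  expect_true(all(assign_secondary_structure(ext)$ss == "C"))
  # ideal two-strand antiparallel sheet: strand residues E, no helix
  sheet <- assign_secondary_structure(antiparallel_sheet_trimer())
  paired <- sheet$ss[sheet$peptide %in% 1:2]
  expect_gte(sum(paired == "E"), 16)
  expect_false(any(paired == "H"))
  expect_true(all(sheet$ss[sheet$peptide == 3] == "C"))
  # stacked cross-beta trimer: inter-peptide ladders make strand residues
  cross_beta <- assign_secondary_structure(build_trimer_template("extended"))
  expect_gte(sum(cross_beta$ss == "E"), 30)
})

test_that("assigner validates backbone completeness", {
  tri <- build_trimer_template("hairpin")
  broken <- dplyr::filter(tri, !(peptide == 2 & residue == 5 & atom == "N"))
  expect_error(assign_secondary_structure(broken),
               regexp = "peptide 2 residue 5", class = "ffbench_input_error")
})

test_that("DSSP output parsing maps 8 states to 3", {
  codes <- list(
    A = c("H", "G", "E", "B", "T", "S", " ", "I", rep("H", 8)),
    B = rep("E", 16),
    C = rep(" ", 16)
  )
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp_fixture_lines(codes), path)
  out <- parse_dssp_output(path, chains = c("A", "B", "C"))
  expect_equal(nrow(out), 48)
  a <- out$ss[out$peptide == 1]
  expect_identical(a[1:8], c("H", "C", "E", "C", "C", "C", "C", "C"))
  expect_true(all(out$ss[out$peptide == 2] == "E"))
  expect_true(all(out$ss[out$peptide == 3] == "C"))
  # configurable mapping: count 3-10 helices as helix
  out2 <- parse_dssp_output(path, chains = "A", helix_codes = c("H", "G"))
  expect_identical(out2$ss[2], "H")
  expect_error(parse_dssp_output(path, chains = c("A", "Z")),
               class = "ffbench_selection_error")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("not", "dssp"), bad)
  expect_error(parse_dssp_output(bad), class = "ffbench_format_error")
})

test_that("propensity tables count states with the chosen denominator", {
  series <- tibble::tibble(
    frame = rep(1:2, each = 6),
    peptide = rep(rep(1:3, each = 2), 2),
    residue = rep(1:2, 6),
    ss = c("H", "C", "E", "C", "C", "C", "C", "C", "C", "C", "C", "H")
  )
  # residue 1: H 1, E 1, C 4; residue 2: H 1, C 5
  pt <- propensity_table(series, n_residues = 2)
  expect_equal(pt$H, c(1, 1) / 6)
  expect_equal(pt$E, c(1, 0) / 6)
  expect_equal(pt$C, c(4, 5) / 6)
  expect_equal(pt$H + pt$E + pt$C, c(1, 1))
  ptg <- propensity_table(series, denominator = "global", n_residues = 2)
  expect_equal(ptg$H + ptg$E + ptg$C, c(0.5, 0.5)) # 1 / n_residues each
  # all-coil series
  allc <- dplyr::mutate(series, ss = "C")
  ptc <- propensity_table(allc)
  expect_true(all(ptc$C == 1))
  expect_error(propensity_table(series[0, ]), class = "ffbench_input_error")
})

test_that("consensus reference takes majority votes with ties to coil", {
  one <- tibble::tibble(model = 1L, residue = 1:3, ss = c("E", "H", "C"))
  expect_identical(consensus_reference_ss(one)$ss, c("E", "H", "C"))
  votes <- dplyr::bind_rows(purrr::map(1:20, function(m) {
    tibble::tibble(model = m, residue = 1:2,
                   ss = c(ifelse(m <= 12, "E", "C"),
                          ifelse(m <= 10, "E", "C")))
  }))
  cons <- consensus_reference_ss(votes)
  expect_identical(cons$ss, c("E", "C")) # 12/8 majority; 10/10 tie -> C
})

test_that("SSP score is the floored reference log-likelihood", {
  ref <- rep(c("H", "E", "C"), length.out = 16)
  perfect <- tibble::tibble(residue = 1:16,
                            H = as.numeric(ref == "H"),
                            E = as.numeric(ref == "E"),
                            C = as.numeric(ref == "C"))
  expect_equal(ssp_score(perfect, ref), 0)
  uniform <- tibble::tibble(residue = 1:16, H = 1 / 3, E = 1 / 3, C = 1 / 3)
  expect_equal(ssp_score(uniform, ref), 16 * log(1 / 3), tolerance = 1e-12)
  # zero propensity at one reference label is floored at epsilon
  droppy <- perfect
  droppy$H[1] <- 0
  droppy$C[1] <- 1
  expect_equal(ssp_score(droppy, ref, epsilon = 1e-6), log(1e-6))
  expect_lte(ssp_score(uniform, ref), 0)
  expect_error(ssp_score(uniform, ref[1:5]), class = "ffbench_input_error")
})

test_that("normalized SSP scores are invariant to log base and to the printed global denominator", {
  refs <- list(u = rep(c("E", "C"), 8), l = rep("E", 16))
  set.seed(31)
  tables <- purrr::map(1:4, function(k) {
    raw <- matrix(stats::rexp(48) + 0.5, 16, 3)
    raw <- raw / rowSums(raw)
    tibble::tibble(residue = 1:16, H = raw[, 1], E = raw[, 2], C = raw[, 3])
  })
  series <- purrr::map(1:4, function(k) {
    sample_ss_series(tables[[k]], n_snapshots = 50, seed = 100 + k)
  })
  norm_scores <- function(base, denominator) {
    raw <- vapply(series, function(s) {
      pt <- propensity_table(s, denominator = denominator)
      ssp_score(pt, refs$u, base = base)
    }, numeric(1))
    v <- minmax_normalize(tibble::tibble(force_field = paste0("ff", 1:4),
                                         score = raw), "score")
    v$score_norm
  }
  base_e <- norm_scores(exp(1), "per_residue")
  base_10 <- norm_scores(10, "per_residue")
  expect_lt(max(abs(base_e - base_10)), 1e-12)
  global <- norm_scores(exp(1), "global")
  expect_lt(max(abs(base_e - global)), 1e-12)
  # the global denominator shifts every raw score by the same constant
  raw_pr <- vapply(series, function(s) {
    ssp_score(propensity_table(s, denominator = "per_residue"), refs$u)
  }, numeric(1))
  raw_gl <- vapply(series, function(s) {
    ssp_score(propensity_table(s, denominator = "global"), refs$u)
  }, numeric(1))
  expect_lt(max(abs((raw_gl - raw_pr) - 16 * log(1 / 16))), 1e-9)
})
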