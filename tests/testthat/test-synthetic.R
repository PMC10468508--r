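test_that("the generator is bitwise reproducible and honours its spec", {
  spec <- ensemble_spec(6, c(U = 0.4, L = 0.3, coil = 0.3), 0.2, seed = 77)
  a <- make_trimer_ensemble(spec)
  b <- make_trimer_ensemble(spec)
  expect_identical(a, b)
  expect_identical(sort(unique(a$frame)), 1:6)
  # invalid specs
  expect_error(ensemble_spec(0), class = "ffbench_config_error")
  expect_error(ensemble_spec(5, c(U = 0.6, L = 0.6, coil = -0.2)),
               class = "ffbench_config_error")
})

test_that("noise-free single-state snapshots equal the template exactly", {
  spec <- ensemble_spec(1, c(U = 1, L = 0, coil = 0),
                        coordinate_noise_sd = 0, seed = 5)
  fr <- make_trimer_ensemble(spec)
  tmpl <- build_trimer_template("hairpin")
  expect_equal(fr[, c("x", "y", "z")], tmpl[, c("x", "y", "z")])
  expect_identical(unique(fr$state), "U")
})

test_that("state templates produce the intended Rg structure", {
  spec_u <- ensemble_spec(30, c(U = 1, L = 0, coil = 0), 0.2, seed = 41)
  rg_u <- rg_samples(make_trimer_ensemble(spec_u), "trimer")$rg
  tmpl_rg <- compute_rg(build_trimer_template("hairpin"))
  expect_lt(abs(mean(rg_u) - tmpl_rg), 0.5)
  expect_lt(sd(rg_u), 0.5)
  spec_l <- ensemble_spec(10, c(U = 0, L = 1, coil = 0), 0.2, seed = 42)
  rg_l <- rg_samples(make_trimer_ensemble(spec_l), "trimer")$rg
  expect_gt(mean(rg_l), mean(rg_u) + 4) # extended state is far less compact
})

test_that("coil peptides reproduce Flory random-coil dimensions", {
  spec <- ensemble_spec(40, c(U = 0, L = 0, coil = 1), 0.1, seed = 43)
  frames <- make_trimer_ensemble(spec)
  rg_pep <- rg_samples(frames, "peptide")$rg
  target <- flory_rg(16)
  expect_lt(abs(median(rg_pep) - target) / target, 0.20)
  # separated coils are predominantly monomeric
  states <- vapply(split(frames, frames$frame),
                   function(fr) oligomer_state(fr)$state, character(1))
  expect_gt(mean(states == "monomer"), 0.8)
})

test_that("mixture sampling matches its parameters within CLT bounds", {
  w <- c(0.6, 0.4); mu <- c(10, 16); s <- c(1, 2)
  x <- sample_rg_mixture(w, mu, s, 20000, seed = 9)
  exp_mean <- sum(w * mu)
  exp_var <- sum(w * (s^2 + mu^2)) - exp_mean^2
  se <- sqrt(exp_var / 20000)
  expect_lt(abs(mean(x) - exp_mean), 3 * se)
  expect_identical(x, sample_rg_mixture(w, mu, s, 20000, seed = 9))
  y <- sample_rg_mixture(c(1, 0), mu, s, 5000, seed = 10)
  expect_lt(abs(mean(y) - 10), 3 / sqrt(5000))
})

test_that("sampled label series recover their propensity table", {
  set.seed(77)
  raw <- matrix(stats::rexp(48) + 0.3, 16, 3)
  raw <- raw / rowSums(raw)
  pt <- tibble::tibble(residue = 1:16, H = raw[, 1], E = raw[, 2],
                       C = raw[, 3])
  series <- sample_ss_series(pt, n_snapshots = 10000, seed = 12)
  est <- propensity_table(series)
  expect_lt(max(abs(est$H - pt$H)), 0.02)
  expect_lt(max(abs(est$E - pt$E)), 0.02)
  expect_lt(max(abs(est$C - pt$C)), 0.02)
  # plug-in likelihood close to its closed form
  ref <- rep(c("E", "C"), 8)
  closed_form <- sum(log(vapply(1:16, function(i) pt[[ref[i]]][i],
                                numeric(1))))
  expect_lt(abs(ssp_score(est, ref) - closed_form), 0.05)
  # degenerate table
  allc <- tibble::tibble(residue = 1:16, H = 0, E = 0, C = 1)
  expect_true(all(sample_ss_series(allc, 5, seed = 1)$ss == "C"))
})

test_that("contact series match the analytic confusion expectation", {
  ref <- eligible_pairs(16)
  withr::with_seed(15, {
    ref$contact <- seq_len(105) %in% sample.int(105, 20)
  })
  prev <- 20 / 105
  # perfect detector
  perfect <- sample_contact_series(ref, 1, 1, 50, seed = 2)
  expect_equal(mcc(accumulate_confusion(perfect, ref)), 1.0)
  # sensitivity = 1 - specificity: prediction independent of the reference
  expect_equal(analytic_mcc(0.3, 0.7, prev), 0, tolerance = 1e-12)
  # stochastic detector within 3 SE of the closed form (SE calibrated by
  # repeated simulation at this problem size)
  series <- sample_contact_series(ref, 0.9, 0.9, 5000, seed = 16)
  got <- mcc(accumulate_confusion(series, ref))
  expect_lt(abs(got - analytic_mcc(0.9, 0.9, prev)), 0.004)
})

test_that("generated PDB fixtures round-trip through the IO layer", {
  spec <- ensemble_spec(2, c(U = 0.5, L = 0.5, coil = 0), 0.2, seed = 19)
  path <- withr::local_tempfile(fileext = ".pdb")
  frames <- make_trimer_ensemble(spec, path = path)
  expect_true(file.exists(path))
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(manifest$seed, 19)
  back <- read_trimer_models(path, first_residue = 1)
  expect_equal(length(unique(back$model)), 2)
  expect_lt(max(abs(sort(back$x) - sort(frames$x))), 1e-3 + 1e-9)
})
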