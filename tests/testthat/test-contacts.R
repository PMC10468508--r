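test_that("eligible pair universe excludes sequence neighbours", {
  u16 <- eligible_pairs(16)
  expect_equal(nrow(u16), 105)
  # brute-force enumeration oracle
  brute <- 0
  for (i in 1:16) for (j in 1:16) if (j >= i + 2) brute <- brute + 1
  expect_equal(nrow(u16), brute)
  expect_true(all(u16$j >= u16$i + 2))
  u3 <- eligible_pairs(3)
  expect_identical(as.data.frame(u3), data.frame(i = 1L, j = 3L))
  expect_equal(nrow(eligible_pairs(2)), 0)
  expect_error(eligible_pairs(1), class = "ffbench_input_error")
})

test_that("snapshot contact detection matches a brute-force all-pairs oracle", {
  for (seed in c(5, 6)) {
    atoms <- random_trimer_atoms(seed)
    for (p in 1:3) {
      fast <- snapshot_contact_map(atoms, peptide = p, cutoff = 5)
      slow <- brute_force_contact_map(atoms, peptide = p, cutoff = 5)
      expect_identical(fast, slow)
    }
  }
  # cutoff boundary is inclusive
  expect_true(snapshot_contact_map(two_residue_probe(4.9), cutoff = 5,
                                   n_residues = 3)$contact)
  expect_true(snapshot_contact_map(two_residue_probe(5.0), cutoff = 5,
                                   n_residues = 3)$contact)
  expect_false(snapshot_contact_map(two_residue_probe(5.1), cutoff = 5,
                                    n_residues = 3)$contact)
  # hydrogens never create contacts
  probe <- dplyr::bind_rows(two_residue_probe(20),
                            atom_row(1, 1, "H", "H", 20, 0.5, 0))
  expect_false(any(snapshot_contact_map(probe, cutoff = 5,
                                        n_residues = 3)$contact))
})

test_that("ensemble frequencies filter below threshold per peptide then average", {
  pairs <- eligible_pairs(4) # (1,3) (1,4) (2,4)
  mk <- function(frame, peptide, contacts) {
    dplyr::mutate(pairs, frame = frame, peptide = peptide,
                  contact = contacts)
  }
  # pair (1,3): present 30% in peptide 1, 0% in 2, 60% in 3
  series <- dplyr::bind_rows(purrr::map(1:10, function(f) {
    dplyr::bind_rows(
      mk(f, 1, c(f <= 3, TRUE, FALSE)),
      mk(f, 2, c(FALSE, TRUE, FALSE)),
      mk(f, 3, c(f <= 6, TRUE, FALSE))
    )
  }))
  freq <- ensemble_contact_frequencies(series, min_freq = 0.01)
  expect_equal(freq$frequency[freq$i == 1 & freq$j == 3], 0.3)
  expect_equal(freq$frequency[freq$i == 1 & freq$j == 4], 1.0)
  expect_equal(freq$frequency[freq$i == 2 & freq$j == 4], 0.0)
  # sub-threshold frequencies are zeroed per peptide before averaging
  series2 <- dplyr::bind_rows(purrr::map(1:200, function(f) {
    dplyr::bind_rows(
      mk(f, 1, c(f == 1, FALSE, FALSE)), # 0.5% < 1%
      mk(f, 2, c(f == 1, FALSE, FALSE)),
      mk(f, 3, c(f == 1, FALSE, FALSE))
    )
  }))
  freq2 <- ensemble_contact_frequencies(series2, min_freq = 0.01)
  expect_equal(freq2$frequency[freq2$i == 1 & freq2$j == 3], 0.0)
  freq3 <- ensemble_contact_frequencies(series2, min_freq = 0)
  expect_equal(freq3$frequency[freq3$i == 1 & freq3$j == 3], 0.005)
})

test_that("reference contact maps carry contact classes and medium-range flags", {
  triU <- build_trimer_template("hairpin")
  refU <- reference_contact_map(triU, peptide = 1)
  expect_true(all(refU$class[refU$contact] %in%
                    c("Bb-Bb", "Sc-Bb", "Sc-Sc")))
  expect_true(all(is.na(refU$class[!refU$contact])))
  expect_gt(sum(refU$medium), 0) # compact hairpin has medium-range contacts
  triL <- build_trimer_template("extended")
  refL <- reference_contact_map(triL, peptide = 1)
  expect_equal(sum(refL$medium), 0) # extended strand: none beyond i+5
  expect_lt(sum(refL$contact), sum(refU$contact))
  # contact flags agree with the plain detector
  plain <- snapshot_contact_map(triU, peptide = 1)
  expect_identical(refU$contact, plain$contact)
})

test_that("confusion accumulation reproduces exact marginal fractions", {
  ref <- eligible_pairs(16)
  withr::with_seed(8, {
    ref$contact <- seq_len(105) %in% sample.int(105, 20)
  })
  mk_series <- function(n, contacts) {
    dplyr::bind_rows(purrr::map(seq_len(n), function(f) {
      dplyr::mutate(ref, frame = f, contact = contacts)
    }))
  }
  perfect <- accumulate_confusion(mk_series(7, ref$contact), ref)
  expect_equal(perfect$tp, 100 * 20 / 105, tolerance = 1e-9)
  expect_equal(perfect$tn, 100 * 85 / 105, tolerance = 1e-9)
  expect_equal(perfect$fp + perfect$fn, 0)
  empty <- accumulate_confusion(mk_series(7, FALSE), ref)
  expect_equal(empty$fn, 100 * 20 / 105, tolerance = 1e-9)
  expect_equal(empty$tn, 100 * 85 / 105, tolerance = 1e-9)
  full <- accumulate_confusion(mk_series(7, TRUE), ref)
  expect_equal(full$tp, 100 * 20 / 105, tolerance = 1e-9)
  expect_equal(full$fp, 100 * 85 / 105, tolerance = 1e-9)
  # marginal conservation and total = 100 for arbitrary predictions
  withr::with_seed(9, {
    rand <- mk_series(11, ref$contact)
    rand$contact <- runif(nrow(rand)) < 0.4
  })
  cm <- accumulate_confusion(rand, ref)
  expect_equal(cm$tp + cm$fn, 100 * 20 / 105, tolerance = 1e-9)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 100, tolerance = 1e-6)
  # universe mismatch is an error
  expect_error(accumulate_confusion(rand, eligible_pairs(15) |>
                                      dplyr::mutate(contact = FALSE)),
               class = "ffbench_input_error")
})

test_that("MCC follows its closed form, conventions, and symmetry", {
  # published confusion matrix of the top contact-map ensemble
  expect_equal(mcc(13.75, fp = 3.52, fn = 5.3, tn = 77.43), 0.70418,
               tolerance = 0.005 / 0.70418)
  expect_equal(mcc(19.048, fp = 0, fn = 0, tn = 80.952), 1.0)
  # independent predictions: zero correlation
  expect_equal(mcc(9.52, fp = 40.48, fn = 9.52, tn = 40.48), 0,
               tolerance = 1e-12)
  # degenerate marginals return 0 by convention
  expect_equal(mcc(0, fp = 0, fn = 20, tn = 80), 0)
  expect_equal(mcc(0, fp = 0, fn = 0, tn = 100), 0)
  # symmetry: swapping prediction and reference transposes FP and FN
  expect_equal(mcc(13.75, fp = 5.3, fn = 3.52, tn = 77.43),
               mcc(13.75, fp = 3.52, fn = 5.3, tn = 77.43))
  expect_gte(mcc(50, fp = 0, fn = 0, tn = 50), -1)
})

test_that("oligomer classification follows the contact-count rules", {
  triU <- build_trimer_template("hairpin")
  expect_identical(oligomer_state(triU)$state, "trimer")
  # separated coils are monomers
  pep <- build_peptide(rep(-139, 16), rep(135, 16))
  mono <- isolated_trimer(pep)
  expect_identical(oligomer_state(mono)$state, "monomer")
  expect_error(middle_peptide_index(mono), class = "ffbench_input_error")
  # dimer: peptides 1-2 stacked, 3 far away
  dimer <- toy_inter_trimer(y_off = c(0, 4, 500))
  st <- oligomer_state(dimer)
  expect_identical(st$state, "dimer")
  expect_identical(st$pair_contacts$n_contacts[st$pair_contacts$pair ==
                                                 "1-2"], 16L)
  # middle peptide: stacked trimer -> peptide 2; dimer tie -> lowest index
  expect_identical(middle_peptide_index(toy_inter_trimer(c(0, 4, 8))), 2L)
  expect_identical(middle_peptide_index(dimer), 1L)
})

test_that("inter-peptide confusion scores middle-edge maps with the edge FP rule", {
  tri <- toy_inter_trimer(c(0, 4, 8))
  tri$frame <- 1L
  frames <- dplyr::bind_rows(tri, dplyr::mutate(tri, frame = 2L))
  # reference: middle peptide (row role) against one edge
  ref_ab <- inter_reference_map(tri, peptides = c(2, 1))
  expect_equal(sum(ref_ab$contact), 16) # in-register single-atom ladder
  res <- inter_contact_confusion(frames, ref_ab)
  expect_identical(res$states$state, c("trimer", "trimer"))
  expect_equal(res$mcc, 1.0)
  expect_equal(res$confusion$fp, 0)
  expect_equal(res$confusion$n_instances, 2 * 3 * 256)
  # snapshots whose only contacts disagree with the reference: MCC <= 0
  off_ref <- ref_ab
  off_ref$contact <- off_ref$j == ((off_ref$i + 4 - 1) %% 16) + 1
  res2 <- inter_contact_confusion(frames, off_ref)
  expect_equal(res2$confusion$tp, 0)
  expect_gt(res2$confusion$fp, 0)
  expect_lte(res2$mcc, 0)
  # monomer snapshots contribute predicted negatives only
  mono <- toy_inter_trimer(c(0, 500, 1000))
  mono$frame <- 1L
  res3 <- inter_contact_confusion(mono, ref_ab)
  expect_identical(res3$states$state, "monomer")
  expect_equal(res3$confusion$tp + res3$confusion$fp, 0)
  expect_gt(res3$confusion$fn, 0)
})
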