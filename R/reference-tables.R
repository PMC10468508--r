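# Published score tables of the R2-FUS-LC force-field benchmark (13 force
# field / water model combinations). These constants drive the regression
# harness in verify_printed_tables(): every derivable value (normalized
# columns, combined scores, MCC from the confusion matrices) is recomputed
# by this package's scoring layer and compared against the printed numbers.

#' Published benchmark score tables
#'
#' The printed score tables of the R2-FUS-LC force-field benchmark, embedded
#' as data: the final-summary table (normalized Rg/SSP/contact-map scores,
#' final score and rank), the three-component Rg table (U-shaped, L-shaped,
#' unfolded normalized scores and their renormalized product), the
#' intra-peptide contact-map table (raw and normalized MCC), four published
#' intra-peptide confusion matrices (percentages), and the SSP table
#' (U-shaped, L-shaped normalized scores and their renormalized product).
#'
#' @return Named list of tibbles: `summary`, `rg`, `contact`, `confusion`,
#'   `ssp`.
#' @seealso [verify_printed_tables()]
#' @export
published_scores <- function() {
  summary <- tibble::tribble(
    ~force_field, ~rg, ~ssp, ~contact_map, ~final, ~rank,
    "c36m2021s3p",  1,       0.65613, 0.77657, 5.10e-01, 1L,
    "a99sb4pew",    0.39845, 1,       0.64988, 2.59e-01, 2L,
    "c36ms3p",      0.8692,  0.31996, 0.85621, 2.38e-01, 3L,
    "a19sbopc",     0.30691, 0.61874, 0.7161,  1.36e-01, 4L,
    "a99disp",      0.21986, 0.51499, 0.543,   6.15e-02, 5L,
    "a99sbildn4pd", 0.19783, 0.45716, 0.47616, 4.31e-02, 6L,
    "a99sbCufix3p", 0.07391, 0.7345,  0.34292, 1.86e-02, 7L,
    "c22s3p",       0.05156, 0.4001,  0.53323, 1.10e-02, 8L,
    "a03ws",        0.02029, 0.10312, 0.1012,  2.12e-04, 9L,
    "a14sb3p",      0.00001, 0.76161, 0.40067, 3.05e-06, 10L,
    "c36m3pm",      0.00029, 0.0032,  0.9946,  9.23e-07, 11L,
    "c36m2021s3pm", 0.04438, 0.00001, 1,       4.44e-07, 12L,
    "c27s3p",       0.0313,  0.00001, 0.00001, 3.13e-12, 13L
  )
  rg <- tibble::tribble(
    ~force_field, ~u, ~l, ~unfolded, ~final,
    "c36m2021s3p",  0.05654, 0.26227, 0.04817, 1.00000,
    "c36ms3p",      0.02194, 1.00000, 0.02830, 0.86920,
    "a99sb4pew",    1.00000, 0.43082, 0.00066, 0.39845,
    "a19sbopc",     0.11252, 0.17544, 0.01111, 0.30691,
    "a99disp",      0.09730, 0.16614, 0.00972, 0.21986,
    "a99sbildn4pd", 0.06440, 0.20090, 0.01092, 0.19783,
    "a99sbCufix3p", 0.14855, 0.21916, 0.00162, 0.07391,
    "c22s3p",       0.04650, 0.11735, 0.00675, 0.05156,
    "c36m2021s3pm", 0.00035, 0.08977, 1.00000, 0.04438,
    "c27s3p",       0.07513, 0.13992, 0.00213, 0.03130,
    "a03ws",        0.03703, 0.10192, 0.00384, 0.02029,
    "c36m3pm",      0.00001, 0.08983, 0.22404, 0.00029,
    "a14sb3p",      0.91433, 0.00001, 0.00001, 0.00001
  )
  contact <- tibble::tribble(
    ~force_field, ~mcc_raw, ~mcc_norm,
    "c36m2021s3pm", 0.70418, 1.00000,
    "c36m3pm",      0.70323, 0.99460,
    "c36ms3p",      0.67892, 0.85621,
    "c36m2021s3p",  0.66494, 0.77657,
    "a19sbopc",     0.65431, 0.71610,
    "a99sb4pew",    0.64268, 0.64988,
    "a99disp",      0.62391, 0.54300,
    "c22s3p",       0.62219, 0.53323,
    "a99sbildn4pd", 0.61217, 0.47616,
    "a14sb3p",      0.59891, 0.40067,
    "a99sbCufix3p", 0.58877, 0.34292,
    "a03ws",        0.54631, 0.10120,
    "c27s3p",       0.52854, 0.00001
  )
  confusion <- tibble::tribble(
    ~force_field, ~tp, ~fp, ~fn, ~tn,
    "c36m2021s3p",  13.86, 5.13, 5.18, 75.82,
    "a99sbCufix3p", 14.17, 8.99, 4.88, 71.96,
    "c36m2021s3pm", 13.75, 3.52, 5.30, 77.43,
    "c36m3pm",      13.75, 3.57, 5.29, 77.38
  )
  ssp <- tibble::tribble(
    ~force_field, ~u, ~l, ~final,
    "a99sb4pew",    1,        1,        1,
    "a14sb3p",      0.852963, 0.892893, 0.761607,
    "a99sbCufix3p", 0.823343, 0.892089, 0.734498,
    "c36m2021s3p",  0.787453, 0.833228, 0.656131,
    "a19sbopc",     0.725248, 0.853141, 0.618743,
    "a99disp",      0.708013, 0.727370, 0.514992,
    "a99sbildn4pd", 0.677607, 0.674657, 0.457158,
    "c22s3p",       0.630039, 0.635035, 0.400103,
    "c36ms3p",      0.564177, 0.567119, 0.319962,
    "a03ws",        0.330989, 0.311533, 0.103123,
    "c36m3pm",      0.044558, 0.071552, 0.003198,
    "c36m2021s3pm", 0.000010, 0.057822, 0.000010,
    "c27s3p",       0.011461, 0.000010, 0.000010
  )
  list(summary = summary, rg = rg, contact = contact,
       confusion = confusion, ssp = ssp)
}

#' Recompute every derivable published table value
#'
#' Regression harness over the embedded published tables
#' ([published_scores()]): recomputes (a) the raw MCC of the four published
#' confusion matrices, (b) the normalized contact-map column from the raw
#' MCC column, (c) the final Rg score from the three normalized Rg
#' components, (d) the final SSP score from its two components, and (e) the
#' final summary score as the product of the three normalized measures —
#' all with this package's scoring functions — and reports the deviation
#' from each printed value.
#'
#' @return Tibble with columns `check`, `force_field`, `printed`,
#'   `computed`, `abs_error`.
#' @export
verify_printed_tables <- function() {
  tabs <- published_scores()
  rows <- list()
  add <- function(check, ff, printed, computed) {
    tibble(check = check, force_field = ff, printed = printed,
           computed = computed, abs_error = abs(printed - computed))
  }
  # (a) MCC from published confusion matrices vs the raw MCC column
  for (k in seq_len(nrow(tabs$confusion))) {
    cm <- tabs$confusion[k, ]
    computed <- mcc(cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    printed <- tabs$contact$mcc_raw[tabs$contact$force_field ==
                                      cm$force_field]
    rows[[length(rows) + 1]] <-
      add("mcc_from_confusion", cm$force_field, printed, computed)
  }
  # (b) normalized contact-map column from the raw MCC column
  norm <- minmax_normalize(tabs$contact, "mcc_raw", name = "computed")
  rows[[length(rows) + 1]] <- add("contact_map_normalized",
                                  norm$force_field, norm$mcc_norm,
                                  norm$computed)
  # (c) final Rg score from the three normalized components
  tov <- function(tab, col) tibble(force_field = tab$force_field,
                                   value = tab[[col]])
  rg_final <- combine_product(tov(tabs$rg, "u"), tov(tabs$rg, "l"),
                              tov(tabs$rg, "unfolded"), renormalize = TRUE)
  rows[[length(rows) + 1]] <- add("rg_final", rg_final$force_field,
                                  tabs$rg$final, rg_final$value_norm)
  # (d) final SSP score from its two components
  ssp_final <- combine_product(tov(tabs$ssp, "u"), tov(tabs$ssp, "l"),
                               renormalize = TRUE)
  rows[[length(rows) + 1]] <- add("ssp_final", ssp_final$force_field,
                                  tabs$ssp$final, ssp_final$value_norm)
  # (e) final summary score = bare product of the three normalized measures
  fin <- combine_product(tov(tabs$summary, "rg"), tov(tabs$summary, "ssp"),
                         tov(tabs$summary, "contact_map"),
                         renormalize = FALSE)
  rows[[length(rows) + 1]] <- add("final_score", fin$force_field,
                                  tabs$summary$final, fin$value)
  bind_rows(rows)
}
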