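#' Assemble a benchmark configuration
#'
#' Collects every option of the full benchmark in one object. Ensembles may
#' be given as in-memory snapshot streams (atom tibbles with a `frame`
#' column) or as [ensemble_source()] objects pointing at multi-model PDB
#' replica files; reference structures as atom tibbles (multi-model for the
#' U-shaped NMR reference) or PDB paths.
#'
#' @param ensembles Named list (>= 2 entries, one per force field) of atom
#'   tibbles or [ensemble_source()] objects.
#' @param reference_u U-shaped reference: multi-model atom tibble or PDB
#'   path.
#' @param reference_l L-shaped reference: single-model atom tibble or PDB
#'   path.
#' @param chains,first_residue,n_residues Selection window applied when
#'   references/ensembles are read from PDB files.
#' @param cutoff Contact cutoff, angstrom (inclusive).
#' @param min_freq Intra-peptide contact frequency filter.
#' @param representative_model Model index of `reference_u` used for the
#'   reference intra-peptide contact map.
#' @param mixture Options for [fit_rg_mixture()]: `n_init`, `tol`.
#' @param flory `r0` and `nu` of the Flory prediction.
#' @param ssp `epsilon` floor and `denominator` convention for the SSP
#'   score; an optional `files` element (named list: force field ->
#'   character vector of DSSP output files, one per snapshot) switches the
#'   secondary-structure source from the internal assigner to external DSSP
#'   output.
#' @param normalization `method` (`"subtractive"`/`"printed"`), `floor`, and
#'   `final_renormalize` (renormalize the final product; the published
#'   summary table uses the bare product).
#' @param seed Global seed; per-force-field child seeds are derived from it.
#' @param output_dir Optional directory for CSV output
#'   ([write_benchmark_tables()] is called on the result when set).
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(ensembles, reference_u, reference_l,
                             chains = c("A", "B", "C"), first_residue = 1,
                             n_residues = 16, cutoff = 5, min_freq = 0.01,
                             representative_model = 1,
                             mixture = list(n_init = 10, tol = 1e-6),
                             flory = list(r0 = 2.54, nu = 0.522),
                             ssp = list(epsilon = 1e-6,
                                        denominator = "per_residue"),
                             normalization = list(method = "subtractive",
                                                  floor = 1e-5,
                                                  final_renormalize = FALSE),
                             seed = 1L, output_dir = NULL) {
  if (length(ensembles) < 2) {
    abort("At least two force-field ensembles are required (normalization needs a range).",
          class = "ffbench_config_error")
  }
  if (is.null(names(ensembles)) || any(names(ensembles) == "")) {
    abort("Ensembles must be a named list (one name per force field).",
          class = "ffbench_config_error")
  }
  structure(
    list(ensembles = ensembles, reference_u = reference_u,
         reference_l = reference_l, chains = chains,
         first_residue = first_residue, n_residues = n_residues,
         cutoff = cutoff, min_freq = min_freq,
         representative_model = representative_model, mixture = mixture,
         flory = flory, ssp = ssp, normalization = normalization,
         seed = as.integer(seed), output_dir = output_dir),
    class = "benchmark_config"
  )
}

#' Read a benchmark configuration from a YAML file
#'
#' The YAML mirrors [benchmark_config()]: `ensembles` is a map of force
#' field name to `paths` (replica PDB files), optional `time_per_frame`
#' (ps) and `discard_initial` (ns); `reference_u`/`reference_l` are PDB
#' paths; all remaining keys are passed through.
#'
#' @param path YAML file path.
#' @return A `benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  y <- yaml::read_yaml(path)
  ens <- purrr::map(y$ensembles, function(e) {
    ensemble_source(
      paths = unlist(e$paths),
      time_per_frame = e$time_per_frame %||% 20,
      discard_initial = e$discard_initial %||% 100
    )
  })
  args <- y[setdiff(names(y), c("ensembles", "reference_u", "reference_l"))]
  do.call(benchmark_config, c(
    list(ensembles = ens, reference_u = y$reference_u,
         reference_l = y$reference_l),
    args
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(stage, label, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage '", stage, "' failed for '", label, "': ",
                 conditionMessage(e)),
          class = "ffbench_stage_error", parent = e)
  })
}

.resolve_structure <- function(x, config) {
  if (is.data.frame(x)) {
    return(x)
  }
  read_trimer_models(x, chains = config$chains,
                     first_residue = config$first_residue,
                     n_residues = config$n_residues)
}

.resolve_ensemble <- function(x, config) {
  if (is.data.frame(x)) {
    return(x)
  }
  if (inherits(x, "ensemble_source")) {
    return(read_ensemble(x, chains = config$chains,
                         first_residue = config$first_residue,
                         n_residues = config$n_residues))
  }
  abort("Ensemble must be an atom tibble or an ensemble_source.",
        class = "ffbench_config_error")
}

# per-model trimer Rg averaged over models (the U-shaped reference Rg)
.mean_model_rg <- function(models_atoms) {
  frames <- models_atoms
  key <- if ("model" %in% names(frames)) "model" else "frame"
  mean(vapply(split(frames, frames[[key]]), compute_rg, numeric(1)))
}

#' Run the full multi-measure benchmark
#'
#' Executes the three measures for every force-field ensemble and combines
#' them into the final ranking:
#' Rg (two-Gaussian mixture fit of the trimer Rg distribution scored
#' against the U-shaped mean-model Rg, the L-shaped Rg and the Flory
#' unfolded prediction), intra-peptide contact-map MCC against the
#' representative U-shaped reference map, and the SSP log-likelihood against
#' the U- and L-shaped reference secondary structures. Raw scores are
#' min-max normalized across force fields; the final Rg and SSP scores are
#' renormalized products of their components; the final score is the
#' product of the three normalized measures.
#'
#' @param config A [benchmark_config()] or the path of a YAML file for
#'   [read_benchmark_config()].
#' @return List of class `ff_benchmark`: `summary` (the final
#'   `ff_score_table`), per-measure tables `rg_table`, `contact_table`,
#'   `ssp_table`, per-force-field `confusion` matrices and mixture `fits`,
#'   the `references` used (Rg values, contact map, secondary structures),
#'   and `options`.
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) {
    config <- read_benchmark_config(config)
  }
  stopifnot(inherits(config, "benchmark_config"))
  n_res <- config$n_residues

  ref_u <- .stage("references", "reference_u",
                  .resolve_structure(config$reference_u, config))
  ref_l <- .stage("references", "reference_l",
                  .resolve_structure(config$reference_l, config))
  if (!"model" %in% names(ref_u)) ref_u$model <- 1L
  if (!"model" %in% names(ref_l)) ref_l$model <- 1L

  rg_u_ref <- .mean_model_rg(ref_u)
  rg_l_ref <- .mean_model_rg(ref_l)
  rg_fl <- flory_rg(n_res, config$flory$r0, config$flory$nu)

  rep_model <- ref_u[ref_u$model == config$representative_model, ,
                     drop = FALSE]
  if (nrow(rep_model) == 0) {
    abort("representative_model not present in reference_u.",
          class = "ffbench_config_error")
  }
  # intra-peptide reference map from the representative model's middle
  # peptide (the fibril-interior peptide)
  mid <- tryCatch(middle_peptide_index(rep_model, cutoff = config$cutoff,
                                       n_residues = n_res),
                  error = function(e) 1L)
  ref_map <- reference_contact_map(rep_model, peptide = mid,
                                   cutoff = config$cutoff,
                                   n_residues = n_res)

  # reference secondary structures: majority vote over models x peptides
  ss_models <- function(atoms) {
    purrr::map_dfr(unique(atoms$model), function(m) {
      assign_secondary_structure(atoms[atoms$model == m, , drop = FALSE],
                                 n_residues = n_res) %>%
        mutate(model = m)
    })
  }
  ref_ss_u <- consensus_reference_ss(.stage("ssp_analysis", "reference_u",
                                            ss_models(ref_u)))
  ref_ss_l <- consensus_reference_ss(.stage("ssp_analysis", "reference_l",
                                            ss_models(ref_l)))

  labels <- names(config$ensembles)
  per_ff <- purrr::imap(config$ensembles, function(ens, ff) {
    k <- match(ff, labels)
    frames <- .stage("ensemble_io", ff, .resolve_ensemble(ens, config))
    rg <- .stage("rg_analysis", ff, {
      rg_tri <- rg_samples(frames, "trimer")
      rg_pep <- rg_samples(frames, "peptide")
      fit <- fit_rg_mixture(rg_tri$rg, seed = child_seed(config$seed, k),
                            n_init = config$mixture$n_init,
                            tol = config$mixture$tol)
      list(fit = fit,
           scores = c(u = reference_rg_score(fit, rg_u_ref),
                      l = reference_rg_score(fit, rg_l_ref),
                      unfolded = unfolded_rg_score(rg_pep$rg, rg_fl)))
    })
    contact <- .stage("contact_analysis", ff, {
      series <- intra_contact_series(frames, cutoff = config$cutoff,
                                     n_residues = n_res)
      conf <- accumulate_confusion(series,
                                   ref_map[, c("i", "j", "contact")])
      list(confusion = conf, mcc = mcc(conf),
           frequencies = ensemble_contact_frequencies(
             series, min_freq = config$min_freq))
    })
    ssp <- .stage("ssp_analysis", ff, {
      labels_series <- if (!is.null(config$ssp$files)) {
        fls <- config$ssp$files[[ff]]
        if (is.null(fls)) {
          abort(paste0("No DSSP files configured for '", ff, "'."),
                class = "ffbench_config_error")
        }
        purrr::imap_dfr(fls, function(f, k) {
          parse_dssp_output(f, chains = config$chains) %>%
            mutate(frame = k,
                   residue = .data$resno - config$first_residue + 1L) %>%
            select("frame", "peptide", "residue", "ss")
        })
      } else {
        ssp_assignments(frames, n_residues = n_res)
      }
      ptab <- propensity_table(labels_series,
                               denominator = config$ssp$denominator,
                               n_residues = n_res)
      list(ptable = ptab,
           u = ssp_score(ptab, ref_ss_u, epsilon = config$ssp$epsilon),
           l = ssp_score(ptab, ref_ss_l, epsilon = config$ssp$epsilon))
    })
    list(fit = rg$fit, rg_scores = rg$scores, contact = contact, ssp = ssp,
         n_frames = length(unique(frames$frame)))
  })

  norm_opts <- config$normalization
  vec <- function(values) tibble(force_field = labels, value = values)
  normalize <- function(values) {
    minmax_normalize(vec(values), "value", method = norm_opts$method,
                     floor = norm_opts$floor, name = "norm")
  }
  rg_u_n <- normalize(vapply(per_ff, function(x) x$rg_scores[["u"]],
                             numeric(1)))
  rg_l_n <- normalize(vapply(per_ff, function(x) x$rg_scores[["l"]],
                             numeric(1)))
  rg_f_n <- normalize(vapply(per_ff, function(x) x$rg_scores[["unfolded"]],
                             numeric(1)))
  mcc_n <- normalize(vapply(per_ff, function(x) x$contact$mcc, numeric(1)))
  ssp_u_n <- normalize(vapply(per_ff, function(x) x$ssp$u, numeric(1)))
  ssp_l_n <- normalize(vapply(per_ff, function(x) x$ssp$l, numeric(1)))

  as_value <- function(nrm) tibble(force_field = nrm$force_field,
                                   value = nrm$norm)
  rg_final <- combine_product(as_value(rg_u_n), as_value(rg_l_n),
                              as_value(rg_f_n), renormalize = TRUE,
                              floor = norm_opts$floor)
  ssp_final <- combine_product(as_value(ssp_u_n), as_value(ssp_l_n),
                               renormalize = TRUE, floor = norm_opts$floor)

  summary <- final_score(
    tibble(force_field = labels,
           value = rg_final$value_norm[match(labels,
                                             rg_final$force_field)]),
    tibble(force_field = labels,
           value = ssp_final$value_norm[match(labels,
                                              ssp_final$force_field)]),
    as_value(mcc_n),
    renormalize = norm_opts$final_renormalize
  )

  rg_table <- tibble(
    force_field = labels,
    raw_u = rg_u_n$value, raw_l = rg_l_n$value, raw_unfolded = rg_f_n$value,
    u = rg_u_n$norm, l = rg_l_n$norm, unfolded = rg_f_n$norm,
    final = rg_final$value_norm[match(labels, rg_final$force_field)]
  )
  ssp_table <- tibble(
    force_field = labels,
    raw_u = ssp_u_n$value, raw_l = ssp_l_n$value,
    u = ssp_u_n$norm, l = ssp_l_n$norm,
    final = ssp_final$value_norm[match(labels, ssp_final$force_field)]
  )
  contact_table <- tibble(
    force_field = labels,
    mcc_raw = mcc_n$value, mcc_norm = mcc_n$norm
  )

  result <- structure(
    list(
      summary = summary, rg_table = rg_table, ssp_table = ssp_table,
      contact_table = contact_table,
      confusion = purrr::map(per_ff, ~ .x$contact$confusion),
      frequencies = purrr::map(per_ff, ~ .x$contact$frequencies),
      fits = purrr::map(per_ff, ~ .x$fit),
      propensities = purrr::map(per_ff, ~ .x$ssp$ptable),
      references = list(rg_u = rg_u_ref, rg_l = rg_l_ref, rg_flory = rg_fl,
                        contact_map = ref_map, middle_peptide = mid,
                        ss_u = ref_ss_u, ss_l = ref_ss_l),
      options = list(cutoff = config$cutoff, min_freq = config$min_freq,
                     seed = config$seed, mixture = config$mixture,
                     flory = config$flory, ssp = config$ssp,
                     normalization = norm_opts,
                     representative_model = config$representative_model,
                     n_frames = purrr::map_int(per_ff, "n_frames"))
    ),
    class = "ff_benchmark"
  )
  if (!is.null(config$output_dir)) {
    write_benchmark_tables(result, config$output_dir)
  }
  result
}

#' @export
print.ff_benchmark <- function(x, ...) {
  cat("Multi-measure force-field benchmark of",
      nrow(x$summary), "ensembles\n")
  cat(sprintf("References: Rg(U) %.2f A, Rg(L) %.2f A, Rg(Flory) %.2f A; %d reference contacts\n",
              x$references$rg_u, x$references$rg_l, x$references$rg_flory,
              sum(x$references$contact_map$contact)))
  print(as_tibble(x$summary))
  invisible(x)
}

#' Write all benchmark tables as CSV
#'
#' Emits the final summary, the per-measure score tables, the per-force
#' field confusion matrices and contact-frequency maps, the reference data,
#' and a JSON manifest of every option and seed.
#'
#' @param result An `ff_benchmark` from [run_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$summary, file.path(dir, "summary.csv"))
  readr::write_csv(result$rg_table, file.path(dir, "rg_scores.csv"))
  readr::write_csv(result$ssp_table, file.path(dir, "ssp_scores.csv"))
  readr::write_csv(result$contact_table, file.path(dir, "contact_scores.csv"))
  conf <- purrr::imap_dfr(result$confusion, function(cm, ff) {
    tibble(force_field = ff, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
           mcc = mcc(cm))
  })
  readr::write_csv(conf, file.path(dir, "confusion_matrices.csv"))
  freq <- purrr::imap_dfr(result$frequencies,
                          ~ mutate(.x, force_field = .y, .before = 1))
  readr::write_csv(freq, file.path(dir, "contact_frequencies.csv"))
  readr::write_csv(result$references$contact_map,
                   file.path(dir, "reference_contact_map.csv"))
  prop <- purrr::imap_dfr(result$propensities,
                          ~ mutate(.x, force_field = .y, .before = 1))
  readr::write_csv(prop, file.path(dir, "ss_propensities.csv"))
  jsonlite::write_json(result$options, file.path(dir, "options.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
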