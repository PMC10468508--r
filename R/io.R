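#' Read trimer models from a multi-model PDB file
#'
#' Parses a (possibly multi-model) PDB file with [bio3d::read.pdb()] and
#' selects the trimer region: `n_residues` consecutive residues starting at
#' `first_residue` on each of three chains. One atom table is returned per
#' MODEL record, stacked into a single tibble with a `model` column.
#'
#' Hydrogens are retained but flagged `is_heavy = FALSE`; every distance and
#' radius-of-gyration computation downstream uses heavy atoms only. Alternate
#' locations are resolved by [bio3d::read.pdb()] to a single conformer.
#'
#' @param path Path to a PDB file.
#' @param chains Character vector of exactly three chain identifiers, in the
#'   order they should become peptides 1, 2, 3.
#' @param first_residue First residue number (author numbering) of the window.
#' @param n_residues Window length in residues (16 for R2-FUS-LC).
#' @return A tibble of atoms with columns `model`, `peptide`, `chain`,
#'   `resno` (original author numbering), `residue` (1..`n_residues` within
#'   the window), `resname`, `eleno`, `atom`, `element`, `x`, `y`, `z`
#'   (angstrom), `mass`, `is_heavy`, `is_backbone`.
#' @seealso [select_region()], [write_trimer_pdb()]
#' @export
read_trimer_models <- function(path, chains = c("A", "B", "C"),
                               first_residue = 50, n_residues = 16) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "ffbench_format_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      abort(paste0("Could not parse PDB file '", path, "': ",
                   conditionMessage(e)),
            class = "ffbench_format_error")
    }
  )
  keep_rows <- which(pdb$atom$type %in% c("ATOM", "HETATM") &
                       pdb$atom$resid != "HOH")
  at <- pdb$atom[keep_rows, , drop = FALSE]
  n_models <- nrow(pdb$xyz)
  base <- tibble(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resname = as.character(at$resid),
    eleno = as.integer(at$eleno),
    atom = as.character(at$elety),
    element = .atom_element(at$elety, at$elesy)
  )
  idx <- atom2xyz_idx(keep_rows)
  models <- purrr::map(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, idx], ncol = 3, byrow = TRUE)
    dplyr::mutate(base, model = m, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  atoms <- bind_rows(models)
  select_region(atoms, chains = chains, first_residue = first_residue,
                n_residues = n_residues)
}

atom2xyz_idx <- function(which_rows) {
  as.vector(rbind(3 * (which_rows - 1) + 1,
                  3 * (which_rows - 1) + 2,
                  3 * (which_rows - 1) + 3))
}

.atom_element <- function(name, elesy = NULL) {
  ele <- if (is.null(elesy)) rep(NA_character_, length(name)) else
    toupper(trimws(as.character(elesy)))
  miss <- is.na(ele) | ele == ""
  if (any(miss)) {
    # first alphabetic character of the atom name (handles names like 1HG1)
    guess <- toupper(sub("^[0-9' ]*([A-Za-z]).*$", "\\1", name[miss]))
    ele[miss] <- guess
  }
  bad <- !ele %in% names(.atomic_masses)
  if (any(bad)) {
    abort(paste0("Unrecognised element(s): ",
                 paste(unique(ele[bad]), collapse = ", ")),
          class = "ffbench_format_error")
  }
  ele
}

#' Select the trimer peptide window from an atom table
#'
#' Keeps three chains and a consecutive residue window on each, renumbers the
#' window 1..`n_residues` into the `residue` column (original author numbering
#' stays in `resno`), assigns peptide indices 1..3 following the order of
#' `chains`, and attaches masses and heavy-atom/backbone flags. Selection is
#' idempotent: reapplying the same window reproduces the same table.
#'
#' @param atoms Atom tibble with at least `chain`, `resno`, `atom`, `element`,
#'   `x`, `y`, `z` (a `model` column is preserved if present).
#' @inheritParams read_trimer_models
#' @return The selected atom tibble (see [read_trimer_models()]).
#' @export
select_region <- function(atoms, chains = c("A", "B", "C"),
                          first_residue = 1, n_residues = 16) {
  if (n_residues < 1) {
    abort("Residue window must have positive length.",
          class = "ffbench_selection_error")
  }
  if (length(chains) != 3) {
    abort("Exactly three chains must be selected for a trimer.",
          class = "ffbench_selection_error")
  }
  window <- first_residue + seq_len(n_residues) - 1L
  missing_chains <- setdiff(chains, unique(atoms$chain))
  if (length(missing_chains) > 0) {
    abort(paste0("Chain(s) not present in structure: ",
                 paste(missing_chains, collapse = ", ")),
          class = "ffbench_selection_error")
  }
  sel <- atoms %>% filter(.data$chain %in% chains, .data$resno %in% window)
  for (ch in chains) {
    have <- unique(sel$resno[sel$chain == ch])
    gap <- setdiff(window, have)
    if (length(gap) > 0) {
      abort(paste0("Chain ", ch, " does not cover residue(s) ",
                   paste(gap, collapse = ", "), " of the requested window."),
            class = "ffbench_selection_error")
    }
  }
  sel <- sel %>%
    mutate(
      resno = as.integer(.data$resno),
      peptide = match(.data$chain, chains),
      residue = as.integer(.data$resno - first_residue + 1L),
      mass = unname(.atomic_masses[.data$element]),
      is_heavy = .data$element != "H",
      is_backbone = .data$atom %in% .backbone_atoms & .data$element != "H"
    )
  ord_cols <- intersect(c("model", "peptide", "residue", "eleno"), names(sel))
  sel <- sel %>% arrange(across(all_of(ord_cols)))
  keep <- intersect(
    c("model", "frame", "peptide", "chain", "resno", "residue", "resname",
      "eleno", "atom", "element", "x", "y", "z", "mass", "is_heavy",
      "is_backbone"),
    names(sel)
  )
  sel[, keep]
}

#' Write an atom table to a (multi-model) PDB file
#'
#' Writes one MODEL record per distinct value of the `model` (or `frame`)
#' column, so snapshot streams round-trip through the standard multi-model
#' PDB interchange format. Coordinates are written at PDB precision (0.001
#' angstrom).
#'
#' @param atoms Atom tibble as produced by [read_trimer_models()] or the
#'   synthetic generator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trimer_pdb <- function(atoms, path) {
  frame_col <- if ("model" %in% names(atoms)) "model" else "frame"
  if (!frame_col %in% names(atoms)) {
    atoms[[frame_col]] <- 1L
  }
  frames <- split(atoms, atoms[[frame_col]])
  first <- frames[[1]]
  xyz <- do.call(rbind, purrr::map(frames, function(fr) {
    as.vector(t(as.matrix(fr[, c("x", "y", "z")])))
  }))
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = first$resno, resid = first$resname,
    eleno = seq_len(nrow(first)), elety = first$atom,
    chain = first$chain
  ))
  invisible(path)
}

#' Describe an ensemble replica stored as a multi-model PDB file
#'
#' Bundles a snapshot file with its acquisition metadata: the time between
#' saved snapshots and the initial equilibration span to discard before
#' analysis.
#'
#' @param paths Character vector of multi-model PDB paths, one per replica,
#'   in replica order.
#' @param time_per_frame Time between consecutive snapshots, picoseconds.
#' @param discard_initial Initial span to discard from each replica,
#'   nanoseconds.
#' @return An object of class `ensemble_source`.
#' @export
ensemble_source <- function(paths, time_per_frame = 20, discard_initial = 100) {
  if (discard_initial < 0) {
    abort("discard_initial must be >= 0.", class = "ffbench_config_error")
  }
  structure(
    list(paths = paths, time_per_frame = time_per_frame,
         discard_initial = discard_initial),
    class = "ensemble_source"
  )
}

#' Indices of production frames after discarding equilibration
#'
#' Frame `k` (1-based) is assigned time `(k - 1) * time_per_frame`; frames
#' with time at or beyond `discard_initial` are kept. 25,000 frames saved
#' every 20 ps with 100 ns discarded leave 20,000 production frames.
#'
#' @param n_frames Number of frames in the replica.
#' @param time_per_frame Picoseconds between frames.
#' @param discard_initial Nanoseconds to discard.
#' @return Integer vector of kept frame indices (possibly empty).
#' @export
production_frame_indices <- function(n_frames, time_per_frame = 20,
                                     discard_initial = 100) {
  k <- seq_len(n_frames)
  k[(k - 1) * time_per_frame >= discard_initial * 1000]
}

#' Read an ensemble source into a snapshot stream
#'
#' Reads every replica file, drops the discarded initial span of each
#' replica, concatenates replicas in order and renumbers snapshots into a
#' single `frame` column.
#'
#' @param source An [ensemble_source()].
#' @inheritParams read_trimer_models
#' @return Atom tibble with `frame` (global snapshot index) and `replica`
#'   columns in addition to the columns of [read_trimer_models()].
#' @export
read_ensemble <- function(source, chains = c("A", "B", "C"),
                          first_residue = 1, n_residues = 16) {
  stopifnot(inherits(source, "ensemble_source"))
  reps <- purrr::imap(source$paths, function(p, r) {
    atoms <- read_trimer_models(p, chains = chains,
                                first_residue = first_residue,
                                n_residues = n_residues)
    n_frames <- length(unique(atoms$model))
    keep <- production_frame_indices(n_frames, source$time_per_frame,
                                     source$discard_initial)
    message(sprintf("replica %d: %d frames read, %d kept after discarding %g ns",
                    r, n_frames, length(keep), source$discard_initial))
    atoms %>%
      filter(.data$model %in% keep) %>%
      mutate(replica = r)
  })
  out <- bind_rows(reps)
  if (nrow(out) == 0) {
    abort("No snapshots remain after discarding the initial span.",
          class = "ffbench_config_error")
  }
  out %>%
    mutate(frame = match(
      paste(.data$replica, .data$model),
      unique(paste(.data$replica, .data$model))
    )) %>%
    select(-"model")
}
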