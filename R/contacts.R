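#' Eligible intra-peptide residue pairs
#'
#' All residue pairs `(i, j)` with `j >= i + 2`: pairs of residues adjacent
#' along the sequence are excluded from contact analysis. For a 16-residue
#' peptide this universe has 105 pairs, which fixes the reference marginal of
#' the confusion matrix (20/105 = 19.048% for a 20-contact reference).
#'
#' @param n_residues Peptide length (>= 2).
#' @return Tibble with integer columns `i`, `j` (`i < j`).
#' @export
eligible_pairs <- function(n_residues) {
  if (n_residues < 2) {
    abort("Need at least two residues.", class = "ffbench_input_error")
  }
  grid <- expand.grid(i = seq_len(n_residues), j = seq_len(n_residues))
  out <- grid[grid$j >= grid$i + 2, c("i", "j")]
  as_tibble(out[order(out$i, out$j), ])
}

# Minimum over rows within residue groups; m is a distance(-squared) matrix.
.group_min_rows <- function(m, groups, levels) {
  out <- matrix(Inf, length(levels), ncol(m))
  for (k in seq_along(levels)) {
    ix <- which(groups == levels[k])
    if (length(ix) == 1) {
      out[k, ] <- m[ix, ]
    } else if (length(ix) > 1) {
      out[k, ] <- do.call(pmin, asplit(m[ix, , drop = FALSE], 1))
    }
  }
  out
}

# n x n matrix of minimum heavy-atom distances between residues of two atom
# sets (which may be the same set).
.residue_min_dist <- function(xyz1, res1, xyz2, res2, n_residues) {
  d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") -
    2 * tcrossprod(xyz1, xyz2)
  d2[d2 < 0] <- 0
  a <- .group_min_rows(d2, res1, seq_len(n_residues))
  b <- t(.group_min_rows(t(a), res2, seq_len(n_residues)))
  sqrt(b)
}

.peptide_heavy <- function(atoms, pep) {
  a <- atoms[atoms$peptide == pep & atoms$is_heavy, , drop = FALSE]
  list(xyz = cbind(a$x, a$y, a$z), res = a$residue,
       bb = a$is_backbone)
}

#' Boolean intra-peptide contact map of one snapshot
#'
#' A residue pair is in contact when any pair of heavy atoms, one from each
#' residue, lies within `cutoff` (inclusive). Sequence-adjacent pairs are
#' excluded (see [eligible_pairs()]).
#'
#' @param atoms Atom tibble of a single snapshot.
#' @param peptide Peptide index (1..3).
#' @param cutoff Contact distance cutoff, angstrom (inclusive; default 5).
#' @param n_residues Peptide length.
#' @return Tibble `i`, `j`, `contact` (logical) over the eligible-pair
#'   universe.
#' @export
snapshot_contact_map <- function(atoms, peptide = 1, cutoff = 5,
                                 n_residues = 16) {
  if (cutoff <= 0) {
    abort("cutoff must be positive.", class = "ffbench_input_error")
  }
  p <- .peptide_heavy(atoms, peptide)
  dmin <- .residue_min_dist(p$xyz, p$res, p$xyz, p$res, n_residues)
  pairs <- eligible_pairs(n_residues)
  pairs$contact <- dmin[cbind(pairs$i, pairs$j)] <= cutoff
  pairs
}

#' Per-snapshot intra-peptide contact series for an ensemble
#'
#' @param frames Atom tibble with `frame` column.
#' @inheritParams snapshot_contact_map
#' @return Tibble `frame`, `peptide`, `i`, `j`, `contact`.
#' @export
intra_contact_series <- function(frames, cutoff = 5, n_residues = 16) {
  frames %>%
    group_by(.data$frame) %>%
    dplyr::group_modify(function(fr, key) {
      purrr::map_dfr(sort(unique(fr$peptide)), function(p) {
        cm <- snapshot_contact_map(fr, peptide = p, cutoff = cutoff,
                                   n_residues = n_residues)
        mutate(cm, peptide = p, .before = 1)
      })
    }) %>%
    ungroup()
}

#' Ensemble contact frequencies with a minimum-frequency filter
#'
#' Per peptide, the fraction of snapshots in which each pair is in contact;
#' frequencies below `min_freq` are zeroed per peptide; the filtered
#' per-peptide frequencies are then averaged across the three peptides.
#'
#' @param series Contact series from [intra_contact_series()].
#' @param min_freq Frequency filter threshold (default 0.01, i.e. 1%).
#' @return Tibble `i`, `j`, `frequency`.
#' @export
ensemble_contact_frequencies <- function(series, min_freq = 0.01) {
  series %>%
    group_by(.data$peptide, .data$i, .data$j) %>%
    summarise(frequency = mean(.data$contact), .groups = "drop") %>%
    mutate(frequency = if_else(.data$frequency < min_freq, 0,
                               .data$frequency)) %>%
    group_by(.data$i, .data$j) %>%
    summarise(frequency = mean(.data$frequency), .groups = "drop")
}

#' Reference intra-peptide contact map with side-chain/backbone classes
#'
#' Contact map of a reference structure snapshot, with each contact labelled
#' `Bb-Bb`, `Sc-Bb` or `Sc-Sc` by the class of the closest heavy-atom pair
#' (backbone = N, CA, C, O), and a `medium` flag for sequence separations
#' `j > i + 5` (the medium-distance contacts that distinguish the U-shaped
#' from the L-shaped conformation).
#'
#' @inheritParams snapshot_contact_map
#' @return Tibble `i`, `j`, `contact`, `class`, `medium`.
#' @export
reference_contact_map <- function(atoms, peptide = 1, cutoff = 5,
                                  n_residues = 16) {
  p <- .peptide_heavy(atoms, peptide)
  pairs <- eligible_pairs(n_residues)
  classes <- list(
    "Bb-Bb" = list(a = p$bb, b = p$bb),
    "Sc-Bb" = list(a = !p$bb, b = p$bb),
    "Sc-Sc" = list(a = !p$bb, b = !p$bb)
  )
  dmin_class <- purrr::map(classes, function(cl) {
    if (!any(cl$a) || !any(cl$b)) {
      return(matrix(Inf, n_residues, n_residues))
    }
    d <- .residue_min_dist(p$xyz[cl$a, , drop = FALSE], p$res[cl$a],
                           p$xyz[cl$b, , drop = FALSE], p$res[cl$b],
                           n_residues)
    # Sc-Bb is orientation-free: either residue may contribute the side chain
    if (any(cl$a) && any(cl$b)) pmin(d, t(d)) else d
  })
  dmin_all <- Reduce(pmin, dmin_class)
  idx <- cbind(pairs$i, pairs$j)
  pairs$contact <- dmin_all[idx] <= cutoff
  per_class <- vapply(dmin_class, function(m) m[idx],
                      numeric(nrow(pairs)))
  cls <- names(classes)[apply(per_class, 1, which.min)]
  pairs$class <- if_else(pairs$contact, cls, NA_character_)
  pairs$medium <- pairs$contact & (pairs$j > pairs$i + 5)
  pairs
}

#' Accumulate a confusion matrix of snapshot contacts against a reference
#'
#' Every (snapshot, peptide, pair) instance is classified as TP/FP/FN/TN
#' against the reference boolean map; replicas and peptides are pooled, and
#' the four cells are reported as percentages of all instances (summing to
#' 100).
#'
#' @param series Boolean contact series with columns `i`, `j`, `contact`
#'   (plus any instance keys such as `frame`, `peptide`).
#' @param reference Reference boolean map with columns `i`, `j`, `contact`.
#' @return An object of class `contact_confusion`: percentages `tp`, `fp`,
#'   `fn`, `tn`, raw `counts`, and `n_instances`.
#' @export
accumulate_confusion <- function(series, reference) {
  u1 <- distinct(series[, c("i", "j")]) %>% arrange(.data$i, .data$j)
  u2 <- distinct(reference[, c("i", "j")]) %>% arrange(.data$i, .data$j)
  if (!identical(as.data.frame(u1), as.data.frame(u2))) {
    abort("Pair universes of series and reference differ.",
          class = "ffbench_input_error")
  }
  ref <- reference %>% select("i", "j", ref = "contact")
  joined <- left_join(series, ref, by = c("i", "j"))
  counts <- c(
    tp = sum(joined$contact & joined$ref),
    fp = sum(joined$contact & !joined$ref),
    fn = sum(!joined$contact & joined$ref),
    tn = sum(!joined$contact & !joined$ref)
  )
  .confusion_from_counts(counts)
}

.confusion_from_counts <- function(counts) {
  n <- sum(counts)
  pct <- 100 * counts / n
  structure(
    list(tp = pct[["tp"]], fp = pct[["fp"]], fn = pct[["fn"]],
         tn = pct[["tn"]], counts = counts, n_instances = n),
    class = "contact_confusion"
  )
}

#' @export
print.contact_confusion <- function(x, ...) {
  cat(sprintf("Contact confusion matrix (%d instances, %%):\n", x$n_instances))
  cat(sprintf("  TP %7.3f  FP %7.3f\n  FN %7.3f  TN %7.3f\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  MCC %.5f\n", mcc(x)))
  invisible(x)
}

#' Matthews correlation coefficient of a confusion matrix
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' in \eqn{[-1, 1]}. If any marginal factor is zero the value is undefined
#' and 0 is returned by convention. Cells may be counts or percentages (the
#' statistic is scale-invariant).
#'
#' @param cm A `contact_confusion` object, or TP value if the four cells are
#'   given separately.
#' @param fp,fn,tn Remaining cells when `cm` is numeric.
#' @return MCC value.
#' @export
mcc <- function(cm, fp = NULL, fn = NULL, tn = NULL) {
  if (inherits(cm, "contact_confusion")) {
    tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  } else {
    tp <- cm
  }
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 <= 0) {
    return(0)
  }
  ((tp * tn) - (fp * fn)) / sqrt(denom2)
}

# 16 x 16 logical contact matrices for the three peptide pairs of one frame.
.inter_pair_matrices <- function(atoms, cutoff, n_residues) {
  peps <- purrr::map(1:3, ~ .peptide_heavy(atoms, .x))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  purrr::map(pairs, function(pr) {
    a <- peps[[pr[1]]]; b <- peps[[pr[2]]]
    .residue_min_dist(a$xyz, a$res, b$xyz, b$res, n_residues) <= cutoff
  }) %>% setNames(c("1-2", "1-3", "2-3"))
}

#' Oligomeric state of a trimer snapshot
#'
#' Two peptides are in contact when any heavy-atom pair across them lies
#' within `cutoff`. A snapshot is a monomer when no peptide pair is in
#' contact, a dimer when exactly one pair is, and a trimer when every peptide
#' contacts at least one other.
#'
#' @inheritParams snapshot_contact_map
#' @return List with `state` (`"monomer"`, `"dimer"` or `"trimer"`) and
#'   `pair_contacts`, a tibble of residue-pair contact counts per peptide
#'   pair.
#' @export
oligomer_state <- function(atoms, cutoff = 5, n_residues = 16) {
  mats <- .inter_pair_matrices(atoms, cutoff, n_residues)
  pair_contacts <- tibble(
    pair = names(mats),
    peptide_a = c(1L, 1L, 2L),
    peptide_b = c(2L, 3L, 3L),
    n_contacts = unname(vapply(mats, sum, integer(1)))
  )
  in_contact <- pair_contacts$n_contacts > 0
  state <- if (!any(in_contact)) {
    "monomer"
  } else if (sum(in_contact) == 1) {
    "dimer"
  } else {
    "trimer"
  }
  list(state = state, pair_contacts = pair_contacts)
}

#' Middle peptide of a fibril-like snapshot
#'
#' The peptide with the largest number of inter-peptide residue-pair
#' contacts; ties are broken by the lowest peptide index. Undefined for
#' monomers.
#'
#' @inheritParams snapshot_contact_map
#' @return Integer peptide index in 1..3.
#' @export
middle_peptide_index <- function(atoms, cutoff = 5, n_residues = 16) {
  st <- oligomer_state(atoms, cutoff = cutoff, n_residues = n_residues)
  .middle_from_pairs(st)
}

.middle_from_pairs <- function(st) {
  if (st$state == "monomer") {
    abort("Middle peptide is undefined for a monomer snapshot.",
          class = "ffbench_input_error")
  }
  pc <- st$pair_contacts
  per_pep <- vapply(1:3, function(p) {
    sum(pc$n_contacts[pc$peptide_a == p | pc$peptide_b == p])
  }, numeric(1))
  which.max(per_pep) # ties -> lowest index
}

#' Inter-peptide reference contact map between two chains
#'
#' Residue-pair contact map (full 16 x 16 universe, no sequence-separation
#' exclusion since the residues belong to different peptides) between two
#' peptides of a reference structure. Row index `i` refers to the first
#' peptide of `peptides` (the chain-A role).
#'
#' @inheritParams snapshot_contact_map
#' @param peptides Length-2 integer vector of peptide indices, row role
#'   first.
#' @return Tibble `i`, `j`, `contact`.
#' @export
inter_reference_map <- function(atoms, peptides = c(1, 2), cutoff = 5,
                                n_residues = 16) {
  a <- .peptide_heavy(atoms, peptides[1])
  b <- .peptide_heavy(atoms, peptides[2])
  m <- .residue_min_dist(a$xyz, a$res, b$xyz, b$res, n_residues) <= cutoff
  grid <- expand.grid(j = seq_len(n_residues), i = seq_len(n_residues))
  tibble(i = grid$i, j = grid$j, contact = m[cbind(grid$i, grid$j)])
}

#' Inter-peptide confusion matrix and MCC for an ensemble
#'
#' Scores each snapshot's inter-peptide contacts against the reference map
#' of the experimental structure's adjacent-chain pair. In trimer snapshots
#' the middle peptide (most inter-peptide contacts, row role) is compared
#' with each edge peptide against the reference, and every contact between
#' the two edge peptides counts as a false positive (non-contacts there as
#' true negatives). In dimer snapshots the contacting pair is scored against
#' the same reference (lower peptide index takes the row role) and the
#' non-participating pairs contribute predicted negatives (FN at reference
#' positives, TN elsewhere). Monomer snapshots contribute predicted
#' negatives for all three pairs. Every snapshot thus contributes
#' 3 x 16 x 16 instances.
#'
#' @param frames Atom tibble with `frame` column.
#' @param reference_ab Reference map from [inter_reference_map()].
#' @inheritParams snapshot_contact_map
#' @return List with `confusion` (`contact_confusion`), `mcc`, and `states`
#'   (tibble of per-frame oligomer states).
#' @export
inter_contact_confusion <- function(frames, reference_ab, cutoff = 5,
                                    n_residues = 16) {
  ref <- matrix(FALSE, n_residues, n_residues)
  ref[cbind(reference_ab$i, reference_ab$j)] <- reference_ab$contact
  n_ref_pos <- sum(ref)
  n_cells <- n_residues^2
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  frame_ids <- unique(frames$frame)
  states <- character(length(frame_ids))
  score_vs_ref <- function(pred) {
    c(tp = sum(pred & ref), fp = sum(pred & !ref),
      fn = sum(!pred & ref), tn = sum(!pred & !ref))
  }
  neg_vs_ref <- c(tp = 0, fp = 0, fn = n_ref_pos, tn = n_cells - n_ref_pos)
  for (k in seq_along(frame_ids)) {
    fr <- frames[frames$frame == frame_ids[k], , drop = FALSE]
    mats <- .inter_pair_matrices(fr, cutoff, n_residues)
    n_pair <- vapply(mats, sum, numeric(1))
    st <- list(state = NULL, pair_contacts = tibble(
      pair = names(mats), peptide_a = c(1L, 1L, 2L),
      peptide_b = c(2L, 3L, 3L), n_contacts = as.integer(n_pair)
    ))
    n_in_contact <- sum(n_pair > 0)
    st$state <- if (n_in_contact == 0) "monomer" else
      if (n_in_contact == 1) "dimer" else "trimer"
    states[k] <- st$state
    # orient a pair matrix so the row index is peptide `row_pep`
    oriented <- function(pair_name, row_pep) {
      m <- mats[[pair_name]]
      first <- as.integer(substr(pair_name, 1, 1))
      if (first == row_pep) m else t(m)
    }
    pair_name_of <- function(a, b) paste(sort(c(a, b)), collapse = "-")
    if (st$state == "monomer") {
      counts <- counts + 3 * neg_vs_ref
    } else if (st$state == "dimer") {
      contact_pair <- which(n_pair > 0)
      pn <- names(mats)[contact_pair]
      members <- as.integer(strsplit(pn, "-")[[1]])
      counts <- counts + score_vs_ref(oriented(pn, min(members)))
      counts <- counts + 2 * neg_vs_ref
    } else {
      mid <- .middle_from_pairs(st)
      edges <- setdiff(1:3, mid)
      for (e in edges) {
        counts <- counts + score_vs_ref(oriented(pair_name_of(mid, e), mid))
      }
      ee <- mats[[pair_name_of(edges[1], edges[2])]]
      counts <- counts + c(tp = 0, fp = sum(ee), fn = 0, tn = sum(!ee))
    }
  }
  confusion <- .confusion_from_counts(counts)
  list(confusion = confusion, mcc = mcc(confusion),
       states = tibble(frame = frame_ids, state = states))
}
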