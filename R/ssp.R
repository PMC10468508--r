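#' Assign 3-state secondary structure to one trimer snapshot
#'
#' Simplified hydrogen-bond-based assigner in the Kabsch–Sander spirit. The
#' backbone amide hydrogen is taken from the structure when present (atom
#' `H`/`HN`) and otherwise reconstructed 1 angstrom from N along the previous
#' residue's C=O direction. The electrostatic hydrogen-bond energy between an
#' acceptor carbonyl (C, O of residue i) and a donor amide (N, H of residue
#' j) is
#' \deqn{E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' kcal/mol, and a bond is recorded when \eqn{E < -0.5}. Helix (`H`) is
#' assigned from runs of i -> i+4 bonds (two consecutive turns), strand
#' (`E`) from parallel/antiparallel bridge patterns (within-chain separation
#' >= 3, or across peptides), everything else is coil (`C`). Helix takes
#' precedence over strand; terminal residues lacking partners default to
#' coil.
#'
#' @param atoms Atom tibble of one snapshot (3 peptides x `n_residues`).
#' @param n_residues Peptide length.
#' @return Tibble `peptide`, `residue`, `ss` (factor-free character,
#'   `"H"`/`"E"`/`"C"`).
#' @export
assign_secondary_structure <- function(atoms, n_residues = 16) {
  n_pep <- 3L
  n_tot <- n_pep * n_residues
  get_bb <- function(name) {
    bb <- atoms[atoms$atom == name, , drop = FALSE]
    m <- matrix(NA_real_, n_tot, 3)
    g <- (bb$peptide - 1L) * n_residues + bb$residue
    m[g, ] <- cbind(bb$x, bb$y, bb$z)
    m
  }
  N <- get_bb("N"); CA <- get_bb("CA"); Cc <- get_bb("C"); O <- get_bb("O")
  missing_bb <- which(is.na(N[, 1]) | is.na(CA[, 1]) | is.na(Cc[, 1]) |
                        is.na(O[, 1]))
  if (length(missing_bb) > 0) {
    pep <- (missing_bb - 1L) %/% n_residues + 1L
    res <- (missing_bb - 1L) %% n_residues + 1L
    abort(paste0("Missing backbone atoms for residue(s): ",
                 paste(sprintf("peptide %d residue %d", pep, res),
                       collapse = "; ")),
          class = "ffbench_input_error")
  }
  chain <- rep(seq_len(n_pep), each = n_residues)
  resname <- atoms$resname[match(seq_len(n_tot),
                                 (atoms$peptide - 1L) * n_residues +
                                   atoms$residue)]
  # amide hydrogen: explicit if present, else reconstructed from C(-1)=O(-1)
  H <- matrix(NA_real_, n_tot, 3)
  hat <- atoms[atoms$atom %in% c("H", "HN") & atoms$element == "H", ,
               drop = FALSE]
  if (nrow(hat) > 0) {
    g <- (hat$peptide - 1L) * n_residues + hat$residue
    H[g, ] <- cbind(hat$x, hat$y, hat$z)
  }
  for (g in seq_len(n_tot)) {
    first_of_chain <- ((g - 1L) %% n_residues) == 0L
    if (!is.na(H[g, 1]) || first_of_chain || resname[g] == "PRO") next
    co <- Cc[g - 1L, ] - O[g - 1L, ]
    H[g, ] <- N[g, ] + co / sqrt(sum(co^2))
  }
  hb <- .hbond_matrix(N, CA, Cc, O, H, chain)
  .labels_from_hbonds(hb, chain, n_residues)
}

# hb[i, j] TRUE when CO(i) accepts an H-bond from NH(j).
.hbond_matrix <- function(N, CA, Cc, O, H, chain, e_cut = -0.5,
                          ca_prefilter = 9) {
  n <- nrow(N)
  q <- 0.084 * 332
  dca <- as.matrix(dist(CA))
  hb <- matrix(FALSE, n, n)
  donors <- which(!is.na(H[, 1]))
  for (i in seq_len(n)) {
    js <- donors[dca[i, donors] < ca_prefilter]
    js <- js[js != i & !(chain[js] == chain[i] & abs(js - i) <= 1)]
    if (length(js) == 0) next
    r_on <- sqrt(rowSums((N[js, , drop = FALSE] -
                            matrix(O[i, ], length(js), 3, byrow = TRUE))^2))
    r_ch <- sqrt(rowSums((H[js, , drop = FALSE] -
                            matrix(Cc[i, ], length(js), 3, byrow = TRUE))^2))
    r_oh <- sqrt(rowSums((H[js, , drop = FALSE] -
                            matrix(O[i, ], length(js), 3, byrow = TRUE))^2))
    r_cn <- sqrt(rowSums((N[js, , drop = FALSE] -
                            matrix(Cc[i, ], length(js), 3, byrow = TRUE))^2))
    e <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    hb[i, js[e < e_cut]] <- TRUE
  }
  hb
}

.labels_from_hbonds <- function(hb, chain, n_residues) {
  n <- length(chain)
  ss <- rep("C", n)
  same_chain <- function(a, b) !is.na(a) && !is.na(b) && a >= 1 && b <= n &&
    chain[a] == chain[b]
  # turns: CO(i) -> NH(i+4) within one chain
  turn <- vapply(seq_len(n), function(i) {
    i + 4 <= n && chain[i] == chain[i + 4] && hb[i, i + 4]
  }, logical(1))
  # two consecutive turns make residues i..i+3 helical
  for (i in 2:n) {
    if (turn[i] && turn[i - 1]) ss[i:(i + 3)] <- "H"
  }
  # bridges
  safe_hb <- function(a, b) {
    a >= 1 && a <= n && b >= 1 && b <= n && hb[a, b]
  }
  is_bridge <- function(i, j) {
    anti <- (safe_hb(i, j) && safe_hb(j, i)) ||
      (same_chain(i - 1, i + 1) && same_chain(j - 1, j + 1) &&
         safe_hb(i - 1, j + 1) && safe_hb(j - 1, i + 1))
    par <- (same_chain(i - 1, i + 1) && safe_hb(i - 1, j) &&
              safe_hb(j, i + 1)) ||
      (same_chain(j - 1, j + 1) && safe_hb(j - 1, i) && safe_hb(i, j + 1))
    anti || par
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (chain[i] == chain[j] && j - i < 3) next
      if (is_bridge(i, j)) {
        if (ss[i] != "H") ss[i] <- "E"
        if (ss[j] != "H") ss[j] <- "E"
      }
    }
  }
  tibble(
    peptide = rep(seq_along(unique(chain)), each = n_residues),
    residue = rep(seq_len(n_residues), times = length(unique(chain))),
    ss = ss
  )
}

#' Secondary-structure assignments for every snapshot of an ensemble
#'
#' @param frames Atom tibble with `frame` column.
#' @inheritParams assign_secondary_structure
#' @return Tibble `frame`, `peptide`, `residue`, `ss`.
#' @export
ssp_assignments <- function(frames, n_residues = 16) {
  frames %>%
    group_by(.data$frame) %>%
    dplyr::group_modify(
      ~ assign_secondary_structure(.x, n_residues = n_residues)
    ) %>%
    ungroup()
}

#' Parse a DSSP output file into 3-state labels
#'
#' Reads the classic fixed-column DSSP text format and maps the 8-state
#' codes to 3 states: `H` stays helix, `E` stays strand, and everything else
#' (`G`, `I`, `B`, `T`, `S`, blank) becomes coil. The mapping is
#' configurable via `helix_codes`/`strand_codes`.
#'
#' @param path DSSP output file.
#' @param chains Chain identifiers to keep, mapped to peptides 1..3 in
#'   order; `NULL` keeps all chains in file order.
#' @param helix_codes DSSP codes mapped to `H`.
#' @param strand_codes DSSP codes mapped to `E`.
#' @return Tibble `peptide`, `chain`, `resno`, `aa`, `ss8`, `ss`.
#' @export
parse_dssp_output <- function(path, chains = NULL, helix_codes = "H",
                              strand_codes = "E") {
  if (!file.exists(path)) {
    abort(paste0("DSSP output file not found: ", path),
          class = "ffbench_format_error")
  }
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) {
    abort("Not a DSSP output file (missing '  #  RESIDUE' header).",
          class = "ffbench_format_error")
  }
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"] # chain breaks
  out <- tibble(
    resno = as.integer(trimws(substr(body, 6, 10))),
    chain = substr(body, 12, 12),
    aa = substr(body, 14, 14),
    ss8 = substr(body, 17, 17)
  )
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(out$chain))
    if (length(missing) > 0) {
      abort(paste0("DSSP file lacks chain(s): ",
                   paste(missing, collapse = ", ")),
            class = "ffbench_selection_error")
    }
    out <- out %>%
      filter(.data$chain %in% chains) %>%
      mutate(peptide = match(.data$chain, chains))
  } else {
    out <- out %>% mutate(peptide = match(.data$chain, unique(.data$chain)))
  }
  out %>%
    mutate(ss = dplyr::case_when(
      .data$ss8 %in% helix_codes ~ "H",
      .data$ss8 %in% strand_codes ~ "E",
      TRUE ~ "C"
    )) %>%
    select("peptide", "chain", "resno", "aa", "ss8", "ss")
}

#' Per-residue secondary-structure propensity table
#'
#' Counts each state per residue over all peptides and snapshots. With the
#' default `denominator = "per_residue"` the three probabilities of each
#' residue sum to 1 (counts divided by peptides x snapshots). The
#' `"global"` variant divides by the grand total over all residues and
#' states instead, so each residue's probabilities sum to 1/N; the two
#' variants shift every ensemble's log-likelihood score by the same additive
#' constant and leave normalized scores unchanged.
#'
#' @param series Label series with columns `residue`, `ss` and instance keys
#'   (e.g. `frame`, `peptide`), as from [ssp_assignments()] or
#'   [sample_ss_series()].
#' @param denominator `"per_residue"` or `"global"`.
#' @param n_residues Peptide length.
#' @return Tibble `residue`, `H`, `E`, `C`.
#' @export
propensity_table <- function(series, denominator = c("per_residue", "global"),
                             n_residues = 16) {
  denominator <- match.arg(denominator)
  if (nrow(series) == 0) {
    abort("Empty label series.", class = "ffbench_input_error")
  }
  counts <- series %>%
    count(.data$residue, .data$ss) %>%
    tidyr::pivot_wider(names_from = "ss", values_from = "n",
                       values_fill = 0L)
  for (s in c("H", "E", "C")) {
    if (!s %in% names(counts)) counts[[s]] <- 0L
  }
  counts <- counts %>% arrange(.data$residue)
  tot <- counts$H + counts$E + counts$C
  den <- if (denominator == "per_residue") tot else rep(sum(tot), nrow(counts))
  tibble(
    residue = counts$residue,
    H = counts$H / den, E = counts$E / den, C = counts$C / den
  )
}

#' Consensus reference secondary structure across models
#'
#' Per-residue majority vote across the models of a multi-model reference
#' structure (e.g. the 20 NMR models of the U-shaped conformation); ties go
#' to coil. A single model passes through unchanged.
#'
#' @param models Tibble with columns `model`, `residue`, `ss` (one row per
#'   model x residue; peptides may be included as extra rows and are pooled
#'   into the vote).
#' @return Tibble `residue`, `ss`.
#' @export
consensus_reference_ss <- function(models) {
  models %>%
    count(.data$residue, .data$ss) %>%
    group_by(.data$residue) %>%
    summarise(
      ss = {
        top <- max(.data$n)
        winners <- .data$ss[.data$n == top]
        if (length(winners) == 1) winners else "C"
      },
      .groups = "drop"
    )
}

#' Secondary-structure-propensity log-likelihood score
#'
#' Log-likelihood of observing the reference secondary structure under the
#' ensemble's propensity table, assuming residues are independent:
#' \deqn{\mathrm{SSP} = \sum_i \log p_{i, ref_i},} with propensities floored
#' at `epsilon` so that unobserved reference states contribute a large but
#' finite penalty. Always <= 0 (for a per-residue-normalized table); equal
#' to 0 only when the ensemble puts probability 1 on every reference label.
#'
#' @param ptable Propensity table from [propensity_table()].
#' @param ref Reference labels: character vector (length = number of
#'   residues) or tibble with `residue`, `ss`.
#' @param epsilon Probability floor for zero propensities.
#' @param base Logarithm base (natural log by default; any base rescales all
#'   ensembles' scores by the same constant and leaves normalized scores
#'   unchanged).
#' @return Raw SSP score (scalar).
#' @export
ssp_score <- function(ptable, ref, epsilon = 1e-6, base = exp(1)) {
  if (is.data.frame(ref)) {
    ref <- ref$ss[order(ref$residue)]
  }
  if (length(ref) != nrow(ptable)) {
    abort("Reference length does not match the propensity table.",
          class = "ffbench_input_error")
  }
  p <- vapply(seq_along(ref), function(i) ptable[[ref[i]]][i], numeric(1))
  sum(log(pmax(p, epsilon)) / log(base))
}
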