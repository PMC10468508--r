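#' @name synthetic
#' @title Synthetic trimer ensembles
#' @description
#' The synthetic generator builds conformational ensembles with the
#' statistical structure the analysis assumes — compact hairpin-trimer
#' (U-like) snapshots, extended cross-beta (L-like) snapshots and
#' self-avoiding random-coil snapshots — so every scoring stage can be
#' exercised without molecular-dynamics trajectories. Peptides are built
#' from ideal backbone internal coordinates (N, CA, C, O plus CB for
#' non-glycine residues) at prescribed backbone torsions.
NULL

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension-reference-frame placement: returns D with |CD| = len,
# angle(B,C,D) = ang (degrees), dihedral(A,B,C,D) = dih (degrees).
.place_atom <- function(a, b, c, len, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- len * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + cbind(bc, m, n) %*% d2
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Ideal backbone geometry (angstrom / degrees).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, omega = 180
)

#' Build one peptide backbone from torsion angles
#'
#' Constructs N, CA, C, O (and CB for non-glycine) heavy atoms for a peptide
#' at the given phi/psi backbone torsions, with ideal bond lengths/angles
#' and trans peptide bonds.
#'
#' @param phi,psi Numeric vectors of backbone torsions in degrees, one per
#'   residue (`phi[1]` and the final `psi` only affect terminal-atom
#'   placement).
#' @param sequence One-letter amino-acid codes, same length as `phi`.
#' @return Atom tibble (single peptide, `peptide = 1`, `chain = "A"`).
#' @export
build_peptide <- function(phi, psi, sequence = r2_fus_lc_sequence()) {
  n <- length(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  g <- .bb_geom
  N <- CA <- Cc <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  # place C1 in the xy-plane at the ideal N-CA-C angle
  ang <- g$ang_n_ca_c * pi / 180
  Cc[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], Cc[i, ], g$c_n,
                                g$ang_ca_c_n, psi[i])
      CA[i + 1, ] <- .place_atom(CA[i, ], Cc[i, ], N[i + 1, ], g$n_ca,
                                 g$ang_c_n_ca, g$omega)
      Cc[i + 1, ] <- .place_atom(Cc[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c,
                                 g$ang_n_ca_c, phi[i + 1])
      # carbonyl O opposite the next amide N
      O[i, ] <- .place_atom(N[i, ], CA[i, ], Cc[i, ], g$c_o,
                            g$ang_ca_c_o, psi[i] + 180)
    } else {
      O[i, ] <- .place_atom(N[i, ], CA[i, ], Cc[i, ], g$c_o,
                            g$ang_ca_c_o, psi[i] + 180)
    }
    if (sequence[i] != "G") {
      CB[i, ] <- .place_atom(Cc[i, ], N[i, ], CA[i, ], g$ca_cb,
                             g$ang_n_ca_cb, -122.6)
    }
  }
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    at <- tibble(
      atom = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(N[i, 1], CA[i, 1], Cc[i, 1], O[i, 1]),
      y = c(N[i, 2], CA[i, 2], Cc[i, 2], O[i, 2]),
      z = c(N[i, 3], CA[i, 3], Cc[i, 3], O[i, 3])
    )
    if (sequence[i] != "G") {
      at <- bind_rows(at, tibble(atom = "CB", element = "C",
                                 x = CB[i, 1], y = CB[i, 2], z = CB[i, 3]))
    }
    mutate(at, residue = i, .before = 1)
  })
  rows %>%
    mutate(
      peptide = 1L, chain = "A", resno = .data$residue,
      resname = unname(.aa1to3[sequence[.data$residue]]),
      eleno = row_number(),
      mass = unname(.atomic_masses[.data$element]),
      is_heavy = TRUE,
      is_backbone = .data$atom %in% .backbone_atoms
    ) %>%
    select("peptide", "chain", "resno", "residue", "resname", "eleno",
           "atom", "element", "x", "y", "z", "mass", "is_heavy",
           "is_backbone")
}

#' Torsion templates for the synthetic conformational states
#'
#' `"hairpin"` is a compact two-strand beta-hairpin (the U-like state),
#' `"extended"` a single straight beta-strand (the L-like state).
#'
#' @param state `"hairpin"` or `"extended"`.
#' @param n_residues Peptide length.
#' @return List with `phi` and `psi` vectors (degrees).
#' @export
template_torsions <- function(state = c("hairpin", "extended"),
                              n_residues = 16) {
  state <- match.arg(state)
  beta_phi <- -139; beta_psi <- 135
  phi <- rep(beta_phi, n_residues)
  psi <- rep(beta_psi, n_residues)
  if (state == "hairpin") {
    # type I' turn at residues 8-9 reverses the chain direction
    phi[8] <- 60; psi[8] <- 30
    phi[9] <- 90; psi[9] <- 0
  }
  list(phi = phi, psi = psi)
}

# principal-plane normal of a peptide's CA trace
.peptide_normal <- function(pep_atoms) {
  ca <- pep_atoms[pep_atoms$atom == "CA", c("x", "y", "z")]
  m <- sweep(as.matrix(ca), 2, colMeans(as.matrix(ca)))
  v <- svd(m)$v[, 3]
  v / sqrt(sum(v^2))
}

.shift_peptide <- function(pep_atoms, shift) {
  mutate(pep_atoms, x = .data$x + shift[1], y = .data$y + shift[2],
         z = .data$z + shift[3])
}

.as_trimer <- function(pep_list, chains = c("A", "B", "C")) {
  purrr::imap_dfr(pep_list, function(p, k) {
    mutate(p, peptide = as.integer(k), chain = chains[k])
  }) %>%
    mutate(eleno = row_number())
}

#' Build a stacked cross-beta trimer template
#'
#' Three copies of a peptide template stacked at `spacing` angstrom along
#' the normal of the peptide plane, mimicking the in-register peptide
#' stacking of a cross-beta protofibril (adjacent peptides in contact, the
#' two edge peptides not).
#'
#' @inheritParams template_torsions
#' @param spacing Inter-peptide stacking distance, angstrom (cross-beta
#'   sheet spacing ~4.8).
#' @return Atom tibble of one trimer snapshot.
#' @export
build_trimer_template <- function(state = c("hairpin", "extended"),
                                  spacing = 4.8, n_residues = 16) {
  state <- match.arg(state)
  tor <- template_torsions(state, n_residues)
  pep <- build_peptide(tor$phi, tor$psi,
                       sequence = r2_fus_lc_sequence()[seq_len(n_residues)])
  nrm <- .peptide_normal(pep)
  peps <- purrr::map(c(-1, 0, 1), ~ .shift_peptide(pep, .x * spacing * nrm))
  .as_trimer(peps)
}

# one self-avoiding coil peptide; rejection on CA clashes and on the
# end-to-end distance band that reproduces Flory random-coil dimensions
.build_coil_peptide <- function(n_residues = 16, max_tries = 200,
                                ree_band = c(14, 42)) {
  basins <- list(
    beta = c(-139, 135), ppii = c(-75, 145), alpha_r = c(-60, -45),
    alpha_l = c(60, 45)
  )
  wts <- c(0.35, 0.35, 0.2, 0.1)
  for (try in seq_len(max_tries)) {
    pick <- sample(seq_along(basins), n_residues, replace = TRUE, prob = wts)
    phi <- vapply(pick, function(k) basins[[k]][1], numeric(1)) +
      rnorm(n_residues, 0, 15)
    psi <- vapply(pick, function(k) basins[[k]][2], numeric(1)) +
      rnorm(n_residues, 0, 15)
    pep <- build_peptide(phi, psi,
                         sequence = r2_fus_lc_sequence()[seq_len(n_residues)])
    ca <- as.matrix(pep[pep$atom == "CA", c("x", "y", "z")])
    d <- as.matrix(dist(ca))
    clash <- any(d[abs(row(d) - col(d)) >= 3] < 4.0)
    ree <- sqrt(sum((ca[n_residues, ] - ca[1, ])^2))
    if (!clash && ree >= ree_band[1] && ree <= ree_band[2]) {
      return(pep)
    }
  }
  abort("Coil construction failed after bounded retries.",
        class = "ffbench_generation_error")
}

# three independent coils with centroids spread along one random axis
# (predominantly monomeric snapshots)
.build_coil_trimer <- function(n_residues = 16, separation = 30) {
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  peps <- purrr::map(1:3, function(k) {
    pep <- .build_coil_peptide(n_residues)
    ctr <- colMeans(as.matrix(pep[, c("x", "y", "z")]))
    .shift_peptide(pep, (k - 2) * separation * u + rnorm(3, 0, 2) - ctr)
  })
  .as_trimer(peps)
}

#' Specification of a synthetic trimer ensemble
#'
#' @param n_snapshots Number of snapshots to generate.
#' @param state_weights Named probabilities over the conformational states
#'   `U` (compact hairpin trimer), `L` (extended cross-beta trimer) and
#'   `coil` (three separated self-avoiding coils); must sum to 1.
#' @param coordinate_noise_sd Isotropic Gaussian coordinate noise, angstrom.
#' @param seed Integer seed; the generator is bitwise reproducible per seed.
#' @param n_residues Peptide length.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_snapshots = 100,
                          state_weights = c(U = 1, L = 0, coil = 0),
                          coordinate_noise_sd = 0.2, seed = 1L,
                          n_residues = 16) {
  if (n_snapshots < 1) {
    abort("n_snapshots must be >= 1.", class = "ffbench_config_error")
  }
  state_weights <- state_weights[c("U", "L", "coil")]
  if (any(is.na(state_weights)) || any(state_weights < 0) ||
      abs(sum(state_weights) - 1) > 1e-9) {
    abort("state_weights must be named probabilities over U, L, coil summing to 1.",
          class = "ffbench_config_error")
  }
  structure(
    list(n_snapshots = as.integer(n_snapshots), state_weights = state_weights,
         coordinate_noise_sd = coordinate_noise_sd, seed = as.integer(seed),
         n_residues = as.integer(n_residues)),
    class = "ensemble_spec"
  )
}

# fixed documented child-seed scheme so partial pipelines are reproducible
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k) %% 2147483647)
}

#' Generate a synthetic trimer ensemble
#'
#' Per snapshot, draws a conformational state from `state_weights`, builds
#' the corresponding trimer (templates for U/L, a fresh self-avoiding coil
#' triple for `coil`) and adds isotropic Gaussian coordinate noise. With
#' zero noise and a single template state, coordinates equal the template
#' exactly.
#'
#' @param spec An [ensemble_spec()].
#' @param path Optional path; when given, the ensemble is also written as a
#'   multi-model PDB with a JSON manifest (`<path>.json`) recording the
#'   spec.
#' @return Atom tibble with `frame` and `state` columns.
#' @export
make_trimer_ensemble <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  templates <- list(
    U = build_trimer_template("hairpin", n_residues = spec$n_residues),
    L = build_trimer_template("extended", n_residues = spec$n_residues)
  )
  frames <- withr::with_seed(child_seed(spec$seed, 1L), {
    states <- sample(names(spec$state_weights), spec$n_snapshots,
                     replace = TRUE, prob = spec$state_weights)
    purrr::map_dfr(seq_len(spec$n_snapshots), function(t) {
      base <- if (states[t] == "coil") {
        .build_coil_trimer(spec$n_residues)
      } else {
        templates[[states[t]]]
      }
      if (spec$coordinate_noise_sd > 0) {
        base <- mutate(
          base,
          x = .data$x + rnorm(n(), 0, spec$coordinate_noise_sd),
          y = .data$y + rnorm(n(), 0, spec$coordinate_noise_sd),
          z = .data$z + rnorm(n(), 0, spec$coordinate_noise_sd)
        )
      }
      mutate(base, frame = t, state = states[t], .before = 1)
    })
  })
  if (!is.null(path)) {
    write_trimer_pdb(frames, path)
    jsonlite::write_json(
      list(n_snapshots = spec$n_snapshots,
           state_weights = as.list(spec$state_weights),
           coordinate_noise_sd = spec$coordinate_noise_sd,
           seed = spec$seed, n_residues = spec$n_residues),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  frames
}

#' Sample from a two-component Gaussian Rg mixture
#'
#' @param weights,means,sds Length-2 mixture parameters.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Numeric vector of draws.
#' @export
sample_rg_mixture <- function(weights, means, sds, n, seed = 1L) {
  stopifnot(length(weights) == 2, abs(sum(weights) - 1) < 1e-9)
  withr::with_seed(seed, {
    comp <- sample(1:2, n, replace = TRUE, prob = weights)
    rnorm(n, means[comp], sds[comp])
  })
}

#' Sample a secondary-structure label series from a propensity table
#'
#' Independent draws per (residue, peptide, snapshot), so
#' [propensity_table()] of the output converges to the input table.
#'
#' @param ptable Propensity table (`residue`, `H`, `E`, `C`).
#' @param n_snapshots Number of snapshots.
#' @param n_peptides Peptides per snapshot.
#' @param seed Integer seed.
#' @return Tibble `frame`, `peptide`, `residue`, `ss`.
#' @export
sample_ss_series <- function(ptable, n_snapshots, n_peptides = 3, seed = 1L) {
  states <- c("H", "E", "C")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(ptable)), function(r) {
      p <- c(ptable$H[r], ptable$E[r], ptable$C[r])
      tidyr::expand_grid(frame = seq_len(n_snapshots),
                         peptide = seq_len(n_peptides)) %>%
        mutate(residue = ptable$residue[r],
               ss = sample(states, dplyr::n(), replace = TRUE, prob = p))
    })
  })
}

#' Sample a boolean contact series with known sensitivity/specificity
#'
#' Each reference-positive pair is in contact with probability
#' `sensitivity`, each reference-negative pair with probability
#' `1 - specificity`, independently per snapshot — the generative model
#' whose accumulated confusion matrix has a closed-form expectation (see
#' [analytic_mcc()]).
#'
#' @param reference Boolean reference map (`i`, `j`, `contact`).
#' @param sensitivity,specificity Probabilities.
#' @param n_snapshots Number of snapshots.
#' @param seed Integer seed.
#' @return Tibble `frame`, `i`, `j`, `contact`.
#' @export
sample_contact_series <- function(reference, sensitivity, specificity,
                                  n_snapshots, seed = 1L) {
  p <- if_else(reference$contact, sensitivity, 1 - specificity)
  n_pairs <- nrow(reference)
  withr::with_seed(seed, {
    tibble(
      frame = rep(seq_len(n_snapshots), each = n_pairs),
      i = rep(reference$i, n_snapshots),
      j = rep(reference$j, n_snapshots),
      contact = runif(n_snapshots * n_pairs) < rep(p, n_snapshots)
    )
  })
}

#' Expected MCC of a sensitivity/specificity contact model
#'
#' Matthews correlation coefficient evaluated at the expected confusion
#' matrix TP = prevalence x sensitivity, FN = prevalence x (1 -
#' sensitivity), TN = (1 - prevalence) x specificity, FP = (1 - prevalence)
#' x (1 - specificity).
#'
#' @param sensitivity,specificity,prevalence Probabilities.
#' @return Expected MCC.
#' @export
analytic_mcc <- function(sensitivity, specificity, prevalence) {
  tp <- prevalence * sensitivity
  fn <- prevalence * (1 - sensitivity)
  tn <- (1 - prevalence) * specificity
  fp <- (1 - prevalence) * (1 - specificity)
  mcc(tp, fp = fp, fn = fn, tn = tn)
}
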