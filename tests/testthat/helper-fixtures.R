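# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

far_shift <- function(pep, k) dplyr::mutate(pep, x = x + k * 100)

# a trimer whose three peptides are copies of `pep` placed 100 A apart
# (no inter-peptide interactions)
isolated_trimer <- function(pep) {
  ffbench:::.as_trimer(list(pep, far_shift(pep, 1), far_shift(pep, 2)))
}

# minimal atom row constructor
atom_row <- function(peptide, residue, atom, element, x, y, z,
                     chain = c("A", "B", "C")[peptide], resname = "GLY") {
  tibble::tibble(
    peptide = as.integer(peptide), chain = chain,
    resno = as.integer(residue), residue = as.integer(residue),
    resname = resname, eleno = 1L, atom = atom, element = element,
    x = x, y = y, z = z,
    mass = unname(ffbench:::.atomic_masses[element]),
    is_heavy = element != "H",
    is_backbone = atom %in% c("N", "CA", "C", "O") & element != "H"
  )
}

# trimer of single-atom residues on a line: peptide p at y = y_off[p],
# residue i at x = 10 * i. Only the in-register inter-peptide pairs (i, i)
# can be in contact, at distance |y_a - y_b|.
toy_inter_trimer <- function(y_off = c(0, 4, 8), n_residues = 16) {
  purrr::map_dfr(1:3, function(p) {
    purrr::map_dfr(seq_len(n_residues), function(i) {
      atom_row(p, i, "CA", "C", x = 10 * i, y = y_off[p], z = 0)
    })
  }) |>
    dplyr::mutate(eleno = dplyr::row_number())
}

# ideal antiparallel two-strand sheet: strand 2 is strand 1 flipped 180
# degrees about the in-plane axis perpendicular to the chain and offset so
# that backbone H-bond ladders form; third peptide far away.
antiparallel_sheet_trimer <- function() {
  ext <- build_peptide(rep(-139, 16), rep(135, 16))
  m <- as.matrix(ext[, c("x", "y", "z")])
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  pcs <- svd(mc)$v
  P <- mc %*% pcs
  P2 <- P
  P2[, 1] <- -P2[, 1]
  P2[, 3] <- -P2[, 3]
  P2[, 1] <- P2[, 1] - 0.5
  P2[, 2] <- P2[, 2] + 4.0
  s1 <- ext
  s1$x <- P[, 1]; s1$y <- P[, 2]; s1$z <- P[, 3]
  s2 <- ext
  s2$x <- P2[, 1]; s2$y <- P2[, 2]; s2$z <- P2[, 3]
  ffbench:::.as_trimer(list(s1, s2, far_shift(s1, 3)))
}

# random trimer coordinates: 3 peptides x n_residues residues x 4 heavy
# atoms, uniform in a box (exercises the brute-force contact oracle)
random_trimer_atoms <- function(seed, n_residues = 16, box = 25) {
  withr::with_seed(seed, {
    purrr::map_dfr(1:3, function(p) {
      purrr::map_dfr(seq_len(n_residues), function(i) {
        ctr <- stats::runif(3, 0, box)
        purrr::map_dfr(c("N", "CA", "C", "O"), function(a) {
          atom_row(p, i, a, substr(a, 1, 1),
                   x = ctr[1] + stats::rnorm(1, 0, 1),
                   y = ctr[2] + stats::rnorm(1, 0, 1),
                   z = ctr[3] + stats::rnorm(1, 0, 1))
        })
      })
    }) |>
      dplyr::mutate(eleno = dplyr::row_number())
  })
}

# classic fixed-column DSSP output text for given per-residue codes;
# `codes` is a named list chain -> character vector of 8-state codes
dssp_fixture_lines <- function(codes, first_resno = 1) {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE ...",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N"
  )
  num <- 0
  body <- purrr::imap(codes, function(ss, ch) {
    vapply(seq_along(ss), function(i) {
      num <<- num + 1
      sprintf("%5d%5d %s %s  %s", num, first_resno + i - 1, ch, "S", ss[i])
    }, character(1))
  })
  c(header, unlist(body))
}

# independent brute-force Rg implementation (plain loops)
brute_force_rg <- function(atoms, mass_weighted = TRUE) {
  atoms <- atoms[atoms$is_heavy, ]
  w <- if (mass_weighted) atoms$mass else rep(1, nrow(atoms))
  cx <- sum(atoms$x * w) / sum(w)
  cy <- sum(atoms$y * w) / sum(w)
  cz <- sum(atoms$z * w) / sum(w)
  s <- 0
  for (a in seq_len(nrow(atoms))) {
    s <- s + w[a] * ((atoms$x[a] - cx)^2 + (atoms$y[a] - cy)^2 +
                       (atoms$z[a] - cz)^2)
  }
  sqrt(s / sum(w))
}

# independent brute-force contact map: all heavy-atom pairs, double loop
brute_force_contact_map <- function(atoms, peptide, cutoff,
                                    n_residues = 16) {
  a <- atoms[atoms$peptide == peptide & atoms$is_heavy, ]
  pairs <- eligible_pairs(n_residues)
  pairs$contact <- vapply(seq_len(nrow(pairs)), function(k) {
    ai <- a[a$residue == pairs$i[k], ]
    aj <- a[a$residue == pairs$j[k], ]
    for (u in seq_len(nrow(ai))) {
      for (v in seq_len(nrow(aj))) {
        d <- sqrt((ai$x[u] - aj$x[v])^2 + (ai$y[u] - aj$y[v])^2 +
                    (ai$z[u] - aj$z[v])^2)
        if (d <= cutoff) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  pairs
}

# peptide of single-atom residues 1..3 with residues 1 and 3 at distance d
two_residue_probe <- function(d) {
  dplyr::bind_rows(
    atom_row(1, 1, "CA", "C", 0, 0, 0),
    atom_row(1, 2, "CA", "C", 100, 100, 0),
    atom_row(1, 3, "CA", "C", d, 0, 0)
  )
}
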