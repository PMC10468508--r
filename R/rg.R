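#' Radius of gyration of an atom set
#'
#' Mass-weighted root-mean-square distance of atoms from their centre of
#' mass, over heavy atoms by default:
#' \deqn{R_g = \sqrt{\sum_a m_a |r_a - r_{com}|^2 / \sum_a m_a}.}
#'
#' @param atoms Atom tibble with `x`, `y`, `z`, `mass`, `is_heavy`.
#' @param heavy_only Drop hydrogens before computing (default `TRUE`).
#' @param mass_weighted Weight by atomic mass (default `TRUE`); unweighted
#'   uses equal weights, for sensitivity checks.
#' @return Radius of gyration in angstrom.
#' @export
compute_rg <- function(atoms, heavy_only = TRUE, mass_weighted = TRUE) {
  if (heavy_only) atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  if (nrow(atoms) == 0) {
    abort("No atoms left after filtering; cannot compute Rg.",
          class = "ffbench_input_error")
  }
  w <- if (mass_weighted) atoms$mass else rep(1, nrow(atoms))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  com <- colSums(xyz * w) / sum(w)
  d2 <- (xyz[, 1] - com[1])^2 + (xyz[, 2] - com[2])^2 + (xyz[, 3] - com[3])^2
  sqrt(sum(w * d2) / sum(w))
}

#' Per-snapshot Rg samples from a snapshot stream
#'
#' @param frames Atom tibble with a `frame` column (see [read_ensemble()] or
#'   [make_trimer_ensemble()]).
#' @param level `"trimer"` (all three peptides pooled per snapshot) or
#'   `"peptide"` (one value per peptide per snapshot).
#' @inheritParams compute_rg
#' @return Tibble with columns `frame`, (`peptide`,) `rg`.
#' @export
rg_samples <- function(frames, level = c("trimer", "peptide"),
                       heavy_only = TRUE, mass_weighted = TRUE) {
  level <- match.arg(level)
  keys <- if (level == "trimer") "frame" else c("frame", "peptide")
  frames %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      rg = compute_rg(dplyr::pick(everything()), heavy_only = heavy_only,
                      mass_weighted = mass_weighted),
      .groups = "drop"
    )
}

#' Flory random-coil radius of gyration
#'
#' Power law \eqn{R_g = R_0 N^{\nu}} with parameters optimised for
#' intrinsically disordered proteins (\eqn{R_0 = 2.54} angstrom,
#' \eqn{\nu = 0.522}); for a 16-residue peptide it predicts 10.8 angstrom.
#'
#' @param n_residues Chain length in residues (>= 1).
#' @param r0 Persistence-length prefactor, angstrom.
#' @param nu Scaling exponent.
#' @return Predicted unfolded-state Rg in angstrom.
#' @export
#' @examples
#' flory_rg(16) # ~10.8
flory_rg <- function(n_residues, r0 = 2.54, nu = 0.522) {
  if (any(n_residues < 1)) {
    abort("n_residues must be >= 1.", class = "ffbench_input_error")
  }
  r0 * n_residues^nu
}

#' Fit a two-component Gaussian mixture to an Rg sample
#'
#' Expectation-maximisation fit of a univariate two-component Gaussian
#' mixture, with k-means-style initialisation restarted `n_init` times; the
#' best log-likelihood wins. Deterministic for a fixed `seed`. Components are
#' reported sorted by ascending mean.
#'
#' @param values Numeric vector of Rg values (angstrom), length >= 10 with
#'   nonzero variance.
#' @param n_components Number of components; only 2 is supported.
#' @param seed Integer seed controlling the restarts.
#' @param n_init Number of random restarts.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations per restart.
#' @return An object of class `rg_mixture_fit` with elements `weights`,
#'   `means`, `sds`, `loglik`, `n`, `iterations`, `converged`, `seed`, and the
#'   input `values`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
fit_rg_mixture <- function(values, n_components = 2, seed = 1L, n_init = 10,
                           tol = 1e-6, max_iter = 500) {
  if (n_components != 2) {
    abort("Only a two-component mixture is supported.",
          class = "ffbench_input_error")
  }
  values <- as.numeric(values)
  if (length(values) < 10) {
    abort("At least 10 Rg values are required for a mixture fit.",
          class = "ffbench_input_error")
  }
  if (var(values) == 0) {
    abort(paste("Degenerate sample: all Rg values identical;",
                "a single-component fallback is out of scope."),
          class = "ffbench_input_error")
  }
  best <- NULL
  withr::with_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- sort(sample(values, 2))
      if (centers[1] == centers[2]) {
        centers <- range(values)
      }
      fit <- .em_univariate_2(values, centers, tol = tol, max_iter = max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  ord <- order(best$means)
  structure(
    list(
      weights = best$weights[ord], means = best$means[ord],
      sds = best$sds[ord], loglik = best$loglik, n = length(values),
      iterations = best$iterations, converged = best$converged,
      seed = seed, n_init = n_init, tol = tol, values = values
    ),
    class = "rg_mixture_fit"
  )
}

# EM for a univariate 2-component Gaussian mixture from given centers.
# SDs are floored at 1e-6 * sd(x) to avoid component collapse on ties.
.em_univariate_2 <- function(x, centers, tol, max_iter) {
  n <- length(x)
  sd_floor <- max(1e-6 * sd(x), 1e-12)
  assign0 <- as.integer(abs(x - centers[1]) > abs(x - centers[2])) + 1L
  mu <- vapply(1:2, function(k) mean(x[assign0 == k]), numeric(1))
  mu[is.nan(mu)] <- centers[is.nan(mu)]
  sigma <- vapply(1:2, function(k) {
    s <- sd(x[assign0 == k])
    if (is.na(s) || s < sd_floor) sd(x) / 2 else s
  }, numeric(1))
  w <- pmax(tabulate(assign0, 2) / n, 1e-3)
  w <- w / sum(w)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dens <- cbind(w[1] * dnorm(x, mu[1], sigma[1]),
                  w[2] * dnorm(x, mu[2], sigma[2]))
    rowsum_d <- pmax(rowSums(dens), .Machine$double.xmin)
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(pmax(
      colSums(resp * (outer(x, mu, "-"))^2) / nk, sd_floor^2
    ))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sigma, loglik = ll_old,
       iterations = iter, converged = converged)
}

#' @export
print.rg_mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit (n =", x$n, ")\n")
  for (k in 1:2) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f\n",
                k, x$weights[k], x$means[k], x$sds[k]))
  }
  cat(sprintf("  log-likelihood %.3f (%s in %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' @rdname fit_rg_mixture
#' @param x An `rg_mixture_fit`.
#' @param ... Unused.
#' @export
tidy.rg_mixture_fit <- function(x, ...) {
  tibble(component = 1:2, weight = x$weights, mean = x$means, sd = x$sds)
}

#' @rdname fit_rg_mixture
#' @export
glance.rg_mixture_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n = x$n, iterations = x$iterations,
         converged = x$converged, seed = x$seed)
}

#' Reference-structure Rg score from a mixture fit
#'
#' For a reference Rg value, computes the Z-score of the reference under each
#' mixture component, \eqn{Z_i = (R_{g,ref} - \mu_i)/\sigma_i}, takes the
#' smallest absolute value \eqn{z^*} and returns \eqn{1/z^*}. Values of
#' \eqn{z^* < 10^{-8}} are capped at `cap` so that downstream min-max
#' normalisation stays finite.
#'
#' @param fit An [fit_rg_mixture()] result (or any list with `means`, `sds`).
#' @param ref_rg Reference Rg, angstrom.
#' @param cap Score cap for a vanishing Z-score.
#' @return Raw Rg score (higher = reference better covered).
#' @export
reference_rg_score <- function(fit, ref_rg, cap = 1e8) {
  z <- abs((ref_rg - fit$means) / fit$sds)
  zmin <- min(z)
  if (zmin < 1e-8) cap else 1 / zmin
}

#' Unfolded-state Rg score from a peptide-level sample
#'
#' Interquartile range of the per-peptide Rg sample divided by the absolute
#' distance between the sample median and the Flory prediction:
#' \eqn{(q_3 - q_1)/|R_{g,FL} - \tilde{R}_g|}. Percentiles use the linear
#' interpolation convention (R type 7). A median within `1e-8` of the Flory
#' value returns `cap`.
#'
#' @param values Numeric vector of single-peptide Rg values (>= 4).
#' @param rg_fl Flory reference Rg, angstrom (see [flory_rg()]).
#' @param cap Score cap for a vanishing denominator.
#' @return Raw unfolded-Rg score.
#' @export
unfolded_rg_score <- function(values, rg_fl, cap = 1e8) {
  if (length(values) < 4) {
    abort("At least 4 peptide Rg values are required.",
          class = "ffbench_input_error")
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  den <- abs(rg_fl - median(values))
  if (den < 1e-8) cap else (q[2] - q[1]) / den
}
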