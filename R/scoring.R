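#' Min-max normalize raw scores across force fields
#'
#' Linearly rescales a raw score column across force fields so the maximum
#' maps to exactly 1 and the minimum to the floor value 0.00001:
#' \deqn{S_{norm} = (S_{raw} - \min S)/(\max S - \min S),} with the minimum
#' entry then set to `floor` (the subtractive form; this is the form that
#' reproduces the published score tables). `method = "printed"` instead
#' divides the raw score by the range without subtracting the minimum, for
#' comparison.
#'
#' @param scores Tibble with a force-field label column and a raw score
#'   column.
#' @param value Name of the raw score column (string).
#' @param method `"subtractive"` (default) or `"printed"`.
#' @param floor Value assigned to the minimum entry.
#' @param name Name of the output column (default `paste0(value, "_norm")`).
#' @return `scores` with the normalized column appended.
#' @export
minmax_normalize <- function(scores, value = "score",
                             method = c("subtractive", "printed"),
                             floor = 1e-5, name = NULL) {
  method <- match.arg(method)
  x <- scores[[value]]
  if (length(x) < 2) {
    abort("Normalization needs at least two force fields.",
          class = "ffbench_input_error")
  }
  rng <- max(x) - min(x)
  if (rng == 0) {
    abort("All raw scores are equal; normalization is undefined.",
          class = "ffbench_input_error")
  }
  norm <- if (method == "subtractive") (x - min(x)) / rng else x / rng
  if (method == "subtractive") {
    norm[x == min(x)] <- floor
  }
  if (is.null(name)) name <- paste0(value, "_norm")
  scores[[name]] <- norm
  scores
}

#' Multiply normalized score columns, optionally renormalizing the product
#'
#' Entrywise product of aligned score vectors (same force-field labels in
#' each), optionally followed by [minmax_normalize()] of the products — the
#' operation behind the final Rg score (product of the U-shaped, L-shaped
#' and unfolded normalized scores, renormalized) and the final SSP score.
#'
#' @param ... Tibbles each with columns `force_field` and `value`, or a
#'   single list of such tibbles.
#' @param renormalize Apply min-max normalization to the products.
#' @param floor Floor for the renormalization step.
#' @return Tibble `force_field`, `value` (and `value_norm` when
#'   renormalized).
#' @export
combine_product <- function(..., renormalize = TRUE, floor = 1e-5) {
  vecs <- list(...)
  if (length(vecs) == 1 && !is.data.frame(vecs[[1]])) vecs <- vecs[[1]]
  labels <- vecs[[1]]$force_field
  for (v in vecs[-1]) {
    if (!setequal(v$force_field, labels)) {
      abort("Force-field label sets differ between score vectors.",
            class = "ffbench_input_error")
    }
  }
  prod <- rep(1, length(labels))
  for (v in vecs) {
    prod <- prod * v$value[match(labels, v$force_field)]
  }
  out <- tibble(force_field = labels, value = prod)
  if (renormalize) {
    out <- minmax_normalize(out, "value", floor = floor, name = "value_norm")
  }
  out
}

#' Final multi-measure score table
#'
#' Combines the three normalized component scores (Rg, SSP, contact map)
#' into the final score by bare multiplication (the form the published final
#' ranking uses; set `renormalize = TRUE` for a min-max-rescaled final
#' column) and ranks force fields by descending final score.
#'
#' @param rg_norm,ssp_norm,mcc_norm Tibbles `force_field`, `value` holding
#'   the normalized component scores.
#' @param renormalize Renormalize the final product across force fields.
#' @return A tibble of class `ff_score_table` with columns `force_field`,
#'   `rg`, `ssp`, `contact_map`, `final`, `rank`, sorted by rank.
#' @export
final_score <- function(rg_norm, ssp_norm, mcc_norm, renormalize = FALSE) {
  combined <- combine_product(rg_norm, ssp_norm, mcc_norm,
                              renormalize = renormalize)
  labels <- combined$force_field
  out <- tibble(
    force_field = labels,
    rg = rg_norm$value[match(labels, rg_norm$force_field)],
    ssp = ssp_norm$value[match(labels, ssp_norm$force_field)],
    contact_map = mcc_norm$value[match(labels, mcc_norm$force_field)],
    final = if (renormalize) combined$value_norm else combined$value
  )
  out <- out %>%
    arrange(desc(.data$final)) %>%
    mutate(rank = row_number())
  class(out) <- c("ff_score_table", class(out))
  out
}
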