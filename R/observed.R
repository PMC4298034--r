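#' Observed handedness proportions from the literature
#'
#' A small fixed table of meta-analytic observations against which the model
#' predictions are conventionally compared: the proportion of monozygotic
#' twin pairs discordant for handedness (19.3% of 10,001 pairs) and the
#' corresponding dizygotic rate (20.3%) from a meta-analysis of twin
#' studies, the rate of left-handedness among MZ twins in the same
#' meta-analysis (12.74%), and the pooled rate of left-handedness among
#' offspring of two left-handed parents (26% of 417 offspring across 25
#' family studies).
#'
#' @return A tibble with columns `measure`, `observed` (proportion), `n`
#'   (count behind the proportion where published, otherwise `NA`) and
#'   `source`.
#' @examples
#' observed_handedness()
#' @export
observed_handedness <- function() {
  tibble::tibble(
    measure = c("mz_discordance", "dz_discordance", "mz_left_rate",
                "lxl_offspring_left"),
    observed = c(0.193, 0.203, 0.1274, 0.26),
    n = c(10001L, NA_integer_, NA_integer_, 417L),
    source = c(
      "meta-analysis of twin studies (10,001 MZ pairs)",
      "meta-analysis of twin studies (DZ pairs)",
      "meta-analysis of twin studies (MZ individuals)",
      "pooled estimate across 25 family studies"
    )
  )
}

#' Compare model predictions with observed proportions
#'
#' Places the exact model predictions beside the observed proportions from
#' [observed_handedness()], with a binomial standard error on each observed
#' value whose denominator is published.
#'
#' @param model A [dc_model()].
#' @param observed A tibble shaped like [observed_handedness()]; rows with
#'   unknown `measure` values are kept with `NA` predictions.
#' @return A tibble with columns `measure`, `predicted`, `observed`, `n`,
#'   `observed_se` and `source`.
#' @examples
#' compare_observed(dc_model(c = 0.2))
#' @export
compare_observed <- function(model, observed = observed_handedness()) {
  check_model(model)
  if (!is.data.frame(observed)) stop_invalid("`observed` must be a data frame.")
  observed <- tibble::as_tibble(observed)
  if (nrow(observed) == 0) {
    return(tibble::tibble(
      measure = character(), predicted = numeric(), observed = numeric(),
      n = integer(), observed_se = numeric(), source = character()
    ))
  }
  preds <- c(
    mz_discordance = twin_distribution(model, "MZ")$prob[[2]],
    dz_discordance = twin_distribution(model, "DZ")$prob[[2]],
    mz_left_rate = population_left_rate(model),
    lxl_offspring_left = offspring_left_rate(model, "LxL")
  )
  dplyr::mutate(
    observed,
    predicted = unname(preds[.data$measure]),
    observed_se = ifelse(is.na(.data$n), NA_real_,
                         sqrt(.data$observed * (1 - .data$observed) / .data$n)),
    .after = "measure"
  )
}
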