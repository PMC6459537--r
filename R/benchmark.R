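#' Bundled benchmark model-comparison grids
#'
#' Loads the packaged reference grid of out-of-sample CoDa-RMSE /
#' CoDa-MAPE values for three national young/middle/old age-share series
#' (annual data, 48 training and 9 test years), covering the full
#' transform-by-model grid this package implements. The grid is bundled as
#' a plain CSV and is used to exercise the selection rule against known
#' published minima.
#'
#' @param country One of `"china"`, `"india"`, `"vietnam"`.
#' @return A `coda_evaluation` whose entries are the published grid values
#'   for that country.
#' @export
benchmark_grid <- function(country = c("china", "india", "vietnam")) {
  country <- match.arg(country)
  path <- system.file("extdata", "benchmark_grid.csv", package = "codaf",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$country == country, , drop = FALSE]
  entries <- data.frame(transform = df$transform, model = df$model,
                        coda_rmse = df$coda_rmse, coda_mape = df$coda_mape,
                        n_invalid = 0L, n_clamped = 0L,
                        error = NA_character_, stringsAsFactors = FALSE)
  structure(list(entries = entries,
                 split = list(train_end_year = 2007L, n_train = 48L,
                              n_test = 9L),
                 configs = list(), seed = NA_integer_),
            class = "coda_evaluation")
}
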