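#' Generate a synthetic feature table with known structure
#'
#' Builds a regression table in which the label is a known linear function of
#' the informative columns plus Gaussian noise, each redundant column is a
#' noisy copy of an informative parent (population correlation
#' `config$redundant_r`), and noise columns are independent standard normals.
#' Column naming encodes the truth: `inf1..`, `red1..` (with a `parent`
#' attribute), `noise1..`.
#'
#' @param config A [table_config()].
#' @return A tibble with the feature columns and a numeric `label` column.
#'   Attributes: `informative`, `redundant`, `noise` (column name vectors)
#'   and `redundant_parents` (named character vector mapping each redundant
#'   column to its informative parent).
#' @examples
#' tab <- generate_feature_table(table_config(n_samples = 100, seed = 7))
#' cor(tab$red1, tab$inf1)  # close to the configured redundant_r
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "table_config"))
  n <- config$n_samples
  with_seed(config$seed, {
    inf <- matrix(rnorm(n * config$n_informative), n)
    colnames(inf) <- paste0("inf", seq_len(config$n_informative))

    red <- NULL
    parents <- character(0)
    if (config$n_redundant > 0) {
      # x_red = r * parent + sqrt(1 - r^2) * e keeps unit variance and
      # population correlation exactly r with the parent.
      r <- config$redundant_r
      idx <- ((seq_len(config$n_redundant) - 1L) %% config$n_informative) + 1L
      red <- r * inf[, idx, drop = FALSE] +
        sqrt(1 - r^2) * matrix(rnorm(n * config$n_redundant), n)
      colnames(red) <- paste0("red", seq_len(config$n_redundant))
      parents <- stats::setNames(colnames(inf)[idx], colnames(red))
    }

    noise <- NULL
    if (config$n_noise > 0) {
      noise <- matrix(rnorm(n * config$n_noise), n)
      colnames(noise) <- paste0("noise", seq_len(config$n_noise))
    }

    label <- as.vector(inf %*% config$effect_sizes) +
      rnorm(n, 0, config$noise_sd)

    out <- as_tibble(as.data.frame(cbind(inf, red, noise)))
    out$label <- label
    attr(out, "informative") <- colnames(inf)
    attr(out, "redundant") <- if (is.null(red)) character(0) else colnames(red)
    attr(out, "noise") <- if (is.null(noise)) character(0) else colnames(noise)
    attr(out, "redundant_parents") <- parents
    out
  })
}
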