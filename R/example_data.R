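#' Published insomnia prioritization example
#'
#' The top-30 rows of a published insomnia target prioritization run:
#' gene symbol, the published aggregate score (3 decimals) and the five
#' normalized feature scores. Bundled as a regression surface for the
#' aggregation rule: the mean of the five feature columns reproduces the
#' published score on every row.
#'
#' @return Data.frame with columns `gene`, `published_score` and the five
#'   feature columns.
#' @export
#' @examples
#' ex <- insomnia_example()
#' all(abs(stargazer_score(ex) - ex$published_score) <= 5e-4)
insomnia_example <- function() {
  path <- system.file("extdata", "insomnia_prioritization_example.tsv",
                      package = "stargazeR", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
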