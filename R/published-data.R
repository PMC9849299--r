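#' Published transporter expression summaries
#'
#' Loads the group summary statistics (mean, SD, n, with ULQ bounds)
#' published for absolute transporter expression in crude membrane
#' fractions: a wild-type vs 5xFAD mouse comparison alongside the
#' companion wild-type vs TgF344-AD rat study, for isolated brain
#' microvessels and brain prefrontal cortex. Units are fmol/ug total
#' protein. These tables are inputs to the summary-statistic layer
#' ([summarizeFromStats()], [crossModelFlags()], [powerSpec()]); the
#' package does not re-measure them.
#'
#' @param tissue `"microvessel"` or `"cortex"`.
#' @return data.frame with columns `model` (`"mouse"`, `"rat"`),
#'   `protein`, `gene`, `group`, `mean`, `sd`, `n`, `status`, `lloq`.
#' @examples
#' ms <- publishedSummaries("microvessel")
#' rows <- summarizeFromStats(ms[ms$model == "mouse", ], "WT", "5xFAD")
#' formatComparisonTable(rows[rows$protein == "ASCT1", ])
#' @export
publishedSummaries <- function(tissue = c("microvessel", "cortex")) {
  tissue <- match.arg(tissue)
  path <- system.file("extdata",
                      paste0(tissue, "_summaries.csv"), package = "qtap",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(model = "character", protein = "character",
                                 gene = "character", group = "character",
                                 mean = "numeric", sd = "numeric",
                                 n = "integer", status = "character",
                                 lloq = "numeric"))
}
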