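# Published reference results shipped with the package.

#' Published metabolite-heart failure MR screen results
#'
#' The summary results of a published two-sample MR screen of 486 blood
#' metabolites against heart failure, shipped as plain-text reference data:
#' `"ivw"` gives the 22 nominally significant IVW rows (beta, SE, p, OR with
#' 95% CI); `"models"` gives the five-model detail (with heterogeneity and
#' pleiotropy p-values) for the 11 known metabolites. Useful for worked
#' examples and for checking the pipeline's reporting identities
#' (OR = exp(beta)) and its candidate decision rule against published
#' numbers.
#'
#' @param which `"ivw"` or `"models"`.
#' @return A data.frame.
#' @export
published_screen_results <- function(which = c("ivw", "models")) {
  which <- match.arg(which)
  file <- switch(which,
                 ivw = "metabolite_hf_ivw_published.tsv",
                 models = "metabolite_hf_models_published.tsv")
  path <- system.file("extdata", file, package = "mrmetab", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
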