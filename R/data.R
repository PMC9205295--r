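#' Published multi-environment benchmark summary (example data)
#'
#' Across-environment (Global) mean squared errors — plus two normalized
#' RMSE values — of six supervised learners (M1 generalized boosted
#' machine, M2 elastic net, M3 support vector machine, M4 random forest,
#' M5 Bayesian regression, M6 deep neural network) on two public
#' genome-based prediction benchmarks: a wheat panel (599 lines, 1447
#' DArT markers, grain yield in 4 mega-environments) and a maize hybrid
#' panel (722 hybrids, 54k SNPs, 4 environments). Used to demonstrate
#' the relative-performance arithmetic of [percent_outperformance()].
#'
#' @return data frame with columns `dataset`, `model`, `metric`,
#'   `global_mean`.
#' @export
benchmark_global_means <- function() {
  utils::read.csv(system.file("extdata", "benchmark_global_mse.csv",
                              package = "sparsekm"),
                  stringsAsFactors = FALSE)
}
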