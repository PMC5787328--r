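#' Reference posterior-mean estimates for two commercial pig lines
#'
#' Published posterior-mean variance components, asymmetry parameters,
#' inbreeding depression, genetic variances, variance ratios and model
#' comparison criteria for litter size in two commercial pig lines, under
#' the four model specifications this package fits.  Units: `sigma2_a` and
#' `sigma2_d` are per-SNP effect variances (trait units squared), `lambda`
#' is in trait units per auxiliary unit, `I_D` in piglets per 1 %
#' inbreeding, `V_A`/`V_D` in piglets squared.
#'
#' These values serve as arithmetic-consistency anchors: `h2` and `d2` must
#' be recoverable from the five variance components through
#' [variance_ratios()].
#'
#' @return Data frame with one row per line x model.
#' @export
reference_estimates <- function() {
  path <- system.file("extdata", "pig_lines_reference.tsv",
                      package = "dirdom", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA")
}

#' Recompute variance ratios from the reference components
#'
#' Applies [variance_ratios()] to every row of [reference_estimates()] and
#' returns the recomputed `h2`/`d2` next to the published values.
#'
#' @return Data frame with `line`, `model`, published and recomputed ratios.
#' @export
reference_ratio_check <- function() {
  ref <- reference_estimates()
  rec <- t(vapply(seq_len(nrow(ref)), function(i) {
    vr <- variance_ratios(ref$V_A[i], ref$V_D[i], ref$sigma2_c[i],
                          ref$sigma2_r[i], ref$sigma2_e[i])
    c(h2 = vr$h2, d2 = vr$d2)
  }, numeric(2)))
  data.frame(line = ref$line, model = ref$model,
             h2_published = ref$h2, h2_recomputed = rec[, "h2"],
             d2_published = ref$d2, d2_recomputed = rec[, "d2"])
}
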