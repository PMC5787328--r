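#' Allele substitution effects
#'
#' `alpha_j = a_j + (q_j - p_j) d_j`, the average effect of substituting one
#' allele for the other under Hardy-Weinberg proportions; breeding values are
#' linear in alpha.
#'
#' @param a,d per-SNP additive and dominance effects.
#' @param p per-SNP frequency of the counted allele.
#' @return Vector of substitution effects.
#' @export
substitution_effects <- function(a, d, p) {
  if (length(a) != length(d) || length(a) != length(p))
    stop("a, d and p must have equal length")
  a + (1 - 2 * p) * d
}

#' Additive and dominance genetic variances
#'
#' Orthogonal decomposition under Hardy-Weinberg and linkage equilibrium:
#' `V_A = sum 2 p q alpha^2` and `V_D = sum (2 p q d)^2`.
#'
#' @inheritParams substitution_effects
#' @return Named list with `V_A` and `V_D`.
#' @export
genetic_variances <- function(a, d, p) {
  alpha <- substitution_effects(a, d, p)
  twopq <- 2 * p * (1 - p)
  list(V_A = sum(twopq * alpha^2), V_D = sum((twopq * d)^2))
}

#' Heritability and dominance-variance ratio
#'
#' The phenotypic variance is `V_P = V_A + V_D + sigma2_c + sigma2_r +
#' sigma2_e` (permanent-environment and contemporary-group variances are
#' both part of the denominator), and `h2 = V_A / V_P`, `d2 = V_D / V_P`.
#'
#' @param V_A,V_D genetic variances.
#' @param sigma2_c permanent-environment variance.
#' @param sigma2_r contemporary-group (farm-year-month) variance.
#' @param sigma2_e residual variance.
#' @return Named list with `h2`, `d2` and `V_P`.
#' @export
variance_ratios <- function(V_A, V_D, sigma2_c, sigma2_r, sigma2_e) {
  vals <- c(V_A, V_D, sigma2_c, sigma2_r, sigma2_e)
  if (any(vals < 0)) stop("variance components must be >= 0")
  V_P <- sum(vals)
  if (V_P == 0) stop("total phenotypic variance is zero")
  list(h2 = V_A / V_P, d2 = V_D / V_P, V_P = V_P)
}

#' Expected inbreeding depression per 1 % of inbreeding
#'
#' When inbreeding rises by `F = 0.01`, expected homozygosity rises by
#' `F * mean(2 p q)` (acting through the covariate `b`) and each SNP's
#' heterozygosity falls by the factor `1 - F` (acting through the dominance
#' effects), so
#'
#'   I_D = 0.01 * ( b * mean_j(2 p_j q_j) - sum_j 2 p_j q_j d_j ).
#'
#' Negative values mean the trait declines with inbreeding.
#'
#' @param b homozygosity regression coefficient (0 when the model excludes
#'   it).
#' @param d per-SNP dominance effects.
#' @param p per-SNP allele frequencies.
#' @return Inbreeding depression in trait units per 1 % inbreeding.
#' @export
inbreeding_depression <- function(b, d, p) {
  if (length(d) != length(p)) stop("d and p must have equal length")
  twopq <- 2 * p * (1 - p)
  0.01 * (b * mean(twopq) - sum(twopq * d))
}

#' Dominance-deviation design codes
#'
#' Classical partition codes: count 2 maps to `-2 q^2`, count 1 to `2 p q`,
#' count 0 to `-2 p^2`.  Used for dominance deviations `s_d`; missing counts
#' code to zero (their Hardy-Weinberg expectation).
#'
#' @param counts allele-count matrix (individuals x SNPs).
#' @param p per-SNP allele frequencies.
#' @return Matrix of the same dimension.
#' @export
dominance_deviation_codes <- function(counts, p) {
  q <- 1 - p
  W <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_along(p)) {
    xj <- counts[, j]
    wj <- ifelse(is.na(xj), 0,
                 ifelse(xj == 2, -2 * q[j]^2,
                        ifelse(xj == 1, 2 * p[j] * q[j], -2 * p[j]^2)))
    W[, j] <- wj
  }
  W
}

#' Breeding values and dominance deviations
#'
#' `s_a,i = sum_j (x_ij - 2 p_j) alpha_j` and `s_d,i = sum_j w_ij d_j` with
#' the dominance-deviation codes of [dominance_deviation_codes()].  Both
#' have (near-)zero population mean under frequency-centred coding.
#'
#' @param G a [geno_matrix()] after QC.
#' @param a,d per-SNP additive and dominance effects.
#' @return Data frame with `id`, `s_a`, `s_d`.
#' @export
genomic_values <- function(G, a, d) {
  stopifnot(inherits(G, "geno_matrix"))
  if (length(a) != length(G$freqs) || length(d) != length(G$freqs))
    stop("effect vectors do not match the number of SNPs")
  alpha <- substitution_effects(a, d, G$freqs)
  Z <- encode_design(G, "freq")$Z
  W <- dominance_deviation_codes(G$counts, G$freqs)
  data.frame(id = G$ind_ids,
             s_a = as.numeric(Z %*% alpha),
             s_d = as.numeric(W %*% d),
             row.names = NULL)
}

#' Per-draw derived genetic quantities
#'
#' Applies [genetic_variances()], [variance_ratios()] and
#' [inbreeding_depression()] to every retained MCMC draw of the SNP effects.
#'
#' @param fit a [dirdom_fit()] object.
#' @return Data frame with one row per retained draw: `V_A`, `V_D`, `h2`,
#'   `d2`, `I_D` (plus the draw's chain index).
#' @export
derived_draws <- function(fit) {
  stopifnot(inherits(fit, "dirdom_fit"))
  p <- fit$freqs
  twopq <- 2 * p * (1 - p)
  A <- fit$a_draws
  D <- fit$d_draws
  sc <- fit$draws
  S <- nrow(A)
  out <- matrix(NA_real_, S, 5,
                dimnames = list(NULL, c("V_A", "V_D", "h2", "d2", "I_D")))
  for (s in seq_len(S)) {
    gv <- genetic_variances(A[s, ], D[s, ], p)
    vr <- variance_ratios(gv$V_A, gv$V_D, sc$sigma2_c[s], sc$sigma2_r[s],
                          sc$sigma2_e[s])
    out[s, ] <- c(gv$V_A, gv$V_D, vr$h2, vr$d2,
                  inbreeding_depression(sc$b[s], D[s, ], p))
  }
  data.frame(chain = sc$chain, out)
}
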