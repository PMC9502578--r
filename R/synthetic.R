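#' Specification of a synthetic descriptor table
#'
#' Emulates the statistical regime the workflow is designed for: a small
#' (default 66 chemicals) but wide descriptor table in which a handful of
#' informative features carry a linear signal plus one mild multiplicative
#' interaction, most features are pure noise, and a known set of decoy
#' features each violates exactly one of the three uninformative-feature
#' criteria (scarcity, extreme values, low variation). Defaults give
#' 5 informative + 95 noise + 20 decoys = 120 columns.
#'
#' Informative and noise features are standard normal. The clearance index is
#' `intercept + X beta + nonlinear_strength * x1 * x2 + N(0, noise_sd)`;
#' the intercept is shifted (not truncated) so the CI stays nonnegative,
#' keeping the linear model exact. Effect sizes default to 0.5-1 SD and the
#' noise SD to 0.2, i.e. clearly detectable but not trivial signal for n=66.
#'
#' @param n_chemicals number of chemicals (rows).
#' @param n_informative number of signal-carrying features.
#' @param n_noise number of uninformative standard-normal features.
#' @param n_scarce_decoys,n_extreme_decoys,n_lowvar_decoys decoy counts, one
#'   filter criterion each.
#' @param coefficients linear coefficients of the informative features.
#' @param nonlinear_strength coefficient of the `x1 * x2` interaction term.
#' @param noise_sd standard deviation of the additive Gaussian noise; > 0.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chemicals = 66, n_informative = 5, n_noise = 95,
                           n_scarce_decoys = 10, n_extreme_decoys = 5,
                           n_lowvar_decoys = 5,
                           coefficients = c(1, 0.85, 0.7, 0.6, 0.5),
                           nonlinear_strength = 0.3, noise_sd = 0.2,
                           seed = 1) {
  stopifnot(n_chemicals >= 3, n_informative >= 1, n_noise >= 0,
            n_scarce_decoys >= 0, n_extreme_decoys >= 0, n_lowvar_decoys >= 0,
            length(coefficients) == n_informative,
            nonlinear_strength >= 0, noise_sd > 0)
  if (n_lowvar_decoys > 0 && n_chemicals < 13)
    stop("low-variation decoys are infeasible below 13 chemicals ",
         "(cannot have fewer than 12 distinct values and still be a decoy)")
  structure(list(n_chemicals = as.integer(n_chemicals),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_scarce_decoys = as.integer(n_scarce_decoys),
                 n_extreme_decoys = as.integer(n_extreme_decoys),
                 n_lowvar_decoys = as.integer(n_lowvar_decoys),
                 coefficients = as.numeric(coefficients),
                 nonlinear_strength = nonlinear_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Decoy builders. Each violates exactly its own filter criterion and is
# engineered not to trip an earlier one (filters run extreme -> scarce ->
# low variation).
make_scarce <- function(n) {
  v <- stats::rnorm(n)
  v[sample.int(n, ceiling(0.4 * n))] <- 0
  v
}
make_extreme <- function(n) {
  v <- stats::rnorm(n)
  i <- sample.int(n, 1)
  v[i] <- sample(c(-1, 1), 1) * 200 * mean(abs(v[-i]))
  v
}
make_lowvar <- function(n) {
  # 8 distinct nonzero levels: < 12 distinct, no zeros, no extremes
  sample(seq(0.5, 3, length.out = 8), n, replace = TRUE)
}

#' Generate a synthetic descriptor table
#'
#' @param spec a [synthetic_spec()].
#' @return A [descriptor_table()] with `ci`, carrying the ground truth as
#'   attribute `"ground_truth"`: the linear coefficients, intercept, the
#'   names of informative, noise and per-criterion decoy features, and the
#'   noise settings.
#' @export
generate_descriptor_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  n <- spec$n_chemicals

  inf_names <- sprintf("INF%02d", seq_len(spec$n_informative))
  noise_names <- if (spec$n_noise)
    sprintf("RND%03d", seq_len(spec$n_noise)) else character(0)
  scz_names <- if (spec$n_scarce_decoys)
    sprintf("DECOY_SCARCE%02d", seq_len(spec$n_scarce_decoys)) else character(0)
  ext_names <- if (spec$n_extreme_decoys)
    sprintf("DECOY_EXTREME%02d", seq_len(spec$n_extreme_decoys)) else character(0)
  low_names <- if (spec$n_lowvar_decoys)
    sprintf("DECOY_LOWVAR%02d", seq_len(spec$n_lowvar_decoys)) else character(0)

  Xinf <- matrix(stats::rnorm(n * spec$n_informative), n, spec$n_informative)
  Xnoise <- matrix(stats::rnorm(n * spec$n_noise), n, spec$n_noise)
  Xscz <- vapply(seq_len(spec$n_scarce_decoys), function(k) make_scarce(n),
                 numeric(n))
  Xext <- vapply(seq_len(spec$n_extreme_decoys), function(k) make_extreme(n),
                 numeric(n))
  Xlow <- vapply(seq_len(spec$n_lowvar_decoys), function(k) make_lowvar(n),
                 numeric(n))
  X <- cbind(Xinf, Xnoise,
             if (spec$n_scarce_decoys) Xscz,
             if (spec$n_extreme_decoys) Xext,
             if (spec$n_lowvar_decoys) Xlow)
  colnames(X) <- c(inf_names, noise_names, scz_names, ext_names, low_names)

  signal <- drop(Xinf %*% spec$coefficients)
  if (spec$nonlinear_strength > 0 && spec$n_informative >= 2)
    signal <- signal + spec$nonlinear_strength * Xinf[, 1] * Xinf[, 2]
  eps <- stats::rnorm(n, 0, spec$noise_sd)
  raw <- signal + eps
  intercept <- max(0, -min(raw)) + 0.05  # shift, not truncate: CI >= 0
  ci <- raw + intercept

  tab <- descriptor_table(X, chemical_ids = sprintf("chem%03d", seq_len(n)),
                          ci = ci)
  attr(tab, "ground_truth") <- list(
    beta = stats::setNames(spec$coefficients, inf_names),
    intercept = intercept,
    informative = inf_names, noise = noise_names,
    decoys = list(scarce = scz_names, extreme = ext_names,
                  low_variation = low_names),
    nonlinear_strength = spec$nonlinear_strength,
    noise_sd = spec$noise_sd, seed = spec$seed)
  tab
}

#' Generate a synthetic external test set
#'
#' A small table (default 7 chemicals) drawn from the same generative process
#' as [generate_descriptor_table()], with the targets an external evaluation
#' needs: the reported `ci` (true value plus noise), a positive experimental
#' variation `ci_variation`, and the minimum CI `ci_min = ci - ci_variation`
#' floored at zero.
#'
#' @param spec the [synthetic_spec()] that generated the training table; the
#'   external set uses a seed derived from it so the two are independent but
#'   jointly reproducible.
#' @param n_chemicals size of the external set (default 7).
#' @param variation_mean mean experimental variation (default 0.15).
#' @return A [descriptor_table()] with `ci`, `ci_min` and `ci_variation`,
#'   carrying its ground truth as attribute `"ground_truth"`.
#' @export
generate_external_table <- function(spec, n_chemicals = 7,
                                    variation_mean = 0.15) {
  stopifnot(inherits(spec, "synthetic_spec"), n_chemicals >= 3)
  train <- generate_descriptor_table(spec)
  truth <- attr(train, "ground_truth")

  ext_spec <- spec
  ext_spec$n_chemicals <- as.integer(n_chemicals)
  ext_spec$n_lowvar_decoys <- 0L  # infeasible and pointless at n = 7
  ext_spec$seed <- spec$seed + 104729L  # distinct, reproducible stream
  ext <- generate_descriptor_table(ext_spec)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(ext_spec$seed + 1L)
  # rebuild CI with the TRAINING intercept so external truth matches the
  # model the training table implies
  Xinf <- ext$values[, truth$informative, drop = FALSE]
  signal <- drop(Xinf %*% truth$beta)
  if (truth$nonlinear_strength > 0 && length(truth$informative) >= 2)
    signal <- signal + truth$nonlinear_strength * Xinf[, 1] * Xinf[, 2]
  ci <- pmax(signal + truth$intercept +
               stats::rnorm(n_chemicals, 0, spec$noise_sd), 0)
  variation <- abs(stats::rnorm(n_chemicals, variation_mean,
                                variation_mean / 3)) + 0.02
  out <- descriptor_table(ext$values, chemical_ids = ext$chemical_ids,
                          ci = ci, ci_min = pmax(ci - variation, 0),
                          ci_variation = variation)
  attr(out, "ground_truth") <- utils::modifyList(
    attr(ext, "ground_truth"),
    list(beta = truth$beta, intercept = truth$intercept))
  out
}
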