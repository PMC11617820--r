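# Run code under an explicit seed without touching the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Lognormal draws parameterised by mean and coefficient of variation.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2,
                sdlog = sqrt(sigma2))
}

#' Generate synthetic release experiments with known ground truth
#'
#' Emulates the statistical structure of a short-duration abrasion release
#' experiment: per-sample initial areal loads are drawn lognormally around a
#' nominal mean, the truly released mass follows first-order kinetics with a
#' known rate constant, and the observed release carries multiplicative
#' lognormal measurement noise (mean 1). Lognormal noise reflects
#' ICP-MS-style replicate scatter that is proportional to level. With zero
#' noise, [estimate_rate_constant()] recovers `true_k` exactly on every
#' sample.
#'
#' @param true_k True first-order release constant (1/min).
#' @param n_samples Number of samples (>= 1).
#' @param load_mean_ng_cm2 Mean initial areal load (ng/cm^2); default 1530,
#'   a typical coated-textile batch average.
#' @param load_cv Coefficient of variation of the loads (default 0.3).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on the observed release (default 0.1).
#' @param duration_min Release duration (min); default 1/6 (10 s).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A data.frame with columns `sample`, `medium`, `duration_s`,
#'   `duration_min`, `load_ng_cm2`, `release_ng_cm2`, `true_k` — the same
#'   dialect [read_release_csv()] reads (plus `duration_min`, `true_k`).
#' @examples
#' d <- generate_release_dataset(0.086, 6, noise_cv = 0, seed = 1)
#' fit_release_rates(d)$per_sample$k_per_min  # all exactly 0.086
#' @export
generate_release_dataset <- function(true_k, n_samples,
                                     load_mean_ng_cm2 = 1530,
                                     load_cv = 0.3,
                                     noise_cv = 0.1,
                                     duration_min = 10 / 60,
                                     seed = 1) {
  if (!is.finite(true_k) || true_k < 0) {
    stop("true_k must be >= 0", call. = FALSE)
  }
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (load_cv < 0 || noise_cv < 0) {
    stop("coefficients of variation must be >= 0", call. = FALSE)
  }
  if (duration_min <= 0) stop("duration_min must be > 0", call. = FALSE)
  with_local_seed(seed, {
    loads <- rlnorm_mean_cv(n_samples, load_mean_ng_cm2, load_cv)
    true_release <- loads * released_fraction(duration_min, true_k)
    noise <- rlnorm_mean_cv(n_samples, 1, noise_cv)
    observed <- pmin(true_release * noise, loads * (1 - 1e-12))
    data.frame(
      sample = sprintf("synth%03d", seq_len(n_samples)),
      medium = "abrasion-sweat",
      duration_s = duration_min * 60,
      duration_min = duration_min,
      load_ng_cm2 = loads,
      release_ng_cm2 = observed,
      true_k = true_k,
      stringsAsFactors = FALSE)
  })
}

#' Generate synthetic textile batches for a coating family
#'
#' Draws areal loads for `n` synthetic batches of a coating family from a
#' normal distribution with the measured batch means and standard deviations
#' (see [textile_load_data()]), truncated at zero. Batches are sampled with
#' replacement from the family's measured batch list, so large `n` converges
#' to the family's mean load.
#'
#' @param family One of `"AgCur"`, `"AgHEC6.4"`, `"AgHEC"`.
#' @param n Number of synthetic batches.
#' @param area_cm2 Contact area assigned to each product (default 1 cm^2).
#' @param seed Integer seed.
#' @return A list of `n` [textile_product()]s.
#' @export
generate_textile_family <- function(family = c("AgCur", "AgHEC6.4", "AgHEC"),
                                    n, area_cm2 = 1, seed = 1) {
  family <- match.arg(family)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  batches <- textile_load_data()
  batches <- batches[batches$family == family, ]
  with_local_seed(seed, {
    idx <- sample.int(nrow(batches), n, replace = TRUE)
    loads <- pmax(0, stats::rnorm(n, mean = batches$load_ng_cm2[idx],
                                  sd = batches$sd_ng_cm2[idx]))
    lapply(seq_len(n), function(i) {
      textile_product(loads[i], area_cm2,
                      label = sprintf("%s synthetic batch %d (from %s)",
                                      family, i, batches$sample[idx[i]]))
    })
  })
}
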