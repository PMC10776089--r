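#' admixmate: ancestry-assortative mating simulation and inference
#'
#' Forward-in-time simulation of three-way admixed populations (sub-Saharan
#' African = ancestry 1, Native American = 2, European = 3) under a mating
#' model in which couple formation depends on the difference in genome-wide
#' ancestry proportions between male and female, plus simulation-based
#' inference of the mating parameters from continuous ancestry tract-length
#' profiles.
#'
#' Sign convention used throughout: the ancestry difference of a couple is
#' \eqn{d = a_m - a_f} (male minus female), so a positive sex-bias parameter
#' means couples in which the male carries more of that ancestry are favoured.
#'
#' @keywords internal
#' @importFrom stats rpois runif rnorm rbinom quantile var cov sd rmultinom
#'   dpois cor
#' @importFrom utils head tail read.table write.table modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib admixmate, .registration = TRUE
"_PACKAGE"

ANCESTRY_NAMES <- c("AFR", "NAT", "EUR")

#' Mating parameter vector
#'
#' Bundles the per-ancestry assortative-mating strengths (AM), sex biases
#' (SB) and, for two-pulse scenarios, gene-flow rates (GFR). AM values live
#' in \[0, 1\] (0 = random mating, 1 = very strong assortment). SB values sum
#' to zero across the three ancestries; only SB1 and SB2 are free and SB3 is
#' derived. GFR values in \[0, 1\] give, per ancestry, the fraction of that
#' ancestry's migrant gene pool arriving in the second pulse.
#'
#' @param am numeric length 3, each in \[0, 1\].
#' @param sb numeric length 2 (SB1, SB2) or length 3 summing to zero.
#' @param gfr optional numeric length 3 in \[0, 1\].
#' @return an object of class `mating_params`.
#' @examples
#' mating_params(am = c(0.7, 0.2, 0.2), sb = c(0.1, -0.05))
#' @export
mating_params <- function(am, sb = c(0, 0), gfr = NULL) {
  am <- as.numeric(am)
  sb <- as.numeric(sb)
  if (length(am) != 3L) stop("`am` must have length 3")
  if (any(!is.finite(am)) || any(am < 0) || any(am > 1)) {
    stop("`am` values must be finite and in [0, 1]")
  }
  if (length(sb) == 2L) sb <- c(sb, -sum(sb))
  if (length(sb) != 3L) stop("`sb` must have length 2 or 3")
  if (abs(sum(sb)) > 1e-9) stop("`sb` components must sum to 0")
  if (!is.null(gfr)) {
    gfr <- as.numeric(gfr)
    if (length(gfr) != 3L) stop("`gfr` must have length 3")
    if (any(!is.finite(gfr)) || any(gfr < 0) || any(gfr > 1)) {
      stop("`gfr` values must be finite and in [0, 1]")
    }
  }
  structure(list(am = am, sb = sb, gfr = gfr), class = "mating_params")
}

#' @export
print.mating_params <- function(x, ...) {
  cat("Mating parameters (ancestries: ", paste(ANCESTRY_NAMES, collapse = ", "),
      ")\n", sep = "")
  cat("  AM :", format(x$am, digits = 4), "\n")
  cat("  SB :", format(x$sb, digits = 4), "\n")
  if (!is.null(x$gfr)) cat("  GFR:", format(x$gfr, digits = 4), "\n")
  invisible(x)
}

#' @export
format.mating_params <- function(x, ...) {
  paste0("AM=(", paste(signif(x$am, 3), collapse = ","), ") SB=(",
         paste(signif(x$sb, 3), collapse = ","), ")",
         if (!is.null(x$gfr)) paste0(" GFR=(", paste(signif(x$gfr, 3),
                                                     collapse = ","), ")"))
}

#' Convert an assortative-mating strength to a mating-kernel variance
#'
#' The AM scale is logarithmic in the variance of the mate ancestry-difference
#' distribution: `sigma2 = 3^(3 - 7 * am)`, so AM = 0 (random mating) maps to
#' the widest variance 27 and AM = 1 to the tightest, 3^-4 = 1/81.
#'
#' @param am numeric in \[0, 1\] (vectorised).
#' @return the variance(s) sigma^2, strictly decreasing in `am`.
#' @seealso [variance_to_am()]
#' @export
am_to_variance <- function(am) {
  am <- as.numeric(am)
  if (any(!is.finite(am)) || any(am < 0) || any(am > 1)) {
    stop("`am` must be in [0, 1]")
  }
  3^(3 - 7 * am)
}

#' Inverse of [am_to_variance()]
#'
#' @param variance numeric in \[3^-4, 27\] (vectorised).
#' @return the AM value(s) in \[0, 1\].
#' @export
variance_to_am <- function(variance) {
  variance <- as.numeric(variance)
  if (any(!is.finite(variance)) || any(variance < 3^-4 - 1e-12) ||
      any(variance > 27 + 1e-12)) {
    stop("`variance` must be in [3^-4, 27]")
  }
  (3 - log(variance, base = 3)) / 7
}

#' Build the Gaussian mating kernel from mating parameters
#'
#' Because the three ancestry-difference coordinates sum to zero, the
#' three-dimensional normal is degenerate and is represented in the first two
#' coordinates: mean `mu = (SB1, SB2)` and covariance with diagonal
#' `(sigma1^2, sigma2^2)` and off-diagonal
#' `Cov12 = (sigma3^2 - sigma1^2 - sigma2^2) / 2`, where each `sigma_s^2`
#' comes from [am_to_variance()]. Not every AM triple yields a valid
#' (positive-definite) covariance; infeasible triples raise an error of class
#' `admixmate_kernel_infeasible` carrying the offending AM values.
#'
#' @param params a [mating_params()] object.
#' @return an object of class `mating_kernel` with fields `mu`, `sigma`,
#'   `sigma3_sq` and the originating `params`.
#' @examples
#' k <- build_kernel(mating_params(am = c(0.5, 0.5, 0.5), sb = c(0, 0)))
#' k$sigma
#' @export
build_kernel <- function(params) {
  stopifnot(inherits(params, "mating_params"))
  v <- am_to_variance(params$am)
  cov12 <- (v[3] - v[1] - v[2]) / 2
  sigma <- matrix(c(v[1], cov12, cov12, v[2]), 2, 2)
  det_sigma <- v[1] * v[2] - cov12^2
  # require strict positive-definiteness with a small margin; the degenerate
  # boundary (det = 0) gives an improper density and is rejected too
  if (det_sigma <= 1e-10) {
    cond <- structure(
      class = c("admixmate_kernel_infeasible", "error", "condition"),
      list(message = sprintf(
             "AM triple (%s) gives a non-positive-definite mating covariance (det = %.4g)",
             paste(signif(params$am, 4), collapse = ", "), det_sigma),
           call = sys.call(-1), am = params$am))
    stop(cond)
  }
  structure(list(mu = params$sb[1:2], sigma = sigma, sigma3_sq = v[3],
                 params = params),
            class = "mating_kernel")
}

#' @export
print.mating_kernel <- function(x, ...) {
  cat("Gaussian mating kernel on d = a_m - a_f (first two ancestries)\n")
  cat("  mu   :", format(x$mu, digits = 4), "\n")
  cat("  sigma:\n")
  print(signif(x$sigma, 4))
  invisible(x)
}

# 2-d normal density of rows of `d` (n x 2) under the kernel; vectorised.
dmvn2 <- function(d, mu, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
  if (det_s <= 0) stop("singular mating covariance")
  inv <- matrix(c(sigma[2, 2], -sigma[1, 2], -sigma[1, 2], sigma[1, 1]),
                2, 2) / det_s
  dc <- sweep(d, 2, mu)
  q <- dc[, 1]^2 * inv[1, 1] + 2 * dc[, 1] * dc[, 2] * inv[1, 2] +
    dc[, 2]^2 * inv[2, 2]
  exp(-q / 2) / (2 * pi * sqrt(det_s))
}

#' Mating density of one couple
#'
#' Evaluates the bivariate normal density of the kernel at the couple's
#' ancestry difference `d = a_m - a_f` (first two ancestry coordinates).
#'
#' @param kernel a [build_kernel()] result.
#' @param a_f,a_m ancestry-proportion vectors (length 3, summing to 1) of the
#'   female and the male.
#' @return a non-negative density value.
#' @export
couple_density <- function(kernel, a_f, a_m) {
  stopifnot(inherits(kernel, "mating_kernel"))
  check_ancestry_vector(a_f)
  check_ancestry_vector(a_m)
  d <- matrix(a_m[1:2] - a_f[1:2], 1, 2)
  as.numeric(dmvn2(d, kernel$mu, kernel$sigma))
}

check_ancestry_vector <- function(a) {
  if (length(a) != 3L || any(!is.finite(a)) || any(a < -1e-9) ||
      abs(sum(a) - 1) > 1e-9) {
    stop("an ancestry vector must be 3 non-negative proportions summing to 1")
  }
  invisible(TRUE)
}

#' Conditional mate-choice probabilities for one initiator
#'
#' Given an individual who initiates a mating event, returns the probability
#' of choosing each candidate of the opposite sex: kernel densities at the
#' couple differences, normalised over the candidates.
#'
#' @param kernel a [build_kernel()] result.
#' @param initiator ancestry vector of the initiating individual.
#' @param candidates matrix (n x 3) or list of ancestry vectors of the
#'   opposite-sex candidates.
#' @param initiator_sex "F" or "M"; determines the sign of the difference
#'   (d is always male minus female).
#' @return probability vector summing to 1.
#' @export
conditional_mate_probs <- function(kernel, initiator, candidates,
                                   initiator_sex = c("F", "M")) {
  initiator_sex <- match.arg(initiator_sex)
  if (is.list(candidates)) candidates <- do.call(rbind, candidates)
  candidates <- as.matrix(candidates)
  if (nrow(candidates) < 1L) stop("need at least one candidate")
  check_ancestry_vector(initiator)
  d <- if (initiator_sex == "F") {
    sweep(candidates[, 1:2, drop = FALSE], 2, initiator[1:2])
  } else {
    -sweep(candidates[, 1:2, drop = FALSE], 2, initiator[1:2])
  }
  dens <- dmvn2(d, kernel$mu, kernel$sigma)
  if (sum(dens) == 0) {  # numerically flushed tails: fall back to uniform
    return(rep(1 / nrow(candidates), nrow(candidates)))
  }
  dens / sum(dens)
}

#' Probability of one specific couple mating
#'
#' Combines the two initiation routes: with probability 1/2 a uniformly chosen
#' female initiates and picks among all males, and symmetrically for a male
#' initiator. Summed over all F x M couples the probabilities total 1.
#'
#' @param kernel a [build_kernel()] result.
#' @param f_index,m_index indices of the couple within `females` / `males`.
#' @param females,males matrices (rows = individuals) or lists of ancestry
#'   vectors for each sex class.
#' @return the couple's mating probability.
#' @export
couple_probability <- function(kernel, f_index, m_index, females, males) {
  if (is.list(females)) females <- do.call(rbind, females)
  if (is.list(males)) males <- do.call(rbind, males)
  females <- as.matrix(females); males <- as.matrix(males)
  if (nrow(females) < 1L || nrow(males) < 1L) {
    stop("both sex classes must be non-empty")
  }
  p_m_given_f <- conditional_mate_probs(kernel, females[f_index, ], males, "F")
  p_f_given_m <- conditional_mate_probs(kernel, males[m_index, ], females, "M")
  0.5 * (1 / nrow(females)) * p_m_given_f[m_index] +
    0.5 * (1 / nrow(males)) * p_f_given_m[f_index]
}

#' Prior configuration for mating parameters
#'
#' Uniform, independent priors matching the simulation study: AM on
#' `am_range` (default \[0, 1\]), SB1 and SB2 on `sb_range` (default
#' \[-1, 1\]; SB3 is derived), and GFR on `gfr_range` when a two-pulse
#' scenario is simulated. `reject_non_psd` resamples AM triples whose
#' implied covariance is not positive definite, preserving the model exactly.
#'
#' @param am_range,sb_range,gfr_range numeric length-2 intervals.
#' @param reject_non_psd logical; resample infeasible AM triples.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(am_range = c(0, 1), sb_range = c(-1, 1),
                         gfr_range = c(0, 1), reject_non_psd = TRUE) {
  chk <- function(r, lo, hi, nm) {
    if (length(r) != 2L || r[1] > r[2]) stop("`", nm, "` must be a valid interval")
    if (!is.null(lo) && (r[1] < lo - 1e-12 || r[2] > hi + 1e-12)) {
      stop("`", nm, "` must lie within [", lo, ", ", hi, "]")
    }
  }
  chk(am_range, 0, 1, "am_range")
  chk(sb_range, NULL, NULL, "sb_range")
  chk(gfr_range, 0, 1, "gfr_range")
  structure(list(am_range = as.numeric(am_range),
                 sb_range = as.numeric(sb_range),
                 gfr_range = as.numeric(gfr_range),
                 reject_non_psd = isTRUE(reject_non_psd)),
            class = "prior_config")
}

#' Draw mating parameters from the prior
#'
#' @param prior a [prior_config()] object.
#' @param include_gfr draw GFR values too (two-pulse scenarios)?
#' @return a [mating_params()] object. Uses the current RNG state; call
#'   `set.seed()` beforehand for reproducibility.
#' @export
sample_mating_params <- function(prior = prior_config(), include_gfr = FALSE) {
  stopifnot(inherits(prior, "prior_config"))
  for (i in seq_len(10000L)) {
    am <- runif(3, prior$am_range[1], prior$am_range[2])
    sb12 <- runif(2, prior$sb_range[1], prior$sb_range[2])
    gfr <- if (include_gfr) runif(3, prior$gfr_range[1], prior$gfr_range[2])
    p <- mating_params(am = am, sb = sb12, gfr = gfr)
    if (!prior$reject_non_psd) return(p)
    ok <- tryCatch({ build_kernel(p); TRUE },
                   admixmate_kernel_infeasible = function(e) FALSE)
    if (ok) return(p)
  }
  stop("10,000 consecutive prior draws rejected: prior incompatible with a ",
       "positive-definite mating kernel")
}

#' Serialise / deserialise mating parameters as a flat JSON record
#'
#' @param params a [mating_params()] object.
#' @param path file path.
#' @return `read_mating_params` returns a [mating_params()] object.
#' @export
write_mating_params <- function(params, path) {
  stopifnot(inherits(params, "mating_params"))
  rec <- list(am1 = params$am[1], am2 = params$am[2], am3 = params$am[3],
              sb1 = params$sb[1], sb2 = params$sb[2], sb3 = params$sb[3])
  if (!is.null(params$gfr)) {
    rec <- c(rec, list(gfr1 = params$gfr[1], gfr2 = params$gfr[2],
                       gfr3 = params$gfr[3]))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mating_params
#' @export
read_mating_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  gfr <- if (!is.null(rec$gfr1)) c(rec$gfr1, rec$gfr2, rec$gfr3)
  mating_params(am = c(rec$am1, rec$am2, rec$am3),
                sb = c(rec$sb1, rec$sb2, rec$sb3), gfr = gfr)
}
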