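#' Simulate a reference tract-count distribution under fixed parameters
#'
#' Runs `R` independent scenario replicates and averages the raw population
#' tract-length profiles cell-wise, adding a pseudocount of 0.5 so every
#' cell supports a proper Poisson term in the composite likelihood.
#'
#' @param params a [mating_params()].
#' @param config a [scenario_config()]; its `seed` anchors the replicate
#'   seeds.
#' @param R number of replicates (>= 2).
#' @param pseudocount added to every cell mean (default 0.5).
#' @return an object of class `ref_bins`: list with `mean` (22 x 3 x 2
#'   array of per-individual mean counts + pseudocount), `n_individuals`,
#'   `R` and `pseudocount`.
#' @export
simulate_reference <- function(params, config, R = 10L, pseudocount = 0.5) {
  if (R < 2L) stop("need R >= 2 reference replicates")
  base_seed <- if (!is.null(config$seed)) config$seed else
    sample.int(1e6, 1)
  acc <- NULL
  n_ind <- 0
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- base_seed + r
    sim <- run_scenario(cfg, params)
    prof <- population_profile(sim$population)
    acc <- if (is.null(acc)) prof$counts else acc + prof$counts
    n_ind <- prof$n_individuals
  }
  structure(list(mean = acc / R + pseudocount, n_individuals = n_ind,
                 R = R, pseudocount = pseudocount),
            class = "ref_bins")
}

#' Composite log-likelihood of an observed profile under a reference
#'
#' Treats every (bin, ancestry, chromosome-class) cell as an independent
#' Poisson observation with mean given by the reference distribution.
#' Mean-per-individual profiles are evaluated at total counts: observed and
#' reference means are both multiplied by the observed number of
#' individuals and the observation rounded to an integer.
#'
#' @param observed a raw `tract_profile` (population mean counts).
#' @param ref a [simulate_reference()] result.
#' @param cells optional logical array selecting the profile cells to sum
#'   over (for per-ancestry / per-chromosome-class likelihoods).
#' @return the composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, ref, cells = NULL) {
  stopifnot(inherits(observed, "tract_profile"), inherits(ref, "ref_bins"))
  if (!identical(dim(observed$counts), dim(ref$mean))) {
    stop("observed profile and reference have different shapes")
  }
  n <- observed$n_individuals
  obs_tot <- round(observed$counts * n)
  mu_tot <- pmax(ref$mean * n, 1e-12)
  ll <- dpois(obs_tot, mu_tot, log = TRUE)
  if (!is.null(cells)) ll <- ll[cells]
  sum(ll)
}

#' Composite likelihood ratio: two-pulse vs one-pulse fit
#'
#' `CLR = logCL(observed | two-pulse reference) - logCL(observed |
#' one-pulse reference)`, computed separately for each ancestry and
#' chromosome class (positive values favour the two-pulse model), with a
#' 95% bootstrap confidence interval obtained by resampling the observed
#' per-individual tract histograms.
#'
#' @param per_individual list of per-individual raw count arrays for the
#'   observed population (see [individual_profile()]).
#' @param params_1p,params_2p fitted [mating_params()] for the two models
#'   (the two-pulse set must carry GFR).
#' @param config_1p,config_2p matching [scenario_config()]s (one-pulse and
#'   two-pulse migration models).
#' @param R reference replicates per model.
#' @param B bootstrap resamples of the observed profile.
#' @param sexes optional per-individual sexes for female-only X averaging.
#' @return data.frame with columns `ancestry`, `chrom_class`, `clr`,
#'   `lower`, `upper`, plus a row `overall`/`all` summing every cell.
#' @export
clr <- function(per_individual, params_1p, params_2p, config_1p, config_2p,
                R = 10L, B = 200L, sexes = NULL) {
  ref1 <- simulate_reference(params_1p, config_1p, R = R)
  ref2 <- simulate_reference(params_2p, config_2p, R = R)
  clr_from_refs(per_individual, ref1, ref2, B = B, sexes = sexes)
}

#' @rdname clr
#' @param ref_1p,ref_2p pre-computed [simulate_reference()] results (skips
#'   the simulation step).
#' @export
clr_from_refs <- function(per_individual, ref_1p, ref_2p, B = 200L,
                          sexes = NULL) {
  n <- length(per_individual)
  if (is.null(sexes)) sexes <- rep("F", n)
  observed <- mean_of_individual_counts(per_individual, sexes)
  cells_list <- clr_cells(dim(observed$counts))
  point <- vapply(cells_list, function(cl) {
    composite_loglik(observed, ref_2p, cl) -
      composite_loglik(observed, ref_1p, cl)
  }, numeric(1))
  boot <- matrix(NA_real_, B, length(cells_list))
  for (b in seq_len(B)) {
    res <- bootstrap_profile(per_individual, B = 1L,
                             female_x_sexes = sexes)$mean_profile
    res$n_individuals <- n
    boot[b, ] <- vapply(cells_list, function(cl) {
      composite_loglik(res, ref_2p, cl) - composite_loglik(res, ref_1p, cl)
    }, numeric(1))
  }
  lab <- do.call(rbind, strsplit(names(cells_list), "\\."))
  data.frame(ancestry = lab[, 1], chrom_class = lab[, 2], clr = point,
             lower = apply(boot, 2, quantile, 0.025, names = FALSE),
             upper = apply(boot, 2, quantile, 0.975, names = FALSE),
             row.names = NULL)
}

mean_of_individual_counts <- function(per_individual, sexes) {
  n <- length(per_individual)
  acc <- Reduce(`+`, per_individual) / n
  x_idx <- which(sexes == "F")
  if (length(x_idx)) {
    acc[, , 2] <- Reduce(`+`, lapply(per_individual[x_idx],
                                     function(m) m[, , 2])) / length(x_idx)
  } else acc[, , 2] <- 0
  tract_profile_obj(acc, n_individuals = n)
}

clr_cells <- function(dm) {
  out <- list()
  template <- array(FALSE, dim = dm)
  for (a in 1:3) for (cls in 1:2) {
    cl <- template
    cl[, a, cls] <- TRUE
    out[[paste(ANCESTRY_NAMES[a], CHROM_CLASSES[cls], sep = ".")]] <- cl
  }
  all_cells <- template
  all_cells[] <- TRUE
  out[["overall.all"]] <- all_cells
  out
}

#' Generalized variance of paired parameter estimates
#'
#' Determinant of the 2x2 sample covariance matrix of two estimate vectors:
#' `GV = var(x) * var(y) - cov(x, y)^2`. Zero for perfectly concordant
#' pairs, close to `var(x) * var(y)` for independent ones; always >= 0.
#'
#' @param x,y equal-length numeric vectors of paired estimates (e.g. the
#'   same parameter estimated from two local-ancestry methods across an
#'   ensemble).
#' @return the generalized variance (scalar).
#' @export
generalized_variance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two paired estimates")
  var(x) * var(y) - cov(x, y)^2
}
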