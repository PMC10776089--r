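#' Founding-proportion presets for the six study populations
#'
#' Mean genome-wide ancestry proportions (sub-Saharan African, Native
#' American, European; per cent) of the six admixed American populations of
#' the 1000 Genomes Project, as inferred by window-grid local-ancestry
#' analysis; autosomal and X-chromosome means are both carried, and the
#' autosomal means (renormalised to sum exactly to 1) are used as founding
#' proportions, since sex-balanced founding reproduces the X proportions
#' endogenously.
#'
#' @return a data.frame with one row per population (`ACB`, `ASW`, `CLM`,
#'   `MXL`, `PEL`, `PUR`) and columns `aut_AFR` ... `x_EUR` (per cent).
#' @export
preset_scenarios <- function() {
  df <- data.frame(
    population = c("ACB", "ASW", "CLM", "MXL", "PEL", "PUR"),
    aut_AFR = c(88.3, 76.9, 8.2, 4.4, 3.2, 13.8),
    aut_NAT = c(0.1, 1.5, 26.8, 49.3, 75.4, 14.4),
    aut_EUR = c(11.8, 21.7, 65.1, 46.5, 21.6, 72.0),
    x_AFR = c(94.0, 77.5, 8.0, 5.2, 5.1, 15.4),
    x_NAT = c(0.1, 3.7, 40.1, 61.2, 81.9, 21.2),
    x_EUR = c(5.4, 18.3, 51.5, 33.2, 12.5, 63.0),
    stringsAsFactors = FALSE)
  df
}

#' Founding proportions of one preset population
#'
#' @param population one of "ACB", "ASW", "CLM", "MXL", "PEL", "PUR".
#' @return numeric length-3 autosomal proportions renormalised to sum to 1.
#' @export
preset_proportions <- function(population) {
  df <- preset_scenarios()
  row <- df[df$population == population, ]
  if (nrow(row) != 1L) {
    stop("unknown population preset: ", population)
  }
  p <- c(row$aut_AFR, row$aut_NAT, row$aut_EUR)
  p <- p / sum(p)
  names(p) <- ANCESTRY_NAMES
  p
}

#' Build a uniform-rate toy genetic map
#'
#' @param cm_lengths autosomal genetic lengths in cM.
#' @param include_x append an X chromosome?
#' @param x_cm X genetic length (cM).
#' @return a [genetic_map()].
#' @export
toy_genetic_map <- function(cm_lengths = c(250, 200, 150, 120, 100),
                            include_x = TRUE, x_cm = 180) {
  n <- length(cm_lengths)
  chrom <- paste0("chr", seq_len(n))
  lens <- as.numeric(cm_lengths)
  is_x <- rep(FALSE, n)
  if (include_x) {
    chrom <- c(chrom, "chrX")
    lens <- c(lens, x_cm)
    is_x <- c(is_x, TRUE)
  }
  genetic_map(chrom, lens, is_x)
}

#' Desk-scale scenario configuration
#'
#' The scaled-down default used for development and testing: N = 200
#' individuals on 5 autosomes (250, 200, 150, 120, 100 cM) plus a 180 cM
#' X, 19 generations. The full-scale study configuration (N = 1000, 22
#' autosomes + X) is available from [full_scale_config()].
#'
#' @param founding_proportions length-3 ancestry proportions (default: the
#'   PEL preset).
#' @param ... passed to [scenario_config()].
#' @return a [scenario_config()].
#' @export
desk_scale_config <- function(founding_proportions = preset_proportions("PEL"),
                              ...) {
  scenario_config(founding_proportions = founding_proportions,
                  population_size = 200L, generations = 19L,
                  map = toy_genetic_map(), ...)
}

#' Full-scale scenario configuration (cluster-scale reproduction)
#'
#' N = 1000 diploids on the bundled 22-autosome + X map, 19 generations —
#' the configuration under which the study-scale training sets (10,000
#' simulations per population, 1000-network ensembles) are generated.
#'
#' @param population preset name (see [preset_scenarios()]).
#' @param ... passed to [scenario_config()].
#' @return a [scenario_config()].
#' @export
full_scale_config <- function(population = "PEL", ...) {
  scenario_config(founding_proportions = preset_proportions(population),
                  population_size = 1000L, generations = 19L,
                  map = default_genetic_map(), ...)
}

#' Generate a simulation-based training set
#'
#' Draws `n_sims` parameter sets from the prior, simulates each scenario,
#' reduces the final population to a normalised flattened tract-length
#' profile, and returns features, scaled targets and a manifest recording
#' every seed and parameter draw. Fully reproducible from `seed`: per-sim
#' seeds are derived as `seed + sim_offset + i`, so two half-size runs with
#' the appropriate offsets concatenate into one full run.
#'
#' @param config a [scenario_config()] (its `migration_model` decides
#'   whether GFR is drawn and simulated).
#' @param prior a [prior_config()].
#' @param n_sims number of simulations.
#' @param seed master seed.
#' @param sim_offset index offset for resumable / parallel generation.
#' @param normalization,windows profile normalisation (defaults to the
#'   prioritised all-windows, divided-by-total configuration).
#' @return an object of class `training_set`: list with `features`
#'   (n_sims x 132), `targets` (n_sims x 5 or 8, scaled), `manifest`
#'   (data.frame of seeds and natural-scale parameter draws), plus the
#'   `normalization`/`windows` tags and the `config` used.
#' @export
make_training_set <- function(config, prior = prior_config(),
                              n_sims = 2000L, seed = 1L, sim_offset = 0L,
                              normalization = "divided_by_total",
                              windows = "all_windows") {
  stopifnot(inherits(config, "scenario_config"), n_sims >= 1)
  include_gfr <- config$migration_model == "two_pulses"
  n_par <- if (include_gfr) 8L else 5L
  n_feat <- if (windows == "all_windows") 132L else 126L
  features <- matrix(NA_real_, n_sims, n_feat)
  targets <- matrix(NA_real_, n_sims, n_par)
  manifest <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    sim_seed <- as.integer(seed + sim_offset + i)
    set.seed(sim_seed)
    params <- sample_mating_params(prior, include_gfr = include_gfr)
    cfg <- config
    cfg$seed <- sim_seed
    sim <- run_scenario(cfg, params)
    prof <- normalize_profile(population_profile(sim$population),
                              mode = normalization, windows = windows)
    features[i, ] <- flatten_profile(prof)
    targets[i, ] <- scale_targets(params, include_gfr = include_gfr)
    rec <- data.frame(sim = sim_offset + i, seed = sim_seed,
                      am1 = params$am[1], am2 = params$am[2],
                      am3 = params$am[3], sb1 = params$sb[1],
                      sb2 = params$sb[2], sb3 = params$sb[3])
    if (include_gfr) {
      rec$gfr1 <- params$gfr[1]; rec$gfr2 <- params$gfr[2]
      rec$gfr3 <- params$gfr[3]
    }
    manifest[[i]] <- rec
  }
  colnames(targets) <- if (include_gfr) {
    c("AM1", "AM2", "AM3", "SB1", "SB2", "GFR1", "GFR2", "GFR3")
  } else c("AM1", "AM2", "AM3", "SB1", "SB2")
  structure(list(features = features, targets = targets,
                 manifest = do.call(rbind, manifest),
                 normalization = normalization, windows = windows,
                 config = config, seed = seed),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("Training set:", nrow(x$features), "simulations x",
      ncol(x$features), "features,", ncol(x$targets), "targets (",
      x$config$migration_model, ")\n")
  invisible(x)
}

#' Write / read a training set (TSV features+targets, JSON manifest)
#'
#' @param ts a `training_set`.
#' @param dir output directory (created if missing).
#' @return `read_training_set` returns a `training_set`.
#' @export
write_training_set <- function(ts, dir) {
  stopifnot(inherits(ts, "training_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ts$features, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(ts$targets, file.path(dir, "targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(normalization = ts$normalization, windows = ts$windows,
         seed = ts$seed, migration_model = ts$config$migration_model,
         manifest = ts$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  features <- as.matrix(read.table(file.path(dir, "features.tsv"),
                                   sep = "\t", header = FALSE))
  dimnames(features) <- NULL
  targets <- as.matrix(read.table(file.path(dir, "targets.tsv"),
                                  sep = "\t", header = TRUE))
  structure(list(features = features, targets = targets,
                 manifest = man$manifest, normalization = man$normalization,
                 windows = man$windows, config = NULL, seed = man$seed),
            class = "training_set")
}

#' Emulate window-grid local-ancestry calls from a simulation
#'
#' Discretises the true tracts of every individual onto a window grid
#' (call = true ancestry at the window midpoint), then flips each window's
#' call independently with probability `miscall_rate` to a uniformly chosen
#' other ancestry — emulating the isolated-window miscalls of real
#' local-ancestry methods, which break long tracts into short fragments.
#'
#' @param sim a `sim_result` from [run_scenario()], or a [population].
#' @param window_cM grid resolution (default 0.1 cM).
#' @param miscall_rate per-window flip probability in \[0, 0.5).
#' @return an `ancestry_grid` (write it with [write_ancestry_grid()]).
#'   Uses the current RNG state; seed beforehand for reproducibility.
#' @export
emulate_local_ancestry_calls <- function(sim, window_cM = 0.1,
                                         miscall_rate = 0) {
  if (inherits(sim, "sim_result")) sim <- sim$population
  stopifnot(inherits(sim, "population"))
  if (miscall_rate < 0 || miscall_rate >= 0.5) {
    stop("`miscall_rate` must be in [0, 0.5)")
  }
  map <- sim$map
  calls <- list()
  sex <- character(0)
  for (i in seq_along(sim$individuals)) {
    ind <- sim$individuals[[i]]
    nm <- sprintf("ind%04d", i)
    sex[nm] <- ind$sex
    for (ci in seq_along(map$chrom)) {
      n_win <- floor(map$length_cm[ci] / window_cM)
      if (n_win < 1L) next
      mids <- (seq_len(n_win) - 0.5) * window_cM
      for (hap in seq_along(ind$haps[[ci]])) {
        h <- ind$haps[[ci]][[hap]]
        cv <- h$anc[findInterval(mids, h$ends) + 1L]
        cv[is.na(cv)] <- h$anc[length(h$anc)]
        if (miscall_rate > 0) {
          flip <- runif(n_win) < miscall_rate
          if (any(flip)) {
            cv[flip] <- vapply(cv[flip], function(a) {
              sample(setdiff(1:3, a), 1L)
            }, integer(1))
          }
        }
        calls[[nm]][[map$chrom[ci]]][[hap]] <- cv
      }
    }
  }
  structure(list(window_cM = window_cM, sex = sex, calls = calls),
            class = "ancestry_grid")
}
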