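#' Scenario configuration for the forward simulator
#'
#' Defaults mirror the study design: a constant population of 1000 diploids,
#' 19 non-overlapping generations starting from unadmixed founders
#' (generation 0 is the founding migration), and for the two-pulse migration
#' model a second wave of unadmixed migrants arriving when cohort 10 is
#' formed (9 generations before the present).
#'
#' @param founding_proportions length-3 ancestry proportions of the total
#'   gene flow (AFR, NAT, EUR); must sum to 1.
#' @param population_size constant diploid population size (even).
#' @param generations number of generations simulated after founding.
#' @param migration_model "one_pulse" or "two_pulses".
#' @param pulse_generation cohort index at which the second pulse arrives.
#' @param map a [genetic_map()]; defaults to the bundled uniform-rate
#'   22-autosome + X human-like map.
#' @param physical_scale physical down-scaling factor kept for provenance;
#'   genetic lengths in cM are preserved, so it does not alter tract
#'   statistics.
#' @param seed integer RNG seed used by [run_scenario()]; NULL to use the
#'   current RNG state.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(founding_proportions,
                            population_size = 1000L,
                            generations = 19L,
                            migration_model = c("one_pulse", "two_pulses"),
                            pulse_generation = 10L,
                            map = default_genetic_map(),
                            physical_scale = 1000,
                            seed = NULL) {
  migration_model <- match.arg(migration_model)
  founding_proportions <- as.numeric(founding_proportions)
  check_ancestry_vector(founding_proportions)
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  pulse_generation <- as.integer(pulse_generation)
  if (population_size < 2L || population_size %% 2L != 0L) {
    stop("`population_size` must be an even number >= 2")
  }
  if (generations < 1L) stop("`generations` must be >= 1")
  if (migration_model == "two_pulses" &&
      (pulse_generation <= 1L || pulse_generation > generations)) {
    stop("`pulse_generation` must lie in (1, generations]")
  }
  stopifnot(inherits(map, "genetic_map"))
  structure(list(founding_proportions = founding_proportions,
                 population_size = population_size,
                 generations = generations,
                 migration_model = migration_model,
                 pulse_generation = pulse_generation,
                 map = map,
                 physical_scale = physical_scale,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "scenario_config")
}

#' Bundled uniform-rate human-like genetic map (22 autosomes + X)
#' @return a [genetic_map()].
#' @export
default_genetic_map <- function() {
  genetic_map(chrom = c(paste0("chr", 1:22), "chrX"),
              length_cm = c(HUMAN_CM, HUMAN_X_CM),
              is_x = c(rep(FALSE, 22), TRUE))
}

# ---- internal genome representation -------------------------------------
# haplotype: list(ends = numeric tract end positions (cM, last == L),
#                 anc  = integer ancestries, same length)
# individual: list(sex = "F"/"M", haps = list over chromosomes of a list of
#                 1 or 2 haplotypes, prop = cached ancestry proportions)

new_haplotype <- function(ends, anc) list(ends = ends, anc = as.integer(anc))

founder_individual <- function(ancestry, sex, map) {
  haps <- lapply(seq_along(map$chrom), function(i) {
    h <- new_haplotype(map$length_cm[i], ancestry)
    if (map$is_x[i]) {
      if (sex == "F") list(h, h) else list(h)
    } else {
      list(h, h)
    }
  })
  ind <- list(sex = sex, haps = haps)
  ind$prop <- ancestry_proportions_raw(ind, map)
  ind
}

ancestry_proportions_raw <- function(ind, map) {
  hs <- unlist(ind$haps, recursive = FALSE, use.names = FALSE)
  tot <- .anc_lengths_cpp(hs)
  tot / sum(tot)
}

#' Genome-wide ancestry proportions of an individual
#'
#' Genetic-length-weighted fraction of each ancestry across all carried
#' haplotypes (autosomes plus one or two X copies depending on sex).
#'
#' @param individual an individual from a simulated [population].
#' @param map the [genetic_map()] the individual was simulated on.
#' @return numeric length-3 proportions summing to 1.
#' @export
ancestry_proportions <- function(individual, map) {
  p <- ancestry_proportions_raw(individual, map)
  names(p) <- ANCESTRY_NAMES
  p
}

# Largest-remainder apportionment of `total` into integer counts ~ weights.
largest_remainder <- function(weights, total) {
  if (sum(weights) <= 0) stop("weights must have positive sum")
  q <- weights / sum(weights) * total
  n <- floor(q)
  rem <- total - sum(n)
  if (rem > 0) {
    ord <- order(q - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  as.integer(n)
}

# Exactly N/2 of each sex in random order.
balanced_sexes <- function(n) sample(rep(c("F", "M"), n / 2))

#' Found an unadmixed population
#'
#' Creates generation 0: unadmixed individuals with single full-chromosome
#' tracts, ancestry counts apportioned to the founding proportions (for the
#' two-pulse model, to the first-wave composition proportional to
#' `(1 - GFR_s) * c_s`), and exactly half of each sex.
#'
#' @param config a [scenario_config()].
#' @param params a [mating_params()]; GFR values are consulted for the
#'   two-pulse first-wave composition.
#' @return an object of class `population`.
#' @export
found_population <- function(config, params) {
  stopifnot(inherits(config, "scenario_config"))
  c_s <- config$founding_proportions
  w <- if (config$migration_model == "two_pulses") {
    if (is.null(params$gfr)) stop("two-pulse scenarios need GFR values")
    (1 - params$gfr) * c_s
  } else c_s
  if (sum(w) <= 0) stop("founding composition has zero total weight")
  counts <- largest_remainder(w, config$population_size)
  if (any(counts == 0 & w > 0)) {
    warning("largest-remainder rounding left an ancestry with positive ",
            "target but zero founders")
  }
  sexes <- balanced_sexes(config$population_size)
  anc <- rep(1:3, counts)
  inds <- vector("list", config$population_size)
  for (i in seq_along(inds)) {
    inds[[i]] <- founder_individual(anc[i], sexes[i], config$map)
  }
  structure(list(individuals = inds, map = config$map, generation = 0L),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  p <- population_proportions(x)
  cat("Population of", length(x$individuals), "individuals (generation",
      x$generation, ")\n")
  cat("  mean ancestry:", paste(sprintf("%s=%.3f", ANCESTRY_NAMES, p),
                                collapse = " "), "\n")
  invisible(x)
}

#' Mean ancestry proportions of a population
#' @param pop a [population].
#' @return numeric length-3.
#' @export
population_proportions <- function(pop) {
  props <- t(vapply(pop$individuals, `[[`, numeric(3), "prop"))
  p <- colMeans(props)
  names(p) <- ANCESTRY_NAMES
  p
}

# Recombine two haplotypes of genetic length L: crossover count is
# Poisson(L/100) (cM -> Morgans, no interference), positions uniform in
# genetic distance, random starting homolog; returns a maximal-merged
# haplotype.
recombine_hap <- function(h1, h2, L) {
  n_x <- rpois(1L, L / 100)
  first <- runif(1) < 0.5
  if (n_x == 0L) return(if (first) h1 else h2)
  cx <- runif(n_x, 0, L)
  .recombine_cpp(h1$ends, h1$anc, h2$ends, h2$anc, cx,
                 as.integer(first))
}

#' Simulate one gamete (meiosis)
#'
#' Per autosome (and the female X): Poisson-recombined mosaic of the two
#' parental haplotypes. A male's X is returned without recombination (it is
#' transmitted intact to daughters).
#'
#' @param parent an individual.
#' @param map the [genetic_map()].
#' @return a list with one haplotype per chromosome.
#' @export
meiosis <- function(parent, map) {
  lapply(seq_along(map$chrom), function(i) {
    hp <- parent$haps[[i]]
    if (length(hp) == 1L) hp[[1L]]  # hemizygous male X
    else recombine_hap(hp[[1L]], hp[[2L]], map$length_cm[i])
  })
}

make_child <- function(mother, father, sex, map) {
  gm <- meiosis(mother, map)
  gf <- meiosis(father, map)
  haps <- vector("list", length(map$chrom))
  for (i in seq_along(map$chrom)) {
    if (map$is_x[i]) {
      haps[[i]] <- if (sex == "F") list(gm[[i]], gf[[i]]) else list(gm[[i]])
    } else {
      haps[[i]] <- list(gm[[i]], gf[[i]])
    }
  }
  ind <- list(sex = sex, haps = haps)
  ind$prop <- ancestry_proportions_raw(ind, map)
  ind
}

# Pairwise mating-density matrix (females x males) under the kernel.
density_matrix <- function(kernel, prop_f, prop_m) {
  d1 <- outer(-prop_f[, 1], prop_m[, 1], `+`)  # a_m - a_f, coordinate 1
  d2 <- outer(-prop_f[, 2], prop_m[, 2], `+`)
  dens <- dmvn2(cbind(as.vector(d1), as.vector(d2)), kernel$mu, kernel$sigma)
  matrix(dens, nrow = nrow(prop_f))
}

# Produce `n` offspring from `pop` under the kernel, with the given sexes.
produce_offspring <- function(pop, kernel, sexes) {
  inds <- pop$individuals
  is_f <- vapply(inds, `[[`, character(1), "sex") == "F"
  fem <- which(is_f); mal <- which(!is_f)
  if (length(fem) == 0L || length(mal) == 0L) {
    stop("both sexes must be present to mate")
  }
  prop_f <- t(vapply(inds[fem], `[[`, numeric(3), "prop"))
  prop_m <- t(vapply(inds[mal], `[[`, numeric(3), "prop"))
  D <- density_matrix(kernel, prop_f, prop_m)
  rs <- rowSums(D); cs <- colSums(D)
  # guard against fully flushed rows/cols (extreme AM): fall back to uniform
  rs[rs == 0] <- 1; cs[cs == 0] <- 1
  n <- length(sexes)
  children <- vector("list", n)
  init_female <- runif(n) < 0.5
  for (k in seq_len(n)) {
    if (init_female[k]) {
      f <- sample.int(length(fem), 1L)
      m <- sample.int(length(mal), 1L, prob = D[f, ] / rs[f])
    } else {
      m <- sample.int(length(mal), 1L)
      f <- sample.int(length(fem), 1L, prob = D[, m] / cs[m])
    }
    children[[k]] <- make_child(inds[[fem[f]]], inds[[mal[m]]], sexes[k],
                                pop$map)
  }
  children
}

#' Advance the population one generation
#'
#' Forms N offspring: for each, a coin decides whether a uniformly chosen
#' female or male initiates, and the initiator's mate is drawn with
#' probability proportional to the kernel density over all opposite-sex
#' candidates. Offspring sexes are an exact half/half permutation.
#'
#' @param pop a [population].
#' @param kernel a [build_kernel()] result.
#' @param config a [scenario_config()].
#' @return the next-generation [population].
#' @export
step_generation <- function(pop, kernel, config) {
  sexes <- balanced_sexes(config$population_size)
  children <- produce_offspring(pop, kernel, sexes)
  structure(list(individuals = children, map = pop$map,
                 generation = pop$generation + 1L),
            class = "population")
}

#' Form a generation that includes the second migration pulse
#'
#' The new cohort consists of `(1 - rho) * N` offspring of the resident
#' population plus `rho * N` unadmixed migrants, where
#' `rho = sum_s GFR_s * c_s` and the migrant counts per ancestry are
#' apportioned to `GFR_s * c_s`. In expectation the post-pulse composition
#' returns exactly to the founding proportions `c`.
#'
#' @param pop the resident [population] (generation `pulse_generation - 1`).
#' @param config a [scenario_config()] with `migration_model = "two_pulses"`.
#' @param params a [mating_params()] carrying GFR.
#' @param kernel a [build_kernel()] result.
#' @return the pulse-generation [population].
#' @export
apply_pulse <- function(pop, config, params, kernel) {
  if (config$migration_model != "two_pulses") {
    stop("apply_pulse requires a two-pulse scenario")
  }
  if (is.null(params$gfr)) stop("two-pulse scenarios need GFR values")
  c_s <- config$founding_proportions
  w_mig <- params$gfr * c_s
  rho <- sum(w_mig)
  n <- config$population_size
  if (rho >= 1) stop("total pulse fraction rho >= 1 leaves no offspring")
  mig_counts <- if (rho > 0) largest_remainder(w_mig, round(rho * n)) else
    integer(3)
  n_mig <- sum(mig_counts)
  sexes <- balanced_sexes(n)
  mig_sex <- sexes[seq_len(n_mig)]
  off_sex <- sexes[seq_len(n - n_mig) + n_mig]
  children <- produce_offspring(pop, kernel, off_sex)
  mig_anc <- rep(1:3, mig_counts)
  migrants <- vector("list", n_mig)
  for (i in seq_len(n_mig)) {
    migrants[[i]] <- founder_individual(mig_anc[i], mig_sex[i], pop$map)
  }
  inds <- c(children, migrants)
  inds <- inds[sample.int(length(inds))]
  structure(list(individuals = inds, map = pop$map,
                 generation = pop$generation + 1L),
            class = "population")
}

#' Run a full admixture scenario
#'
#' Founds the population, then iterates [step_generation()] for
#' `config$generations` cohorts, inserting the migration pulse via
#' [apply_pulse()] at `pulse_generation` when the two-pulse model is
#' configured. Deterministic given `config$seed`.
#'
#' @param config a [scenario_config()].
#' @param params a [mating_params()].
#' @param keep_history keep every intermediate [population] (memory-hungry;
#'   for diagnostics only).
#' @return an object of class `sim_result` with the final `population`, the
#'   per-generation mean ancestry `trajectory` (rows = generations 0..G),
#'   the `params`, `config` and `seed` used.
#' @export
run_scenario <- function(config, params, keep_history = FALSE) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(params, "mating_params"))
  if (!is.null(config$seed)) set.seed(config$seed)
  kernel <- build_kernel(params)
  pop <- found_population(config, params)
  traj <- matrix(NA_real_, config$generations + 1L, 3,
                 dimnames = list(NULL, ANCESTRY_NAMES))
  traj[1L, ] <- population_proportions(pop)
  history <- if (keep_history) list(pop)
  for (g in seq_len(config$generations)) {
    pop <- if (config$migration_model == "two_pulses" &&
               g == config$pulse_generation) {
      apply_pulse(pop, config, params, kernel)
    } else {
      step_generation(pop, kernel, config)
    }
    traj[g + 1L, ] <- population_proportions(pop)
    if (keep_history) history[[g + 1L]] <- pop
  }
  structure(list(population = pop, trajectory = traj, params = params,
                 config = config, seed = config$seed, history = history),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Admixture simulation:", x$config$generations, "generations,",
      x$config$migration_model, "model,", format(x$params), "\n")
  cat("  final mean ancestry:",
      paste(sprintf("%s=%.3f", ANCESTRY_NAMES,
                    x$trajectory[nrow(x$trajectory), ]), collapse = " "), "\n")
  invisible(x)
}
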