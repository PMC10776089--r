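# Shared fixture builders. Everything is generated in code: no stored data.

tiny_map <- function(lengths = c(100, 80), x_cm = 60) {
  toy_genetic_map(lengths, include_x = TRUE, x_cm = x_cm)
}

# very small, fast scenario for structural tests
tiny_config <- function(props = c(0.5, 0.2, 0.3), n = 20L, g = 3L,
                        seed = 1L, ...) {
  scenario_config(props, population_size = n, generations = g,
                  map = tiny_map(), seed = seed, ...)
}

# the spec'd smoke-scale configuration for the recovery experiments:
# N = 100, 2 autosomes (250, 200 cM) + X (180 cM), 19 generations
smoke_config <- function(props = preset_proportions("PEL"), seed = NULL,
                         ...) {
  scenario_config(props, population_size = 100L, generations = 19L,
                  map = toy_genetic_map(c(250, 200)), seed = seed, ...)
}

# a PSD-feasible mid-range parameter set
feasible_params <- function(am = c(0.5, 0.45, 0.45), sb = c(0.1, -0.05),
                            gfr = NULL) {
  mating_params(am = am, sb = sb, gfr = gfr)
}

# n random ancestry vectors (rows sum to 1)
rand_ancestry <- function(n) {
  x <- matrix(stats::rexp(3 * n), n)
  x / rowSums(x)
}

make_hap <- function(ends, anc) {
  list(ends = as.numeric(ends), anc = as.integer(anc))
}

# hand-built individual; `haps` is a list (per map chromosome) of lists of
# haplotypes
make_ind <- function(sex, haps) list(sex = sex, haps = haps)

# founder population with ancestry tied to sex (females get `f_anc`, males
# `m_anc`); exercises the X/autosome inheritance asymmetry
sexed_founder_pop <- function(n, f_anc, m_anc, map) {
  sexes <- rep(c("F", "M"), each = n / 2)
  inds <- lapply(seq_len(n), function(i) {
    admixmate:::founder_individual(if (sexes[i] == "F") f_anc else m_anc,
                                   sexes[i], map)
  })
  structure(list(individuals = inds, map = map, generation = 0L),
            class = "population")
}

# exact tract-tiling check for every haplotype of a population
expect_tiling <- function(pop) {
  map <- pop$map
  for (ind in pop$individuals) {
    for (ci in seq_along(map$chrom)) {
      for (h in ind$haps[[ci]]) {
        expect_equal(h$ends[length(h$ends)], map$length_cm[ci])
        expect_true(all(diff(c(0, h$ends)) > 0))
        if (length(h$anc) > 1) expect_true(all(diff(h$anc) != 0))
      }
    }
  }
}

total_tract_count <- function(pop) {
  sum(vapply(pop$individuals, function(ind) {
    sum(vapply(unlist(ind$haps, recursive = FALSE),
               function(h) length(h$anc), numeric(1)))
  }, numeric(1)))
}
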