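#' Log-spaced tract-length bin edges
#'
#' The 21 breakpoints `b_k = 2^((k+1)/2) / 10` cM (k = 1..21) define 22
#' length windows: `[0, 0.2)`, then sqrt(2)-spaced windows up to
#' `[204.8, Inf)`. The 0.2 cM floor of window 1 matches the 0.1 cM
#' resolution of typical window-grid local-ancestry calls.
#'
#' @return numeric vector of 21 strictly increasing breakpoints (cM).
#' @export
bin_edges <- function() {
  k <- 1:21
  2^((k + 1) / 2) / 10
}

N_BINS <- 22L
CHROM_CLASSES <- c("autosome", "X")

empty_profile_counts <- function(n_bins = N_BINS) {
  array(0, dim = c(n_bins, 3L, 2L),
        dimnames = list(bin = paste0("w", seq_len(n_bins)),
                        ancestry = ANCESTRY_NAMES,
                        chrom_class = CHROM_CLASSES))
}

tract_profile_obj <- function(counts, normalization = "raw",
                              windows = "all_windows", n_individuals = 1L) {
  structure(list(counts = counts, normalization = normalization,
                 windows = windows, n_individuals = n_individuals),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat("Tract-length profile (", dim(x$counts)[1], " bins x 3 ancestries x ",
      "{autosome, X}), ", x$normalization, ", ", x$windows,
      ", mean of ", x$n_individuals, " individual(s)\n", sep = "")
  cat("  autosome slab total:", signif(sum(x$counts[, , 1]), 6),
      "| X slab total:", signif(sum(x$counts[, , 2]), 6), "\n")
  invisible(x)
}

# Tally tract lengths (cM) into the 22 windows; lower-inclusive bins.
bin_lengths <- function(lengths, edges) {
  tabulate(findInterval(lengths, edges) + 1L, nbins = N_BINS)
}

#' Per-individual tract-length counts
#'
#' Counts every maximal ancestry tract once, in the window containing its cM
#' length (lower-inclusive, upper-exclusive), per ancestry, separately for
#' autosomes and the X chromosome.
#'
#' @param individual a simulated individual (see [run_scenario()]) or any
#'   list with fields `sex` and `haps` as produced by the simulator.
#' @param map the [genetic_map()] the genome lives on.
#' @param edges breakpoints from [bin_edges()].
#' @param female_x_only if TRUE (default) the X slab is left empty for
#'   males, mirroring the use of female X calls only.
#' @return a 22 x 3 x 2 integer array of raw counts.
#' @export
individual_profile <- function(individual, map, edges = bin_edges(),
                               female_x_only = TRUE) {
  counts <- empty_profile_counts()
  for (i in seq_along(map$chrom)) {
    cls <- if (map$is_x[i]) 2L else 1L
    if (cls == 2L && female_x_only && individual$sex != "F") next
    for (h in individual$haps[[i]]) {
      len <- diff(c(0, h$ends))
      for (a in 1:3) {
        sel <- h$anc == a
        if (any(sel)) {
          counts[, a, cls] <- counts[, a, cls] + bin_lengths(len[sel], edges)
        }
      }
    }
  }
  counts
}

#' Population mean tract-length profile
#'
#' Element-wise mean of the per-individual raw count matrices; the
#' permutation-invariant summary fed to the neural network. With
#' `female_x_only` the X slab is averaged over females only (autosome slab
#' over everyone).
#'
#' @param individuals list of individuals, or a [population].
#' @param map the [genetic_map()]; taken from the population if omitted.
#' @param edges breakpoints from [bin_edges()].
#' @param female_x_only average the X slab over females only (default TRUE).
#' @return a `tract_profile` with `normalization = "raw"`.
#' @export
population_profile <- function(individuals, map = NULL, edges = bin_edges(),
                               female_x_only = TRUE) {
  if (inherits(individuals, "population")) {
    map <- individuals$map
    individuals <- individuals$individuals
  }
  if (length(individuals) == 0L) stop("need at least one individual")
  if (is.null(map)) stop("`map` is required when passing a plain list")
  acc <- empty_profile_counts()
  n_x <- 0L
  for (ind in individuals) {
    acc <- acc + individual_profile(ind, map, edges, female_x_only)
    if (!female_x_only || ind$sex == "F") n_x <- n_x + 1L
  }
  counts <- acc
  counts[, , 1] <- counts[, , 1] / length(individuals)
  counts[, , 2] <- counts[, , 2] / max(n_x, 1L)
  tract_profile_obj(counts, n_individuals = length(individuals))
}

#' Normalise a raw tract-length profile
#'
#' `divided_by_total` divides the autosome slab by its total count and the X
#' slab by its total (each slab then sums to 1); `no_shortest` drops window 1
#' (< 0.2 cM) before any division. The `all_windows` + `divided_by_total`
#' combination is the default downstream configuration.
#'
#' @param profile a raw `tract_profile`.
#' @param mode "raw" or "divided_by_total".
#' @param windows "all_windows" or "no_shortest".
#' @return a normalised `tract_profile`.
#' @export
normalize_profile <- function(profile,
                              mode = c("divided_by_total", "raw"),
                              windows = c("all_windows", "no_shortest")) {
  stopifnot(inherits(profile, "tract_profile"))
  mode <- match.arg(mode)
  windows <- match.arg(windows)
  if (profile$normalization != "raw") {
    stop("`profile` must be a raw (unnormalised) profile")
  }
  counts <- profile$counts
  if (windows == "no_shortest") {
    counts <- counts[-1L, , , drop = FALSE]
  }
  if (mode == "divided_by_total") {
    for (cls in 1:2) {
      tot <- sum(counts[, , cls])
      if (tot > 0) {
        counts[, , cls] <- counts[, , cls] / tot
      } else {
        warning("zero total tract count in the ", CHROM_CLASSES[cls],
                " slab; left as zeros")
      }
    }
  }
  tract_profile_obj(counts, normalization = mode, windows = windows,
                    n_individuals = profile$n_individuals)
}

#' Bootstrap the per-individual tract histograms
#'
#' For each individual and each (ancestry, chromosome-class) histogram,
#' resamples its tracts (bin labels) with replacement `B` times and replaces
#' the observed histogram by the bootstrap mean; the population mean is then
#' taken across individuals.
#'
#' @param per_individual list of per-individual raw count arrays
#'   (from [individual_profile()]).
#' @param B number of bootstrap resamples (default 1000).
#' @param female_x_sexes optional character vector of sexes matching
#'   `per_individual`, used to average the X slab over females only.
#' @return list with `mean_profile` (a `tract_profile`) and `individual`
#'   (the list of per-individual bootstrap-mean arrays). Uses the current
#'   RNG state; seed beforehand for reproducibility.
#' @export
bootstrap_profile <- function(per_individual, B = 1000L,
                              female_x_sexes = NULL) {
  if (length(per_individual) == 0L) stop("need at least one individual")
  boot_one <- function(counts) {
    out <- counts * 0
    nb <- dim(counts)[1]
    for (a in 1:3) for (cls in 1:2) {
      h <- counts[, a, cls]
      tot <- sum(h)
      if (tot == 0) next
      # multinomial resampling of the tract labels, B replicates at once
      res <- rmultinom(B, size = tot, prob = h / tot)
      out[, a, cls] <- rowMeans(res)
    }
    out
  }
  boot_means <- lapply(per_individual, boot_one)
  acc <- Reduce(`+`, lapply(boot_means, function(m) {
    m2 <- m; m2[, , 2] <- 0; m2
  }))
  n <- length(boot_means)
  if (is.null(female_x_sexes)) female_x_sexes <- rep("F", n)
  x_idx <- which(female_x_sexes == "F")
  acc_x <- if (length(x_idx)) {
    Reduce(`+`, lapply(boot_means[x_idx], function(m) m[, , 2]))
  } else 0
  counts <- acc / n
  counts[, , 2] <- if (length(x_idx)) acc_x / length(x_idx) else 0
  list(mean_profile = tract_profile_obj(counts, n_individuals = n),
       individual = boot_means)
}

#' Flatten a profile into the network feature vector
#'
#' Row-major over (bin, ancestry, chromosome-class): all autosome-slab bins
#' for ancestry 1, then 2, then 3, followed by the X slab in the same order.
#' Length 132 for `all_windows` profiles, 126 for `no_shortest`.
#'
#' @param profile a `tract_profile`.
#' @return numeric feature vector.
#' @export
flatten_profile <- function(profile) {
  stopifnot(inherits(profile, "tract_profile"))
  v <- as.vector(profile$counts)  # column-major: bins fastest, then ancestry, class
  attr(v, "n_bins") <- dim(profile$counts)[1]
  v
}

#' Inverse of [flatten_profile()]
#'
#' @param x numeric vector of length 132 or 126.
#' @param normalization,windows tags to stamp on the rebuilt profile.
#' @param n_individuals individuals averaged.
#' @return a `tract_profile`.
#' @export
unflatten_profile <- function(x, normalization = "divided_by_total",
                              windows = NULL, n_individuals = 1L) {
  n_bins <- length(x) / 6L
  if (n_bins != floor(n_bins) || !(n_bins %in% c(21L, 22L))) {
    stop("feature vector length must be 126 or 132")
  }
  if (is.null(windows)) {
    windows <- if (n_bins == 22L) "all_windows" else "no_shortest"
  }
  counts <- array(as.numeric(x), dim = c(n_bins, 3L, 2L),
                  dimnames = list(bin = paste0("w", seq_len(n_bins)),
                                  ancestry = ANCESTRY_NAMES,
                                  chrom_class = CHROM_CLASSES))
  tract_profile_obj(counts, normalization = normalization, windows = windows,
                    n_individuals = n_individuals)
}

#' Read/write profiles as long-format TSV
#'
#' Columns: `bin`, `ancestry`, `chrom_class`, `value`, with normalization
#' tags in `#`-prefixed header comments.
#'
#' @param profile a `tract_profile`.
#' @param path file path.
#' @return `read_profile_tsv` returns a `tract_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "tract_profile"))
  dn <- dimnames(profile$counts)
  df <- expand.grid(bin = dn$bin, ancestry = dn$ancestry,
                    chrom_class = dn$chrom_class, stringsAsFactors = FALSE)
  df$value <- as.vector(profile$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalization=%s windows=%s n_individuals=%d",
                     profile$normalization, profile$windows,
                     profile$n_individuals), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[A-Za-z0-9_]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  tags <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  bins <- unique(df$bin)
  counts <- array(0, dim = c(length(bins), 3L, 2L),
                  dimnames = list(bin = bins, ancestry = ANCESTRY_NAMES,
                                  chrom_class = CHROM_CLASSES))
  for (r in seq_len(nrow(df))) {
    counts[df$bin[r], df$ancestry[r], df$chrom_class[r]] <- df$value[r]
  }
  tract_profile_obj(counts, normalization = tags[["normalization"]],
                    windows = tags[["windows"]],
                    n_individuals = as.integer(tags[["n_individuals"]]))
}
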