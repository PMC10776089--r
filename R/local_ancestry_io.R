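#' Window-grid local-ancestry calls
#'
#' The canonical interchange format for per-window local-ancestry calls is a
#' plain TSV with one row per haplotype and columns `sample`, `hap`,
#' `chrom`, `calls`, where `calls` is a space-separated string of ancestry
#' codes (1 = AFR, 2 = NAT, 3 = EUR), one per consecutive window of
#' `window_cM` (default 0.1 cM). `#`-prefixed header lines carry
#' `window_cM` and per-sample `sex` tags. An RFMix-viterbi-like "matrix"
#' dialect (rows = windows, one column per haplotype, single chromosome) is
#' supported through a configurable column map.
#'
#' @param path file path.
#' @param dialect either "generic" (default) or a list
#'   `list(format = "matrix", chrom = ..., samples = ..., window_cM = ...)`
#'   describing a matrix-layout file whose column j belongs to haplotype
#'   `((j - 1) %% 2) + 1` of sample `samples[ceiling(j / 2)]`.
#' @return an object of class `ancestry_grid`: list with `window_cM`,
#'   `sex` (named character vector) and `calls`, a nested list
#'   `calls[[sample]][[chrom]][[hap]]` of integer vectors.
#' @export
read_ancestry_grid <- function(path, dialect = "generic") {
  if (is.list(dialect) && identical(dialect$format, "matrix")) {
    return(read_grid_matrix(path, dialect))
  }
  lines <- readLines(path)
  window_cm <- 0.1
  sex <- character(0)
  hdr <- grep("^#", lines)
  for (h in hdr) {
    ln <- lines[h]
    m <- regmatches(ln, regexec("window_cM=([0-9.]+)", ln))[[1]]
    if (length(m) == 2L) window_cm <- as.numeric(m[2])
    m <- regmatches(ln, regexec("sex\\s+(\\S+)\\s+([FM])", ln))[[1]]
    if (length(m) == 3L) sex[m[2]] <- m[3]
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("empty ancestry grid file: ", path)
  header_row <- strsplit(body[1], "\t")[[1]]
  if (!identical(header_row[1:3], c("sample", "hap", "chrom"))) {
    stop("ancestry grid parse error line 1: expected columns ",
         "sample/hap/chrom/calls")
  }
  calls <- list()
  for (r in seq_along(body[-1])) {
    fields <- strsplit(body[r + 1L], "\t")[[1]]
    if (length(fields) != 4L) {
      stop("ancestry grid parse error line ", r + 1L, ": expected 4 columns")
    }
    cv <- suppressWarnings(as.integer(strsplit(fields[4], " +")[[1]]))
    if (any(is.na(cv)) || any(!cv %in% 1:3)) {
      stop("ancestry grid parse error line ", r + 1L,
           ": unknown ancestry code (allowed: 1, 2, 3)")
    }
    calls[[fields[1]]][[fields[3]]][[as.integer(fields[2])]] <- cv
  }
  structure(list(window_cM = window_cm, sex = sex, calls = calls),
            class = "ancestry_grid")
}

read_grid_matrix <- function(path, dialect) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (any(is.na(m)) || any(!m %in% 1:3)) {
    stop("ancestry grid parse error: unknown ancestry code in matrix file")
  }
  samples <- dialect$samples
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(m) / 2))
  if (ncol(m) != 2L * length(samples)) {
    stop("matrix dialect: expected 2 columns per sample")
  }
  window_cm <- if (is.null(dialect$window_cM)) 0.1 else dialect$window_cM
  chrom <- if (is.null(dialect$chrom)) "chr1" else dialect$chrom
  calls <- list()
  for (j in seq_len(ncol(m))) {
    s <- samples[ceiling(j / 2)]
    hap <- ((j - 1L) %% 2L) + 1L
    calls[[s]][[chrom]][[hap]] <- as.integer(m[, j])
  }
  structure(list(window_cM = window_cm, sex = character(0), calls = calls),
            class = "ancestry_grid")
}

#' Write an [read_ancestry_grid()] object in the generic TSV layout
#' @param grid an `ancestry_grid`.
#' @param path output path.
#' @export
write_ancestry_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ancestry_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_cM=%g", grid$window_cM), con)
  for (s in names(grid$sex)) {
    writeLines(sprintf("# sex %s %s", s, grid$sex[s]), con)
  }
  writeLines("sample\thap\tchrom\tcalls", con)
  for (s in names(grid$calls)) {
    for (cc in names(grid$calls[[s]])) {
      for (hap in seq_along(grid$calls[[s]][[cc]])) {
        cv <- grid$calls[[s]][[cc]][[hap]]
        if (is.null(cv)) next
        writeLines(paste(s, hap, cc, paste(cv, collapse = " "),
                         sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Collapse window-grid calls into maximal ancestry segments
#'
#' Maximal runs of identical calls become one segment of length
#' (run length x window size), reproducing the concatenation of contiguous
#' same-ancestry windows into continuous ancestry tracts.
#'
#' @param grid an `ancestry_grid`.
#' @return a data.frame of segment records: `sample`, `hap`, `chrom`,
#'   `start_cM`, `end_cM`, `ancestry`.
#' @export
grid_to_tracts <- function(grid) {
  stopifnot(inherits(grid, "ancestry_grid"))
  out <- list()
  for (s in names(grid$calls)) {
    for (cc in names(grid$calls[[s]])) {
      for (hap in seq_along(grid$calls[[s]][[cc]])) {
        cv <- grid$calls[[s]][[cc]][[hap]]
        if (is.null(cv)) next
        r <- rle(cv)
        ends <- cumsum(r$lengths) * grid$window_cM
        starts <- c(0, head(ends, -1))
        out[[length(out) + 1L]] <- data.frame(
          sample = s, hap = hap, chrom = cc, start_cM = starts,
          end_cM = ends, ancestry = r$values, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(empty_segments())
  }
  do.call(rbind, out)
}

empty_segments <- function() {
  data.frame(sample = character(0), hap = integer(0), chrom = character(0),
             start_cM = numeric(0), end_cM = numeric(0),
             ancestry = integer(0), stringsAsFactors = FALSE)
}

validate_segments <- function(segs) {
  req <- c("sample", "hap", "chrom", "start_cM", "end_cM", "ancestry")
  if (!all(req %in% names(segs))) {
    stop("segment table must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(segs) == 0L) return(invisible(segs))
  if (any(segs$start_cM >= segs$end_cM)) {
    stop("segment validation error: start_cM must be < end_cM")
  }
  if (any(!segs$ancestry %in% 1:3)) {
    stop("segment validation error: unknown ancestry code")
  }
  key <- interaction(segs$sample, segs$hap, segs$chrom, drop = TRUE)
  for (k in levels(key)) {
    sub <- segs[key == k, ]
    sub <- sub[order(sub$start_cM), ]
    if (any(abs(sub$start_cM[-1] - sub$end_cM[-nrow(sub)]) > 1e-9)) {
      stop("segment validation error: overlap or gap within haplotype ", k)
    }
  }
  invisible(segs)
}

#' Read/write ancestry segments as a BED-like TSV
#'
#' Columns: `sample`, `hap`, `chrom`, `start_cM`, `end_cM`, `ancestry`
#' (half-open cM intervals). On both read and write the per-haplotype
#' records are checked to tile their chromosome without overlaps or gaps
#' and sorted by sample, hap, chrom, start.
#'
#' @param path file path.
#' @param segs a segment data.frame (see [grid_to_tracts()]).
#' @return `read_segments_bed` returns the validated, sorted data.frame.
#' @export
read_segments_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(empty_segments())
  segs <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  segs <- segs[order(segs$sample, segs$hap, segs$chrom, segs$start_cM), ]
  rownames(segs) <- NULL
  validate_segments(segs)
  segs
}

#' @rdname read_segments_bed
#' @export
write_segments_bed <- function(segs, path) {
  validate_segments(segs)
  segs <- segs[order(segs$sample, segs$hap, segs$chrom, segs$start_cM), ]
  write.table(segs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a simulated population to a segment table
#'
#' @param pop a [population].
#' @param prefix sample-name prefix.
#' @return a segment data.frame plus a `sex` attribute (named vector).
#' @export
population_to_segments <- function(pop, prefix = "ind") {
  stopifnot(inherits(pop, "population"))
  map <- pop$map
  out <- list()
  sex <- character(0)
  for (i in seq_along(pop$individuals)) {
    ind <- pop$individuals[[i]]
    nm <- sprintf("%s%04d", prefix, i)
    sex[nm] <- ind$sex
    for (ci in seq_along(map$chrom)) {
      for (hap in seq_along(ind$haps[[ci]])) {
        h <- ind$haps[[ci]][[hap]]
        out[[length(out) + 1L]] <- data.frame(
          sample = nm, hap = hap, chrom = map$chrom[ci],
          start_cM = c(0, head(h$ends, -1)), end_cM = h$ends,
          ancestry = h$anc, stringsAsFactors = FALSE)
      }
    }
  }
  segs <- do.call(rbind, out)
  attr(segs, "sex") <- sex
  segs
}

#' Rebuild profile-ready individuals from a segment table
#'
#' @param segs a validated segment data.frame.
#' @param map the [genetic_map()] naming the chromosomes (drives the
#'   autosome/X split).
#' @param sex named character vector of sample sexes; samples missing from
#'   it default to "F" (so their X, if present, enters the profile).
#' @return a named list of individuals usable with [individual_profile()]
#'   and [population_profile()].
#' @export
segments_to_individuals <- function(segs, map, sex = NULL) {
  validate_segments(segs)
  if (is.null(sex)) sex <- attr(segs, "sex")
  inds <- list()
  for (s in unique(segs$sample)) {
    sub <- segs[segs$sample == s, ]
    haps <- vector("list", length(map$chrom))
    for (ci in seq_along(map$chrom)) {
      subc <- sub[sub$chrom == map$chrom[ci], ]
      if (nrow(subc) == 0L) { haps[[ci]] <- list(); next }
      haps[[ci]] <- lapply(sort(unique(subc$hap)), function(hh) {
        hs <- subc[subc$hap == hh, ]
        hs <- hs[order(hs$start_cM), ]
        new_haplotype(hs$end_cM, hs$ancestry)
      })
    }
    sx <- if (!is.null(sex) && !is.na(sex[s])) unname(sex[s]) else "F"
    inds[[s]] <- list(sex = sx, haps = haps)
  }
  inds
}
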