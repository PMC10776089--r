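#' Genetic maps
#'
#' A genetic map is a list of chromosomes, each with an identifier, a total
#' genetic length in cM, an `is_x` flag and (optionally) a monotone
#' physical-to-genetic interpolation table. The simulator only consumes
#' genetic lengths: tract coordinates are kept in cM throughout, so the
#' customary 1/1000 physical down-scaling used to speed up sequence-level
#' simulators leaves all tract-length statistics untouched here.
#'
#' @param chrom character chromosome identifiers.
#' @param length_cm numeric total genetic lengths (cM), one per chromosome.
#' @param is_x logical flags, one per chromosome.
#' @param tables optional named list of data.frames with columns `pos_bp`
#'   and `map_cm` (non-decreasing) giving the physical-to-genetic map.
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(chrom, length_cm, is_x = rep(FALSE, length(chrom)),
                        tables = NULL) {
  chrom <- as.character(chrom)
  length_cm <- as.numeric(length_cm)
  stopifnot(length(chrom) == length(length_cm),
            length(chrom) == length(is_x))
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("chromosome genetic lengths must be positive")
  }
  if (anyDuplicated(chrom)) stop("duplicate chromosome identifiers")
  if (sum(is_x) > 1L) stop("at most one X chromosome is supported")
  if (!is.null(tables)) {
    for (nm in names(tables)) {
      tb <- tables[[nm]]
      if (is.unsorted(tb$map_cm) || is.unsorted(tb$pos_bp)) {
        stop("map table for ", nm, " must be non-decreasing")
      }
    }
  }
  structure(list(chrom = chrom, length_cm = length_cm, is_x = as.logical(is_x),
                 tables = tables),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(x$chrom), "chromosomes,",
      round(sum(x$length_cm[!x$is_x]), 1), "cM autosomal",
      if (any(x$is_x)) paste0("+ ", round(x$length_cm[x$is_x], 1), " cM X"),
      "\n")
  invisible(x)
}

#' Read a HapMap-style recombination map
#'
#' Expects whitespace/tab-separated files with four columns per chromosome:
#' chromosome, physical position (bp), rate (cM/Mb) and cumulative map
#' position (cM). Several chromosomes may share one file.
#'
#' @param path file path (uncompressed text).
#' @param x_chrom identifier to flag as the X chromosome (e.g. "chrX");
#'   NULL for none.
#' @param header does the file carry a header line?
#' @return a [genetic_map()].
#' @export
read_hapmap_map <- function(path, x_chrom = "chrX", header = TRUE) {
  df <- read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("HapMap map needs >= 4 columns")
  names(df)[1:4] <- c("chrom", "pos_bp", "rate_cm_mb", "map_cm")
  chroms <- unique(df$chrom)
  tables <- lapply(chroms, function(cc) {
    sub <- df[df$chrom == cc, c("pos_bp", "map_cm")]
    sub <- sub[order(sub$pos_bp), ]
    if (is.unsorted(sub$map_cm)) {
      stop("map positions for ", cc, " are not monotone")
    }
    sub
  })
  names(tables) <- chroms
  genetic_map(chrom = as.character(chroms),
              length_cm = vapply(tables, function(tb) max(tb$map_cm) - min(tb$map_cm),
                                 numeric(1)),
              is_x = as.character(chroms) %in% x_chrom,
              tables = tables)
}

#' Write a genetic map in the HapMap four-column layout
#'
#' Maps built without interpolation tables are written as uniform-rate
#' two-point tables spanning `length_cm` over one Mb per cM.
#'
#' @param map a [genetic_map()].
#' @param path output file path.
#' @export
write_hapmap_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(seq_along(map$chrom), function(i) {
    tb <- map$tables[[map$chrom[i]]]
    if (is.null(tb)) {
      tb <- data.frame(pos_bp = c(0, map$length_cm[i] * 1e6),
                       map_cm = c(0, map$length_cm[i]))
    }
    rate <- c(diff(tb$map_cm) / pmax(diff(tb$pos_bp) / 1e6, 1e-12), 0)
    data.frame(chrom = map$chrom[i], pos_bp = tb$pos_bp,
               rate_cm_mb = rate, map_cm = tb$map_cm)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Approximate human per-chromosome genetic lengths (cM): 22 autosomes summing
# to ~3,400 cM plus a ~180 cM X, used by the bundled default map.
HUMAN_CM <- c(276, 258, 214, 206, 196, 184, 180, 161, 159, 174,
              152, 168, 121, 114, 135, 129, 123, 112, 103, 104,
              60, 71)
HUMAN_X_CM <- 180
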