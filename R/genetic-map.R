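#' Genetic maps
#'
#' A genetic map is an ordered set of (physical position, cM) knots per
#' chromosome.  Queries between knots are linearly interpolated; queries
#' beyond the ends use constant extrapolation.  The HMM only consumes cM
#' *differences* between adjacent sites, so the map's intercept is
#' irrelevant downstream.
#'
#' @param knots a tibble/data frame with columns `chrom`, `pos`, `cm`
#'   (`cm` non-decreasing within chromosome).
#' @return an object of class `genetic_map`.
#' @export
genetic_map <- function(knots) {
  knots <- tibble::as_tibble(knots)
  stopifnot(all(c("chrom", "pos", "cm") %in% names(knots)))
  knots <- dplyr::arrange(knots, .data$chrom, .data$pos)
  ok <- vapply(split(knots$cm, knots$chrom),
               function(x) all(diff(x) >= -1e-12), logical(1))
  if (!all(ok)) stop("cm must be non-decreasing within each chromosome")
  structure(list(knots = knots), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", nrow(x$knots), " knots on ",
      length(unique(x$knots$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Build a constant-rate genetic map over a set of positions
#'
#' `cm(pos) = rate_cm_per_mb * pos / 1e6`, an exact linear map — the
#' synthetic stand-in for an empirical recombination map.
#'
#' @param positions sorted physical positions (bp).
#' @param rate_cm_per_mb recombination rate in cM per Mb (0 = complete
#'   linkage).
#' @param chrom chromosome label.
#' @return a `genetic_map`.
#' @examples
#' m <- make_genetic_map(c(1e6, 2e6), rate_cm_per_mb = 1.3)
#' map_cm(m, 2e6) # 2.6
#' @export
make_genetic_map <- function(positions, rate_cm_per_mb = 1.2, chrom = "chrS") {
  if (is.unsorted(positions, strictly = FALSE)) {
    stop("positions must be sorted ascending")
  }
  genetic_map(tibble::tibble(chrom = chrom, pos = as.numeric(positions),
                             cm = rate_cm_per_mb * positions / 1e6))
}

#' Query a genetic map
#'
#' @param map a `genetic_map`.
#' @param pos physical positions to query.
#' @param chrom chromosome label(s); defaults to the map's single
#'   chromosome.
#' @return numeric cM positions (linear interpolation between knots,
#'   constant beyond the ends).
#' @export
map_cm <- function(map, pos, chrom = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  kn <- map$knots
  if (is.null(chrom)) {
    if (length(unique(kn$chrom)) > 1) {
      stop("map has several chromosomes; supply `chrom`")
    }
    chrom <- rep(kn$chrom[1], length(pos))
  } else if (length(chrom) == 1) {
    chrom <- rep(chrom, length(pos))
  }
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    k <- kn[kn$chrom == ch, ]
    if (nrow(k) == 0) stop("map has no knots for chromosome ", ch)
    if (nrow(k) == 1) {
      out[sel] <- k$cm
    } else {
      out[sel] <- approx(k$pos, k$cm, xout = pos[sel], rule = 2, ties = "ordered")$y
    }
  }
  out
}

#' Read a genetic map from disk
#'
#' Supports the HapMap-style four-column text format
#' (`chromosome  position  rate(cM/Mb)  map(cM)`, whitespace separated,
#' with or without a header) and the internal two/three-column knot format
#' (`pos  cm` or `chrom  pos  cm`).
#'
#' @param path file path.
#' @param format `"hapmap"` or `"knots"`.
#' @param chrom chromosome label used when the file has no chrom column.
#' @return a `genetic_map`.
#' @export
read_genetic_map <- function(path, format = c("hapmap", "knots"),
                             chrom = "chrS") {
  format <- match.arg(format)
  first <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  # header detection: a non-numeric second token means a header row
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))
  tab <- readr::read_table(path, col_names = FALSE, show_col_types = FALSE,
                           skip = if (has_header) 1L else 0L)
  if (format == "hapmap") {
    if (ncol(tab) < 4) stop("hapmap map format needs 4 columns")
    genetic_map(tibble::tibble(chrom = as.character(tab[[1]]),
                               pos = as.numeric(tab[[2]]),
                               cm = as.numeric(tab[[4]])))
  } else {
    if (ncol(tab) >= 3) {
      genetic_map(tibble::tibble(chrom = as.character(tab[[1]]),
                                 pos = as.numeric(tab[[2]]),
                                 cm = as.numeric(tab[[3]])))
    } else {
      genetic_map(tibble::tibble(chrom = chrom,
                                 pos = as.numeric(tab[[1]]),
                                 cm = as.numeric(tab[[2]])))
    }
  }
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a
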