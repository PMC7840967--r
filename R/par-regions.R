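#' Pseudoautosomal regions of the X chromosome
#'
#' Coordinates of PAR1 and PAR2 on GRCh37, 1-based inclusive. Variants in
#' these regions are excluded from all X-specific analyses because they
#' recombine with the Y and are diploid in males.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and `name`.
#' @export
#' @examples
#' par_regions()
par_regions <- function() {
  tibble::tibble(
    chrom = c("X", "X"),
    start = c(60001L, 154931044L),
    end   = c(2699520L, 155260560L),
    name  = c("PAR1", "PAR2")
  )
}

#' Test positions for pseudoautosomal membership
#'
#' @param chrom Character vector of chromosome names ("X", "chrX" and
#'   "x" are all recognised as the X chromosome).
#' @param pos Integer vector of 1-based positions.
#' @param par PAR table as returned by [par_regions()] or [read_par_bed()].
#' @return Logical vector, `TRUE` where the position falls inside a PAR.
#' @export
in_par <- function(chrom, pos, par = par_regions()) {
  stopifnot(length(chrom) == length(pos))
  is_x <- sub("^chr", "", tolower(chrom)) == "x"
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par))) {
    hit <- hit | (is_x & pos >= par$start[i] & pos <= par$end[i])
  }
  hit
}

#' Read a PAR mask from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' @param path Path to a BED file (chrom, start, end, optional name).
#' @return A tibble with 1-based inclusive `start`/`end`.
#' @export
read_par_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, show_col_types = FALSE, comment = "#"
  )
  if (ncol(bed) < 3) abort("BED file must have at least 3 columns")
  out <- tibble::tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end   = as.integer(bed[[3]]),
    name  = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_
  )
  out
}
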