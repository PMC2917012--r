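#' Define a genome assembly
#'
#' A minimal genome model: chromosome names, lengths, and a centromere
#' interval per chromosome. Coordinates are 1-based inclusive throughout the
#' package. The p-arm is \code{[1, cen_start - 1]} and the q-arm
#' \code{[cen_end + 1, length]}.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @param cen_start,cen_end Centromere interval per chromosome, 1-based
#'   inclusive, strictly inside the chromosome so that both arms are
#'   non-empty.
#' @return A \code{data.frame} of class \code{genome_assembly} with columns
#'   \code{chrom}, \code{length}, \code{cen_start}, \code{cen_end}.
#' @examples
#' genome_assembly("chr1", 1e6, 4e5, 4.2e5)
#' @export
genome_assembly <- function(chrom, length, cen_start, cen_end) {
  chrom <- as.character(chrom)
  stopifnot(!anyDuplicated(chrom))
  length <- as.numeric(length)
  cen_start <- as.numeric(cen_start)
  cen_end <- as.numeric(cen_end)
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (any(cen_start > cen_end)) stop("centromere start must be <= end")
  if (any(cen_start <= 1) || any(cen_end >= length)) {
    stop("centromere interval must lie strictly inside the chromosome ",
         "(both arms non-empty)")
  }
  out <- data.frame(chrom = chrom, length = length,
                    cen_start = cen_start, cen_end = cen_end,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_assembly", "data.frame")
  out
}

#' Default synthetic assembly
#'
#' Four autosome-like chromosomes of 150/110/80/50 Mb with 1-Mb centromeres
#' placed at 40\% of each length: small enough for minutes-scale simulation,
#' large enough for 250-kb smoothing windows and firestorm arm geometry.
#'
#' @return A \code{genome_assembly}.
#' @export
default_assembly <- function() {
  len <- c(150e6, 110e6, 80e6, 50e6)
  cs <- round(0.4 * len)
  genome_assembly(paste0("chr", 1:4), len, cs, cs + 1e6 - 1)
}

#' Chromosome-arm membership of genomic positions
#'
#' @param chrom Chromosome name(s).
#' @param position Position(s), 1-based; recycled against \code{chrom}.
#' @param assembly A \code{genome_assembly}.
#' @return Character vector: \code{"p"}, \code{"q"}, or \code{"cen"} for
#'   positions inside the centromere interval.
#' @examples
#' arm_of("chr1", 1, default_assembly())
#' @export
arm_of <- function(chrom, position, assembly) {
  n <- max(length(chrom), length(position))
  chrom <- rep_len(as.character(chrom), n)
  position <- rep_len(as.numeric(position), n)
  i <- match(chrom, assembly$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]])
  if (any(position < 1 | position > assembly$length[i])) {
    stop("position out of chromosome bounds")
  }
  ifelse(position < assembly$cen_start[i], "p",
         ifelse(position > assembly$cen_end[i], "q", "cen"))
}

#' Arm boundaries and lengths
#'
#' @param assembly A \code{genome_assembly}.
#' @return Data frame with one row per arm: \code{chrom}, \code{arm},
#'   \code{start}, \code{end}, \code{arm_length}.
#' @export
arm_table <- function(assembly) {
  p <- data.frame(chrom = assembly$chrom, arm = "p", start = 1,
                  end = assembly$cen_start - 1, stringsAsFactors = FALSE)
  q <- data.frame(chrom = assembly$chrom, arm = "q",
                  start = assembly$cen_end + 1, end = assembly$length,
                  stringsAsFactors = FALSE)
  out <- rbind(p, q)
  out$arm_length <- out$end - out$start + 1
  out <- out[order(match(out$chrom, assembly$chrom), out$arm), ]
  rownames(out) <- NULL
  out
}
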