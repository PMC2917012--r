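#' Construct a probe set
#'
#' Probes are the atomic measurement units (BAC-clone-like array elements).
#' The set is sorted by chromosome (assembly order when given, else first
#' appearance) then start; ids must be unique; \code{center} is
#' \code{floor((start + end) / 2)}.
#'
#' @param id Unique probe identifiers.
#' @param chrom Chromosome per probe.
#' @param start,end 1-based inclusive probe intervals, \code{start <= end}.
#' @param assembly Optional \code{genome_assembly}; when supplied, probes are
#'   checked against chromosome bounds and ordered by assembly chromosome
#'   order.
#' @return A \code{data.frame} of class \code{probe_set} with columns
#'   \code{probe}, \code{chrom}, \code{start}, \code{end}, \code{center}.
#' @export
probe_set <- function(id, chrom, start, end, assembly = NULL) {
  id <- as.character(id)
  chrom <- rep_len(as.character(chrom), length(id))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (anyDuplicated(id)) {
    stop("duplicate probe id: ", id[duplicated(id)][1])
  }
  if (any(start > end)) stop("probe start > end")
  if (any(start < 1)) stop("probe start < 1")
  if (!is.null(assembly)) {
    ci <- match(chrom, assembly$chrom)
    if (anyNA(ci)) stop("probe on unknown chromosome: ", chrom[is.na(ci)][1])
    if (any(end > assembly$length[ci])) stop("probe beyond chromosome end")
    ord <- order(ci, start)
  } else {
    ord <- order(match(chrom, unique(chrom)), start)
  }
  out <- data.frame(probe = id, chrom = chrom, start = start, end = end,
                    center = floor((start + end) / 2),
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  class(out) <- c("probe_set", "data.frame")
  out
}

#' Tile an assembly with a regular probe grid
#'
#' One probe per \code{spacing}-bp window, contiguous from position 1; a
#' trailing partial window is dropped. Emulates an evenly spaced BAC array.
#'
#' @param assembly A \code{genome_assembly}.
#' @param spacing Probe width/spacing in bp (default 100 kb).
#' @return A \code{probe_set}.
#' @export
make_probe_grid <- function(assembly, spacing = 1e5) {
  stopifnot(spacing > 0)
  pieces <- lapply(seq_len(nrow(assembly)), function(i) {
    n <- floor(assembly$length[i] / spacing)
    s <- (seq_len(n) - 1) * spacing + 1
    data.frame(chrom = assembly$chrom[i], start = s, end = s + spacing - 1,
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  probe_set(sprintf("%s_p%05d", g$chrom,
                    unlist(lapply(pieces, function(x) seq_len(nrow(x))))),
            g$chrom, g$start, g$end, assembly = assembly)
}

# Row indices of probes on one chromosome (probes are sorted, so contiguous).
probe_rows_chrom <- function(probes, chrom) {
  which(probes$chrom == chrom)
}

# Row indices of probes overlapping a 1-based inclusive interval.
probe_rows_overlap <- function(probes, chrom, start, end) {
  which(probes$chrom == chrom & probes$start <= end & probes$end >= start)
}
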