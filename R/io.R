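#' @importFrom utils read.delim write.table packageVersion
NULL

io_header_comment <- function(seed = NA) {
  sprintf("# cnascan %s seed=%s",
          as.character(utils::packageVersion("cnascan")),
          ifelse(is.na(seed), "NA", format(seed)))
}

#' Write a probe-level log2-ratio table
#'
#' Tab-delimited: a comment line recording tool version and seed, then a
#' header \code{probe chrom start end} followed by one column per sample.
#' Values are written with full double precision so that a write/read
#' round trip is exact.
#'
#' @param probes A \code{probe_set}.
#' @param cn Numeric matrix, probes x samples, with column names.
#' @param path Output file.
#' @param seed Optional seed to record in the header comment.
#' @export
write_ratio_table <- function(probes, cn, path, seed = NA) {
  stopifnot(nrow(cn) == nrow(probes), !is.null(colnames(cn)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header_comment(seed), con)
  writeLines(paste(c("probe", "chrom", "start", "end", colnames(cn)),
                   collapse = "\t"), con)
  vals <- apply(cn, 1, function(r) {
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t")
  })
  writeLines(paste(probes$probe, probes$chrom,
                   format(probes$start, scientific = FALSE, trim = TRUE),
                   format(probes$end, scientific = FALSE, trim = TRUE),
                   vals, sep = "\t"), con)
  invisible(path)
}

#' Read a probe-level log2-ratio table
#'
#' @param path Tab-delimited file with header
#'   \code{probe chrom start end <sample...>}; lines starting with \code{#}
#'   are ignored.
#' @param assembly Optional assembly used to validate probe coordinates and
#'   fix the chromosome order.
#' @return A list with \code{probes} (a \code{probe_set}, sorted) and
#'   \code{cn} (numeric matrix, probes x samples, aligned to the probes).
#' @export
read_ratio_table <- function(path, assembly = NULL) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("probe", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("ratio table must have header columns: ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$probe)) {
    stop("duplicate probe id: ", df$probe[duplicated(df$probe)][1])
  }
  num <- function(x, what) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(y) & !(is.na(x) | x %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s', data row %d",
                   x[bad[1]], what, bad[1]))
    }
    y
  }
  samples <- setdiff(names(df), need)
  if (!length(samples)) stop("no sample columns found")
  probes <- probe_set(df$probe, df$chrom, num(df$start, "start"),
                      num(df$end, "end"), assembly = assembly)
  cn <- vapply(samples, function(s) num(df[[s]], s), numeric(nrow(df)))
  cn <- matrix(cn, nrow = nrow(df),
               dimnames = list(df$probe, samples))
  cn <- cn[match(probes$probe, df$probe), , drop = FALSE]
  rownames(cn) <- probes$probe
  list(probes = probes, cn = cn)
}

#' Write segments in IGV SEG format
#'
#' Dialect: a \code{#} comment line with tool version and seed, then the
#' header \code{ID chrom loc.start loc.end num.mark seg.mean}; coordinates
#' are 1-based inclusive; segment means carry 6 decimals.
#'
#' @param seg Segment table with columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{n_probes}, \code{seg_mean}.
#' @param path Output file.
#' @param seed Optional seed recorded in the comment line.
#' @export
write_seg <- function(seg, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header_comment(seed), con)
  writeLines("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean", con)
  if (nrow(seg)) {
    writeLines(paste(seg$sample, seg$chrom,
                     format(seg$start, scientific = FALSE, trim = TRUE),
                     format(seg$end, scientific = FALSE, trim = TRUE),
                     seg$n_probes, sprintf("%.6f", seg$seg_mean),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read an IGV SEG file
#'
#' Accepts the IGV header (\code{ID/chrom/loc.start/loc.end/num.mark/
#' seg.mean}) or this package's canonical names. Segments overlapping within
#' one sample are rejected.
#'
#' @param path SEG file; \code{#} comment lines are skipped.
#' @return Segment table (\code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{n_probes}, \code{seg_mean}), sorted by sample,
#'   chromosome, start.
#' @export
read_seg <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  canon <- c(ID = "sample", sample = "sample", Sample = "sample",
             chrom = "chrom", chromosome = "chrom", Chromosome = "chrom",
             "loc.start" = "start", start = "start", Start = "start",
             "loc.end" = "end", end = "end", End = "end",
             "num.mark" = "n_probes", num_probes = "n_probes",
             n_probes = "n_probes",
             "seg.mean" = "seg_mean", seg_mean = "seg_mean")
  hit <- canon[names(df)]
  if (anyNA(hit) || !setequal(hit, unique(unname(canon)))) {
    stop("SEG file must carry columns ID, chrom, loc.start, loc.end, ",
         "num.mark, seg.mean")
  }
  names(df) <- hit
  df <- df[, c("sample", "chrom", "start", "end", "n_probes", "seg_mean")]
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  df <- df[order(df$sample, match(df$chrom, unique(df$chrom)), df$start), ]
  rownames(df) <- NULL
  by <- split(seq_len(nrow(df)), paste(df$sample, df$chrom))
  for (idx in by) {
    if (length(idx) < 2) next
    s <- df$start[idx]; e <- df$end[idx]
    bad <- which(s[-1] <= e[-length(e)])
    if (length(bad)) {
      stop(sprintf(
        "overlapping segments in sample %s: %s:%d-%d and %s:%d-%d",
        df$sample[idx[1]], df$chrom[idx[1]], s[bad[1]], e[bad[1]],
        df$chrom[idx[1]], s[bad[1] + 1], e[bad[1] + 1]))
    }
  }
  df
}

#' Remap segmented profiles to a common fixed-width probe grid
#'
#' Builds one pseudo-probe per \code{bin_size} window and assigns each bin
#' the mean of the segment(s) covering the bin center; bins whose center no
#' segment covers are missing. Used to combine cohorts measured on
#' different platforms on a common (default 100-kb) grid.
#'
#' @param seg Segment table (see \code{\link{read_seg}}).
#' @param assembly A \code{genome_assembly} fixing bin layout.
#' @param bin_size Bin width in bp, > 0 (default 100 kb).
#' @return A list with \code{probes} (the pseudo-probe grid) and \code{cn}
#'   (bins x samples matrix of segment means).
#' @export
map_to_common_grid <- function(seg, assembly, bin_size = 1e5) {
  stopifnot(bin_size > 0)
  grid <- make_probe_grid(assembly, bin_size)
  samples <- unique(seg$sample)
  if (!length(samples)) {
    warning("empty segmentation: all bins missing")
    return(list(probes = grid,
                cn = matrix(NA_real_, nrow(grid), 0,
                            dimnames = list(grid$probe, NULL))))
  }
  cn <- matrix(NA_real_, nrow(grid), length(samples),
               dimnames = list(grid$probe, samples))
  for (s in samples) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    if (!nrow(ss)) {
      warning("sample ", s, " has no segments: all bins missing")
      next
    }
    for (chr in unique(grid$chrom)) {
      gi <- probe_rows_chrom(grid, chr)
      sc <- ss[ss$chrom == chr, , drop = FALSE]
      if (!nrow(sc)) next
      sc <- sc[order(sc$start), ]
      pos <- findInterval(grid$center[gi], sc$start)
      ok <- pos >= 1 & ifelse(pos >= 1, grid$center[gi] <= sc$end[pmax(pos, 1)],
                              FALSE)
      cn[gi[ok], s] <- sc$seg_mean[pos[ok]]
    }
  }
  list(probes = grid, cn = cn)
}

#' Export regions as BED
#'
#' 3+1 column BED (half-open, 0-based starts as the format requires) with a
#' comment line recording tool version and seed.
#'
#' @param regions Data frame with \code{chrom}, \code{start}, \code{end} and
#'   optionally \code{name}.
#' @param path Output file.
#' @param seed Optional seed for the header comment.
#' @export
write_bed <- function(regions, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header_comment(seed), con)
  if (nrow(regions)) {
    nm <- if ("name" %in% names(regions)) regions$name else
      sprintf("region_%d", seq_len(nrow(regions)))
    writeLines(paste(regions$chrom,
                     format(regions$start - 1, scientific = FALSE, trim = TRUE),
                     format(regions$end, scientific = FALSE, trim = TRUE),
                     nm, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a generic annotated matrix (expression, states) as TSV
#'
#' @param anno Data frame of row annotations (e.g. gene coordinates).
#' @param mat Matrix aligned to \code{anno} rows, with column names.
#' @param path Output file.
#' @param seed Optional seed for the header comment.
#' @export
write_matrix_tsv <- function(anno, mat, path, seed = NA) {
  stopifnot(nrow(anno) == nrow(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header_comment(seed), con)
  df <- cbind(anno, as.data.frame(mat, check.names = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sample metadata table
#' @param metadata Data frame of per-sample covariates.
#' @param path Output file.
#' @param seed Optional seed for the header comment.
#' @export
write_metadata_tsv <- function(metadata, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header_comment(seed), con)
  write.table(metadata, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
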