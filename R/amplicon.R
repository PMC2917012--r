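#' Shortest region of amplification overlap (SRO)
#'
#' For every carrier (sample whose anchor-overlapping probes all reach
#' \code{min_state}), take the maximal run of consecutive probes at or above
#' \code{min_state} containing the anchor; the SRO is the genomic
#' intersection of these runs, i.e. \code{[max of run starts, min of run
#' ends]} using probe start/end coordinates. The SRO therefore contains the
#' anchor and is contained in every carrier's run.
#'
#' @param states State matrix from \code{\link{call_states}}.
#' @param probes Aligned \code{probe_set}.
#' @param anchor List or vector with \code{chrom}, \code{start}, \code{end}.
#' @param min_state State name defining involvement (default
#'   \code{"amplification"}).
#' @return List: \code{chrom}, \code{start}, \code{end}, \code{carriers}
#'   (sample names), \code{runs} (per-carrier run intervals); \code{NULL}
#'   with a warning when no sample carries the anchor.
#' @export
sro <- function(states, probes, anchor, min_state = "amplification") {
  mc <- state_code(min_state)
  chrom <- as.character(anchor[["chrom"]])
  a_start <- as.numeric(anchor[["start"]])
  a_end <- as.numeric(anchor[["end"]])
  rows <- probe_rows_chrom(probes, chrom)
  anc <- rows[probes$start[rows] <= a_end & probes$end[rows] >= a_start]
  if (!length(anc)) stop("anchor interval overlaps no probe")
  runs <- list()
  for (s in seq_len(ncol(states))) {
    v <- states[rows, s]
    loc <- match(anc, rows)
    if (any(is.na(v[loc])) || any(v[loc] < mc)) next
    lo <- min(loc); hi <- max(loc)
    while (lo > 1 && !is.na(v[lo - 1]) && v[lo - 1] >= mc) lo <- lo - 1
    while (hi < length(v) && !is.na(v[hi + 1]) && v[hi + 1] >= mc)
      hi <- hi + 1
    runs[[colnames(states)[s]]] <- c(start = probes$start[rows[lo]],
                                     end = probes$end[rows[hi]])
  }
  if (!length(runs)) {
    warning("no carriers for anchor ", chrom, ":", a_start, "-", a_end)
    return(NULL)
  }
  rs <- vapply(runs, `[`, numeric(1), "start")
  re <- vapply(runs, `[`, numeric(1), "end")
  list(chrom = chrom, start = max(rs), end = min(re),
       carriers = names(runs),
       runs = data.frame(sample = names(runs), start = unname(rs),
                         end = unname(re), stringsAsFactors = FALSE))
}

#' Interval length in kbp
#'
#' \code{(end - start + 1) / 1000}, rounded half-up to \code{decimals}
#' places (1-based inclusive coordinates).
#'
#' @param start Interval start, or a list/region with \code{start} and
#'   \code{end}.
#' @param end Interval end (ignored when \code{start} is a region).
#' @param decimals Decimal places (default 2).
#' @return Length in kbp.
#' @examples
#' interval_length_kbp(35074472, 35160391)  # 85.92
#' @export
interval_length_kbp <- function(start, end = NULL, decimals = 2) {
  if (is.list(start)) {
    end <- start[["end"]]
    start <- start[["start"]]
  }
  x <- (end - start + 1) / 1000
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

#' Recurrent high-level amplification peaks
#'
#' Computes the per-probe carrier frequency of \code{state} (ordinal: a
#' probe counts when its state is at or above \code{state}), identifies
#' maximal plateaus that are local frequency maxima on each chromosome, and
#' for every plateau with frequency above \code{min_freq} reports the peak
#' as the SRO of its carriers anchored at the plateau. Peaks on one
#' chromosome separated by a frequency valley are distinct; plateau ties
#' break by leftmost genomic position.
#'
#' @param states State matrix.
#' @param probes Aligned \code{probe_set}.
#' @param min_freq Minimum carrier frequency, exclusive (default 0.02: more
#'   than 2\% of tumors).
#' @param state State name defining a carrier (default
#'   \code{"high_amplification"}).
#' @return Data frame with one row per peak: \code{chrom}, \code{start},
#'   \code{end}, \code{n_carriers}, \code{frequency}, plus a list column
#'   \code{members} of carrier sample names.
#' @export
recurrent_peaks <- function(states, probes, min_freq = 0.02,
                            state = "high_amplification") {
  mc <- state_code(state)
  n <- ncol(states)
  hit <- !is.na(states) & states >= mc
  freq <- rowMeans(hit)
  peaks <- list()
  for (chr in unique(probes$chrom)) {
    rows <- probe_rows_chrom(probes, chr)
    f <- freq[rows]
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] <= min_freq) next
      left <- if (k == 1) -Inf else r$values[k - 1]
      right <- if (k == length(r$values)) -Inf else r$values[k + 1]
      if (r$values[k] <= left || r$values[k] <= right) next
      plat <- rows[starts[k]:ends[k]]
      anchor <- list(chrom = chr, start = probes$start[plat[1]],
                     end = probes$end[plat[length(plat)]])
      reg <- sro(states, probes, anchor, min_state = state)
      if (is.null(reg)) next
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = chr, start = reg$start, end = reg$end,
        n_carriers = length(reg$carriers),
        frequency = length(reg$carriers) / n,
        stringsAsFactors = FALSE)
      peaks[[length(peaks)]]$members <- list(reg$carriers)
    }
  }
  if (!length(peaks)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_carriers = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Co-amplification fraction between two peaks
#'
#' \code{mode = "min"}: shared carriers divided by the smaller of the two
#' carrier counts (symmetric). \code{mode = "row"}: shared carriers divided
#' by the first peak's carrier count (asymmetric, one matrix row per peak).
#'
#' @param members_a,members_b Carrier sample vectors of the two peaks.
#' @param mode \code{"min"} or \code{"row"}.
#' @return Fraction in [0, 1].
#' @export
coamp_fraction <- function(members_a, members_b, mode = c("min", "row")) {
  mode <- match.arg(mode)
  na <- length(unique(members_a)); nb <- length(unique(members_b))
  if (na == 0 || nb == 0) stop("co-amplification undefined: a peak has ",
                               "zero carriers")
  n_co <- length(intersect(members_a, members_b))
  if (mode == "min") n_co / min(na, nb) else n_co / na
}

#' Mutual exclusivity / co-occurrence test for two peaks
#'
#' Two-sided Fisher's exact test on the 2x2 carrier-membership table over
#' the cohort, with the sample odds ratio (Haldane 0.5 correction when any
#' cell is zero, flagged).
#'
#' @param members_a,members_b Carrier sample vectors.
#' @param samples All cohort sample names.
#' @return List: \code{table}, \code{odds_ratio}, \code{haldane} (logical),
#'   \code{p_value}.
#' @export
mutual_exclusivity_test <- function(members_a, members_b, samples) {
  ina <- samples %in% members_a
  inb <- samples %in% members_b
  tab <- matrix(c(sum(ina & inb), sum(ina & !inb),
                  sum(!ina & inb), sum(!ina & !inb)), 2, 2,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margins: p = 1")
    return(list(table = tab, odds_ratio = NA_real_, haldane = FALSE,
                p_value = 1))
  }
  hald <- any(tab == 0)
  tc <- if (hald) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, haldane = hald, p_value = p)
}

#' HER2/TOP2A amplicon classification
#'
#' For samples whose HER2-locus segmented mean reaches the amplification
#' threshold: co-amplified when the TOP2A-locus mean also reaches it;
#' TOP2A-deleted when that mean is at or below the sample's adaptive loss
#' threshold; TOP2A-neutral otherwise. Samples without HER2 amplification
#' get status NA (not in the HER2-amplified cohort).
#'
#' @param seg Segment table.
#' @param probes Aligned \code{probe_set}.
#' @param her2_locus,top2a_locus Lists with \code{chrom}, \code{start},
#'   \code{end}.
#' @param thresholds Data frame from \code{\link{adaptive_thresholds}}
#'   (supplies the per-sample loss threshold).
#' @param amp_threshold Amplification threshold (default 0.5).
#' @return Data frame: \code{sample}, \code{her2_mean}, \code{top2a_mean},
#'   \code{status}.
#' @export
her2_top2a_status <- function(seg, probes, her2_locus, top2a_locus,
                              thresholds, amp_threshold = 0.5) {
  X <- seg_means_matrix(seg, probes, samples = thresholds$sample)
  hrows <- probe_rows_overlap(probes, her2_locus$chrom, her2_locus$start,
                              her2_locus$end)
  trows <- probe_rows_overlap(probes, top2a_locus$chrom, top2a_locus$start,
                              top2a_locus$end)
  if (!length(hrows) || !length(trows)) stop("locus overlaps no probe")
  hm <- colMeans(X[hrows, , drop = FALSE], na.rm = TRUE)
  tm <- colMeans(X[trows, , drop = FALSE], na.rm = TRUE)
  hm[is.nan(hm)] <- NA_real_; tm[is.nan(tm)] <- NA_real_
  status <- rep(NA_character_, length(hm))
  amp <- !is.na(hm) & hm >= amp_threshold
  status[amp & !is.na(tm) & tm >= amp_threshold] <- "coamplified"
  del <- amp & !is.na(tm) & tm < amp_threshold &
    tm <= thresholds$loss_thr
  status[del] <- "top2a_deleted"
  status[amp & is.na(status) & !is.na(tm)] <- "top2a_neutral"
  data.frame(sample = thresholds$sample, her2_mean = unname(hm),
             top2a_mean = unname(tm), status = status,
             stringsAsFactors = FALSE)
}

#' Detect firestorm amplification patterns
#'
#' Per sample and chromosome arm: peaks are maximal runs of consecutive
#' high-level-amplification probes spanning at least \code{min_peak_probes}
#' probes (strictly more than three under the default); an arm is called a
#' firestorm when it carries at least \code{min_peaks} such peaks, every
#' adjacent peak pair is separated by at least one probe below the
#' amplification state, and the maximum center-to-center distance between
#' adjacent peaks (or over all pairs with \code{distance = "pairwise"}) is
#' below \code{max_gap_frac} of the arm length.
#'
#' @param states State matrix.
#' @param probes Aligned \code{probe_set}.
#' @param assembly The \code{genome_assembly}.
#' @param min_peaks Minimum qualifying peaks per arm (default 3).
#' @param min_peak_probes Minimum probes per peak (default 4 = "larger than
#'   three probes").
#' @param max_gap_frac Maximum inter-peak distance as a fraction of arm
#'   length, exclusive (default 0.5).
#' @param distance \code{"adjacent"} (default) or \code{"pairwise"}.
#' @return Data frame with one row per firestorm call: \code{sample},
#'   \code{chrom}, \code{arm}, \code{n_peaks}, \code{max_gap},
#'   \code{arm_length}, plus a list column \code{peaks} of per-peak
#'   intervals.
#' @export
detect_firestorms <- function(states, probes, assembly, min_peaks = 3,
                              min_peak_probes = 4, max_gap_frac = 0.5,
                              distance = c("adjacent", "pairwise")) {
  distance <- match.arg(distance)
  high <- state_code("high_amplification")
  amp <- state_code("amplification")
  arms <- arm_table(assembly)
  calls <- list()
  for (s in seq_len(ncol(states))) {
    for (a in seq_len(nrow(arms))) {
      rows <- which(probes$chrom == arms$chrom[a] &
                      probes$center >= arms$start[a] &
                      probes$center <= arms$end[a])
      if (length(rows) < min_peaks * min_peak_probes) next
      v <- states[rows, s]
      ishigh <- !is.na(v) & v == high
      r <- rle(ishigh)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      qual <- which(r$values & r$lengths >= min_peak_probes)
      if (length(qual) < min_peaks) next
      # separation: >= 1 probe strictly below amplification between
      # adjacent qualifying peaks
      sep_ok <- TRUE
      for (k in seq_len(length(qual) - 1)) {
        between <- (ends[qual[k]] + 1):(starts[qual[k + 1]] - 1)
        vv <- v[between]
        if (!any(!is.na(vv) & vv < amp)) { sep_ok <- FALSE; break }
      }
      if (!sep_ok) next
      pk_start <- probes$start[rows[starts[qual]]]
      pk_end <- probes$end[rows[ends[qual]]]
      centers <- floor((pk_start + pk_end) / 2)
      max_gap <- if (distance == "adjacent") max(diff(centers)) else
        max(centers) - min(centers)
      if (max_gap >= max_gap_frac * arms$arm_length[a]) next
      row <- data.frame(sample = colnames(states)[s], chrom = arms$chrom[a],
                        arm = arms$arm[a], n_peaks = length(qual),
                        max_gap = max_gap, arm_length = arms$arm_length[a],
                        stringsAsFactors = FALSE)
      row$peaks <- list(data.frame(start = pk_start, end = pk_end))
      calls[[length(calls) + 1]] <- row
    }
  }
  if (!length(calls)) {
    out <- data.frame(sample = character(), chrom = character(),
                      arm = character(), n_peaks = integer(),
                      max_gap = numeric(), arm_length = numeric(),
                      stringsAsFactors = FALSE)
    out$peaks <- list()
    return(out)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
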