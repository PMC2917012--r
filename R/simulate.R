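#' @importFrom stats rnorm runif rexp rbinom median mad sd cor quantile
NULL

new_event <- function(type, fields) {
  ev <- c(list(type = type), fields)
  if (!is.null(ev$frequency) &&
      (ev$frequency <= 0 || ev$frequency > 1)) {
    stop("event frequency must be in (0, 1]")
  }
  class(ev) <- "cna_event"
  ev
}

#' Planted event constructors
#'
#' Events compose additively in log2 space on carrier samples; carriers are
#' drawn independently per event with the event's frequency.
#'
#' \describe{
#'   \item{\code{event_broad}}{whole-arm (or whole-chromosome) gain/loss;
#'     \code{amplitude} > 0 for gains, < 0 for losses.}
#'   \item{\code{event_focal_amp}}{focal amplicon with a fixed driver
#'     interval; per carrier the realized interval extends the driver left
#'     and right by independent Exponential(\code{ext_mean}) distances, so a
#'     carrier set shares the driver as its shortest region of overlap.}
#'   \item{\code{event_firestorm}}{several disjoint high-level peaks on one
#'     arm, separated by baseline gaps, emulating a firestorm pattern.}
#'   \item{\code{event_cep17}}{a pericentromeric gain spanning the probes
#'     nearest the centromere on both arms.}
#'   \item{\code{event_her2_amplicon}}{two adjacent driver loci ("HER2" and,
#'     700 kb telomeric, "TOP2A"); the \code{variant} realizes
#'     co-amplification, TOP2A deletion (negative \code{del_amplitude} on the
#'     TOP2A locus), or a TOP2A-neutral amplicon.}
#' }
#'
#' @param chrom Target chromosome.
#' @param arm \code{"p"}, \code{"q"} or \code{"both"}.
#' @param amplitude Log2-ratio shift added on carriers (sign checked per
#'   event class).
#' @param frequency Carrier frequency in (0, 1].
#' @param driver_start,driver_end Driver interval (bp, 1-based inclusive).
#' @param ext_mean Mean of the exponential boundary extension (bp); 0 means
#'   no extension.
#' @param n_peaks,peak_width_probes,gap_probes Firestorm layout in probes.
#' @param her2_start,her2_end HER2 driver locus.
#' @param top2a_offset Gap between HER2 end and TOP2A start (default 700 kb).
#' @param top2a_width TOP2A locus width (default 100 kb).
#' @param variant One of \code{"coamplified"}, \code{"top2a_deleted"},
#'   \code{"top2a_neutral"}.
#' @param del_amplitude Negative amplitude applied to the TOP2A locus for the
#'   deleted variant.
#' @name events
NULL

#' @rdname events
#' @export
event_broad <- function(chrom, arm = "both", amplitude, frequency) {
  stopifnot(amplitude != 0)
  new_event(if (amplitude > 0) "broad_gain" else "broad_loss",
            list(chrom = chrom, arm = arm, amplitude = amplitude,
                 frequency = frequency))
}

#' @rdname events
#' @export
event_focal_amp <- function(chrom, driver_start, driver_end, amplitude = 1.5,
                            frequency, ext_mean = 0) {
  stopifnot(amplitude > 0, driver_start <= driver_end, ext_mean >= 0)
  new_event("focal_amp",
            list(chrom = chrom, driver_start = driver_start,
                 driver_end = driver_end, amplitude = amplitude,
                 frequency = frequency, ext_mean = ext_mean))
}

#' @rdname events
#' @export
event_firestorm <- function(chrom, arm = "q", n_peaks = 3, amplitude = 1.5,
                            peak_width_probes = 5, gap_probes = 10,
                            frequency) {
  stopifnot(amplitude > 0, n_peaks >= 1, peak_width_probes >= 1,
            gap_probes >= 1)
  new_event("firestorm",
            list(chrom = chrom, arm = arm, n_peaks = n_peaks,
                 amplitude = amplitude,
                 peak_width_probes = peak_width_probes,
                 gap_probes = gap_probes, frequency = frequency))
}

#' @rdname events
#' @export
event_cep17 <- function(chrom, amplitude = 1.0, frequency) {
  stopifnot(amplitude > 0)
  new_event("cep17_amp",
            list(chrom = chrom, amplitude = amplitude, frequency = frequency))
}

#' @rdname events
#' @export
event_her2_amplicon <- function(chrom, her2_start, her2_end,
                                variant = c("coamplified", "top2a_deleted",
                                            "top2a_neutral"),
                                amplitude = 1.5, top2a_offset = 7e5,
                                top2a_width = 1e5, del_amplitude = -0.8,
                                frequency, ext_mean = 0) {
  variant <- match.arg(variant)
  stopifnot(amplitude > 0, del_amplitude < 0, her2_start <= her2_end)
  new_event("her2_amplicon",
            list(chrom = chrom, her2_start = her2_start, her2_end = her2_end,
                 variant = variant, amplitude = amplitude,
                 top2a_offset = top2a_offset, top2a_width = top2a_width,
                 del_amplitude = del_amplitude, frequency = frequency,
                 ext_mean = ext_mean))
}

#' Expression block configuration
#'
#' @param n_genes Number of genes to place uniformly over the genome.
#' @param frac_responsive Fraction of genes given a linear gene-dosage
#'   component (default 0.3).
#' @param beta Dosage slope in log2-expression per log2-copy-number unit for
#'   responsive genes (default 0.8).
#' @param noise_sd Expression noise SD (log2 units, default 0.5).
#' @param baseline_sd SD of per-gene baseline means around 0 (default 0).
#' @param gene_width Gene footprint in bp (default 10 kb).
#' @return A list of class \code{expr_config}.
#' @export
expr_config <- function(n_genes = 1000, frac_responsive = 0.3, beta = 0.8,
                        noise_sd = 0.5, baseline_sd = 0, gene_width = 1e4) {
  stopifnot(n_genes >= 1, frac_responsive >= 0, frac_responsive <= 1,
            noise_sd >= 0, baseline_sd >= 0)
  structure(list(n_genes = n_genes, frac_responsive = frac_responsive,
                 beta = beta, noise_sd = noise_sd, baseline_sd = baseline_sd,
                 gene_width = gene_width), class = "expr_config")
}

#' Cohort simulation configuration
#'
#' The defaults define the package's reference simulation conditions: a
#' 4-chromosome 390-Mb genome tiled at 100-kb spacing (~3,900 probes),
#' Gaussian probe noise of SD 0.15 log2 units around piecewise-constant
#' event sums, and an expression block with a 30\% dosage-responsive gene
#' fraction at slope 0.8 and noise SD 0.5.
#'
#' @param n_samples Number of tumors to simulate (>= 1).
#' @param assembly A \code{genome_assembly}.
#' @param probe_spacing Probe width/spacing in bp.
#' @param noise_sd Per-probe Gaussian noise SD (log2 units, >= 0).
#' @param events List of event specs (see \code{\link{events}}).
#' @param expression An \code{\link{expr_config}}, or \code{NULL} to skip
#'   the expression block.
#' @param covariate_link Optional association of one event with a metadata
#'   covariate: \code{list(event = <index>, covariate = "ER",
#'   prob_carrier = , prob_other = )} giving the probability of the
#'   covariate's first level for carriers vs non-carriers.
#' @param seed Integer seed; recorded in every output.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples, assembly = default_assembly(),
                       probe_spacing = 1e5, noise_sd = 0.15, events = list(),
                       expression = expr_config(), covariate_link = NULL,
                       seed = 1) {
  stopifnot(n_samples >= 1, noise_sd >= 0, probe_spacing > 0)
  for (ev in events) {
    if (!inherits(ev, "cna_event")) stop("events must be cna_event objects")
    if (!ev$chrom %in% assembly$chrom) {
      stop("event targets unknown chromosome ", ev$chrom)
    }
  }
  structure(list(n_samples = n_samples, assembly = assembly,
                 probe_spacing = probe_spacing, noise_sd = noise_sd,
                 events = events, expression = expression,
                 covariate_link = covariate_link, seed = as.integer(seed)),
            class = "sim_config")
}

#' Realize a focal amplicon on one profile
#'
#' Adds \code{amplitude} to the probes whose centers fall in the realized
#' interval: the driver extended left and right by independent
#' Exponential(\code{ext_mean}) draws, truncated at the chromosome ends. The
#' realized interval always contains the driver.
#'
#' @param values Numeric probe vector for the whole genome (one sample).
#' @param probes The \code{probe_set} aligned to \code{values}.
#' @param chrom,driver_start,driver_end Driver interval.
#' @param amplitude Log2 shift added (> 0).
#' @param ext_mean Mean boundary extension in bp (0 = none).
#' @param chrom_length Chromosome length for truncation.
#' @return List with \code{values} (updated vector) and \code{interval}
#'   (realized \code{c(start, end)}).
#' @export
plant_focal_amp <- function(values, probes, chrom, driver_start, driver_end,
                            amplitude, ext_mean = 0, chrom_length = Inf) {
  lext <- if (ext_mean > 0) rexp(1, 1 / ext_mean) else 0
  rext <- if (ext_mean > 0) rexp(1, 1 / ext_mean) else 0
  s <- max(1, floor(driver_start - lext))
  e <- min(chrom_length, ceiling(driver_end + rext))
  idx <- which(probes$chrom == chrom & probes$center >= s & probes$center <= e)
  values[idx] <- values[idx] + amplitude
  list(values = values, interval = c(start = s, end = e))
}

#' Realize a firestorm layout on one profile
#'
#' Places \code{n_peaks} disjoint runs of \code{peak_width_probes} probes at
#' \code{amplitude}, separated by \code{gap_probes} baseline probes, starting
#' at the first probe of the arm. Errors when the arm cannot hold the
#' requested layout.
#'
#' @inheritParams plant_focal_amp
#' @param arm \code{"p"} or \code{"q"}.
#' @param assembly The \code{genome_assembly}.
#' @param n_peaks,peak_width_probes,gap_probes Layout in probes.
#' @return List with \code{values} and \code{peaks} (data frame of realized
#'   peak intervals with probe index ranges).
#' @export
plant_firestorm <- function(values, probes, chrom, arm, assembly, n_peaks,
                            amplitude, peak_width_probes, gap_probes) {
  arms <- arm_table(assembly)
  a <- arms[arms$chrom == chrom & arms$arm == arm, ]
  idx <- which(probes$chrom == chrom & probes$center >= a$start &
                 probes$center <= a$end)
  need <- n_peaks * peak_width_probes + (n_peaks - 1) * gap_probes
  if (length(idx) < need) {
    stop(sprintf(
      "firestorm layout infeasible on %s%s: need %d probes, arm has %d",
      chrom, arm, need, length(idx)))
  }
  peaks <- vector("list", n_peaks)
  at <- 1
  for (k in seq_len(n_peaks)) {
    run <- idx[at:(at + peak_width_probes - 1)]
    values[run] <- values[run] + amplitude
    peaks[[k]] <- data.frame(peak = k, chrom = chrom, arm = arm,
                             start = probes$start[run[1]],
                             end = probes$end[run[length(run)]],
                             probe_first = run[1],
                             probe_last = run[length(run)],
                             stringsAsFactors = FALSE)
    at <- at + peak_width_probes + gap_probes
  }
  list(values = values, peaks = do.call(rbind, peaks))
}

# Genomic interval a non-focal event occupies.
event_span <- function(ev, assembly, probes) {
  ai <- match(ev$chrom, assembly$chrom)
  len <- assembly$length[ai]
  switch(ev$type,
    broad_gain = ,
    broad_loss = {
      arms <- arm_table(assembly)
      if (identical(ev$arm, "both")) c(1, len) else {
        a <- arms[arms$chrom == ev$chrom & arms$arm == ev$arm, ]
        c(a$start, a$end)
      }
    },
    cep17_amp = {
      cs <- assembly$cen_start[ai]; ce <- assembly$cen_end[ai]
      p_near <- probes$center[probes$chrom == ev$chrom & probes$center < cs]
      q_near <- probes$center[probes$chrom == ev$chrom & probes$center > ce]
      p_sel <- sort(utils::tail(sort(p_near), 3))
      q_sel <- utils::head(sort(q_near), 3)
      c(min(p_sel), max(q_sel))
    },
    stop("no span for event type ", ev$type))
}

#' Simulate a synthetic tumor cohort
#'
#' Generates probe-level log2 ratios (sum of the planted events carried by
#' each sample plus Gaussian probe noise), a matched expression matrix with
#' a linear dosage component for responsive genes, categorical metadata, and
#' a truth ledger recording every realized event. Fully deterministic given
#' \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{cna_cohort}: \code{probes}, \code{cn}
#'   (probes x samples log2-ratio matrix), \code{expression} (list with
#'   \code{genes} and \code{expr}, or \code{NULL}), \code{metadata},
#'   \code{truth}, \code{assembly}, \code{seed}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  assembly <- config$assembly
  probes <- make_probe_grid(assembly, config$probe_spacing)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  cn <- matrix(0, nrow(probes), n, dimnames = list(probes$probe, samples))
  truth_events <- list()
  truth_peaks <- list()
  carriers_by_event <- list()
  for (e in seq_along(config$events)) {
    ev <- config$events[[e]]
    carriers <- which(runif(n) < ev$frequency)
    carriers_by_event[[e]] <- samples[carriers]
    len <- assembly$length[match(ev$chrom, assembly$chrom)]
    for (s in carriers) {
      if (ev$type == "focal_amp") {
        r <- plant_focal_amp(cn[, s], probes, ev$chrom, ev$driver_start,
                             ev$driver_end, ev$amplitude, ev$ext_mean, len)
        cn[, s] <- r$values
        truth_events[[length(truth_events) + 1]] <- data.frame(
          event = e, type = ev$type, sample = samples[s], chrom = ev$chrom,
          start = r$interval[1], end = r$interval[2],
          amplitude = ev$amplitude, stringsAsFactors = FALSE)
      } else if (ev$type == "firestorm") {
        r <- plant_firestorm(cn[, s], probes, ev$chrom, ev$arm, assembly,
                             ev$n_peaks, ev$amplitude, ev$peak_width_probes,
                             ev$gap_probes)
        cn[, s] <- r$values
        pk <- r$peaks
        pk$event <- e
        pk$sample <- samples[s]
        truth_peaks[[length(truth_peaks) + 1]] <- pk
        truth_events[[length(truth_events) + 1]] <- data.frame(
          event = e, type = ev$type, sample = samples[s], chrom = ev$chrom,
          start = min(pk$start), end = max(pk$end),
          amplitude = ev$amplitude, stringsAsFactors = FALSE)
      } else if (ev$type == "her2_amplicon") {
        t_start <- ev$her2_end + ev$top2a_offset + 1
        t_end <- t_start + ev$top2a_width - 1
        span <- switch(ev$variant,
          coamplified = c(ev$her2_start, t_end),
          c(ev$her2_start, ev$her2_end))
        r <- plant_focal_amp(cn[, s], probes, ev$chrom, span[1], span[2],
                             ev$amplitude, ev$ext_mean, len)
        cn[, s] <- r$values
        if (ev$variant == "top2a_deleted") {
          rd <- plant_focal_amp(cn[, s], probes, ev$chrom, t_start, t_end,
                                ev$del_amplitude, 0, len)
          cn[, s] <- rd$values
        }
        truth_events[[length(truth_events) + 1]] <- data.frame(
          event = e, type = paste0("her2_", ev$variant),
          sample = samples[s], chrom = ev$chrom,
          start = r$interval[1], end = r$interval[2],
          amplitude = ev$amplitude, stringsAsFactors = FALSE)
      } else {
        span <- event_span(ev, assembly, probes)
        idx <- which(probes$chrom == ev$chrom & probes$center >= span[1] &
                       probes$center <= span[2])
        cn[idx, s] <- cn[idx, s] + ev$amplitude
        truth_events[[length(truth_events) + 1]] <- data.frame(
          event = e, type = ev$type, sample = samples[s], chrom = ev$chrom,
          start = span[1], end = span[2], amplitude = ev$amplitude,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (config$noise_sd > 0) {
    cn <- cn + matrix(rnorm(length(cn), 0, config$noise_sd), nrow(cn))
  }
  metadata <- simulate_metadata(samples, config, carriers_by_event)
  expression <- NULL
  genes_truth <- NULL
  if (!is.null(config$expression)) {
    expression <- simulate_expression(cn, probes, config$expression,
                                      assembly)
    genes_truth <- expression$genes
  }
  truth <- list(
    events = if (length(truth_events)) do.call(rbind, truth_events) else
      data.frame(event = integer(), type = character(), sample = character(),
                 chrom = character(), start = numeric(), end = numeric(),
                 amplitude = numeric()),
    firestorm_peaks = if (length(truth_peaks)) do.call(rbind, truth_peaks)
      else NULL,
    carriers = carriers_by_event,
    genes = genes_truth,
    seed = config$seed)
  structure(list(probes = probes, cn = cn, expression = expression,
                 metadata = metadata, truth = truth, assembly = assembly,
                 seed = config$seed),
            class = "cna_cohort")
}

simulate_metadata <- function(samples, config, carriers_by_event) {
  n <- length(samples)
  md <- data.frame(
    sample = samples,
    ER = ifelse(runif(n) < 0.5, "pos", "neg"),
    LN = ifelse(runif(n) < 0.5, "pos", "neg"),
    grade = sample(c("1", "2", "3"), n, replace = TRUE,
                   prob = c(0.15, 0.35, 0.5)),
    ploidy = ifelse(runif(n) < 0.7, "aneuploid", "diploid"),
    size = ifelse(runif(n) < 0.5, "le20mm", "gt20mm"),
    age = ifelse(runif(n) < 0.6, "ge50", "lt50"),
    stringsAsFactors = FALSE)
  link <- config$covariate_link
  if (!is.null(link)) {
    carrier <- md$sample %in% carriers_by_event[[link$event]]
    lv <- levels_for_covariate(link$covariate)
    p <- ifelse(carrier, link$prob_carrier, link$prob_other)
    md[[link$covariate]] <- ifelse(runif(n) < p, lv[1], lv[2])
  }
  md
}

levels_for_covariate <- function(cov) {
  switch(cov,
         ER = c("pos", "neg"), LN = c("pos", "neg"),
         ploidy = c("aneuploid", "diploid"),
         size = c("gt20mm", "le20mm"), age = c("ge50", "lt50"),
         grade = c("3", "2"),
         stop("unknown covariate ", cov))
}

#' Simulate an expression block with a gene-dosage component
#'
#' Places genes uniformly over the genome; each dosage-responsive gene g gets
#' \code{expr[g, s] = mu_g + beta * cn[probe(g), s] + eps}, where
#' \code{probe(g)} is the probe containing the gene midpoint (nearest probe
#' center on the same chromosome when the midpoint falls outside every
#' probe); non-responsive genes get \code{mu_g + eps} only.
#'
#' @param cn Probe-level log2-ratio matrix (probes x samples).
#' @param probes The aligned \code{probe_set}.
#' @param cfg An \code{\link{expr_config}}.
#' @param assembly The \code{genome_assembly} genes are placed on.
#' @return List with \code{genes} (coordinates, responsiveness flag, slope,
#'   matched probe row) and \code{expr} (genes x samples matrix).
#' @export
simulate_expression <- function(cn, probes, cfg, assembly) {
  n_s <- ncol(cn)
  w <- assembly$length / sum(assembly$length)
  g_chr <- sample(assembly$chrom, cfg$n_genes, replace = TRUE, prob = w)
  g_len <- assembly$length[match(g_chr, assembly$chrom)]
  mid <- floor(runif(cfg$n_genes, cfg$gene_width, g_len - cfg$gene_width))
  genes <- data.frame(
    gene = sprintf("G%05d", seq_len(cfg$n_genes)),
    chrom = g_chr,
    start = pmax(1, mid - floor(cfg$gene_width / 2)),
    end = pmin(g_len, mid + floor(cfg$gene_width / 2)),
    stringsAsFactors = FALSE)
  genes$mid <- floor((genes$start + genes$end) / 2)
  genes$responsive <- runif(cfg$n_genes) < cfg$frac_responsive
  genes$beta <- ifelse(genes$responsive, cfg$beta, 0)
  genes$mu <- if (cfg$baseline_sd > 0)
    rnorm(cfg$n_genes, 0, cfg$baseline_sd) else rep(0, cfg$n_genes)
  genes$probe_row <- match_gene_probes(genes, probes)
  expr <- matrix(rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd), cfg$n_genes, n_s,
                 dimnames = list(genes$gene, colnames(cn)))
  expr <- expr + genes$mu
  resp <- which(genes$beta != 0 & !is.na(genes$probe_row))
  if (length(resp)) {
    expr[resp, ] <- expr[resp, ] +
      genes$beta[resp] * cn[genes$probe_row[resp], , drop = FALSE]
  }
  list(genes = genes, expr = expr)
}

# Nearest-probe matching: the probe containing the gene midpoint, else the
# probe with the nearest center on the same chromosome; NA when the
# chromosome carries no probes.
match_gene_probes <- function(genes, probes) {
  out <- rep(NA_integer_, nrow(genes))
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    pi <- probe_rows_chrom(probes, chr)
    if (!length(pi)) next
    centers <- probes$center[pi]
    pos <- findInterval(genes$mid[gi], centers)
    lo <- pmax(pos, 1)
    hi <- pmin(pos + 1, length(centers))
    d_lo <- abs(genes$mid[gi] - centers[lo])
    d_hi <- abs(genes$mid[gi] - centers[hi])
    out[gi] <- pi[ifelse(d_lo <= d_hi, lo, hi)]
  }
  out
}

#' Write the truth ledger as JSON
#'
#' @param truth The \code{truth} component of a \code{cna_cohort}.
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
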