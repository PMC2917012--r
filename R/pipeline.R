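#' Pipeline configuration
#'
#' Exactly one of \code{ratio_path} (probe-level ratio table on disk) or
#' \code{simulation} (a \code{\link{sim_config}}) must be given.
#'
#' @param ratio_path Path to a probe-level log2-ratio table.
#' @param simulation A \code{\link{sim_config}}.
#' @param assembly Assembly for file input (defaults to
#'   \code{\link{default_assembly}}).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed controlling every stochastic stage.
#' @param segmentation A \code{\link{seg_config}}.
#' @param calling A \code{\link{calling_config}} (its \code{mode} selects
#'   the her2 vs reference high-amplification rule).
#' @param gistic A \code{\link{gistic_config}}.
#' @param dosage List of dosage-scan options (\code{n_perm},
#'   \code{sd_min}, \code{alpha}).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(ratio_path = NULL, simulation = NULL,
                            assembly = default_assembly(), out_dir, seed = 1,
                            segmentation = seg_config(),
                            calling = calling_config(),
                            gistic = gistic_config(),
                            dosage = list(n_perm = 1000, sd_min = 0.5,
                                          alpha = 0.05)) {
  if (is.null(ratio_path) == is.null(simulation)) {
    stop("specify exactly one of ratio_path or simulation")
  }
  structure(list(ratio_path = ratio_path, simulation = simulation,
                 assembly = assembly, out_dir = out_dir,
                 seed = as.integer(seed), segmentation = segmentation,
                 calling = calling, gistic = gistic, dosage = dosage),
            class = "pipeline_config")
}

#' Run the full copy-number analysis pipeline
#'
#' Stages: input (simulate or read), CBS segmentation, minimum-probe
#' filtering, 250-kb smoothing and sample-adaptive thresholds, state
#' calling, FGA, GISTIC-style gain/loss scans, recurrent high-level
#' amplification peaks, co-amplification matrix, firestorm detection, and
#' (when expression data exist) the genome-wide dosage scan. Every output
#' file records the tool version and seed; a JSON manifest makes the run
#' reproducible. Any stage failure aborts with the stage name and the
#' artifacts already written.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisible list of class \code{cna_report} holding every stage
#'   result and the manifest.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  done <- character(0)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s\ncompleted artifacts: %s",
                   name, conditionMessage(e),
                   paste(done, collapse = ", ")), call. = FALSE)
    })
  }
  set.seed(config$seed)
  out <- function(f) file.path(config$out_dir, f)

  inp <- stage("input", function() {
    if (!is.null(config$simulation)) {
      cohort <- simulate_cohort(config$simulation)
      list(probes = cohort$probes, cn = cohort$cn, cohort = cohort,
           assembly = cohort$assembly)
    } else {
      r <- read_ratio_table(config$ratio_path, config$assembly)
      list(probes = r$probes, cn = r$cn, cohort = NULL,
           assembly = config$assembly)
    }
  })
  seg <- stage("segmentation", function() {
    s <- cbs_segment(inp$cn, inp$probes, config$segmentation)
    filter_min_probes(s, config$segmentation$min_probes_keep)
  })
  write_seg(seg, out("segments.seg"), config$seed)
  done <- c(done, out("segments.seg"))

  thr <- stage("thresholds", function() {
    sm <- smooth_windows(inp$cn, inp$probes,
                         config$segmentation$smooth_window)
    adaptive_thresholds(sm, config$calling$adaptive_k)
  })
  states <- stage("calling", function() {
    call_states(seg, inp$probes, thr, config$calling)
  })
  write_matrix_tsv(inp$probes, states, out("states.tsv"), config$seed)
  fga_tab <- stage("fga", function() fga(states))
  fga_tab <- merge(fga_tab, thr, by = "sample", sort = FALSE)
  write_metadata_tsv(fga_tab, out("fga.tsv"), config$seed)
  done <- c(done, out("states.tsv"), out("fga.tsv"))

  X <- seg_means_matrix(seg, inp$probes, samples = thr$sample)
  gain <- stage("gistic_gain", function() {
    gistic_scan(X, thr, inp$probes, "gain", config$gistic)
  })
  loss <- stage("gistic_loss", function() {
    gistic_scan(X, thr, inp$probes, "loss", config$gistic)
  })
  regions <- rbind(gain$regions, loss$regions)
  write_metadata_tsv(regions, out("gistic_regions.tsv"), config$seed)
  if (nrow(regions)) {
    write_bed(data.frame(chrom = regions$chrom, start = regions$wide_start,
                         end = regions$wide_end,
                         name = paste0(regions$direction, "_",
                                       seq_len(nrow(regions)))),
              out("gistic_regions.bed"), config$seed)
  }
  done <- c(done, out("gistic_regions.tsv"))

  peaks <- stage("recurrent_peaks", function() {
    recurrent_peaks(states, inp$probes)
  })
  if (nrow(peaks)) {
    write_bed(data.frame(chrom = peaks$chrom, start = peaks$start,
                         end = peaks$end,
                         name = sprintf("peak_%d", seq_len(nrow(peaks)))),
              out("amplicon_peaks.bed"), config$seed)
  }
  coamp <- stage("coamplification", function() {
    n <- nrow(peaks)
    m <- matrix(NA_real_, n, n)
    if (n >= 2) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j) m[i, j] <- coamp_fraction(peaks$members[[i]],
                                              peaks$members[[j]], "row")
      }
    }
    m
  })
  utils::write.table(coamp, out("coamplification.tsv"), sep = "\t",
                     quote = FALSE)
  fs <- stage("firestorms", function() {
    detect_firestorms(states, inp$probes, inp$assembly)
  })
  write_metadata_tsv(fs[, setdiff(names(fs), "peaks")],
                     out("firestorms.tsv"), config$seed)
  done <- c(done, out("amplicon_peaks.bed"), out("coamplification.tsv"),
            out("firestorms.tsv"))

  dosage_res <- NULL
  if (!is.null(inp$cohort) && !is.null(inp$cohort$expression)) {
    dosage_res <- stage("dosage", function() {
      global_dosage_scan(inp$cohort$expression$expr,
                         inp$cohort$expression$genes, X, inp$probes,
                         n_perm = config$dosage$n_perm,
                         sd_min = config$dosage$sd_min,
                         alpha = config$dosage$alpha)
    })
    write_metadata_tsv(dosage_res, out("dosage.tsv"), config$seed)
    done <- c(done, out("dosage.tsv"))
  }
  if (!is.null(inp$cohort)) {
    write_truth_json(inp$cohort$truth, out("truth.json"))
    write_metadata_tsv(inp$cohort$metadata, out("metadata.tsv"),
                       config$seed)
  }
  manifest <- list(
    tool = "cnascan",
    version = as.character(utils::packageVersion("cnascan")),
    seed = config$seed,
    n_samples = ncol(inp$cn), n_probes = nrow(inp$cn),
    n_segments = nrow(seg),
    thresholds = thr,
    calling = unclass(config$calling),
    segmentation = unclass(config$segmentation),
    gistic = unclass(config$gistic),
    n_regions_gain = nrow(gain$regions),
    n_regions_loss = nrow(loss$regions),
    n_peaks = nrow(peaks), n_firestorms = nrow(fs),
    outputs = done)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(
    list(probes = inp$probes, cn = inp$cn, cohort = inp$cohort,
         assembly = inp$assembly, seg = seg, thresholds = thr,
         states = states, X = X, fga = fga_tab, gain = gain, loss = loss,
         regions = regions, peaks = peaks, coamp = coamp, firestorms = fs,
         dosage = dosage_res, manifest = manifest),
    class = "cna_report"))
}

#' Compare alteration frequencies between two cohorts
#'
#' For each region, counts altered vs non-altered samples in the two
#' reports (a sample is altered when any probe in the region reaches the
#' gain state, or the loss state for \code{direction = "loss"}), tests the
#' 2x2 table with Fisher's exact test and applies Bonferroni adjustment
#' across regions. Both reports must share the probe grid; remap with
#' \code{\link{map_to_common_grid}} first if they do not.
#'
#' @param report_a,report_b \code{cna_report} objects (or lists with
#'   \code{states}, \code{probes}).
#' @param regions Region table (defaults to the union of both reports'
#'   GISTIC regions).
#' @param direction \code{"gain"} or \code{"loss"}.
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @return Data frame: region coordinates, per-cohort altered counts,
#'   Fisher \code{p}, \code{p_bonf}, \code{significant}.
#' @export
compare_cohorts <- function(report_a, report_b, regions = NULL,
                            direction = c("gain", "loss"), alpha = 0.05) {
  direction <- match.arg(direction)
  if (!identical(report_a$probes$probe, report_b$probes$probe)) {
    stop("cohorts are on different probe grids; remap both with ",
         "map_to_common_grid() before comparing")
  }
  if (is.null(regions)) regions <- rbind(report_a$regions, report_b$regions)
  if (!nrow(regions)) return(data.frame())
  probes <- report_a$probes
  gain_code <- state_code("gain")
  altered <- function(states, rows) {
    if (direction == "gain") {
      colSums(!is.na(states[rows, , drop = FALSE]) &
                states[rows, , drop = FALSE] >= gain_code) > 0
    } else {
      colSums(!is.na(states[rows, , drop = FALSE]) &
                states[rows, , drop = FALSE] == 0L) > 0
    }
  }
  res <- lapply(seq_len(nrow(regions)), function(r) {
    start <- if (!is.null(regions$start)) regions$start[r] else
      regions$wide_start[r]
    end <- if (!is.null(regions$end)) regions$end[r] else
      regions$wide_end[r]
    rows <- probe_rows_overlap(probes, regions$chrom[r], start, end)
    a <- altered(report_a$states, rows)
    b <- altered(report_b$states, rows)
    tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2, 2)
    data.frame(chrom = regions$chrom[r], start = start, end = end,
               altered_a = sum(a), n_a = length(a),
               altered_b = sum(b), n_b = length(b),
               p = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_bonf < alpha
  rownames(out) <- NULL
  out
}
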