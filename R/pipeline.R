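# Orchestration of the three named analyses (trajectories, opening
# attribution, STARR consensus) plus fixture generation. Each run_* function
# is the package's equivalent of a pipeline subcommand: it takes the inputs
# and parameters, optionally writes all outputs plus a manifest and a run
# log into a run directory, and returns the computed objects.

write_run_log <- function(out_dir, stage, config) {
  lines <- c(
    sprintf("pouchrom %s", as.character(utils::packageVersion("pouchrom"))),
    sprintf("stage: %s", stage),
    "config:",
    vapply(names(config), function(nm) {
      sprintf("  %s: %s", nm, paste(format(config[[nm]], trim = TRUE),
                                    collapse = " "))
    }, character(1))
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}

write_manifest <- function(out_dir, stage, config, files) {
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("pouchrom")),
    config = config,
    files = lapply(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_tsv <- function(x, path) {
  x <- x[!vapply(x, is.list, logical(1))]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate and write the full synthetic fixture directory
#'
#' Runs [simulate_scenario()] and writes the genome FASTA, per-condition
#' summit BEDs and ChIP narrowPeak files, per-condition ATAC fragment and
#' peak BEDs, STARR replicate/merged BEDs, all truth tables (planted
#' motifs, binding states, accessibility states) as TSV, plus
#' `manifest.json` and `run_log.txt`. Re-running with the same
#' configuration reproduces the directory byte for byte.
#'
#' @param out_dir Output directory (created if missing).
#' @param ... Passed to [simulate_scenario()].
#' @return The scenario list, invisibly.
#' @export
run_simulate <- function(out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- simulate_scenario(...)
  write_genome(sc$genome, file.path(out_dir, "genome.fa"))
  write_tsv(sc$truth, file.path(out_dir, "truth_motifs.tsv"))
  write_tsv(sc$binding, file.path(out_dir, "truth_binding.tsv"))
  write_tsv(sc$atac$state, file.path(out_dir, "truth_accessibility.tsv"))
  for (src in unique(sc$summits$source)) {
    s <- sc$summits[sc$summits$source == src, ]
    write_intervals(
      tibble::tibble(chrom = s$chrom, start = s$pos, end = s$pos + 1,
                     name = s$locus_id),
      file.path(out_dir, sprintf("summits_%s.bed", src)), "bed"
    )
    write_intervals(sc$chip_peaks[sc$chip_peaks$source == src, ],
                    file.path(out_dir, sprintf("peaks_%s.narrowPeak", src)),
                    "narrowpeak")
  }
  for (cond in names(sc$atac$fragments)) {
    write_intervals(sc$atac$fragments[[cond]],
                    file.path(out_dir, sprintf("atac_fragments_%s.bed", cond)),
                    "bed")
    write_intervals(sc$atac$peaks[[cond]],
                    file.path(out_dir, sprintf("atac_peaks_%s.bed", cond)),
                    "bed")
  }
  for (r in seq_along(sc$starr$replicate_peaks)) {
    write_intervals(sc$starr$replicate_peaks[[r]],
                    file.path(out_dir, sprintf("starr_rep%d.bed", r)), "bed")
  }
  write_intervals(sc$starr$merged_peaks,
                  file.path(out_dir, "starr_merged.bed"), "bed")
  cfg <- sc$config
  write_run_log(out_dir, "simulate", cfg)
  write_manifest(out_dir, "simulate", cfg,
                 setdiff(list.files(out_dir), c("manifest.json", "run_log.txt")))
  invisible(sc)
}

#' Occupancy-trajectory analysis
#'
#' Assigns binary occupancy codes across the ordered conditions, summarises
#' group sizes and computes per-group motif-class fractions. Optionally
#' writes per-code BED files (`loci_<code>.bed`), the trajectory summary
#' and the motif-fraction table.
#'
#' @param summits Summit tibble (`chrom`, `pos`, `source`).
#' @param conditions Ordered condition labels (the code digits, left to
#'   right).
#' @param genome Genome (named character vector or FASTA path) for motif
#'   annotation; `NULL` skips annotation.
#' @param pwms PWM list (default [pou_pwms()]).
#' @param max_dist Summit merge distance (default 100).
#' @param scan_window Motif scan window (default 200).
#' @param out_dir Optional run directory.
#' @return List: `loci` (coded loci), `summary`, `annotations`,
#'   `fractions`.
#' @export
run_trajectories <- function(summits, conditions, genome = NULL,
                             pwms = pou_pwms(), max_dist = 100,
                             scan_window = 200, out_dir = NULL) {
  loci <- assign_occupancy_codes(summits, conditions, max_dist = max_dist)
  summary <- trajectory_summary(loci)
  annotations <- NULL
  fractions <- NULL
  if (!is.null(genome)) {
    annotations <- annotate_loci(loci, genome, pwms, window = scan_window)
    fractions <- motif_fractions(annotations, loci$code)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cd in unique(loci$code)) {
      sub <- loci[loci$code == cd, ]
      write_intervals(
        tibble::tibble(chrom = sub$chrom, start = sub$start, end = sub$end,
                       name = sub$locus_id),
        file.path(out_dir, sprintf("loci_%s.bed", cd)), "bed"
      )
    }
    write_tsv(summary, file.path(out_dir, "trajectory_summary.tsv"))
    if (!is.null(fractions)) {
      write_tsv(fractions, file.path(out_dir, "motif_fractions.tsv"))
    }
    cfg <- list(conditions = conditions, max_dist = max_dist,
                scan_window = scan_window, n_summits = nrow(summits))
    write_run_log(out_dir, "trajectories", cfg)
    write_manifest(out_dir, "trajectories", cfg,
                   setdiff(list.files(out_dir), c("manifest.json", "run_log.txt")))
  }
  list(loci = loci, summary = summary, annotations = annotations,
       fractions = fractions)
}

#' Chromatin-opening attribution analysis
#'
#' Classifies the MEF/day-1 locus universe into PO/OC/CO chromatin
#' trajectories, tiers loci by raw MEF fragment counts, and for the CO
#' (close-to-open) loci attributes opening to factor co-binding: loci are
#' grouped by overlap with the two factors' day-1 peaks and their day/MEF
#' accessibility ratios compared pairwise (rank-sum, Holm-adjusted).
#'
#' The attribution universe defaults to the CO loci of the peak-derived
#' chromatin trajectory. When a `universe` of candidate loci is supplied
#' (typically the day-1 ChIP-bound regions), attribution instead runs over
#' the universe loci closed in MEF (no MEF peak overlap), whether or not
#' they reached an ATAC peak later: this asks the pioneer-factor question
#' directly — which binding configurations open MEF-closed chromatin —
#' without conditioning every locus on already having opened.
#'
#' @param mef_peaks,day_peaks ATAC peak tibbles for MEF and the later
#'   condition.
#' @param mef_fragments,day_fragments ATAC fragment tibbles.
#' @param peaks_a,peaks_b Day-1 ChIP peak tibbles of the two factors
#'   (e.g. Sox2 and the POU factor).
#' @param universe Optional interval tibble of candidate loci for the
#'   attribution step (see Details); `NULL` uses the CO trajectory loci.
#' @param class_labels Labels for (A-only, B-only, shared, neither).
#' @param mef_library_size,day_library_size Library sizes (defaults:
#'   fragment counts).
#' @param epsilon Ratio stabilizer (default 0.1).
#' @param tier_low,tier_high Accessibility-tier boundaries (default 15/30).
#' @param min_n Minimum class size for testing (default 3).
#' @param out_dir Optional run directory.
#' @return List: `trajectory` (universe with PO/OC/CO labels and a `tier`
#'   column from MEF counts), `co_loci`, `classes`, `ratios`, `report`
#'   (an `attribution_report`, or `NULL` with a message when fewer than two
#'   classes are testable).
#' @export
run_opening <- function(mef_peaks, day_peaks, mef_fragments, day_fragments,
                        peaks_a, peaks_b, universe = NULL,
                        class_labels = c("Sox2_only", "POU_only", "shared",
                                         "neither"),
                        mef_library_size = nrow(mef_fragments),
                        day_library_size = nrow(day_fragments),
                        epsilon = 0.1, tier_low = 15, tier_high = 30,
                        min_n = 3, out_dir = NULL) {
  if (nrow(mef_peaks) == 0L && nrow(day_peaks) == 0L) {
    stop("both peak sets are empty: no locus universe", call. = FALSE)
  }
  traj <- chromatin_trajectory(mef_peaks, day_peaks)
  if (all(traj$label == "OC")) {
    warning("no day peaks: every universe locus is open-to-close",
            call. = FALSE)
  }
  mef_counts <- count_coverage(traj, mef_fragments)
  traj$mef_count <- mef_counts
  traj$tier <- accessibility_tier(mef_counts, tier_low, tier_high)
  co <- if (is.null(universe)) {
    traj[traj$label == "CO", , drop = FALSE]
  } else {
    validate_intervals(universe)
    u <- universe[!overlaps_any(universe, mef_peaks), , drop = FALSE]
    u$mef_count <- count_coverage(u, mef_fragments)
    u
  }
  classes <- NULL; ratios <- NULL; report <- NULL
  if (nrow(co)) {
    classes <- classify_cobinding(co, peaks_a, peaks_b, labels = class_labels)
    width <- co$end - co$start
    day_sig <- normalize_fpkpm(count_coverage(co, day_fragments), width,
                               day_library_size)
    mef_sig <- normalize_fpkpm(co$mef_count, width, mef_library_size)
    ratios <- accessibility_ratio(day_sig, mef_sig, epsilon)
    n_classes <- sum(table(classes) >= min_n)
    if (n_classes >= 2L) {
      report <- opening_attribution(classes, ratios, min_n = min_n)
    } else {
      message("fewer than two co-binding classes with n >= ", min_n,
              "; attribution testing skipped")
    }
  } else {
    message("no close-to-open loci; attribution skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(traj, file.path(out_dir, "chromatin_trajectories.tsv"))
    if (!is.null(classes)) {
      write_intervals(
        tibble::tibble(chrom = co$chrom, start = co$start, end = co$end,
                       name = as.character(classes)),
        file.path(out_dir, "co_cobinding_classes.bed"), "bed"
      )
    }
    if (!is.null(report)) {
      write_attribution_report(report, file.path(out_dir, "attribution"))
    }
    cfg <- list(epsilon = epsilon, tier_low = tier_low, tier_high = tier_high,
                min_n = min_n, class_labels = class_labels)
    write_run_log(out_dir, "opening", cfg)
    write_manifest(out_dir, "opening", cfg,
                   setdiff(list.files(out_dir), c("manifest.json", "run_log.txt")))
  }
  list(trajectory = traj, co_loci = co, classes = classes, ratios = ratios,
       report = report)
}

#' STARR-seq consensus enhancer analysis
#'
#' Calls consensus enhancers (merged peaks supported by at least
#' `min_replicates` replicates) and, when a truth set or a query region set
#' is supplied, reports recall and overlap fractions.
#'
#' @param merged_peaks Merged-library peak tibble, or a `starr_call_set`
#'   from [simulate_starr()] (in which case `replicate_peaks` is taken from
#'   it).
#' @param replicate_peaks List of per-replicate peak tibbles.
#' @param min_replicates Support threshold (default 2).
#' @param truth Optional true-enhancer tibble for recall.
#' @param query Optional bound-region tibble; reports the fraction of query
#'   regions covered by consensus enhancers.
#' @param out_dir Optional run directory.
#' @return List: `consensus`, `recall` (or `NA`), `query_overlap`
#'   (or `NA`).
#' @export
run_starr <- function(merged_peaks, replicate_peaks = NULL,
                      min_replicates = 2, truth = NULL, query = NULL,
                      out_dir = NULL) {
  if (inherits(merged_peaks, "starr_call_set")) {
    cs <- merged_peaks
    replicate_peaks <- cs$replicate_peaks
    if (is.null(truth)) truth <- cs$truth
    merged_peaks <- cs$merged_peaks
  }
  if (length(replicate_peaks) < 2L) {
    stop("need >= 2 replicates", call. = FALSE)
  }
  consensus <- call_consensus_enhancers(merged_peaks, replicate_peaks,
                                        min_replicates = min_replicates)
  recall <- if (!is.null(truth) && nrow(truth)) {
    mean(overlaps_any(truth, consensus))
  } else NA_real_
  query_overlap <- if (!is.null(query) && nrow(query)) {
    overlap_fraction(query, consensus)
  } else NA_real_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_intervals(consensus[c("chrom", "start", "end")],
                    file.path(out_dir, "consensus_enhancers.bed"), "bed")
    cfg <- list(min_replicates = min_replicates,
                n_replicates = length(replicate_peaks),
                recall = recall, query_overlap = query_overlap)
    write_run_log(out_dir, "starr", cfg)
    write_manifest(out_dir, "starr", cfg,
                   setdiff(list.files(out_dir), c("manifest.json", "run_log.txt")))
  }
  list(consensus = consensus, recall = recall, query_overlap = query_overlap)
}
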