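# Reproducible pipeline runner: wires configuration and the analysis stages
# together, writes TSV/BED/JSON outputs and a machine-readable manifest
# (effective configuration, seed, package version, input checksums), so a
# run can be reproduced bit-exactly from the manifest alone.

#' Pipeline run configuration
#'
#' One flat configuration object whose defaults are the parameter values
#' the analyses were designed around: area factor 40, one million
#' permutations, ten thousand bootstrap resamples, 95% confidence level,
#' alignment gap open 10 / extension 1.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param area_factor,estimator,permutations,bootstrap,ci_level Migration
#'   stage parameters.
#' @param match,mismatch,gap_open,gap_extend,identity_denominator Alignment
#'   stage parameters.
#' @param orientation,control_condition,negative_controls Reporter stage
#'   parameters.
#' @param calibrator qPCR calibrator sample label.
#' @param motif_consensus Named list of motif consensus sets.
#' @param seed_classes Site classes scanned.
#' @param out_dir Output directory (created if missing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, area_factor = 40,
                       estimator = "area_corrected",
                       permutations = 1e6, bootstrap = 1e4, ci_level = 0.95,
                       match = 1, mismatch = -2, gap_open = 10,
                       gap_extend = 1,
                       identity_denominator = "alignment_length",
                       orientation = "firefly_over_renilla",
                       control_condition = NULL, negative_controls = NULL,
                       calibrator = "calibrator",
                       motif_consensus = motif_consensus_default(),
                       seed_classes = SITE_CLASSES, out_dir = ".") {
  structure(list(seed = as.integer(seed), area_factor = area_factor,
                 estimator = estimator, permutations = permutations,
                 bootstrap = bootstrap, ci_level = ci_level, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 identity_denominator = identity_denominator,
                 orientation = orientation,
                 control_condition = control_condition,
                 negative_controls = negative_controls,
                 calibrator = calibrator,
                 motif_consensus = motif_consensus,
                 seed_classes = seed_classes, out_dir = out_dir),
            class = "run_config")
}

require_input <- function(path, what) {
  if (!file.exists(path)) stopf("input file not found: %s (%s)", path, what)
  path
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline on a set of input files
#'
#' Executes the stages for which inputs are provided and writes their
#' outputs plus a run manifest into `config$out_dir`. Stages:
#'
#' * `scan` (`utr_fasta` + `mirna_fasta`): seed sites and motifs per UTR
#'   record, as BED6 plus a JSON summary with counts and cooperative pairs.
#' * `align` (`align_fasta`): all pairwise global alignments of the
#'   records, identity matrix as TSV.
#' * `reporter` (`wells_tsv`): normalized activities; when
#'   `negative_controls` is configured, also baseline, repression percent
#'   and two-sided Student p-values versus the pooled negative controls.
#' * `qpcr` (`qpcr_tsv`): delta-delta-Ct relative quantities.
#' * `migration` (`migration_tsv`): estimates, permutation test and
#'   bootstrap CIs, as JSON.
#'
#' Any missing input file raises an error naming the path. All randomness
#' derives from `config$seed`, and the manifest's declared seed suffices to
#' reproduce every stochastic output bit-exactly.
#'
#' @param config A [run_config].
#' @param inputs Named list of paths: any of `utr_fasta`, `mirna_fasta`,
#'   `align_fasta`, `wells_tsv`, `qpcr_tsv`, `migration_tsv`.
#' @return Invisibly, a named list of stage results (plus the manifest).
#' @export
run_pipeline <- function(config, inputs) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(inputs)) require_input(inputs[[nm]], nm)
  results <- list()
  stages <- character()

  if (!is.null(inputs$utr_fasta) && !is.null(inputs$mirna_fasta)) {
    utrs <- read_fasta(inputs$utr_fasta, moltype = "DNA")
    mirna_recs <- read_fasta(inputs$mirna_fasta, moltype = "RNA")
    mirnas <- lapply(mirna_recs, function(r) mature_mirna(r$id, r$residues))
    scan <- lapply(utrs, function(u) {
      sites <- scan_seed_sites(u, mirnas, classes = config$seed_classes)
      motifs <- dplyr::bind_rows(lapply(names(config$motif_consensus),
        function(k) find_motifs(u, k, config$motif_consensus[[k]])))
      pairs <- cooperative_pairs(sites)
      list(utr = u$id, sites = sites, motifs = motifs,
           cooperative_pairs = pairs)
    })
    all_sites <- dplyr::bind_rows(lapply(scan, function(s) {
      if (nrow(s$sites)) cbind(seq_id = s$utr, s$sites) else NULL
    }))
    all_motifs <- dplyr::bind_rows(lapply(scan, function(s) {
      if (nrow(s$motifs)) cbind(seq_id = s$utr, s$motifs) else NULL
    }))
    if (nrow(all_sites) > 0) {
      bed <- data.frame(chrom = all_sites$seq_id, start = all_sites$start,
                        end = all_sites$end,
                        name = paste(all_sites$mirna, all_sites$site_class,
                                     sep = "|"),
                        score = 0L, strand = "+")
      write.table(bed, file.path(out_dir, "sites.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    if (nrow(all_motifs) > 0) {
      bed <- data.frame(chrom = all_motifs$seq_id, start = all_motifs$start,
                        end = all_motifs$end, name = all_motifs$kind,
                        score = 0L, strand = "+")
      write.table(bed, file.path(out_dir, "motifs.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    summary <- lapply(scan, function(s) {
      list(utr = s$utr, n_sites = nrow(s$sites), n_motifs = nrow(s$motifs),
           cooperative_pairs = s$cooperative_pairs)
    })
    jsonlite::write_json(summary, file.path(out_dir, "scan_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$scan <- scan
    stages <- c(stages, "scan")
  }

  if (!is.null(inputs$align_fasta)) {
    recs <- read_fasta(inputs$align_fasta, moltype = "DNA")
    scheme <- scoring_scheme(config$match, config$mismatch, config$gap_open,
                             config$gap_extend)
    mat <- identity_matrix(recs, scheme = scheme,
                           identity_denominator = config$identity_denominator)
    write_tsv(data.frame(id = rownames(mat), mat, check.names = FALSE),
              file.path(out_dir, "identity_matrix.tsv"))
    results$align <- mat
    stages <- c(stages, "align")
  }

  if (!is.null(inputs$wells_tsv)) {
    wells <- read.delim(inputs$wells_tsv, sep = "\t",
                        stringsAsFactors = FALSE)
    if (is.null(config$control_condition)) {
      stopf("reporter stage requires `control_condition` in the config")
    }
    norm <- normalize_wells(wells, orientation = config$orientation,
                            control_condition = config$control_condition)
    if (!is.null(config$negative_controls)) {
      bl <- unrepressed_baseline(norm, config$negative_controls)
      norm$repression_percent <- repression_percent(norm$normalized_activity,
                                                    bl)
      ratio <- if (config$orientation == "firefly_over_renilla") {
        wells$firefly / wells$renilla
      } else {
        wells$renilla / wells$firefly
      }
      neg <- ratio[wells$condition %in% config$negative_controls]
      norm$p_value <- vapply(norm$condition, function(cond) {
        x <- ratio[wells$condition == cond]
        if (length(x) < 2 || length(neg) < 2) return(NA_real_)
        two_sided_t_test(x, neg, variant = "student")$p_value
      }, 1.0)
    }
    write_tsv(norm, file.path(out_dir, "reporter_results.tsv"))
    results$reporter <- norm
    stages <- c(stages, "reporter")
  }

  if (!is.null(inputs$qpcr_tsv)) {
    ct <- read.delim(inputs$qpcr_tsv, sep = "\t", stringsAsFactors = FALSE)
    rq <- qpcr_quantify(ct, method = "delta_delta_ct",
                        calibrator = config$calibrator)
    write_tsv(rq, file.path(out_dir, "qpcr_results.tsv"))
    results$qpcr <- rq
    stages <- c(stages, "qpcr")
  }

  if (!is.null(inputs$migration_tsv)) {
    counts <- read.delim(inputs$migration_tsv, sep = "\t",
                         stringsAsFactors = FALSE)
    design <- migration_design(area_factor = config$area_factor)
    inf <- migration_inference(counts, design = design,
                               estimator = config$estimator,
                               n_permutations = config$permutations,
                               n_bootstrap = config$bootstrap,
                               level = config$ci_level, seed = config$seed)
    out <- list(
      per_treatment = as.list(inf$estimate$per_treatment),
      observed_diff = inf$permutation$observed_diff,
      p_value = inf$permutation$p_value,
      n_permutations = inf$permutation$n_permutations,
      method = inf$permutation$method,
      ci = inf$bootstrap, seed = config$seed)
    jsonlite::write_json(out, file.path(out_dir, "migration_inference.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(inf$estimate$per_observation,
              file.path(out_dir, "migration_observations.tsv"))
    results$migration <- inf
    stages <- c(stages, "migration")
  }

  manifest <- list(
    package = "mirval",
    version = as.character(packageVersion("mirval")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stages = stages,
    config = config[setdiff(names(config), "motif_consensus")],
    motif_consensus = config$motif_consensus,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
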