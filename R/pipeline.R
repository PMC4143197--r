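#' Run the scanning and feature-generation stages on a study
#'
#' Convenience wrapper binding the pipeline front end together: extracts the
#' TSS-anchored regions from the study genome, draws seeded random background
#' regions, estimates the background base composition from them, builds and
#' calibrates one PSSM per motif (about one hit per \code{1/target_rate} bp),
#' scans every region, builds the structural-feature library from the
#' positive regions and binarizes it over the whole cohort.
#'
#' @param study A \code{crm_study} from [generate_study()], or a list with
#'   elements \code{genome}, \code{tss}, \code{motifs}, \code{positives},
#'   \code{negatives} read from files.
#' @param n_background Number of random background regions used for
#'   threshold calibration (default 200; the reference recipe uses 1000).
#' @param target_rate Calibration target hit rate (default 1/5000 per bp).
#' @param pseudocount PSSM pseudocount fraction.
#' @param window,max_order Feature enumeration parameters.
#' @param upstream,downstream Region extent (defaults follow the study).
#' @param seed Seed for the background draw; defaults to the study seed.
#' @return List(regions, labels, background, pssms, hits, library, fm).
#' @export
study_feature_matrix <- function(study, n_background = 200L,
                                 target_rate = 1 / 5000, pseudocount = 0.01,
                                 window = 100L, max_order = 3L,
                                 upstream = NULL, downstream = NULL,
                                 seed = NULL) {
  upstream <- upstream %||% study$params$upstream %||% 1500L
  downstream <- downstream %||% study$params$downstream %||% 500L
  seed <- seed %||% study$params$seed %||% 1L
  ids <- c(study$positives, study$negatives)
  tss <- study$tss[match(ids, study$tss$gene_id), ]
  regs <- extract_regions(study$genome, tss, upstream, downstream)
  labels <- as.integer(regs$gene_id %in% study$positives)
  bg <- random_regions(n_background, upstream + downstream,
                       base_composition =
                         study$params$base_composition %||% rep(0.25, 4),
                       seed = sub_seed(seed, 7L))
  bg_freq <- estimate_background(bg)
  pssms <- lapply(study$motifs, function(m)
    calibrate_threshold(build_pssm(m, bg_freq, pseudocount), bg,
                        target_rate))
  hits <- scan_regions(pssms, regs)
  lib <- build_feature_library(hits[hits$gene_id %in% study$positives, ],
                               region_ids = study$positives,
                               window = window, max_order = max_order)
  fm <- binarize(lib, hits, regs$gene_id, labels,
                 window = window, max_order = max_order)
  list(regions = regs, labels = labels, background = bg, pssms = pssms,
       hits = hits, library = lib, fm = fm)
}

#' Read a study back from files written by [write_study()]
#'
#' @param dir Directory containing genome.fa, tss.tsv, motifs.jaspar,
#'   positives.txt, negatives.txt (truth.json is loaded when present).
#' @return A list usable by [study_feature_matrix()].
#' @export
read_study <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(
    truth_path, simplifyVector = TRUE) else NULL
  params <- truth$params
  if (!is.null(params$base_composition))
    params$base_composition <- as.numeric(params$base_composition)
  motifs <- read_motifs(file.path(dir, "motifs.jaspar"), "jaspar")
  names(motifs) <- vapply(motifs, `[[`, character(1), "motif_id")
  structure(list(genome = read_genome(file.path(dir, "genome.fa")),
                 tss = read_tss_table(file.path(dir, "tss.tsv")),
                 motifs = motifs,
                 positives = readLines(file.path(dir, "positives.txt")),
                 negatives = readLines(file.path(dir, "negatives.txt")),
                 truth = truth$truth,
                 truth_features = truth$truth_features,
                 params = params),
            class = "crm_study")
}
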