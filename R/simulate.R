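#' Study design for the synthetic expression generator
#'
#' The default mirrors a three-class polyploid grass design: two sexual
#' diploid genotypes, three apomictic tetraploid genotypes and one sexual
#' tetraploid genotype, each grown as three clonal replicates, leaf tissue.
#'
#' @param classes named integer vector: phenotypic class label -> number of
#'   genotypes (all >= 1).
#' @param clones_per_genotype clonal replicates per genotype (>= 1).
#' @param tissues tissue labels; samples are replicated per tissue.
#' @return list of class `study_design`.
#' @export
study_design <- function(classes = c("2X_sex" = 2L, "4X_apo" = 3L, "4X_sex" = 1L),
                         clones_per_genotype = 3L,
                         tissues = "leaf") {
  stopifnot(length(classes) >= 1, all(classes >= 1),
            clones_per_genotype >= 1, length(tissues) >= 1)
  if (is.null(names(classes)) || any(names(classes) == ""))
    stop("classes must be a named vector of genotype counts")
  structure(list(classes = classes,
                 clones_per_genotype = as.integer(clones_per_genotype),
                 tissues = tissues),
            class = "study_design")
}

#' Simulation parameters
#'
#' Negative-binomial counts are parameterized by mean and dispersion
#' (variance = mu + mu^2 * dispersion, i.e. NB size = 1/dispersion), with a
#' per-transcript baseline drawn log-uniformly, a multiplicative log-normal
#' genotype effect shared by all clones of a genotype, class-specific
#' transcripts zeroed outside their class, and differential transcripts
#' shifted by +/- `de_log2fc` in the designated class (`de_class`) relative
#' to every other class.
#'
#' @param n_transcripts number of transcripts.
#' @param baseline_mean_log_range range (natural-log scale) of baseline
#'   mean expression.
#' @param nb_dispersion shared NB dispersion (> 0; variance = mu + mu^2 d).
#' @param genotype_sd log-scale SD of the per-(transcript, genotype)
#'   random effect (>= 0).
#' @param frac_specific named fractions of class-specific transcripts, one
#'   per class label (may omit classes; jointly with `frac_de` must sum to
#'   <= 1).
#' @param frac_de fraction of transcripts differentially expressed in
#'   `de_class` versus all other classes.
#' @param de_log2fc absolute planted log2 fold change (>= 0).
#' @param de_class class label receiving the DE shift.
#' @param frac_acr fraction of transcripts planted as hits inside the
#'   synteny intervals (the simulated apomixis-controlling region).
#' @param n_modules,module_size,module_noise_sd coexpression modules: number
#'   of modules, transcripts per module, log-scale SD of the noise around
#'   the shared latent profile.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_transcripts = 2000L,
                       baseline_mean_log_range = c(log(5), log(500)),
                       nb_dispersion = 0.1,
                       genotype_sd = 0.1,
                       frac_specific = c("2X_sex" = 0.02, "4X_apo" = 0.10,
                                         "4X_sex" = 0.005),
                       frac_de = 0.05,
                       de_log2fc = 2,
                       de_class = "4X_apo",
                       frac_acr = 0.03,
                       n_modules = 10L,
                       module_size = 30L,
                       module_noise_sd = 0.25,
                       seed = 1L) {
  stopifnot(n_transcripts >= 1, length(baseline_mean_log_range) == 2,
            nb_dispersion > 0, genotype_sd >= 0,
            all(frac_specific >= 0), all(frac_specific <= 1),
            frac_de >= 0, frac_de <= 1, de_log2fc >= 0,
            frac_acr >= 0, frac_acr <= 1,
            n_modules >= 0, module_size >= 2, module_noise_sd >= 0)
  if (sum(frac_specific) + frac_de > 1)
    stop("frac_specific and frac_de jointly exceed 1")
  if (n_modules * module_size > n_transcripts)
    stop("n_modules * module_size exceeds n_transcripts")
  structure(as.list(environment()), class = "sim_params")
}

new_ground_truth <- function(transcript_ids) {
  structure(list(transcript_ids = transcript_ids,
                 specific_sets = list(),
                 de_sets = list(),
                 module_assignment = NULL,
                 acr_set = character(0),
                 go_map = NULL),
            class = "ground_truth")
}

comparison_label <- function(a, b) paste0(a, "_vs_", b)

design_metadata <- function(design) {
  rows <- list()
  for (cl in names(design$classes)) {
    for (j in seq_len(design$classes[[cl]])) {
      geno <- sprintf("%s_g%d", cl, j)
      for (k in seq_len(design$clones_per_genotype)) {
        for (ti in design$tissues) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_c%d_%s", geno, k, ti),
            genotype = geno, clone = sprintf("c%d", k), tissue = ti,
            phenotypic_class = cl, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a seeded negative-binomial count matrix with planted truth
#'
#' @param design a [study_design()].
#' @param params a [sim_params()].
#' @return list with `counts` (count expression matrix), `meta` (sample
#'   metadata), `lengths` (named transcript lengths, bp), and `truth`
#'   (`ground_truth`: planted specific sets per class, up/down DE sets per
#'   comparison against `de_class`, and the planted ACR transcript set).
#' @export
generate_counts <- function(design, params) {
  stopifnot(inherits(design, "study_design"), inherits(params, "sim_params"))
  if (params$frac_de > 0 && !params$de_class %in% names(design$classes))
    stop("de_class not present in design classes")
  set.seed(params$seed)
  n <- params$n_transcripts
  ids <- sprintf("tr%05d", seq_len(n))
  meta <- design_metadata(design)
  genotypes <- unique(meta$genotype)
  truth <- new_ground_truth(ids)

  # planted labels: specific sets per class, then DE, disjoint (floor rule)
  pool <- ids
  for (cl in names(params$frac_specific)) {
    if (!cl %in% names(design$classes)) next
    k <- floor(params$frac_specific[[cl]] * n)
    picked <- sample(pool, k)
    truth$specific_sets[[cl]] <- sort(picked)
    pool <- setdiff(pool, picked)
  }
  n_de <- floor(params$frac_de * n)
  de_ids <- sort(sample(pool, n_de))
  up <- de_ids[seq_len(ceiling(n_de / 2))]
  down <- setdiff(de_ids, up)
  other_classes <- setdiff(names(design$classes), params$de_class)
  for (cl in other_classes)
    truth$de_sets[[comparison_label(params$de_class, cl)]] <-
      list(up = up, down = down)
  truth$acr_set <- sort(sample(ids, floor(params$frac_acr * n)))

  base_mu <- exp(stats::runif(n, params$baseline_mean_log_range[1],
                              params$baseline_mean_log_range[2]))
  geno_eff <- matrix(exp(stats::rnorm(n * length(genotypes),
                                      sd = params$genotype_sd)),
                     nrow = n, dimnames = list(ids, genotypes))

  class_of_geno <- meta$phenotypic_class[match(genotypes, meta$genotype)]
  size <- 1 / params$nb_dispersion
  counts <- matrix(0, n, nrow(meta), dimnames = list(ids, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    gt <- meta$genotype[s]
    cl <- meta$phenotypic_class[s]
    mu <- base_mu * geno_eff[, gt]
    if (cl == params$de_class) {
      mu[up] <- mu[up] * 2^params$de_log2fc
      mu[down] <- mu[down] * 2^(-params$de_log2fc)
    }
    for (sp_cl in names(truth$specific_sets))
      if (sp_cl != cl) mu[truth$specific_sets[[sp_cl]]] <- 0
    counts[, s] <- stats::rnbinom(n, mu = mu, size = size)
  }
  lengths <- stats::setNames(round(stats::runif(n, 200, 5000)), ids)
  list(counts = expression_matrix(counts, unit = "count"),
       meta = meta, lengths = lengths, truth = truth)
}

#' Plant coexpression modules into an expression matrix
#'
#' Each module's transcripts are rewritten to share one latent log-normal
#' sample profile (log-scale SD 1) times the transcript's original mean
#' magnitude, plus independent log-normal noise of SD `module_noise_sd`, so
#' that expected within-module pairwise Pearson correlation exceeds the
#' network cutoff. With `module_noise_sd = 0` within-module correlations
#' are exactly 1. Module members are drawn from transcripts that carry no
#' other planted label when a `ground_truth` is supplied.
#'
#' @param x expression matrix (counts are rounded back to integers).
#' @param params a [sim_params()].
#' @param truth optional `ground_truth` to update (and to avoid planting on
#'   specific/DE transcripts).
#' @return list with `matrix` and `truth` (module assignment filled in).
#' @export
plant_modules <- function(x, params, truth = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n_needed <- params$n_modules * params$module_size
  if (n_needed > nrow(x)) stop("not enough transcripts for requested modules")
  if (is.null(truth)) truth <- new_ground_truth(rownames(x))
  set.seed(params$seed + 7919L)
  avoid <- unique(c(unlist(truth$specific_sets),
                    unlist(lapply(truth$de_sets, unlist))))
  pool <- setdiff(rownames(x), avoid)
  if (length(pool) < n_needed)
    stop("not enough unlabeled transcripts for requested modules")
  members <- sample(pool, n_needed)
  assignment <- stats::setNames(rep(seq_len(params$n_modules),
                                    each = params$module_size), members)
  n_s <- ncol(x)
  for (m in seq_len(params$n_modules)) {
    ids <- members[assignment == m]
    latent <- stats::rnorm(n_s, sd = 1)
    base <- pmax(rowMeans(x[ids, , drop = FALSE]), 1)
    prof <- exp(outer(log(base), latent, "+") +
                  matrix(stats::rnorm(length(ids) * n_s,
                                      sd = params$module_noise_sd),
                         nrow = length(ids)))
    if (identical(attr(x, "unit"), "count")) prof <- round(prof)
    x[ids, ] <- prof
  }
  truth$module_assignment <- assignment
  list(matrix = expression_matrix(x, unit = attr(x, "unit")), truth = truth)
}

#' Synthetic marker-delimited synteny intervals
#'
#' Two intervals standing in for the marker-delimited apospory-linked
#' segments of rice chromosomes 2 and 12 (real marker-to-base-pair
#' coordinates are not published; these are fabricated for simulation).
#'
#' @return interval data.frame (`chrom`, `start`, `end`, `label`), 1-based
#'   inclusive coordinates.
#' @export
synthetic_intervals <- function() {
  data.frame(chrom = c("chr2", "chr12"),
             start = c(1000000L, 2000000L),
             end = c(1600000L, 2500000L),
             label = c("C560-C932", "C1069-C996"),
             stringsAsFactors = FALSE)
}

#' Generate a random GO map and a synthetic alignment-hit table
#'
#' Every transcript receives 0..`max_terms` GO terms uniformly at random.
#' Each planted ACR transcript gets one tabular hit whose subject span lies
#' inside one of the intervals with e-value well below the cutoff; decoy
#' hits (a `decoy_frac` fraction of non-ACR transcripts) fall either
#' outside every interval or inside one but with e-value above 1e-05, so
#' interval + e-value filtering must remove them.
#'
#' @param truth a `ground_truth` with `acr_set` and `transcript_ids`.
#' @param n_go_terms size of the GO vocabulary.
#' @param intervals interval data.frame (see [synthetic_intervals()]).
#' @param seed integer seed.
#' @param max_terms maximum GO terms per transcript.
#' @param decoy_frac fraction of non-ACR transcripts given decoy hits.
#' @return list with `go_map` (data.frame transcript_id, term_id), `hits`
#'   (12-column tabular alignment data.frame) and the updated `truth`.
#' @export
generate_annotation_and_hits <- function(truth, n_go_terms = 50L,
                                         intervals = synthetic_intervals(),
                                         seed = 1L, max_terms = 5L,
                                         decoy_frac = 0.2) {
  stopifnot(inherits(truth, "ground_truth"), nrow(intervals) >= 1)
  set.seed(seed + 104729L)
  ids <- truth$transcript_ids
  terms <- sprintf("GO:%07d", seq_len(n_go_terms))
  n_terms <- sample(0:max_terms, length(ids), replace = TRUE)
  go_map <- data.frame(
    transcript_id = rep(ids, n_terms),
    term_id = unlist(lapply(n_terms, function(k) sample(terms, k))),
    stringsAsFactors = FALSE)

  hit_row <- function(qid, chrom, s_start, s_end, evalue) {
    len <- abs(s_end - s_start) + 1L
    data.frame(query_id = qid, subject_id = chrom,
               pident = round(stats::runif(1, 85, 100), 2),
               length = len, mismatch = sample(0:10, 1), gapopen = sample(0:3, 1),
               qstart = 1L, qend = len,
               sstart = s_start, send = s_end,
               evalue = evalue, bitscore = round(stats::runif(1, 50, 500), 1),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (qid in truth$acr_set) {
    iv <- intervals[sample(nrow(intervals), 1), ]
    len <- sample(100:500, 1)
    start <- sample(iv$start:(max(iv$start, iv$end - len)), 1)
    end <- min(start + len - 1L, iv$end)
    minus <- stats::runif(1) < 0.3  # minus-strand: subject coords reversed
    ev <- 10^(-stats::runif(1, 6, 50))
    rows[[length(rows) + 1L]] <-
      if (minus) hit_row(qid, iv$chrom, end, start, ev) else
        hit_row(qid, iv$chrom, start, end, ev)
  }
  decoys <- sample(setdiff(ids, truth$acr_set),
                   floor(decoy_frac * length(ids)))
  for (qid in decoys) {
    iv <- intervals[sample(nrow(intervals), 1), ]
    if (stats::runif(1) < 0.5) {  # off-interval, good e-value
      start <- iv$end + sample(10000:100000, 1)
      rows[[length(rows) + 1L]] <-
        hit_row(qid, iv$chrom, start, start + sample(100:500, 1),
                10^(-stats::runif(1, 6, 50)))
    } else {                      # in-interval, e-value above cutoff
      start <- sample(iv$start:(iv$end - 500), 1)
      rows[[length(rows) + 1L]] <-
        hit_row(qid, iv$chrom, start, start + sample(100:500, 1),
                10^(-stats::runif(1, 0.5, 4)))
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    utils::read.table(text = "", col.names = names(hit_row("q", "c", 1, 1, 1)))
  truth$go_map <- go_map
  list(go_map = go_map, hits = hits, truth = truth)
}

#' Write a complete synthetic analysis bundle
#'
#' Generates the default-design dataset (2,000 transcripts, 18 leaf
#' samples: 6 genotypes x 3 clones) with planted specific, DE, module and
#' ACR labels, and writes every input the pipeline consumes: counts,
#' transcript lengths, sample metadata, GO map, alignment hits, intervals,
#' plus the ground-truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param params optional [sim_params()] override.
#' @param design optional [study_design()] override.
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
make_fixtures <- function(dir, seed = 1L, params = NULL, design = study_design()) {
  if (is.null(params)) params <- sim_params(seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_counts(design, params)
  pm <- plant_modules(sim$counts, params, sim$truth)
  ann <- generate_annotation_and_hits(pm$truth, seed = params$seed)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    go_map = file.path(dir, "go_map.tsv"),
    hits = file.path(dir, "hits.tsv"),
    intervals = file.path(dir, "intervals.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression_matrix(pm$matrix, paths$counts)
  utils::write.table(
    data.frame(transcript_id = names(sim$lengths), length = sim$lengths),
    paths$lengths, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$go_map, paths$go_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$hits, paths$hits, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  iv <- synthetic_intervals()
  writeLines(c("#coords=1-based-inclusive",
               paste("chrom", "start", "end", "label", sep = "\t"),
               paste(iv$chrom, iv$start, iv$end, iv$label, sep = "\t")),
             paths$intervals)
  truth <- ann$truth
  truth_json <- list(
    transcript_ids = truth$transcript_ids,
    specific_sets = truth$specific_sets,
    de_sets = truth$de_sets,
    module_assignment = as.list(truth$module_assignment),
    acr_set = truth$acr_set)
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = FALSE)
  invisible(list(counts = pm$matrix, meta = sim$meta, lengths = sim$lengths,
                 truth = truth, go_map = ann$go_map, hits = ann$hits,
                 intervals = iv, paths = paths))
}

#' Read a ground-truth JSON written by [make_fixtures()]
#' @param path truth.json path.
#' @return a `ground_truth` list.
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- new_ground_truth(j$transcript_ids)
  truth$specific_sets <- j$specific_sets
  truth$de_sets <- j$de_sets
  truth$module_assignment <- unlist(j$module_assignment)
  truth$acr_set <- j$acr_set
  truth
}
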