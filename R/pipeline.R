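#' Pipeline configuration
#'
#' Bundles input locations and the analysis thresholds. The defaults are
#' the published settings of the workflow this package implements:
#' PPEE/PPDE 0.95, log2 fold change 1.5, Pearson cutoff 0.8, HRR limit 30,
#' 3-step node vicinity networks, alignment e-value 1e-05, low-expression
#' zero-fraction 0.5, detection epsilon 0, Bonferroni alpha 0.05.
#'
#' @param counts,lengths,metadata,go_map,hits,intervals input file paths
#'   (TSV; see the reader functions), or in-memory objects of the matching
#'   types.
#' @param out_dir output directory.
#' @param ppee,ppde,log2fc,r_cutoff,hrr_limit,nvn_steps,evalue,theta,epsilon,alpha
#'   thresholds (see Description).
#' @param s_min,s_max HCCA cluster-core size bounds.
#' @param seed integer seed echoed into the log (the analysis itself is
#'   deterministic given its inputs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, lengths, metadata, go_map = NULL,
                            hits = NULL, intervals = NULL,
                            out_dir = "apomixnet_out",
                            ppee = 0.95, ppde = 0.95, log2fc = 1.5,
                            r_cutoff = 0.8, hrr_limit = 30L, nvn_steps = 3L,
                            evalue = 1e-05, theta = 0.5, epsilon = 0,
                            s_min = 10L, s_max = 200L, alpha = 0.05,
                            seed = 1L) {
  stopifnot(ppee > 0, ppee <= 1, ppde > 0, ppde <= 1, log2fc >= 0,
            r_cutoff >= -1, r_cutoff <= 1, hrr_limit >= 1, nvn_steps >= 1,
            evalue > 0, theta >= 0, theta <= 1, epsilon >= 0,
            s_min <= s_max, alpha > 0, alpha <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  # small FNV-1a over the deparsed threshold settings, for output headers
  keep <- config[setdiff(names(config), c("counts", "lengths", "metadata",
                                          "go_map", "hits", "intervals",
                                          "out_dir"))]
  txt <- paste(deparse(keep), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- ((bitwXor(h, b)) * 16777619) %% 2^32
  sprintf("%08x", h)
}

write_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full candidate-discovery pipeline
#'
#' Stages, in order: load inputs; FPKM normalization (when counts are
#' supplied); class-specificity Venn partition; low-expression filter;
#' two-step empirical-Bayes DE workflow; consistent DEGs between the two
#' apomict-vs-sexual comparisons; alignment-hit interval filtering;
#' candidate seed assembly (ACR intersect specific/DE); Pearson + HRR
#' coexpression network; HCCA clustering; seed first-neighbor subnetwork;
#' GO enrichment of (a) the consistent DEGs against the common-expressed
#' background and (b) the subnetwork members against the whole
#' transcriptome. Every intermediate table is written under
#' `config$out_dir` together with a JSON summary of all set sizes and a
#' log echoing the configuration and seed. Any stage error aborts with
#' the stage name; tables already written are preserved.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with all in-memory stage
#'   outputs and `summary` (the set sizes written to summary.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("apomixnet ", as.character(utils::packageVersion("apomixnet")),
           " | R ", as.character(getRversion()))
  log_line("config_hash=", hash, " seed=", config$seed)
  for (nm in c("ppee", "ppde", "log2fc", "r_cutoff", "hrr_limit", "nvn_steps",
               "evalue", "theta", "epsilon", "s_min", "s_max", "alpha"))
    log_line("  ", nm, "=", format(config[[nm]]))
  set.seed(config$seed)

  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(f) file.path(config$out_dir, f)

  counts <- stage("load", {
    m <- load_input(config$counts, read_expression_matrix)
    expression_matrix(m, unit = attr(m, "unit") %||% "count")
  })
  lengths <- stage("load", load_input(config$lengths, read_transcript_lengths))
  meta <- stage("load", validate_metadata(
    load_input(config$metadata, read_sample_metadata),
    sample_ids = colnames(counts)))

  fpkm <- stage("fpkm", {
    if (identical(attr(counts, "unit"), "count"))
      fpkm_from_counts(counts, lengths) else counts
  })
  stage("fpkm", write_expression_matrix(fpkm, out("fpkm.tsv")))

  partition <- stage("specificity", classify_specific(fpkm, meta,
                                                      epsilon = config$epsilon))
  stage("specificity", write_partition(partition, out("venn_partition.tsv")))
  stage("specificity",
        write_stamped(venn_counts(partition), out("venn_counts.tsv"), hash))

  workflow <- stage("two_step_de", two_step_workflow(
    fpkm, meta, ppee_threshold = config$ppee,
    ppde_threshold = config$ppde, log2fc_threshold = config$log2fc))
  for (nm in names(workflow$comparisons))
    stage("two_step_de", write_posterior_table(
      workflow$comparisons[[nm]], out(paste0("posteriors_", nm, ".tsv"))))

  # consistent DEGs: the two comparisons pitting the apomict class against
  # a sexual class (identified as the class appearing in two comparisons
  # against different partners; with three classes this is unambiguous
  # only by name, so the first class is taken as reference order)
  consistent <- stage("consistent_degs", {
    cmp <- names(workflow$comparisons)
    apo <- grep("apo", workflow$classes, value = TRUE)
    pair_names <- if (length(apo) == 1) {
      grep(paste0("(^", apo, "_vs_)|(_vs_", apo, "$)"), cmp, value = TRUE)
    } else cmp
    if (length(pair_names) < 2) character(0) else
      consistent_degs(workflow$comparisons[[pair_names[1]]],
                      workflow$comparisons[[pair_names[2]]])
  })
  stage("consistent_degs", writeLines(consistent, out("consistent_degs.txt")))

  have_hits <- !is.null(config$hits) && !is.null(config$intervals)
  acr <- candidates <- NULL
  if (have_hits) {
    hits <- stage("hit_filter", load_input(config$hits, parse_hits))
    intervals <- stage("hit_filter",
                       validate_intervals(load_input(config$intervals,
                                                     read_intervals)))
    acr <- stage("hit_filter", filter_hits(hits, intervals,
                                           evalue_cutoff = config$evalue))
    stage("hit_filter",
          write_stamped(acr$per_interval, out("acr_per_interval.tsv"), hash))
    candidates <- stage("candidates",
                        build_candidates(acr$acr_transcripts, partition,
                                         workflow))
    stage("candidates", write_candidates(candidates, out("candidates.tsv")))
  }

  net_matrix <- stage("network_filter",
                      filter_low_expression(fpkm, theta = config$theta))
  graph <- stage("network", hrr_edges(
    pearson_all_pairs(net_matrix, r_cutoff = config$r_cutoff),
    hrr_limit = config$hrr_limit))
  stage("network", write_edge_list(graph, out("network_edges.tsv")))
  stage("network", write_graphml(graph, out("network.graphml")))

  clusters <- stage("hcca", hcca_cluster(graph, nvn_steps = config$nvn_steps,
                                         s_min = config$s_min,
                                         s_max = config$s_max))
  stage("hcca", write_cluster_membership(clusters, out("clusters.tsv")))

  subnet <- NULL
  if (!is.null(candidates) && length(candidates$seed_transcripts)) {
    subnet <- stage("subnetwork", suppressWarnings(
      extract_subnetwork(graph, candidates$seed_transcripts)))
    stage("subnetwork", writeLines(subnet$members, out("subnetwork_members.txt")))
    stage("subnetwork", write_stamped(subnet$edges,
                                      out("subnetwork_edges.tsv"), hash))
  }

  enrich_degs <- enrich_subnet <- NULL
  if (!is.null(config$go_map)) {
    annot <- stage("enrichment", load_input(config$go_map, read_annotation_map))
    if (length(consistent))
      enrich_degs <- stage("enrichment", hypergeometric_enrich(
        consistent, workflow$common_expressed, annot, alpha = config$alpha))
    if (!is.null(subnet) && length(subnet$members))
      enrich_subnet <- stage("enrichment", hypergeometric_enrich(
        subnet$members, rownames(counts), annot, alpha = config$alpha))
    if (!is.null(enrich_degs))
      stage("enrichment",
            write_enrichment(enrich_degs, out("enrichment_consistent_degs.tsv")))
    if (!is.null(enrich_subnet))
      stage("enrichment",
            write_enrichment(enrich_subnet, out("enrichment_subnetwork.tsv")))
  }

  summary <- list(
    config_hash = hash,
    seed = config$seed,
    n_transcripts = nrow(counts),
    n_samples = ncol(counts),
    specific = lapply(partition$specific, length),
    venn_cells = length(partition$cells),
    step1_retained = lapply(workflow$step1_retained, length),
    common_expressed = length(workflow$common_expressed),
    de_calls = lapply(workflow$comparisons,
                      function(f) sum(f$table$call != "not_DE")),
    consistent_degs = length(consistent),
    acr_transcripts = if (!is.null(acr)) length(acr$acr_transcripts) else NULL,
    seed_transcripts = if (!is.null(candidates))
      length(candidates$seed_transcripts) else NULL,
    network_nodes = length(graph$nodes),
    network_edges = nrow(graph$edges),
    clusters = length(clusters$clusters),
    unassigned = length(clusters$unassigned),
    subnetwork_members = if (!is.null(subnet)) length(subnet$members) else NULL,
    subnetwork_edges = if (!is.null(subnet)) nrow(subnet$edges) else NULL,
    enriched_terms_consistent = if (!is.null(enrich_degs))
      sum(enrich_degs$enriched) else NULL,
    enriched_terms_subnetwork = if (!is.null(enrich_subnet))
      sum(enrich_subnet$enriched) else NULL)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       null = "null")
  log_line("done")
  structure(list(counts = counts, fpkm = fpkm, meta = meta,
                 partition = partition, workflow = workflow,
                 consistent_degs = consistent, acr = acr,
                 candidates = candidates, graph = graph, clusters = clusters,
                 subnetwork = subnet, enrichment_degs = enrich_degs,
                 enrichment_subnetwork = enrich_subnet,
                 summary = summary, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run summary\n")
  s <- x$summary
  flat <- unlist(s[setdiff(names(s), "config_hash")])
  for (nm in names(flat)) cat(sprintf("  %s: %s\n", nm, flat[[nm]]))
  invisible(x)
}
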