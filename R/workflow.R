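#' Two-step differential-expression workflow across phenotypic classes
#'
#' Step 1 screens out genotype-driven expression differences: within every
#' phenotypic class having at least two genotypes, each genotype pair is
#' tested with [fit_two_group()] (clones as replicates) and only
#' transcripts posterior-equally-expressed (PPEE >= `ppee_threshold`) in
#' every pair of the class are retained; a transcript with zero counts in
#' both genotypes of a pair carries no evidence of genotype effect and is
#' retained. Classes with a single genotype skip step 1 and retain all
#' their expressed transcripts. The transcripts retained and expressed in
#' every class form `common_expressed`. Step 2 then runs the pairwise
#' class comparisons restricted to `common_expressed`.
#'
#' "Expressed in a class" means a value > 0 in at least one sample of the
#' class.
#'
#' @param counts expression matrix (counts, or FPKM which is rounded by
#'   the test engine).
#' @param meta sample metadata covering all matrix samples.
#' @param ppee_threshold step-1 retention threshold (default 0.95).
#' @param ppde_threshold,log2fc_threshold step-2 call thresholds passed to
#'   [fit_two_group()] (defaults 0.95 and 1.5).
#' @param classes optional subset/order of phenotypic classes to analyze.
#' @return list of class `workflow_result`: `step1_retained` (per class),
#'   `expressed_by_class`, `common_expressed`, `comparisons` (named list of
#'   `eb_fit`s for each class pair, names `A_vs_B`), `step1_fits`.
#' @export
two_step_workflow <- function(counts, meta,
                              ppee_threshold = 0.95,
                              ppde_threshold = 0.95,
                              log2fc_threshold = 1.5,
                              classes = NULL) {
  meta <- validate_metadata(meta, sample_ids = colnames(counts))
  meta <- meta[meta$sample_id %in% colnames(counts), ]
  if (is.null(classes)) classes <- unique(meta$phenotypic_class)
  miss <- setdiff(classes, meta$phenotypic_class)
  if (length(miss))
    stop("class absent from metadata: ", paste(miss, collapse = ", "))
  if (length(classes) < 2) stop("need at least 2 phenotypic classes")

  samples_of <- function(cl) meta$sample_id[meta$phenotypic_class == cl]
  expressed_by_class <- lapply(stats::setNames(classes, classes), function(cl) {
    sub <- counts[, samples_of(cl), drop = FALSE]
    rownames(counts)[rowSums(sub > 0) >= 1]
  })

  step1_retained <- list()
  step1_fits <- list()
  for (cl in classes) {
    genos <- unique(meta$genotype[meta$phenotypic_class == cl])
    if (length(genos) < 2) {           # single genotype: nothing to screen
      step1_retained[[cl]] <- expressed_by_class[[cl]]
      next
    }
    keep <- rownames(counts)
    for (pair in utils::combn(genos, 2, simplify = FALSE)) {
      a <- meta$sample_id[meta$genotype == pair[1]]
      b <- meta$sample_id[meta$genotype == pair[2]]
      fit <- fit_two_group(counts[, c(a, b), drop = FALSE], a, b,
                           ppde_threshold = ppde_threshold,
                           log2fc_threshold = log2fc_threshold)
      step1_fits[[paste0(cl, ":", pair[1], "_vs_", pair[2])]] <- fit
      ok <- is.na(fit$table$PPEE) | fit$table$PPEE >= ppee_threshold
      keep <- intersect(keep, fit$table$transcript_id[ok])
    }
    step1_retained[[cl]] <- keep
  }

  common_expressed <- Reduce(intersect, lapply(classes, function(cl)
    intersect(step1_retained[[cl]], expressed_by_class[[cl]])))

  comparisons <- list()
  for (pair in utils::combn(classes, 2, simplify = FALSE)) {
    a <- samples_of(pair[1]); b <- samples_of(pair[2])
    comparisons[[comparison_label(pair[1], pair[2])]] <-
      fit_two_group(counts[common_expressed, c(a, b), drop = FALSE], a, b,
                    ppde_threshold = ppde_threshold,
                    log2fc_threshold = log2fc_threshold)
  }
  structure(list(step1_retained = step1_retained,
                 expressed_by_class = expressed_by_class,
                 common_expressed = common_expressed,
                 comparisons = comparisons,
                 step1_fits = step1_fits,
                 classes = classes),
            class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("Two-step DE workflow over classes:",
      paste(x$classes, collapse = ", "), "\n")
  for (cl in names(x$step1_retained))
    cat(sprintf("  step-1 retained [%s]: %d\n", cl,
                length(x$step1_retained[[cl]])))
  cat("  common expressed:", length(x$common_expressed), "\n")
  for (nm in names(x$comparisons)) {
    tab <- x$comparisons[[nm]]$table
    cat(sprintf("  %s: %d DE calls\n", nm, sum(tab$call != "not_DE")))
  }
  invisible(x)
}

#' Transcripts called differentially expressed in a posterior table
#' @param fit an `eb_fit` or posterior table data.frame.
#' @return character vector of DE-called transcript ids.
#' @export
de_called <- function(fit) {
  if (is.null(fit)) stop("NULL posterior table (check the comparison name)")
  tab <- if (inherits(fit, "eb_fit")) fit$table else fit
  tab$transcript_id[tab$call != "not_DE"]
}

#' Consistently differentially expressed transcripts
#'
#' Intersection of the DE-called sets of two pairwise comparisons —
#' typically the apomict class against each of the two sexual classes, so
#' membership does not depend on the sexual sample's ploidy.
#'
#' @param fit_a,fit_b `eb_fit`s or posterior tables over the same
#'   transcript universe.
#' @return character vector of transcripts DE in both comparisons.
#' @export
consistent_degs <- function(fit_a, fit_b) {
  sort(intersect(de_called(fit_a), de_called(fit_b)))
}
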