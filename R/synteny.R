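#' Parse a 12-column tabular alignment hit file
#'
#' Reads the standard tab-separated alignment output (query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Subject start may
#' exceed subject end for minus-strand hits; the record is stored as-is
#' and a `minus_strand` flag derived. Malformed lines are collected and
#' reported with their line numbers; parsing continues, but if more than
#' 10% of lines are malformed an error is raised at the end.
#'
#' @param path file path.
#' @return data.frame of typed hit records with attribute `malformed`
#'   (integer line numbers skipped).
#' @export
parse_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 12L
  if (any(!ok)) {
    bad <- which(!ok)
    warning(length(bad), " malformed line(s) skipped (expected 12 columns): ",
            paste(utils::head(bad, 10), collapse = ", "))
    if (mean(!ok) > 0.10)
      stop("more than 10% of lines malformed in ", path)
  }
  if (!any(ok)) {
    hits <- data.frame(query_id = character(), subject_id = character(),
                       pident = numeric(), length = integer(),
                       mismatch = integer(), gapopen = integer(),
                       qstart = integer(), qend = integer(),
                       sstart = integer(), send = integer(),
                       evalue = numeric(), bitscore = numeric(),
                       minus_strand = logical())
    attr(hits, "malformed") <- which(!ok)
    return(hits)
  }
  m <- do.call(rbind, fields[ok])
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) stop("negative e-value in ", path)
  hits$minus_strand <- hits$sstart > hits$send
  attr(hits, "malformed") <- which(!ok)
  hits
}

#' Read marker-delimited intervals
#'
#' Native format: TSV with header `chrom start end label` and 1-based
#' inclusive coordinates (declare with a leading comment line
#' `#coords=1-based-inclusive`). BED input (`.bed`, 0-based half-open, no
#' header) is converted to 1-based inclusive on read.
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end`, `label` (1-based
#'   inclusive), unique labels, start <= end.
#' @export
read_intervals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    iv <- data.frame(chrom = df[[1]],
                     start = as.integer(df[[2]]) + 1L,  # 0-based half-open in
                     end = as.integer(df[[3]]),
                     label = if (ncol(df) >= 4) df[[4]] else
                       paste0("iv", seq_len(nrow(df))),
                     stringsAsFactors = FALSE)
  } else {
    iv <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  validate_intervals(iv)
}

validate_intervals <- function(iv) {
  need <- c("chrom", "start", "end", "label")
  if (!all(need %in% colnames(iv)))
    stop("intervals need columns: ", paste(need, collapse = ", "))
  if (any(iv$start > iv$end)) stop("interval start exceeds end")
  if (anyDuplicated(iv$label)) stop("interval labels must be unique")
  iv
}

#' Filter alignment hits to marker-delimited intervals
#'
#' Keeps hits with e-value <= `evalue_cutoff` whose subject span
#' (min to max of subject start/end, so strand does not matter) overlaps
#' an interval on the same chromosome by at least 1 bp. A query is in the
#' returned set if any of its hits qualifies.
#'
#' @param hits hit table from [parse_hits()].
#' @param intervals interval table from [read_intervals()].
#' @param evalue_cutoff maximum e-value (default 1e-05).
#' @return list: `acr_transcripts` (sorted unique query ids),
#'   `per_interval` (data.frame label, n_hits, n_queries), `kept_hits`
#'   (qualifying hit rows with an `interval` column).
#' @export
filter_hits <- function(hits, intervals, evalue_cutoff = 1e-05) {
  stopifnot(evalue_cutoff > 0)
  intervals <- validate_intervals(intervals)
  lo <- pmin(hits$sstart, hits$send)
  hi <- pmax(hits$sstart, hits$send)
  pass_e <- hits$evalue <= evalue_cutoff
  kept <- list()
  per_interval <- data.frame(label = intervals$label,
                             n_hits = 0L, n_queries = 0L,
                             stringsAsFactors = FALSE)
  for (k in seq_len(nrow(intervals))) {
    ov <- pass_e & hits$subject_id == intervals$chrom[k] &
      lo <= intervals$end[k] & hi >= intervals$start[k]
    per_interval$n_hits[k] <- sum(ov)
    per_interval$n_queries[k] <- length(unique(hits$query_id[ov]))
    if (any(ov)) {
      h <- hits[ov, , drop = FALSE]
      h$interval <- intervals$label[k]
      kept[[length(kept) + 1L]] <- h
    }
  }
  kept_hits <- if (length(kept)) do.call(rbind, kept) else
    cbind(hits[0, , drop = FALSE], interval = character(0))
  rownames(kept_hits) <- NULL
  list(acr_transcripts = sort(unique(kept_hits$query_id)),
       per_interval = per_interval,
       kept_hits = kept_hits)
}

#' Assemble the candidate seed list
#'
#' Intersects the interval-filtered (putative ACR) transcripts with the
#' class-specific sets and the DE calls of every pairwise comparison.
#' Seeds are ACR transcripts that are specific to some class and/or DE in
#' some comparison; a transcript contributing through several sources
#' appears once, with one provenance flag per source.
#'
#' @param acr_set character vector of interval-qualified transcript ids.
#' @param partition a `venn_partition` (or NULL).
#' @param workflow a `workflow_result` (or NULL).
#' @return list of class `candidate_set`: `acr_transcripts`,
#'   `seed_transcripts`, `provenance` (data.frame transcript_id, source).
#' @export
build_candidates <- function(acr_set, partition = NULL, workflow = NULL) {
  prov <- list()
  if (!is.null(partition)) {
    for (cl in names(partition$specific)) {
      ids <- intersect(acr_set, partition$specific[[cl]])
      if (length(ids))
        prov[[length(prov) + 1L]] <- data.frame(
          transcript_id = ids, source = paste0("specific:", cl),
          stringsAsFactors = FALSE)
    }
  }
  if (!is.null(workflow)) {
    for (nm in names(workflow$comparisons)) {
      ids <- intersect(acr_set, de_called(workflow$comparisons[[nm]]))
      if (length(ids))
        prov[[length(prov) + 1L]] <- data.frame(
          transcript_id = ids, source = paste0("DE:", nm),
          stringsAsFactors = FALSE)
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(transcript_id = character(), source = character(),
               stringsAsFactors = FALSE)
  structure(list(acr_transcripts = sort(unique(acr_set)),
                 seed_transcripts = sort(unique(provenance$transcript_id)),
                 provenance = provenance),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d ACR transcripts, %d seeds\n",
              length(x$acr_transcripts), length(x$seed_transcripts)))
  if (nrow(x$provenance))
    print(table(x$provenance$source))
  invisible(x)
}

#' Write the candidate table (transcript_id, is_seed, sources)
#' @param candidates a `candidate_set`.
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  src <- vapply(candidates$acr_transcripts, function(id) {
    s <- candidates$provenance$source[candidates$provenance$transcript_id == id]
    paste(s, collapse = ";")
  }, character(1))
  df <- data.frame(transcript_id = candidates$acr_transcripts,
                   is_seed = candidates$acr_transcripts %in%
                     candidates$seed_transcripts,
                   sources = src, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
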