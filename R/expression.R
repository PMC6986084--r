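#' Validate a transcript-by-sample expression matrix
#'
#' Expression data are held as a plain numeric matrix with transcript ids as
#' row names and sample ids as column names, plus a `unit` attribute
#' (`"count"` or `"fpkm"`). This helper enforces the container invariants:
#' unique ids, no negative or missing values, consistent dimensions.
#'
#' @param x numeric matrix, transcripts in rows, samples in columns.
#' @param unit expression unit, `"count"` or `"fpkm"`. If `NULL` the matrix
#'   must already carry a `unit` attribute.
#' @return the matrix, with its `unit` attribute set.
#' @export
expression_matrix <- function(x, unit = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs transcript row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicated transcript ids in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample ids in expression matrix")
  if (anyNA(x))
    stop("expression matrix contains missing values")
  if (any(x < 0))
    stop("expression matrix contains negative values")
  unit <- unit %||% attr(x, "unit")
  if (is.null(unit) || !unit %in% c("count", "fpkm"))
    stop("unit must be \"count\" or \"fpkm\"")
  attr(x, "unit") <- unit
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is tab-separated with a header row of sample ids and a
#' first column `transcript_id`.
#'
#' @param path file path.
#' @param unit unit of the stored values.
#' @return for the reader, a validated expression matrix.
#' @export
read_expression_matrix <- function(path, unit = c("count", "fpkm")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (colnames(df)[1] != "transcript_id")
    stop("expected first column 'transcript_id' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  expression_matrix(m, unit = unit)
}

#' @rdname read_expression_matrix
#' @param x expression matrix to write.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(transcript_id = rownames(x), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' One row per sample with columns `sample_id`, `genotype`, `clone`,
#' `tissue`, `phenotypic_class`. Every matrix sample must have exactly one
#' record and each genotype must belong to exactly one phenotypic class.
#'
#' @param path TSV file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_metadata(meta)
}

validate_metadata <- function(meta, sample_ids = NULL) {
  need <- c("sample_id", "genotype", "clone", "tissue", "phenotypic_class")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata")
  g2c <- unique(meta[, c("genotype", "phenotypic_class")])
  if (anyDuplicated(g2c$genotype))
    stop("a genotype maps to more than one phenotypic class")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, meta$sample_id)
    if (length(miss))
      stop("samples without metadata: ", paste(miss, collapse = ", "))
  }
  meta
}

#' Read transcript lengths
#'
#' @param path TSV with columns `transcript_id`, `length` (bp, >= 1).
#' @return named integer vector of lengths.
#' @export
read_transcript_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("transcript_id", "length") %in% colnames(df)))
    stop("expected columns transcript_id, length")
  if (any(df$length < 1)) stop("transcript lengths must be >= 1")
  stats::setNames(as.numeric(df$length), df$transcript_id)
}

#' FPKM from raw counts
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \deqn{FPKM_{g,i} = 10^9 \, C_{g,i} / (N_i \, L_g)}
#' where `C` is the fragment count, `N_i` the total mapped fragments of
#' sample `i` (taken as the column sum) and `L_g` the transcript length in
#' bp.
#'
#' @param counts count expression matrix.
#' @param lengths named numeric vector of transcript lengths (bp); every
#'   transcript in `counts` must be present.
#' @return expression matrix in FPKM units.
#' @export
fpkm_from_counts <- function(counts, lengths) {
  counts <- expression_matrix(counts, unit = attr(counts, "unit") %||% "count")
  if (!identical(attr(counts, "unit"), "count"))
    stop("fpkm_from_counts expects a count matrix")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing transcript lengths for: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  L <- lengths[rownames(counts)]
  if (any(L <= 0)) stop("transcript lengths must be positive")
  N <- colSums(counts)
  if (any(N == 0))
    stop("zero total fragments in sample(s): ",
         paste(colnames(counts)[N == 0], collapse = ", "))
  fpkm <- 1e9 * sweep(counts / L, 2, N, "/")
  expression_matrix(fpkm, unit = "fpkm")
}

#' Drop transcripts with mostly-zero expression
#'
#' Removes transcripts whose fraction of zero-valued samples is strictly
#' greater than `theta`; a transcript with zeros in exactly
#' `theta * ncol` samples is retained. Row order of survivors is preserved.
#'
#' @param x expression matrix.
#' @param theta maximum tolerated zero fraction, in \[0, 1\] (default 0.5).
#' @return filtered expression matrix.
#' @export
filter_low_expression <- function(x, theta = 0.5) {
  stopifnot(theta >= 0, theta <= 1)
  zero_frac <- rowMeans(x == 0)
  expression_matrix(x[zero_frac <= theta, , drop = FALSE],
                    unit = attr(x, "unit"))
}

#' Partition transcripts by the groups they are expressed in
#'
#' A transcript counts as "expressed in group G" when its value exceeds
#' `epsilon` in at least one sample of every genotype of G
#' (`rule = "all_genotypes"`, the default), or in at least one sample of G
#' overall (`rule = "any_sample"`). Each transcript expressed in at least
#' one group is assigned to exactly one Venn cell: the exact subset of
#' groups it is expressed in. Cells whose subset is a single group are that
#' group's class-specific set.
#'
#' @param x expression matrix.
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param epsilon detection threshold; expressed means value > epsilon
#'   (default 0, i.e. strict positivity).
#' @param group_by metadata grouping: `"phenotypic_class"` or
#'   `"class_tissue"` (class crossed with tissue).
#' @param rule detection rule, see Details.
#' @return an object of class `venn_partition`: list with `groups`
#'   (character vector of group labels), `cells` (named list mapping a
#'   subset label `"A+B"` to a character vector of transcript ids) and
#'   `specific` (named list, one id vector per single-group cell).
#' @export
classify_specific <- function(x, meta, epsilon = 0,
                              group_by = c("phenotypic_class", "class_tissue"),
                              rule = c("all_genotypes", "any_sample")) {
  stopifnot(epsilon >= 0)
  group_by <- match.arg(group_by)
  rule <- match.arg(rule)
  meta <- validate_metadata(meta, sample_ids = colnames(x))
  meta <- meta[match(colnames(x), meta$sample_id), ]
  grp <- if (group_by == "phenotypic_class") meta$phenotypic_class else
    paste(meta$phenotypic_class, meta$tissue, sep = ":")
  groups <- sort(unique(grp))

  # logical transcripts x groups: expressed in group?
  expressed <- matrix(FALSE, nrow(x), length(groups),
                      dimnames = list(rownames(x), groups))
  for (g in groups) {
    idx <- which(grp == g)
    if (!length(idx)) stop("group with zero samples: ", g)
    if (rule == "any_sample") {
      expressed[, g] <- rowSums(x[, idx, drop = FALSE] > epsilon) >= 1
    } else {
      res <- rep(TRUE, nrow(x))
      for (gt in unique(meta$genotype[idx])) {
        cols <- idx[meta$genotype[idx] == gt]
        res <- res & (rowSums(x[, cols, drop = FALSE] > epsilon) >= 1)
      }
      expressed[, g] <- res
    }
  }

  any_expr <- rowSums(expressed) > 0
  key <- if (!any(any_expr)) character(0) else
    apply(expressed[any_expr, , drop = FALSE], 1,
          function(e) paste(groups[e], collapse = "+"))
  cells <- split(rownames(x)[any_expr], key)
  specific <- cells[names(cells) %in% groups]
  structure(list(groups = groups, cells = cells,
                 specific = specific[order(match(names(specific), groups))]),
            class = "venn_partition")
}

#' Tabulate Venn cell sizes
#'
#' @param partition a `venn_partition` from [classify_specific()].
#' @return data.frame with one row per non-empty cell: `subset`, `count`.
#'   Counts sum to the number of transcripts expressed in at least one
#'   group.
#' @export
venn_counts <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  if (!length(partition$cells))
    return(data.frame(subset = character(), count = integer(),
                      stringsAsFactors = FALSE))
  data.frame(subset = names(partition$cells),
             count = lengths(partition$cells),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over groups:", paste(x$groups, collapse = ", "), "\n")
  print(venn_counts(x))
  invisible(x)
}

#' Write a Venn partition as TSV (transcript_id, subset)
#' @param partition a `venn_partition`.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(
    transcript_id = unlist(partition$cells, use.names = FALSE),
    subset = rep(names(partition$cells), lengths(partition$cells)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
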