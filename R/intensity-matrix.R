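#' Intensity matrix container
#'
#' A light container for a variables-by-samples intensity table.  Rows are
#' variables (probes, clones, bins), columns are samples.  The `scale` flag
#' records whether values are raw (strictly positive) intensities or base-2
#' logarithms; all statistics in the package (log-ratios, M-values) are
#' computed on the log2 scale.  An optional block structure records
#' contiguous runs of variables that form independent ordered units
#' (e.g. chromosomes); the hidden Markov chain is restarted at every block
#' boundary.
#'
#' @param values numeric matrix, variables in rows, samples in columns.
#' @param variable_ids character vector of unique row identifiers; defaults
#'   to existing rownames or `v1..vn`.
#' @param sample_ids character vector of column identifiers; defaults to
#'   existing colnames or `s1..ss`.
#' @param scale `"raw"` (strictly positive intensities) or `"log2"`.
#' @param blocks integer vector of length `nrow(values)` assigning each
#'   variable to a block; must be constant on contiguous runs.  Default: a
#'   single block.
#' @return An object of class `IntensityMatrix`: a list with elements
#'   `values`, `scale` and `blocks`.
#' @examples
#' m <- intensity_matrix(matrix(2^rnorm(20, 9), 10, 2), scale = "raw")
#' lm2 <- to_log2(m)
#' @export
intensity_matrix <- function(values, variable_ids = NULL, sample_ids = NULL,
                             scale = c("raw", "log2"), blocks = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  s <- ncol(values)
  if (is.null(variable_ids)) {
    variable_ids <- rownames(values)
    if (is.null(variable_ids)) variable_ids <- paste0("v", seq_len(n))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(s))
  }
  if (length(variable_ids) != n)
    stop("length(variable_ids) does not match nrow(values)")
  if (length(sample_ids) != s)
    stop("length(sample_ids) does not match ncol(values)")
  if (anyDuplicated(variable_ids))
    stop("duplicate variable id: ",
         variable_ids[duplicated(variable_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyNA(values)) stop("values must not contain missing entries")
  if (scale == "raw" && any(values <= 0))
    stop("raw-scale intensities must be strictly positive")
  if (is.null(blocks)) blocks <- rep.int(1L, n)
  blocks <- as.integer(blocks)
  if (length(blocks) != n) stop("blocks must have one entry per variable")
  if (any(blocks[-1L] != blocks[-n] & duplicated(blocks)[-1L]))
    stop("blocks must partition the variable range into contiguous runs")
  dimnames(values) <- list(variable_ids, sample_ids)
  structure(list(values = values, scale = scale, blocks = blocks),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf("IntensityMatrix: %d variables x %d samples (%s scale, %d block%s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              length(unique(x$blocks)),
              if (length(unique(x$blocks)) == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

variable_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Convert a raw intensity matrix to log2 scale
#'
#' @param m an [intensity_matrix()] on the raw scale (all values > 0).
#' @return An `IntensityMatrix` on the log2 scale with the same ids and
#'   block structure.
#' @export
to_log2 <- function(m) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale == "log2") stop("matrix is already log2")
  if (any(m$values <= 0))
    stop("cannot log-transform non-positive intensities")
  out <- m
  out$values <- log2(m$values)
  out$scale <- "log2"
  out
}

#' Read an intensity matrix from a tab-separated file
#'
#' Expected layout: a header row of sample ids, a first column `id` of
#' variable identifiers, optional `chrom` and `pos` columns immediately
#' after `id` (rows are then sorted by chromosome and position and each
#' chromosome becomes one order block), then one numeric column per sample.
#' Variables with any missing value (empty cell or `NA`) are dropped; the
#' number removed is available as `attr(x, "dropped")`.
#'
#' @param path file path.
#' @param scale declared scale of the stored values, `"raw"` or `"log2"`.
#' @return An `IntensityMatrix` with attribute `dropped` (count of removed
#'   rows).
#' @export
read_intensity_matrix <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed matrix file: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate variable id in ", path, ": ",
         ids[duplicated(ids)][1L])
  df <- df[-1L]
  has_coords <- all(c("chrom", "pos") %in% names(df)[1:2])
  if (has_coords) {
    chrom <- df[["chrom"]]
    pos <- suppressWarnings(as.numeric(df[["pos"]]))
    if (anyNA(pos)) stop("non-numeric 'pos' value in ", path)
    df <- df[setdiff(names(df), c("chrom", "pos"))]
  }
  vals <- matrix(NA_real_, nrow(df), ncol(df),
                 dimnames = list(ids, names(df)))
  for (j in seq_along(df)) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   col[bad[1L]], ids[bad[1L]], names(df)[j]))
    vals[, j] <- num
  }
  keep <- !apply(is.na(vals), 1L, any)
  dropped <- sum(!keep)
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) == 0L) stop("no complete rows in ", path)
  blocks <- NULL
  if (has_coords) {
    chrom <- chrom[keep]
    pos <- pos[keep]
    ord <- order(chrom, pos)
    vals <- vals[ord, , drop = FALSE]
    blocks <- as.integer(factor(chrom[ord], levels = unique(chrom[ord])))
  }
  out <- intensity_matrix(vals, scale = scale, blocks = blocks)
  attr(out, "dropped") <- dropped
  out
}

#' Write an intensity matrix as tab-separated text
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the doubles exactly.
#'
#' @param m an `IntensityMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(m, path) {
  stopifnot(inherits(m, "IntensityMatrix"))
  txt <- format(m$values, digits = 17, trim = TRUE, scientific = FALSE)
  df <- data.frame(id = variable_ids(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", sample_ids(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample-to-arm design
#'
#' Assigns each sample of an experiment to the treatment or the reference
#' arm.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param arm character vector, one of `"treatment"`/`"reference"` per
#'   sample.
#' @return An object of class `GroupDesign`: a data frame with columns
#'   `sample_id` and `arm`.
#' @export
group_design <- function(sample_ids, arm) {
  sample_ids <- as.character(sample_ids)
  arm <- as.character(arm)
  if (length(sample_ids) != length(arm))
    stop("sample_ids and arm must have the same length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in design: ",
         sample_ids[duplicated(sample_ids)][1L])
  ok <- arm %in% c("treatment", "reference")
  if (!all(ok))
    stop("unknown arm label: ", arm[!ok][1L])
  if (!any(arm == "treatment") || !any(arm == "reference"))
    stop("design needs at least one treatment and one reference sample")
  structure(data.frame(sample_id = sample_ids, arm = arm,
                       stringsAsFactors = FALSE),
            class = c("GroupDesign", "data.frame"))
}

#' Read a two-column (sample_id, arm) design file
#'
#' @param path tab-separated file with columns `sample_id` and `arm`.
#' @return A [group_design()] object.
#' @export
read_group_design <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "arm") %in% names(df)))
    stop("design file must have columns 'sample_id' and 'arm'")
  group_design(df$sample_id, df$arm)
}

arm_ids <- function(d, which) d$sample_id[d$arm == which]

# check that every design sample is a column of m and vice versa
check_design <- function(m, d) {
  miss <- setdiff(d$sample_id, sample_ids(m))
  if (length(miss)) stop("design sample not in matrix: ", miss[1L])
  extra <- setdiff(sample_ids(m), d$sample_id)
  if (length(extra)) stop("matrix sample not in design: ", extra[1L])
  invisible(TRUE)
}

#' Record a keyed analysis result with provenance
#'
#' A minimal carrier for scalar/vector results plus the method name,
#' parameters and seed that produced them; serializes losslessly to JSON.
#'
#' @param method method label.
#' @param values named list of numeric scalars or vectors.
#' @param parameters named list of parameters used.
#' @param seed integer seed or `NULL`.
#' @return An object of class `ResultRecord`.
#' @export
result_record <- function(method, values, parameters = list(), seed = NULL) {
  stopifnot(is.character(method), length(method) == 1L, is.list(values))
  structure(list(method = method, values = values,
                 parameters = parameters, seed = seed),
            class = "ResultRecord")
}

#' Write a `ResultRecord` to JSON (full double precision)
#'
#' @param x a [result_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  stopifnot(inherits(x, "ResultRecord"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a `ResultRecord` back from JSON
#'
#' @param path JSON path written by [write_result()].
#' @return A `ResultRecord`.
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  result_record(x$method, as.list(x$values),
                as.list(x$parameters), x$seed)
}
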