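#' Per-sample reaction abundance datasets
#'
#' A `sample_dataset` holds, for each sample, a multiset of reaction tokens:
#' each row of `counts` records a (sample, reaction) pair with an integer
#' multiplicity, and a token is one instance of a reaction in a sample --
#' the unit that receives a (metabosystem, subnetwork) label during
#' inference. `I[n]` is the total token count of sample n.
#'
#' @param sample_ids Character vector of distinct sample identifiers.
#' @param sample Integer vector of sample indices (per row).
#' @param reaction Integer vector of catalog reaction indices (per row).
#' @param count Integer multiplicities, all >= 1.
#' @param catalog The [reaction_catalog()] the reaction indices refer to.
#' @return An object of class `sample_dataset` with components `sample_ids`,
#'   `counts` (data frame sample/reaction/count) and `I`.
#' @export
sample_dataset <- function(sample_ids, sample, reaction, count, catalog) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_usage("duplicate sample identifiers")
  sample <- as.integer(sample)
  reaction <- as.integer(reaction)
  if (any(count <= 0) || any(count != as.integer(count))) {
    stop_format("all counts must be positive integers")
  }
  count <- as.integer(count)
  N <- length(sample_ids)
  if (any(sample < 1L | sample > N)) stop_reference("sample index out of range")
  if (any(reaction < 1L | reaction > n_reactions(catalog))) {
    stop_reference("reaction index out of range for the catalog")
  }
  # merge duplicate (sample, reaction) rows
  key <- paste(sample, reaction)
  if (anyDuplicated(key)) {
    agg <- rowsum(count, key)
    parts <- matrix(as.integer(unlist(strsplit(rownames(agg), " "))),
                    ncol = 2, byrow = TRUE)
    o <- order(parts[, 1], parts[, 2])
    sample <- parts[o, 1]; reaction <- parts[o, 2]
    count <- as.integer(agg[o, 1])
  }
  I <- integer(N)
  tot <- rowsum(count, sample)
  I[as.integer(rownames(tot))] <- as.integer(tot[, 1])
  if (any(I < 1L)) stop_usage("every sample must contain at least one token")
  structure(
    list(sample_ids = sample_ids,
         counts = data.frame(sample = sample, reaction = reaction,
                             count = count),
         I = I),
    class = "sample_dataset")
}

#' @export
print.sample_dataset <- function(x, ...) {
  cat(sprintf("<sample_dataset> %d samples, %d tokens (%d distinct sample x reaction rows)\n",
              length(x$sample_ids), sum(x$I), nrow(x$counts)))
  invisible(x)
}

n_samples <- function(dataset) length(dataset$sample_ids)
n_tokens <- function(dataset) sum(dataset$I)

#' Read per-sample reaction abundances
#'
#' Expects a tab-separated file with columns `sample_id`, `reaction_id`,
#' `count` (positive integer). `#`-prefixed comment lines are skipped;
#' duplicate (sample, reaction) rows are summed.
#'
#' @param path Path to the file.
#' @param catalog The [reaction_catalog()] the reaction IDs must belong to.
#' @return A [sample_dataset()].
#' @export
read_abundances <- function(path, catalog) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_format(sprintf("no abundance rows in '%s'", path))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 3L)
  if (length(bad) > 0L) {
    stop_format(sprintf("%s line %d: expected 3 tab-separated fields",
                        path, lineno[[bad[[1]]]]))
  }
  sid <- vapply(f, `[[`, "", 1L)
  rid <- vapply(f, `[[`, "", 2L)
  cnt_chr <- vapply(f, `[[`, "", 3L)
  cnt <- suppressWarnings(as.numeric(cnt_chr))
  bad <- which(is.na(cnt) | cnt != floor(cnt) | cnt <= 0)
  if (length(bad) > 0L) {
    stop_format(sprintf("%s line %d: count must be a positive integer (got '%s')",
                        path, lineno[[bad[[1]]]], cnt_chr[[bad[[1]]]]))
  }
  ridx <- match(rid, catalog$reaction_ids)
  if (anyNA(ridx)) {
    missing <- rid[which(is.na(ridx))[1]]
    stop_reference(sprintf("reaction '%s' is not in the catalog", missing))
  }
  sample_ids <- unique(sid)
  sample_dataset(sample_ids,
                 sample = match(sid, sample_ids),
                 reaction = ridx,
                 count = as.integer(cnt),
                 catalog = catalog)
}

#' Write per-sample reaction abundances
#'
#' Inverse of [read_abundances()].
#'
#' @param dataset A [sample_dataset()].
#' @param catalog Its [reaction_catalog()].
#' @param path Output path.
#' @export
write_abundances <- function(dataset, catalog, path) {
  stopifnot(inherits(dataset, "sample_dataset"))
  writeLines(paste(dataset$sample_ids[dataset$counts$sample],
                   catalog$reaction_ids[dataset$counts$reaction],
                   dataset$counts$count, sep = "\t"),
             path, useBytes = TRUE)
  invisible(NULL)
}
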