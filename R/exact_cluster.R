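#' Dereplicate reads at 100% sequence identity
#'
#' Collapses reads into exact OTUs: two reads share an OTU iff their
#' sequences are identical strings — same length, same characters ('N'
#' compares literally). This is the strictest reading of clustering "at
#' 100% similarity"; no substring or length-tolerant matching is done.
#' OTU ids are assigned by rank of first appearance after sorting reads by
#' `(sample_id, read_id)`, so the labelling is deterministic for a given
#' read multiset regardless of input order.
#'
#' @param reads Read table (`read_id`, `sample_id`, `sequence`), e.g. from
#'   [read_fasta()] or a generated cohort.
#' @return An object of class `exact_otus`: a list with
#'   \describe{
#'     \item{otus}{`data.frame(otu_id, representative, n_reads)`}
#'     \item{members}{`data.frame(otu_id, read_id, sample_id)`}
#'   }
#' @examples
#' reads <- data.frame(read_id = c("r1", "r2", "r3"),
#'                     sample_id = "s1",
#'                     sequence = c("ACGT", "ACGT", "ACGA"))
#' dereplicate(reads)$otus
#' @export
dereplicate <- function(reads) {
  validate_reads(reads)
  if (nrow(reads) == 0L) {
    return(structure(list(
      otus = data.frame(otu_id = character(), representative = character(),
                        n_reads = integer(), stringsAsFactors = FALSE),
      members = data.frame(otu_id = character(), read_id = character(),
                           sample_id = character(), stringsAsFactors = FALSE)),
      class = "exact_otus"))
  }
  ord <- order(reads$sample_id, reads$read_id, method = "radix")
  reads <- reads[ord, ]
  seqs <- toupper(reads$sequence)
  reps <- unique(seqs)  # first-appearance order
  idx <- match(seqs, reps)
  ids <- sprintf("OTU%06d", seq_along(reps))
  structure(list(
    otus = data.frame(otu_id = ids, representative = reps,
                      n_reads = tabulate(idx, nbins = length(reps)),
                      stringsAsFactors = FALSE),
    members = data.frame(otu_id = ids[idx], read_id = reads$read_id,
                         sample_id = reads$sample_id,
                         stringsAsFactors = FALSE)),
    class = "exact_otus")
}

#' @export
print.exact_otus <- function(x, ...) {
  cat("exact_otus: ", nrow(x$otus), " OTUs from ", nrow(x$members),
      " reads\n", sep = "")
  invisible(x)
}

#' Build the OTU-by-sample count table
#'
#' @param otus An `exact_otus` object from [dereplicate()].
#' @param manifest A `sample_manifest`; every member's `sample_id` must be
#'   listed there. Columns of the result follow manifest order; samples
#'   with no reads get an all-zero column.
#' @return Integer matrix (OTU x sample) with `otu_id` rownames and
#'   `sample_id` colnames; attribute `representatives` carries the OTU
#'   representative sequences.
#' @export
build_otu_table <- function(otus, manifest) {
  stopifnot(inherits(otus, "exact_otus"))
  manifest <- validate_manifest(as.data.frame(manifest))
  unknown <- setdiff(unique(otus$members$sample_id), manifest$sample_id)
  if (length(unknown))
    stop("OTU members reference sample(s) absent from the manifest: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  counts <- table(factor(otus$members$otu_id, levels = otus$otus$otu_id),
                  factor(otus$members$sample_id, levels = manifest$sample_id))
  m <- matrix(as.integer(counts), nrow = nrow(counts), ncol = ncol(counts),
              dimnames = list(otus$otus$otu_id, manifest$sample_id))
  attr(m, "representatives") <- stats::setNames(otus$otus$representative,
                                                otus$otus$otu_id)
  m
}

#' Write OTU membership and count table to TSV
#'
#' @param otus An `exact_otus` object.
#' @param table OTU count matrix from [build_otu_table()].
#' @param members_path,table_path Output paths (either may be `NULL`).
#' @export
write_otus <- function(otus, table = NULL, members_path = NULL,
                       table_path = NULL) {
  if (!is.null(members_path))
    write_tsv(otus$members, members_path)
  if (!is.null(table_path)) {
    df <- data.frame(otu_id = rownames(table), as.data.frame(table),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, table_path)
  }
  invisible(NULL)
}
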