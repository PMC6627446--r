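# Controlled vocabularies for the cohort design: two body sites, two
# sampling timepoints (baseline / post-intervention), four subject groups.
SITE_LEVELS <- c("saliva", "feces")
TIMEPOINT_LEVELS <- c("F1", "F2")
GROUP_LEVELS <- c("Control", "INR", "IR", "VU")

MANIFEST_COLUMNS <- c("sample_id", "subject_id", "site", "timepoint",
                      "group", "fasta_path")

#' Read an amplicon FASTA file into a read table
#'
#' Parses a (possibly line-wrapped) FASTA file into one row per read.
#' Sequences are uppercased and must use the alphabet `A,C,G,T,N` only;
#' any other character is an error, because downstream clustering is exact
#' string identity and a stray character would silently split clusters.
#'
#' @param path Path to a FASTA file.
#' @param sample_id Sample identifier attached to every read in the file.
#' @return A `data.frame` with columns `read_id`, `sample_id`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "AC", "GT", ">r2", "TTTT"), fa)
#' read_fasta(fa, "s1")
#' @export
read_fasta <- function(path, sample_id) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), sample_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L])
    stop("FASTA format error in ", path, ": line ", line_no[1L],
         " precedes any '>' header")
  rec <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids)  # id = first token of the header
  seqs <- unname(vapply(split(lines[!is_header],
                              factor(rec[!is_header],
                                     levels = seq_along(ids))),
                        paste0, character(1L), collapse = ""))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA format error in ", path, ": empty sequence under header '",
         ids[which(empty)[1L]], "' (line ",
         line_no[is_header][which(empty)[1L]], ")")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA alphabet error in ", path, ": read '", ids[which(bad)[1L]],
         "' contains characters outside {A,C,G,T,N}")
  if (anyDuplicated(ids))
    stop("duplicate read id within sample '", sample_id, "': ",
         ids[duplicated(ids)][1L])
  data.frame(read_id = ids, sample_id = sample_id, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTA
#'
#' @param reads Read table as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  validate_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads))
  need <- c("read_id", "sample_id", "sequence")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    stop("read table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(reads$sequence)))
    stop("empty sequence in read table")
  if (any(grepl("[^ACGTN]", reads$sequence)))
    stop("read sequences must use the alphabet {A,C,G,T,N} only")
  dup <- duplicated(reads[, c("sample_id", "read_id")])
  if (any(dup))
    stop("duplicate read_id within sample: ",
         reads$read_id[dup][1L], " (", reads$sample_id[dup][1L], ")")
  invisible(reads)
}

#' Read and validate a sample manifest
#'
#' The manifest is a tab-separated table with a header row naming the six
#' columns `sample_id`, `subject_id`, `site`, `timepoint`, `group`,
#' `fasta_path`. Lines starting with `#` are ignored. A *paired subject* at
#' a timepoint is one contributing both a saliva and a feces sample there;
#' pairing is the backbone of the co-occurrence analysis.
#'
#' @param path Path to the TSV manifest.
#' @return A validated manifest `data.frame` (class `sample_manifest`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  validate_manifest(df)
}

#' Validate a sample manifest data frame
#'
#' @param df Data frame with the six manifest columns.
#' @return The manifest with class `sample_manifest` prepended.
#' @export
validate_manifest <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(miss))
    stop("manifest schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  df <- df[, MANIFEST_COLUMNS]
  for (col in c("site", "timepoint", "group")) {
    levels <- switch(col, site = SITE_LEVELS, timepoint = TIMEPOINT_LEVELS,
                     group = GROUP_LEVELS)
    bad <- !df[[col]] %in% levels
    if (any(bad))
      stop("manifest validation error: unknown ", col, " '",
           df[[col]][bad][1L], "' (allowed: ",
           paste(levels, collapse = ", "), ")")
  }
  if (anyDuplicated(df$sample_id))
    stop("manifest validation error: duplicate sample_id '",
         df$sample_id[duplicated(df$sample_id)][1L], "'")
  key <- paste(df$subject_id, df$site, df$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    off <- df$subject_id[duplicated(key)][1L]
    stop("manifest validation error: duplicate (subject, site, timepoint) ",
         "for subject '", off, "'")
  }
  rownames(df) <- NULL
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Write a manifest to TSV
#' @param manifest A `sample_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Subjects paired (saliva + feces) at a timepoint
#'
#' @param manifest A `sample_manifest`.
#' @param timepoint `"F1"` or `"F2"`.
#' @return Sorted character vector of subject ids with both sites sampled.
#' @export
paired_subjects <- function(manifest, timepoint) {
  stopifnot(timepoint %in% TIMEPOINT_LEVELS)
  m <- manifest[manifest$timepoint == timepoint, ]
  tab <- table(factor(m$subject_id), factor(m$site, levels = SITE_LEVELS))
  subj <- as.character(rownames(tab)[rowSums(tab > 0) == 2L])
  sort(subj)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
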