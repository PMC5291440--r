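# Reading, writing and encoding fixed-length promoter windows.

#' Construct a set of sequence records
#'
#' Records are stored as a plain `data.frame` with columns `id`, `sequence`,
#' `label` and `tss_index`. Sequences are uppercased and must use the
#' alphabet A, C, G, T, N. `label`, when present, is `"promoter"` or
#' `"nonpromoter"`; `tss_index` is the 1-based position of the transcription
#' start site inside the window (201 for the conventional 251-nt eukaryotic
#' window spanning -200..+50, 61 for the 81-nt bacterial window spanning
#' -60..+20).
#'
#' @param id character vector of record identifiers.
#' @param sequence character vector of DNA sequences (equal length to `id`).
#' @param label optional labels, `"promoter"`/`"nonpromoter"` or `NA`.
#' @param tss_index optional 1-based TSS position within each window.
#' @return a `data.frame` with one row per record.
#' @examples
#' sequence_records("p1", "ACGT")
#' @export
sequence_records <- function(id, sequence, label = NA_character_,
                             tss_index = NA_integer_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop_data("id (%d) and sequence (%d) lengths differ",
              length(id), length(sequence))
  label <- rep_len(as.character(label), length(id))
  tss_index <- rep_len(as.integer(tss_index), length(id))
  validate_sequences(sequence, id)
  bad_lab <- !is.na(label) & !label %in% c("promoter", "nonpromoter")
  if (any(bad_lab))
    stop_data("invalid label '%s' for record '%s' (want promoter/nonpromoter)",
              label[bad_lab][1L], id[bad_lab][1L])
  n <- nchar(sequence)
  bad_tss <- !is.na(tss_index) & (tss_index < 1L | tss_index > n)
  if (any(bad_tss))
    stop_data("tss_index %d outside sequence of length %d for record '%s'",
              tss_index[bad_tss][1L], n[bad_tss][1L], id[bad_tss][1L])
  data.frame(id = id, sequence = sequence, label = label,
             tss_index = tss_index, stringsAsFactors = FALSE)
}

validate_sequences <- function(sequence, id) {
  if (any(nchar(sequence) == 0L))
    stop_data("empty sequence for record '%s'", id[nchar(sequence) == 0L][1L])
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    ch <- regmatches(sequence[bad][1L],
                     regexpr("[^ACGTN]", sequence[bad][1L]))
    stop_data("invalid character '%s' in sequence of record '%s'",
              ch, id[bad][1L])
  }
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet;
#' entry order is preserved and labels are left unset (labels come from
#' which file a record was read from, or from a manifest — never from
#' headers). The record id is the first whitespace-delimited token of the
#' header line.
#'
#' @param path path to a FASTA file (multi-record, wrapped or single-line).
#' @param tss_index optional 1-based TSS position to attach to every record.
#' @return a record `data.frame` as from [sequence_records()]; an empty file
#'   yields zero rows.
#' @export
read_fasta <- function(path, tss_index = NA_integer_) {
  if (!file.exists(path)) stop_data("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop_data("malformed FASTA in '%s': %s",
                                  path, conditionMessage(e)))
  if (length(set) == 0L)
    return(sequence_records(character(), character()))
  ids <- sub("\\s.*$", "", names(set))
  sequence_records(ids, as.character(set), tss_index = tss_index)
}

#' Write records to a FASTA file
#'
#' @param records a record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read or write a label manifest
#'
#' The manifest is two-column tab-delimited text: record id, then label
#' (`promoter` or `nonpromoter`), no header.
#'
#' @param path manifest path.
#' @return for `read_label_manifest`, a `data.frame` with columns `id`,
#'   `label`.
#' @export
read_label_manifest <- function(path) {
  if (!file.exists(path)) stop_data("label manifest not found: %s", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               col.names = c("id", "label"), colClasses = "character"),
    error = function(e) stop_data("malformed label manifest '%s': %s",
                                  path, conditionMessage(e)))
  bad <- !df$label %in% c("promoter", "nonpromoter")
  if (any(bad))
    stop_data("invalid label '%s' for id '%s' in manifest",
              df$label[bad][1L], df$id[bad][1L])
  df
}

#' @rdname read_label_manifest
#' @param records record `data.frame` whose `id`/`label` columns to write.
#' @export
write_label_manifest <- function(records, path) {
  write.table(records[, c("id", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach manifest labels to records
#'
#' @param records record `data.frame`.
#' @param manifest manifest `data.frame` from [read_label_manifest()].
#' @return `records` with the `label` column filled from the manifest.
#' @export
apply_labels <- function(records, manifest) {
  m <- match(records$id, manifest$id)
  if (anyNA(m))
    stop_data("record '%s' has no entry in the label manifest",
              records$id[is.na(m)][1L])
  records$label <- manifest$label[m]
  records
}

#' One-hot encode a DNA sequence
#'
#' Each base becomes a four-dimensional indicator vector in column order
#' A, T, G, C: A = (1,0,0,0), T = (0,1,0,0), G = (0,0,1,0), C = (0,0,0,1).
#' The ambiguous base N encodes as the all-zero row, so it contributes
#' nothing to any filter dot product.
#'
#' @param x a single sequence string, or a one-row record `data.frame`.
#' @return an n x 4 numeric matrix with colnames `A`,`T`,`G`,`C`.
#' @examples
#' encode_one_hot("ATGC")
#' @export
encode_one_hot <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- x$sequence
  }
  x <- toupper(as.character(x))
  stopifnot(length(x) == 1L)
  validate_sequences(x, "<input>")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  m <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  hit <- match(chars, DNA_BASES)        # NA for N
  keep <- !is.na(hit)
  m[cbind(which(keep), hit[keep])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [encode_one_hot()]; all-zero rows decode to `"N"`.
#'
#' @param m an n x 4 matrix with entries in \{0, 1\} and row sums in \{0, 1\}.
#' @return the decoded sequence string.
#' @export
decode_one_hot <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 4L)
    stop_data("one-hot matrix must have 4 columns, got %d", ncol(m))
  if (!all(m %in% c(0, 1)))
    stop_data("one-hot matrix has non-binary entries")
  rs <- rowSums(m)
  if (!all(rs %in% c(0, 1)))
    stop_data("one-hot matrix row %d sums to %g (want 0 or 1)",
              which(!rs %in% c(0, 1))[1L], rs[!rs %in% c(0, 1)][1L])
  out <- rep("N", nrow(m))
  hit <- max.col(m, ties.method = "first")
  out[rs == 1] <- DNA_BASES[hit[rs == 1]]
  paste0(out, collapse = "")
}

# Encode many equal-length sequences into a 3-D array (positions x 4 x n).
# Internal workhorse behind batched forward passes.
encode_set <- function(sequences) {
  n <- length(sequences)
  if (n == 0L) stop_data("cannot encode an empty sequence set")
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop_data("sequences have unequal lengths: %s",
              paste(len, collapse = ", "))
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE),
                         use.names = FALSE), nrow = len, ncol = n)
  arr <- array(0, dim = c(len, 4L, n))
  hit <- match(chars, DNA_BASES)
  keep <- which(!is.na(hit))
  pos <- (keep - 1L) %% len + 1L
  seqi <- (keep - 1L) %/% len + 1L
  arr[cbind(pos, hit[keep], seqi)] <- 1
  arr
}

# TSS-relative coordinate of 1-based position p: r = p - tss_index, so the
# TSS itself is 0 and position 171 of a 251-nt window with tss_index 201
# is -30.
tss_relative <- function(position, tss_index) {
  as.integer(position) - as.integer(tss_index)
}
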