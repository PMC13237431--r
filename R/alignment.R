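#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
#' @importFrom utils read.delim write.table
NULL

# Allowed residue alphabet: the 20 standard amino acids, the alignment gap,
# and 'X' for unknown. 'X' never matches any profile state.
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
ALN_ALPHABET <- c(AA_ALPHABET, "-", "X")

VALID_GROUPS <- c("GROUP_A", "GROUP_B", "QUERY", "REFERENCE_ONLY")

#' Construct a reference-anchored alignment
#'
#' A `ref_alignment` holds a set of aligned, gapped protein sequences together
#' with a column-to-reference-position map anchored on one record, so that a
#' residue number such as "position 27" means the same thing in every
#' downstream analysis. Columns where the reference record carries a gap
#' (insertions relative to the reference) have no reference number: diagnostic
#' analyses skip them and indel analyses consume them.
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (names are record ids; alphabet: 20 amino acids, `-`, `X`).
#' @param meta optional data frame with columns `id`, `species`, `group`
#'   (`group` one of `GROUP_A`, `GROUP_B`, `QUERY`, `REFERENCE_ONLY`). Records
#'   absent from `meta` default to species `NA` and group `QUERY`.
#' @param reference_id id of the record anchoring the 1-based residue
#'   numbering; defaults to the first record.
#' @return an object of class `ref_alignment` with elements `seqs`, `meta`,
#'   `width`, `reference_id`, `col_to_ref` (integer, `NA` at reference-gap
#'   columns) and `ref_to_col` (its inverse over defined columns).
#' @export
ref_alignment <- function(seqs, meta = NULL, reference_id = NULL) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named with non-empty ids", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate record ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(widths), collapse = "-"), ")", call. = FALSE)
  }
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    any(!ch %in% ALN_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    stop("illegal characters (outside 20 AA + '-' + 'X') in: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(reference_id)) reference_id <- names(seqs)[1L]
  if (!reference_id %in% names(seqs)) {
    stop("reference_id '", reference_id, "' not found in alignment",
         call. = FALSE)
  }

  ids <- names(seqs)
  if (is.null(meta)) {
    meta <- data.frame(id = ids, species = NA_character_,
                       group = "QUERY", stringsAsFactors = FALSE)
  } else {
    if (!all(c("id", "species", "group") %in% names(meta))) {
      stop("labels table must have columns id, species, group", call. = FALSE)
    }
    meta <- meta[, c("id", "species", "group")]
    meta[] <- lapply(meta, as.character)
    unknown <- setdiff(meta$group, VALID_GROUPS)
    if (length(unknown)) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(ids, meta$id)
    if (length(missing)) {
      meta <- rbind(meta, data.frame(id = missing, species = NA_character_,
                                     group = "QUERY"))
    }
    meta <- meta[match(ids, meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  }

  ref_chars <- strsplit(seqs[[reference_id]], "", fixed = TRUE)[[1L]]
  nongap <- ref_chars != "-"
  col_to_ref <- rep(NA_integer_, length(ref_chars))
  col_to_ref[nongap] <- seq_len(sum(nongap))
  ref_to_col <- which(nongap)

  structure(list(seqs = seqs, meta = meta, width = unname(widths[1L]),
                 reference_id = reference_id,
                 col_to_ref = col_to_ref, ref_to_col = ref_to_col),
            class = "ref_alignment")
}

#' Read an aligned FASTA file into a reference-anchored alignment
#'
#' @param path aligned protein FASTA. Description lines are split at the first
#'   whitespace; the leading token is the record id.
#' @param reference_id numbering anchor; defaults to the first record.
#' @param labels optional labels table: a data frame or path to a TSV/CSV with
#'   columns `id`, `species`, `group`.
#' @return a [ref_alignment()].
#' @export
read_alignment <- function(path, reference_id = NULL, labels = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs <- stats::setNames(as.character(aa), ids)
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)
  ref_alignment(seqs, meta = labels, reference_id = reference_id)
}

#' Read a labels table (TSV or CSV with columns id, species, group)
#' @param path file path.
#' @return data frame with columns `id`, `species`, `group`.
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Write an alignment back to FASTA (60-column wrapping)
#' @param aln a [ref_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "ref_alignment"))
  aa <- Biostrings::AAStringSet(aln$seqs)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Write a labels table as TSV
#' @param aln a [ref_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(aln, path) {
  write.table(aln$meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Alignment as a character matrix (records x columns)
#' @param aln a [ref_alignment()].
#' @return character matrix with record ids as rownames.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

#' Ungapped length of the reference record
#' @param aln a [ref_alignment()].
#' @return integer.
#' @export
reference_length <- function(aln) length(aln$ref_to_col)

#' Alignment column holding a given reference position
#' @param aln a [ref_alignment()].
#' @param ref_pos 1-based residue number on the reference record.
#' @return 1-based column index (vectorised over `ref_pos`).
#' @export
column_of <- function(aln, ref_pos) {
  stopifnot(inherits(aln, "ref_alignment"))
  n <- reference_length(aln)
  if (any(ref_pos < 1L | ref_pos > n)) {
    stop("reference position out of range 1..", n, call. = FALSE)
  }
  aln$ref_to_col[ref_pos]
}

#' Reference position of a given alignment column (NA at insertion columns)
#' @param aln a [ref_alignment()].
#' @param col 1-based column index.
#' @return 1-based reference position, or `NA` where the reference is gapped.
#' @export
ref_position_of <- function(aln, col) {
  stopifnot(inherits(aln, "ref_alignment"))
  if (any(col < 1L | col > aln$width)) {
    stop("column out of range 1..", aln$width, call. = FALSE)
  }
  aln$col_to_ref[col]
}

#' Extract the sub-alignment spanning a reference region
#'
#' The slice covers the columns of reference positions `ref_start..ref_end`
#' plus any insertion columns strictly inside that span. Residue numbering is
#' rebuilt from 1 on the sliced reference; the original offset is kept in
#' `attr(, "ref_offset")`.
#'
#' @param aln a [ref_alignment()].
#' @param ref_start,ref_end 1-based inclusive reference positions.
#' @return a [ref_alignment()] over the selected columns.
#' @export
slice_region <- function(aln, ref_start, ref_end) {
  stopifnot(inherits(aln, "ref_alignment"))
  n <- reference_length(aln)
  if (ref_start < 1L || ref_end > n || ref_start > ref_end) {
    stop("empty or out-of-range region [", ref_start, ",", ref_end,
         "] for reference of length ", n, call. = FALSE)
  }
  cols <- column_of(aln, ref_start):column_of(aln, ref_end)
  seqs <- vapply(aln$seqs, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1L]][cols], collapse = ""),
    character(1))
  out <- ref_alignment(seqs, meta = aln$meta, reference_id = aln$reference_id)
  attr(out, "ref_offset") <- ref_start - 1L
  out
}

#' Read a region annotation track (TSV: name, start, end; 1-based inclusive)
#'
#' Note the convention: unlike BED, coordinates here are 1-based and
#' end-inclusive residue numbers on the reference protein.
#'
#' @param path TSV file with columns `name`, `start`, `end`.
#' @param aln optional [ref_alignment()] used to range-check the track.
#' @return data frame of regions, checked for overlap.
#' @export
read_regions <- function(path, aln = NULL) {
  reg <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(reg))) {
    stop("region track needs columns name, start, end", call. = FALSE)
  }
  if (any(reg$start < 1L) || any(reg$start > reg$end)) {
    stop("regions must satisfy 1 <= start <= end", call. = FALSE)
  }
  reg <- reg[order(reg$start), , drop = FALSE]
  if (nrow(reg) > 1L && any(reg$start[-1L] <= reg$end[-nrow(reg)])) {
    stop("regions overlap within the annotation track", call. = FALSE)
  }
  if (!is.null(aln) && any(reg$end > reference_length(aln))) {
    stop("region extends beyond reference length ", reference_length(aln),
         call. = FALSE)
  }
  rownames(reg) <- NULL
  reg
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat("Reference-anchored alignment\n")
  cat("  records:   ", nrow(x$meta), "\n", sep = "")
  cat("  width:     ", x$width, " columns\n", sep = "")
  cat("  reference: ", x$reference_id, " (", reference_length(x),
      " residues)\n", sep = "")
  tab <- table(factor(x$meta$group, levels = VALID_GROUPS))
  cat("  groups:    ", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}
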