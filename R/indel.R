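# Lineage-specific indel blocks and pairwise percent identity.
#
# Insertions relative to the reference are maximal runs of reference-gap
# columns where a record carries residues; deletions are maximal runs of
# reference positions where a record is gapped. Records sharing *exactly* the
# same block coordinates are merged into one carrier set; near-identical
# blocks stay separate so calls remain auditable.

#' Detect insertion/deletion blocks relative to the reference frame
#'
#' @param aln a [ref_alignment()].
#' @param min_length blocks shorter than this are dropped (default 3,
#'   suppressing single-gap alignment noise).
#' @return data frame with columns `kind` (`INSERTION`/`DELETION`),
#'   `ref_anchor` (for insertions, the reference position *after which* the
#'   block sits, 0 for an N-terminal insertion; for deletions, the first
#'   deleted reference position), `length`, `carriers` (comma-separated record
#'   ids), sorted by `ref_anchor` then kind.
#' @export
detect_indel_blocks <- function(aln, min_length = 3L) {
  stopifnot(inherits(aln, "ref_alignment"))
  m <- aln_matrix(aln)
  ins_cols <- is.na(aln$col_to_ref)
  blocks <- list()

  add_block <- function(kind, anchor, len, id) {
    key <- paste(kind, anchor, len, sep = ":")
    blocks[[key]] <<- c(blocks[[key]], id)
  }

  # reference position preceding each column (0 before the first)
  prev_ref <- cummax(ifelse(is.na(aln$col_to_ref), 0L, aln$col_to_ref))

  for (id in rownames(m)) {
    row <- m[id, ]
    # insertions: runs of reference-gap columns where this record has residue
    if (any(ins_cols)) {
      r <- rle(ins_cols & row != "-")
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        add_block("INSERTION", prev_ref[starts[k]], r$lengths[k], id)
      }
    }
    # deletions: runs over the reference coordinate (insertion cols skipped)
    if (id != aln$reference_id) {
      gap_at_ref <- row[aln$ref_to_col] == "-"
      r <- rle(gap_at_ref)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        add_block("DELETION", starts[k], r$lengths[k], id)
      }
    }
  }

  if (length(blocks) == 0L) {
    return(data.frame(kind = character(0), ref_anchor = integer(0),
                      length = integer(0), carriers = character(0),
                      stringsAsFactors = FALSE))
  }
  keys <- strsplit(names(blocks), ":", fixed = TRUE)
  out <- data.frame(kind = vapply(keys, `[[`, character(1), 1L),
                    ref_anchor = as.integer(vapply(keys, `[[`, character(1), 2L)),
                    length = as.integer(vapply(keys, `[[`, character(1), 3L)),
                    carriers = vapply(blocks, function(ids)
                      paste(sort(ids), collapse = ","), character(1)),
                    stringsAsFactors = FALSE)
  out <- out[out$length >= min_length, , drop = FALSE]
  out <- out[order(out$ref_anchor, out$kind, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise percent identity under an explicit convention
#'
#' Conventions differ only in the denominator: `"ungapped_columns"` (default)
#' compares only columns where both records carry residues;
#' `"shorter_seq"` divides the same identical-residue count by the shorter
#' ungapped sequence length; `"all_columns"` divides by the full alignment
#' width. `X` is treated as unknown and never counts as identical.
#'
#' @param aln a [ref_alignment()].
#' @param id_x,id_y record ids.
#' @param convention one of `"ungapped_columns"`, `"shorter_seq"`,
#'   `"all_columns"`.
#' @return one-row data frame: `id_x`, `id_y`, `n_identical`, `n_compared`,
#'   `percent` (unrounded), `convention`.
#' @export
pairwise_identity <- function(aln, id_x, id_y,
                              convention = c("ungapped_columns",
                                             "shorter_seq", "all_columns")) {
  stopifnot(inherits(aln, "ref_alignment"))
  convention <- match.arg(convention)
  for (id in c(id_x, id_y)) {
    if (!id %in% names(aln$seqs)) stop("unknown id: ", id, call. = FALSE)
  }
  x <- strsplit(aln$seqs[[id_x]], "", fixed = TRUE)[[1L]]
  y <- strsplit(aln$seqs[[id_y]], "", fixed = TRUE)[[1L]]
  both <- x != "-" & y != "-"
  n_identical <- sum(both & x == y & x != "X")
  n_compared <- switch(convention,
    ungapped_columns = sum(both),
    shorter_seq = min(sum(x != "-"), sum(y != "-")),
    all_columns = aln$width)
  data.frame(id_x = id_x, id_y = id_y, n_identical = n_identical,
             n_compared = n_compared,
             percent = 100 * n_identical / n_compared,
             convention = convention, stringsAsFactors = FALSE)
}

#' Symmetric percent-identity matrix
#'
#' @param aln a [ref_alignment()].
#' @param convention see [pairwise_identity()].
#' @return numeric matrix of percents with record ids as dimnames and 100 on
#'   the diagonal.
#' @export
identity_matrix <- function(aln, convention = "ungapped_columns") {
  ids <- names(aln$seqs)
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      p <- pairwise_identity(aln, ids[i], ids[j], convention)$percent
      m[i, j] <- p; m[j, i] <- p
    }
  }
  m
}
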