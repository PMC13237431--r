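# Diagnostic-site discovery and profile classification.
#
# A diagnostic (fingerprint) position is a reference-numbered alignment
# position whose residue states are invariant within each paralog group and
# disjoint between groups, so that a single residue assigns a query sequence
# to one group. "Consistently and unambiguously" is formalised as
# within-group invariance + between-group disjointness with no gap or X in
# either group (strict mode); relaxed mode allows within-group polymorphism
# and only requires the two state sets to be disjoint.

group_rows <- function(aln, group) aln$meta$id[aln$meta$group == group]

#' Discover positions that distinguish two paralog groups
#'
#' Scans every reference-numbered column (insertion columns carry no reference
#' number and are skipped) and reports those whose states separate the
#' `GROUP_A` records from the `GROUP_B` records.
#'
#' @param aln a [ref_alignment()] with at least one `GROUP_A` and one
#'   `GROUP_B` record.
#' @param strict if `TRUE` (default) a position qualifies only when each group
#'   is fixed for a single residue, the two residues differ, and neither group
#'   carries a gap or `X` there. If `FALSE`, per-group state sets are collected
#'   and the position qualifies when the sets are disjoint (gap/X still
#'   disqualify, since an unknown residue cannot be unambiguous).
#' @param min_group_size smallest accepted group; a warning is issued for
#'   groups smaller than 4, the size below which fixation within a group is
#'   weak evidence.
#' @return a `diagnostic_profile`: data frame with columns `position`,
#'   `state_a`, `state_b` (multi-residue states are concatenated, e.g. "ST"),
#'   `pocket_proximal` (initialised `TRUE`; see [partition_by_pocket()]), plus
#'   attributes `reference_id`, `strict`, `min_group_size`.
#' @export
discover_diagnostic_positions <- function(aln, strict = TRUE,
                                          min_group_size = 2L) {
  stopifnot(inherits(aln, "ref_alignment"))
  a_ids <- group_rows(aln, "GROUP_A")
  b_ids <- group_rows(aln, "GROUP_B")
  if (length(a_ids) == 0L || length(b_ids) == 0L) {
    stop("discovery needs at least one GROUP_A and one GROUP_B record",
         call. = FALSE)
  }
  if (length(a_ids) < min_group_size || length(b_ids) < min_group_size) {
    stop("group sizes (", length(a_ids), ", ", length(b_ids),
         ") below min_group_size = ", min_group_size, call. = FALSE)
  }
  if (length(a_ids) < 4L || length(b_ids) < 4L) {
    warning("fewer than 4 sequences in a group; within-group fixation is ",
            "weak evidence of a diagnostic state", call. = FALSE)
  }

  m <- aln_matrix(aln)
  pos <- integer(0); sa <- character(0); sb <- character(0)
  for (col in which(!is.na(aln$col_to_ref))) {
    ca <- m[a_ids, col]; cb <- m[b_ids, col]
    if (any(c(ca, cb) %in% c("-", "X"))) next
    ua <- unique(ca); ub <- unique(cb)
    ok <- if (strict) {
      length(ua) == 1L && length(ub) == 1L && ua != ub
    } else {
      length(intersect(ua, ub)) == 0L
    }
    if (ok) {
      pos <- c(pos, aln$col_to_ref[col])
      sa <- c(sa, paste(sort(ua), collapse = ""))
      sb <- c(sb, paste(sort(ub), collapse = ""))
    }
  }
  profile <- data.frame(position = pos, state_a = sa, state_b = sb,
                        pocket_proximal = rep(TRUE, length(pos)),
                        stringsAsFactors = FALSE)
  structure(profile, class = c("diagnostic_profile", "data.frame"),
            reference_id = aln$reference_id, strict = strict,
            min_group_size = min(length(a_ids), length(b_ids)))
}

#' Mark pocket-distal positions on a diagnostic profile
#'
#' Splits the profile into pocket-proximal positions (lining the
#' ligand-binding site, where a mismatch is expected to alter ligand
#' selectivity) and pocket-distal positions (unlikely to have functional
#' consequences).
#'
#' @param profile a `diagnostic_profile`.
#' @param distal_positions reference positions to flag as distal; must be a
#'   subset of the profile's positions.
#' @return list with the updated `profile` and integer vectors `proximal` and
#'   `distal`.
#' @export
partition_by_pocket <- function(profile, distal_positions) {
  stopifnot(inherits(profile, "diagnostic_profile"))
  unknown <- setdiff(distal_positions, profile$position)
  if (length(unknown)) {
    stop("positions not in profile: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  profile$pocket_proximal <- !(profile$position %in% distal_positions)
  list(profile = profile,
       proximal = profile$position[profile$pocket_proximal],
       distal = profile$position[!profile$pocket_proximal])
}

#' Count substitution differences between two aligned records
#'
#' Counts columns where both records carry a residue (no gap) and the residues
#' differ. Indel columns are excluded here; they are reported by
#' [detect_indel_blocks()] instead.
#'
#' @param aln a [ref_alignment()].
#' @param id_x,id_y record ids.
#' @return integer count.
#' @export
count_pairwise_differences <- function(aln, id_x, id_y) {
  stopifnot(inherits(aln, "ref_alignment"))
  for (id in c(id_x, id_y)) {
    if (!id %in% names(aln$seqs)) stop("unknown id: ", id, call. = FALSE)
  }
  x <- strsplit(aln$seqs[[id_x]], "", fixed = TRUE)[[1L]]
  y <- strsplit(aln$seqs[[id_y]], "", fixed = TRUE)[[1L]]
  sum(x != "-" & y != "-" & x != y)
}

#' Positions where the groups differ but are not diagnostic
#'
#' Secondary report: reference positions where some `GROUP_A` record differs
#' from some `GROUP_B` record, yet the position fails the diagnostic
#' criterion (within-group polymorphism, shared states, or gap/X). Reported
#' without interpretation.
#'
#' @param aln a [ref_alignment()].
#' @param strict passed to [discover_diagnostic_positions()].
#' @return integer vector of reference positions.
#' @export
nondiagnostic_difference_positions <- function(aln, strict = TRUE) {
  profile <- suppressWarnings(discover_diagnostic_positions(aln, strict))
  m <- aln_matrix(aln)
  a_ids <- group_rows(aln, "GROUP_A"); b_ids <- group_rows(aln, "GROUP_B")
  differing <- integer(0)
  for (col in which(!is.na(aln$col_to_ref))) {
    ca <- m[a_ids, col]; cb <- m[b_ids, col]
    if (any(c(ca, cb) == "-")) next
    if (any(outer(ca, cb, `!=`))) differing <- c(differing, aln$col_to_ref[col])
  }
  setdiff(differing, profile$position)
}

profile_states <- function(s) strsplit(s, "", fixed = TRUE)

#' Classify one query sequence against a diagnostic profile
#'
#' Per profile position the query residue is called `MATCH_A` if it belongs to
#' the group-A state set, `MATCH_B` for group B, `AMBIGUOUS` if it is a gap or
#' `X` (unknowable is distinct from mismatching), and `NEITHER` otherwise.
#'
#' The default verdict rule (`rule = "pocket"`) follows the functional
#' argument that pocket-distal mismatches are unlikely to matter: `A_LIKE`
#' requires a strict majority of A-matches *and* no B-match at any
#' pocket-proximal position (`pocket_n_b == 0`); `B_LIKE` is symmetric; count
#' ties give `MIXED`; no informative position gives `UNDETERMINED`.
#' `rule = "majority"` uses the counts alone.
#'
#' @param aln a [ref_alignment()] containing the query in the same frame the
#'   profile was built in.
#' @param query_id record id of the query.
#' @param profile a `diagnostic_profile`.
#' @param rule `"pocket"` (default) or `"majority"`.
#' @return a `classification_result`: list with `query_id`, `calls` (data
#'   frame: position, residue, call, pocket_proximal), counts `n_a`, `n_b`,
#'   `n_neither`, `n_ambiguous`, `pocket_n_a`, `pocket_n_b`, `verdict`, `rule`.
#' @export
classify_sequence <- function(aln, query_id, profile,
                              rule = c("pocket", "majority")) {
  stopifnot(inherits(aln, "ref_alignment"),
            inherits(profile, "diagnostic_profile"))
  rule <- match.arg(rule)
  if (nrow(profile) == 0L) stop("empty diagnostic profile", call. = FALSE)
  if (!query_id %in% names(aln$seqs)) {
    stop("unknown query id: ", query_id, call. = FALSE)
  }
  if (max(profile$position) > reference_length(aln)) {
    stop("profile positions exceed reference length: frame mismatch",
         call. = FALSE)
  }
  q <- strsplit(aln$seqs[[query_id]], "", fixed = TRUE)[[1L]]
  res <- q[column_of(aln, profile$position)]
  states_a <- profile_states(profile$state_a)
  states_b <- profile_states(profile$state_b)
  call <- character(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    call[i] <- if (res[i] %in% c("-", "X")) "AMBIGUOUS"
      else if (res[i] %in% states_a[[i]]) "MATCH_A"
      else if (res[i] %in% states_b[[i]]) "MATCH_B"
      else "NEITHER"
  }
  calls <- data.frame(position = profile$position, residue = res, call = call,
                      pocket_proximal = profile$pocket_proximal,
                      stringsAsFactors = FALSE)
  n_a <- sum(call == "MATCH_A"); n_b <- sum(call == "MATCH_B")
  n_neither <- sum(call == "NEITHER"); n_ambiguous <- sum(call == "AMBIGUOUS")
  prox <- profile$pocket_proximal
  pocket_n_a <- sum(call == "MATCH_A" & prox)
  pocket_n_b <- sum(call == "MATCH_B" & prox)

  verdict <- if (n_a + n_b == 0L) "UNDETERMINED"
    else if (n_a == n_b) "MIXED"
    else if (rule == "majority") { if (n_a > n_b) "A_LIKE" else "B_LIKE" }
    else if (n_a > n_b && pocket_n_b == 0L) "A_LIKE"
    else if (n_b > n_a && pocket_n_a == 0L) "B_LIKE"
    else "MIXED"

  structure(list(query_id = query_id, calls = calls, n_a = n_a, n_b = n_b,
                 n_neither = n_neither, n_ambiguous = n_ambiguous,
                 pocket_n_a = pocket_n_a, pocket_n_b = pocket_n_b,
                 verdict = verdict, rule = rule),
            class = "classification_result")
}

#' Classify a cohort of query sequences
#'
#' @param aln a [ref_alignment()].
#' @param profile a `diagnostic_profile`.
#' @param query_ids record ids to classify; defaults to all `QUERY` records.
#' @param rule verdict rule, see [classify_sequence()].
#' @return list with `results` (one `classification_result` per query, input
#'   order) and `summary` (one row per query with the counts and verdict).
#' @export
classify_cohort <- function(aln, profile, query_ids = NULL,
                            rule = c("pocket", "majority")) {
  rule <- match.arg(rule)
  if (is.null(query_ids)) query_ids <- group_rows(aln, "QUERY")
  results <- lapply(query_ids, classify_sequence, aln = aln,
                    profile = profile, rule = rule)
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(query_id = r$query_id,
               species = aln$meta$species[match(r$query_id, aln$meta$id)],
               n_a = r$n_a, n_b = r$n_b, n_neither = r$n_neither,
               n_ambiguous = r$n_ambiguous, pocket_n_a = r$pocket_n_a,
               pocket_n_b = r$pocket_n_b, verdict = r$verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' @export
print.diagnostic_profile <- function(x, ...) {
  cat("Diagnostic profile: ", nrow(x), " positions (reference ",
      attr(x, "reference_id"), ", ",
      if (isTRUE(attr(x, "strict"))) "strict" else "relaxed", " mode)\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Classification of ", x$query_id, ": ", x$verdict,
      " (rule = ", x$rule, ")\n", sep = "")
  cat(sprintf("  A: %d  B: %d  neither: %d  ambiguous: %d  (pocket A: %d, B: %d)\n",
              x$n_a, x$n_b, x$n_neither, x$n_ambiguous,
              x$pocket_n_a, x$pocket_n_b))
  invisible(x)
}
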