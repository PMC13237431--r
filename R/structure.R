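# C-alpha superposition (Kabsch), RMSD over stated residue ranges, and the
# paired t comparison of two RMSD samples.

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one C-alpha per residue (altloc 'A' or blank only), ordered by
#' residue number.
#'
#' @param path PDB file with ATOM records.
#' @param chain chain identifier; `NULL` takes the only chain present.
#' @param residue_range optional `c(first, last)` residue numbers (inclusive).
#' @param model_id label stored with the coordinates (default: file name).
#' @return a `coord_set`: data frame with columns `resno`, `x`, `y`, `z`
#'   (Angstrom), residue numbers strictly increasing.
#' @export
read_ca_coords <- function(path, chain = NULL, residue_range = NULL,
                           model_id = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0L) stop("no C-alpha ATOM records in ", path, call. = FALSE)
  if (is.null(chain)) {
    chains <- unique(at$chain)
    if (length(chains) > 1L) {
      stop("multiple chains (", paste(chains, collapse = ", "),
           "); specify one", call. = FALSE)
    }
  } else {
    if (!chain %in% at$chain) stop("chain '", chain, "' not found", call. = FALSE)
    at <- at[at$chain == chain, , drop = FALSE]
  }
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (anyDuplicated(at$resno)) {
    stop("duplicate C-alpha for residue(s) ",
         paste(unique(at$resno[duplicated(at$resno)]), collapse = ", "),
         " without resolving altloc", call. = FALSE)
  }
  at <- at[order(at$resno), , drop = FALSE]
  if (!is.null(residue_range)) {
    at <- at[at$resno >= residue_range[1L] & at$resno <= residue_range[2L], ,
             drop = FALSE]
  }
  coord_set(at$resno, cbind(at$x, at$y, at$z),
            model_id = if (is.null(model_id)) basename(path) else model_id)
}

#' Construct a coordinate set from residue numbers and an n x 3 matrix
#' @param resno integer residue numbers (strictly increasing).
#' @param xyz numeric matrix with one row per residue and columns x, y, z.
#' @param model_id label.
#' @return a `coord_set`.
#' @export
coord_set <- function(resno, xyz, model_id = "model") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, length(resno) == nrow(xyz))
  if (any(diff(resno) <= 0L)) {
    stop("residue numbers must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  structure(data.frame(resno = as.integer(resno), x = xyz[, 1L],
                       y = xyz[, 2L], z = xyz[, 3L]),
            class = c("coord_set", "data.frame"), model_id = model_id)
}

#' Write a coordinate set as a minimal PDB file (CA atoms only)
#' @param cs a `coord_set`.
#' @param path output file.
#' @param chain chain id to write.
#' @return `path`, invisibly.
#' @export
write_ca_coords <- function(cs, path, chain = "A") {
  stopifnot(inherits(cs, "coord_set"))
  n <- nrow(cs)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(cbind(cs$x, cs$y, cs$z))),
                   resno = cs$resno, resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep(chain, n),
                   eleno = seq_len(n))
  invisible(path)
}

pair_by_resno <- function(mobile, target) {
  common <- intersect(mobile$resno, target$resno)
  list(m = as.matrix(mobile[match(common, mobile$resno), c("x", "y", "z")]),
       t = as.matrix(target[match(common, target$resno), c("x", "y", "z")]),
       resno = common)
}

#' Optimal rigid superposition of two C-alpha sets (Kabsch algorithm)
#'
#' Pairs atoms by residue-number intersection, then finds the proper rotation
#' `R` and translation `t` minimising the RMSD of `R %*% x + t` against the
#' target, via SVD of the covariance matrix with the standard sign correction
#' that forbids reflections.
#'
#' @param mobile,target `coord_set`s sharing at least 3 residue numbers.
#' @return a `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (Angstrom), `n_atoms`, `range_used`.
#' @export
kabsch_superpose <- function(mobile, target) {
  p <- pair_by_resno(mobile, target)
  n <- length(p$resno)
  if (n < 3L) stop("need >= 3 paired atoms, got ", n, call. = FALSE)
  cm <- colMeans(p$m); ct <- colMeans(p$t)
  X <- sweep(p$m, 2L, cm); Y <- sweep(p$t, 2L, ct)
  H <- crossprod(X, Y)                     # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1)) {
    stop("degenerate (collinear) geometry; superposition is not unique",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(ct - R %*% cm)
  fitted <- sweep(p$m %*% t(R), 2L, trans, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - p$t)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 n_atoms = n, range_used = range(p$resno)),
            class = "superposition")
}

#' RMSD after superposition restricted to a residue interval
#'
#' Both models must cover every residue in the interval; missing residues are
#' an error (listing them), never silently dropped, so `n` stays identical
#' across comparisons.
#'
#' @param model_a,model_b `coord_set`s.
#' @param range `c(first, last)` residue numbers, inclusive.
#' @return a `superposition` (see [kabsch_superpose()]) computed on exactly
#'   the residues of `range`.
#' @export
rmsd_over_range <- function(model_a, model_b, range) {
  stopifnot(length(range) == 2L, range[1L] <= range[2L])
  wanted <- range[1L]:range[2L]
  for (m in list(a = model_a, b = model_b)) {
    miss <- setdiff(wanted, m$resno)
    if (length(miss)) {
      stop("model '", attr(m, "model_id"), "' missing residues ",
           paste(utils::head(miss, 10L), collapse = ", "),
           if (length(miss) > 10L) " ..." else "", call. = FALSE)
    }
  }
  sub <- function(cs) cs[cs$resno %in% wanted, , drop = FALSE]
  a <- sub(model_a); b <- sub(model_b)
  class(a) <- class(b) <- c("coord_set", "data.frame")
  out <- kabsch_superpose(a, b)
  out$range_used <- range
  out
}

#' Two-tailed paired t-test on matched RMSD samples
#'
#' Classical paired t on the differences `x - y`, aligned by model identity:
#' `t = mean(d) / (sd(d) / sqrt(n))`, p two-tailed from Student's t with
#' `n - 1` degrees of freedom. Zero-variance differences with nonzero mean are
#' reported as `t = +/-Inf`, `p = 0`, flagged `degenerate`.
#'
#' @param rmsd_to_a,rmsd_to_b equal-length numeric vectors (n >= 2), the i-th
#'   entries belonging to the same model.
#' @return a `paired_ttest`: list with `n`, `mean_diff`, `sd_diff`,
#'   `t_statistic`, `df`, `p_value`, `degenerate`.
#' @export
paired_ttest <- function(rmsd_to_a, rmsd_to_b) {
  if (length(rmsd_to_a) != length(rmsd_to_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  n <- length(rmsd_to_a)
  if (n < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- rmsd_to_a - rmsd_to_b
  md <- mean(d); sdd <- stats::sd(d)
  degenerate <- sdd == 0
  if (degenerate) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  structure(list(n = n, mean_diff = md, sd_diff = sdd, t_statistic = t_stat,
                 df = n - 1L, p_value = p, degenerate = degenerate),
            class = "paired_ttest")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD %.4f A over %d atoms (residues %d-%d)\n",
              x$rmsd, x$n_atoms, x$range_used[1L], x$range_used[2L]))
  invisible(x)
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g (mean diff %.4f)\n",
              x$t_statistic, x$df, x$p_value, x$mean_diff))
  if (x$degenerate) cat("  note: zero variance of differences\n")
  invisible(x)
}
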