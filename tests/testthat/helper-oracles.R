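# Independent oracles: brute-force or alternative-method implementations used
# to cross-check the package. Deliberately written against the raw inputs,
# not the package's internal representations.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# ---- diagnostic-site discovery: exhaustive per-column scan ------------------
# seqs: named character vector; groups: named vector "A"/"B"/other; ref: id.
oracle_discover <- function(seqs, groups, ref, strict = TRUE) {
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  refc <- chars[[ref]]
  a <- names(groups)[groups == "A"]; b <- names(groups)[groups == "B"]
  hits <- integer(0); sa <- character(0); sb <- character(0)
  refpos <- 0L
  for (col in seq_along(refc)) {
    if (refc[col] == "-") next
    refpos <- refpos + 1L
    ca <- vapply(a, function(id) chars[[id]][col], character(1))
    cb <- vapply(b, function(id) chars[[id]][col], character(1))
    if (any(ca %in% c("-", "X")) || any(cb %in% c("-", "X"))) next
    ok <- if (strict) {
      length(unique(ca)) == 1L && length(unique(cb)) == 1L && ca[1L] != cb[1L]
    } else {
      !any(unique(ca) %in% unique(cb))
    }
    if (ok) {
      hits <- c(hits, refpos)
      sa <- c(sa, paste(sort(unique(ca)), collapse = ""))
      sb <- c(sb, paste(sort(unique(cb)), collapse = ""))
    }
  }
  list(positions = hits, state_a = sa, state_b = sb)
}

random_alignment <- function(nseq = 8L, ncols = 50L, gap_prob = 0.05,
                             x_prob = 0.02) {
  alphabet <- c(AA20, "-", "X")
  probs <- c(rep((1 - gap_prob - x_prob) / 20, 20), gap_prob, x_prob)
  seqs <- vapply(seq_len(nseq), function(i)
    paste(sample(alphabet, ncols, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(seqs) <- paste0("s", seq_len(nseq))
  # reference must be gap-free at column 1 at least; force a residue-bearing ref
  ref <- sub("-", "A", seqs[[1L]], fixed = TRUE)
  if (!grepl("[^-X]", ref)) ref <- paste(rep("A", ncols), collapse = "")
  seqs[[1L]] <- ref
  seqs
}

# ---- reconciliation: ancestor-set LCA + explicit path walking ---------------
oracle_reconcile <- function(gene_tree, species_tree, delim = "|") {
  parent_of <- function(tree) {
    p <- integer(ape::Ntip(tree) + tree$Nnode)
    p[tree$edge[, 2]] <- tree$edge[, 1]
    p
  }
  ancestors <- function(node, parent) {      # node itself first, root last
    out <- node
    while (parent[node] != 0L) { node <- parent[node]; out <- c(out, node) }
    out
  }
  ps <- parent_of(species_tree); pg <- parent_of(gene_tree)
  anc_s <- lapply(seq_along(ps), ancestors, parent = ps)
  depth_s <- vapply(anc_s, length, integer(1))  # root depth 1

  glab <- gene_tree$tip.label
  gsp <- sub(paste0("^.*\\", delim), "", glab)
  ntg <- ape::Ntip(gene_tree)
  # leaves under each gene node
  leaves_under <- function(node) {
    if (node <= ntg) return(node)
    kids <- gene_tree$edge[gene_tree$edge[, 1] == node, 2]
    unlist(lapply(kids, leaves_under))
  }
  M <- integer(ntg + gene_tree$Nnode)
  for (v in seq_along(M)) {
    tipset <- leaves_under(v)
    imgs <- match(gsp[tipset], species_tree$tip.label)
    common <- Reduce(intersect, anc_s[imgs])
    M[v] <- common[which.max(depth_s[common])]  # deepest common ancestor
  }
  children_g <- function(v) gene_tree$edge[gene_tree$edge[, 1] == v, 2]
  is_dup <- vapply(seq_along(M), function(v) {
    v > ntg && any(M[children_g(v)] == M[v])
  }, logical(1))
  losses <- 0L
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]; v <- gene_tree$edge[i, 2]
    d <- depth_s[M[v]] - depth_s[M[u]]
    losses <- losses + max(0L, d - 1L + as.integer(is_dup[u]))
  }
  list(n_duplications = sum(is_dup), n_losses = losses,
       events = ifelse(is_dup[(ntg + 1L):length(M)], "DUPLICATION",
                       "SPECIATION"))
}

random_tree_pair <- function(max_species = 6L, max_genes = 12L) {
  k <- sample(2:max_species, 1L)
  st <- ape::rtree(k, tip.label = paste0("sp", seq_len(k)))
  n <- sample(2:max_genes, 1L)
  gt <- ape::rtree(n)
  gt$tip.label <- paste0("g", seq_len(n), "|",
                         sample(st$tip.label, n, replace = TRUE))
  list(gene = gt, species = st)
}

# ---- superposition: Horn's quaternion method --------------------------------
oracle_quaternion_rmsd <- function(m, t) {
  m <- sweep(m, 2, colMeans(m)); t <- sweep(t, 2, colMeans(t))
  S <- crossprod(m, t)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(m^2) + sum(t^2) - 2 * lam) / nrow(m)
  sqrt(max(msd, 0))
}

random_coord_cloud <- function(n = 20L, spread = 10) {
  matrix(stats::runif(3L * n, -spread, spread), n, 3L)
}
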