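# Gene-tree/species-tree reconciliation by LCA (last-common-ancestor) mapping.
#
# Each gene-tree leaf maps to its species; each internal node maps to the
# species-tree LCA of its children's images. An internal node is a DUPLICATION
# iff its image equals the image of at least one child, otherwise a
# SPECIATION. Losses are counted along each gene-tree edge (u -> v) from the
# species-tree path between the images: with d = depth(M(v)) - depth(M(u)),
# a speciation parent implies d - 1 losses and a duplication parent d losses,
# each placed on the sibling branch bypassed along the path.

#' @importFrom ape read.tree write.tree is.rooted is.binary multi2di
#'   is.monophyletic Ntip Nnode
NULL

split_gene_labels <- function(labels, delim = "|") {
  pos <- regexpr(delim, labels, fixed = TRUE)
  if (any(pos < 0L)) {
    stop("gene-tree leaf labels must be '<gene>", delim, "<species>'; bad: ",
         paste(labels[pos < 0L], collapse = ", "), call. = FALSE)
  }
  data.frame(gene = substr(labels, 1L, pos - 1L),
             species = substr(labels, pos + nchar(delim), nchar(labels)),
             stringsAsFactors = FALSE)
}

check_tree <- function(tree, what, resolve_polytomies = FALSE) {
  if (!inherits(tree, "phylo")) stop(what, " is not a phylo tree", call. = FALSE)
  if (!ape::is.rooted(tree)) stop(what, " must be rooted", call. = FALSE)
  if (!ape::is.binary(tree)) {
    if (resolve_polytomies) {
      message(what, ": polytomies resolved arbitrarily (multi2di)")
      tree <- ape::multi2di(tree, random = FALSE)
    } else {
      stop(what, " contains polytomies; set resolve_polytomies = TRUE to ",
           "resolve them arbitrarily", call. = FALSE)
    }
  }
  if (anyDuplicated(tree$tip.label)) {
    stop(what, " has duplicate leaf labels", call. = FALSE)
  }
  tree
}

#' Read a rooted gene tree (leaves labelled `gene<delim>species`)
#'
#' @param path Newick file; alternatively pass the Newick string as `text`.
#' @param text Newick string (used when `path` is missing).
#' @param delim delimiter between gene id and species id in leaf labels.
#' @param resolve_polytomies resolve multifurcations arbitrarily instead of
#'   rejecting them.
#' @return an `ape::phylo`, validated (rooted, binary, unique leaves,
#'   parseable labels).
#' @export
read_gene_tree <- function(path, text = NULL, delim = "|",
                           resolve_polytomies = FALSE) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  tree <- check_tree(tree, "gene tree", resolve_polytomies)
  split_gene_labels(tree$tip.label, delim)  # validates labels
  tree
}

#' Read a rooted species tree (leaves are species ids)
#' @inheritParams read_gene_tree
#' @return an `ape::phylo`.
#' @export
read_species_tree <- function(path, text = NULL, resolve_polytomies = FALSE) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  check_tree(tree, "species tree", resolve_polytomies)
}

#' Write a tree to Newick
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root a tree on an outgroup or at the midpoint (explicit, never silent)
#' @param tree an `ape::phylo`.
#' @param outgroup tip label(s) to root on; ignored when `midpoint = TRUE`.
#' @param midpoint use midpoint rooting instead.
#' @return rooted `ape::phylo`.
#' @export
root_tree <- function(tree, outgroup = NULL, midpoint = FALSE) {
  if (midpoint) {
    message("rooting at midpoint")
    return(phangorn::midpoint(tree))
  }
  if (is.null(outgroup)) stop("supply an outgroup or midpoint = TRUE",
                              call. = FALSE)
  message("rooting on outgroup: ", paste(outgroup, collapse = ", "))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# parent vector indexed by node number (0 at the root)
parent_vector <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

node_depths <- function(tree, parent) {
  root <- ape::Ntip(tree) + 1L
  d <- rep(NA_integer_, length(parent))
  d[root] <- 0L
  # edges in preorder guarantee parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) d[pre[i, 2L]] <- d[pre[i, 1L]] + 1L
  d
}

lca_pair <- function(a, b, parent, depth) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
  }
  a
}

species_node_names <- function(tree) {
  n <- ape::Ntip(tree)
  inner <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("mrca(", vapply(seq_len(tree$Nnode), function(i) {
      tips <- ape::extract.clade(tree, n + i)$tip.label
      paste(range(sort(tips)), collapse = ",")
    }, character(1)), ")")
  }
  c(tree$tip.label, inner)
}

#' Reconcile a rooted gene tree with a rooted species tree (LCA mapping)
#'
#' @param gene_tree rooted binary `phylo`; leaves `gene<delim>species`.
#' @param species_tree rooted binary `phylo`; leaves are species ids covering
#'   every species in the gene tree.
#' @param delim gene/species delimiter in gene-tree leaf labels.
#' @return a `reconciliation`: list with `events` (per internal gene-tree
#'   node, `"SPECIATION"`/`"DUPLICATION"`), `mapping` (gene-tree node number
#'   -> species-tree node number), `n_duplications`, `n_losses`,
#'   `loss_branches` (data frame placing each loss on the species-tree branch
#'   above the named node), and `edge_losses`.
#' @export
lca_reconcile <- function(gene_tree, species_tree, delim = "|") {
  gene_tree <- check_tree(gene_tree, "gene tree")
  species_tree <- check_tree(species_tree, "species tree")
  lab <- split_gene_labels(gene_tree$tip.label, delim)
  missing <- setdiff(lab$species, species_tree$tip.label)
  if (length(missing)) {
    stop("species absent from species tree: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }

  ntg <- ape::Ntip(gene_tree)
  nng <- gene_tree$Nnode
  parent_s <- parent_vector(species_tree)
  depth_s <- node_depths(species_tree, parent_s)
  s_names <- species_node_names(species_tree)

  # children lists for the gene tree
  kids <- split(gene_tree$edge[, 2L], gene_tree$edge[, 1L])

  M <- integer(ntg + nng)
  M[seq_len(ntg)] <- match(lab$species, species_tree$tip.label)

  post <- ape::reorder.phylo(gene_tree, "postorder")$edge
  internal <- unique(post[, 1L])  # postorder: children settled before parents
  for (v in internal) {
    ch <- kids[[as.character(v)]]
    m <- M[ch[1L]]
    for (c2 in ch[-1L]) m <- lca_pair(m, M[c2], parent_s, depth_s)
    M[v] <- m
  }

  events <- vapply(internal, function(v) {
    ch <- kids[[as.character(v)]]
    if (any(M[ch] == M[v])) "DUPLICATION" else "SPECIATION"
  }, character(1))
  names(events) <- internal
  is_dup <- stats::setNames(events == "DUPLICATION", internal)

  # losses along each gene-tree edge
  loss_nodes <- integer(0)
  loss_edge <- integer(0)
  edge_losses <- integer(nrow(gene_tree$edge))
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1L]; v <- gene_tree$edge[i, 2L]
    d <- depth_s[M[v]] - depth_s[M[u]]
    k <- d - 1L + as.integer(is_dup[[as.character(u)]])
    if (k > 0L) {
      # walk up from M(v); each bypassed step loses the sibling lineage
      p <- M[v]
      for (step in seq_len(k)) {
        par <- parent_s[p]
        ch <- species_tree$edge[species_tree$edge[, 1L] == par, 2L]
        loss_nodes <- c(loss_nodes, setdiff(ch, p))
        loss_edge <- c(loss_edge, i)
        p <- par
      }
    }
    edge_losses[i] <- max(k, 0L)
  }

  loss_branches <- data.frame(
    species_node = s_names[loss_nodes],
    gene_edge = loss_edge,
    stringsAsFactors = FALSE)

  structure(list(events = events,
                 mapping = M,
                 mapping_names = s_names[M],
                 n_duplications = sum(events == "DUPLICATION"),
                 n_losses = sum(edge_losses),
                 loss_branches = loss_branches,
                 edge_losses = edge_losses,
                 gene_tree = gene_tree, species_tree = species_tree,
                 delim = delim),
            class = "reconciliation")
}

#' Total inferred losses of a reconciliation (with per-branch placements)
#' @param recon a `reconciliation` from [lca_reconcile()].
#' @return integer loss count; placements in `attr(, "loss_branches")`.
#' @export
count_losses <- function(recon) {
  stopifnot(inherits(recon, "reconciliation"))
  structure(recon$n_losses, loss_branches = recon$loss_branches)
}

#' Gene-conversion expectation: do gene copies cluster by species?
#'
#' Under gene conversion, paralogs within a genome are homogenised and are
#' expected to form species-specific clades. For each species with at least
#' two gene copies this tests whether its copies are monophyletic in the gene
#' tree; single-copy species are reported as `NA`.
#'
#' @param gene_tree rooted `phylo`, leaves `gene<delim>species`.
#' @param delim gene/species delimiter.
#' @return list with `table` (species, n_copies, monophyletic) and `fraction`
#'   (share of multi-copy species that cluster; `NA` if there are none).
#' @export
species_clustering_test <- function(gene_tree, delim = "|") {
  lab <- split_gene_labels(gene_tree$tip.label, delim)
  species <- sort(unique(lab$species))
  n_copies <- vapply(species, function(s) sum(lab$species == s), integer(1))
  mono <- rep(NA, length(species))
  for (i in seq_along(species)) {
    if (n_copies[i] >= 2L) {
      tips <- gene_tree$tip.label[lab$species == species[i]]
      mono[i] <- ape::is.monophyletic(gene_tree, tips)
    }
  }
  tab <- data.frame(species = species, n_copies = n_copies,
                    monophyletic = mono, stringsAsFactors = FALSE,
                    row.names = NULL)
  multi <- !is.na(mono)
  list(table = tab,
       fraction = if (any(multi)) mean(mono[multi]) else NA_real_)
}

#' Compare competing duplication scenarios by duplication/loss cost
#'
#' Reconciles each candidate gene tree (all over the same gene set) against
#' the species tree and ranks them by
#' `cost = dup_cost * n_duplications + loss_cost * n_losses`.
#' Ties are reported explicitly, never broken silently.
#'
#' @param scenarios named list of rooted gene trees over identical leaf sets.
#' @param species_tree rooted species tree.
#' @param dup_cost,loss_cost positive event weights (default 1 each).
#' @param delim gene/species delimiter.
#' @return a `scenario_comparison`: data frame (scenario, n_duplications,
#'   n_losses, cost) with attributes `preferred` (character vector of all
#'   minimal-cost scenarios) and `tie` (logical).
#' @export
compare_scenarios <- function(scenarios, species_tree, dup_cost = 1,
                              loss_cost = 1, delim = "|") {
  if (length(scenarios) < 2L || is.null(names(scenarios)) ||
      any(!nzchar(names(scenarios)))) {
    stop("supply >= 2 named scenarios", call. = FALSE)
  }
  leafsets <- lapply(scenarios, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets[-1L], identical, logical(1), leafsets[[1L]]))) {
    stop("scenarios must share an identical gene leaf set", call. = FALSE)
  }
  rec <- lapply(scenarios, lca_reconcile, species_tree = species_tree,
                delim = delim)
  tab <- data.frame(
    scenario = names(scenarios),
    n_duplications = vapply(rec, `[[`, integer(1), "n_duplications"),
    n_losses = vapply(rec, `[[`, integer(1), "n_losses"),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$cost <- dup_cost * tab$n_duplications + loss_cost * tab$n_losses
  best <- tab$scenario[tab$cost == min(tab$cost)]
  structure(tab, class = c("scenario_comparison", "data.frame"),
            preferred = best, tie = length(best) > 1L,
            dup_cost = dup_cost, loss_cost = loss_cost,
            reconciliations = rec)
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("LCA reconciliation: ", x$n_duplications, " duplication(s), ",
      x$n_losses, " loss(es)\n", sep = "")
  if (nrow(x$loss_branches)) {
    cat("  losses on species branches above: ",
        paste(x$loss_branches$species_node, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (dup_cost = ", attr(x, "dup_cost"),
      ", loss_cost = ", attr(x, "loss_cost"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  pref <- attr(x, "preferred")
  if (attr(x, "tie")) {
    cat("  tie between: ", paste(pref, collapse = ", "), "\n", sep = "")
  } else {
    cat("  preferred: ", pref, "\n", sep = "")
  }
  invisible(x)
}
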