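# Synthetic worked-example data for the HCAR2/HCAR3 receptor family.
#
# No real receptor sequence is shipped. The alignment built here is SYNTHETIC:
# a fixed repeating-pattern background of 363 residues (the length of human
# HCAR2) with residues placed so that the published *pattern* of the family
# holds — which positions are diagnostic, which lineages match which profile,
# the residues stated verbatim in the literature for positions 27, 91, 167,
# 168 and 173, the 18 differing positions between human HCAR2 and HCAR3, the
# 24-residue C-terminal insertion absent from gorilla HCAR3, and the
# 11-residue Colobinae deletion. States at the other diagnostic positions are
# invented. It supports worked examples and tests that must run offline; it is
# not a substitute for the real sequences.

HCAR_DIAG <- data.frame(
  position = c(27L, 83L, 86L, 91L, 103L, 107L, 142L, 167L, 168L, 173L, 176L, 178L),
  a = c("V", "S", "F", "R", "T", "I", "D", "K", "Y", "G", "E", "N"),
  b = c("A", "N", "L", "Q", "M", "V", "E", "L", "H", "T", "D", "S"),
  stringsAsFactors = FALSE)

HCAR_NONDIAG <- c(50L, 120L, 200L, 250L, 280L, 310L)
HCAR_INSERTION <- "PQSTAPSGNGTSQEEKAAGSPLTK"   # 24 residues, synthetic
HCAR_INS_ANCHOR <- 330L
HCAR_DEL_RANGE <- c(337L, 347L)                # 11 residues, Colobinae-like

#' Pocket-distal diagnostic positions of the HCAR2/HCAR3 profile
#'
#' The five diagnostic positions located away from the ligand-binding pocket;
#' the complementary seven positions line the pocket.
#' @return integer vector.
#' @export
hcar_distal_positions <- function() c(27L, 142L, 167L, 168L, 173L)

hcar_base_seq <- function(L = 363L) rep(AA_ALPHABET, length.out = L)

hcar_variant <- function(res) if (res == "W") "C" else "W"

#' Synthetic HCAR2/HCAR3 worked-example alignment
#'
#' 23 records: four hominine HCAR2 (`GROUP_A`) and four HCAR3 (`GROUP_B`)
#' sequences defining the profile, plus orangutan, gibbon and non-ape query
#' records whose diagnostic residues follow the published per-lineage match
#' patterns (see the package vignette for exactly which facts are text-derived
#' and which are invented).
#'
#' @return a [ref_alignment()] anchored on `human_HCAR2` (363 residues).
#' @export
hcar_fixture_alignment <- function() {
  L <- 363L
  base <- hcar_base_seq(L)
  dg <- HCAR_DIAG

  mk <- function(states, extra = NULL) {
    s <- base
    s[dg$position] <- states
    if (!is.null(extra)) s[as.integer(names(extra))] <- unname(extra)
    s
  }
  a_at <- function(pos) ifelse(dg$position %in% pos, dg$a, dg$b)  # b except a at pos
  b_at <- function(pos) ifelse(dg$position %in% pos, dg$b, dg$a)  # a except b at pos

  nd_var <- vapply(base[HCAR_NONDIAG], hcar_variant, character(1))
  names(nd_var) <- HCAR_NONDIAG

  seqs <- list(
    human_HCAR2   = mk(dg$a),
    chimp_HCAR2   = mk(dg$a),
    bonobo_HCAR2  = mk(dg$a),
    gorilla_HCAR2 = mk(dg$a),
    human_HCAR3   = mk(dg$b, nd_var),
    chimp_HCAR3   = mk(dg$b),
    bonobo_HCAR3  = mk(dg$b),
    gorilla_HCAR3 = mk(dg$b),
    pongo_abelii_HCAR2like   = mk(dg$a),
    pongo_pygmaeus_HCAR2like = mk(dg$a),
    pongo_abelii_HCAR3like   = mk(a_at(c(86L, 142L))),
    pongo_pygmaeus_HCAR3like = mk(a_at(c(86L, 142L))),
    siamang_HCAR2like = mk(b_at(27L)),
    hylobates_single  = mk(b_at(27L)),
    nomascus_single   = mk(b_at(27L)),
    siamang_HCAR3like = mk(a_at(c(86L, 142L, 176L)), c(`91` = "P")),
    hoolock_copy1     = mk(a_at(c(86L, 142L, 176L)), c(`91` = "X")),
    hoolock_copy2     = mk(b_at(c(27L, 83L, 168L))),
    macaque_HCAR23    = mk(b_at(173L)),
    snubnosed_HCAR23  = mk(b_at(173L)),
    marmoset_HCAR23   = mk(b_at(168L), c(`27` = "S", `173` = "N")),
    tarsier_HCAR23    = mk(b_at(c(27L, 168L)), c(`173` = "S")),
    sifaka_HCAR23     = mk(b_at(c(27L, 168L)), c(`173` = "P")))

  # 24-residue C-terminal insertion: human/chimp/bonobo HCAR3 only
  ins <- strsplit(HCAR_INSERTION, "", fixed = TRUE)[[1L]]
  stopifnot(length(ins) == 24L)
  carriers <- c("human_HCAR3", "chimp_HCAR3", "bonobo_HCAR3")
  seqs <- lapply(stats::setNames(names(seqs), names(seqs)), function(id) {
    piece <- if (id %in% carriers) ins else rep("-", 24L)
    append(seqs[[id]], piece, after = HCAR_INS_ANCHOR)
  })
  # 11-residue C-terminal deletion in the colobine record
  del_cols <- (HCAR_DEL_RANGE[1L]:HCAR_DEL_RANGE[2L]) + 24L  # after insertion
  seqs$snubnosed_HCAR23[del_cols] <- "-"

  species <- c(rep(c("Homo_sapiens", "Pan_troglodytes", "Pan_paniscus",
                     "Gorilla_gorilla"), 2L),
               "Pongo_abelii", "Pongo_pygmaeus", "Pongo_abelii",
               "Pongo_pygmaeus",
               "Symphalangus_syndactylus", "Hylobates_agilis",
               "Nomascus_leucogenys", "Symphalangus_syndactylus",
               "Hoolock_leuconedys", "Hoolock_leuconedys",
               "Macaca_fascicularis", "Rhinopithecus_roxellana",
               "Callithrix_jacchus", "Carlito_syrichta",
               "Propithecus_coquereli")
  meta <- data.frame(id = names(seqs), species = species,
                     group = c(rep("GROUP_A", 4L), rep("GROUP_B", 4L),
                               rep("QUERY", 15L)),
                     stringsAsFactors = FALSE)
  ref_alignment(vapply(seqs, paste, character(1), collapse = ""),
                meta = meta, reference_id = "human_HCAR2")
}

#' Transmembrane-domain annotation for the worked example (synthetic bounds)
#' @return data frame with columns `name`, `start`, `end` (1-based inclusive).
#' @export
hcar_fixture_regions <- function() {
  data.frame(name = paste0("TM", 1:7),
             start = c(12L, 66L, 95L, 130L, 185L, 230L, 270L),
             end = c(40L, 88L, 125L, 155L, 215L, 260L, 295L),
             stringsAsFactors = FALSE)
}

#' Worked-example gene tree (observed-topology transcription)
#'
#' The gene tree observed for the family: paralogs cluster by gene lineage
#' within the hominine, orangutan and gibbon clades (three independent
#' duplications plus a nested one in Hoolock), non-ape primates carry single
#' copies. Branch lengths are nominal.
#'
#' @return an `ape::phylo` with leaves `gene|species`.
#' @export
hcar_fixture_gene_tree <- function() {
  read_gene_tree(text = hcar_gene_tree_newick())
}

hcar_gene_tree_newick <- function() {
  apes <- paste0(
    "((((human_HCAR2|Homo_sapiens:1,(chimp_HCAR2|Pan_troglodytes:1,",
    "bonobo_HCAR2|Pan_paniscus:1):1):1,gorilla_HCAR2|Gorilla_gorilla:1):1,",
    "((human_HCAR3|Homo_sapiens:1,(chimp_HCAR3|Pan_troglodytes:1,",
    "bonobo_HCAR3|Pan_paniscus:1):1):1,gorilla_HCAR3|Gorilla_gorilla:1):1):1,",
    "((pongo_abelii_HCAR2like|Pongo_abelii:1,",
    "pongo_pygmaeus_HCAR2like|Pongo_pygmaeus:1):1,",
    "(pongo_abelii_HCAR3like|Pongo_abelii:1,",
    "pongo_pygmaeus_HCAR3like|Pongo_pygmaeus:1):1):1):1,",
    "((siamang_HCAR2like|Symphalangus_syndactylus:1,",
    "(hylobates_single|Hylobates_agilis:1,",
    "nomascus_single|Nomascus_leucogenys:1):1):1,",
    "(siamang_HCAR3like|Symphalangus_syndactylus:1,",
    "(hoolock_copy1|Hoolock_leuconedys:1,",
    "hoolock_copy2|Hoolock_leuconedys:1):1):1):1")
  paste0("(sifaka_HCAR23|Propithecus_coquereli:1,",
         "(tarsier_HCAR23|Carlito_syrichta:1,",
         "(marmoset_HCAR23|Callithrix_jacchus:1,",
         "((macaque_HCAR23|Macaca_fascicularis:1,",
         "snubnosed_HCAR23|Rhinopithecus_roxellana:1):1,",
         "(", apes, "):1):1):1):1):1;")
}

hcar_single_duplication_newick <- function() {
  # alternative hypothesis: one ancestral duplication, with the non-ape single
  # copies as orthologs of the HCAR2 clade — the interpretation this package's
  # scenario comparison is designed to cost out
  hcar2 <- paste0(
    "(sifaka_HCAR23|Propithecus_coquereli:1,",
    "(tarsier_HCAR23|Carlito_syrichta:1,",
    "(marmoset_HCAR23|Callithrix_jacchus:1,",
    "((macaque_HCAR23|Macaca_fascicularis:1,",
    "snubnosed_HCAR23|Rhinopithecus_roxellana:1):1,",
    "((((human_HCAR2|Homo_sapiens:1,(chimp_HCAR2|Pan_troglodytes:1,",
    "bonobo_HCAR2|Pan_paniscus:1):1):1,gorilla_HCAR2|Gorilla_gorilla:1):1,",
    "(pongo_abelii_HCAR2like|Pongo_abelii:1,",
    "pongo_pygmaeus_HCAR2like|Pongo_pygmaeus:1):1):1,",
    "((hylobates_single|Hylobates_agilis:1,",
    "nomascus_single|Nomascus_leucogenys:1):1,",
    "(hoolock_copy2|Hoolock_leuconedys:1,",
    "siamang_HCAR2like|Symphalangus_syndactylus:1):1):1):1):1):1):1):1")
  hcar3 <- paste0(
    "((((human_HCAR3|Homo_sapiens:1,(chimp_HCAR3|Pan_troglodytes:1,",
    "bonobo_HCAR3|Pan_paniscus:1):1):1,gorilla_HCAR3|Gorilla_gorilla:1):1,",
    "(pongo_abelii_HCAR3like|Pongo_abelii:1,",
    "pongo_pygmaeus_HCAR3like|Pongo_pygmaeus:1):1):1,",
    "(hoolock_copy1|Hoolock_leuconedys:1,",
    "siamang_HCAR3like|Symphalangus_syndactylus:1):1):1")
  paste0("(", hcar2, ",", hcar3, ");")
}

#' Competing duplication scenarios for the worked example
#'
#' Two hypotheses over the identical gene set: `observed` (the
#' multiple-independent-duplications topology of [hcar_fixture_gene_tree()])
#' and `single_duplication` (one ancestral duplication, non-ape single copies
#' orthologous to the HCAR2 clade).
#'
#' @return named list of two `ape::phylo` gene trees.
#' @export
hcar_fixture_scenarios <- function() {
  list(observed = hcar_fixture_gene_tree(),
       single_duplication = read_gene_tree(
         text = hcar_single_duplication_newick()))
}

#' Species tree for the worked example
#' @return an `ape::phylo` over the 15 primate species of the fixture.
#' @export
hcar_fixture_species_tree <- function() {
  read_species_tree(text = primate_species_tree())
}
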