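# Regenerates the plain-text fixtures under inst/extdata from the in-code
# builders. Run from the package root: Rscript tools/make_fixtures.R
devtools::load_all(".", quiet = TRUE)

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
aln <- hcar_fixture_alignment()
write_alignment(aln, "inst/extdata/hcar_synthetic_alignment.fasta")
write_labels(aln, "inst/extdata/hcar_synthetic_labels.tsv")
writeLines(paralogdx:::hcar_gene_tree_newick(),
           "inst/extdata/hcar_synthetic_gene_tree.nwk")
writeLines(paralogdx:::hcar_single_duplication_newick(),
           "inst/extdata/hcar_synthetic_single_duplication.nwk")
writeLines(primate_species_tree(), "inst/extdata/primate_species_tree.nwk")
write.table(hcar_fixture_regions(), "inst/extdata/hcar_synthetic_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixtures written\n")
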